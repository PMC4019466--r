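#' Kabsch least-squares superposition
#'
#' Finds the proper rotation and translation minimising the RMSD between
#' paired coordinate sets. Reflections are excluded by correcting the sign
#' of the smallest singular vector, so `det(rotation) = +1` always.
#'
#' @param mobile N x 3 matrix of coordinates to transform
#' @param reference N x 3 matrix of paired target coordinates
#' @return list of class `superposition`: `rotation` (3 x 3), `translation`
#'   (length 3), `rmsd` (Angstrom, after transformation), `n_atoms`.
#'   Transformed mobile coordinates are `mobile %*% t(R) + t`, see
#'   [apply_superposition()].
#' @export
kabsch_superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (ncol(mobile) != 3 || ncol(reference) != 3)
    stop("coordinate sets must be N x 3")
  n <- nrow(mobile)
  if (n != nrow(reference)) stop("coordinate sets must be paired (equal N)")
  if (n < 3) stop("need at least 3 paired atoms")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  A <- sweep(mobile, 2, cm); B <- sweep(reference, 2, cr)
  H <- crossprod(A, B)                      # 3x3 covariance
  s <- svd(H)
  if (s$d[2] < 1e-8 * max(s$d[1], 1))
    stop("degenerate (rank-deficient) coordinate sets")
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  t_vec <- cr - as.vector(R %*% cm)
  moved <- A %*% t(R)
  rmsd <- sqrt(mean(rowSums((moved - B)^2)))
  structure(list(rotation = R, translation = t_vec, rmsd = rmsd,
                 n_atoms = n), class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition: %d atoms, rmsd %.4f A>\n", x$n_atoms, x$rmsd))
  invisible(x)
}

#' Apply a superposition to coordinates
#' @param sp a `superposition` from [kabsch_superpose()]
#' @param xyz N x 3 coordinate matrix
#' @return transformed N x 3 matrix
#' @export
apply_superposition <- function(sp, xyz) {
  sweep(as.matrix(xyz) %*% t(sp$rotation), 2, sp$translation, `+`)
}

#' Cross-set neighbour pairs within a distance cutoff
#'
#' Returns exactly the pairs (i in `a`, j in `b`) with Euclidean distance
#' `<= cutoff`, identical to brute-force all-pairs enumeration but computed
#' with a uniform spatial grid (cell width = cutoff, 27-cell stencil) for
#' sub-quadratic behaviour on typical protein sizes.
#'
#' @param a,b `structure_model`s or N x 3 coordinate matrices
#' @param cutoff distance cutoff, Angstrom (> 0)
#' @return data.frame with columns `i`, `j` (row indices into `a` and `b`)
#'   and `distance`
#' @export
neighbor_pairs <- function(a, b, cutoff) {
  if (cutoff <= 0) stop("cutoff must be positive")
  xa <- if (inherits(a, "structure_model")) coords(a) else as.matrix(a)
  xb <- if (inherits(b, "structure_model")) coords(b) else as.matrix(b)
  empty <- data.frame(i = integer(0), j = integer(0), distance = numeric(0))
  if (!nrow(xa) || !nrow(xb)) return(empty)

  org <- pmin(apply(xa, 2, min), apply(xb, 2, min))
  ixb <- floor(sweep(xb, 2, org) / cutoff)
  keyb <- paste(ixb[, 1], ixb[, 2], ixb[, 3])
  bmap <- split(seq_len(nrow(xb)), keyb)
  ixa <- floor(sweep(xa, 2, org) / cutoff)
  out_i <- vector("list", nrow(xa)); out_j <- out_i; out_d <- out_i
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  for (i in seq_len(nrow(xa))) {
    keys <- paste(ixa[i, 1] + offs[, 1], ixa[i, 2] + offs[, 2],
                  ixa[i, 3] + offs[, 3])
    cand <- unlist(bmap[keys], use.names = FALSE)
    if (!length(cand)) next
    d2 <- (xb[cand, 1] - xa[i, 1])^2 + (xb[cand, 2] - xa[i, 2])^2 +
      (xb[cand, 3] - xa[i, 3])^2
    hit <- d2 <= cutoff^2
    if (any(hit)) {
      out_i[[i]] <- rep.int(i, sum(hit))
      out_j[[i]] <- cand[hit]
      out_d[[i]] <- sqrt(d2[hit])
    }
  }
  data.frame(i = unlist(out_i) %||% integer(0),
             j = unlist(out_j) %||% integer(0),
             distance = unlist(out_d) %||% numeric(0))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' C-alpha distance matrix between two protein chains
#'
#' All pairwise CA-CA distances between two chains, as used for residue
#' contact maps. Residues lacking a CA atom are dropped with a warning;
#' row/column names carry author residue numbering (`resid resno`).
#'
#' @param model a [structure_model()] containing both chains
#' @param chain_a,chain_b chain identifiers
#' @param bin_edges optional distance-class edges for rendering; the default
#'   classes are 0-5, 5-8, 8-12 and >12 Angstrom
#' @return a `distance_matrix`: list with `values` (labelled matrix, A),
#'   `bins` (integer class matrix) and `bin_edges`
#' @export
ca_distance_matrix <- function(model, chain_a, chain_b,
                               bin_edges = c(5, 8, 12)) {
  get_ca <- function(ch) {
    sel <- model$atoms[model$atoms$chain == ch &
                         model$atoms$kind == "protein", , drop = FALSE]
    if (!nrow(sel)) stop("no protein atoms in chain ", ch)
    key <- paste(sel$resno, sel$insert)
    all_res <- unique(key)
    ca <- sel[sel$elety == "CA", , drop = FALSE]
    missing <- setdiff(all_res, paste(ca$resno, ca$insert))
    if (length(missing))
      warning(sprintf("chain %s: %d residue(s) lack CA and are excluded",
                      ch, length(missing)))
    ca <- ca[!duplicated(paste(ca$resno, ca$insert)), , drop = FALSE]
    list(xyz = as.matrix(ca[, c("x", "y", "z")]),
         labels = paste0(ca$resid, ca$resno,
                         ifelse(ca$insert == "", "", ca$insert)))
  }
  A <- get_ca(chain_a); B <- get_ca(chain_b)
  d <- sqrt(outer(rowSums(A$xyz^2), rowSums(B$xyz^2), `+`) -
              2 * tcrossprod(A$xyz, B$xyz))
  d[d < 0 | is.nan(d)] <- 0
  dimnames(d) <- list(A$labels, B$labels)
  bins <- matrix(findInterval(d, bin_edges) + 1L, nrow = nrow(d),
                 dimnames = dimnames(d))
  structure(list(values = d, bins = bins, bin_edges = bin_edges),
            class = "distance_matrix")
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat(sprintf("<distance_matrix %d x %d, min %.2f A>\n",
              nrow(x$values), ncol(x$values), min(x$values)))
  invisible(x)
}

#' Write a labelled distance matrix as TSV
#' @param dm a `distance_matrix`
#' @param path output file
#' @export
write_distance_matrix <- function(dm, path) {
  utils::write.table(format(dm$values, digits = 6), path, sep = "\t",
                     quote = FALSE, col.names = NA)
  invisible(path)
}
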