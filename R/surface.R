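#' Deterministic golden-spiral points on the unit sphere
#'
#' Fibonacci lattice: near-uniform, reproducible without a random number
#' generator, so SASA values are bit-stable across runs.
#'
#' @param n number of points (>= 32)
#' @return n x 3 matrix of unit vectors
#' @export
sphere_points <- function(n) {
  if (n < 32) stop("need at least 32 sphere points")
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Each atom's van der Waals sphere is expanded by the probe radius and
#' sampled with a deterministic golden-spiral point set; a point is
#' accessible when it lies outside every other expanded sphere. The area
#' per atom is `4 pi (r + probe)^2 * accessible/total` points.
#'
#' @param model a [structure_model()]
#' @param probe probe radius, Angstrom (water = 1.4)
#' @param n_points sample points per atom (>= 32); 960 gives ~1% accuracy
#' @return `sasa_result`: list with `per_atom` (A^2, one per atom row),
#'   `per_residue` (data.frame chain/resno/insert/resid/area), `total`,
#'   `probe_radius`, `n_points`
#' @export
sasa <- function(model, probe = 1.4, n_points = 960) {
  a <- model$atoms
  if (!nrow(a)) stop("empty model")
  if (probe < 0) stop("probe radius must be >= 0")
  if (any(is.na(a$vdw) | a$vdw <= 0))
    stop("atom without a positive vdW radius: ",
         a$elety[which(is.na(a$vdw) | a$vdw <= 0)[1]])
  xyz <- as.matrix(a[, c("x", "y", "z")])
  r_exp <- a$vdw + probe
  pts <- sphere_points(n_points)
  n <- nrow(a)
  max_cut <- 2 * max(r_exp)
  nb <- neighbor_pairs(xyz, xyz, cutoff = max_cut)
  nb <- nb[nb$i != nb$j & nb$distance < r_exp[nb$i] + r_exp[nb$j], ,
           drop = FALSE]
  nb_list <- split(nb$j, factor(nb$i, levels = seq_len(n)))
  acc <- numeric(n)
  for (i in seq_len(n)) {
    p <- sweep(pts * r_exp[i], 2, xyz[i, ], `+`)
    ok <- rep(TRUE, n_points)
    for (j in nb_list[[i]]) {
      if (!any(ok)) break
      dx <- p[ok, 1] - xyz[j, 1]; dy <- p[ok, 2] - xyz[j, 2]
      dz <- p[ok, 3] - xyz[j, 3]
      ok[ok] <- dx * dx + dy * dy + dz * dz > r_exp[j]^2
    }
    acc[i] <- sum(ok)
  }
  per_atom <- 4 * pi * r_exp^2 * acc / n_points
  key <- paste(a$chain, a$resno, a$insert, sep = "|")
  first <- !duplicated(key)
  per_res <- data.frame(a[first, c("chain", "resno", "insert", "resid")],
                        area = as.vector(tapply(per_atom, factor(key, levels = key[first]), sum)),
                        row.names = NULL)
  structure(list(per_atom = per_atom, per_residue = per_res,
                 total = sum(per_atom), probe_radius = probe,
                 n_points = n_points), class = "sasa_result")
}

#' @export
print.sasa_result <- function(x, ...) {
  cat(sprintf("<sasa: %.1f A^2 over %d atoms (probe %.2f, %d points)>\n",
              x$total, length(x$per_atom), x$probe_radius, x$n_points))
  invisible(x)
}

# shared core: SASA of each partner free and in complex
.bsa_core <- function(complex, part_a, part_b, probe, n_points) {
  if (!inherits(part_a, "structure_model") ||
      !inherits(part_b, "structure_model"))
    stop("part_a/part_b must be structure_model selections of `complex`")
  key_a <- with(part_a$atoms, paste(chain, resno, insert, elety))
  key_b <- with(part_b$atoms, paste(chain, resno, insert, elety))
  if (length(intersect(key_a, key_b)))
    stop("partner selections overlap")
  key_c <- with(complex$atoms, paste(chain, resno, insert, elety))
  ia <- match(key_a, key_c); ib <- match(key_b, key_c)
  if (anyNA(ia) || anyNA(ib))
    stop("partner selections contain atoms absent from the complex")
  both <- structure_model(complex$atoms[c(ia, ib), , drop = FALSE],
                          complex$entry_id)
  s_ab <- sasa(both, probe, n_points)
  s_a <- sasa(part_a, probe, n_points)
  s_b <- sasa(part_b, probe, n_points)
  na <- nrow(part_a$atoms)
  list(s_a = s_a, s_b = s_b,
       in_complex_a = s_ab$per_atom[seq_len(na)],
       in_complex_b = s_ab$per_atom[na + seq_len(nrow(part_b$atoms))])
}

.residue_delta <- function(part, free_sasa, complexed_atom_area) {
  a <- part$atoms
  key <- paste(a$chain, a$resno, a$insert, sep = "|")
  first <- !duplicated(key)
  delta <- free_sasa$per_atom - complexed_atom_area
  data.frame(a[first, c("chain", "resno", "insert", "resid")],
             dsasa = as.vector(tapply(delta, factor(key, levels = key[first]), sum)),
             row.names = NULL)
}

#' Buried surface area and interface report for a binary complex
#'
#' BSA of partner X is `SASA(X alone) - SASA(X in complex)`; the interface
#' area is the mean of the two partner BSAs (the PISA convention), and
#' `fraction_of_surface_a` relates partner A's buried area to its free
#' surface.
#'
#' @param complex a [structure_model()] holding both partners
#' @param part_a,part_b disjoint [select_atoms()] selections of `complex`
#' @param probe,n_points passed to [sasa()]
#' @param delta_threshold minimum per-residue delta-SASA (A^2) for a residue
#'   to be listed as interfacial (0 = any positive burial)
#' @return `interface_report`: `bsa_a`, `bsa_b`, `interface_area`,
#'   `fraction_of_surface_a`, `fraction_of_surface_b`,
#'   `interface_residues_a`, `interface_residues_b` (data.frames with
#'   per-residue `dsasa`), plus the free-surface totals
#' @export
buried_surface <- function(complex, part_a, part_b, probe = 1.4,
                           n_points = 960, delta_threshold = 0) {
  core <- .bsa_core(complex, part_a, part_b, probe, n_points)
  bsa_a <- core$s_a$total - sum(core$in_complex_a)
  bsa_b <- core$s_b$total - sum(core$in_complex_b)
  res_a <- .residue_delta(part_a, core$s_a, core$in_complex_a)
  res_b <- .residue_delta(part_b, core$s_b, core$in_complex_b)
  tol <- 1e-9
  structure(list(
    bsa_a = bsa_a, bsa_b = bsa_b,
    interface_area = (bsa_a + bsa_b) / 2,
    surface_a = core$s_a$total, surface_b = core$s_b$total,
    fraction_of_surface_a = bsa_a / core$s_a$total,
    fraction_of_surface_b = bsa_b / core$s_b$total,
    interface_residues_a = res_a[res_a$dsasa > delta_threshold + tol, ,
                                 drop = FALSE],
    interface_residues_b = res_b[res_b$dsasa > delta_threshold + tol, ,
                                 drop = FALSE],
    per_residue_a = res_a, per_residue_b = res_b,
    probe_radius = probe, n_points = n_points,
    delta_threshold = delta_threshold), class = "interface_report")
}

#' @export
print.interface_report <- function(x, ...) {
  cat(sprintf(paste0(
    "<interface_report>\n  BSA partner A: %.0f A^2 (%.1f%% of free surface)\n",
    "  BSA partner B: %.0f A^2\n  interface area: %.0f A^2\n",
    "  interface residues: %d (A) / %d (B)\n"),
    x$bsa_a, 100 * x$fraction_of_surface_a, x$bsa_b, x$interface_area,
    nrow(x$interface_residues_a), nrow(x$interface_residues_b)))
  invisible(x)
}

#' Interface residue sets by delta-SASA
#'
#' Convenience wrapper around [buried_surface()] returning only the
#' per-partner residue sets whose burial on complexation exceeds
#' `delta_threshold`.
#'
#' @inheritParams buried_surface
#' @return list with data.frames `residues_a` and `residues_b`
#' @export
interface_residues <- function(complex, part_a, part_b, probe = 1.4,
                               n_points = 960, delta_threshold = 0) {
  rep <- buried_surface(complex, part_a, part_b, probe, n_points,
                        delta_threshold)
  list(residues_a = rep$interface_residues_a,
       residues_b = rep$interface_residues_b)
}
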