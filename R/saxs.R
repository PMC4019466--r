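#' Scattering profile container
#'
#' @param q momentum transfer, 1/Angstrom; strictly increasing, `>= 0`
#' @param intensity intensity, arbitrary units
#' @param sigma optional per-point experimental error (> 0)
#' @return a `scattering_profile`
#' @export
scattering_profile <- function(q, intensity, sigma = NULL) {
  if (length(q) != length(intensity)) stop("q and intensity lengths differ")
  if (any(q < 0) || any(diff(q) <= 0)) stop("q must be strictly increasing and >= 0")
  if (!is.null(sigma)) {
    if (length(sigma) != length(q)) stop("sigma length differs from q")
    if (any(sigma <= 0)) stop("sigma must be positive")
  }
  structure(list(q = as.numeric(q), intensity = as.numeric(intensity),
                 sigma = if (is.null(sigma)) NULL else as.numeric(sigma)),
            class = "scattering_profile")
}

#' @export
print.scattering_profile <- function(x, ...) {
  cat(sprintf("<scattering_profile: %d points, q %.4f-%.4f%s>\n",
              length(x$q), min(x$q), max(x$q),
              if (is.null(x$sigma)) "" else ", with sigma"))
  invisible(x)
}

#' Read a (q, I[, sigma]) profile from text
#'
#' Whitespace- or comma-separated columns, `#` comments (ATSAS-style .dat
#' dialect). Two columns are read as (q, I), three as (q, I, sigma).
#'
#' @param path input file
#' @return a [scattering_profile()]
#' @export
read_saxs_profile <- function(path) {
  raw <- readLines(path, warn = FALSE)
  raw <- raw[!grepl("^\\s*(#|$)", raw)]
  d <- utils::read.table(text = gsub(",", " ", raw))
  if (ncol(d) < 2) stop("profile needs at least (q, I) columns")
  scattering_profile(d[[1]], d[[2]], if (ncol(d) >= 3) d[[3]] else NULL)
}

#' Write a profile as whitespace-delimited text
#' @param profile a [scattering_profile()]
#' @param path output file
#' @export
write_saxs_profile <- function(profile, path) {
  d <- data.frame(q = profile$q, I = profile$intensity)
  if (!is.null(profile$sigma)) d$sigma <- profile$sigma
  writeLines(c("# q I [sigma]",
               apply(format(d, digits = 8), 1, paste, collapse = " ")), path)
  invisible(path)
}

#' Guinier analysis
#'
#' Linear fit of `ln I` against `q^2` over a low-angle window that is
#' shrunk from high q until `qmax * Rg < qmax_rg` self-consistently
#' (default rule constant 1.3). `Rg = sqrt(-3 slope)`,
#' `I(0) = exp(intercept)`.
#'
#' @param profile a [scattering_profile()]
#' @param qmax_rg the Guinier validity rule constant
#' @param min_points smallest admissible window
#' @return `guinier_result`: `Rg` (A), `I0`, `q_window` (c(qmin, qmax)),
#'   `qmax_rg` (achieved `qmax * Rg`), `n_points`
#' @export
guinier_fit <- function(profile, qmax_rg = 1.3, min_points = 5) {
  q <- profile$q; I <- profile$intensity
  pos <- I > 0
  if (!all(pos)) {
    warning("dropping ", sum(!pos), " non-positive intensity point(s)")
    q <- q[pos]; I <- I[pos]
  }
  if (length(q) < min_points) stop("fewer than ", min_points, " usable points")
  m <- length(q)
  for (iter in 1:100) {
    fit <- stats::lm.fit(cbind(1, q[1:m]^2), log(I[1:m]))
    slope <- fit$coefficients[2]
    if (slope > 1e-12)
      stop("no Guinier region: intensity does not decay at low q")
    rg <- sqrt(-3 * min(slope, 0))
    if (q[m] * rg < qmax_rg) break
    m_new <- max(sum(q <= qmax_rg / rg), min_points)
    if (m_new >= m) m_new <- m - 1
    m <- m_new
    if (m < min_points)
      stop("no Guinier window of >= ", min_points,
           " points satisfies qmax*Rg < ", qmax_rg)
  }
  structure(list(Rg = unname(rg), I0 = unname(exp(fit$coefficients[1])),
                 q_window = c(q[1], q[m]), qmax_rg = unname(q[m] * rg),
                 n_points = m), class = "guinier_result")
}

#' @export
print.guinier_result <- function(x, ...) {
  cat(sprintf("<guinier: Rg %.2f A, I0 %.4g, %d pts, qmax*Rg %.2f>\n",
              x$Rg, x$I0, x$n_points, x$qmax_rg))
  invisible(x)
}

# weighted pair-distance histogram, computed in row chunks so large clouds
# never materialise a full distance matrix
.pair_histogram <- function(xyz, weights, bin_width) {
  n <- nrow(xyz)
  if (n < 2) stop("need at least 2 scatterers")
  if (length(weights) == 1) weights <- rep(weights, n)
  dmax_bound <- 2 * max(sqrt(rowSums(sweep(xyz, 2, colMeans(xyz))^2))) + bin_width
  nb <- ceiling(dmax_bound / bin_width) + 1L
  counts <- numeric(nb)
  dmax <- 0
  chunk <- max(1L, floor(2e6 / n))
  for (s in seq(1, n - 1, by = chunk)) {
    rows <- s:min(s + chunk - 1L, n - 1L)
    d2 <- outer(rowSums(xyz[rows, , drop = FALSE]^2), rowSums(xyz^2), `+`) -
      2 * tcrossprod(xyz[rows, , drop = FALSE], xyz)
    for (k in seq_along(rows)) {
      i <- rows[k]
      dd <- sqrt(pmax(d2[k, (i + 1):n], 0))
      if (length(dd)) {
        dmax <- max(dmax, max(dd))
        idx <- pmin(floor(dd / bin_width) + 1L, nb)
        w <- weights[i] * weights[(i + 1):n]
        agg <- tapply(w, idx, sum)
        bins <- as.integer(names(agg))
        counts[bins] <- counts[bins] + as.numeric(agg)
      }
    }
  }
  list(counts = counts, centers = (seq_len(nb) - 0.5) * bin_width,
       dmax = dmax, sum_f = sum(weights), sum_f2 = sum(weights^2))
}

#' Debye model scattering profile from coordinates
#'
#' In-vacuo point-scatterer Debye sum
#' `I(q) = sum_ij f_i f_j sin(q r_ij)/(q r_ij)`, evaluated through a fine
#' pair-distance histogram (bin width `bin_width`); the `q -> 0` limit is
#' handled analytically. No hydration layer or excluded-volume term is
#' applied.
#'
#' @param model a [structure_model()] or an N x 3 coordinate matrix
#' @param q momentum-transfer grid, 1/Angstrom (may include 0)
#' @param weights per-atom scattering weights (default 1 per atom)
#' @param bin_width histogram resolution, Angstrom
#' @return a [scattering_profile()]
#' @export
debye_profile <- function(model, q, weights = 1, bin_width = 0.02) {
  xyz <- if (inherits(model, "structure_model")) coords(model) else as.matrix(model)
  n <- nrow(xyz)
  if (n < 1) stop("need at least one scatterer")
  if (length(weights) == 1) weights <- rep(weights, n)
  if (n == 1)
    return(scattering_profile(q, rep(weights[1]^2, length(q))))
  h <- .pair_histogram(xyz, weights, bin_width)
  keep <- h$counts > 0
  r <- h$centers[keep]; w <- h$counts[keep]
  I <- vapply(q, function(qk) {
    if (qk == 0) return(h$sum_f^2)
    x <- qk * r
    h$sum_f2 + 2 * sum(w * sin(x) / x)
  }, numeric(1))
  scattering_profile(q, I)
}

#' Pair-distance distribution function from coordinates
#'
#' Weighted histogram of all pairwise distances. `Dmax` is the maximum
#' pair distance and `Rg_pr` the second-moment radius of gyration
#' `Rg^2 = integral(r^2 P) / (2 integral(P))`.
#'
#' @param model a [structure_model()] or N x 3 coordinate matrix (N >= 2)
#' @param r_bin histogram bin width, Angstrom
#' @param weights per-atom scattering weights
#' @return `pr_result`: `r` (grid, A), `pr` (with `P(0) = P(rmax) = 0`),
#'   `Dmax`, `Rg_pr`, `I0_pr` (= (sum f)^2, the q=0 Debye intensity)
#' @export
pr_from_structure <- function(model, r_bin = 1, weights = 1) {
  xyz <- if (inherits(model, "structure_model")) coords(model) else as.matrix(model)
  if (nrow(xyz) < 2) stop("degenerate: P(r) needs at least 2 scatterers")
  h <- .pair_histogram(xyz, weights, r_bin)
  nb <- max(which(h$counts > 0))
  pr <- h$counts[1:nb] / (sum(h$counts) * r_bin)   # normalised density
  r <- h$centers[1:nb]
  rg <- sqrt(sum(r^2 * pr) / (2 * sum(pr)))
  structure(list(r = c(0, r, r[nb] + r_bin / 2),
                 pr = c(0, pr, 0),
                 Dmax = h$dmax, Rg_pr = rg, I0_pr = h$sum_f^2),
            class = "pr_result")
}

#' @export
print.pr_result <- function(x, ...) {
  cat(sprintf("<pr_result: Dmax %.2f A, Rg %.2f A>\n", x$Dmax, x$Rg_pr))
  invisible(x)
}

#' Porod volume estimate
#'
#' `V = 2 pi^2 I(0) / Q`, with the Porod invariant
#' `Q = integral q^2 I(q) dq`. A constant background (the flat
#' self-scattering term of point models, or detector background) is first
#' estimated by fitting `I = B + K q^-4` over the high-q tail; the
#' invariant integral uses the Guinier-extrapolated `I(0)` at `q = 0` and
#' an analytic `K/qmax` tail beyond the data.
#'
#' @param profile a [scattering_profile()]
#' @param tail_fraction fraction of the q range (from the top) used for the
#'   background/Porod-constant fit
#' @return `porod_result`: `volume` (A^3), `I0`, `invariant`, `background`,
#'   `porod_constant`, `reliable` (FALSE, with a warning, when the profile
#'   does not extend to `qmax * Rg >= 2` or no q^-4 plateau is found)
#' @export
porod_volume <- function(profile, tail_fraction = 0.5) {
  q <- profile$q; I <- profile$intensity
  if (length(q) < 10) stop("profile too short for a Porod estimate")
  g <- guinier_fit(profile)
  tail <- q >= (1 - tail_fraction) * max(q)
  X <- cbind(1, 1 / q[tail]^4)
  cf <- stats::lm.fit(X, I[tail])$coefficients
  B <- unname(cf[1]); K <- unname(cf[2])
  reliable <- TRUE
  if (max(q) * g$Rg < 2) {
    warning("profile truncated (qmax*Rg < 2): Porod estimate unreliable")
    reliable <- FALSE
  }
  if (K <= 0) {
    warning("no q^-4 plateau detected: Porod estimate unreliable")
    reliable <- FALSE
    K <- 0
  }
  Ic <- pmax(I - B, 0)
  qq <- c(0, q); II <- c(g$I0, Ic)
  Q <- sum(diff(qq) * (qq[-1]^2 * II[-1] + qq[-length(qq)]^2 * II[-length(II)]) / 2) +
    if (K > 0) K / max(q) else 0
  structure(list(volume = 2 * pi^2 * g$I0 / Q, I0 = g$I0, invariant = Q,
                 background = unname(B), porod_constant = unname(K),
                 reliable = reliable), class = "porod_result")
}

#' @export
print.porod_result <- function(x, ...) {
  cat(sprintf("<porod: V %.0f A^3%s>\n", x$volume,
              if (x$reliable) "" else " (unreliable)"))
  invisible(x)
}

#' Chi-square agreement between a model and an experimental profile
#'
#' The model curve is linearly interpolated onto the experimental q grid,
#' the scale `c` minimising chi^2 is obtained in closed form
#' (`c = sum(I_exp I_m / sigma^2) / sum(I_m^2 / sigma^2)`), and
#' `chi^2 = (1/N) sum((I_exp - c I_m)^2 / sigma^2)`.
#'
#' @param model_profile a [scattering_profile()] for the model (sigma
#'   ignored)
#' @param experimental_profile a [scattering_profile()] with `sigma`
#' @return list: `chi2`, `chi` (= sqrt(chi2)), `c` (scale), `residuals`
#'   (per-point `(I_exp - c I_m)/sigma`), `q` (grid used)
#' @export
chi2_fit <- function(model_profile, experimental_profile) {
  ep <- experimental_profile
  if (is.null(ep$sigma)) stop("experimental profile lacks sigma")
  qs <- ep$q
  inside <- qs >= min(model_profile$q) & qs <= max(model_profile$q)
  if (sum(inside) < 2)
    stop("model and experimental q grids do not overlap")
  if (!all(inside))
    warning("dropping ", sum(!inside),
            " experimental point(s) outside the model q range")
  qs <- qs[inside]
  Ie <- ep$intensity[inside]; s <- ep$sigma[inside]
  Im <- stats::approx(model_profile$q, model_profile$intensity, xout = qs)$y
  cc <- sum(Ie * Im / s^2) / sum(Im^2 / s^2)
  res <- (Ie - cc * Im) / s
  chi2 <- mean(res^2)
  list(chi2 = chi2, chi = sqrt(chi2), c = cc, residuals = res, q = qs)
}

#' Radius of gyration directly from coordinates
#'
#' Weight-averaged second moment about the weighted centroid; the
#' coordinate-space counterpart of the Guinier Rg.
#'
#' @param model a [structure_model()] or N x 3 matrix
#' @param weights per-atom weights
#' @return Rg in Angstrom
#' @export
rg_from_coords <- function(model, weights = 1) {
  xyz <- if (inherits(model, "structure_model")) coords(model) else as.matrix(model)
  if (length(weights) == 1) weights <- rep(weights, nrow(xyz))
  ctr <- colSums(xyz * weights) / sum(weights)
  sqrt(sum(weights * rowSums(sweep(xyz, 2, ctr)^2)) / sum(weights))
}
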