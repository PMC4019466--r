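# Independent brute-force / closed-form oracles used across the suite.
# These deliberately avoid the package's own algorithms.

# all-pairs cross-distance enumeration
brute_pairs <- function(xa, xb, cutoff) {
  out <- list()
  for (i in seq_len(nrow(xa))) {
    d <- sqrt(colSums((t(xb) - xa[i, ])^2))
    hit <- which(d <= cutoff)
    if (length(hit))
      out[[length(out) + 1]] <- data.frame(i = i, j = hit, distance = d[hit])
  }
  if (!length(out))
    return(data.frame(i = integer(0), j = integer(0), distance = numeric(0)))
  do.call(rbind, out)
}

pair_key <- function(df) sort(paste(df$i, df$j))

# accessible area of each of two equal spheres (radius rho, centre distance
# d): full sphere minus the spherical cap hidden inside the partner
two_sphere_area <- function(rho, d) {
  h <- rho - d / 2
  4 * pi * rho^2 - 2 * pi * rho * h
}

# analytic sphere form factor (normalised intensity)
sphere_form_factor <- function(qR) {
  ifelse(qR == 0, 1, (3 * (sin(qR) - qR * cos(qR)) / qR^3)^2)
}

# grid search of the chi2 scale factor
chi2_grid_c <- function(Ie, Im, s, c_grid) {
  sse <- vapply(c_grid, function(cc) mean(((Ie - cc * Im) / s)^2), 0)
  list(c = c_grid[which.min(sse)], chi2 = min(sse))
}

# coarse-to-fine grid search of Michaelis-Menten SSE
mm_grid_sse <- function(S, v, km_range, vmax_range, n = 60) {
  best <- c(Inf, NA, NA)
  for (pass in 1:2) {
    kms <- seq(km_range[1], km_range[2], length.out = n)
    vms <- seq(vmax_range[1], vmax_range[2], length.out = n)
    for (km in kms) for (vm in vms) {
      sse <- sum((v - vm * S / (km + S))^2)
      if (sse < best[1]) best <- c(sse, km, vm)
    }
    dk <- diff(km_range) / n; dv <- diff(vmax_range) / n
    km_range <- c(best[2] - 2 * dk, best[2] + 2 * dk)
    vmax_range <- c(best[3] - 2 * dv, best[3] + 2 * dv)
  }
  list(sse = best[1], Km = best[2], Vmax = best[3])
}

# RNA helix-23 style chain fixture: C1' pseudo-atoms with author numbering
make_rna_chain <- function(resno, letters_seq, chain = "R") {
  n <- length(resno)
  atoms <- data.frame(
    eleno = seq_len(n), elety = "C1'", altloc = "", resid = letters_seq,
    chain = chain, resno = resno, insert = "",
    x = 6 * seq_len(n), y = 0, z = 0, o = 1, b = 0, elem = "C",
    vdw = 1.70, kind = "nucleic", stringsAsFactors = FALSE)
  structure_model(atoms, "rna_fixture")
}

# random rigid transform (proper rotation + translation)
random_rigid <- function() {
  A <- matrix(rnorm(9), 3)
  qr_ <- qr(A)
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  list(R = R, t = rnorm(3, 0, 10))
}

# directory holding full deposited coordinate files (not shipped with the
# package; the archaeal complex and ribosome analyses need them)
structure_dir <- function() {
  getOption("rnamimicry.structure_dir",
            file.path(path.expand("~"), "rnamimicry-structures"))
}
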