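## Synthetic fixtures with known ground truth.  Every generator is
## deterministic for a fixed seed and returns the truth it was built from in
## a `manifest`, so each analysis stage can be tested without any downloaded
## data.

.atom_df <- function(elety, resid, chain, resno, x, y, z, kind = NULL,
                     elem = NULL) {
  if (is.null(elem)) elem <- .element_from_name(elety, resid)
  if (is.null(kind)) kind <- .residue_kind(resid)
  vdw <- unname(.vdw_radii[elem]); vdw[is.na(vdw)] <- .vdw_default
  data.frame(eleno = seq_along(elety), elety = elety, altloc = "",
             resid = resid, chain = chain, resno = resno, insert = "",
             x = x, y = y, z = z, o = 1, b = 0, elem = elem, vdw = vdw,
             kind = kind, stringsAsFactors = FALSE)
}

.renumber_atoms <- function(atoms) {
  atoms$eleno <- seq_len(nrow(atoms))
  rownames(atoms) <- NULL
  atoms
}

#' Ideal CA-only alpha-helix fixture
#'
#' @param n_res residue count
#' @param chain chain id
#' @param rise rise per residue, Angstrom
#' @param radius helix radius, Angstrom
#' @param twist rotation per residue, degrees
#' @return a [structure_model()] of CA atoms (ALA)
#' @export
make_helix <- function(n_res = 20, chain = "A", rise = 1.5, radius = 2.3,
                       twist = 100) {
  i <- seq_len(n_res)
  th <- (i - 1) * twist * pi / 180
  atoms <- .atom_df("CA", "ALA", chain, i,
                    radius * cos(th), radius * sin(th), (i - 1) * rise)
  structure_model(atoms, "helix_fixture")
}

# side-chain atom chains used to engineer contacts; `arm` atoms are laid
# out along +y from the CA so the terminal atom lands at a controlled
# position between the two backbones
.engineered_residues <- list(
  salt_bridge = list(
    a = list(resid = "ASP", atoms = c("CB", "CG", "OD1"), terminal = "OD1"),
    b = list(resid = "ARG", atoms = c("CB", "CG", "CD", "NE", "NH1"),
             terminal = "NH1")),
  hbond = list(
    a = list(resid = "ASN", atoms = c("CB", "CG", "OD1"), terminal = "OD1"),
    b = list(resid = "GLN", atoms = c("CB", "CG", "CD", "NE2"),
             terminal = "NE2"))
)

.backbone <- function(n_res, chain, y0, seed_jitter = NULL) {
  i <- seq_len(n_res)
  x <- (i - 1) * 3.8
  rows <- lapply(i, function(k) {
    .atom_df(c("N", "CA", "C", "O"), "ALA", chain, k,
             x[k] + c(-0.8, 0, 0.9, 1.1),
             y0 + c(0.3, 0, 0.4, 1.5),
             c(0.5, 0, -0.5, -0.6))
  })
  at <- do.call(rbind, rows)
  if (!is.null(seed_jitter)) {
    at$x <- at$x + seed_jitter(nrow(at)); at$y <- at$y + seed_jitter(nrow(at))
    at$z <- at$z + seed_jitter(nrow(at))
  }
  at
}

#' Two-chain toy complex with engineered contacts
#'
#' Builds two extended poly-alanine backbones `gap` Angstrom apart and
#' engineers side-chain pairs bridging them: Asp-Arg salt bridges and
#' Asn-Gln hydrogen bonds whose terminal heavy atoms sit at the exact
#' requested distances. The manifest records the intended contacts and
#' interface residues, giving ground truth for the surface and contact
#' stages.
#'
#' @param n_res_a,n_res_b residues per chain (A and B)
#' @param salt_bridges numeric vector of N-O distances to engineer
#' @param hbonds numeric vector of donor-acceptor distances to engineer
#' @param gap backbone separation, Angstrom
#' @param seed RNG seed for the small backbone jitter (0.03 A sd), making
#'   repeated calls with one seed byte-identical
#' @return list: `model` (a [structure_model()]) and `manifest` (intended
#'   `salt_bridges`, `hbonds`, `interface_residues_a/_b`)
#' @export
make_toy_complex <- function(n_res_a = 12, n_res_b = 12,
                             salt_bridges = numeric(0),
                             hbonds = numeric(0), gap = 16, seed = 1) {
  n_sites <- length(salt_bridges) + length(hbonds)
  if (3 * (n_sites + 1) > min(n_res_a, n_res_b))
    stop("chains too short for ", n_sites, " engineered sites")
  set.seed(seed)
  jit <- function(n) stats::rnorm(n, 0, 0.03)
  at_a <- .backbone(n_res_a, "A", 0, jit)
  at_b <- .backbone(n_res_b, "B", gap, jit)

  specs <- c(lapply(salt_bridges, function(d) list(kind = "salt_bridge", d = d)),
             lapply(hbonds, function(d) list(kind = "hbond", d = d)))
  man_sb <- list(); man_hb <- list(); res_a <- integer(0); res_b <- integer(0)
  site_res <- 3 * seq_len(max(n_sites, 0))   # residues 3, 6, 9, ...
  for (k in seq_along(specs)) {
    sp <- specs[[k]]
    arm <- (gap - sp$d) / 2
    if (arm < 1.5 || arm > 8)
      stop(sprintf("infeasible geometry: distance %.1f with gap %.1f", sp$d, gap))
    rs <- site_res[k]
    er <- .engineered_residues[[sp$kind]]
    xs <- (rs - 1) * 3.8
    place <- function(side, y_ca, dir) {
      def <- er[[side]]
      n_at <- length(def$atoms)
      yy <- y_ca + dir * seq(arm / n_at, arm, length.out = n_at)
      .atom_df(def$atoms, def$resid, if (side == "a") "A" else "B",
               rs, rep(xs, n_at), yy, rep(0, n_at))
    }
    sc_a <- place("a", 0, +1)
    sc_b <- place("b", gap, -1)
    # retype the backbone of the engineered residues
    at_a$resid[at_a$resno == rs] <- er$a$resid
    at_b$resid[at_b$resno == rs] <- er$b$resid
    at_a <- rbind(at_a, sc_a); at_b <- rbind(at_b, sc_b)
    res_a <- c(res_a, rs); res_b <- c(res_b, rs)
    rec <- data.frame(res_a = paste0(er$a$resid, rs),
                      res_b = paste0(er$b$resid, rs), distance = sp$d)
    if (sp$kind == "salt_bridge") man_sb[[length(man_sb) + 1]] <- rec
    else man_hb[[length(man_hb) + 1]] <- rec
  }
  ord <- function(at) at[order(at$chain, at$resno,
                               match(at$elety, c("N", "CA", "C", "O",
                                                 "CB", "CG", "CD", "NE",
                                                 "NE2", "NH1", "OD1"))), ]
  atoms <- .renumber_atoms(rbind(ord(at_a), ord(at_b)))
  model <- structure_model(atoms, "toy_complex")
  manifest <- list(
    salt_bridges = if (length(man_sb)) do.call(rbind, man_sb) else NULL,
    hbonds = if (length(man_hb)) do.call(rbind, man_hb) else NULL,
    interface_residues_a = res_a, interface_residues_b = res_b,
    gap = gap, seed = seed)
  list(model = model, manifest = manifest)
}

.pseudo_model <- function(xyz, entry_id) {
  n <- nrow(xyz)
  at <- .atom_df(rep("C", n), rep("DUM", n), "A", seq_len(n),
                 xyz[, 1], xyz[, 2], xyz[, 3], kind = "other", elem = "C")
  structure_model(at, entry_id)
}

#' Pseudo-atom ball of uniform density
#'
#' `method = "random"` draws points uniformly in the ball (seeded);
#' `method = "grid"` returns the cubic-lattice points falling inside the
#' ball - a deterministic quasi-uniform cloud whose Debye profile tracks
#' the analytic sphere form factor far more tightly than a random draw of
#' the same size.
#'
#' @param R ball radius, Angstrom
#' @param n target point count (>= 100); for `"grid"` the lattice spacing
#'   is chosen to approximate `n` and the realised count may differ
#' @param seed RNG seed (random method)
#' @param method `"random"` or `"grid"`
#' @return list: `model` (pseudo-atom [structure_model()]), `manifest`
#'   (`R`, `n`, `Rg_true = sqrt(3/5) R`, `Dmax_true = 2R`)
#' @export
make_sphere_cloud <- function(R, n = 1000, seed = 1,
                              method = c("random", "grid")) {
  method <- match.arg(method)
  if (n < 100) stop("need n >= 100 points")
  if (method == "random") {
    set.seed(seed)
    u <- matrix(stats::rnorm(3 * n), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    r <- R * stats::runif(n)^(1 / 3)
    xyz <- u * r
  } else {
    a <- (4 / 3 * pi * R^3 / n)^(1 / 3)
    g <- seq(-R, R, by = a)
    xyz <- as.matrix(expand.grid(x = g, y = g, z = g))
    xyz <- xyz[rowSums(xyz^2) <= R^2, , drop = FALSE]
  }
  list(model = .pseudo_model(xyz, "sphere_cloud"),
       manifest = list(R = R, n = nrow(xyz), Rg_true = sqrt(3 / 5) * R,
                       Dmax_true = 2 * R, method = method, seed = seed))
}

#' Random-walk pseudo-atom chain
#'
#' Freely jointed chain with fixed step length: an elongated-particle
#' counterpart to [make_sphere_cloud()] for scattering tests.
#'
#' @param n number of points
#' @param step step length, Angstrom
#' @param seed RNG seed
#' @return list: `model`, `manifest` (`n`, `step`)
#' @export
make_chain_cloud <- function(n = 200, step = 3.8, seed = 1) {
  set.seed(seed)
  u <- matrix(stats::rnorm(3 * (n - 1)), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  xyz <- rbind(0, apply(u * step, 2, cumsum))
  list(model = .pseudo_model(xyz, "chain_cloud"),
       manifest = list(n = n, step = step, seed = seed))
}

#' Synthetic Michaelis-Menten rate data
#'
#' Rates from `v = Vmax [S]/(Km + [S])` with multiplicative Gaussian noise
#' of coefficient of variation `noise_cv`. Defaults reproduce the
#' free-yFap7 adenylate-kinase parameters (Km 52 uM, kcat 6.12e-3 1/s)
#' measured against ATP at fixed AMP, with 5 uM enzyme.
#'
#' @param Km uM
#' @param kcat 1/s
#' @param enzyme_conc uM
#' @param substrate substrate levels, uM (default 8 levels, 5-1000 uM)
#' @param noise_cv coefficient of variation of the multiplicative noise
#' @param seed RNG seed
#' @return list: `data` (data.frame substrate, rate), `enzyme_conc`,
#'   `manifest` (true parameters)
#' @export
make_kinetics_data <- function(Km = 52, kcat = 6.12e-3, enzyme_conc = 5,
                               substrate = c(5, 10, 25, 50, 100, 250, 500, 1000),
                               noise_cv = 0, seed = 1) {
  Vmax <- kcat * enzyme_conc
  v <- Vmax * substrate / (Km + substrate)
  if (noise_cv > 0) {
    set.seed(seed)
    v <- v * (1 + stats::rnorm(length(v), 0, noise_cv))
    v <- pmax(v, 0)
  }
  list(data = data.frame(substrate = substrate, rate = v),
       enzyme_conc = enzyme_conc,
       manifest = list(Km = Km, kcat = kcat, Vmax = Vmax,
                       enzyme_conc = enzyme_conc, noise_cv = noise_cv,
                       seed = seed))
}

#' Synthetic single-site binding curve
#'
#' `signal = s [P]/(Kd + [P])` with multiplicative Gaussian noise. The
#' default titration spans 0.0036-3.6 uM in seven log-spaced steps, and
#' the default Kd of 1.50 uM matches the yRps14-helix-23 rRNA affinity
#' used as the generating value in tests.
#'
#' @param Kd uM
#' @param s scale factor
#' @param protein_conc titration concentrations, uM
#' @param noise_cv multiplicative noise CV
#' @param seed RNG seed
#' @return list: `data` (data.frame protein_conc, signal), `manifest`
#' @export
make_binding_data <- function(Kd = 1.5, s = 1,
                              protein_conc = 0.0036 * 1000^(0:6 / 6),
                              noise_cv = 0, seed = 1) {
  y <- s * protein_conc / (Kd + protein_conc)
  if (noise_cv > 0) {
    set.seed(seed)
    y <- pmax(y * (1 + stats::rnorm(length(y), 0, noise_cv)), 0)
  }
  list(data = data.frame(protein_conc = protein_conc, signal = y),
       manifest = list(Kd = Kd, s = s, noise_cv = noise_cv, seed = seed))
}

#' Synthetic Guinier-regime scattering profile
#'
#' `I(q) = I0 exp(-q^2 Rg^2 / 3)` with optional multiplicative noise and a
#' proportional error column.
#'
#' @param Rg Angstrom
#' @param I0 forward intensity
#' @param q momentum-transfer grid
#' @param noise_cv multiplicative noise CV
#' @param sigma_frac sigma as a fraction of I
#' @param seed RNG seed
#' @return list: `profile` (a [scattering_profile()]), `manifest`
#' @export
make_guinier_profile <- function(Rg = 23.40, I0 = 1,
                                 q = seq(0.005, 1.25 / Rg, length.out = 40),
                                 noise_cv = 0, sigma_frac = 0.01, seed = 1) {
  I <- I0 * exp(-q^2 * Rg^2 / 3)
  if (noise_cv > 0) {
    set.seed(seed)
    I <- I * (1 + stats::rnorm(length(I), 0, noise_cv))
  }
  list(profile = scattering_profile(q, I, sigma_frac * I),
       manifest = list(Rg = Rg, I0 = I0, noise_cv = noise_cv, seed = seed))
}

#' Synthetic coupled-assay absorbance trace
#'
#' Linear NADH-decay segment (slope `-rate * epsilon * path / 1e6`) with an
#' optional initial exponential burst, emulating mixing transients.
#'
#' @param rate true steady-state rate, uM/s
#' @param duration seconds
#' @param n number of points
#' @param a0 starting absorbance
#' @param epsilon,path Beer-Lambert constants (as in [rate_from_trace()])
#' @param burst_amplitude absorbance amplitude of the initial transient
#' @param burst_tau transient time constant, s
#' @param noise_sd additive absorbance noise
#' @param seed RNG seed
#' @return list: `data` (data.frame time, a340), `manifest`
#' @export
make_absorbance_trace <- function(rate, duration = 900, n = 91, a0 = 0.8,
                                  epsilon = 6220, path = 1,
                                  burst_amplitude = 0, burst_tau = 30,
                                  noise_sd = 0, seed = 1) {
  t <- seq(0, duration, length.out = n)
  slope <- -rate * epsilon * path / 1e6
  a <- a0 + slope * t + burst_amplitude * exp(-t / burst_tau)
  if (noise_sd > 0) {
    set.seed(seed)
    a <- a + stats::rnorm(n, 0, noise_sd)
  }
  list(data = data.frame(time = t, a340 = a),
       manifest = list(rate = rate, slope = slope,
                       burst_amplitude = burst_amplitude, seed = seed))
}

#' Write the standard fixture set to a directory
#'
#' Generates one instance of each fixture kind (toy complex, sphere cloud,
#' kinetics, binding, Guinier profile) as PDB/CSV/profile files with JSON
#' manifests alongside.
#'
#' @param dir output directory (created if needed)
#' @param seed master RNG seed
#' @return invisibly, the manifest list
#' @export
generate_fixtures <- function(dir, seed = 1) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- list()
  tc <- make_toy_complex(n_res_a = 12, n_res_b = 12,
                         salt_bridges = 3.2, hbonds = 2.9, seed = seed)
  write_structure(tc$model, file.path(dir, "toy_complex.pdb"))
  man$toy_complex <- tc$manifest
  sc <- make_sphere_cloud(R = 30, n = 2000, seed = seed)
  write_structure(sc$model, file.path(dir, "sphere_cloud.pdb"))
  man$sphere_cloud <- sc$manifest
  kd <- make_kinetics_data(noise_cv = 0.05, seed = seed)
  utils::write.csv(kd$data, file.path(dir, "kinetics.csv"), row.names = FALSE)
  man$kinetics <- kd$manifest
  bd <- make_binding_data(noise_cv = 0.05, seed = seed)
  utils::write.csv(bd$data, file.path(dir, "binding.csv"), row.names = FALSE)
  man$binding <- bd$manifest
  gp <- make_guinier_profile(seed = seed)
  write_saxs_profile(gp$profile, file.path(dir, "guinier.dat"))
  man$guinier <- gp$manifest
  jsonlite::write_json(man, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(man)
}
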