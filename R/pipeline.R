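## High-level runners tying the analysis stages together.  Each writes a
## JSON report plus TSV tables and embeds a provenance block (inputs,
## resolved parameters, package version) so identical inputs and config give
## identical outputs.

.provenance <- function(inputs, config) {
  list(inputs = inputs, config = config,
       package = as.character(utils::packageVersion("rnamimicry")),
       r_version = paste(R.version$major, R.version$minor, sep = "."))
}

.write_report <- function(report, out_prefix, tables = list()) {
  dir.create(dirname(out_prefix), recursive = TRUE, showWarnings = FALSE)
  json <- paste0(out_prefix, ".json")
  jsonlite::write_json(report, json, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  for (nm in names(tables))
    utils::write.table(tables[[nm]], paste0(out_prefix, "_", nm, ".tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(json)
}

#' Run the full interface analysis on one binary complex
#'
#' Buried surfaces, interface residues, hydrogen bonds and salt bridges for
#' two chain groups of a structure file; writes `<out_prefix>.json` plus
#' per-residue and contact TSV tables.
#'
#' @param structure_path PDB file
#' @param chains_a,chains_b chain ids of the two partners
#' @param out_prefix output path prefix
#' @param probe,n_points SASA parameters
#' @param hbond_d_max,salt_bridge_d_max contact cutoffs, Angstrom
#' @return the report list, invisibly
#' @export
run_interface <- function(structure_path, chains_a, chains_b, out_prefix,
                          probe = 1.4, n_points = 960, hbond_d_max = 3.5,
                          salt_bridge_d_max = 4.0) {
  model <- read_structure(structure_path)
  part_a <- select_atoms(model, chain = chains_a,
                         kind = c("protein", "nucleic"))
  part_b <- select_atoms(model, chain = chains_b,
                         kind = c("protein", "nucleic"))
  rep <- buried_surface(model, part_a, part_b, probe, n_points)
  hb <- hydrogen_bonds(part_a, part_b, hbond_d_max, salt_bridge_d_max)
  sb <- salt_bridges(part_a, part_b, salt_bridge_d_max)
  report <- list(
    bsa_a = rep$bsa_a, bsa_b = rep$bsa_b, interface_area = rep$interface_area,
    fraction_of_surface_a = rep$fraction_of_surface_a,
    fraction_of_surface_b = rep$fraction_of_surface_b,
    n_interface_residues_a = nrow(rep$interface_residues_a),
    n_interface_residues_b = nrow(rep$interface_residues_b),
    n_hbonds = nrow(hb), n_salt_bridges = nrow(sb),
    provenance = .provenance(
      list(structure = structure_path, chains_a = chains_a,
           chains_b = chains_b),
      list(probe = probe, n_points = n_points, hbond_d_max = hbond_d_max,
           salt_bridge_d_max = salt_bridge_d_max)))
  .write_report(report, out_prefix,
                list(interface_residues_a = rep$interface_residues_a,
                     interface_residues_b = rep$interface_residues_b,
                     hbonds = hb, salt_bridges = sb))
  invisible(c(report, list(interface_report = rep, hbonds = hb,
                           salt_bridges = sb)))
}

#' Run the cross-complex mimicry analysis
#'
#' Quantifies how far the interface of a shared (homologous) chain in
#' complex A is reused in complex B: residue map, interface overlap with
#' both denominators, and the contact replacement table.
#'
#' @param path_a,path_b structure files for the two complexes
#' @param shared_a,shared_b chain id of the mimicked chain in each file
#' @param partner_a,partner_b chain ids of the partner (protein or RNA)
#' @param out_prefix output path prefix
#' @param probe,n_points SASA parameters
#' @return the report list, invisibly
#' @export
run_mimicry <- function(path_a, shared_a, partner_a,
                        path_b, shared_b, partner_b, out_prefix,
                        probe = 1.4, n_points = 960) {
  ma <- read_structure(path_a); mb <- read_structure(path_b)
  sa <- select_atoms(ma, chain = shared_a, kind = "protein")
  pa <- select_atoms(ma, chain = partner_a, kind = c("protein", "nucleic"))
  sb_ <- select_atoms(mb, chain = shared_b, kind = "protein")
  pb <- select_atoms(mb, chain = partner_b, kind = c("protein", "nucleic"))
  seq_a <- extract_sequence(sa); seq_b <- extract_sequence(sb_)
  map <- align_and_map(seq_a$sequence, seq_b$sequence,
                       resno_x = seq_a$resno, resno_y = seq_b$resno)
  ia <- buried_surface(ma, sa, pa, probe, n_points)$interface_residues_a
  ib <- buried_surface(mb, sb_, pb, probe, n_points)$interface_residues_a
  ov <- interface_overlap(ia$resno, ib$resno, map)
  inv_a <- contact_inventory(shared_a,
                             salt_bridges(sa, pa), hydrogen_bonds(sa, pa))
  inv_b <- contact_inventory(shared_b,
                             salt_bridges(sb_, pb), hydrogen_bonds(sb_, pb))
  repl <- contact_replacement(inv_a, inv_b, map)
  report <- list(
    identity = map$identity,
    n_interface_a = ov$n_interface_a, n_interface_b = ov$n_interface_b,
    n_shared = ov$n_shared,
    overlap_fraction = ov$overlap_fraction,
    overlap_fraction_min = ov$overlap_fraction_min,
    provenance = .provenance(
      list(complex_a = path_a, complex_b = path_b,
           shared = c(shared_a, shared_b),
           partner = c(partner_a, partner_b)),
      list(probe = probe, n_points = n_points)))
  .write_report(report, out_prefix,
                list(shared_residues = ov$shared,
                     replacements = repl$replacements))
  invisible(c(report, list(map = map, overlap = ov, replacement = repl)))
}

#' Run the scattering analysis of a profile file
#'
#' Guinier fit and Porod volume of an experimental profile; when a model
#' structure is supplied, also its Debye profile, P(r) parameters, and the
#' chi-square fit against the data.
#'
#' @param profile_path (q, I[, sigma]) text file
#' @param out_prefix output path prefix
#' @param model_path optional PDB file for model-based analysis
#' @param qmax_rg Guinier validity rule constant
#' @return the report list, invisibly
#' @export
run_saxs <- function(profile_path, out_prefix, model_path = NULL,
                     qmax_rg = 1.3) {
  prof <- read_saxs_profile(profile_path)
  g <- guinier_fit(prof, qmax_rg = qmax_rg)
  p <- tryCatch(porod_volume(prof), warning = function(w) {
    suppressWarnings(porod_volume(prof))
  })
  report <- list(Rg_guinier = g$Rg, I0_guinier = g$I0,
                 guinier_window = g$q_window, qmax_rg = g$qmax_rg,
                 porod_volume = p$volume, porod_reliable = p$reliable)
  if (!is.null(model_path)) {
    model <- read_structure(model_path)
    pr <- pr_from_structure(model)
    dp <- debye_profile(model, prof$q)
    report$Rg_pr <- pr$Rg_pr
    report$Dmax <- pr$Dmax
    if (!is.null(prof$sigma)) {
      fit <- chi2_fit(dp, prof)
      report$chi2 <- fit$chi2
      report$chi <- fit$chi
      report$scale_c <- fit$c
    }
  }
  report$provenance <- .provenance(
    list(profile = profile_path, model = model_path),
    list(qmax_rg = qmax_rg))
  .write_report(report, out_prefix)
  invisible(report)
}

#' Run the kinetics fits on rate or binding tables
#'
#' @param rate_csv optional CSV with columns `substrate`, `rate` (uM, uM/s)
#' @param binding_csv optional CSV with columns `protein_conc`, `signal`
#' @param out_prefix output path prefix
#' @param enzyme_conc uM, for kcat
#' @return the report list, invisibly
#' @export
run_kinetics <- function(out_prefix, rate_csv = NULL, binding_csv = NULL,
                         enzyme_conc = 5) {
  report <- list()
  if (!is.null(rate_csv)) {
    d <- utils::read.csv(rate_csv)
    fit <- mm_fit(d$substrate, d$rate, enzyme_conc)
    report$Km <- fit$Km
    report$Vmax <- fit$Vmax
    report$kcat <- fit$kcat
    report$efficiency <- fit$efficiency
    report$se <- as.list(fit$se)
  }
  if (!is.null(binding_csv)) {
    d <- utils::read.csv(binding_csv)
    bf <- binding_fit(d$protein_conc, d$signal)
    report$Kd <- bf$Kd
    report$scale_s <- bf$s
  }
  if (!length(report)) stop("supply rate_csv and/or binding_csv")
  report$provenance <- .provenance(
    list(rate_csv = rate_csv, binding_csv = binding_csv),
    list(enzyme_conc = enzyme_conc))
  .write_report(report, out_prefix)
  invisible(report)
}
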