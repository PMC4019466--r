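#' Global alignment and residue map between two homologous chains
#'
#' End-gap-free global alignment (Needleman-Wunsch with affine gaps, free
#' terminal gaps) under BLOSUM62, via `Biostrings::pairwiseAlignment`.
#' Identity is identical pairs over aligned (both non-gap) columns.
#'
#' @param seq_x,seq_y protein sequences (1-letter strings, length >= 10)
#' @param resno_x,resno_y optional author residue numbers per sequence
#'   position (defaults to 1-based positions), so downstream reports keep
#'   crystallographic numbering
#' @param gap_open,gap_extend affine gap penalties
#' @param substitution substitution matrix name (a Biostrings data set)
#' @return `residue_map`: list with `pairs` (data.frame `pos_x`, `pos_y`,
#'   `resno_x`, `resno_y`, `aa_x`, `aa_y`, `match`), `identity`,
#'   `aligned_x`, `aligned_y` (gapped strings covering the aligned region)
#' @export
align_and_map <- function(seq_x, seq_y, resno_x = NULL, resno_y = NULL,
                          gap_open = 10, gap_extend = 0.5,
                          substitution = "BLOSUM62") {
  if (!nzchar(seq_x) || !nzchar(seq_y)) stop("empty sequence")
  if (nchar(seq_x) < 10 || nchar(seq_y) < 10)
    stop("sequences must have length >= 10")
  if (is.null(resno_x)) resno_x <- seq_len(nchar(seq_x))
  if (is.null(resno_y)) resno_y <- seq_len(nchar(seq_y))
  mat <- local({
    e <- new.env()
    utils::data(list = substitution, package = "Biostrings", envir = e)
    get(substitution, envir = e)
  })
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_x), Biostrings::AAString(seq_y),
    type = "overlap", substitutionMatrix = mat,
    gapOpening = gap_open, gapExtension = gap_extend)
  ax <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  ay <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  px <- Biostrings::start(Biostrings::pattern(aln)) - 1L
  py <- Biostrings::start(Biostrings::subject(aln)) - 1L
  pos_x <- pos_y <- integer(length(ax))
  cx <- px; cy <- py
  for (k in seq_along(ax)) {
    if (ax[k] != "-") cx <- cx + 1L
    if (ay[k] != "-") cy <- cy + 1L
    pos_x[k] <- if (ax[k] != "-") cx else NA_integer_
    pos_y[k] <- if (ay[k] != "-") cy else NA_integer_
  }
  both <- !is.na(pos_x) & !is.na(pos_y)
  pairs <- data.frame(pos_x = pos_x[both], pos_y = pos_y[both],
                      resno_x = resno_x[pos_x[both]],
                      resno_y = resno_y[pos_y[both]],
                      aa_x = ax[both], aa_y = ay[both],
                      match = ax[both] == ay[both])
  structure(list(pairs = pairs,
                 identity = mean(pairs$match),
                 n_aligned = nrow(pairs),
                 aligned_x = paste(ax, collapse = ""),
                 aligned_y = paste(ay, collapse = "")),
            class = "residue_map")
}

#' @export
print.residue_map <- function(x, ...) {
  cat(sprintf("<residue_map: %d aligned pairs, identity %.1f%%>\n",
              x$n_aligned, 100 * x$identity))
  invisible(x)
}

#' Interface overlap between two complexes sharing a homologous chain
#'
#' Counts the residues of interface A whose homologous position (through
#' `map`) is also interfacial in complex B. Because the printed "fraction
#' of the total" is ambiguous between the larger and the smaller interface,
#' both denominators are reported; `overlap_fraction` uses the larger set.
#'
#' @param interface_a residue numbers (chain X numbering) interfacial in
#'   complex A
#' @param interface_b residue numbers (chain Y numbering) interfacial in
#'   complex B
#' @param map a [align_and_map()] result mapping chain X to chain Y
#' @return `mimicry_report`: `n_interface_a`, `n_interface_b`, `n_shared`,
#'   `overlap_fraction` (= n_shared / max(nA, nB)),
#'   `overlap_fraction_min` (= n_shared / min(nA, nB)), `shared`
#'   (data.frame of mapped residue pairs), `unmapped_a` (interface-A
#'   residues with no aligned partner, flagged unshared)
#' @export
interface_overlap <- function(interface_a, interface_b, map) {
  interface_a <- unique(interface_a); interface_b <- unique(interface_b)
  idx <- match(interface_a, map$pairs$resno_x)
  mapped <- !is.na(idx)
  partner <- map$pairs$resno_y[idx[mapped]]
  shared_mask <- partner %in% interface_b
  n_a <- length(interface_a); n_b <- length(interface_b)
  n_shared <- sum(shared_mask)
  denom_max <- max(n_a, n_b)
  structure(list(
    n_interface_a = n_a, n_interface_b = n_b, n_shared = n_shared,
    overlap_fraction = if (denom_max) n_shared / denom_max else 0,
    overlap_fraction_min = if (min(n_a, n_b)) n_shared / min(n_a, n_b) else 0,
    shared = data.frame(resno_a = interface_a[mapped][shared_mask],
                        resno_b = partner[shared_mask]),
    unmapped_a = interface_a[!mapped]), class = "mimicry_report")
}

#' @export
print.mimicry_report <- function(x, ...) {
  cat(sprintf(paste0("<mimicry_report: %d vs %d interface residues, ",
                     "%d shared (%.0f%% of larger, %.0f%% of smaller)>\n"),
              x$n_interface_a, x$n_interface_b, x$n_shared,
              100 * x$overlap_fraction, 100 * x$overlap_fraction_min))
  invisible(x)
}

#' Contact inventory of one chain in a binary interface
#'
#' Flattens salt-bridge and hydrogen-bond tables into one per-residue
#' contact list for the chain of interest, classifying each partner group
#' as `"carboxylate"`, `"phosphate"`, `"backbone"` or `"sidechain"`.
#'
#' @param chain chain id of the residues to inventory
#' @param bridges a [salt_bridges()] table (optional)
#' @param hbonds a [hydrogen_bonds()] table (optional); `res_a`/`chain_a`
#'   columns are matched against `chain` on either side
#' @return data.frame: `resno`, `res`, `partner`, `partner_kind`
#' @export
contact_inventory <- function(chain, bridges = NULL, hbonds = NULL) {
  rows <- list()
  if (!is.null(bridges) && nrow(bridges)) {
    on_basic <- bridges$basic_chain == chain
    if (any(on_basic))
      rows[[length(rows) + 1]] <- data.frame(
        resno = bridges$basic_resno[on_basic],
        res = bridges$basic_res[on_basic],
        partner = bridges$acidic_res[on_basic],
        partner_kind = bridges$partner_kind[on_basic])
    on_acidic <- bridges$acidic_chain == chain
    if (any(on_acidic))
      rows[[length(rows) + 1]] <- data.frame(
        resno = bridges$acidic_resno[on_acidic],
        res = bridges$acidic_res[on_acidic],
        partner = bridges$basic_res[on_acidic],
        partner_kind = "basic")
  }
  if (!is.null(hbonds) && nrow(hbonds)) {
    classify <- function(atom) {
      ifelse(atom %in% .phosphate_oxygens, "phosphate",
             ifelse(atom %in% c("N", "O", "C", "CA", "OXT"), "backbone",
                    "sidechain"))
    }
    on_a <- hbonds$chain_a == chain
    if (any(on_a))
      rows[[length(rows) + 1]] <- data.frame(
        resno = hbonds$resno_a[on_a], res = hbonds$res_a[on_a],
        partner = hbonds$res_b[on_a],
        partner_kind = classify(hbonds$atom_b[on_a]))
    on_b <- hbonds$chain_b == chain
    if (any(on_b))
      rows[[length(rows) + 1]] <- data.frame(
        resno = hbonds$resno_b[on_b], res = hbonds$res_b[on_b],
        partner = hbonds$res_a[on_b],
        partner_kind = classify(hbonds$atom_a[on_b]))
  }
  if (!length(rows))
    return(data.frame(resno = integer(0), res = character(0),
                      partner = character(0), partner_kind = character(0)))
  out <- unique(do.call(rbind, rows))
  out[order(out$resno), , drop = FALSE]
}

#' Contact replacement table across two complexes
#'
#' For each residue of the mimicked chain that makes contacts in both
#' complexes, pairs its partners in complex A with its partners in complex
#' B and classifies the replacement (e.g. `"phosphate->carboxylate"` when
#' an rRNA phosphate contact is substituted by an acidic side chain).
#'
#' @param inventory_a,inventory_b [contact_inventory()] tables for the
#'   mimicked chain in complexes A and B (numbering of chains X and Y)
#' @param map a [align_and_map()] result mapping chain X to chain Y
#' @return list with `replacements` (data.frame `resno_a`, `res_a`,
#'   `partners_a`, `kind_a`, `resno_b`, `res_b`, `partners_b`, `kind_b`,
#'   `class`) and `unmatched` (contacts present in only one complex)
#' @export
contact_replacement <- function(inventory_a, inventory_b, map) {
  agg <- function(inv) {
    if (!nrow(inv))
      return(data.frame(resno = integer(0), res = character(0),
                        partners = character(0), kind = character(0)))
    sp <- split(inv, inv$resno)
    data.frame(resno = as.integer(names(sp)),
               res = vapply(sp, function(d) d$res[1], ""),
               partners = vapply(sp, function(d)
                 paste(unique(d$partner), collapse = ","), ""),
               kind = vapply(sp, function(d)
                 paste(unique(d$partner_kind), collapse = "+"), ""),
               row.names = NULL)
  }
  A <- agg(inventory_a); B <- agg(inventory_b)
  A$resno_b <- map$pairs$resno_y[match(A$resno, map$pairs$resno_x)]
  if (!nrow(A)) A$resno_b <- integer(0)
  hit <- !is.na(A$resno_b) & A$resno_b %in% B$resno
  jb <- match(A$resno_b[hit], B$resno)
  replacements <- data.frame(
    resno_a = A$resno[hit], res_a = A$res[hit], partners_a = A$partners[hit],
    kind_a = A$kind[hit],
    resno_b = A$resno_b[hit], res_b = B$res[jb], partners_b = B$partners[jb],
    kind_b = B$kind[jb],
    class = if (any(hit)) paste0(A$kind[hit], "->", B$kind[jb]) else character(0))
  unmatched <- list(
    only_a = A[!hit, c("resno", "res", "partners", "kind"), drop = FALSE],
    only_b = B[!B$resno %in% A$resno_b[hit],
               c("resno", "res", "partners", "kind"), drop = FALSE])
  list(replacements = replacements, unmatched = unmatched)
}
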