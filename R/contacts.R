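# donor / acceptor capability per atom (heavy-atom criterion; the crystal
# structures handled here carry no hydrogens, so direction is inferred from
# residue-type tables only)
.hb_capability <- function(atoms) {
  don <- rep(FALSE, nrow(atoms)); acc <- don
  prot <- atoms$kind == "protein"
  don[prot & atoms$elety %in% .hb_donors$backbone_protein] <- TRUE
  acc[prot & atoms$elety %in% .hb_acceptors$backbone_protein] <- TRUE
  for (res in setdiff(names(.hb_donors), "backbone_protein")) {
    m <- prot & atoms$resid == res & atoms$elety %in% .hb_donors[[res]]
    don[m] <- TRUE
  }
  for (res in setdiff(names(.hb_acceptors), "backbone_protein")) {
    m <- prot & atoms$resid == res & atoms$elety %in% .hb_acceptors[[res]]
    acc[m] <- TRUE
  }
  nuc <- atoms$kind == "nucleic" & atoms$elem %in% c("N", "O")
  acc[nuc] <- TRUE
  don[nuc & !atoms$elety %in% .phosphate_oxygens] <- TRUE
  list(donor = don, acceptor = acc)
}

# charged-group atoms for salt-bridge detection
.charged_atoms <- function(atoms, count_his = TRUE) {
  basic <- rep(FALSE, nrow(atoms)); acidic <- basic
  for (res in names(.basic_atoms)) {
    if (res == "HIS" && !count_his) next
    basic[atoms$resid == res & atoms$elety %in% .basic_atoms[[res]]] <- TRUE
  }
  for (res in names(.acidic_atoms))
    acidic[atoms$resid == res & atoms$elety %in% .acidic_atoms[[res]]] <- TRUE
  acidic[atoms$kind == "protein" & atoms$elety == "OXT"] <- TRUE  # C-terminus
  phosphate <- atoms$kind == "nucleic" & atoms$elety %in% .phosphate_oxygens
  acidic[phosphate] <- TRUE
  list(basic = basic, acidic = acidic, phosphate = phosphate)
}

.res_label <- function(atoms, idx) {
  paste0(atoms$resid[idx], atoms$resno[idx],
         ifelse(atoms$insert[idx] == "", "", atoms$insert[idx]))
}

#' Salt bridges between two partners
#'
#' Charged-group nitrogens (Arg NE/NH1/NH2, Lys NZ, His ND1/NE2) paired
#' with carboxylate oxygens (Asp OD1/OD2, Glu OE1/OE2, terminal OXT) or
#' nucleic-acid phosphate oxygens (OP1/OP2), at N-O distance `<= d_max`.
#' One row per residue pair, carrying the minimum N-O distance.
#'
#' @param a,b [structure_model()] selections of the two partners. Passing
#'   the same selection twice inventories intramolecular bridges.
#' @param d_max N-O distance cutoff, Angstrom
#' @param count_his treat histidine as basic (assumed protonated)
#' @return data.frame: `basic_res`, `basic_chain`, `acidic_res`,
#'   `acidic_chain`, `partner_kind` (`"carboxylate"` or `"phosphate"`),
#'   `distance`, plus atom names of the closest pair
#' @export
salt_bridges <- function(a, b, d_max = 4.0, count_his = TRUE) {
  empty <- data.frame(basic_res = character(0), basic_chain = character(0),
                      basic_resno = integer(0),
                      acidic_res = character(0), acidic_chain = character(0),
                      acidic_resno = integer(0),
                      partner_kind = character(0), basic_atom = character(0),
                      acidic_atom = character(0), distance = numeric(0))
  aa <- a$atoms; ab <- b$atoms
  ca <- .charged_atoms(aa, count_his); cb <- .charged_atoms(ab, count_his)
  rows <- list(list(at1 = aa, at2 = ab, m1 = ca$basic, m2 = cb$acidic,
                    ph2 = cb$phosphate, swap = FALSE),
               list(at1 = ab, at2 = aa, m1 = cb$basic, m2 = ca$acidic,
                    ph2 = ca$phosphate, swap = TRUE))
  out <- list()
  same <- identical(a$atoms, b$atoms)
  for (r in rows) {
    if (!any(r$m1) || !any(r$m2)) next
    i1 <- which(r$m1); i2 <- which(r$m2)
    np <- neighbor_pairs(as.matrix(r$at1[i1, c("x", "y", "z")]),
                         as.matrix(r$at2[i2, c("x", "y", "z")]), d_max)
    if (!nrow(np)) next
    bi <- i1[np$i]; ai <- i2[np$j]
    if (same) {
      keep <- paste(r$at1$chain[bi], r$at1$resno[bi], r$at1$insert[bi]) !=
        paste(r$at2$chain[ai], r$at2$resno[ai], r$at2$insert[ai])
      bi <- bi[keep]; ai <- ai[keep]; np <- np[keep, , drop = FALSE]
      if (!nrow(np)) next
    }
    out[[length(out) + 1]] <- data.frame(
      basic_res = .res_label(r$at1, bi), basic_chain = r$at1$chain[bi],
      basic_resno = r$at1$resno[bi],
      acidic_res = .res_label(r$at2, ai), acidic_chain = r$at2$chain[ai],
      acidic_resno = r$at2$resno[ai],
      partner_kind = ifelse(r$ph2[ai], "phosphate", "carboxylate"),
      basic_atom = r$at1$elety[bi], acidic_atom = r$at2$elety[ai],
      distance = np$distance)
    if (same) break  # both directions identical when a == b
  }
  if (!length(out)) return(empty)
  tab <- do.call(rbind, out)
  key <- paste(tab$basic_chain, tab$basic_res, tab$acidic_chain,
               tab$acidic_res)
  tab <- tab[order(key, tab$distance), , drop = FALSE]
  tab <- tab[!duplicated(paste(tab$basic_chain, tab$basic_res,
                               tab$acidic_chain, tab$acidic_res)), ,
             drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Hydrogen bonds between two partners (heavy-atom criterion)
#'
#' Cross-partner donor-acceptor pairs (N/O/S atoms classified by
#' residue-type tables) with distance `<= d_max`. Atom pairs already
#' qualifying as salt bridges under the same geometry are excluded, so the
#' two inventories are disjoint. No angular term is applied because the
#' structures carry no hydrogens.
#'
#' @param a,b [structure_model()] selections of the two partners
#' @param d_max donor-acceptor distance cutoff, Angstrom
#' @param salt_bridge_d_max cutoff used to exclude salt-bridge atom pairs
#' @return data.frame: `res_a`, `chain_a`, `atom_a`, `res_b`, `chain_b`,
#'   `atom_b`, `distance`
#' @export
hydrogen_bonds <- function(a, b, d_max = 3.5, salt_bridge_d_max = 4.0) {
  empty <- data.frame(res_a = character(0), chain_a = character(0),
                      resno_a = integer(0), atom_a = character(0),
                      res_b = character(0), chain_b = character(0),
                      resno_b = integer(0), atom_b = character(0),
                      distance = numeric(0))
  aa <- a$atoms; ab <- b$atoms
  ha <- .hb_capability(aa); hb <- .hb_capability(ab)
  pa <- ha$donor | ha$acceptor; pb <- hb$donor | hb$acceptor
  if (!any(pa) || !any(pb)) return(empty)
  i1 <- which(pa); i2 <- which(pb)
  np <- neighbor_pairs(as.matrix(aa[i1, c("x", "y", "z")]),
                       as.matrix(ab[i2, c("x", "y", "z")]), d_max)
  if (!nrow(np)) return(empty)
  ia <- i1[np$i]; ib <- i2[np$j]
  ok <- (ha$donor[ia] & hb$acceptor[ib]) | (ha$acceptor[ia] & hb$donor[ib])
  # drop pairs that are salt bridges (charged N against charged/phosphate O)
  ca <- .charged_atoms(aa); cb <- .charged_atoms(ab)
  sb <- (ca$basic[ia] & cb$acidic[ib]) | (ca$acidic[ia] & cb$basic[ib])
  sb <- sb & np$distance <= salt_bridge_d_max
  keep <- ok & !sb
  if (!any(keep)) return(empty)
  data.frame(res_a = .res_label(aa, ia[keep]), chain_a = aa$chain[ia[keep]],
             resno_a = aa$resno[ia[keep]], atom_a = aa$elety[ia[keep]],
             res_b = .res_label(ab, ib[keep]), chain_b = ab$chain[ib[keep]],
             resno_b = ab$resno[ib[keep]], atom_b = ab$elety[ib[keep]],
             distance = np$distance[keep])
}
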