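#' Atomic structure container
#'
#' A `structure_model` is a light S3 container holding one flat atom table
#' (one row per atom) plus an entry identifier. Chains, residues and atoms
#' are recovered from the `chain`, `resno`/`insert` and `elety` columns, so
#' the hierarchy of coordinate files is preserved without nested objects.
#'
#' @param atoms data.frame with columns `eleno, elety, altloc, resid, chain,
#'   resno, insert, x, y, z, o, b, elem, vdw, kind`
#' @param entry_id accession or fixture name
#' @return an object of class `structure_model`
#' @export
structure_model <- function(atoms, entry_id = "model") {
  needed <- c("eleno", "elety", "altloc", "resid", "chain", "resno",
              "insert", "x", "y", "z", "o", "b", "elem", "vdw", "kind")
  missing_cols <- setdiff(needed, names(atoms))
  if (length(missing_cols))
    stop("atom table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(atoms) && !all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite atomic coordinates")
  if (nrow(atoms) && any(atoms$o < 0 | atoms$o > 1, na.rm = TRUE))
    stop("occupancy outside [0,1]")
  structure(list(atoms = atoms, entry_id = entry_id),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  ch <- unique(x$atoms$chain)
  cat(sprintf("<structure_model '%s': %d atoms, %d chain(s) [%s]>\n",
              x$entry_id, nrow(x$atoms), length(ch),
              paste(ch, collapse = ",")))
  invisible(x)
}

#' Number of atoms in a model
#' @param model a `structure_model`
#' @export
n_atoms <- function(model) nrow(model$atoms)

#' Atom coordinates as an N x 3 matrix
#' @param model a `structure_model`
#' @export
coords <- function(model) {
  as.matrix(model$atoms[, c("x", "y", "z")])
}

# residue key strings, unique within the model
.residue_key <- function(atoms) {
  paste(atoms$chain, atoms$resno, trimws(atoms$insert), atoms$resid, sep = "|")
}

#' Read a PDB coordinate file
#'
#' Parses ATOM/HETATM records (via bio3d), drops waters and hydrogens,
#' collapses alternate locations according to `altloc_policy`, and assigns
#' each atom a Bondi-type van der Waals radius (1.80 A fallback for
#' elements missing from the table).
#'
#' @param path PDB-format text file
#' @param altloc_policy `"first"` keeps the first conformer per atom key;
#'   `"highest_occupancy"` keeps the conformer with the largest occupancy.
#' @param keep_hetero keep non-water HETATM records (nucleotide ligands,
#'   ions). They are classified `kind = "other"` and are excluded by the
#'   kind-based selections used in surface and contact analyses unless
#'   selected explicitly.
#' @return a [structure_model()]
#' @examples
#' pdb <- write_structure(make_toy_complex(4, 4)$model, tempfile(fileext = ".pdb"))
#' read_structure(pdb)
#' @export
read_structure <- function(path, altloc_policy = c("first", "highest_occupancy"),
                           keep_hetero = TRUE) {
  altloc_policy <- match.arg(altloc_policy)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM  |HETATM)", lines)
  if (any(rec)) {
    bad <- which(rec & (nchar(lines) < 54 |
      is.na(suppressWarnings(as.numeric(substr(lines, 31, 38)))) |
      is.na(suppressWarnings(as.numeric(substr(lines, 39, 46)))) |
      is.na(suppressWarnings(as.numeric(substr(lines, 47, 54))))))
    if (length(bad))
      stop(sprintf("unparseable coordinate record at line %d of %s",
                   bad[1], path))
  }
  pdb <- bio3d::read.pdb(path, verbose = FALSE,
                         rm.alt = FALSE, hex = TRUE)
  at <- pdb$atom
  at <- at[!(toupper(at$resid) %in% .water_names), , drop = FALSE]
  elem <- toupper(trimws(at$elesy))
  noel <- is.na(elem) | elem == ""
  elem[noel] <- .element_from_name(at$elety[noel], at$resid[noel])
  at <- at[elem != "H" & elem != "D", , drop = FALSE]
  elem <- elem[elem != "H" & elem != "D"]
  if (!keep_hetero)
    at <- at[at$type == "ATOM", , drop = FALSE]
  atoms <- data.frame(
    eleno = at$eleno,
    elety = toupper(trimws(at$elety)),
    altloc = ifelse(is.na(at$alt) | at$alt == "", "", at$alt),
    resid = toupper(trimws(at$resid)),
    chain = ifelse(is.na(at$chain) | at$chain == "", " ", at$chain),
    resno = at$resno,
    insert = ifelse(is.na(at$insert) | at$insert == "", "", at$insert),
    x = at$x, y = at$y, z = at$z,
    o = ifelse(is.na(at$o), 1, at$o),
    b = ifelse(is.na(at$b), 0, at$b),
    stringsAsFactors = FALSE
  )
  atoms$elem <- toupper(trimws(elem[seq_len(nrow(at))]))
  atoms$vdw <- unname(.vdw_radii[atoms$elem])
  atoms$vdw[is.na(atoms$vdw)] <- .vdw_default
  atoms$kind <- .residue_kind(atoms$resid)
  atoms$kind[at$type == "HETATM" & atoms$kind == "nucleic"] <- "other"

  atoms <- .collapse_altloc(atoms, altloc_policy)
  if (!any(atoms$kind %in% c("protein", "nucleic")))
    stop("empty model: no polymer atoms in ", path)
  structure_model(atoms, entry_id = sub("\\.(pdb|ent)$", "", basename(path)))
}

.collapse_altloc <- function(atoms, policy) {
  key <- paste(.residue_key(atoms), atoms$elety, sep = "|")
  if (!anyDuplicated(key)) return(atoms)
  keep <- if (policy == "highest_occupancy") {
    ord <- order(key, -atoms$o, atoms$altloc)
    sel <- ord[!duplicated(key[ord])]   # max-occupancy row per atom key
    seq_len(nrow(atoms)) %in% sel
  } else {
    !duplicated(key)
  }
  atoms[keep, , drop = FALSE]
}

#' Write a model to a PDB file
#'
#' @param model a [structure_model()]
#' @param path output file
#' @return `path`, invisibly usable for re-reading
#' @export
write_structure <- function(model, path) {
  a <- model$atoms
  if (!nrow(a)) stop("refusing to write an empty model")
  bio3d::write.pdb(
    pdb = NULL, file = path,
    xyz = as.vector(t(as.matrix(a[, c("x", "y", "z")]))),
    type = ifelse(a$kind == "other", "HETATM", "ATOM"),
    resno = a$resno, resid = a$resid, eleno = a$eleno, elety = a$elety,
    chain = ifelse(a$chain == " ", "", a$chain), insert = a$insert,
    o = a$o, b = a$b, elesy = a$elem
  )
  invisible(path)
}

#' Select atoms from a model
#'
#' Non-mutating atom selection by chain id, residue number (vectors or
#' ranges), residue kind and atom-name sets, in the style of
#' `bio3d::atom.select`. Criteria combine with AND; `invert = TRUE` returns
#' the complement, so `select_atoms(m, ...)` and
#' `select_atoms(m, ..., invert = TRUE)` partition the atom set.
#'
#' @param model a [structure_model()]
#' @param chain chain identifier(s)
#' @param resno residue numbers (use `a:b` for ranges)
#' @param name atom name(s), e.g. `"CA"`
#' @param kind one or more of `"protein"`, `"nucleic"`, `"other"`
#' @param resid residue name(s), e.g. `"ARG"`
#' @param invert return the complement of the selection
#' @return a new `structure_model`; empty selections warn but do not error
#' @export
select_atoms <- function(model, chain = NULL, resno = NULL, name = NULL,
                         kind = NULL, resid = NULL, invert = FALSE) {
  a <- model$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(chain)) keep <- keep & a$chain %in% chain
  if (!is.null(resno)) keep <- keep & a$resno %in% resno
  if (!is.null(name))  keep <- keep & a$elety %in% toupper(name)
  if (!is.null(kind))  keep <- keep & a$kind %in% kind
  if (!is.null(resid)) keep <- keep & a$resid %in% toupper(resid)
  if (invert) keep <- !keep
  if (!any(keep)) warning("selection matched no atoms")
  structure_model(a[keep, , drop = FALSE], entry_id = model$entry_id)
}

#' Extract the one-letter polymer sequence of a chain
#'
#' Residues are taken in file order, one per (residue number, insertion
#' code). Standard amino acids map through the usual 3-to-1 table (unknown
#' protein residues give `"X"`); ribo- and deoxynucleotides map to their
#' base letter (unknowns give `"N"`).
#'
#' @param model a [structure_model()]
#' @param chain chain id; may be omitted for single-chain models
#' @return list with `sequence` (string), `kind` (`"protein"`, `"nucleic"`
#'   or `"other"`), and `resno` (author numbering per sequence position)
#' @export
extract_sequence <- function(model, chain = NULL) {
  a <- model$atoms
  if (!is.null(chain)) a <- a[a$chain %in% chain, , drop = FALSE]
  if (!nrow(a)) stop("no atoms in requested chain")
  key <- paste(a$chain, a$resno, a$insert, sep = "|")
  first <- !duplicated(key)
  res <- a[first, c("resid", "resno", "kind"), drop = FALSE]
  poly <- res$kind %in% c("protein", "nucleic")
  if (!any(poly))
    return(list(sequence = "", kind = "other", resno = integer(0)))
  res <- res[poly, , drop = FALSE]
  kind <- names(which.max(table(res$kind)))
  res <- res[res$kind == kind, , drop = FALSE]
  list(sequence = paste(.residue_letter(res$resid), collapse = ""),
       kind = kind, resno = res$resno)
}

#' Per-chain residue table
#'
#' @param model a [structure_model()]
#' @return data.frame with one row per residue: chain, resno, insert,
#'   resid, kind
#' @export
residue_table <- function(model) {
  a <- model$atoms
  key <- paste(a$chain, a$resno, a$insert, sep = "|")
  a[!duplicated(key), c("chain", "resno", "insert", "resid", "kind"),
    drop = FALSE]
}
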