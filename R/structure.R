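#' Atomic structure container
#'
#' A `structure_model` is a light wrapper around an atom table in the layout
#' used by crystallographic files: one row per atom with record type
#' (ATOM/HETATM), serial number, atom name, alternate-location id, residue
#' name, chain, residue number, insertion code, coordinates (Angstrom),
#' occupancy, B-factor (Angstrom^2) and element symbol.
#'
#' @param atom data.frame with columns `type`, `eleno`, `elety`, `alt`,
#'   `resid`, `chain`, `resno`, `insert`, `x`, `y`, `z`, `o`, `b`, `elesy`.
#'   Missing optional columns (`type`, `alt`, `insert`, `o`, `b`, `elesy`,
#'   `eleno`) are filled with defaults.
#' @param id character identifier for the model.
#' @return object of class `structure_model`.
#' @export
structure_model <- function(atom, id = "model") {
  stopifnot(is.data.frame(atom))
  need <- c("elety", "resid", "chain", "resno", "x", "y", "z")
  miss <- setdiff(need, names(atom))
  if (length(miss))
    stop("atom table missing column(s): ", paste(miss, collapse = ", "))
  n <- nrow(atom)
  if (n == 0L) stop("empty structure: atom table has no rows")
  atom$type   <- atom$type   %||% rep("ATOM", n)
  atom$eleno  <- atom$eleno  %||% seq_len(n)
  atom$alt    <- atom$alt    %||% rep(NA_character_, n)
  atom$insert <- atom$insert %||% rep(NA_character_, n)
  atom$o      <- atom$o      %||% rep(1, n)
  atom$b      <- atom$b      %||% rep(0, n)
  if (is.null(atom$elesy)) atom$elesy <- guess_element(atom$elety)
  bad <- is.na(atom$elesy) | atom$elesy == ""
  atom$elesy[bad] <- guess_element(atom$elety[bad])
  if (!all(is.finite(atom$x) & is.finite(atom$y) & is.finite(atom$z)))
    stop("non-finite coordinates in atom table")
  atom$het <- atom$type == "HETATM"
  obj <- list(id = id, atom = atom)
  class(obj) <- "structure_model"
  obj
}

# Element symbol from an atom name: strip digits and primes, take the first
# letter. Correct for standard protein/nucleic atom naming (CA, OD1, NZ, ...).
guess_element <- function(elety) {
  s <- gsub("[0-9']", "", trimws(elety))
  toupper(substr(s, 1, 1))
}

#' Read a PDB or mmCIF file into a structure_model
#'
#' Parsing is done by \pkg{bio3d} (`read.pdb`/`read.cif`). For multi-model
#' files only the first model is kept. Alternate locations are resolved to
#' the highest-occupancy record; ties go to the alphabetically first altloc.
#' Waters and other heteroatoms are retained and flagged in the `het`
#' column.
#'
#' @param file path to a `.pdb` or `.cif`/`.mmcif` file.
#' @param id model identifier; defaults to the file name without extension.
#' @return a [structure_model()].
#' @export
read_structure <- function(file, id = NULL) {
  if (!file.exists(file)) stop("file not found: ", file)
  is_cif <- grepl("\\.(cif|mmcif)$", file, ignore.case = TRUE)
  pdb <- if (is_cif) {
    bio3d::read.cif(file, multi = FALSE, verbose = FALSE)
  } else {
    bio3d::read.pdb(file, multi = FALSE, rm.alt = FALSE, verbose = FALSE)
  }
  atom <- pdb$atom
  if (is.null(atom) || nrow(atom) == 0L) stop("empty structure: ", file)
  atom <- resolve_altloc(atom)
  if (!any(atom$type == "ATOM"))
    stop("no polymer ATOM records in ", file, " (heteroatoms/waters only)")
  structure_model(atom, id = id %||% sub("\\.[^.]*$", "", basename(file)))
}

# Keep, per (chain, resno, insert, elety), the altloc record with the highest
# occupancy; ties broken by alphabetical altloc.
resolve_altloc <- function(atom) {
  alt <- atom$alt
  alt[is.na(alt)] <- ""
  if (all(alt == "")) return(atom)
  key <- paste(atom$chain, atom$resno,
               ifelse(is.na(atom$insert), "", atom$insert), atom$elety)
  ord <- order(key, -atom$o, alt)
  atom <- atom[ord, , drop = FALSE]
  atom <- atom[!duplicated(key[ord]), , drop = FALSE]
  atom[order(atom$eleno), , drop = FALSE]
}

#' Write a structure_model to a PDB file
#'
#' Emits fixed-format ATOM/HETATM records through `bio3d::write.pdb`, so a
#' written model re-reads with identical coordinates (8.3f columns).
#'
#' @param model a [structure_model()].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_structure <- function(model, file) {
  stopifnot(inherits(model, "structure_model"))
  a <- model$atom
  bio3d::write.pdb(
    pdb = NULL, file = file,
    xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
    type = a$type, resno = a$resno, resid = a$resid, eleno = a$eleno,
    elety = a$elety, chain = a$chain, o = a$o, b = a$b, elesy = a$elesy
  )
  invisible(file)
}

#' @export
print.structure_model <- function(x, ...) {
  a <- x$atom
  cat("structure_model:", x$id, "\n")
  cat(" ", nrow(a), "atoms,", sum(!a$het), "polymer /", sum(a$het),
      "hetero;", "chains:", paste(unique(a$chain), collapse = " "), "\n")
  invisible(x)
}

# Calpha subset of one chain (polymer atoms only), ordered by residue number.
ca_atoms <- function(model, chain) {
  a <- model$atom
  sel <- a$chain == chain & a$elety == "CA" & !a$het
  ca <- a[sel, , drop = FALSE]
  ca[order(ca$resno), , drop = FALSE]
}

# All atoms of one residue, optionally dropping hydrogens.
residue_atoms <- function(model, chain, resno, include_hydrogens = FALSE) {
  a <- model$atom
  sel <- a$chain == chain & a$resno == resno & !a$het
  r <- a[sel, , drop = FALSE]
  if (!include_hydrogens) r <- r[r$elesy != "H", , drop = FALSE]
  r
}

coords_matrix <- function(atom) {
  as.matrix(atom[, c("x", "y", "z"), drop = FALSE])
}
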