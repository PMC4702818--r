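# Residue-name vocabularies used for polymer-type inference
.aa3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL", "MSE", "SEC", "PYL")
.nuc <- c("A", "C", "G", "U", "I", "DA", "DC", "DG", "DT", "DU", "DI", "T")

#' Construct an atom model
#'
#' Lightweight coordinate-model container: one data frame of atoms, ordered
#' by chain, residue number and insertion code. Chains are classified as
#' protein, nucleic or other from their residue names (a chain is protein or
#' nucleic when at least half of its residues carry standard names).
#'
#' @param atoms data frame with columns `chain`, `resno`, `resid` (residue
#'   name), `elety` (atom name), `x`, `y`, `z`; optional `insert`
#'   (insertion code, `NA` when absent), `elesy` (element symbol, guessed
#'   from the atom name when missing), `o` (occupancy, default 1) and `b`
#'   (temperature factor, default 0).
#' @return An object of class `atom_model`: list with `atoms` (the ordered
#'   data frame) and `chain_types` (named character vector, one of
#'   `"protein"`, `"nucleic"`, `"other"` per chain).
#' @seealso [parse_model()], [classify_trace()]
#' @export
atom_model <- function(atoms) {
  need <- c("chain", "resno", "resid", "elety", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss))
    stop("atoms data frame lacks columns: ", paste(miss, collapse = ", "))
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  n <- nrow(atoms)
  if (!"insert" %in% names(atoms)) atoms$insert <- rep(NA_character_, n)
  if (!"o" %in% names(atoms)) atoms$o <- rep(1, n)
  if (!"b" %in% names(atoms)) atoms$b <- rep(0, n)
  if (!"elesy" %in% names(atoms)) atoms$elesy <- rep(NA_character_, n)
  atoms$chain <- as.character(atoms$chain)
  atoms$resno <- as.integer(atoms$resno)
  guess <- is.na(atoms$elesy) | atoms$elesy == ""
  if (any(guess))
    atoms$elesy[guess] <- substr(gsub("[0-9' \"*]", "", atoms$elety[guess]), 1L, 1L)
  atoms$elesy <- toupper(atoms$elesy)
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("atom coordinates must be finite")
  ins <- ifelse(is.na(atoms$insert), "", atoms$insert)
  atoms <- atoms[order(atoms$chain, atoms$resno, ins), , drop = FALSE]
  rownames(atoms) <- NULL

  chain_types <- vapply(split(atoms, atoms$chain), function(a) {
    res <- unique(paste(a$resno, ifelse(is.na(a$insert), "", a$insert)))
    name_of <- vapply(split(a$resid, paste(a$resno, ifelse(is.na(a$insert), "", a$insert))),
                      function(r) r[1L], character(1))
    aa <- mean(name_of %in% .aa3)
    nu <- mean(name_of %in% .nuc)
    if (aa >= 0.5) "protein" else if (nu >= 0.5) "nucleic" else "other"
  }, character(1))

  structure(list(atoms = atoms, chain_types = chain_types),
            class = "atom_model")
}

#' @export
print.atom_model <- function(x, ...) {
  cat(sprintf("atom_model: %d atoms, %d chains (%s)\n",
              nrow(x$atoms), length(x$chain_types),
              paste(sprintf("%s:%s", names(x$chain_types), x$chain_types),
                    collapse = ", ")))
  invisible(x)
}

#' Parse a coordinate model from PDB or mmCIF
#'
#' Thin wrapper over the bio3d readers. Alternate locations are resolved to
#' the highest-occupancy conformer (ties: first in file order); polymer type
#' is inferred from residue names.
#'
#' @param path path to a coordinate file.
#' @param format `"pdb"`, `"mmcif"`, or `"auto"` to infer from the file
#'   extension (`.cif`/`.mmcif` vs anything else).
#' @return An [atom_model].
#' @export
parse_model <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("model file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE))
      "mmcif" else "pdb"
  parsed <- tryCatch(
    if (format == "pdb") bio3d::read.pdb(path)
    else suppressWarnings(bio3d::read.cif(path)),
    error = function(e)
      stop("failed to parse ", format, " file '", path, "': ",
           conditionMessage(e), call. = FALSE))
  a <- parsed$atom
  atoms <- data.frame(chain = a$chain, resno = a$resno, insert = a$insert,
                      resid = a$resid, elety = a$elety, elesy = a$elesy,
                      x = a$x, y = a$y, z = a$z,
                      o = ifelse(is.na(a$o), 1, a$o),
                      b = ifelse(is.na(a$b), 0, a$b),
                      stringsAsFactors = FALSE)
  atoms$chain[is.na(atoms$chain)] <- "A"
  # resolve altlocs: keep the highest-occupancy copy of each named atom
  key <- paste(atoms$chain, atoms$resno,
               ifelse(is.na(atoms$insert), "", atoms$insert), atoms$elety)
  ord <- order(key, -atoms$o, seq_len(nrow(atoms)))
  atoms <- atoms[ord, , drop = FALSE]
  atoms <- atoms[!duplicated(key[ord]), , drop = FALSE]
  atom_model(atoms)
}

#' Classify chains as trace-only
#'
#' A chain is C-alpha-only when every residue consists of exactly one atom
#' named CA, and P-only when every residue is a single P atom. Chains with
#' any other composition (including mixed trace/full-atom chains) are not
#' traces.
#'
#' @param model an [atom_model].
#' @return A data frame with one row per chain: `chain`, `polymer`,
#'   `is_trace`, `trace_kind` (`"calpha-only"`, `"p-only"` or `"none"`).
#' @export
classify_trace <- function(model) {
  stopifnot(inherits(model, "atom_model"))
  rows <- lapply(names(model$chain_types), function(ch) {
    a <- model$atoms[model$atoms$chain == ch, , drop = FALSE]
    per_res <- split(a$elety, paste(a$resno, ifelse(is.na(a$insert), "", a$insert)))
    single <- all(lengths(per_res) == 1L)
    kind <- if (single && all(unlist(per_res) == "CA")) "calpha-only"
    else if (single && all(unlist(per_res) == "P")) "p-only"
    else "none"
    data.frame(chain = ch, polymer = unname(model$chain_types[ch]),
               is_trace = kind != "none", trace_kind = kind,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# residues of a chain that carry a given single atom name, ordered;
# returns data.frame(resno, insert, x, y, z) or NULL
chain_trace_atoms <- function(model, chain, atom_name) {
  a <- model$atoms
  a <- a[a$chain == chain & a$elety == atom_name, , drop = FALSE]
  if (nrow(a) == 0L) return(NULL)
  a[, c("resno", "insert", "x", "y", "z")]
}
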