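#' Interaction term names of a per-atom score table
#'
#' The eight per-atom interaction terms exported by the docking program for
#' every binding-site atom, in canonical column order. The first three
#' (ChemScore-derived) terms are reported with positive-is-favourable sign in
#' the raw export; the remaining five PLP terms use negative-is-favourable.
#' [make_padif()] normalizes all eight to negative-is-favourable.
#'
#' @return Character vector of length 8.
#' @export
#' @examples
#' padif_terms()
padif_terms <- function() {
  c("ChemScore_PLP.Hbond", "ChemScore_PLP.CHO", "ChemScore_PLP.Metal",
    "PLP.S(hbond)", "PLP.S(metal)", "PLP.S(buried)", "PLP.S(nonpolar)",
    "PLP.S(repulsive)")
}

# columns whose raw export sign is positive-is-favourable
.sign_reversed_terms <- 1:3

.atom_cols <- c("chain", "resnum", "icode", "atom_name")

#' Construct an atom key table
#'
#' Atom identity is (chain, residue number, insertion code, atom name) —
#' deliberately not the PDB serial number, which usually differs between
#' structures of the same protein and is the reason score tables from
#' different crystal structures must be re-mapped before fingerprint
#' comparison.
#'
#' @param chain Character vector of chain identifiers.
#' @param resnum Integer vector of residue numbers.
#' @param icode Character vector of insertion codes; `""` when absent.
#' @param atom_name Character vector of atom names (non-empty).
#' @return A data.frame with columns `chain`, `resnum`, `icode`, `atom_name`.
#' @export
atom_keys <- function(chain, resnum, icode = "", atom_name) {
  df <- data.frame(chain = as.character(chain),
                   resnum = as.integer(resnum),
                   icode = as.character(icode),
                   atom_name = as.character(atom_name),
                   stringsAsFactors = FALSE)
  validate_atom_keys(df)
  df
}

validate_atom_keys <- function(atoms, require_unique = TRUE) {
  if (!is.data.frame(atoms) || !all(.atom_cols %in% names(atoms)))
    stop("atom keys must be a data.frame with columns ",
         paste(.atom_cols, collapse = ", "), call. = FALSE)
  if (any(is.na(atoms$resnum)))
    stop("residue numbers must be integers", call. = FALSE)
  if (any(!nzchar(atoms$atom_name)))
    stop("atom_name must be non-empty", call. = FALSE)
  if (require_unique) {
    ids <- atom_key_id(atoms)
    if (anyDuplicated(ids))
      stop("duplicate atom key: ", ids[duplicated(ids)][1], call. = FALSE)
  }
  invisible(atoms)
}

#' Canonical string form of atom keys
#'
#' @param atoms Atom key data.frame (see [atom_keys()]).
#' @return Character vector `chain:resnum:icode:atom_name`, one per atom.
#' @export
atom_key_id <- function(atoms) {
  paste(atoms$chain, atoms$resnum, atoms$icode, atoms$atom_name, sep = ":")
}

#' Construct a per-atom score table
#'
#' An `atom_score_table` holds the raw per-atom score contributions of one
#' complex or docking pose: one row per binding-site atom, one column per
#' interaction term (see [padif_terms()]). Values carry the exporting
#' program's native sign convention; no normalization happens here.
#'
#' @param atoms Atom key data.frame, N rows (see [atom_keys()]).
#' @param values Numeric N x 8 matrix; columns must be named by
#'   [padif_terms()] in order, or unnamed (names are applied).
#' @param source_id Text label identifying the complex or pose.
#' @return Object of class `atom_score_table` with fields `atoms`, `values`,
#'   `source_id`.
#' @export
atom_score_table <- function(atoms, values, source_id = "") {
  validate_atom_keys(atoms)
  values <- as.matrix(values)
  if (nrow(atoms) < 1L) stop("a score table needs at least one atom", call. = FALSE)
  if (nrow(values) != nrow(atoms) || ncol(values) != 8L)
    stop("values must be an N x 8 matrix matching the atom list", call. = FALSE)
  if (!is.null(colnames(values)) && !identical(colnames(values), padif_terms()))
    stop("value columns must be the 8 canonical terms in order", call. = FALSE)
  if (!all(is.finite(values)))
    stop("score contributions must be finite", call. = FALSE)
  storage.mode(values) <- "double"
  dimnames(values) <- list(atom_key_id(atoms), padif_terms())
  structure(list(atoms = atoms, values = values,
                 source_id = as.character(source_id)[1]),
            class = "atom_score_table")
}

#' @export
print.atom_score_table <- function(x, ...) {
  cat(sprintf("<atom_score_table> %s: %d binding-site atoms x 8 terms (raw signs)\n",
              if (nzchar(x$source_id)) x$source_id else "(unnamed)",
              nrow(x$values)))
  invisible(x)
}

#' Construct a cavity atom list
#'
#' The ordered set of binding-site atoms that defines the row order of every
#' fingerprint derived for a given docking setup.
#'
#' @param atoms Atom key data.frame; duplicates are an error.
#' @return Object of class `cavity_atoms`.
#' @export
cavity_atoms <- function(atoms) {
  validate_atom_keys(atoms)
  if (nrow(atoms) < 1L) stop("cavity atom list must not be empty", call. = FALSE)
  structure(list(atoms = atoms), class = "cavity_atoms")
}

#' @export
print.cavity_atoms <- function(x, ...) {
  cat(sprintf("<cavity_atoms> %d binding-site atoms\n", nrow(x$atoms)))
  invisible(x)
}

same_atoms <- function(a, b) {
  identical(atom_key_id(a), atom_key_id(b))
}

first_atom_mismatch <- function(a, b) {
  ia <- atom_key_id(a); ib <- atom_key_id(b)
  if (length(ia) != length(ib)) return(sprintf("lengths differ (%d vs %d)", length(ia), length(ib)))
  k <- which(ia != ib)[1]
  sprintf("position %d: %s vs %s", k, ia[k], ib[k])
}
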