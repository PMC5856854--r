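#' @section File formats:
#' The canonical on-disk form of a score table is a TSV with header
#' `chain  resnum  icode  atom_name` followed by the eight term columns of
#' [padif_terms()], one row per binding-site atom, decimal points, no
#' thousands separators. Fingerprint files use the same layout preceded by a
#' `#signs:normalized` marker line. Cavity atom lists are header-less
#' four-column TSVs. The dialect is this package's own: the docking program's
#' native rescore/solution formats are treated as a future import adapter.
#' @name padifr-formats
#' @keywords internal
NULL

.table_header <- function() c(.atom_cols, padif_terms())

.read_tsv_lines <- function(path) {
  if (!file.exists(path))
    stop(structure(class = c("padifr_missing_file", "error", "condition"),
                   list(message = paste0("file not found: ", path), call = NULL)))
  readLines(path, warn = FALSE)
}

.split_fields <- function(line) strsplit(line, "\t", fixed = TRUE)[[1]]

.parse_atom_fields <- function(fields, path, lineno) {
  resnum <- suppressWarnings(as.integer(fields[2]))
  if (is.na(resnum))
    stop(sprintf("%s line %d: residue number '%s' is not an integer",
                 path, lineno, fields[2]), call. = FALSE)
  list(chain = fields[1], resnum = resnum, icode = fields[3],
       atom_name = fields[4])
}

.parse_score_body <- function(lines, path, first_lineno) {
  n <- length(lines)
  if (n == 0L) stop(path, ": no atom rows (N >= 1 required)", call. = FALSE)
  atoms <- data.frame(chain = character(n), resnum = integer(n),
                      icode = character(n), atom_name = character(n),
                      stringsAsFactors = FALSE)
  values <- matrix(NA_real_, n, 8L, dimnames = list(NULL, padif_terms()))
  for (i in seq_len(n)) {
    lineno <- first_lineno + i - 1L
    fields <- .split_fields(lines[i])
    if (length(fields) != 12L)
      stop(sprintf("%s line %d: expected 12 tab-separated fields, got %d",
                   path, lineno, length(fields)), call. = FALSE)
    ak <- .parse_atom_fields(fields, path, lineno)
    atoms$chain[i] <- ak$chain; atoms$resnum[i] <- ak$resnum
    atoms$icode[i] <- ak$icode; atoms$atom_name[i] <- ak$atom_name
    v <- suppressWarnings(as.numeric(fields[5:12]))
    if (anyNA(v))
      stop(sprintf("%s line %d: non-numeric score value '%s'",
                   path, lineno, fields[5:12][which(is.na(v))[1]]),
           call. = FALSE)
    values[i, ] <- v
  }
  ids <- atom_key_id(atoms)
  if (anyDuplicated(ids)) {
    d <- which(duplicated(ids))[1]
    stop(sprintf("%s line %d: duplicate atom key %s",
                 path, first_lineno + d - 1L, ids[d]), call. = FALSE)
  }
  list(atoms = atoms, values = values)
}

.check_header <- function(fields, path, lineno) {
  expect <- .table_header()
  if (length(fields) != length(expect) || !all(fields == expect)) {
    bad <- setdiff(expect, fields)
    msg <- if (length(bad)) paste0("missing column(s): ", paste(bad, collapse = ", "))
           else "columns out of order or extraneous"
    stop(sprintf("%s line %d: malformed header (%s)", path, lineno, msg),
         call. = FALSE)
  }
}

#' Read a per-atom score table
#'
#' Reads the canonical TSV export of per-atom score contributions for one
#' complex or pose (see the package format notes). Values are taken verbatim;
#' sign normalization is a separate step ([make_padif()]).
#'
#' @param path Path to a score-table TSV.
#' @param source_id Label for the table; defaults to the file name without
#'   extension.
#' @param dialect Only `"tsv"` is currently defined.
#' @return An [atom_score_table()].
#' @export
read_atom_score_table <- function(path, source_id = NULL, dialect = "tsv") {
  if (!identical(dialect, "tsv"))
    stop("unknown dialect: ", dialect, call. = FALSE)
  lines <- .read_tsv_lines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop(path, ": empty file", call. = FALSE)
  if (startsWith(lines[1], "#"))
    stop(path, ": found a fingerprint marker; use read_padif() for normalized files",
         call. = FALSE)
  .check_header(.split_fields(lines[1]), path, 1L)
  body <- .parse_score_body(lines[-1], path, 2L)
  if (is.null(source_id))
    source_id <- tools::file_path_sans_ext(basename(path))
  atom_score_table(body$atoms, body$values, source_id)
}

.format_num <- function(x) {
  # shortest decimal form that round-trips the double exactly: %.15g when it
  # re-reads bit-identically, %.17g (always exact) otherwise
  s <- sprintf("%.15g", x)
  bad <- as.numeric(s) != x
  s[bad] <- sprintf("%.17g", x[bad])
  s
}

.write_table_body <- function(atoms, values, con) {
  rows <- paste(atoms$chain, atoms$resnum, atoms$icode, atoms$atom_name,
                apply(values, 1L, function(v) paste(.format_num(v), collapse = "\t")),
                sep = "\t")
  writeLines(rows, con)
}

#' Write a per-atom score table
#'
#' @param table An [atom_score_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_atom_score_table <- function(table, path) {
  stopifnot(inherits(table, "atom_score_table"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste(.table_header(), collapse = "\t"), con)
  .write_table_body(table$atoms, table$values, con)
  invisible(path)
}

#' Read a cavity atom list
#'
#' One `chain<TAB>resnum<TAB>icode<TAB>atom_name` row per binding-site atom,
#' no header. Order is preserved: it defines the row order of all derived
#' fingerprints.
#'
#' @param path Path to a cavity-atom TSV.
#' @return A [cavity_atoms()] object.
#' @export
read_cavity_atoms <- function(path) {
  lines <- .read_tsv_lines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L)
    stop(path, ": empty cavity atom list (N >= 1 required)", call. = FALSE)
  n <- length(lines)
  atoms <- data.frame(chain = character(n), resnum = integer(n),
                      icode = character(n), atom_name = character(n),
                      stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    fields <- .split_fields(lines[i])
    if (length(fields) != 4L)
      stop(sprintf("%s line %d: expected 4 tab-separated fields, got %d",
                   path, i, length(fields)), call. = FALSE)
    ak <- .parse_atom_fields(fields, path, i)
    atoms$chain[i] <- ak$chain; atoms$resnum[i] <- ak$resnum
    atoms$icode[i] <- ak$icode; atoms$atom_name[i] <- ak$atom_name
  }
  ids <- atom_key_id(atoms)
  if (anyDuplicated(ids)) {
    d <- which(duplicated(ids))[1]
    stop(sprintf("%s line %d: duplicate cavity atom %s", path, d, ids[d]),
         call. = FALSE)
  }
  cavity_atoms(atoms)
}

#' Write a cavity atom list
#'
#' @param cavity A [cavity_atoms()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cavity_atoms <- function(cavity, path) {
  stopifnot(inherits(cavity, "cavity_atoms"))
  a <- cavity$atoms
  writeLines(paste(a$chain, a$resnum, a$icode, a$atom_name, sep = "\t"), path)
  invisible(path)
}

#' Map atoms between two cavity lists
#'
#' Matches atoms of a reference structure's cavity list to a docking
#' structure's cavity list by exact (chain, residue number, insertion code,
#' atom name) identity. This replaces the renumbering step needed because
#' atom serial numbering usually differs between crystal structures of the
#' same protein.
#'
#' @param ref [cavity_atoms()] of the reference structure.
#' @param target [cavity_atoms()] of the docking structure.
#' @return Object of class `atom_map` with fields `pairs` (data.frame
#'   `ref_index`, `target_index`) and `unmatched` (character vector of
#'   reference atom ids with no counterpart).
#' @export
build_atom_map <- function(ref, target) {
  stopifnot(inherits(ref, "cavity_atoms"), inherits(target, "cavity_atoms"))
  rid <- atom_key_id(ref$atoms)
  tid <- atom_key_id(target$atoms)
  if (anyDuplicated(tid))
    stop("ambiguous match: duplicate atom key in target: ",
         tid[duplicated(tid)][1], call. = FALSE)
  hit <- match(rid, tid)
  matched <- !is.na(hit)
  structure(list(
    pairs = data.frame(ref_index = which(matched),
                       target_index = hit[matched]),
    unmatched = rid[!matched]
  ), class = "atom_map")
}

#' @export
print.atom_map <- function(x, ...) {
  cat(sprintf("<atom_map> %d atoms mapped, %d reference atoms unmatched\n",
              nrow(x$pairs), length(x$unmatched)))
  invisible(x)
}

#' Renumber a score table onto a target cavity ordering
#'
#' Reorders (and relabels) the rows of a reference score table so that row m
#' refers to the same physical atom as row m of any table produced for the
#' docking structure. Target atoms with no mapped reference counterpart get
#' all-zero rows: zero is the "no interaction observed" value of the
#' fingerprint, so an unmapped atom simply contributes nothing.
#'
#' @param table [atom_score_table()] whose atoms are those of the reference
#'   cavity the map was built from.
#' @param map [build_atom_map()] result (reference -> target).
#' @param target_order [cavity_atoms()] of the docking structure; defines the
#'   output row order.
#' @return An [atom_score_table()] over `target_order`'s atoms.
#' @export
renumber_table <- function(table, map, target_order) {
  stopifnot(inherits(table, "atom_score_table"), inherits(map, "atom_map"),
            inherits(target_order, "cavity_atoms"))
  if (nrow(map$pairs) > 0 && max(map$pairs$ref_index) > nrow(table$atoms))
    stop("atom map was not built against this table's atom list", call. = FALSE)
  n_t <- nrow(target_order$atoms)
  out <- matrix(0, n_t, 8L, dimnames = list(NULL, padif_terms()))
  if (nrow(map$pairs) > 0)
    out[map$pairs$target_index, ] <- table$values[map$pairs$ref_index, , drop = FALSE]
  atom_score_table(target_order$atoms, out, table$source_id)
}

#' Read / write a sign-normalized fingerprint
#'
#' Fingerprint files use the score-table TSV layout preceded by a
#' `#signs:normalized` marker line, recording that all eight columns are on
#' the negative-is-favourable convention.
#'
#' @param path File path.
#' @param source_id Optional label; defaults to the file name.
#' @return `read_padif()` returns a [`padif`][make_padif] object.
#' @export
read_padif <- function(path, source_id = NULL) {
  lines <- .read_tsv_lines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L || !identical(lines[1], "#signs:normalized"))
    stop(path, ": missing '#signs:normalized' marker; not a fingerprint file",
         call. = FALSE)
  .check_header(.split_fields(lines[2]), path, 2L)
  body <- .parse_score_body(lines[-(1:2)], path, 3L)
  if (is.null(source_id))
    source_id <- tools::file_path_sans_ext(basename(path))
  new_padif(body$atoms, body$values, source_id)
}

#' @rdname read_padif
#' @param padif A [`padif`][make_padif] object.
#' @export
write_padif <- function(padif, path) {
  stopifnot(inherits(padif, "padif"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("#signs:normalized", paste(.table_header(), collapse = "\t")), con)
  .write_table_body(padif$atoms, padif$values, con)
  invisible(path)
}

#' Read / write a merged reference fingerprint
#'
#' A reference fingerprint is serialized as two parallel TSV matrices over
#' the same atoms: the median fingerprint (a normal fingerprint file) and the
#' weighting matrix, whose header carries the number of merged references in
#' a `#n_references:` marker.
#'
#' @param median_path Path of the median-fingerprint file.
#' @param weights_path Path of the weighting-matrix file.
#' @return `read_reference_padif()` returns a
#'   [`reference_padif`][merge_references] object.
#' @export
read_reference_padif <- function(median_path, weights_path) {
  med <- read_padif(median_path)
  lines <- .read_tsv_lines(weights_path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 3L || !identical(lines[1], "#weights"))
    stop(weights_path, ": missing '#weights' marker", call. = FALSE)
  nref <- suppressWarnings(as.integer(sub("^#n_references:", "", lines[2])))
  if (is.na(nref) || nref < 1L)
    stop(weights_path, ": missing or invalid '#n_references:' marker", call. = FALSE)
  .check_header(.split_fields(lines[3]), weights_path, 3L)
  body <- .parse_score_body(lines[-(1:3)], weights_path, 4L)
  if (!same_atoms(med$atoms, body$atoms))
    stop("median and weight files disagree on atoms: ",
         first_atom_mismatch(med$atoms, body$atoms), call. = FALSE)
  new_reference_padif(med$atoms, med$values, body$values, nref)
}

#' @rdname read_reference_padif
#' @param ref A [`reference_padif`][merge_references] object.
#' @export
write_reference_padif <- function(ref, median_path, weights_path) {
  stopifnot(inherits(ref, "reference_padif"))
  write_padif(new_padif(ref$atoms, ref$median_values, "reference_median"),
              median_path)
  con <- file(weights_path, "w"); on.exit(close(con))
  writeLines(c("#weights",
               sprintf("#n_references:%d", ref$n_references),
               paste(.table_header(), collapse = "\t")), con)
  .write_table_body(ref$atoms, ref$weights, con)
  invisible(c(median_path, weights_path))
}
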