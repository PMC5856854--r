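new_padif <- function(atoms, values, source_id = "") {
  if (!all(is.finite(values))) stop("fingerprint values must be finite", call. = FALSE)
  storage.mode(values) <- "double"
  dimnames(values) <- list(atom_key_id(atoms), padif_terms())
  structure(list(atoms = atoms, values = values,
                 source_id = as.character(source_id)[1]),
            class = "padif")
}

#' Build a sign-normalized fingerprint from a raw score table
#'
#' Converts the raw per-atom score contributions of one complex or docking
#' pose into a PADIF: an N x 8 matrix in which a strictly negative value
#' always means a favourable interaction. The exporting program reports the
#' three ChemScore-derived terms (Hbond, CHO, Metal) with the opposite
#' convention — positive is favourable — so those three columns are negated;
#' the five PLP terms are already negative-is-favourable and are copied
#' unchanged. Applying the same sign map again restores the raw table.
#'
#' @param table An [atom_score_table()].
#' @return Object of class `padif` with fields `atoms` (unchanged order),
#'   `values` (N x 8, negative = favourable), `source_id`.
#' @seealso [merge_references()], [score_pose()]
#' @export
#' @examples
#' tab <- atom_score_table(atom_keys("A", 1:2, "", c("CA", "CB")),
#'                         matrix(c(2.5, rep(0, 15)), 2, 8, byrow = TRUE))
#' make_padif(tab)$values[1, 1]  # raw +2.5 Hbond becomes favourable -2.5
make_padif <- function(table) {
  stopifnot(inherits(table, "atom_score_table"))
  v <- table$values
  v[, .sign_reversed_terms] <- -v[, .sign_reversed_terms]
  new_padif(table$atoms, v, table$source_id)
}

#' @export
print.padif <- function(x, ...) {
  cat(sprintf("<padif> %s: %d atoms x 8 terms, %d favourable element(s)\n",
              if (nzchar(x$source_id)) x$source_id else "(unnamed)",
              nrow(x$values), sum(x$values < 0)))
  invisible(x)
}

new_reference_padif <- function(atoms, median_values, weights, n_references) {
  storage.mode(median_values) <- "double"
  storage.mode(weights) <- "double"
  dimnames(median_values) <- dimnames(weights) <- list(atom_key_id(atoms), padif_terms())
  stopifnot(all(median_values <= 0), all(weights >= 0), all(weights <= 1),
            identical((median_values < 0), (weights > 0)))
  structure(list(atoms = atoms, median_values = median_values,
                 weights = weights, n_references = as.integer(n_references)),
            class = "reference_padif")
}

#' Merge reference fingerprints into a median fingerprint with weights
#'
#' Combines the fingerprints of one or more experimentally determined
#' reference complexes into a single consensus. For each fingerprint element
#' (atom, term) only the favourable (strictly negative) reference values are
#' considered: their median becomes the consensus strength, and the fraction
#' of references in which the element is favourable becomes its weighting
#' factor. An element favourable in four of ten references thus gets weight
#' 0.4. If no reference value is negative at an element, both the median and
#' the weight are 0 — positive (repulsive) reference values contribute
#' nothing. With an even number of favourable values the median is the mean
#' of the two central ones.
#'
#' @param padifs List of [`padif`][make_padif] objects sharing one atom list
#'   and order (use [renumber_table()] first if they come from differently
#'   numbered structures).
#' @return Object of class `reference_padif`: `atoms`, `median_values`
#'   (N x 8, all <= 0), `weights` (N x 8, in `[0, 1]`, positive exactly where
#'   the median is negative), `n_references`.
#' @export
#' @examples
#' keys <- atom_keys("A", 1, "", "CA")
#' refs <- lapply(c(-1, -3, 2), function(v)
#'   make_padif(atom_score_table(keys, matrix(c(0, 0, 0, v, 0, 0, 0, 0), 1))))
#' m <- merge_references(refs)
#' m$median_values[1, 4]  # median of {-1, -3} = -2
#' m$weights[1, 4]        # favourable in 2 of 3 references
merge_references <- function(padifs) {
  if (!is.list(padifs) || length(padifs) < 1L)
    stop("need at least one reference fingerprint", call. = FALSE)
  if (!all(vapply(padifs, inherits, logical(1), "padif")))
    stop("all references must be padif objects", call. = FALSE)
  atoms <- padifs[[1]]$atoms
  for (p in padifs[-1])
    if (!same_atoms(atoms, p$atoms))
      stop("reference fingerprints have mismatched atom lists: ",
           first_atom_mismatch(atoms, p$atoms), call. = FALSE)
  k <- length(padifs)
  arr <- array(unlist(lapply(padifs, `[[`, "values"), use.names = FALSE),
               dim = c(nrow(atoms), 8L, k))
  fav <- arr < 0
  counts <- apply(fav, c(1L, 2L), sum)
  arr[!fav] <- NA_real_
  med <- suppressWarnings(apply(arr, c(1L, 2L), stats::median, na.rm = TRUE))
  med[counts == 0L] <- 0
  new_reference_padif(atoms, med, counts / k, k)
}

#' @export
print.reference_padif <- function(x, ...) {
  cat(sprintf("<reference_padif> %d atoms x 8 terms, merged from %d reference(s); %d favourable element(s)\n",
              nrow(x$median_values), x$n_references, sum(x$median_values < 0)))
  invisible(x)
}

#' Favourable elements of a fingerprint
#'
#' The set of (atom, term) elements with a strictly negative value — the
#' favourable interactions. Exact zero means "no interaction" and positive
#' means repulsive; neither is returned.
#'
#' @param p A [`padif`][make_padif] or [`reference_padif`][merge_references]
#'   (for the latter, the median fingerprint is scanned).
#' @return Integer matrix with columns `atom` and `term`, ordered by atom
#'   then term index.
#' @export
favourable_elements <- function(p) {
  v <- if (inherits(p, "reference_padif")) p$median_values
       else if (inherits(p, "padif")) p$values
       else stop("p must be a padif or reference_padif", call. = FALSE)
  idx <- which(v < 0, arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  dimnames(idx) <- list(NULL, c("atom", "term"))
  idx
}
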