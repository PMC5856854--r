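#' ROC AUC of an active/decoy ranking
#'
#' Area under the receiver operating characteristic curve: the probability
#' that a randomly chosen active is scored above a randomly chosen decoy.
#' Computed via the Mann-Whitney U statistic normalized by
#' `n_active * n_decoy`, with tied scores contributing 1/2 (mid-rank
#' handling). Invariant under any strictly monotone transform of the scores.
#'
#' @param score Numeric vector of scores, higher = better.
#' @param is_active Logical vector of the same length.
#' @return AUC in `[0, 1]`.
#' @export
#' @examples
#' roc_auc(c(3, 2, 1, 0), c(TRUE, TRUE, FALSE, FALSE))  # perfect: 1
roc_auc <- function(score, is_active) {
  stopifnot(length(score) == length(is_active))
  is_active <- as.logical(is_active)
  n_act <- sum(is_active); n_dec <- sum(!is_active)
  if (n_act == 0L || n_dec == 0L)
    stop("AUC needs at least one active and one decoy", call. = FALSE)
  r <- rank(score)  # mid-ranks for ties
  (sum(r[is_active]) - n_act * (n_act + 1) / 2) / (n_act * n_dec)
}

#' Enrichment factor at a fraction of the ranked list
#'
#' `EF = (a_top / n_top) / (A / K)`: the active rate among the best
#' `n_top = ceiling(fraction * K)` scored entries relative to the active rate
#' in the whole set of K entries with A actives. `EF_1%` and `EF_3%`
#' (`fraction` 0.01 and 0.03) are the usual early-enrichment summaries; at
#' `fraction = 1` the factor is exactly 1 for any labelling. Ties are broken
#' by id lexicographically, as in [rank_by_score()].
#'
#' @param score Numeric vector of scores, higher = better.
#' @param is_active Logical vector of the same length.
#' @param fraction Fraction of the list counted as "top", in `(0, 1]`.
#' @param id Optional character ids used only for deterministic tie-breaks;
#'   defaults to the element order.
#' @return Non-negative enrichment factor.
#' @export
#' @examples
#' # 2 actives at ranks 1-2 of 10; top 10% holds 1 entry, an active: EF = 5
#' enrichment_factor(10:1, c(TRUE, TRUE, rep(FALSE, 8)), 0.1)
enrichment_factor <- function(score, is_active, fraction, id = NULL) {
  stopifnot(length(score) == length(is_active))
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1)
    stop("fraction must be in (0, 1]", call. = FALSE)
  is_active <- as.logical(is_active)
  K <- length(score)
  A <- sum(is_active)
  if (A == 0L) stop("enrichment factor needs at least one active", call. = FALSE)
  if (is.null(id)) id <- sprintf("%0*d", nchar(K), seq_len(K))
  o <- .rank_order(score, as.character(id))
  n_top <- ceiling(fraction * K)
  a_top <- sum(is_active[o[seq_len(n_top)]])
  (a_top / n_top) / (A / K)
}

#' ROC curve points
#'
#' False-positive and true-positive rates along the ranked list, one point
#' per distinct score threshold, beginning at (0, 0) and ending at (1, 1).
#'
#' @inheritParams roc_auc
#' @return data.frame with columns `fpr`, `tpr`.
#' @export
roc_points <- function(score, is_active) {
  stopifnot(length(score) == length(is_active))
  is_active <- as.logical(is_active)
  n_act <- sum(is_active); n_dec <- sum(!is_active)
  if (n_act == 0L || n_dec == 0L)
    stop("ROC needs at least one active and one decoy", call. = FALSE)
  o <- order(-score)
  s <- score[o]; a <- is_active[o]
  keep <- c(s[-1] != s[-length(s)], TRUE)  # last index of each tie group
  data.frame(fpr = c(0, cumsum(!a)[keep] / n_dec),
             tpr = c(0, cumsum(a)[keep] / n_act))
}

#' Summarize a labelled screen
#'
#' Convenience wrapper computing the AUC and enrichment factors at the
#' requested fractions in one call.
#'
#' @inheritParams enrichment_factor
#' @param fractions Numeric vector of enrichment fractions; default `c(0.01,
#'   0.03)`, the usual virtual-screening reporting points.
#' @return One-row data.frame: `auc`, then one `ef_<pct>%` column per
#'   fraction.
#' @export
screen_summary <- function(score, is_active, fractions = c(0.01, 0.03),
                           id = NULL) {
  out <- data.frame(auc = roc_auc(score, is_active))
  for (f in fractions) {
    col <- sprintf("ef_%g%%", 100 * f)
    out[[col]] <- enrichment_factor(score, is_active, f, id = id)
  }
  out
}
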