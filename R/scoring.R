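#' Score a docking pose against a merged reference fingerprint
#'
#' Implements the overlap-penalized fingerprint similarity score. With R the
#' number of favourable elements in the reference median fingerprint and P
#' the number of favourable elements in the pose fingerprint:
#' \describe{
#'   \item{O_max}{`min(P / R, 1)` — the best overlap the pose could achieve
#'     given how many favourable interactions it makes at all.}
#'   \item{S(m, n)}{over the R reference elements only: `+w(m, n)` if the
#'     pose value is negative, `0` if exactly zero, `-w(m, n)` if positive
#'     (the pose is repulsive where the references are favourable).}
#'   \item{O_real}{`|P intersect R| / R`.}
#'   \item{O_rel}{`O_real / O_max`.}
#'   \item{S_tot}{`sum(S) - (1 - O_rel) * |sum(S)|`.}
#' }
#' The relative-overlap penalty makes the score fair to small ligands: a pose
#' whose few favourable interactions all fall inside the reference pattern
#' has `O_rel = 1` and keeps its full raw score, instead of losing out to
#' large molecules that blanket the site. The score depends only on the signs
#' of the pose values and on the reference weights, never on pose magnitudes.
#'
#' A pose with no favourable interaction at all (P = 0) leaves `O_rel`
#' undefined (0/0); this implementation takes `O_rel = 0`, so
#' `S_tot = 2 * sum(S) <= 0` and interaction-free poses rank at the bottom.
#'
#' @param ref A [`reference_padif`][merge_references]. Must contain at least
#'   one favourable element (R >= 1), otherwise the score is undefined and an
#'   error is raised.
#' @param pose A [`padif`][make_padif] over the same atom list and order.
#' @return Object of class `padif_score`: a list with `R`, `P`,
#'   `overlap_count`, `O_max`, `O_real`, `O_rel`, `sum_S`, `S_tot`.
#' @export
#' @examples
#' keys <- atom_keys("A", 1:2, "", c("CA", "CB"))
#' raw <- matrix(0, 2, 8); raw[1, 4] <- -1.2; raw[2, 6] <- -0.8
#' ref <- merge_references(list(make_padif(atom_score_table(keys, raw, "1abc"))))
#' pose <- make_padif(atom_score_table(keys, raw, "pose_1"))
#' score_pose(ref, pose)  # perfect match: S_tot = sum of weights = 2
score_pose <- function(ref, pose) {
  stopifnot(inherits(ref, "reference_padif"), inherits(pose, "padif"))
  if (!same_atoms(ref$atoms, pose$atoms))
    stop("reference and pose atom lists differ: ",
         first_atom_mismatch(ref$atoms, pose$atoms), call. = FALSE)
  ref_fav <- ref$median_values < 0
  R <- sum(ref_fav)
  if (R == 0L)
    stop("reference fingerprint has no favourable element (R = 0); score undefined",
         call. = FALSE)
  pose_fav <- pose$values < 0
  P <- sum(pose_fav)
  overlap <- sum(ref_fav & pose_fav)
  O_max <- min(P / R, 1)
  O_real <- overlap / R
  O_rel <- if (O_max == 0) 0 else O_real / O_max
  w <- ref$weights[ref_fav]
  pv <- pose$values[ref_fav]
  sum_S <- sum(w * sign(-pv))  # +w where pose < 0, 0 at 0, -w where pose > 0
  S_tot <- sum_S - (1 - O_rel) * abs(sum_S)
  structure(list(R = R, P = P, overlap_count = overlap,
                 O_max = O_max, O_real = O_real, O_rel = O_rel,
                 sum_S = sum_S, S_tot = S_tot),
            class = "padif_score")
}

#' @export
print.padif_score <- function(x, ...) {
  cat(sprintf(
    "<padif_score> R=%d P=%d overlap=%d | O_max=%.3f O_real=%.3f O_rel=%.3f | sum_S=%.4f S_tot=%.4f\n",
    x$R, x$P, x$overlap_count, x$O_max, x$O_real, x$O_rel, x$sum_S, x$S_tot))
  invisible(x)
}

#' Score many poses against one reference fingerprint
#'
#' @param ref A [`reference_padif`][merge_references].
#' @param poses List of [`padif`][make_padif] objects; names (or the poses'
#'   `source_id`s) become the `pose_id` column.
#' @return data.frame with columns `pose_id`, `R`, `P`, `overlap`, `O_max`,
#'   `O_real`, `O_rel`, `sum_S`, `S_tot`, one row per pose.
#' @export
score_poses <- function(ref, poses) {
  ids <- names(poses)
  if (is.null(ids))
    ids <- vapply(poses, `[[`, character(1), "source_id")
  if (anyDuplicated(ids) || any(!nzchar(ids)))
    stop("poses need unique non-empty ids", call. = FALSE)
  rows <- lapply(poses, function(p) {
    s <- score_pose(ref, p)
    data.frame(R = s$R, P = s$P, overlap = s$overlap_count,
               O_max = s$O_max, O_real = s$O_real, O_rel = s$O_rel,
               sum_S = s$sum_S, S_tot = s$S_tot)
  })
  out <- do.call(rbind, rows)
  out <- cbind(data.frame(pose_id = ids, stringsAsFactors = FALSE), out)
  rownames(out) <- NULL
  out
}

.rank_order <- function(score, id) {
  # descending score, ties broken by id in C-locale lexicographic order
  order(-score, id, method = "radix")
}

#' Rank poses by score
#'
#' Higher score is better (docking-fitness convention). Ties are broken by
#' pose id in lexicographic (C locale) order so rankings are reproducible.
#'
#' @param scores Named numeric vector of scores (names are pose ids).
#' @return data.frame `pose_id`, `score`, `rank` (1 = best), in rank order.
#' @export
rank_by_score <- function(scores) {
  if (length(scores) == 0L) stop("no scores to rank", call. = FALSE)
  ids <- names(scores)
  if (is.null(ids) || anyDuplicated(ids) || any(!nzchar(ids)))
    stop("scores must be named with unique non-empty pose ids", call. = FALSE)
  o <- .rank_order(scores, ids)
  data.frame(pose_id = ids[o], score = unname(scores[o]),
             rank = seq_along(scores), stringsAsFactors = FALSE)
}

#' Combine a conventional and a fingerprint ranking
#'
#' Produces the combined ranking used for virtual screening: the head of the
#' list is the best `top_fraction` of poses by the conventional (docking)
#' score, in conventional-score order; all remaining poses follow, ordered by
#' their fingerprint score. The head block captures the conventional score's
#' strong early enrichment while the fingerprint orders the bulk of the list.
#' The head size is `ceiling(top_fraction * K)`, so at least one pose is
#' always taken from the conventional ranking.
#'
#' @param conventional Named numeric vector of conventional (e.g. docking
#'   fitness) scores; higher is better.
#' @param padif Named numeric vector of fingerprint scores over exactly the
#'   same pose ids.
#' @param top_fraction Fraction of the list taken from the conventional
#'   ranking; default 0.03 (the best three percent).
#' @return data.frame `pose_id`, `rank`, `block` (`"conventional"` or
#'   `"padif"`), `conventional`, `padif`, in combined-rank order.
#' @export
combined_rank <- function(conventional, padif, top_fraction = 0.03) {
  if (!is.numeric(top_fraction) || top_fraction <= 0 || top_fraction >= 1)
    stop("top_fraction must be in (0, 1)", call. = FALSE)
  cid <- names(conventional); pid <- names(padif)
  if (is.null(cid) || is.null(pid) || anyDuplicated(cid) || anyDuplicated(pid))
    stop("both score vectors must be named with unique pose ids", call. = FALSE)
  if (!setequal(cid, pid))
    stop("conventional and fingerprint rankings cover different pose ids",
         call. = FALSE)
  padif <- padif[cid]  # align
  K <- length(conventional)
  n_top <- ceiling(top_fraction * K)
  o_conv <- .rank_order(conventional, cid)
  head_idx <- o_conv[seq_len(n_top)]
  rest <- setdiff(seq_len(K), head_idx)
  o_rest <- rest[.rank_order(padif[rest], cid[rest])]
  idx <- c(head_idx, o_rest)
  data.frame(pose_id = cid[idx],
             rank = seq_len(K),
             block = rep(c("conventional", "padif"), c(n_top, K - n_top)),
             conventional = unname(conventional[idx]),
             padif = unname(padif[idx]),
             stringsAsFactors = FALSE)
}
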