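# Independent brute-force evaluation of the pose score: walks every one of
# the 8N fingerprint elements with explicit loops and the published case
# split, never touching the package's vectorized path.
oracle_score <- function(median_values, weights, pose_values) {
  N <- nrow(median_values)
  R <- 0L; P <- 0L; ov <- 0L
  for (m in seq_len(N)) for (n in 1:8) {
    if (median_values[m, n] < 0) R <- R + 1L
    if (pose_values[m, n] < 0) P <- P + 1L
    if (median_values[m, n] < 0 && pose_values[m, n] < 0) ov <- ov + 1L
  }
  stopifnot(R >= 1L)
  S <- 0
  for (m in seq_len(N)) for (n in 1:8) {
    if (median_values[m, n] < 0) {
      if (pose_values[m, n] < 0) S <- S + unname(weights[m, n])
      else if (pose_values[m, n] > 0) S <- S - unname(weights[m, n])
    }
  }
  O_max <- min(P / R, 1)
  O_real <- ov / R
  O_rel <- if (O_max == 0) 0 else O_real / O_max
  list(R = R, P = P, overlap = ov, O_max = O_max, O_real = O_real,
       O_rel = O_rel, sum_S = S, S_tot = S - (1 - O_rel) * abs(S))
}

# Pairwise O(n^2) AUC oracle: fraction of active-decoy pairs won, ties 1/2.
oracle_auc <- function(score, is_active) {
  a <- score[is_active]; d <- score[!is_active]
  tot <- 0
  for (x in a) for (y in d)
    tot <- tot + if (x > y) 1 else if (x == y) 0.5 else 0
  tot / (length(a) * length(d))
}

test_keys <- function(n) {
  atom_keys(chain = "A", resnum = seq_len(n), icode = "", atom_name = "CA")
}

# normalized fingerprint with random sign pattern:
# P(neg) = p_neg, P(pos) = p_pos, rest exactly 0
random_padif <- function(keys, p_neg = 0.3, p_pos = 0.1, id = "pose") {
  n <- nrow(keys)
  u <- matrix(stats::runif(n * 8), n, 8)
  mag <- matrix(abs(stats::rnorm(n * 8)) + 0.1, n, 8)
  v <- matrix(0, n, 8)
  v[u < p_neg] <- -mag[u < p_neg]
  v[u > 1 - p_pos] <- mag[u > 1 - p_pos]
  padifr:::new_padif(keys, v, id)
}

# merged reference over random fingerprints, redrawn until R >= 1
random_reference <- function(keys, n_refs = 3, p_neg = 0.3, p_pos = 0.1) {
  repeat {
    refs <- lapply(seq_len(n_refs), function(i)
      random_padif(keys, p_neg, p_pos, sprintf("ref_%d", i)))
    ref <- merge_references(refs)
    if (any(ref$median_values < 0)) return(ref)
  }
}

# raw score table whose normalized form has the given favourable elements
# (matrix of atom/term) and optional positive values elsewhere
table_with_pattern <- function(keys, fav_elements,
                               repulsive_elements = NULL, id = "tab") {
  v <- matrix(0, nrow(keys), 8)
  flip <- function(term, x) ifelse(term <= 3, -x, x)  # normalized -> raw
  if (!is.null(fav_elements) && nrow(fav_elements) > 0)
    v[fav_elements] <- flip(fav_elements[, 2], -1)
  if (!is.null(repulsive_elements) && nrow(repulsive_elements) > 0)
    v[repulsive_elements] <- flip(repulsive_elements[, 2], 1)
  atom_score_table(keys, v, id)
}

el <- function(...) matrix(c(...), ncol = 2, byrow = TRUE,
                           dimnames = list(NULL, c("atom", "term")))
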