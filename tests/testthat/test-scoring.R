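# reference with prescribed weights via repetition counts over 10 references:
# elements (1,4), (2,5), (3,6) favourable in 10, 5 and 4 references
make_worked_reference <- function(keys) {
  counts <- c(10, 5, 4)
  elements <- el(1, 4, 2, 5, 3, 6)
  refs <- lapply(1:10, function(i) {
    fav <- elements[counts >= i, , drop = FALSE]
    make_padif(table_with_pattern(keys, fav, id = sprintf("r%02d", i)))
  })
  merge_references(refs)
}

test_that("a pose matching the full reference pattern scores the weight sum", {
  keys <- test_keys(3)
  ref <- make_worked_reference(keys)
  pose <- make_padif(table_with_pattern(keys, el(1, 4, 2, 5, 3, 6), id = "p"))
  s <- score_pose(ref, pose)
  expect_equal(s$R, 3); expect_equal(s$P, 3)
  expect_equal(s$O_max, 1); expect_equal(s$O_real, 1); expect_equal(s$O_rel, 1)
  expect_equal(s$S_tot, 1.0 + 0.5 + 0.4)
})

test_that("a partially matching pose is penalized by its relative overlap", {
  keys <- test_keys(3)
  ref <- make_worked_reference(keys)  # weights 1.0, 0.5, 0.4
  # favourable at the first two reference elements plus one non-reference
  # element; repulsive (+0.2 normalized) at the third reference element
  raw <- table_with_pattern(keys, el(1, 4, 2, 5, 1, 7),
                            repulsive_elements = el(3, 6), id = "p")
  raw$values[3, 6] <- 0.2  # term 6 is not sign-reversed: raw = normalized
  s <- score_pose(ref, make_padif(raw))
  expect_equal(s$R, 3); expect_equal(s$P, 3); expect_equal(s$overlap_count, 2)
  expect_equal(s$sum_S, 1.0 + 0.5 - 0.4)
  expect_equal(s$O_max, 1)
  expect_equal(s$O_real, 2 / 3)
  expect_equal(s$O_rel, 2 / 3)
  expect_equal(s$S_tot, 1.1 - (1 / 3) * 1.1)
})

test_that("an interaction-free pose scores zero and a favourable-free reference errors", {
  keys <- test_keys(3)
  ref <- make_worked_reference(keys)
  empty <- make_padif(table_with_pattern(keys, NULL, id = "p"))
  s <- score_pose(ref, empty)
  expect_equal(s$P, 0)
  expect_equal(s$sum_S, 0)
  expect_equal(s$S_tot, 0)

  norefs <- merge_references(list(make_padif(table_with_pattern(keys, NULL))))
  expect_error(score_pose(norefs, empty), "R = 0")

  other <- make_padif(table_with_pattern(
    cavity_atoms(atom_keys("B", 1:3, "", "CA"))$atoms, el(1, 4)))
  expect_error(score_pose(ref, other), "atom lists differ.*B:1::CA")
})

test_that("score_pose agrees with the element-by-element brute-force oracle", {
  set.seed(101)
  for (i in 1:200) {
    keys <- test_keys(sample(1:5, 1))
    ref <- random_reference(keys, n_refs = sample(1:4, 1))
    pose <- random_padif(keys, p_neg = runif(1, 0, 0.5), p_pos = runif(1, 0, 0.3))
    got <- score_pose(ref, pose)
    want <- oracle_score(ref$median_values, ref$weights, pose$values)
    expect_equal(got$R, want$R); expect_equal(got$P, want$P)
    expect_equal(got$overlap_count, want$overlap)
    expect_equal(got$O_max, want$O_max, tolerance = 1e-12)
    expect_equal(got$O_rel, want$O_rel, tolerance = 1e-12)
    expect_equal(got$sum_S, want$sum_S, tolerance = 1e-12)
    expect_equal(got$S_tot, want$S_tot, tolerance = 1e-12)
  }
})

test_that("the score depends on pose signs only, never magnitudes", {
  set.seed(55)
  keys <- test_keys(4)
  ref <- random_reference(keys)
  for (i in 1:20) {
    pose <- random_padif(keys)
    scaled <- padifr:::new_padif(keys, pose$values * runif(1, 0.01, 100), "s")
    expect_identical(score_pose(ref, pose)$S_tot, score_pose(ref, scaled)$S_tot)
  }
})

test_that("overlap factors stay in bounds and the penalty never helps", {
  set.seed(77)
  for (i in 1:100) {
    keys <- test_keys(sample(1:5, 1))
    ref <- random_reference(keys)
    s <- score_pose(ref, random_padif(keys))
    expect_true(s$O_max >= 0 && s$O_max <= 1)
    expect_true(s$O_real >= 0 && s$O_real <= 1)
    expect_true(s$O_rel >= 0 && s$O_rel <= 1)
    expect_true(s$overlap_count <= min(s$P, s$R))
    expect_lte(s$S_tot, s$sum_S)
    if (s$O_rel == 1) expect_equal(s$S_tot, s$sum_S)
  }
})

test_that("completing a missed reference interaction never lowers the score", {
  set.seed(88)
  tried <- 0
  while (tried < 100) {
    keys <- test_keys(sample(2:5, 1))
    ref <- random_reference(keys)
    pose <- random_padif(keys)
    miss <- which(ref$median_values < 0 & pose$values == 0)
    if (length(miss) == 0) next
    tried <- tried + 1
    v2 <- pose$values
    v2[miss[sample.int(length(miss), 1)]] <- -0.5
    better <- padifr:::new_padif(keys, v2, "b")
    expect_gte(score_pose(ref, better)$S_tot, score_pose(ref, pose)$S_tot)
  }
})

test_that("poses matching only inside the reference pattern keep their full score", {
  set.seed(202)
  tried <- 0
  while (tried < 100) {
    keys <- test_keys(sample(1:5, 1))
    ref <- random_reference(keys)
    fav <- which(ref$median_values < 0)
    # pose favourable on a random subset of the reference pattern only
    sub <- fav[runif(length(fav)) < 0.6]
    if (length(sub) == 0) next
    tried <- tried + 1
    v <- matrix(0, nrow(keys), 8)
    v[sub] <- -abs(rnorm(length(sub))) - 0.1
    s <- score_pose(ref, padifr:::new_padif(keys, v, "sub"))
    expect_equal(s$O_rel, 1)
    expect_equal(s$S_tot, s$sum_S)
    expect_equal(s$sum_S, sum(ref$weights[sub]))
  }
})

test_that("ranking is by descending score with lexicographic tie-breaks", {
  r <- rank_by_score(c(a = 1.0, b = 2.0))
  expect_equal(r$pose_id, c("b", "a"))
  expect_equal(r$rank, 1:2)

  r2 <- rank_by_score(c(b = 1.0, a = 1.0))
  expect_equal(r2$pose_id, c("a", "b"))

  set.seed(3)
  sc <- setNames(sample(c(runif(80), runif(20))),  # includes no exact ties
                 sprintf("p%03d", 1:100))
  got <- rank_by_score(sc)$pose_id
  want <- names(sc)[order(sc, decreasing = TRUE)]  # independent sort oracle
  expect_equal(got, want)
})

test_that("the combined ranking takes the conventional head then the fingerprint tail", {
  set.seed(9)
  ids <- sprintf("p%03d", 1:100)
  conv <- setNames(runif(100), ids)
  pad <- setNames(runif(100), ids)
  comb <- combined_rank(conv, pad, 0.03)
  head3 <- names(sort(conv, decreasing = TRUE))[1:3]
  expect_equal(comb$pose_id[1:3], head3)
  expect_equal(comb$block, rep(c("conventional", "padif"), c(3, 97)))
  rest <- setdiff(ids, head3)
  expect_equal(comb$pose_id[4:100],
               rest[order(-pad[rest], rest, method = "radix")])

  # ceil: 3% of 10 poses still takes one conventional pose
  comb10 <- combined_rank(conv[1:10], pad[1:10], 0.03)
  expect_equal(sum(comb10$block == "conventional"), 1)
  expect_equal(comb10$pose_id[1], names(which.max(conv[1:10])))

  # identical scores: combined ranking collapses to the plain ranking
  same <- combined_rank(conv, conv, 0.03)
  expect_equal(same$pose_id, rank_by_score(conv)$pose_id)

  expect_error(combined_rank(conv[1:5], pad[2:6]), "different pose ids")
  expect_error(combined_rank(conv, pad, 0), "top_fraction")
})
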