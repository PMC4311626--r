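test_that("organism matching intersects, sorts and counts pairs", {
  withr::local_seed(2)
  M1 <- mat_from_upper(runif(10, 0.1, 1), c("A", "B", "C", "D", "E"))
  M2 <- mat_from_upper(runif(10, 0.1, 1), c("B", "C", "D", "E", "F"))
  pair <- match_organisms(M1, M2)
  expect_equal(pair$N, 4L)
  expect_equal(pair$n, 6)
  expect_equal(pair$organisms, c("B", "C", "D", "E"))

  labs <- sprintf("t%02d", 1:13)
  M <- mat_from_upper(runif(78, 0.1, 1), labs)
  pair13 <- match_organisms(M, M)
  expect_equal(pair13$N, 13L)
  expect_equal(pair13$n, 78)

  M3 <- mat_from_upper(runif(10, 0.1, 1), c("P", "Q", "R", "S", "T"))
  expect_error(match_organisms(M1, M3), "insufficient common organisms",
               class = "mirrortree_input_error")
})

test_that("matched vectors pair the same organisms in both matrices", {
  withr::local_seed(3)
  labs <- c("d", "b", "a", "c")
  M1 <- mat_from_upper(runif(6), labs)
  M2 <- M1[c(2, 4, 1, 3), c(2, 4, 1, 3)]  # same matrix, scrambled storage
  pair <- match_organisms(M1, M2)
  expect_equal(pair$R, pair$S)
})

test_that("the correlation follows its defining formula", {
  labs <- letters[1:3]
  pair <- structure(list(organisms = labs, N = 3L, n = 3L,
                         R = c(0.2, 0.4, 0.6), S = c(0.1, 0.3, 0.2),
                         M1 = mat_from_upper(c(0.2, 0.4, 0.6), labs),
                         M2 = mat_from_upper(c(0.1, 0.3, 0.2), labs)),
                    class = "matched_pair")
  expect_equal(tree_correlation(pair), 0.5, tolerance = 1e-15)

  # identity and positive-affine invariance; sign flip under negation
  withr::local_seed(7)
  labs6 <- letters[1:6]
  v <- runif(15, 0.1, 1)
  M <- mat_from_upper(v, labs6)
  expect_equal(tree_correlation(match_organisms(M, M)), 1)
  M2 <- mat_from_upper(2 * v + 0.3, labs6)
  expect_equal(tree_correlation(match_organisms(M, M2)), 1)
  M3 <- mat_from_upper(1 - v, labs6)  # negative scaling plus shift
  expect_equal(tree_correlation(match_organisms(M, M3)), -1)

  # agrees with an independent direct evaluation (stats::cor)
  for (rep in 1:20) {
    a <- mat_from_upper(runif(15, 0.05, 1), labs6)
    b <- mat_from_upper(runif(15, 0.05, 1), labs6)
    pr <- match_organisms(a, b)
    expect_equal(tree_correlation(pr), stats::cor(pr$R, pr$S),
                 tolerance = 1e-12)
  }

  # zero variance is degenerate
  flat <- mat_from_upper(rep(0.4, 15), labs6)
  expect_error(tree_correlation(match_organisms(M, flat)),
               "degenerate distance matrix",
               class = "mirrortree_degenerate_error")
})

test_that("correlation is symmetric and invariant to joint relabeling", {
  withr::local_seed(13)
  labs <- letters[1:7]
  A <- mat_from_upper(runif(21, 0.1, 1), labs)
  B <- mat_from_upper(runif(21, 0.1, 1), labs)
  r_ab <- tree_correlation(match_organisms(A, B))
  r_ba <- tree_correlation(match_organisms(B, A))
  expect_equal(r_ab, r_ba, tolerance = 1e-14)

  relab <- setNames(sample(labs), labs)
  A2 <- A; dimnames(A2) <- list(relab[rownames(A)], relab[colnames(A)])
  B2 <- B; dimnames(B2) <- list(relab[rownames(B)], relab[colnames(B)])
  expect_equal(tree_correlation(match_organisms(A2, B2)), r_ab,
               tolerance = 1e-14)
})

test_that("permutation test: extremes, determinism, distance conservation", {
  withr::local_seed(23)
  labs <- letters[1:8]
  M <- mat_from_upper(runif(28, 0.1, 1), labs)
  res <- permutation_pvalue(match_organisms(M, M), B = 99, seed = 5)
  expect_equal(res$r, 1)
  expect_equal(res$p_value, 0.01)  # minimum attainable at B = 99

  res2 <- permutation_pvalue(match_organisms(M, M), B = 99, seed = 5)
  expect_identical(res$p_value, res2$p_value)
  expect_identical(res$r_perm, res2$r_perm)

  # permuting labels never changes the multiset of distances
  pair <- match_organisms(M, mat_from_upper(runif(28, 0.1, 1), labs))
  for (k in 1:20) {
    perm <- sample(pair$N)
    Sp <- pair$M2[perm, perm]
    expect_equal(sort(upper_tri <- Sp[upper.tri(Sp)]), sort(pair$S))
  }

  expect_error(permutation_pvalue(pair, B = 5), ">= 19",
               class = "mirrortree_input_error")
  expect_gte(res$p_value, 1 / (res$B_permutations + 1))
})

test_that("one-sided alternative counts only as-large correlations", {
  withr::local_seed(29)
  labs <- letters[1:8]
  A <- mat_from_upper(runif(28, 0.1, 1), labs)
  B <- mat_from_upper(runif(28, 0.1, 1), labs)
  pair <- match_organisms(A, B)
  two <- permutation_pvalue(pair, B = 199, seed = 1)
  one <- permutation_pvalue(pair, B = 199, seed = 1, alternative = "greater")
  expect_identical(two$r_perm, one$r_perm)
  expect_equal(one$p_value,
               (1 + sum(one$r_perm >= one$r)) / 200)
})

test_that("mirror_trees runs end to end from trees", {
  withr::local_seed(37)
  tr1 <- random_additive_tree(8)
  res <- mirror_trees(tr1, tr1, B = 49, seed = 2)
  expect_equal(res$r, 1)
  expect_s3_class(res, "mirrortree_result")
  td <- tidy(res)
  expect_equal(td$estimate, 1)
  expect_equal(td$n_pairs, 28)
  gl <- glance(res)
  expect_equal(gl$seed, 2L)
  p <- autoplot(res)
  expect_s3_class(p, "ggplot")
  p2 <- autoplot(res, type = "null")
  expect_s3_class(p2, "ggplot")
})

test_that("a shared distant clade does not weaken the coevolution signal", {
  run_mean_r <- function(distant, seeds) {
    mean(vapply(seeds, function(s) {
      cfg <- simulation_config(n_organisms = 12, seq_length = 150,
                               distant_clade = distant, seed = s)
      p <- make_family_pair(cfg)
      M1 <- patristic_matrix(nj_tree(p_distance_matrix(p$family1)))
      M2 <- patristic_matrix(nj_tree(p_distance_matrix(p$family2)))
      tree_correlation(match_organisms(M1, M2))
    }, numeric(1)))
  }
  seeds <- 1:12
  expect_gte(run_mean_r(TRUE, seeds), run_mean_r(FALSE, seeds))
})
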