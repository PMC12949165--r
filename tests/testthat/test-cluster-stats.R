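test_that("pointwise paired t handles identical, weighted and degenerate input", {
  set.seed(1)
  A <- matrix(rnorm(60), 6)
  res <- pointwise_paired_t(A, A)
  expect_true(all(res$t == 0))
  expect_equal(res$df, 5)

  B <- matrix(rnorm(60), 6)
  W <- matrix(1 / 6, 6, 10)
  expect_equal(pointwise_paired_t(A, B, "weighted", W)$t,
               pointwise_paired_t(A, B, "unweighted")$t, tolerance = 1e-12)

  # unequal weights differ from the classical statistic in general
  W2 <- matrix(runif(60), 6)
  W2 <- sweep(W2, 2, colSums(W2), "/")
  expect_false(isTRUE(all.equal(pointwise_paired_t(A, B, "weighted", W2)$t,
                                pointwise_paired_t(A, B, "unweighted")$t)))

  # zero-variance non-zero shift: capped finite value with a flag
  C <- A + 2
  res2 <- pointwise_paired_t(C, A)
  expect_true(all(abs(res2$t) == 1e6))
  expect_true(all(res2$t > 0))
  expect_true(all(res2$capped))
  expect_error(pointwise_paired_t(A[1, , drop = FALSE], A[1, , drop = FALSE]),
               "two participants")
})

test_that("cyclic clusters merge across the wrap and match brute force", {
  # all significant, one sign: a single cluster covering the cycle
  cl <- find_clusters_cyclic(rep(3, 40), 2)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$size, 40)
  # wrap contract on a 200-point grid
  tv <- rep(0, 200)
  tv[c(1, 2, 199, 200)] <- 3
  cl2 <- find_clusters_cyclic(tv, 2)
  expect_equal(nrow(cl2), 1)
  expect_equal(cl2$start_idx, 199)
  expect_equal(cl2$end_idx, 2)
  expect_equal(cl2$size, 4)
  expect_equal(cl2$mass, 12)
  # opposite signs at the wrap stay separate
  tv[c(1, 2)] <- -3
  expect_equal(nrow(find_clusters_cyclic(tv, 2)), 2)
  expect_equal(nrow(find_clusters_cyclic(rep(0, 50), 2)), 0)

  set.seed(2)
  for (r in 1:100) {
    n <- sample(c(8, 20, 50, 200), 1)
    tvr <- rnorm(n, 0, 1.5)
    tc <- runif(1, 0.5, 2.5)
    cl <- find_clusters_cyclic(tvr, tc)
    mine <- lapply(seq_len(nrow(cl)), function(i) cluster_members(cl[i, ], n))
    bf <- brute_clusters_cyclic(tvr, tc)
    expect_equal(length(mine), length(bf))
    for (m in mine) expect_true(any(vapply(bf, identical, logical(1), m)))
    # cluster masses equal the sum of member t-values
    for (i in seq_len(nrow(cl))) {
      expect_equal(cl$mass[i], sum(tvr[cluster_members(cl[i, ], n)]),
                   tolerance = 1e-12)
    }
  }
})

test_that("permutation test respects the p floor and null contracts", {
  set.seed(5)
  A <- matrix(rnorm(10 * 40), 10)
  res <- cluster_permutation_test(A, A, n_permutations = 200, seed = 3)
  expect_equal(nrow(res$clusters), 0)
  expect_length(res$null_max_mass, 200)

  # overwhelming effect: p at the floor 1/n_permutations (with 20
  # participants the chance of drawing the identity sign pattern among the
  # 1000 permutations is negligible, so no tie with the observed mass)
  set.seed(15)
  A <- matrix(rnorm(20 * 40), 20)
  B <- A + 3
  res2 <- cluster_permutation_test(B, A, n_permutations = 1000, seed = 3)
  expect_gte(nrow(res2$clusters), 1)
  expect_equal(min(res2$clusters$p_value), 0.001)
  expect_true(any(res2$clusters$significant))
  expect_true(all(res2$clusters$p_value >= 1 / 1000))

  # reproducible from the seed
  res3 <- cluster_permutation_test(B, A, n_permutations = 200, seed = 9)
  res4 <- cluster_permutation_test(B, A, n_permutations = 200, seed = 9)
  expect_identical(res3$null_max_mass, res4$null_max_mass)
  expect_warning(cluster_permutation_test(B, A, n_permutations = 50, seed = 1),
                 "coarse")
})

test_that("record-level permutation equals curve-level on the same smoothing", {
  d <- simulate_outcome_samples(n_participants = 6, n_stim = 60,
                                effect_factor = 1.5, seed = 21)
  res_rec <- cluster_permutation_test_records(d$b, d$a,
                                              n_permutations = 150, seed = 7)
  g <- cyclic_grid()
  sm <- function(df) smooth_cyclic(df$cycle_pct, df$value, g)$values
  A <- do.call(rbind, lapply(d$b, sm))
  B <- do.call(rbind, lapply(d$a, sm))
  res_cur <- cluster_permutation_test(A, B, n_permutations = 150, seed = 7)
  expect_equal(res_rec$clusters, res_cur$clusters, tolerance = 1e-12)
  expect_equal(res_rec$null_max_mass, res_cur$null_max_mass,
               tolerance = 1e-12)
})

test_that("scalar paired t matches the reference implementation", {
  set.seed(6)
  for (r in 1:50) {
    n <- sample(3:20, 1)
    a <- rnorm(n)
    b <- rnorm(n)
    mine <- paired_t_scalar(a, b)
    ref <- t.test(a, b, paired = TRUE)
    expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
    expect_equal(mine$df, unname(ref$parameter))
  }
  eq <- paired_t_scalar(c(1, 2, 3), c(1, 2, 3))
  expect_equal(eq$t, 0)
  expect_equal(eq$p_value, 1)
  deg <- paired_t_scalar(c(1, 2, 3), c(2, 3, 4))
  expect_true(deg$degenerate)
  expect_equal(deg$t, -1e6)
  expect_error(paired_t_scalar(1, 1), "n >= 2")
})
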