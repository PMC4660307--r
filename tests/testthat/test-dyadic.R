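make_matrix <- function(values, ids) {
  dimnames(values) <- list(ids, ids)
  diag(values) <- NA_real_
  structure(list(ids = ids, values = values, index_kind = "HWI",
                 counts = NULL, flags = list()), class = "assoc_matrix")
}

two_block_matrix <- function(n1, n2, within = 0.5, between = 0.1) {
  n <- n1 + n2
  v <- matrix(between, n, n)
  v[1:n1, 1:n1] <- within
  v[(n1 + 1):n, (n1 + 1):n] <- within
  make_matrix(v, sprintf("i%02d", 1:n))
}

test_that("the class test recovers constructed block structure", {
  m <- two_block_matrix(3, 3)
  cls <- setNames(rep(c("A", "B"), each = 3), m$ids)
  r <- mantel_class_test(m, cls, n_permutations = 1000, seed = 1)
  expect_equal(r$statistic, 0.4)
  # only label arrangements reproducing the blocks reach |stat| = 0.4:
  # 2 of choose(6, 3) = 20, so the exact two-sided p is 0.1 and the
  # (1+b)/(1+n) estimate converges there
  expect_equal(r$p_value, 0.1, tolerance = 0.05)

  # no signal: statistic 0, p = 1
  m0 <- two_block_matrix(3, 3, within = 0.2, between = 0.2)
  r0 <- mantel_class_test(m0, cls, n_permutations = 200, seed = 1)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)

  # a stronger case: 10 + 10 block matrix gives the minimal attainable p
  m2 <- two_block_matrix(10, 10)
  cls2 <- setNames(rep(c("A", "B"), each = 10), m2$ids)
  r2 <- mantel_class_test(m2, cls2, n_permutations = 500, seed = 2,
                          alternative = "greater")
  expect_equal(r2$p_value, 1 / 501)

  expect_error(mantel_class_test(m, setNames(c("A", "A", "A", "A", "A", "B"),
                                             m$ids)), "< 2 members")
})

test_that("node-label permutation p-values converge to exhaustive enumeration", {
  set.seed(42)
  for (rep in 1:4) {
    n <- 7
    v <- matrix(0, n, n)
    v[upper.tri(v)] <- runif(n * (n - 1) / 2)
    v <- v + t(v)
    m <- make_matrix(v, letters[1:n])
    cls <- setNames(rep(c("A", "B"), c(4, 3)), m$ids)

    ut <- which(upper.tri(v), arr.ind = TRUE)
    vals <- v[ut]
    stat_fun <- function(lab) {
      w <- lab[ut[, 1]] == lab[ut[, 2]]
      mean(vals[w]) - mean(vals[!w])
    }
    exact_stats <- enumerate_two_class_stats(v, cls, stat_fun)
    obs <- stat_fun(cls)
    p_exact <- mean(abs(exact_stats) >= abs(obs) - 1e-12)

    n_mc <- 4000
    r <- mantel_class_test(m, cls, n_permutations = n_mc, seed = rep)
    se <- sqrt(p_exact * (1 - p_exact) / n_mc)
    expect_lt(abs(r$p_value - p_exact), 3 * se + 2 / n_mc)
  }
})

test_that("randomization test matches enumeration and handles its contracts", {
  set.seed(99)
  n <- 7
  v <- matrix(0, n, n)
  v[upper.tri(v)] <- runif(n * (n - 1) / 2)
  v <- v + t(v)
  m <- make_matrix(v, letters[1:n])
  ids_a <- letters[1:4]; ids_b <- letters[5:7]

  # exhaustive: permute which individuals carry the A/B labels and rebuild
  # the within-set dyad sets
  stat_fun <- function(lab) {
    A <- which(lab == "A"); B <- which(lab == "B")
    mean(v[A, A][upper.tri(diag(length(A)))]) -
      mean(v[B, B][upper.tri(diag(length(B)))])
  }
  cls <- setNames(rep(c("A", "B"), c(4, 3)), letters[1:7])
  exact_stats <- enumerate_two_class_stats(v, cls, stat_fun)
  obs <- stat_fun(cls)
  p_exact <- mean(abs(exact_stats) >= abs(obs) - 1e-12)

  r <- randomization_mean_difference(m, dyad_set(within = ids_a),
                                     dyad_set(within = ids_b),
                                     n = 4000, seed = 3)
  expect_equal(r$observed_difference, obs)
  se <- sqrt(p_exact * (1 - p_exact) / 4000)
  expect_lt(abs(r$p_value - p_exact), 3 * se + 2 / 4000)

  # identical value multisets: difference 0, p 1
  mu <- make_matrix(matrix(0.3, 6, 6), letters[1:6])
  ru <- randomization_mean_difference(mu, dyad_set(within = letters[1:3]),
                                      dyad_set(within = letters[4:6]),
                                      n = 100, seed = 1)
  expect_equal(ru$observed_difference, 0)
  expect_equal(ru$p_value, 1)

  expect_error(randomization_mean_difference(m, dyad_set(within = ids_a),
                                             dyad_set(within = ids_b),
                                             n = 0), "at least 1")

  # dyad-unit permutation requires disjoint sets and also converges
  rd <- randomization_mean_difference(m, dyad_set(within = ids_a),
                                      dyad_set(within = ids_b),
                                      unit = "dyad", n = 2000, seed = 4)
  expect_true(rd$p_value > 0 && rd$p_value <= 1)
  expect_error(randomization_mean_difference(
    m, dyad_set(within = ids_a), dyad_set(within = letters[3:6]),
    unit = "dyad"), "disjoint")

  # cross-set (between) dyad sets work and respect the class structure
  rb <- randomization_mean_difference(
    m, dyad_set(between = ids_a, and = ids_b),
    dyad_set(within = ids_b), n = 500, seed = 5)
  expect_equal(rb$n_dyads_a, 12L)
  expect_equal(rb$n_dyads_b, 3L)
})

test_that("label permutation preserves the matrix value multiset", {
  set.seed(5)
  n <- 6
  v <- matrix(0, n, n)
  v[upper.tri(v)] <- runif(15)
  v <- v + t(v)
  m <- make_matrix(v, letters[1:n])
  cls <- setNames(rep(c("A", "B"), each = 3), m$ids)
  # permuting labels moves rows/columns together: any permutation of ids
  # leaves the sorted off-diagonal values unchanged
  for (i in 1:10) {
    prm <- sample(n)
    expect_equal(sort(v[prm, prm][upper.tri(v)]), sort(v[upper.tri(v)]))
  }
  # and the null statistics all come from that fixed multiset: with a
  # constant matrix every permuted statistic is 0
  mc <- make_matrix(matrix(0.4, n, n), letters[1:n])
  r <- mantel_class_test(mc, cls, n_permutations = 50, seed = 1)
  expect_true(all(r$null_stats == 0))
})

test_that("rejection rate under the null is calibrated", {
  # random labels on random matrices: empirical type-I near alpha
  set.seed(11)
  pvals <- replicate(60, {
    n <- 8
    v <- matrix(0, n, n)
    v[upper.tri(v)] <- runif(28)
    v <- v + t(v)
    m <- make_matrix(v, letters[1:n])
    cls <- setNames(sample(rep(c("A", "B"), each = 4)), m$ids)
    mantel_class_test(m, cls, n_permutations = 300,
                      seed = sample.int(1e6, 1))$p_value
  })
  expect_gte(mean(pvals < 0.05), 0)
  expect_lte(mean(pvals < 0.05), 0.15)
})
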