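test_that("half-weight index matches hand-computable cases", {
  # together in all 10 periods -> HWI 1
  g <- lapply(1:10, function(p)
    list(date = sprintf("2000-01-%02d", p), survey = "s1",
         members = c("a", "b")))
  m <- half_weight_matrix(dataset_from_groups(g))
  expect_equal(m$values["a", "b"], 1)

  # x = 2, y_a = 1, y_b = 3, y_ab = 0 -> HWI = 2 / (2 + 0 + 2) = 0.5
  g <- list(
    list(date = "2000-01-01", survey = "s", members = c("a", "b")),
    list(date = "2000-01-02", survey = "s", members = c("a", "b")),
    list(date = "2000-01-03", survey = "s", members = "a"),
    list(date = "2000-01-04", survey = "s", members = "b"),
    list(date = "2000-01-05", survey = "s", members = "b"),
    list(date = "2000-01-06", survey = "s", members = "b"))
  m <- half_weight_matrix(dataset_from_groups(g))
  expect_equal(m$values["a", "b"], 0.5)

  # disjoint sighting histories -> HWI 0
  g <- c(lapply(1:5, function(p)
    list(date = sprintf("2000-01-%02d", p), survey = "s", members = "a")),
    lapply(6:10, function(p)
      list(date = sprintf("2000-01-%02d", p), survey = "s", members = "b")))
  m <- half_weight_matrix(dataset_from_groups(g))
  expect_equal(m$values["a", "b"], 0)

  # same-day different-survey co-identification counts as y_ab, not x
  g <- list(
    list(date = "2000-01-01", survey = "s1", members = c("a", "x")),
    list(date = "2000-01-01", survey = "s2", members = c("b", "x")),
    list(date = "2000-01-02", survey = "s1", members = c("a", "b")))
  m <- half_weight_matrix(dataset_from_groups(g))
  # dyad (a,b): x = 1, y_ab = 1 -> 1 / (1 + 1 + 0) = 0.5
  expect_equal(m$values["a", "b"], 0.5)

  expect_error(half_weight_matrix(dataset_from_groups(list(
    list(date = "2000-01-01", survey = "s", members = "a")))), "no dyads")
})

test_that("HWI equals the period-enumeration oracle on random datasets", {
  for (s in 1:25) {
    d <- random_small_dataset(s, N = sample(3:8, 1), P = sample(4:15, 1))
    if (is.null(d) || n_individuals(d) < 2) next
    m <- half_weight_matrix(d)
    expect_identical(unname(m$values), unname(oracle_hwi(d)))
  }
})

test_that("HWIG has the stated closed form, bounds and invariances", {
  # uniform gregariousness: every dyad's HWIG is exactly N / (N - 1)
  for (N in c(4, 7)) {
    g <- lapply(1:6, function(p)
      list(date = sprintf("2000-01-%02d", p), survey = "s",
           members = letters[1:N]))
    hg <- hwig_matrix(half_weight_matrix(dataset_from_groups(g)))
    expect_equal(max(abs(hg$values[upper.tri(hg$values)] - N / (N - 1))), 0,
                 tolerance = 1e-12)
  }

  # a lone bonded dyad in an otherwise unsocial society: HWIG > 1
  g <- c(lapply(1:6, function(p)
    list(date = sprintf("2000-01-%02d", p), survey = "s1",
         members = c("a", "b"))),
    unlist(lapply(1:6, function(p) lapply(c("c", "d", "e"), function(id)
      list(date = sprintf("2000-01-%02d", p), survey = paste0("s_", id),
           members = id))), recursive = FALSE),
    list(list(date = "2000-01-07", survey = "s1", members = c("c", "d", "e"))))
  hg <- hwig_matrix(half_weight_matrix(dataset_from_groups(g)))
  expect_gt(hg$values["a", "b"], 1)

  # all-zero HWI -> all-zero HWIG with flags
  g <- c(lapply(1:3, function(p)
    list(date = sprintf("2000-01-%02d", p), survey = "s", members = "a")),
    lapply(4:6, function(p)
      list(date = sprintf("2000-01-%02d", p), survey = "s", members = "b")),
    lapply(7:9, function(p)
      list(date = sprintf("2000-01-%02d", p), survey = "s", members = "c")))
  hg <- hwig_matrix(half_weight_matrix(dataset_from_groups(g)))
  expect_true(all(hg$values[upper.tri(hg$values)] == 0))
  expect_true(all(hg$flags$zero_gregariousness))

  # property sweep: bounds, symmetry, and invariance of HWIG under scaling
  # of the HWI matrix (the gregariousness normalisation cancels any k)
  for (s in 1:10) {
    d <- random_small_dataset(100 + s, N = 7, P = 12)
    hwi <- half_weight_matrix(d)
    v <- hwi$values[upper.tri(hwi$values)]
    expect_true(all(v >= 0 & v <= 1))
    expect_identical(hwi$values, t(hwi$values))
    hg <- hwig_matrix(hwi)
    expect_true(all(hg$values[upper.tri(hg$values)] >= 0))
    expect_identical(hg$values, t(hg$values))
    scaled <- hwi
    scaled$values <- hwi$values * 0.37
    expect_equal(hwig_matrix(scaled)$values, hg$values, tolerance = 1e-12)
  }

  expect_error(hwig_matrix(hwig_matrix(half_weight_matrix(
    random_small_dataset(3, 5, 8)))), "needs an HWI matrix")
})

test_that("subset means enumerate the right dyads", {
  g <- lapply(1:4, function(p)
    list(date = sprintf("2000-01-%02d", p), survey = "s",
         members = c("a", "b", "c", "d")))
  m <- half_weight_matrix(dataset_from_groups(g))
  w <- subset_means(m, c("a", "b", "c"))
  expect_equal(w$n_dyads, 3L)
  expect_equal(w$mean, 1)
  x <- subset_means(m, "a", "b")
  expect_equal(x$n_dyads, 1L)
  expect_equal(x$mean, m$values["a", "b"])
  expect_error(subset_means(m, character(0)), "subsets|empty")

  # oracle: means match direct enumeration on a random matrix
  d <- random_small_dataset(7, N = 8, P = 12)
  m <- half_weight_matrix(d)
  ids <- m$ids
  sa <- ids[1:4]; sb <- ids[5:8]
  direct <- mean(m$values[sa, sb])
  expect_equal(subset_means(m, sa, sb)$mean, direct)
  within_direct <- mean(m$values[sa, sa][upper.tri(diag(4))])
  expect_equal(subset_means(m, sa)$mean, within_direct)
})

test_that("association matrices survive CSV round trips", {
  d <- random_small_dataset(11, N = 6, P = 10)
  m <- half_weight_matrix(d)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_assoc_matrix(m, tmp)
  m2 <- read_assoc_matrix(tmp)
  expect_equal(m2$values, m$values)
  expect_equal(m2$index_kind, "HWI")
})
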