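pair_dataset <- function(P = 12) {
  # two individuals always together, daily
  dataset_from_groups(lapply(seq_len(P), function(p)
    list(date = sprintf("2000-01-%02d", p), survey = "s",
         members = c("a", "b"))))
}

test_that("SLAR is 1 for an inseparable pair and SE is 0", {
  d <- pair_dataset()
  est <- estimate_slar(d, n_bins = 4, n_blocks = 3)
  ok <- !is.na(est$rates)
  expect_true(any(ok))
  expect_true(all(est$rates[ok] == 1))
  expect_true(all(est$se[ok] == 0))
  expect_equal(est$null_rate, 1)   # N = 2: the only possible associate
})

test_that("tallies match the quadruple-loop oracle on tiny datasets", {
  for (s in 1:20) {
    d <- random_small_dataset(400 + s, N = sample(3:5, 1), P = 8)
    if (is.null(d) || n_individuals(d) < 2) next
    edges <- c(0.5, 1.5, 3.5, 7.5)
    est <- estimate_slar(d, lag_bins = edges, n_blocks = 2)
    ora <- oracle_slar_tallies(d, edges)
    expect_identical(est$numerators, ora$num)
    expect_identical(est$denominators, ora$den)
  }
})

test_that("the null rate follows 1/(N-1) and validates inputs", {
  d <- random_small_dataset(3, N = 6, P = 8)
  expect_equal(null_slar(d), 1 / 5)
  expect_equal(null_slar(d, d$individuals$id[1:3]), 1 / 2)
  # periods of size 2 drawn from N = 10 at random: simulated long-run SLAR
  # sits at 1/9
  set.seed(6)
  g <- lapply(1:400, function(p)
    list(date = format(as.Date("1994-01-01") + p, "%Y-%m-%d"), survey = "s",
         members = sample(letters[1:10], 2)))
  d10 <- dataset_from_groups(g)
  est <- estimate_slar(d10, n_bins = 5)
  expect_equal(null_slar(d10), 1 / 9)
  expect_lt(abs(mean(est$rates, na.rm = TRUE) - 1 / 9), 0.03)
  expect_error(null_slar(d, d$individuals$id[1]), "at least 2")
  expect_error(null_slar(d, "nobody"), "missing")
})

test_that("a planted disassociation produces the expected rate drop", {
  # pairs together for the first 30 days, apart afterwards
  g <- c(lapply(1:30, function(p) list(
    date = format(as.Date("2000-01-01") + p - 1, "%Y-%m-%d"),
    survey = "s", members = c("a", "b"))),
    unlist(lapply(31:60, function(p) list(
      list(date = format(as.Date("2000-01-01") + p - 1, "%Y-%m-%d"),
           survey = "s1", members = c("a", "c")),
      list(date = format(as.Date("2000-01-01") + p - 1, "%Y-%m-%d"),
           survey = "s2", members = c("b", "d")))),
      recursive = FALSE))
  d <- dataset_from_groups(g)
  est <- estimate_slar(d, subset = c("a", "b", "c", "d"),
                       lag_bins = c(0.5, 10.5, 25.5, 59.5), n_blocks = 2)
  expect_gt(est$rates[1], 0.8)
  expect_lt(est$rates[3], 0.35)
})

test_that("jackknife behaves at boundaries and shrinks with more data", {
  # fewer periods than blocks: reduced with a warning
  d <- pair_dataset(P = 6)
  expect_warning(est <- estimate_slar(d, n_bins = 2, n_blocks = 15),
                 "reducing")
  expect_lte(est$n_blocks, 6L)
  # 2-point jackknife is valid
  est2 <- estimate_slar(d, n_bins = 2, n_blocks = 2)
  expect_equal(est2$n_blocks, 2L)
  expect_true(all(est2$se[!is.na(est2$se)] >= 0))
  expect_error(jackknife_se(d, n_blocks = 1), "at least 2")

  # SE shrinks as the number of sampling periods grows at fixed structure
  se_at <- function(P, seed) {
    g <- generate_sightings(ff_config(
      n_nc_male = 10, n_sc_male = 0, n_nc_female = 10, n_sc_female = 0,
      n_days = P, span_years = ceiling(P / 300), detection_prob = 0.5,
      male_class_boost = 0, sc_male_extra = 0,
      cross_sex_boost = c(NC = 0, SC = 0), merge_threshold = 4,
      calf_fraction = 0, seed = seed))
    mean(estimate_slar(g$dataset, n_bins = 4)$se, na.rm = TRUE)
  }
  small <- mean(vapply(1:3, function(s) se_at(40, s), numeric(1)))
  large <- mean(vapply(1:3, function(s) se_at(240, s), numeric(1)))
  expect_lt(large, small)
})

test_that("model fits respect nesting, QAIC bookkeeping and recovery", {
  g <- generate_scenario("casual_acquaintances", seed = 61)
  fits <- fit_slar_models(g$dataset)

  ll <- vapply(fits$models, function(m) m$log_likelihood, numeric(1))
  # the 4-parameter model dominates its nested alternatives
  expect_gte(ll[["two_level_casual"]] + 1e-6 * abs(ll[["two_level_casual"]]),
             max(ll[c("preferred_companions", "casual_acquaintances",
                      "constant_plus_casual")]))
  expect_gte(ll[["constant_plus_casual"]] + 1e-6,
             ll[["preferred_companions"]])
  expect_gte(ll[["casual_acquaintances"]] + 1e-6,
             ll[["preferred_companions"]])

  # delta-QAIC recomputes exactly from stored logL and c_hat
  q <- vapply(fits$models, function(m)
    -2 * m$log_likelihood / fits$c_hat + 2 * m$k, numeric(1))
  expect_equal(unname(q - min(q)),
               unname(vapply(fits$models, function(m) m$delta_qaic,
                             numeric(1))))
  expect_true(all(vapply(fits$models, function(m) m$delta_qaic, numeric(1))
                  >= 0))
  expect_gte(fits$c_hat, 1)

  # predicted rates stay within [0, 1] over the observed lag range
  grid <- seq(1, 550, by = 7)
  for (nm in names(fits$models)) {
    p <- predict(fits, grid, model = nm)
    expect_true(all(p >= 0 & p <= 1))
  }

  # decay-rate recovery on this seed within a factor of 2
  b <- coef(fits, "casual_acquaintances")[["b"]]
  expect_gt(b, 0.005)
  expect_lt(b, 0.02)

  # permanent bonds: the constant model is never beaten by more than 2
  gp <- generate_scenario("preferred_companions", seed = 61)
  fp <- fit_slar_models(gp$dataset)
  expect_lte(fp$models$preferred_companions$delta_qaic, 2)

  expect_error(fit_slar_models(), "supply a dataset")
})

test_that("random association keeps mean rate within 3 jackknife SEs of null", {
  g <- generate_scenario("random_association", seed = 503)
  est <- estimate_slar(g$dataset)
  reps_mean <- apply(est$replicates, 2, mean, na.rm = TRUE)
  reps_mean <- reps_mean[!is.na(reps_mean)]
  m <- length(reps_mean)
  se <- sqrt((m - 1) / m * sum((reps_mean - mean(reps_mean))^2))
  expect_lt(abs(mean(est$rates, na.rm = TRUE) - est$null_rate), 3 * se)
})

test_that("curve and model tables are written as CSV", {
  g <- generate_scenario("casual_acquaintances", seed = 62)
  est <- estimate_slar(g$dataset)
  fits <- fit_slar_models(g$dataset, estimate = est)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_slar_curve(est, f1)
  write_slar_model_table(fits, f2)
  curve <- utils::read.csv(f1)
  expect_equal(names(curve), c("bin_center_days", "rate", "se",
                               "numerator", "denominator"))
  tab <- utils::read.csv(f2)
  expect_equal(nrow(tab), 4L)
  expect_true(any(tab$supported))
})
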