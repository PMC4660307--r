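#' Standardized lagged association rate (SLAR)
#'
#' Estimates, for a set of individuals, the probability that if two
#' individuals are associated at some sampling period then, after a given
#' time lag, a randomly chosen associate of the first is that same second
#' individual. For every ordered pair of sampling periods `(t1, t2)` with
#' `t2 > t1` the lag `t2 - t1` (days) is assigned to a bin; the bin's
#' numerator accumulates the number of ordered pairs `(i, j)` associated at
#' both periods, and its denominator accumulates, over pairs `(i, j)`
#' associated at `t1` with `i` identified at `t2`, the number of subset
#' individuals associated with `i` at `t2`. The rate is their ratio.
#'
#' Precision is estimated by a delete-one-block jackknife over contiguous
#' date blocks of sampling periods (the estimator's unit of information is
#' the period pair, so blocks are temporal, not individuals).
#'
#' @param dataset a [sighting_data] object.
#' @param subset character ids (default: all individuals); at least 2.
#' @param lag_bins optional numeric vector of bin edges in days (length
#'   `n_bins + 1`); default: `n_bins` logarithmically spaced bins spanning
#'   the observed lag range (lags span days to years, so log spacing keeps
#'   bin occupancy comparable).
#' @param n_bins number of default bins.
#' @param n_blocks jackknife blocks (default 15; reduced with a warning when
#'   there are fewer periods than blocks).
#' @return Object of class `slar_estimate`: `lag_bins` (data.frame with
#'   `lower`, `upper`, `center` in days), `rates`, `se`, `numerators`,
#'   `denominators` (empty bins have `NA` rate and are excluded from
#'   fitting), `null_rate`, `replicates` (bins x blocks jackknife
#'   re-estimates), `subset`, `n_blocks`.
#' @export
estimate_slar <- function(dataset, subset = NULL, lag_bins = NULL,
                          n_bins = 8, n_blocks = 15) {
  prep <- .slar_prepare(dataset, subset, lag_bins, n_bins, n_blocks)
  tal <- cpp_slar_tallies(prep$period_members, prep$period_groups,
                          prep$times, prep$n_sub, prep$edges,
                          prep$block_of_period)
  nb <- tal$n_bins; B <- tal$n_blocks
  num <- array(tal$num, dim = c(nb, B, B))
  den <- array(tal$den, dim = c(nb, B, B))
  num_tot <- apply(num, 1L, sum)
  den_tot <- apply(den, 1L, sum)
  rates <- ifelse(den_tot > 0, num_tot / den_tot, NA_real_)

  reps <- matrix(NA_real_, nb, B)
  for (k in seq_len(B)) {
    nk <- num_tot - apply(num[, k, , drop = FALSE], 1L, sum) -
      apply(num[, , k, drop = FALSE], 1L, sum) + num[, k, k]
    dk <- den_tot - apply(den[, k, , drop = FALSE], 1L, sum) -
      apply(den[, , k, drop = FALSE], 1L, sum) + den[, k, k]
    reps[, k] <- ifelse(dk > 0, nk / dk, NA_real_)
  }
  se <- vapply(seq_len(nb), function(b) {
    g <- reps[b, !is.na(reps[b, ])]
    m <- length(g)
    if (m < 2L) return(NA_real_)
    sqrt((m - 1) / m * sum((g - mean(g))^2))
  }, numeric(1))

  structure(list(lag_bins = prep$bins, rates = rates, se = se,
                 numerators = num_tot, denominators = den_tot,
                 null_rate = null_slar(dataset, prep$subset),
                 replicates = reps, subset = prep$subset,
                 n_blocks = B),
            class = "slar_estimate")
}

.slar_prepare <- function(dataset, subset, lag_bins, n_bins, n_blocks) {
  stopifnot(inherits(dataset, "sighting_data"))
  if (is.null(subset)) subset <- dataset$individuals$id
  subset <- unique(as.character(subset))
  if (length(subset) < 2L) stop("subset must contain at least 2 individuals")
  if (!all(subset %in% dataset$individuals$id))
    stop("subset ids missing from dataset")
  if (length(dataset$samples) < 2L) stop("need at least 2 sampling periods")
  ix <- .sd_index(dataset, ids = subset)
  present <- lapply(seq_len(ix$n_samples), function(s) which(ix$seen[, s]))
  keep <- lengths(present) > 0L
  periods <- which(keep)
  times <- as.numeric(dataset$samples[periods])
  period_members <- present[periods]
  period_groups <- lapply(periods, function(s) {
    gl <- ix$groups[ix$sample_of_group == s]
    gl[lengths(gl) >= 2L]
  })
  lags <- outer(times, times, "-")
  lags <- lags[lags > 0]
  if (!length(lags)) stop("no positive lags between sampling periods")
  if (is.null(lag_bins)) {
    lo <- max(0.5, min(lags) - 0.5)
    edges <- exp(seq(log(lo), log(max(lags)), length.out = n_bins + 1L))
    edges[length(edges)] <- max(lags)
  } else {
    edges <- as.numeric(lag_bins)
    if (length(edges) < 2L || is.unsorted(edges, strictly = TRUE))
      stop("lag_bins must be strictly increasing edges")
  }
  nb <- length(edges) - 1L
  P <- length(periods)
  if (P < n_blocks) {
    warning("fewer sampling periods (", P, ") than jackknife blocks; ",
            "reducing to ", max(2L, P), " blocks")
    n_blocks <- max(2L, min(P, n_blocks))
  }
  block_of_period <- as.integer(ceiling(seq_len(P) / P * n_blocks))
  bins <- data.frame(lower = edges[-length(edges)], upper = edges[-1L])
  bins$center <- exp((log(pmax(bins$lower, .Machine$double.eps)) +
                        log(bins$upper)) / 2)
  list(period_members = period_members, period_groups = period_groups,
       times = times, n_sub = ix$n_ind, edges = edges, bins = bins,
       block_of_period = block_of_period, subset = subset)
}

#' Null standardized lagged association rate under random association
#'
#' When individuals associate at random the probability that a randomly
#' chosen associate of one individual is a given other individual is
#' `1 / (N - 1)`, where `N` is the number of individuals in the subset:
#' under exchangeable random grouping the identified counts per period
#' cancel between the estimator's numerator and denominator, leaving the
#' uniform choice among the `N - 1` possible partners.
#'
#' @param dataset a [sighting_data] object (validates the subset).
#' @param subset character ids (default all).
#' @return numeric scalar.
#' @export
null_slar <- function(dataset, subset = NULL) {
  stopifnot(inherits(dataset, "sighting_data"))
  if (is.null(subset)) subset <- dataset$individuals$id
  subset <- unique(as.character(subset))
  if (!all(subset %in% dataset$individuals$id))
    stop("subset ids missing from dataset")
  if (length(subset) < 2L) stop("subset must contain at least 2 individuals")
  1 / (length(subset) - 1)
}

#' Jackknife standard errors for the SLAR
#'
#' Convenience wrapper around [estimate_slar()] returning the per-bin
#' delete-one-block jackknife standard errors.
#'
#' @inheritParams estimate_slar
#' @return numeric vector of per-bin SEs.
#' @export
jackknife_se <- function(dataset, subset = NULL, lag_bins = NULL,
                         n_bins = 8, n_blocks = 15) {
  if (n_blocks < 2L) stop("n_blocks must be at least 2")
  estimate_slar(dataset, subset, lag_bins, n_bins, n_blocks)$se
}

#' @export
print.slar_estimate <- function(x, ...) {
  cat("Standardized lagged association rate:", length(x$subset),
      "individuals,", sum(!is.na(x$rates)), "estimable lag bins\n")
  tab <- data.frame(lag_days = round(x$lag_bins$center, 1),
                    rate = round(x$rates, 4), se = round(x$se, 4),
                    num = x$numerators, den = x$denominators)
  print(tab, row.names = FALSE)
  cat(sprintf("  null rate (random association): %.4f\n", x$null_rate))
  invisible(x)
}

#' Write a SLAR curve as CSV
#' @param estimate a `slar_estimate`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_slar_curve <- function(estimate, path) {
  utils::write.csv(data.frame(bin_center_days = estimate$lag_bins$center,
                              rate = estimate$rates, se = estimate$se,
                              numerator = estimate$numerators,
                              denominator = estimate$denominators),
                   path, row.names = FALSE)
  invisible(path)
}

# exact-lag tallies: every distinct day lag is its own cell, so the binomial
# likelihood carries no within-bin averaging bias (sampling periods are
# calendar days, hence lags are integers)
.slar_exact_tallies <- function(dataset, subset) {
  prep <- .slar_prepare(dataset, subset, NULL, 2, 1)
  maxlag <- max(prep$times) - min(prep$times)
  edges <- seq(0.5, maxlag + 0.5, by = 1)
  tal <- cpp_slar_tallies(prep$period_members, prep$period_groups,
                          prep$times, prep$n_sub, edges,
                          rep(1L, length(prep$times)))
  td <- seq_len(length(edges) - 1L)
  keep <- tal$den > 0
  data.frame(td = td[keep], num = tal$num[keep], den = tal$den[keep])
}

# ---- temporal model menu -------------------------------------------------

# Each model: natural parameters mapped from an unconstrained vector so the
# predicted rate stays in [0, 1] for all td >= 0.
.slar_model_defs <- function() {
  list(
    preferred_companions = list(
      k = 1L, label = "Preferred companions",
      natural = function(p) c(a = stats::plogis(p[1L])),
      g = function(par, td) rep(par[["a"]], length(td)),
      equation = function(par) sprintf("%.6g", par[["a"]])),
    casual_acquaintances = list(
      k = 2L, label = "Casual acquaintances",
      natural = function(p) c(a = stats::plogis(p[1L]), b = exp(p[2L])),
      g = function(par, td) par[["a"]] * exp(-par[["b"]] * td),
      equation = function(par)
        sprintf("%.6g*exp(-%.5g*td)", par[["a"]], par[["b"]])),
    constant_plus_casual = list(
      k = 3L, label = "Constant companions and casual acquaintances",
      natural = function(p) {
        s <- stats::plogis(p[1L]); u <- stats::plogis(p[2L])
        c(a = s * u, c = s * (1 - u), d = exp(p[3L]))
      },
      g = function(par, td) par[["a"]] + par[["c"]] * exp(-par[["d"]] * td),
      equation = function(par)
        sprintf("%.6g + %.6g*exp(-%.5g*td)", par[["a"]], par[["c"]],
                par[["d"]])),
    two_level_casual = list(
      k = 4L, label = "Two levels of casual acquaintances",
      natural = function(p) {
        s <- stats::plogis(p[1L]); u <- stats::plogis(p[2L])
        c(a = s * u, b = exp(p[3L]), c = s * (1 - u), d = exp(p[4L]))
      },
      g = function(par, td)
        par[["a"]] * exp(-par[["b"]] * td) + par[["c"]] * exp(-par[["d"]] * td),
      equation = function(par)
        sprintf("%.6g*exp(-%.5g*td) + %.6g*exp(-%.5g*td)",
                par[["a"]], par[["b"]], par[["c"]], par[["d"]])))
}

.slar_loglik <- function(g, num, den) {
  g <- pmin(pmax(g, 1e-12), 1 - 1e-12)
  sum(num * log(g) + (den - num) * log(1 - g))
}

.fit_one_model <- function(def, starts, num, den, td) {
  negll <- function(p) -.slar_loglik(def$g(def$natural(p), td), num, den)
  best <- NULL
  for (s in starts) {
    o <- try(stats::optim(s, negll, method = "Nelder-Mead",
                          control = list(maxit = 5000, reltol = 1e-12)),
             silent = TRUE)
    if (inherits(o, "try-error")) next
    o2 <- try(stats::optim(o$par, negll, method = "BFGS",
                           control = list(maxit = 500, reltol = 1e-12)),
              silent = TRUE)
    if (!inherits(o2, "try-error") && o2$value <= o$value) o <- o2
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (is.null(best)) return(NULL)
  list(par = best$par, params = def$natural(best$par),
       log_likelihood = -best$value)
}

#' Fit the four temporal association models to a SLAR
#'
#' Fits `preferred companions` (constant rate `a`), `casual acquaintances`
#' (`a*exp(-b*td)`), `constant companions and casual acquaintances`
#' (`a + c*exp(-d*td)`) and `two levels of casual acquaintances`
#' (`a*exp(-b*td) + c*exp(-d*td)`) to the binned tallies by maximising the
#' binomial log-likelihood `sum(num*log g + (den-num)*log(1-g))`, with `td`
#' the bin-centre lag in days. Overdispersion of the binned counts is
#' absorbed into `c_hat`, the Pearson chi-square per degree of freedom of
#' the most general (4-parameter) model, floored at 1; models are compared
#' by `QAIC = -2*logL/c_hat + 2k` and `delta_QAIC` relative to the best
#' model, with `delta_QAIC <= 2` flagged as strongly supported.
#'
#' Each model is fitted from a deterministic ladder of starts, including the
#' maxima of its nested submodels, so the maximised likelihoods respect the
#' model nesting.
#'
#' @inheritParams estimate_slar
#' @param estimate optionally, a precomputed `slar_estimate` (skips
#'   re-estimation of the display curve).
#' @param fit_lags `"exact"` (default when a dataset is supplied): the
#'   likelihood is evaluated on exact day-lag tallies, one cell per distinct
#'   lag, avoiding within-bin averaging bias; `"bins"`: the likelihood uses
#'   the display bins of `estimate` (the only option when no dataset is
#'   given).
#' @return Object of class `slar_fits`: per-model fits (natural parameters,
#'   log-likelihood, QAIC, delta-QAIC, support flag), `c_hat`, the
#'   `estimate` used, and a summary `table`.
#' @export
fit_slar_models <- function(dataset = NULL, subset = NULL, lag_bins = NULL,
                            n_bins = 8, n_blocks = 15, estimate = NULL,
                            fit_lags = c("exact", "bins")) {
  fit_lags <- match.arg(fit_lags)
  if (is.null(dataset) && is.null(estimate))
    stop("supply a dataset or an estimate")
  if (is.null(estimate))
    estimate <- estimate_slar(dataset, subset, lag_bins, n_bins, n_blocks)
  if (is.null(dataset)) fit_lags <- "bins"
  if (fit_lags == "exact") {
    cells <- .slar_exact_tallies(dataset, if (is.null(subset))
      dataset$individuals$id else subset)
    td <- cells$td; num <- cells$num; den <- cells$den
  } else {
    use <- !is.na(estimate$rates) & estimate$denominators > 0
    td <- estimate$lag_bins$center[use]
    num <- estimate$numerators[use]
    den <- estimate$denominators[use]
  }
  if (length(td) < 2L) stop("need at least 2 non-empty lag bins")
  defs <- .slar_model_defs()

  m0 <- sum(num) / sum(den)                       # pooled rate
  m0 <- min(max(m0, 1e-8), 1 - 1e-8)
  bgrid <- exp(seq(log(0.01 / max(td)), log(5 / min(td)), length.out = 6))

  fits <- vector("list", length(defs))
  names(fits) <- names(defs)

  # preferred companions: closed-form binomial MLE
  fits$preferred_companions <- list(
    par = stats::qlogis(m0), params = c(a = m0),
    log_likelihood = .slar_loglik(rep(m0, length(td)), num, den))

  starts2 <- lapply(bgrid, function(b)
    c(stats::qlogis(min(max(m0 * 1.5, 1e-6), 1 - 1e-6)), log(b)))
  fits$casual_acquaintances <-
    .fit_one_model(defs$casual_acquaintances, starts2, num, den, td)

  f2 <- fits$casual_acquaintances
  starts3 <- c(
    lapply(bgrid, function(d)
      c(stats::qlogis(min(m0 * 2, 0.99)), stats::qlogis(0.5), log(d))),
    # nested warm starts: pure constant (c ~ 0), pure casual (a ~ 0)
    list(c(stats::qlogis(m0), stats::qlogis(1 - 1e-6), log(bgrid[3L]))),
    if (!is.null(f2)) list(c(stats::qlogis(min(f2$params[["a"]], 1 - 1e-6)),
                             stats::qlogis(1e-6), log(f2$params[["b"]]))))
  fits$constant_plus_casual <-
    .fit_one_model(defs$constant_plus_casual, starts3, num, den, td)

  f3 <- fits$constant_plus_casual
  starts4 <- c(
    lapply(bgrid, function(b)
      c(stats::qlogis(min(m0 * 2, 0.99)), stats::qlogis(0.5), log(b),
        log(min(b * 50, 10)))),
    if (!is.null(f2)) list(c(stats::qlogis(min(f2$params[["a"]], 1 - 1e-6)),
                             stats::qlogis(1 - 1e-6), log(f2$params[["b"]]),
                             log(1))),
    if (!is.null(f3)) list(c(
      stats::qlogis(min(f3$params[["a"]] + f3$params[["c"]], 1 - 1e-6)),
      stats::qlogis(max(min(f3$params[["a"]] /
                              max(f3$params[["a"]] + f3$params[["c"]], 1e-12),
                            1 - 1e-6), 1e-6)),
      log(1e-9), log(f3$params[["d"]]))))
  fits$two_level_casual <-
    .fit_one_model(defs$two_level_casual, starts4, num, den, td)

  # overdispersion from the most general model's Pearson dispersion
  f4 <- fits$two_level_casual
  c_hat <- 1
  if (!is.null(f4)) {
    g4 <- pmin(pmax(defs$two_level_casual$g(f4$params, td), 1e-12), 1 - 1e-12)
    x2 <- sum((num - den * g4)^2 / (den * g4 * (1 - g4)))
    df <- length(td) - 4L
    if (df >= 1L) c_hat <- max(1, x2 / df)
  }

  rows <- lapply(names(defs), function(nm) {
    f <- fits[[nm]]
    if (is.null(f))
      return(list(model = nm, label = defs[[nm]]$label, params = NULL,
                  log_likelihood = NA_real_, k = defs[[nm]]$k,
                  qaic = NA_real_, equation = NA_character_,
                  failed = TRUE))
    list(model = nm, label = defs[[nm]]$label, params = f$params,
         log_likelihood = f$log_likelihood, k = defs[[nm]]$k,
         qaic = -2 * f$log_likelihood / c_hat + 2 * defs[[nm]]$k,
         equation = defs[[nm]]$equation(f$params), failed = FALSE)
  })
  names(rows) <- names(defs)
  qaics <- vapply(rows, function(r) r$qaic, numeric(1))
  best <- min(qaics, na.rm = TRUE)
  for (nm in names(rows)) {
    rows[[nm]]$delta_qaic <- rows[[nm]]$qaic - best
    rows[[nm]]$supported <- isTRUE(rows[[nm]]$delta_qaic <= 2)
  }
  tab <- data.frame(
    model = vapply(rows, `[[`, character(1), "label"),
    equation = vapply(rows, `[[`, character(1), "equation"),
    qaic = vapply(rows, `[[`, numeric(1), "qaic"),
    delta_qaic = vapply(rows, `[[`, numeric(1), "delta_qaic"),
    supported = vapply(rows, `[[`, logical(1), "supported"),
    row.names = NULL)
  structure(list(models = rows, c_hat = c_hat, estimate = estimate,
                 table = tab,
                 best_model = names(rows)[which.min(qaics)]),
            class = "slar_fits")
}

#' @export
print.slar_fits <- function(x, ...) {
  cat("SLAR temporal models (binomial likelihood, QAIC selection)\n")
  cat(sprintf("  overdispersion c_hat = %.4g; best model: %s\n",
              x$c_hat, x$best_model))
  tab <- x$table
  tab$qaic <- round(tab$qaic, 3)
  tab$delta_qaic <- round(tab$delta_qaic, 4)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
coef.slar_fits <- function(object, model = object$best_model, ...) {
  object$models[[model]]$params
}

#' @export
logLik.slar_fits <- function(object, model = object$best_model, ...) {
  m <- object$models[[model]]
  structure(m$log_likelihood, df = m$k, class = "logLik")
}

#' @export
predict.slar_fits <- function(object, lag_days = NULL,
                              model = object$best_model, ...) {
  if (is.null(lag_days)) lag_days <- object$estimate$lag_bins$center
  defs <- .slar_model_defs()
  m <- object$models[[model]]
  if (is.null(m) || m$failed) stop("model ", model, " was not fitted")
  defs[[model]]$g(m$params, lag_days)
}

#' @export
plot.slar_fits <- function(x, ...) {
  est <- x$estimate
  ok <- !is.na(est$rates)
  td <- est$lag_bins$center[ok]
  graphics::plot(td, est$rates[ok], log = "x", pch = 16,
                 xlab = "lag (days)", ylab = "standardized lagged assoc. rate",
                 ylim = range(0, est$rates[ok] + est$se[ok], na.rm = TRUE),
                 ...)
  graphics::arrows(td, est$rates[ok] - est$se[ok], td,
                   est$rates[ok] + est$se[ok],
                   angle = 90, code = 3, length = 0.03)
  graphics::abline(h = est$null_rate, lty = 3)
  grid <- exp(seq(log(min(td)), log(max(td)), length.out = 200))
  graphics::lines(grid, predict(x, grid), lty = 1)
  invisible(x)
}

#' Write the SLAR model-selection table as CSV
#' @param fits a `slar_fits` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_slar_model_table <- function(fits, path) {
  utils::write.csv(fits$table, path, row.names = FALSE)
  invisible(path)
}
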