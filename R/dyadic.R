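#' Node-label permutation test of within- vs between-class association
#'
#' Matrix-correlation ("Mantel-type") test comparing the mean dyadic index
#' among individuals of the same community class with the mean between
#' classes. The statistic is `mean(within-class dyads) - mean(between-class
#' dyads)`; the null distribution is built by permuting the class labels
#' across individuals (rows and columns moved together), which respects the
#' dependence among dyads sharing an individual and preserves the multiset of
#' matrix values exactly.
#'
#' @param matrix an `assoc_matrix`.
#' @param classes named character vector, id -> class label; must cover at
#'   least two classes with two or more members present in the matrix
#'   (unless `cross_only`).
#' @param n_permutations Monte-Carlo permutations (default 10000).
#' @param seed integer seed.
#' @param alternative `"two.sided"` (default), `"greater"` (within >
#'   between) or `"less"`.
#' @param cross_only drop classes with fewer than two members from the
#'   within-class mean instead of erroring.
#' @return Object of class `mantel_class_test`: `statistic`, `p_value`,
#'   `n_permutations`, `class_map`, `seed`, `alternative`, plus the within
#'   and between means.
#' @export
mantel_class_test <- function(matrix, classes, n_permutations = 10000,
                              seed = NULL,
                              alternative = c("two.sided", "greater", "less"),
                              cross_only = FALSE) {
  stopifnot(inherits(matrix, "assoc_matrix"), n_permutations >= 1)
  alternative <- match.arg(alternative)
  ids <- intersect(matrix$ids, names(classes))
  if (length(ids) < 3L) stop("need at least 3 labelled individuals")
  cl <- as.character(classes[ids])
  sizes <- table(cl)
  if (length(sizes) < 2L) stop("need at least 2 classes")
  if (any(sizes < 2L) && !cross_only)
    stop("class(es) with < 2 members: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "),
         " (use cross_only = TRUE)")
  pos <- match(ids, matrix$ids)
  V <- matrix$values[pos, pos, drop = FALSE]
  ut <- which(upper.tri(V), arr.ind = TRUE)
  ii <- ut[, 1L]; jj <- ut[, 2L]
  vals <- V[ut]

  stat_fun <- function(lab) {
    w <- lab[ii] == lab[jj]
    mean(vals[w]) - mean(vals[!w])
  }
  observed <- stat_fun(cl)
  if (!is.null(seed)) set.seed(seed)
  null_stats <- vapply(seq_len(n_permutations),
                       function(p) stat_fun(sample(cl)), numeric(1))
  p <- .perm_p(observed, null_stats, alternative)
  structure(list(statistic = observed,
                 within_mean = mean(vals[cl[ii] == cl[jj]]),
                 between_mean = mean(vals[cl[ii] != cl[jj]]),
                 p_value = p, n_permutations = as.integer(n_permutations),
                 null_stats = null_stats,
                 class_map = stats::setNames(cl, ids), seed = seed,
                 alternative = alternative),
            class = "mantel_class_test")
}

.perm_p <- function(observed, null_stats, alternative, tol = 1e-12) {
  n <- length(null_stats)
  b <- switch(alternative,
              two.sided = sum(abs(null_stats) >= abs(observed) - tol),
              greater = sum(null_stats >= observed - tol),
              less = sum(null_stats <= observed + tol))
  (1 + b) / (1 + n)
}

#' @export
print.mantel_class_test <- function(x, ...) {
  cat("Node-label permutation test (within vs between class)\n")
  cat(sprintf("  within mean %.4f  between mean %.4f  statistic %.4f\n",
              x$within_mean, x$between_mean, x$statistic))
  cat(sprintf("  P = %.4g (%s, %d permutations)\n",
              x$p_value, x$alternative, x$n_permutations))
  invisible(x)
}

#' Define a dyad set for randomization comparisons
#'
#' Either all unordered dyads within one id set (`within`), or all cross
#' dyads between two id sets (`between` together with `and`).
#'
#' @param within character vector of ids (within-set dyads), or NULL.
#' @param between,and character vectors of ids (cross dyads), or NULL.
#' @return An object of class `dyad_set`.
#' @export
dyad_set <- function(within = NULL, between = NULL, and = NULL) {
  if (!is.null(within)) {
    stopifnot(is.null(between), is.null(and))
    structure(list(type = "within", ids = unique(as.character(within))),
              class = "dyad_set")
  } else {
    stopifnot(!is.null(between), !is.null(and))
    structure(list(type = "between", ids_a = unique(as.character(between)),
                   ids_b = unique(as.character(and))),
              class = "dyad_set")
  }
}

# dyads of a spec as a 2-column index matrix into `universe`
.dyad_index <- function(spec, universe) {
  if (spec$type == "within") {
    p <- match(spec$ids, universe)
    if (anyNA(p)) stop("dyad set ids missing from matrix")
    if (length(p) < 2L) stop("empty dyad set")
    t(utils::combn(sort(p), 2L))
  } else {
    pa <- match(spec$ids_a, universe); pb <- match(spec$ids_b, universe)
    if (anyNA(pa) || anyNA(pb)) stop("dyad set ids missing from matrix")
    d <- expand.grid(a = pa, b = pb)
    d <- d[d$a != d$b, , drop = FALSE]
    # unordered: dedupe pairs present in both orientations
    key <- paste(pmin(d$a, d$b), pmax(d$a, d$b))
    d <- d[!duplicated(key), , drop = FALSE]
    if (nrow(d) == 0L) stop("empty dyad set")
    cbind(d$a, d$b)
  }
}

.spec_ids <- function(spec)
  if (spec$type == "within") spec$ids else c(spec$ids_a, spec$ids_b)

#' Randomization test for a difference of dyadic means
#'
#' Compares the mean association index over one dyad set with the mean over
#' another (e.g. within-class male dyads of two classes, or male-female
#' blocks). With `unit = "individual"` (default) the null permutes the
#' individual labels that define the sets and rebuilds the dyad sets each
#' iteration, which respects the non-independence of dyads sharing an
#' individual; with `unit = "dyad"` the pooled dyad values are reassigned to
#' the two sets directly (requires disjoint sets).
#'
#' @param matrix an `assoc_matrix`.
#' @param set_a,set_b [dyad_set] specifications.
#' @param unit `"individual"` or `"dyad"`.
#' @param n number of randomizations (default 10000).
#' @param seed integer seed.
#' @param alternative `"two.sided"` (default), `"greater"`, `"less"`.
#' @return Object of class `randomization_test`: `observed_difference`,
#'   `p_value`, `n_randomizations`, `unit`, `seed`, set means and sizes.
#' @export
randomization_mean_difference <- function(matrix, set_a, set_b,
                                          unit = c("individual", "dyad"),
                                          n = 10000, seed = NULL,
                                          alternative = c("two.sided",
                                                          "greater", "less")) {
  stopifnot(inherits(matrix, "assoc_matrix"),
            inherits(set_a, "dyad_set"), inherits(set_b, "dyad_set"))
  if (n < 1) stop("at least 1 randomization required")
  unit <- match.arg(unit)
  alternative <- match.arg(alternative)
  universe <- sort(unique(c(.spec_ids(set_a), .spec_ids(set_b))))
  if (!all(universe %in% matrix$ids))
    stop("dyad set ids missing from matrix: ",
         paste(setdiff(universe, matrix$ids), collapse = ", "))
  V <- matrix$values[match(universe, matrix$ids),
                     match(universe, matrix$ids), drop = FALSE]
  da <- .dyad_index(set_a, universe)
  db <- .dyad_index(set_b, universe)
  m <- length(universe)
  mean_at <- function(perm, d) mean(V[cbind(perm[d[, 1L]], perm[d[, 2L]])])
  idp <- seq_len(m)
  obs_a <- mean_at(idp, da); obs_b <- mean_at(idp, db)
  observed <- obs_a - obs_b
  if (!is.null(seed)) set.seed(seed)
  if (unit == "individual") {
    null_stats <- vapply(seq_len(n), function(p) {
      prm <- sample.int(m)
      mean_at(prm, da) - mean_at(prm, db)
    }, numeric(1))
  } else {
    key_a <- paste(pmin(da[, 1], da[, 2]), pmax(da[, 1], da[, 2]))
    key_b <- paste(pmin(db[, 1], db[, 2]), pmax(db[, 1], db[, 2]))
    if (length(intersect(key_a, key_b)))
      stop("unit = 'dyad' requires disjoint dyad sets")
    pool <- c(V[da], V[db])
    na <- nrow(da)
    null_stats <- vapply(seq_len(n), function(p) {
      prm <- sample(pool)
      mean(prm[seq_len(na)]) - mean(prm[-seq_len(na)])
    }, numeric(1))
  }
  p <- .perm_p(observed, null_stats, alternative)
  structure(list(observed_difference = observed,
                 mean_a = obs_a, mean_b = obs_b,
                 n_dyads_a = nrow(da), n_dyads_b = nrow(db),
                 p_value = p, n_randomizations = as.integer(n),
                 null_stats = null_stats, unit = unit, seed = seed,
                 alternative = alternative),
            class = "randomization_test")
}

#' @export
print.randomization_test <- function(x, ...) {
  cat("Randomization test for difference of dyadic means\n")
  cat(sprintf("  mean A %.4f (n=%d)  mean B %.4f (n=%d)  diff %.4f\n",
              x$mean_a, x$n_dyads_a, x$mean_b, x$n_dyads_b,
              x$observed_difference))
  cat(sprintf("  P = %.4g (%s, unit = %s, %d randomizations)\n",
              x$p_value, x$alternative, x$unit, x$n_randomizations))
  invisible(x)
}
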