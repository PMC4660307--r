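#' One checkerboard swap ("flip") of the grouped sighting data
#'
#' Picks a sampling period containing at least two groups, two groups `g`,
#' `h` within it and individuals `i` in `g` (not in `h`) and `j` in `h` (not
#' in `g`), and exchanges them. A flip preserves every group's size and every
#' individual's number of sightings within each sampling period — the
#' invariants of the "permute groups within samples" null model. When no
#' valid swap is found within `max_tries` proposals the dataset is returned
#' unchanged with attribute `swapped = FALSE`.
#'
#' @param dataset a [sighting_data] object.
#' @param n_flips number of successive swaps to apply (default 1).
#' @param max_tries bounded number of proposals per swap.
#' @return The permuted [sighting_data]; attribute `n_swapped` reports how
#'   many of the `n_flips` attempts produced a swap.
#' @export
flip <- function(dataset, n_flips = 1, max_tries = 100) {
  stopifnot(inherits(dataset, "sighting_data"), n_flips >= 1)
  ix <- .sd_index(dataset)
  res <- cpp_permute_groups(ix$groups, ix$sample_of_group, ix$n_samples,
                            as.integer(n_flips), as.integer(max_tries))
  out <- .sd_from_index(dataset, res$groups, ix$ids)
  attr(out, "n_swapped") <- res$n_swapped
  attr(out, "swapped") <- res$n_swapped > 0
  out
}

#' Permutation test for nonrandom association (CV statistic)
#'
#' Tests whether individuals associate nonrandomly by permuting groups within
#' sampling periods. The chain is sequential: starting from the observed
#' dataset, each permutation applies `flips` checkerboard swaps to the
#' current permuted dataset, recomputes the association matrix (HWI, or HWIG
#' derived from it), and records the coefficient of variation of the
#' off-diagonal dyadic values. A significantly *higher* observed CV than the
#' permuted CVs indicates nonrandom (preferred/avoided) associations, so the
#' p-value is one-sided: `p = (1 + #\{null >= observed\}) / (1 + n)`.
#'
#' Defaults follow field practice for this test: 10,000 permutations with
#' 100 flips each.
#'
#' @param dataset a [sighting_data] object.
#' @param index_kind `"HWI"` or `"HWIG"`.
#' @param n_permutations number of recorded permutations.
#' @param flips flips between successive recordings.
#' @param seed integer seed for the chain (required for reproducibility).
#' @param burn_in extra flips before the first recording (default 0).
#' @param max_tries bounded proposals per flip.
#' @return An object of class `assoc_permtest`: `observed_cv`, `null_cvs`,
#'   `p_value`, `n_permutations`, `flips_per_permutation`, `index_kind`,
#'   `seed`, `degenerate` (TRUE when no sampling period has two groups, in
#'   which case `p_value` is 1).
#' @export
cv_test <- function(dataset, index_kind = c("HWI", "HWIG"),
                    n_permutations = 10000, flips = 100, seed = NULL,
                    burn_in = 0, max_tries = 100) {
  stopifnot(inherits(dataset, "sighting_data"),
            n_permutations >= 1, flips >= 1)
  index_kind <- match.arg(index_kind)
  ix <- .sd_index(dataset)
  if (ix$n_ind < 2L) stop("no dyads: dataset has fewer than 2 individuals")
  if (!is.null(seed)) set.seed(seed)
  res <- cpp_cv_chain(ix$groups, ix$sample_of_group,
                      as.integer(ix$n_seen), ix$n_ind, ix$n_samples,
                      as.integer(n_permutations), as.integer(flips),
                      as.integer(burn_in), as.integer(max_tries),
                      as.integer(index_kind == "HWIG"))
  degenerate <- isTRUE(res$degenerate)
  p <- if (degenerate) 1 else
    (1 + sum(res$null_cvs >= res$observed_cv)) / (1 + n_permutations)
  structure(list(observed_cv = res$observed_cv,
                 null_cvs = as.numeric(res$null_cvs),
                 p_value = p,
                 n_permutations = as.integer(n_permutations),
                 flips_per_permutation = as.integer(flips),
                 index_kind = index_kind,
                 seed = seed,
                 n_swapped = res$n_swapped,
                 degenerate = degenerate),
            class = "assoc_permtest")
}

#' @export
print.assoc_permtest <- function(x, ...) {
  cat("Permutation test for nonrandom association (", x$index_kind, ")\n",
      sep = "")
  cat(sprintf("  observed CV: %.4f   null CV mean: %.4f\n",
              x$observed_cv, mean(x$null_cvs)))
  cat(sprintf("  one-sided P = %.4g  (%d permutations x %d flips)\n",
              x$p_value, x$n_permutations, x$flips_per_permutation))
  if (x$degenerate)
    cat("  NOTE: degenerate data (no sampling period with >= 2 groups)\n")
  invisible(x)
}

#' Write a permutation-test result as JSON (optionally with the null trace)
#' @param x an `assoc_permtest`.
#' @param path JSON output path.
#' @param trace_path optional CSV path for the null CV trace.
#' @return `path`, invisibly.
#' @export
write_permtest <- function(x, path, trace_path = NULL) {
  stopifnot(inherits(x, "assoc_permtest"))
  jsonlite::write_json(
    list(observed_cv = x$observed_cv, p_value = x$p_value,
         n_permutations = x$n_permutations,
         flips = x$flips_per_permutation,
         seed = x$seed, index_kind = x$index_kind,
         degenerate = x$degenerate),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(trace_path))
    utils::write.csv(data.frame(permutation = seq_along(x$null_cvs),
                                null_cv = x$null_cvs),
                     trace_path, row.names = FALSE)
  invisible(path)
}
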