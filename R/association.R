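#' Half-weight association index matrix
#'
#' For each dyad the half-weight index is
#' `HWI = x / (x + y_ab + 0.5 * (y_a + y_b))`, where over sampling periods
#' `x` counts periods in which the two were associated (together in at least
#' one group of the period), `y_ab` periods in which both were identified but
#' never in the same group, and `y_a`, `y_b` periods in which only one of the
#' two was identified. `HWI` is 0 for dyads never seen together and 1 for
#' dyads always together; values lie in \[0, 1\].
#'
#' With the day-level association definition `y_ab` is usually zero, but it
#' is tallied in full generality (an individual can be seen in several
#' surveys, hence several groups, of one day).
#'
#' @param dataset a [sighting_data] object with at least two individuals and
#'   one sampling period.
#' @return An object of class `assoc_matrix`: list with `ids`, `values`
#'   (symmetric index matrix, diagonal `NA`), `index_kind` (`"HWI"`),
#'   and `counts` (matrices `x`, `both` = periods both identified, and the
#'   vector `n_seen` of per-individual period counts, from which
#'   `y_ab = both - x`, `y_a = n_a - both`, `y_b = n_b - both`).
#' @export
half_weight_matrix <- function(dataset) {
  stopifnot(inherits(dataset, "sighting_data"))
  ix <- .sd_index(dataset)
  if (ix$n_ind < 2L) stop("no dyads: dataset has fewer than 2 individuals")
  if (ix$n_samples < 1L) stop("dataset has no sampling periods")
  x <- cpp_x_matrix(ix$groups, ix$sample_of_group, ix$n_ind, ix$n_samples)
  storage.mode(x) <- "double"
  both <- tcrossprod(ix$seen * 1)        # periods both identified
  y_ab <- both - x
  n <- ix$n_seen
  y_a <- matrix(n, ix$n_ind, ix$n_ind) - both       # rows: y for individual a
  y_b <- t(y_a)
  denom <- x + y_ab + 0.5 * (y_a + y_b)
  values <- ifelse(denom > 0, x / denom, 0)
  diag(values) <- NA_real_
  dimnames(values) <- list(ix$ids, ix$ids)
  dimnames(x) <- dimnames(both) <- dimnames(values)
  structure(list(ids = ix$ids, values = values, index_kind = "HWI",
                 counts = list(x = x, both = both, n_seen = stats::setNames(n, ix$ids)),
                 flags = list(never_seen = n == 0)),
            class = "assoc_matrix")
}

#' Gregariousness-corrected association index (HWIG)
#'
#' Rescales a half-weight index matrix by the partners' gregariousness:
#' `HWIG_ab = HWI_ab * sumHWI / (sumHWI_a * sumHWI_b)`, where `sumHWI_a` is
#' the sum of individual a's HWI values over all partners and `sumHWI` is the
#' sum over all individuals of those row sums (each unordered dyad counted
#' twice). An HWIG above one means the dyad associated more often than
#' expected given the two individuals' gregariousness; below one, less often.
#' Individuals with a zero HWI row sum yield HWIG 0 (flagged).
#'
#' @param hwi an `assoc_matrix` with `index_kind == "HWI"`.
#' @return An `assoc_matrix` with `index_kind == "HWIG"`; entries are
#'   nonnegative and unbounded above.
#' @export
hwig_matrix <- function(hwi) {
  stopifnot(inherits(hwi, "assoc_matrix"))
  if (!identical(hwi$index_kind, "HWI"))
    stop("hwig_matrix needs an HWI matrix, got ", hwi$index_kind)
  v <- hwi$values
  diag(v) <- 0
  rs <- rowSums(v)
  tot <- sum(rs)
  out <- hwi$values * tot
  scale <- outer(rs, rs)
  ok <- scale > 0
  out[ok] <- out[ok] / scale[ok]
  out[!ok] <- 0
  diag(out) <- NA_real_
  res <- hwi
  res$values <- out
  res$index_kind <- "HWIG"
  res$flags$zero_gregariousness <- rs == 0
  res
}

#' @export
print.assoc_matrix <- function(x, ...) {
  v <- x$values[upper.tri(x$values)]
  cat("assoc_matrix (", x$index_kind, "): ", length(x$ids), " individuals, ",
      length(v), " dyads\n", sep = "")
  cat(sprintf("  mean %.4f  sd %.4f  max %.4f  prop. zero %.3f\n",
              mean(v), stats::sd(v), max(v), mean(v == 0)))
  invisible(x)
}

#' Mean and SD of dyadic index values over id subsets
#'
#' With `set_a == set_b` (or `set_b` missing) the mean is over the unordered
#' within-set dyads; otherwise over the cross dyads between the two sets
#' (shared individuals contribute no self-dyads).
#'
#' @param matrix an `assoc_matrix`.
#' @param set_a,set_b character vectors of individual ids.
#' @return list with `mean`, `sd`, `n_dyads`.
#' @export
subset_means <- function(matrix, set_a, set_b = set_a) {
  stopifnot(inherits(matrix, "assoc_matrix"))
  if (!all(set_a %in% matrix$ids) || !all(set_b %in% matrix$ids))
    stop("sets must be subsets of the matrix ids")
  v <- .dyad_values(matrix, set_a, set_b)
  if (length(v) == 0L) stop("empty dyad set")
  list(mean = mean(v), sd = stats::sd(v), n_dyads = length(v))
}

# dyadic values for within- (a==b) or cross-set dyads, each unordered dyad once
.dyad_values <- function(matrix, set_a, set_b = set_a) {
  ia <- match(unique(set_a), matrix$ids)
  ib <- match(unique(set_b), matrix$ids)
  if (setequal(ia, ib)) {
    if (length(ia) < 2L) return(numeric(0))
    m <- matrix$values[ia, ia, drop = FALSE]
    m[upper.tri(m)]
  } else {
    m <- matrix$values[ia, ib, drop = FALSE]
    keep <- outer(ia, ib, "!=")
    shared <- intersect(ia, ib)
    if (length(shared)) {
      # count each dyad of shared individuals once, not twice
      dup <- outer(ia, ib, function(i, j) i %in% shared & j %in% shared & i > j)
      keep <- keep & !dup
    }
    m[keep]
  }
}

#' Coefficient of variation of the dyadic index values
#'
#' Sample SD divided by the mean over all off-diagonal unordered dyads
#' (zeros included); the test statistic of [cv_test()].
#'
#' @param matrix an `assoc_matrix`.
#' @return numeric scalar (NaN when the mean is zero).
#' @export
index_cv <- function(matrix) {
  stopifnot(inherits(matrix, "assoc_matrix"))
  v <- matrix$values[upper.tri(matrix$values)]
  m <- mean(v)
  if (m <= 0) return(NaN)
  stats::sd(v) / m
}

#' Write / read an association matrix as CSV with a JSON sidecar
#'
#' The CSV is square with an id header row and column; the sidecar stores
#' `index_kind`.
#'
#' @param matrix an `assoc_matrix`.
#' @param path CSV path; the sidecar is `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_assoc_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "assoc_matrix"))
  utils::write.csv(as.data.frame(matrix$values), path, row.names = TRUE)
  jsonlite::write_json(list(index_kind = matrix$index_kind,
                            n_individuals = length(matrix$ids)),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_assoc_matrix
#' @export
read_assoc_matrix <- function(path) {
  v <- as.matrix(utils::read.csv(path, row.names = 1, check.names = FALSE))
  meta <- jsonlite::read_json(paste0(path, ".json"))
  structure(list(ids = rownames(v), values = v,
                 index_kind = meta$index_kind, counts = NULL, flags = list()),
            class = "assoc_matrix")
}
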