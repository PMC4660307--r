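#' Average-linkage social dendrogram on association indices
#'
#' Agglomerative clustering operating directly on *similarity*: at each step
#' the two clusters with the largest average pairwise association index are
#' merged, and the merge height records that average. Heights therefore read
#' as association levels and are non-increasing along the merge sequence
#' (average linkage admits no inversions). Ties are broken deterministically
#' by the lexicographically smallest pair of cluster labels, a cluster's
#' label being its smallest member id.
#'
#' @param matrix an `assoc_matrix` (symmetric; diagonal ignored).
#' @return Object of class `social_dendrogram`: `merge` (hclust-style merge
#'   matrix), `height` (association level of each merge, non-increasing),
#'   `labels` (leaf ids), `order` (left-to-right leaf order),
#'   `index_kind`.
#' @export
average_linkage <- function(matrix) {
  stopifnot(inherits(matrix, "assoc_matrix"))
  V <- matrix$values
  n <- length(matrix$ids)
  if (n < 2L) stop("need at least 2 individuals")
  offdiag <- V[upper.tri(V) | lower.tri(V)]
  if (any(abs(V - t(V))[!is.na(V - t(V))] > 1e-12))
    stop("association matrix is not symmetric")
  S <- V
  diag(S) <- NA_real_
  labels <- matrix$ids
  clab <- labels                      # cluster label: smallest member id
  node <- -seq_len(n)                 # hclust coding
  size <- rep(1L, n)
  active <- rep(TRUE, n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)

  for (step in seq_len(n - 1L)) {
    Sa <- S
    Sa[!active, ] <- NA_real_
    Sa[, !active] <- NA_real_
    mx <- max(Sa, na.rm = TRUE)
    cand <- which(Sa == mx & upper.tri(Sa), arr.ind = TRUE)
    if (nrow(cand) > 1L) {
      key <- apply(cand, 1L, function(r) {
        l <- sort(c(clab[r[1L]], clab[r[2L]]))
        paste(l, collapse = "\r")
      })
      cand <- cand[order(key)[1L], , drop = FALSE]
    }
    i <- cand[1L, 1L]; j <- cand[1L, 2L]
    merge[step, ] <- .merge_row(node[i], node[j])
    height[step] <- mx
    # UPGMA update: weighted average of the two clusters' similarities
    newS <- (size[i] * S[i, ] + size[j] * S[j, ]) / (size[i] + size[j])
    newS[c(i, j)] <- NA_real_
    S[i, ] <- newS; S[, i] <- newS
    active[j] <- FALSE
    size[i] <- size[i] + size[j]
    clab[i] <- min(clab[i], clab[j])
    node[i] <- step
  }
  ord <- .leaf_order(merge, n)
  structure(list(merge = merge, height = height, labels = labels,
                 order = ord, index_kind = matrix$index_kind),
            class = "social_dendrogram")
}

.merge_row <- function(a, b) {
  # hclust convention: singletons (negative) listed before earlier merges;
  # two singletons by ascending leaf index, two merges by ascending step
  v <- c(a, b)
  if (all(v < 0)) return(sort(v, decreasing = TRUE))
  if (all(v > 0)) return(sort(v))
  c(v[v < 0], v[v > 0])
}

.leaf_order <- function(merge, n) {
  rec <- function(k) {
    if (k < 0) return(-k)
    c(rec(merge[k, 1L]), rec(merge[k, 2L]))
  }
  rec(n - 1L)
}

#' @export
print.social_dendrogram <- function(x, ...) {
  cat("social_dendrogram (", x$index_kind, "): ", length(x$labels),
      " leaves, first merge at ", sprintf("%.4f", x$height[1L]),
      ", last at ", sprintf("%.4f", x$height[length(x$height)]), "\n",
      sep = "")
  invisible(x)
}

#' @export
as.hclust.social_dendrogram <- function(x, ...) {
  structure(list(merge = x$merge, height = 1 - x$height,
                 order = x$order, labels = x$labels,
                 method = "average", call = match.call(),
                 dist.method = paste0("1 - ", x$index_kind)),
            class = "hclust")
}

#' @export
plot.social_dendrogram <- function(x, ...) {
  graphics::plot(as.hclust(x), ylab = paste0("1 - ", x$index_kind), ...)
}

#' Cophenetic correlation between a dendrogram and its association matrix
#'
#' The cophenetic value of a dyad is the height (association level) of the
#' lowest merge joining the two individuals; the diagnostic is the Pearson
#' correlation between original dyadic indices and cophenetic values over all
#' dyads. Values above about 0.8 are conventionally read as a good match of
#' the dendrogram to the matrix.
#'
#' @param dendrogram a `social_dendrogram`.
#' @param matrix the `assoc_matrix` it was built from (same ids).
#' @return Object of class `cluster_fit`: `cophenetic_correlation` (NA with
#'   `defined = FALSE` when either side has zero variance) and
#'   `quality_flag` (correlation >= 0.8).
#' @export
cophenetic_correlation <- function(dendrogram, matrix) {
  stopifnot(inherits(dendrogram, "social_dendrogram"),
            inherits(matrix, "assoc_matrix"))
  if (!setequal(dendrogram$labels, matrix$ids))
    stop("dendrogram leaves and matrix ids differ")
  coph <- cophenetic_matrix(dendrogram)
  pos <- match(dendrogram$labels, matrix$ids)
  V <- matrix$values[pos, pos, drop = FALSE]
  ut <- upper.tri(V)
  a <- V[ut]; b <- coph[ut]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    return(structure(list(cophenetic_correlation = NA_real_,
                          defined = FALSE, quality_flag = FALSE),
                     class = "cluster_fit"))
  }
  r <- stats::cor(a, b)
  structure(list(cophenetic_correlation = r, defined = TRUE,
                 quality_flag = r >= 0.8),
            class = "cluster_fit")
}

#' @export
print.cluster_fit <- function(x, ...) {
  if (!x$defined) {
    cat("cophenetic correlation: undefined (zero variance)\n")
  } else {
    cat(sprintf("cophenetic correlation: %.4f (%s)\n",
                x$cophenetic_correlation,
                if (x$quality_flag) "good match, >= 0.8" else "< 0.8"))
  }
  invisible(x)
}

#' Cophenetic (merge-height) matrix of a social dendrogram
#' @param dendrogram a `social_dendrogram`.
#' @return Symmetric matrix of merge heights, diagonal NA, dimnames = labels.
#' @export
cophenetic_matrix <- function(dendrogram) {
  n <- length(dendrogram$labels)
  coph <- matrix(NA_real_, n, n, dimnames = list(dendrogram$labels,
                                                 dendrogram$labels))
  members <- vector("list", n - 1L)
  leaves <- function(k) if (k < 0) -k else members[[k]]
  for (step in seq_len(n - 1L)) {
    a <- leaves(dendrogram$merge[step, 1L])
    b <- leaves(dendrogram$merge[step, 2L])
    coph[a, b] <- dendrogram$height[step]
    coph[b, a] <- dendrogram$height[step]
    members[[step]] <- c(a, b)
  }
  coph
}

#' Export a social dendrogram as a Newick tree
#'
#' Branch lengths are derived from merge heights transformed to distances
#' (`1 - index`), so the tree is ultrametric in the distance scale.
#'
#' @param dendrogram a `social_dendrogram`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(dendrogram, path) {
  phy <- ape::as.phylo(as.hclust(dendrogram))
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Write the merge table of a social dendrogram as CSV
#' @param dendrogram a `social_dendrogram`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_merge_table <- function(dendrogram, path) {
  utils::write.csv(data.frame(step = seq_along(dendrogram$height),
                              node_1 = dendrogram$merge[, 1L],
                              node_2 = dendrogram$merge[, 2L],
                              association_level = dendrogram$height),
                   path, row.names = FALSE)
  invisible(path)
}
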