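# Brute-force oracles and fixture builders shared across the test files.
# Every oracle recomputes its quantity by direct enumeration, independently
# of the package's implementation paths.

# build a sighting_data from a list of groups: list(list(date=, survey=,
# members=), ...)
dataset_from_groups <- function(groups) {
  rec <- do.call(rbind, lapply(groups, function(g)
    data.frame(date = g$date, survey_id = g$survey,
               individual_id = g$members, stringsAsFactors = FALSE)))
  sighting_data(rec)
}

# random small dataset: N individuals, P days, 1-2 surveys/day, each survey
# detects a random subset split into 1-3 groups
random_small_dataset <- function(seed, N = 6, P = 10) {
  set.seed(seed)
  ids <- letters[seq_len(N)]
  rec <- NULL
  for (p in seq_len(P)) {
    for (sv in seq_len(sample(1:2, 1))) {
      det <- which(stats::runif(N) < stats::runif(1, 0.3, 0.9))
      if (!length(det)) next
      gsplit <- sample(1:3, length(det), replace = TRUE)
      for (g in unique(gsplit)) {
        rec <- rbind(rec, data.frame(
          date = sprintf("2000-01-%02d", p),
          survey_id = sprintf("d%02ds%dg%d", p, sv, g),
          individual_id = ids[det[gsplit == g]],
          stringsAsFactors = FALSE))
      }
    }
  }
  if (is.null(rec)) return(NULL)
  sighting_data(rec)
}

# naive per-dyad HWI with the explicit x / (x + y_ab + 0.5 (y_a + y_b))
# formula, enumerating sampling periods one by one
oracle_hwi <- function(dataset) {
  ids <- dataset$individuals$id
  N <- length(ids)
  S <- length(dataset$samples)
  seen <- matrix(FALSE, N, S, dimnames = list(ids, NULL))
  together <- array(FALSE, c(N, N, S))
  for (k in seq_along(dataset$groups)) {
    g <- match(dataset$groups[[k]], ids)
    s <- dataset$group_sample[k]
    seen[g, s] <- TRUE
    for (a in g) for (b in g) if (a != b) together[a, b, s] <- TRUE
  }
  out <- matrix(NA_real_, N, N, dimnames = list(ids, ids))
  for (a in seq_len(N - 1)) for (b in (a + 1):N) {
    x <- y_ab <- y_a <- y_b <- 0
    for (s in seq_len(S)) {
      if (together[a, b, s]) x <- x + 1
      else if (seen[a, s] && seen[b, s]) y_ab <- y_ab + 1
      else if (seen[a, s]) y_a <- y_a + 1
      else if (seen[b, s]) y_b <- y_b + 1
    }
    denom <- x + y_ab + 0.5 * (y_a + y_b)
    out[a, b] <- out[b, a] <- if (denom > 0) x / denom else 0
  }
  out
}

# brute-force average linkage on similarity: recompute every cluster-pair
# average from the original matrix at every step; same lexicographic
# tie-break rule as the implementation contract
oracle_avg_linkage <- function(values, ids) {
  clusters <- lapply(seq_along(ids), function(i) i)
  heights <- numeric(0)
  partitions <- list()
  while (length(clusters) > 1L) {
    best <- NULL
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (j <= i) next
      avg <- mean(values[clusters[[i]], clusters[[j]]])
      lab <- sort(c(min(ids[clusters[[i]]]), min(ids[clusters[[j]]])))
      if (is.null(best) || avg > best$avg ||
          (avg == best$avg &&
           (lab[1] < best$lab[1] ||
            (lab[1] == best$lab[1] && lab[2] < best$lab[2])))) {
        best <- list(i = i, j = j, avg = avg, lab = lab)
      }
    }
    heights <- c(heights, best$avg)
    merged <- c(clusters[[best$i]], clusters[[best$j]])
    clusters <- c(clusters[-c(best$i, best$j)], list(merged))
    partitions <- c(partitions,
                    list(sort(vapply(list(merged), function(m)
                      paste(sort(ids[m]), collapse = "+"), character(1)))))
  }
  list(heights = heights, partitions = unlist(partitions))
}

# canonical description of a social_dendrogram: per merge, the sorted member
# labels of the newly formed cluster plus its height
dendrogram_canonical <- function(dend) {
  n <- length(dend$labels)
  members <- vector("list", n - 1L)
  leaves <- function(k) if (k < 0) -k else members[[k]]
  out <- character(n - 1L)
  for (s in seq_len(n - 1L)) {
    m <- c(leaves(dend$merge[s, 1L]), leaves(dend$merge[s, 2L]))
    members[[s]] <- m
    out[s] <- paste(sort(dend$labels[m]), collapse = "+")
  }
  list(partitions = out, heights = dend$height)
}

# quadruple-loop SLAR tallies over (period pair, ordered individual pair)
oracle_slar_tallies <- function(dataset, edges, subset = NULL) {
  if (is.null(subset)) subset <- dataset$individuals$id
  ids <- sort(unique(subset))
  N <- length(ids)
  S <- length(dataset$samples)
  seen <- matrix(FALSE, N, S)
  assoc <- array(FALSE, c(N, N, S))
  for (k in seq_along(dataset$groups)) {
    g <- match(dataset$groups[[k]], ids)
    g <- g[!is.na(g)]
    s <- dataset$group_sample[k]
    seen[g, s] <- TRUE
    for (a in g) for (b in g) if (a != b) assoc[a, b, s] <- TRUE
  }
  tm <- as.numeric(dataset$samples)
  nb <- length(edges) - 1L
  num <- den <- numeric(nb)
  for (t1 in seq_len(S)) for (t2 in seq_len(S)) {
    if (t2 <= t1) next
    lag <- tm[t2] - tm[t1]
    if (lag < edges[1] || lag > edges[nb + 1]) next
    bin <- findInterval(lag, edges, left.open = TRUE,
                        rightmost.closed = TRUE)
    for (i in seq_len(N)) {
      if (!seen[i, t2]) next
      d1 <- sum(assoc[i, , t1])
      if (d1 == 0) next
      den[bin] <- den[bin] + d1 * sum(assoc[i, , t2])
      for (j in seq_len(N))
        if (assoc[i, j, t1] && assoc[i, j, t2]) num[bin] <- num[bin] + 1
    }
  }
  list(num = num, den = den)
}

# all distinct arrangements of a two-class label vector (positions of the
# rarer class), for exact permutation p-values at small N
enumerate_two_class_stats <- function(values_matrix, classes, stat_fun) {
  n <- length(classes)
  lv <- unique(classes)
  stopifnot(length(lv) == 2L)
  k <- sum(classes == lv[2L])
  combos <- utils::combn(n, k)
  apply(combos, 2L, function(pos) {
    lab <- rep(lv[1L], n)
    lab[pos] <- lv[2L]
    stat_fun(lab)
  })
}

# per-sample tallies that any number of flips must conserve
conservation_tallies <- function(dataset) {
  list(
    group_sizes = lapply(split(lengths(dataset$groups),
                               dataset$group_sample), sort),
    per_ind_sample = table(
      rep(dataset$group_sample, lengths(dataset$groups)),
      unlist(dataset$groups, use.names = FALSE)))
}
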