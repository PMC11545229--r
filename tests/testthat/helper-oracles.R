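# Independent brute-force oracles, written from first principles so they
# never share code paths with the implementation.

# Pearson correlation straight from the definition
brute_pearson <- function(x, y) {
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  num <- sum((x - mx) * (y - my))
  den <- sqrt(sum((x - mx)^2)) * sqrt(sum((y - my)^2))
  num / den
}

# variance-explained shares from an explicit covariance matrix and its
# eigendecomposition (observations in rows)
brute_pca_variance_shares <- function(X) {
  n <- nrow(X)
  Xc <- sweep(X, 2, colMeans(X))
  C <- matrix(0, ncol(X), ncol(X))
  for (i in seq_len(ncol(X))) {
    for (j in seq_len(ncol(X))) {
      C[i, j] <- sum(Xc[, i] * Xc[, j]) / (n - 1)
    }
  }
  ev <- sort(eigen(C, symmetric = TRUE)$values, decreasing = TRUE)
  100 * ev / sum(ev)
}

# naive average-linkage agglomeration on a distance matrix; returns the
# member sets merged at each step and the merge heights
brute_average_linkage <- function(D) {
  labels <- rownames(D)
  clusters <- as.list(labels)
  merges <- list()
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA)
    best_d <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i >= j) next
        ds <- outer(clusters[[i]], clusters[[j]],
                    Vectorize(function(a, b) D[a, b]))
        d <- mean(ds)
        if (d < best_d) {
          best_d <- d
          best <- c(i, j)
        }
      }
    }
    merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    merges[[length(merges) + 1]] <- merged
    heights <- c(heights, best_d)
    clusters[[best[1]]] <- merged
    clusters[[best[2]]] <- NULL
  }
  list(merges = merges, heights = heights)
}

# member sets merged at each step of an hclust tree
hclust_merge_sets <- function(hc) {
  sets <- vector("list", nrow(hc$merge))
  for (s in seq_len(nrow(hc$merge))) {
    members <- function(k) {
      if (k < 0) hc$labels[-k] else sets[[k]]
    }
    sets[[s]] <- sort(c(members(hc$merge[s, 1]), members(hc$merge[s, 2])))
  }
  sets
}
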