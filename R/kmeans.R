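#' k-means with correlation distance
#'
#' Lloyd-style k-means on temporal profiles using one minus the Pearson
#' correlation as the distance. Profiles are row-standardized (zero mean,
#' unit variance across time) and centroids are re-standardized after every
#' update, so assignment reduces to maximizing the inner product between a
#' standardized profile and a standardized centroid. An emptied cluster is
#' reseeded with the profile farthest from its current centroid.
#'
#' @param profiles numeric G x T matrix (rows are transcripts); every row
#'   must have nonzero variance across the T columns.
#' @param K number of clusters, `2 <= K <= G` (K = G puts every profile in
#'   its own cluster).
#' @param seed integer seed; identical seeds give identical results.
#' @param max_iter maximum Lloyd iterations (default 100).
#' @return An object of class `cluster_assignment`: list with `labels`
#'   (integer 1..K per row), `K`, `member_counts`, `centroids` (K x T
#'   standardized), and `iterations`.
#' @export
kmeans_correlation <- function(profiles, K, seed = 1L, max_iter = 100L) {
  profiles <- as.matrix(profiles)
  G <- nrow(profiles)
  stopifnot(K >= 1L, G >= K, ncol(profiles) >= 2L)
  Z <- standardize_rows(profiles)
  Tn <- ncol(Z)

  res <- with_seed(seed, {
    centroids <- Z[sample.int(G, K), , drop = FALSE]
    labels <- integer(G)
    iter <- 0L
    repeat {
      iter <- iter + 1L
      # similarity = Pearson correlation; distance = 1 - similarity
      sim <- Z %*% t(centroids) / (Tn - 1)
      new_labels <- max.col(sim, ties.method = "first")
      # reseed emptied clusters with the globally worst-fitting profile;
      # loop because moving a singleton's point can empty its old cluster
      repeat {
        empty <- which(tabulate(new_labels, K) == 0L)
        if (!length(empty)) break
        worst <- which.min(sim[cbind(seq_len(G), new_labels)])
        new_labels[worst] <- empty[1L]
        sim[worst, ] <- Inf   # cannot be stolen again this round
      }
      changed <- !identical(new_labels, labels)
      labels <- new_labels
      centroids <- t(vapply(seq_len(K), function(k) {
        m <- colMeans(Z[labels == k, , drop = FALSE])
        if (stats::sd(m) == 0) m <- Z[which(labels == k)[1L], ]  # degenerate mean
        m
      }, numeric(Tn)))
      centroids <- standardize_rows(centroids, what = "centroid")
      if (!changed || iter >= max_iter) break
    }
    list(labels = labels, centroids = centroids, iterations = iter)
  })

  structure(list(labels = res$labels, K = K,
                 member_counts = tabulate(res$labels, K),
                 centroids = res$centroids,
                 iterations = res$iterations),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("cluster_assignment: K = ", x$K, ", sizes: ",
      paste(x$member_counts, collapse = ", "), "\n", sep = "")
  invisible(x)
}
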