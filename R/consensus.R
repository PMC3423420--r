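#' Consensus clustering over resampled k-means runs
#'
#' For each candidate cluster count K, repeatedly subsamples the profiles
#' (without replacement) and clusters the subsample with
#' [kmeans_correlation()]. The consensus matrix records, for every pair of
#' profiles, the fraction of runs in which they were assigned to the same
#' cluster among the runs that sampled both. The empirical CDF of the
#' off-diagonal consensus values, its area, and the relative area increase
#' between consecutive K ("delta area") summarize clustering stability and
#' drive the choice of K in [select_k()].
#'
#' @param profiles numeric G x T matrix of temporal profiles.
#' @param k_range integer vector of candidate cluster counts (each >= 2).
#' @param n_runs subsampled clustering runs per candidate K (default 1000).
#' @param sample_rate fraction of profiles drawn in each run (default 0.8).
#' @param seed integer base seed; run r for the i-th candidate K uses seed
#'   `seed + (i-1)*n_runs + r`, so every run is individually reproducible.
#' @return An object of class `consensus_result`: list with `k_range`,
#'   `consensus` (list of G x G matrices, values in \[0,1\], diagonal 1),
#'   `co_sampled` (list of G x G integer count matrices), `cdf` (list of
#'   functions F(x) on \[0,1\]), `area` (area under each CDF), `delta_area`
#'   (relative area increase per K; the first entry is the area itself),
#'   and `assignments` (a full-data [kmeans_correlation()] assignment per
#'   K, for downstream template building).
#' @references Monti S. et al. (2003) Consensus clustering: a
#'   resampling-based method for class discovery. Machine Learning 52.
#' @export
consensus_cluster <- function(profiles, k_range = 2:9, n_runs = 1000L,
                              sample_rate = 0.8, seed = 1L) {
  profiles <- as.matrix(profiles)
  G <- nrow(profiles)
  stopifnot(length(k_range) >= 1L, all(k_range >= 2L), all(k_range <= G),
            n_runs >= 1L, sample_rate > 0, sample_rate <= 1)
  tn_log("consensus_cluster: G=%d, K in {%s}, %d runs, rate %.2f, seed %d",
         G, paste(k_range, collapse = ","), n_runs, sample_rate, as.integer(seed))

  n_sub <- max(max(k_range), round(sample_rate * G))
  consensus <- co_sampled <- cdfs <- vector("list", length(k_range))
  assignments <- vector("list", length(k_range))
  area <- numeric(length(k_range))

  for (ki in seq_along(k_range)) {
    K <- k_range[ki]
    co_cluster <- matrix(0, G, G)
    co_sample <- matrix(0, G, G)
    for (r in seq_len(n_runs)) {
      run_seed <- as.integer(seed) + (ki - 1L) * as.integer(n_runs) + r
      idx <- with_seed(run_seed, sort(sample.int(G, n_sub)))
      ca <- kmeans_correlation(profiles[idx, , drop = FALSE], K,
                               seed = run_seed)
      ind <- matrix(0, G, 1L)
      ind[idx] <- 1
      co_sample <- co_sample + tcrossprod(ind)
      lab <- matrix(0, G, K)
      lab[cbind(idx, ca$labels)] <- 1
      co_cluster <- co_cluster + tcrossprod(lab)
    }
    cons <- ifelse(co_sample > 0, co_cluster / pmax(co_sample, 1), 0)
    diag(cons) <- 1
    never <- sum(co_sample[upper.tri(co_sample)] == 0)
    if (never > 0)
      warning(never, " profile pairs were never co-sampled; their consensus is 0",
              call. = FALSE)
    off <- cons[upper.tri(cons)]
    cdfs[[ki]] <- stats::ecdf(off)
    area[ki] <- cdf_area(off)
    consensus[[ki]] <- cons
    co_sampled[[ki]] <- co_sample
    assignments[[ki]] <- kmeans_correlation(profiles, K, seed = as.integer(seed) + ki)
  }
  delta <- numeric(length(k_range))
  delta[1L] <- area[1L]
  if (length(k_range) > 1L)
    for (ki in 2:length(k_range))
      delta[ki] <- if (area[ki - 1L] > 0)
        (area[ki] - area[ki - 1L]) / area[ki - 1L] else area[ki]

  structure(list(k_range = k_range, consensus = consensus,
                 co_sampled = co_sampled, cdf = cdfs, area = area,
                 delta_area = delta, assignments = assignments,
                 n_runs = n_runs, sample_rate = sample_rate, seed = seed),
            class = "consensus_result")
}

# Exact area under the empirical CDF of `values` over [0, 1]; the CDF is a
# right-continuous step function, so the area is a finite sum.
cdf_area <- function(values) {
  x <- sort(values)
  n <- length(x)
  if (n == 0L) return(0)
  knots <- c(0, x, 1)
  F_at <- c(0, seq_len(n) / n)       # CDF value on [knots[i], knots[i+1])
  sum(diff(knots) * F_at)
}

#' @export
print.consensus_result <- function(x, ...) {
  cat("consensus_result over K = {", paste(x$k_range, collapse = ", "),
      "} (", x$n_runs, " runs, rate ", x$sample_rate, ")\n", sep = "")
  out <- data.frame(K = x$k_range, area = signif(x$area, 4),
                    delta_area = signif(x$delta_area, 4))
  print(out, row.names = FALSE)
  invisible(x)
}

#' Choose the number of clusters from a consensus result
#'
#' Returns the largest candidate K whose relative increase in area under
#' the consensus CDF exceeds `delta_threshold`. A flat curve (no candidate
#' exceeds the threshold) falls back to the smallest candidate with a
#' warning. The full delta-area curve is attached for manual override.
#'
#' @param cr a `consensus_result` from [consensus_cluster()].
#' @param delta_threshold minimum relative area increase (default 0.1).
#' @return The selected K (integer) with attributes `delta_area` and
#'   `k_range`.
#' @export
select_k <- function(cr, delta_threshold = 0.1) {
  stopifnot(inherits(cr, "consensus_result"))
  ok <- which(cr$delta_area > delta_threshold)
  if (!length(ok)) {
    warning("flat consensus CDF curve; falling back to K = ",
            min(cr$k_range), call. = FALSE)
    k <- min(cr$k_range)
  } else {
    k <- cr$k_range[max(ok)]
  }
  structure(as.integer(k), delta_area = cr$delta_area, k_range = cr$k_range)
}
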