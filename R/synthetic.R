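#' Generate a sparse time-varying linear system with noisy observations
#'
#' Builds a ground-truth series of T-1 sparse K x K transition matrices and
#' simulates noisy trajectories from `v(t+1) = W(t) v(t)`. The first matrix
#' has exactly `round(density * K^2)` nonzero entries drawn uniformly from
#' \[-1, 1\]; each subsequent matrix copies its predecessor and resamples
#' `n_perturb` uniformly chosen entry positions, each becoming nonzero
#' (fresh uniform value) with probability `density` and zero otherwise, so
#' adjacent matrices differ in at most `n_perturb` positions and the
#' expected density is preserved. Each of the `n_samples` observations
#' starts from its own standard-normal initial state, is propagated
#' noiselessly, and then receives independent Gaussian noise with per-entry
#' standard deviation `noise_frac * |clean value|` (entries whose clean
#' value is exactly zero use `noise_frac` times the root-mean-square of the
#' clean trajectory instead).
#'
#' @param K number of nodes (default 9).
#' @param T number of time points (default 4; there are T-1 transitions).
#' @param density fraction of nonzero entries per matrix (default 0.1).
#' @param n_perturb entry positions resampled between adjacent matrices
#'   (default 10).
#' @param noise_frac observation noise as a fraction of the signal
#'   (default 0.1).
#' @param n_samples number of observed trajectories (default 20).
#' @param seed integer seed; the whole problem is reproducible.
#' @return An object of class `synthetic_problem`: list with `truth` (list
#'   of T-1 matrices), `noiseless` and `observations` (lists of `n_samples`
#'   K x T matrices), and the generating parameters.
#' @export
generate_synthetic <- function(K = 9, T = 4, density = 0.1, n_perturb = 10,
                               noise_frac = 0.1, n_samples = 20, seed = 1L) {
  stopifnot(K >= 2, T >= 2, density > 0, density <= 1,
            n_perturb >= 0, n_perturb <= K^2, noise_frac >= 0, n_samples >= 1)
  nnz <- round(density * K^2)
  if (nnz < 1)
    stop("density * K^2 must round to at least one nonzero entry", call. = FALSE)
  tn_log("generate_synthetic: K=%d T=%d density=%g perturb=%d noise=%g samples=%d seed=%d",
         K, T, density, n_perturb, noise_frac, n_samples, as.integer(seed))

  # A draw is degenerate for recovery purposes when a node receives no
  # input (an all-zero row silences its state from the next frame on) or
  # the cumulative transition product up to that frame is poorly
  # conditioned (the states collapse toward a subspace, leaving
  # downstream transition entries unidentifiable -- or identifiable only
  # with unbounded noise amplification -- even at zero observation
  # noise). When the nonzero budget allows (round(density * K^2) >= K)
  # degenerate draws are rejected and redrawn so the noiseless system
  # stays well-posed; with a budget below K degeneracy is unavoidable and
  # draws are kept as they come.
  constrain <- nnz >= K
  degenerate <- function(W, prod_prev, check_prod) {
    if (!constrain) return(FALSE)
    if (sum(W != 0) < K || any(rowSums(W != 0) == 0L) || rcond(W) < 1e-3)
      return(TRUE)
    check_prod && rcond(W %*% prod_prev) < 0.03
  }
  with_seed(seed, {
    truth <- vector("list", T - 1L)
    prod_prev <- diag(K)
    for (try in seq_len(1000L)) {
      W <- matrix(0, K, K)
      if (constrain) {
        # a permutation support guarantees row/column coverage and generic
        # nonsingularity; extra entries fill the remaining budget
        perm <- seq_len(K) + (sample.int(K) - 1L) * K
        pos <- c(perm, sample(setdiff(seq_len(K^2), perm), nnz - K))
      } else {
        pos <- sample.int(K^2, nnz)
      }
      W[pos] <- stats::runif(nnz, -1, 1)
      if (!degenerate(W, prod_prev, check_prod = T > 2L)) break
    }
    truth[[1L]] <- W
    prod_prev <- W %*% prod_prev
    if (T > 2L) for (t in 2:(T - 1L)) {
      check_prod <- t < T - 1L   # the last frame feeds no later block
      for (try in seq_len(1000L)) {
        W <- truth[[t - 1L]]
        pos <- sample.int(K^2, n_perturb)
        W[pos] <- ifelse(stats::runif(n_perturb) < density,
                         stats::runif(n_perturb, -1, 1), 0)
        if (!degenerate(W, prod_prev, check_prod)) break
      }
      truth[[t]] <- W
      prod_prev <- W %*% prod_prev
    }
    noiseless <- lapply(seq_len(n_samples), function(n) {
      V <- matrix(0, K, T)
      V[, 1L] <- stats::rnorm(K)
      for (t in seq_len(T - 1L)) V[, t + 1L] <- truth[[t]] %*% V[, t]
      V
    })
    observations <- lapply(noiseless, function(V) {
      sd_mat <- noise_frac * abs(V)
      zero <- V == 0
      if (any(zero)) sd_mat[zero] <- noise_frac * sqrt(mean(V^2))
      V + matrix(stats::rnorm(length(V), sd = as.numeric(sd_mat)), K, T)
    })
    structure(list(truth = truth, noiseless = noiseless,
                   observations = observations,
                   K = K, T = T, density = density, n_perturb = n_perturb,
                   noise_frac = noise_frac, n_samples = n_samples,
                   seed = as.integer(seed)),
              class = "synthetic_problem")
  })
}

#' @export
print.synthetic_problem <- function(x, ...) {
  nnz <- vapply(x$truth, function(w) sum(w != 0), numeric(1L))
  cat("synthetic_problem: K = ", x$K, ", T = ", x$T, ", ",
      x$n_samples, " samples, noise ", x$noise_frac, "\n", sep = "")
  cat("  nonzero entries per transition matrix: ",
      paste(nnz, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Score support recovery of an estimated transition series
#'
#' Compares the nonzero support (entries with magnitude above `threshold`)
#' of an estimated transition series against the ground truth, over all
#' (transition, row, column) positions jointly.
#'
#' @param truth ground-truth series: a `synthetic_problem`, a `tvnet` fit,
#'   or a list of K x K matrices.
#' @param estimate estimated series, same forms accepted.
#' @param threshold magnitude above which an entry counts as present
#'   (default 1e-3).
#' @return List of class `recovery_metrics`: `precision` (1 when nothing is
#'   predicted), `recall`, `f1`, `sign_accuracy` (agreement of signs over
#'   true positives; `NA` when there are none), and `frobenius_rmse`
#'   (root-mean-square entrywise error).
#' @export
evaluate_recovery <- function(truth, estimate, threshold = 1e-3) {
  if (inherits(truth, "synthetic_problem")) truth <- truth$truth
  truth <- as_transition_list(truth)
  estimate <- as_transition_list(estimate)
  if (length(truth) != length(estimate) ||
      !all(dim(truth[[1L]]) == dim(estimate[[1L]])))
    stop("truth and estimate shapes differ", call. = FALSE)
  tv <- unlist(truth)
  ev <- unlist(estimate)
  ts <- abs(tv) > threshold
  es <- abs(ev) > threshold
  tp <- sum(ts & es)
  precision <- if (sum(es) == 0) 1 else tp / sum(es)
  recall <- if (sum(ts) == 0) 1 else tp / sum(ts)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  sign_acc <- if (tp == 0) NA_real_ else
    mean(sign(tv[ts & es]) == sign(ev[ts & es]))
  structure(list(precision = precision, recall = recall, f1 = f1,
                 sign_accuracy = sign_acc,
                 frobenius_rmse = sqrt(mean((tv - ev)^2))),
            class = "recovery_metrics")
}

#' @export
print.recovery_metrics <- function(x, ...) {
  cat(sprintf("support recovery: precision %.3f, recall %.3f, F1 %.3f\n",
              x$precision, x$recall, x$f1))
  cat(sprintf("sign accuracy (true positives): %s; Frobenius RMSE: %.4g\n",
              ifelse(is.na(x$sign_accuracy), "NA",
                     sprintf("%.3f", x$sign_accuracy)),
              x$frobenius_rmse))
  invisible(x)
}

#' Generate planted-cluster temporal profiles
#'
#' Creates G temporal profiles organized into K well-separated clusters for
#' exercising the consensus-clustering stage. When `K <= T`, cluster base
#' patterns are the vertices of a regular simplex embedded in the
#' (T-1)-dimensional space of zero-mean profiles, giving pairwise
#' correlation `-1/(K-1)` between patterns; members are base pattern plus
#' independent Gaussian noise. With the default `noise_sd` the
#' within-cluster correlations exceed 0.95.
#'
#' @param G number of profiles (default 40); clusters get equal shares.
#' @param K number of planted clusters (default 4).
#' @param T number of time points (default 4); requires `K <= T`.
#' @param noise_sd standard deviation of member noise relative to the
#'   unit-norm base patterns (default 0.05).
#' @param seed integer seed.
#' @return List with `profiles` (G x T matrix with rownames), `labels`
#'   (planted cluster of each row), and `patterns` (K x T base matrix).
#' @export
generate_planted_profiles <- function(G = 40, K = 4, T = 4, noise_sd = 0.05,
                                      seed = 1L) {
  stopifnot(G >= K, K >= 2, K <= T)
  # Orthonormal basis of the zero-mean subspace of R^T
  B <- qr.Q(qr(cbind(rep(1, T), diag(T)[, seq_len(T - 1L)])))[, -1L, drop = FALSE]
  # Regular simplex: rows of I - 1/K, normalized, are K unit vectors in the
  # subspace of R^K orthogonal to the ones vector, with pairwise inner
  # product -1/(K-1). Express them in an orthonormal basis of that
  # (K-1)-dimensional subspace, pad to dimension T-1, and map into the
  # zero-mean profile space.
  vertices <- t(apply(diag(K) - 1 / K, 1L, function(v) v / sqrt(sum(v^2))))
  U <- qr.Q(qr(cbind(rep(1, K), diag(K)[, seq_len(K - 1L)])))[, -1L, drop = FALSE]
  coords <- vertices %*% U                          # K x (K-1)
  if (K - 1L < T - 1L)
    coords <- cbind(coords, matrix(0, K, (T - 1L) - (K - 1L)))
  patterns <- coords %*% t(B)                       # K x T, zero-mean rows
  rownames(patterns) <- paste0("pattern", seq_len(K))

  labels <- rep(seq_len(K), length.out = G)
  labels <- sort(labels)
  profiles <- with_seed(seed, {
    patterns[labels, , drop = FALSE] +
      matrix(stats::rnorm(G * T, sd = noise_sd), G, T)
  })
  rownames(profiles) <- sprintf("g%03d", seq_len(G))
  colnames(profiles) <- paste0(seq_len(T), "h")
  list(profiles = profiles, labels = labels, patterns = patterns)
}
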