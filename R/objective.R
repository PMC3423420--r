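# Sufficient statistics of the sliding-window weighted loss.
#
# For N data matrices V_n (K x T, columns v_n(t)) and forward window
# weights w(t, t_hat), the loss
#   (1/N) sum_n sum_{t_hat} sum_{t in window} w(t, t_hat) ||v_n(t+1) - W(t_hat) v_n(t)||^2
# depends on the data only through, per centering frame t_hat,
#   S  = (1/N) sum w v(t)   v(t)'   (K x K Gram)
#   C  = (1/N) sum w v(t+1) v(t)'   (K x K cross-product)
#   c0 = (1/N) sum w ||v(t+1)||^2,
# so fitting cost is independent of N after this pass.
loss_suffstats <- function(data, window) {
  data <- as_data_list(data)
  K <- nrow(data[[1L]]); Tn <- ncol(data[[1L]]); N <- length(data)
  n_frames <- Tn - 1L
  S <- C <- vector("list", n_frames)
  c0 <- numeric(n_frames)
  for (th in seq_len(n_frames)) {
    Sth <- Cth <- matrix(0, K, K)
    c0th <- 0
    for (t in th:min(th + window$delta, n_frames)) {
      w <- window_weight(t, th, window)
      for (V in data) {
        vt <- V[, t]; vt1 <- V[, t + 1L]
        Sth <- Sth + w * tcrossprod(vt)
        Cth <- Cth + w * tcrossprod(vt1, vt)
        c0th <- c0th + w * sum(vt1^2)
      }
    }
    S[[th]] <- Sth / N
    C[[th]] <- Cth / N
    c0[th] <- c0th / N
  }
  list(S = S, C = C, c0 = c0, K = K, T = Tn, N = N, n_frames = n_frames)
}

#' Evaluate the inference objective term by term
#'
#' Computes the three components of the objective minimized by [tvnet()]
#' for a given series of transition matrices: the sliding-window weighted
#' reconstruction loss (averaged over the data matrices), the temporal
#' smoothness penalty `sum_{t1<t2} M(t1,t2) ||W(t1) - W(t2)||_F^2`, and the
#' entrywise L1 norm `sum_t ||W(t)||_1`, together with the penalized total
#' `loss + lambda1 * smoothness + lambda2 * sparsity`.
#'
#' @param W a fitted `tvnet` object or a list of T-1 K x K matrices.
#' @param data one K x T matrix or a list of them.
#' @param lambda1,lambda2 non-negative smoothness and sparsity weights.
#' @param window a [tvnet_window()].
#' @param indicator a [tvnet_indicator()].
#' @return List with `loss`, `smoothness`, `sparsity`, `total`.
#' @export
tvnet_objective <- function(W, data, lambda1 = 0, lambda2 = 0,
                            window = tvnet_window(),
                            indicator = tvnet_indicator()) {
  W <- as_transition_list(W)
  stats <- loss_suffstats(data, window)
  if (length(W) != stats$n_frames)
    stop("expected ", stats$n_frames, " transition matrices, got ", length(W),
         call. = FALSE)
  M <- smoothness_matrix(indicator, stats$n_frames)
  objective_terms(W, stats, lambda1, lambda2, M)
}

# Internal objective evaluation from precomputed sufficient statistics.
objective_terms <- function(W, stats, lambda1, lambda2, M) {
  loss <- 0
  for (th in seq_len(stats$n_frames)) {
    Wt <- W[[th]]
    loss <- loss + stats$c0[th] - 2 * sum(Wt * stats$C[[th]]) +
      sum((Wt %*% stats$S[[th]]) * Wt)
  }
  smooth <- 0
  if (stats$n_frames > 1L) {
    for (t1 in 1:(stats$n_frames - 1L)) for (t2 in (t1 + 1L):stats$n_frames)
      if (M[t1, t2] != 0)
        smooth <- smooth + M[t1, t2] * sum((W[[t1]] - W[[t2]])^2)
  }
  sparsity <- sum(vapply(W, function(w) sum(abs(w)), numeric(1L)))
  list(loss = loss, smoothness = smooth, sparsity = sparsity,
       total = loss + lambda1 * smooth + lambda2 * sparsity)
}

#' Smallest sparsity weight that zeroes the whole solution
#'
#' For the objective minimized by [tvnet()], the all-zero transition series
#' is optimal exactly when `lambda2` is at least twice the largest absolute
#' entry of the per-frame weighted cross-products between consecutive
#' states (the gradient of the loss at zero; the smoothness penalty
#' vanishes there). Any `lambda2 >= lambda_max(data, window)` therefore
#' yields an exactly zero estimate.
#'
#' @inheritParams tvnet_objective
#' @return The critical value of `lambda2` (a single number).
#' @export
lambda_max <- function(data, window = tvnet_window()) {
  stats <- loss_suffstats(data, window)
  2 * max(vapply(stats$C, function(C) max(abs(C)), numeric(1L)))
}
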