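#' Sliding-window weighting scheme
#'
#' Describes the forward-looking sliding window used in the reconstruction
#' loss. When estimating the transition matrix centered at frame `t_hat`,
#' the transitions at frames `t_hat, t_hat+1, ..., t_hat+delta` (clipped at
#' the last valid transition) all contribute, with a weight that is 1 at
#' the centering frame and decays with the offset. This borrows strength
#' from adjacent transitions, trading a small bias for variance reduction
#' on short, low-replicate time courses.
#'
#' @param delta non-negative integer window extent (number of forward
#'   offsets beyond the centering frame; default 2).
#' @param decay `"gaussian"` (default), weight `exp(-d^2 / (2 sigma^2))` at
#'   offset d, or `"exponential"`, weight `exp(-d / sigma)`.
#' @param sigma positive decay scale (default 1).
#' @return An object of class `tvnet_window`.
#' @export
tvnet_window <- function(delta = 2L, decay = c("gaussian", "exponential"),
                         sigma = 1) {
  decay <- match.arg(decay)
  stopifnot(delta >= 0L, delta == round(delta), sigma > 0)
  structure(list(delta = as.integer(delta), decay = decay, sigma = sigma),
            class = "tvnet_window")
}

#' Evaluate a sliding-window weight
#'
#' @param t transition frame contributing to the loss.
#' @param t_hat centering frame whose transition matrix is being estimated.
#' @param window a [tvnet_window()].
#' @return The weight: 1 at `t == t_hat`, decaying for `t` up to
#'   `t_hat + delta`, and exactly 0 outside the window (including all
#'   `t < t_hat`; the window is forward-only).
#' @export
window_weight <- function(t, t_hat, window = tvnet_window()) {
  stopifnot(inherits(window, "tvnet_window"))
  d <- t - t_hat
  w <- ifelse(d < 0 | d > window$delta, 0,
              switch(window$decay,
                     gaussian = exp(-d^2 / (2 * window$sigma^2)),
                     exponential = exp(-d / window$sigma)))
  w
}

#' Temporal-smoothness proximity indicator
#'
#' Defines which pairs of transition matrices are tied together by the
#' smoothness penalty and how strongly. The hard indicator ties all pairs
#' of frames within `radius` of each other with weight 1; the soft
#' indicator weights every pair by `exp(-(t1 - t2)^2 / tau)`. Same-frame
#' pairs never enter the penalty.
#'
#' @param kind `"hard"` (default) or `"soft"`.
#' @param radius positive integer radius for the hard indicator (default 1:
#'   adjacent transitions only).
#' @param tau positive scale for the soft indicator (default 1).
#' @return An object of class `tvnet_indicator`.
#' @export
tvnet_indicator <- function(kind = c("hard", "soft"), radius = 1L, tau = 1) {
  kind <- match.arg(kind)
  stopifnot(radius >= 1L, tau > 0)
  structure(list(kind = kind, radius = as.integer(radius), tau = tau),
            class = "tvnet_indicator")
}

#' Smoothness proximity matrix for a series of transition frames
#'
#' @param indicator a [tvnet_indicator()].
#' @param n_frames number of transition matrices (T - 1).
#' @return Symmetric `n_frames` x `n_frames` matrix M with zero diagonal;
#'   `M[t1, t2]` weights the penalty `||W(t1) - W(t2)||_F^2`.
#' @export
smoothness_matrix <- function(indicator = tvnet_indicator(), n_frames) {
  stopifnot(inherits(indicator, "tvnet_indicator"), n_frames >= 1L)
  d <- abs(outer(seq_len(n_frames), seq_len(n_frames), "-"))
  M <- switch(indicator$kind,
              hard = (d > 0 & d <= indicator$radius) * 1,
              soft = exp(-d^2 / indicator$tau))
  diag(M) <- 0
  M
}

#' Solver control parameters for [tvnet()]
#'
#' @param tol_outer relative change in the total objective below which the
#'   block-coordinate cycling stops (default 1e-6).
#' @param tol_inner relative coefficient-change tolerance of the block
#'   subproblem solver (default 1e-8).
#' @param max_cycles maximum block-coordinate cycles (default 500).
#' @param max_inner maximum coordinate-descent sweeps per block update
#'   (default 5000).
#' @param tol_exact coordinate-change tolerance of the exact vectorized
#'   solver (default 1e-9).
#' @param max_sweeps maximum coordinate-descent sweeps of the exact solver
#'   (default 20000).
#' @return A list of class `tvnet_control`.
#' @export
tvnet_control <- function(tol_outer = 1e-6, tol_inner = 1e-8,
                          max_cycles = 500L, max_inner = 5000L,
                          tol_exact = 1e-9, max_sweeps = 20000L) {
  stopifnot(tol_outer > 0, tol_inner > 0, tol_exact > 0,
            max_cycles >= 1L, max_inner >= 1L, max_sweeps >= 1L)
  structure(list(tol_outer = tol_outer, tol_inner = tol_inner,
                 max_cycles = as.integer(max_cycles),
                 max_inner = as.integer(max_inner),
                 tol_exact = tol_exact, max_sweeps = as.integer(max_sweeps)),
            class = "tvnet_control")
}
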