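#' BIC score of a fitted transition model
#'
#' Scores a fit by the Gaussian-likelihood Bayesian information criterion
#' with the lasso degrees-of-freedom convention: the model complexity is
#' the number of nonzero transition coefficients. With `n_eff = N * K * (T-1)`
#' residuals (N data matrices, K templates, T-1 transitions) and RSS the
#' unpenalized sliding-window loss at the solution,
#' `bic = n_eff * log(RSS / n_eff) + df * log(n_eff)`.
#'
#' @param fit a fitted `tvnet`.
#' @param zero_tol magnitude below which a coefficient counts as zero
#'   (default 1e-6, the scale of the solver's soft threshold).
#' @return List with `bic`, `df`, `n_eff`, `rss`. A perfect fit
#'   (`RSS == 0`) returns `bic = -Inf` with a warning.
#' @export
bic_score <- function(fit, zero_tol = 1e-6) {
  stopifnot(inherits(fit, "tvnet"), zero_tol >= 0)
  n_eff <- fit$N * fit$K * (fit$T - 1L)
  rss <- fit$objective$loss
  df <- sum(vapply(fit$W, function(w) sum(abs(w) > zero_tol), numeric(1L)))
  if (rss <= 0) {
    warning("perfect fit (RSS = 0); BIC is -Inf", call. = FALSE)
    return(list(bic = -Inf, df = df, n_eff = n_eff, rss = rss))
  }
  list(bic = n_eff * log(rss / n_eff) + df * log(n_eff),
       df = df, n_eff = n_eff, rss = rss)
}

#' Select regularization weights by BIC over a grid
#'
#' Fits [tvnet()] at every candidate `(lambda1, lambda2)` pair and returns
#' the pair minimizing [bic_score()]. Ties are broken toward larger
#' `lambda2`, then larger `lambda1` (the sparser, smoother model). Each
#' candidate is fitted from a cold start so the result is independent of
#' grid order.
#'
#' @param data one K x T matrix or a list of them (see [tvnet()]).
#' @param lambda1_grid,lambda2_grid candidate values, crossed into the grid
#'   (defaults `10^(-3:1)` each, 25 candidates); alternatively pass `grid`.
#' @param grid optional data frame with columns `lambda1`, `lambda2` giving
#'   explicit candidate pairs (overrides the crossed grids).
#' @param zero_tol passed to [bic_score()].
#' @param ... further arguments (window, indicator, control, method) passed
#'   to [tvnet()].
#' @return An object of class `bic_grid`: list with `table` (data frame of
#'   lambda1, lambda2, rss, df, bic, converged, selected), `selected` (row
#'   index of the minimizer), `fit` (the refitted selected model), and
#'   `n_eff`.
#' @export
select_lambdas <- function(data, lambda1_grid = 10^(-3:1),
                           lambda2_grid = 10^(-3:1), grid = NULL,
                           zero_tol = 1e-6, ...) {
  if (is.null(grid))
    grid <- expand.grid(lambda1 = lambda1_grid, lambda2 = lambda2_grid,
                        KEEP.OUT.ATTRS = FALSE)
  stopifnot(nrow(grid) >= 1L, all(c("lambda1", "lambda2") %in% names(grid)))
  data <- as_data_list(data)

  rows <- lapply(seq_len(nrow(grid)), function(i) {
    fit <- tvnet(data, lambda1 = grid$lambda1[i], lambda2 = grid$lambda2[i], ...)
    if (!fit$converged)
      warning(sprintf("fit at lambda1=%g, lambda2=%g did not converge",
                      grid$lambda1[i], grid$lambda2[i]), call. = FALSE)
    sc <- bic_score(fit, zero_tol = zero_tol)
    data.frame(lambda1 = grid$lambda1[i], lambda2 = grid$lambda2[i],
               rss = sc$rss, df = sc$df, bic = sc$bic,
               converged = fit$converged)
  })
  tab <- do.call(rbind, rows)
  # minimize BIC; break ties toward larger lambda2, then larger lambda1
  ord <- order(tab$bic, -tab$lambda2, -tab$lambda1)
  sel <- ord[1L]
  tab$selected <- seq_len(nrow(tab)) == sel
  fit <- tvnet(data, lambda1 = tab$lambda1[sel], lambda2 = tab$lambda2[sel], ...)
  sc <- bic_score(fit, zero_tol = zero_tol)

  structure(list(table = tab, selected = sel, fit = fit, n_eff = sc$n_eff,
                 zero_tol = zero_tol),
            class = "bic_grid")
}

#' @export
print.bic_grid <- function(x, ...) {
  sel <- x$table[x$selected, ]
  cat("BIC grid over ", nrow(x$table), " (lambda1, lambda2) candidates (n_eff = ",
      x$n_eff, ")\n", sep = "")
  cat(sprintf("selected: lambda1 = %g, lambda2 = %g (bic = %.4g, df = %d)\n",
              sel$lambda1, sel$lambda2, sel$bic, sel$df))
  invisible(x)
}
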