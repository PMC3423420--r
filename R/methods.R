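#' @export
print.tvnet <- function(x, ...) {
  nnz <- sum(vapply(x$W, function(w) sum(w != 0), numeric(1L)))
  cat("tvnet fit: ", x$K, " templates, ", x$T, " time points (",
      length(x$W), " transition matrices), N = ", x$N, " data matrices\n",
      sep = "")
  cat(sprintf("  lambda1 = %g (smoothness), lambda2 = %g (sparsity), method = %s\n",
              x$lambda1, x$lambda2, x$method))
  cat(sprintf("  objective %.6g = loss %.6g + l1*smooth %.6g + l2*sparsity %.6g\n",
              x$objective$total, x$objective$loss,
              x$lambda1 * x$objective$smoothness,
              x$lambda2 * x$objective$sparsity))
  cat(sprintf("  nonzero coefficients: %d / %d; %s after %d %s\n",
              nnz, length(x$W) * x$K^2,
              if (x$converged) "converged" else "NOT converged",
              x$cycles, if (x$method == "bcd") "cycles" else "sweeps"))
  invisible(x)
}

#' @export
summary.tvnet <- function(object, edge_threshold = 1e-3, ...) {
  edges <- network_edges(object, edge_threshold = edge_threshold)
  per_frame <- vapply(seq_along(object$W), function(t)
    sum(abs(object$W[[t]]) > edge_threshold), integer(1L))
  out <- list(fit = object, edges = edges, per_frame = per_frame,
              edge_threshold = edge_threshold)
  class(out) <- "summary.tvnet"
  out
}

#' @export
print.summary.tvnet <- function(x, ...) {
  print(x$fit)
  cat("\nEdges with |weight| > ", x$edge_threshold, " per transition: ",
      paste(x$per_frame, collapse = ", "), "\n", sep = "")
  if (nrow(x$edges)) {
    top <- x$edges[order(-abs(x$edges$weight)), ]
    cat("Strongest edges:\n")
    print(utils::head(top, 10L), row.names = FALSE)
  } else cat("No edges above threshold.\n")
  invisible(x)
}

#' Extract transition coefficients
#'
#' @param object a fitted `tvnet`.
#' @param ... unused.
#' @return A K x K x (T-1) array; `coef(fit)[i, j, t]` is the effect of
#'   template j at time t on template i at time t+1.
#' @export
coef.tvnet <- function(object, ...) {
  arr <- array(unlist(object$W), dim = c(object$K, object$K, length(object$W)),
               dimnames = c(dimnames(object$W[[1L]]), list(names(object$W))))
  arr
}

#' One-step-ahead predictions from a fitted transition model
#'
#' Applies the fitted matrices to the states at times 1..T-1 to predict the
#' states at times 2..T.
#'
#' @param object a fitted `tvnet`.
#' @param newdata one K x T matrix or a list of them; defaults to the
#'   training data.
#' @param ... unused.
#' @return A list (one element per data matrix) of K x (T-1) matrices of
#'   predicted states at times 2..T; a single matrix if `newdata` is one
#'   matrix.
#' @export
predict.tvnet <- function(object, newdata = NULL, ...) {
  single <- is.matrix(newdata)
  data <- as_data_list(if (is.null(newdata)) object$data else newdata)
  if (nrow(data[[1L]]) != object$K)
    stop("newdata must have ", object$K, " rows", call. = FALSE)
  nf <- min(ncol(data[[1L]]) - 1L, length(object$W))
  preds <- lapply(data, function(V) {
    out <- vapply(seq_len(nf), function(t) as.numeric(object$W[[t]] %*% V[, t]),
                  numeric(object$K))
    out <- matrix(out, nrow = object$K,
                  dimnames = list(object$template_ids,
                                  colnames(V)[seq_len(nf) + 1L]))
    out
  })
  if (single) preds[[1L]] else preds
}

#' @export
fitted.tvnet <- function(object, ...) predict(object)

#' One-step-ahead residuals
#'
#' @param object a fitted `tvnet`.
#' @param ... unused.
#' @return Observed minus predicted states at times 2..T, in the same shape
#'   as [predict.tvnet()] (a list over training data matrices).
#' @export
residuals.tvnet <- function(object, ...) {
  preds <- predict(object)
  mapply(function(V, P) V[, -1L, drop = FALSE] - P, object$data, preds,
         SIMPLIFY = FALSE)
}

#' Simulate trajectories from a fitted transition model
#'
#' Propagates initial states through the fitted matrices, optionally adding
#' Gaussian innovations with the per-step residual standard deviation
#' estimated from the training data.
#'
#' @param object a fitted `tvnet`.
#' @param nsim number of trajectories.
#' @param seed integer seed.
#' @param init K-vector or K x nsim matrix of initial states; defaults to
#'   standard-normal draws.
#' @param innovate logical; add residual-scale Gaussian noise at each step
#'   (default `FALSE`, deterministic propagation).
#' @param ... unused.
#' @return A list of `nsim` K x T matrices.
#' @export
simulate.tvnet <- function(object, nsim = 1, seed = NULL, init = NULL,
                           innovate = FALSE, ...) {
  run <- function() {
    sd_innov <- if (innovate) {
      res <- unlist(residuals(object))
      stats::sd(res)
    } else 0
    inits <- if (is.null(init)) matrix(stats::rnorm(object$K * nsim), object$K)
    else matrix(init, nrow = object$K, ncol = nsim)
    lapply(seq_len(nsim), function(s) {
      V <- matrix(0, object$K, object$T,
                  dimnames = list(object$template_ids, NULL))
      V[, 1L] <- inits[, s]
      for (t in seq_along(object$W))
        V[, t + 1L] <- as.numeric(object$W[[t]] %*% V[, t]) +
          stats::rnorm(object$K, sd = sd_innov)
      V
    })
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Heatmaps of the fitted transition matrices
#'
#' Draws one diverging-scale heatmap per transition matrix, rows = target
#' template at time t+1, columns = source template at time t.
#'
#' @param x a fitted `tvnet`.
#' @param ... passed to [graphics::image()].
#' @export
plot.tvnet <- function(x, ...) {
  nf <- length(x$W)
  old <- graphics::par(mfrow = c(1, nf), mar = c(4, 4, 3, 1))
  on.exit(graphics::par(old))
  lim <- max(abs(unlist(x$W)), .Machine$double.eps)
  pal <- grDevices::colorRampPalette(c("#2166AC", "white", "#B2182B"))(101)
  for (t in seq_len(nf)) {
    W <- x$W[[t]]
    graphics::image(seq_len(x$K), seq_len(x$K), t(W[rev(seq_len(x$K)), ]),
                    zlim = c(-lim, lim), col = pal,
                    xlab = paste0("from (t=", t, ")"),
                    ylab = paste0("to (t=", t + 1, ")"),
                    axes = FALSE, main = names(x$W)[t], ...)
    graphics::axis(1, at = seq_len(x$K), labels = x$template_ids, las = 2,
                   cex.axis = 0.7)
    graphics::axis(2, at = seq_len(x$K), labels = rev(x$template_ids), las = 2,
                   cex.axis = 0.7)
  }
  invisible(x)
}
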