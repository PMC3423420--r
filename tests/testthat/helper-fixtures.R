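# Shared fixtures and independent oracles for the test suite.

# Independent nested-loop evaluation of the inference objective; kept free
# of the package's sufficient-statistics path on purpose.
brute_objective <- function(W, data, lambda1 = 0, lambda2 = 0,
                            window = tvnet_window(),
                            indicator = tvnet_indicator()) {
  if (is.matrix(data)) data <- list(data)
  N <- length(data)
  Tn <- ncol(data[[1L]])
  nf <- Tn - 1L
  loss <- 0
  for (V in data) for (th in seq_len(nf)) {
    for (t in th:min(th + window$delta, nf)) {
      d <- t - th
      w <- switch(window$decay,
                  gaussian = exp(-d^2 / (2 * window$sigma^2)),
                  exponential = exp(-d / window$sigma))
      r <- V[, t + 1L] - W[[th]] %*% V[, t]
      loss <- loss + w * sum(r^2)
    }
  }
  loss <- loss / N
  sm <- 0
  if (nf > 1L) for (t1 in 1:(nf - 1L)) for (t2 in (t1 + 1L):nf) {
    dd <- t2 - t1
    m <- if (indicator$kind == "hard") as.numeric(dd <= indicator$radius)
    else exp(-dd^2 / indicator$tau)
    sm <- sm + m * sum((W[[t1]] - W[[t2]])^2)
  }
  sp <- sum(vapply(W, function(w) sum(abs(w)), numeric(1)))
  list(loss = loss, smoothness = sm, sparsity = sp,
       total = loss + lambda1 * sm + lambda2 * sp)
}

# Per-transition ordinary least squares from data matrices (delta = 0,
# no penalties): the closed-form normal-equations oracle.
ols_series <- function(data) {
  if (is.matrix(data)) data <- list(data)
  K <- nrow(data[[1L]])
  nf <- ncol(data[[1L]]) - 1L
  lapply(seq_len(nf), function(th) {
    S <- matrix(0, K, K); C <- matrix(0, K, K)
    for (V in data) {
      S <- S + tcrossprod(V[, th])
      C <- C + tcrossprod(V[, th + 1L], V[, th])
    }
    C %*% solve(S)
  })
}

# Small expression table on disk: G transcripts x (times x replicates),
# values = base + per-transcript temporal profile + replicate noise.
write_expr_fixture <- function(path, profiles, times = seq_len(ncol(profiles)),
                               n_rep = 3, rep_sd = 0.02, seed = 42,
                               condition = NULL) {
  G <- nrow(profiles)
  cn <- as.vector(t(outer(times, seq_len(n_rep), function(tp, r)
    sprintf("%sh_rep%d", tp, r))))
  if (!is.null(condition)) cn <- paste0(condition, "_", cn)
  set.seed(seed)
  vals <- matrix(NA_real_, G, length(cn))
  for (j in seq_along(cn)) {
    tp <- match(as.numeric(sub(".*?([0-9.]+)h_rep.*", "\\1", cn[j])), times)
    vals[, j] <- profiles[, tp] + rnorm(G, sd = rep_sd)
  }
  ids <- rownames(profiles)
  if (is.null(ids)) ids <- sprintf("tx%03d", seq_len(G))
  df <- data.frame(transcript_id = ids, vals, check.names = FALSE)
  colnames(df) <- c("transcript_id", cn)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Two groups of profiles proportional to two orthogonal patterns:
# correlation distance separates them perfectly and deterministically.
orthogonal_groups <- function(n_per = 5, scales = seq(0.5, 2.5, length.out = 5)) {
  p1 <- c(1, -1, 1, -1)
  p2 <- c(1, 1, -1, -1)
  x <- rbind(t(sapply(scales[seq_len(n_per)], function(s) s * p1)),
             t(sapply(scales[seq_len(n_per)], function(s) s * p2)))
  rownames(x) <- c(sprintf("a%d", seq_len(n_per)), sprintf("b%d", seq_len(n_per)))
  x
}
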