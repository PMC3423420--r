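# internal helpers shared across the package

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

soft_threshold <- function(x, a) sign(x) * pmax(abs(x) - a, 0)

# z-score each row; sd uses the n-1 denominator so that for rows x, y
# standardized to zx, zy we have cor(x, y) = sum(zx * zy) / (ncol - 1).
standardize_rows <- function(x, what = "profile") {
  x <- as.matrix(x)
  mu <- rowMeans(x)
  s <- apply(x, 1L, stats::sd)
  bad <- !is.finite(s) | s == 0
  if (any(bad)) {
    ids <- rownames(x)
    lab <- if (is.null(ids)) which(bad) else ids[bad]
    stop("zero-variance ", what, ": ",
         paste(utils::head(lab, 5L), collapse = ", "),
         if (sum(bad) > 5L) " ..." else "", call. = FALSE)
  }
  (x - mu) / s
}

#' Write a timestamped log line
#'
#' Messages are emitted when `options(temponet.verbose = TRUE)` is set and
#' always appended to the file named by `options(temponet.logfile = ...)`,
#' if any. Stochastic operations log their seeds through this hook.
#'
#' @param ... passed to [sprintf()] (a format string plus arguments).
#' @return Invisibly, the formatted line.
#' @export
tn_log <- function(...) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  sprintf(...))
  logfile <- getOption("temponet.logfile", NULL)
  if (!is.null(logfile)) cat(line, "\n", file = logfile, append = TRUE, sep = "")
  if (isTRUE(getOption("temponet.verbose", FALSE))) message(line)
  invisible(line)
}

# Coerce a fitted tvnet object or a plain list of K x K matrices into a
# validated list of transition matrices.
as_transition_list <- function(x) {
  if (inherits(x, "tvnet")) x <- x$W
  if (is.matrix(x)) x <- list(x)
  stopifnot(is.list(x), length(x) >= 1L)
  k <- nrow(x[[1L]])
  for (w in x) {
    if (!is.matrix(w) || !all(dim(w) == k) || !all(is.finite(w)))
      stop("transition series must be a list of finite square matrices of equal size",
           call. = FALSE)
  }
  x
}

# Coerce the `data` argument of the fitting functions (one K x T matrix or a
# list of them) into a list of matrices with identical dimensions.
as_data_list <- function(data) {
  if (is.matrix(data)) data <- list(data)
  if (inherits(data, "template_matrix")) data <- list(data$V)
  stopifnot(is.list(data), length(data) >= 1L)
  d <- dim(data[[1L]])
  if (d[2L] < 2L) stop("need at least two time points", call. = FALSE)
  for (m in data) {
    if (!is.matrix(m) || !all(dim(m) == d) || !all(is.finite(m)))
      stop("data must be finite K x T matrices of identical dimensions",
           call. = FALSE)
  }
  data
}
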