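#' Read a time-course expression table
#'
#' Loads a TSV or CSV matrix of normalized log2 expression values (one row
#' per transcript, one column per sample) and attaches the time/replicate
#' annotation parsed from the column names or supplied explicitly. Values
#' are expected on the log2 scale, e.g. RMA summaries of array data.
#'
#' Column names are matched against `pattern`, whose capture groups are, in
#' order, an optional condition label, the time in hours, and the replicate
#' label; the default matches names like `"1h_rep2"` or `"adaptive_4h_rep1"`.
#' Alternatively pass `times` (and optionally `replicates`, `conditions`)
#' directly, one value per sample column.
#'
#' @param path path to a delimited text file with a header row and
#'   transcript identifiers in the first column.
#' @param sep field separator; by default inferred from the file extension
#'   (`","` for `.csv`, tab otherwise).
#' @param pattern regular expression with capture groups
#'   `(condition)(time)(replicate)` applied to column names when `times` is
#'   not given.
#' @param times,replicates,conditions optional explicit per-sample
#'   annotations overriding `pattern` parsing.
#' @param impute `"none"` (default) rejects missing values; `"row-mean"`
#'   replaces each missing cell by the mean of its transcript's observed
#'   values.
#' @return An object of class `expression_dataset`: a list with elements
#'   `values` (G x S numeric matrix with transcript rownames),
#'   `transcript_ids`, `sample_times`, `sample_replicates`, `condition`
#'   (per-sample labels, possibly all `""`).
#' @seealso [collapse_replicates()], [filter_fold_change()]
#' @export
read_expression <- function(path, sep = NULL,
                            pattern = "^(?:(.*?)_)?([0-9]+(?:\\.[0-9]+)?)h_rep(.+)$",
                            times = NULL, replicates = NULL, conditions = NULL,
                            impute = c("none", "row-mean")) {
  impute <- match.arg(impute)
  if (!file.exists(path)) stop("expression file not found: ", path, call. = FALSE)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.delim(path, sep = sep, header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 3L) stop("expression table needs an ID column and at least two samples",
                           call. = FALSE)
  ids <- as.character(tab[[1L]])
  if (anyNA(ids) || any(!nzchar(ids)))
    stop("empty transcript identifier in row ",
         which(is.na(ids) | !nzchar(ids))[1L], call. = FALSE)
  if (anyDuplicated(ids))
    stop("duplicated transcript identifier: ",
         ids[duplicated(ids)][1L], call. = FALSE)

  raw <- tab[, -1L, drop = FALSE]
  for (j in seq_along(raw)) {
    col <- raw[[j]]
    if (!is.numeric(col)) {
      num <- suppressWarnings(as.numeric(col))
      bad <- which(is.na(num) & !is.na(col) & nzchar(trimws(col)))
      if (length(bad))
        stop("non-numeric value '", col[bad[1L]], "' in column '",
             names(raw)[j], "', row ", bad[1L], " (", ids[bad[1L]], ")",
             call. = FALSE)
      raw[[j]] <- num
    }
  }
  values <- as.matrix(raw)
  rownames(values) <- ids

  if (is.null(times)) {
    cn <- colnames(values)
    hit <- regmatches(cn, regexec(pattern, cn))
    bad <- which(vapply(hit, length, 1L) == 0L)
    if (length(bad))
      stop("cannot parse time annotation from column '", cn[bad[1L]],
           "'; supply `times` or adjust `pattern`", call. = FALSE)
    conditions <- vapply(hit, `[`, "", 2L)
    times <- as.numeric(vapply(hit, `[`, "", 3L))
    replicates <- vapply(hit, `[`, "", 4L)
  } else {
    times <- as.numeric(times)
    if (length(times) != ncol(values))
      stop("`times` must have one entry per sample column", call. = FALSE)
    if (is.null(replicates)) {
      replicates <- stats::ave(seq_along(times), times, FUN = seq_along)
      replicates <- as.character(replicates)
    }
    if (is.null(conditions)) conditions <- rep("", ncol(values))
  }
  if (anyNA(times) || any(!is.finite(times)))
    stop("non-finite time annotation for column '",
         colnames(values)[which(!is.finite(times))[1L]], "'", call. = FALSE)
  if (length(unique(times)) < 2L)
    stop("need at least two distinct time points", call. = FALSE)

  miss <- which(!is.finite(values), arr.ind = TRUE)
  if (nrow(miss)) {
    if (impute == "none") {
      stop("missing value at transcript '", ids[miss[1L, 1L]],
           "', sample '", colnames(values)[miss[1L, 2L]],
           "' (row ", miss[1L, 1L], ", column ", miss[1L, 2L],
           "); set impute = \"row-mean\" to impute", call. = FALSE)
    }
    for (i in unique(miss[, 1L])) {
      row <- values[i, ]
      if (all(!is.finite(row)))
        stop("transcript '", ids[i], "' has no observed values", call. = FALSE)
      values[i, !is.finite(row)] <- mean(row[is.finite(row)])
    }
  }

  structure(list(values = values,
                 transcript_ids = ids,
                 sample_times = times,
                 sample_replicates = as.character(replicates),
                 condition = as.character(conditions)),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cond <- unique(x$condition[nzchar(x$condition)])
  cat("expression_dataset: ", nrow(x$values), " transcripts x ",
      ncol(x$values), " samples\n", sep = "")
  cat("  time points (h): ", paste(sort(unique(x$sample_times)), collapse = ", "),
      "\n", sep = "")
  if (length(cond)) cat("  condition: ", paste(cond, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Collapse replicate samples to one profile per transcript
#'
#' Averages the log2 values of all replicates at each time point and orders
#' the resulting columns by ascending time. Averaging on the log2 scale is
#' the conventional summary for RMA-normalized array data.
#'
#' @param ds an `expression_dataset` from [read_expression()].
#' @return An object of class `time_course`: a list with `values`
#'   (G x T matrix, columns in ascending time order), `transcript_ids`, and
#'   `time_points`.
#' @export
collapse_replicates <- function(ds) {
  stopifnot(inherits(ds, "expression_dataset"))
  conds <- unique(ds$condition[nzchar(ds$condition)])
  if (length(conds) > 1L)
    stop("samples from ", length(conds), " conditions (",
         paste(conds, collapse = ", "),
         ") in one dataset; split the table and process each condition separately",
         call. = FALSE)
  tp <- sort(unique(ds$sample_times))
  vals <- vapply(tp, function(t) {
    rowMeans(ds$values[, ds$sample_times == t, drop = FALSE])
  }, numeric(nrow(ds$values)))
  vals <- matrix(vals, nrow = nrow(ds$values),
                 dimnames = list(ds$transcript_ids, paste0(tp, "h")))
  structure(list(values = vals,
                 transcript_ids = ds$transcript_ids,
                 time_points = tp),
            class = "time_course")
}

#' @export
print.time_course <- function(x, ...) {
  cat("time_course: ", nrow(x$values), " transcripts x ",
      length(x$time_points), " time points (",
      paste(x$time_points, collapse = ", "), " h)\n", sep = "")
  invisible(x)
}

#' Filter transcripts by fold-change range
#'
#' Retains the transcripts whose collapsed log2 profile spans at least
#' `threshold` log2 units between its maximum and its minimum across time.
#' On the log2 scale this max-minus-min range is the maximum fold change of
#' the profile, so the default of 0.5 removes transcripts varying by less
#' than a factor of about 1.41 over the whole time course.
#'
#' @param tc a `time_course` from [collapse_replicates()].
#' @param threshold minimum max-minus-min range in log2 units (default 0.5).
#' @return A `time_course` containing only the retained transcripts, in
#'   their original order.
#' @export
filter_fold_change <- function(tc, threshold = 0.5) {
  stopifnot(inherits(tc, "time_course"), is.numeric(threshold),
            length(threshold) == 1L, threshold >= 0)
  rng <- apply(tc$values, 1L, function(v) max(v) - min(v))
  keep <- rng >= threshold
  if (!any(keep))
    stop("no transcript has a log2 range >= ", threshold,
         "; lower the fold-change threshold", call. = FALSE)
  structure(list(values = tc$values[keep, , drop = FALSE],
                 transcript_ids = tc$transcript_ids[keep],
                 time_points = tc$time_points),
            class = "time_course")
}
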