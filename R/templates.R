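#' Build template profiles from a cluster assignment
#'
#' A template is the representative temporal profile of one cluster: the
#' arithmetic mean of its members' log2 profiles, standardized to zero mean
#' and unit variance across time. Standardization puts all templates on a
#' common scale so transition-matrix magnitudes are comparable.
#'
#' @param profiles numeric G x T matrix the assignment was computed on.
#' @param ca a `cluster_assignment` covering all rows of `profiles`.
#' @return An object of class `template_matrix`: list with `V` (K x T
#'   standardized template matrix), `template_ids`, `time_points` (column
#'   names of `profiles` if numeric, else 1..T), and `membership` (`ca`).
#' @export
build_templates <- function(profiles, ca) {
  profiles <- as.matrix(profiles)
  stopifnot(inherits(ca, "cluster_assignment"),
            length(ca$labels) == nrow(profiles))
  Tn <- ncol(profiles)
  V <- t(vapply(seq_len(ca$K), function(k) {
    colMeans(profiles[ca$labels == k, , drop = FALSE])
  }, numeric(Tn)))
  V <- standardize_rows(V, what = "template")
  ids <- paste0("template", seq_len(ca$K))
  rownames(V) <- ids
  tp <- suppressWarnings(as.numeric(sub("h$", "", colnames(profiles))))
  if (anyNA(tp) || is.null(colnames(profiles))) tp <- seq_len(Tn)
  structure(list(V = V, template_ids = ids, time_points = tp,
                 membership = ca),
            class = "template_matrix")
}

#' @export
print.template_matrix <- function(x, ...) {
  cat("template_matrix: ", nrow(x$V), " templates x ", ncol(x$V),
      " time points\n", sep = "")
  print(signif(x$V, 3))
  invisible(x)
}

#' Sample pseudo-replicate template matrices
#'
#' Draws N data matrices by picking, for each cluster, one member transcript
#' uniformly at random and using its standardized profile as that cluster's
#' row. Because members of a cluster share a temporal signature but retain
#' individual variation, the sampled matrices act as replicates that
#' stabilize the transition-matrix regression. With cluster sizes m_k there
#' are prod(m_k) distinct matrices; duplicates across draws are allowed.
#'
#' @param profiles numeric G x T matrix the assignment was computed on.
#' @param ca a `cluster_assignment` covering all rows of `profiles`.
#' @param N number of matrices to draw.
#' @param seed integer seed; the draw sequence is reproducible.
#' @return A list of N standardized K x T matrices.
#' @export
sample_pseudo_matrices <- function(profiles, ca, N, seed = 1L) {
  profiles <- as.matrix(profiles)
  stopifnot(inherits(ca, "cluster_assignment"),
            length(ca$labels) == nrow(profiles), N >= 1L)
  tn_log("sample_pseudo_matrices: N=%d, seed=%d", N, as.integer(seed))
  Z <- standardize_rows(profiles)
  members <- split(seq_len(nrow(Z)), factor(ca$labels, levels = seq_len(ca$K)))
  with_seed(seed, {
    lapply(seq_len(N), function(n) {
      rows <- vapply(members, function(m) {
        if (length(m) == 1L) m else m[sample.int(length(m), 1L)]
      }, integer(1L))
      mat <- Z[rows, , drop = FALSE]
      rownames(mat) <- paste0("template", seq_len(ca$K))
      mat
    })
  })
}
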