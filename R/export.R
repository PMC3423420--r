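#' Edge list of a fitted transition series
#'
#' One directed edge per (transition, target, source) entry whose magnitude
#' exceeds `edge_threshold`. Entry `W(t)[i, j]` becomes an edge from
#' template j (active at time t) to template i (at time t+1).
#'
#' @param x a fitted `tvnet` or a list of K x K matrices.
#' @param edge_threshold minimum |weight| for an edge (default 1e-3).
#' @return Data frame with columns `source`, `target`, `t`, `weight`,
#'   `sign` (`"+"` or `"-"`).
#' @export
network_edges <- function(x, edge_threshold = 1e-3) {
  stopifnot(edge_threshold >= 0)
  W <- as_transition_list(x)
  ids <- rownames(W[[1L]])
  if (is.null(ids)) ids <- paste0("template", seq_len(nrow(W[[1L]])))
  rows <- lapply(seq_along(W), function(t) {
    hit <- which(abs(W[[t]]) > edge_threshold, arr.ind = TRUE)
    if (!nrow(hit)) return(NULL)
    data.frame(source = ids[hit[, 2L]], target = ids[hit[, 1L]],
               t = t, weight = W[[t]][hit],
               sign = ifelse(W[[t]][hit] > 0, "+", "-"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(source = character(), target = character(),
                      t = integer(), weight = numeric(), sign = character(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Export a fitted network to file
#'
#' Writes the thresholded directed network in one of three formats:
#' `"edge_list"` (TSV with source, target, t, weight, sign), `"sif"`
#' (Cytoscape simple-interaction format; the relation encodes transition
#' index and sign, e.g. `t1+`), or `"graphml"` (via the igraph writer, with
#' `weight`, `t`, and `sign` edge attributes).
#'
#' @inheritParams network_edges
#' @param file output path.
#' @param format `"edge_list"`, `"sif"`, or `"graphml"`.
#' @return Invisibly, the edge data frame written.
#' @export
export_network <- function(x, file, edge_threshold = 1e-3,
                           format = c("edge_list", "sif", "graphml")) {
  format <- match.arg(format)
  edges <- network_edges(x, edge_threshold = edge_threshold)
  W <- as_transition_list(x)
  ids <- rownames(W[[1L]])
  if (is.null(ids)) ids <- paste0("template", seq_len(nrow(W[[1L]])))
  switch(format,
    edge_list = {
      out <- edges
      out$weight <- signif(out$weight, 12)
      utils::write.table(out, file, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    },
    sif = {
      lines <- if (nrow(edges))
        sprintf("%s\t%s\t%s", edges$source,
                paste0("t", edges$t, edges$sign), edges$target)
      else character()
      writeLines(lines, file)
    },
    graphml = {
      g <- igraph::graph_from_data_frame(
        edges[, c("source", "target", "weight", "t", "sign")],
        directed = TRUE,
        vertices = data.frame(name = ids, stringsAsFactors = FALSE))
      igraph::write_graph(g, file, format = "graphml")
    })
  invisible(edges)
}
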