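#' Read a pipeline configuration file
#'
#' Configurations are YAML with sections `io`, `filter`, `cluster`,
#' `infer`, and `bic`; every key has a default, so a minimal config only
#' names the expression file. See [run_pipeline()] for the keys.
#'
#' @param path path to a YAML file, or a list already in config shape.
#' @return A nested list of configuration values with defaults filled in.
#' @export
read_config <- function(path) {
  user <- if (is.list(path)) path else {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    yaml::read_yaml(path)
  }
  defaults <- list(
    io = list(expression = NULL, out_dir = "temponet_out",
              pattern = NULL, times = NULL, logfile = NULL),
    filter = list(threshold = 0.5, impute = "none"),
    cluster = list(k_range = 2:9, runs = 1000L, sample_rate = 0.8,
                   seed = 1L, k = NULL, delta_threshold = 0.1),
    infer = list(n_pseudo = 20L, seed = 1L, delta = 2L, decay = "gaussian",
                 sigma = 1, indicator = "hard", radius = 1L, tau = 1,
                 lambda1 = NULL, lambda2 = NULL, edge_threshold = 1e-3),
    bic = list(lambda1_grid = 10^(-3:1), lambda2_grid = 10^(-3:1),
               zero_tol = 1e-6))
  for (sec in names(defaults))
    if (!is.null(user[[sec]]))
      defaults[[sec]] <- utils::modifyList(defaults[[sec]], user[[sec]])
  defaults$cluster$k_range <- parse_range(defaults$cluster$k_range)
  defaults
}

# accept 2:9, c(2,...,9), "2:9", or a plain vector
parse_range <- function(x) {
  if (is.character(x) && length(x) == 1L && grepl(":", x)) {
    p <- as.integer(strsplit(x, ":", fixed = TRUE)[[1L]])
    return(p[1L]:p[2L])
  }
  as.integer(x)
}

#' Run the full inference pipeline
#'
#' Orchestrates one reproducible run over a single condition: load the
#' expression table, collapse replicates, filter by fold-change range,
#' consensus-cluster into templates, draw pseudo-replicate matrices, select
#' `(lambda1, lambda2)` by BIC (or use fixed values from the config), fit
#' the transition series, and export the network. All stage outputs are
#' written as plain TSV/SIF/GraphML under `out_dir`, with floating-point
#' values rounded to 12 significant digits so re-runs are byte-identical,
#' plus a JSON manifest recording the config, seeds, package version, file
#' hashes, and timestamps.
#'
#' Config keys (YAML sections / defaults): `io`: `expression` (input path,
#' required), `out_dir`, `pattern`, `times`, `logfile`; `filter`:
#' `threshold` (0.5), `impute`; `cluster`: `k_range` (2:9), `runs` (1000),
#' `sample_rate` (0.8), `seed`, `k` (optional override of the automatic
#' choice, mirroring a manual read of the consensus CDF),
#' `delta_threshold`; `infer`: `n_pseudo` (20), `delta` (2), `decay`,
#' `sigma`, `indicator`, `radius`, `tau`, `seed`, `lambda1`/`lambda2`
#' (fixed values skip BIC), `edge_threshold`; `bic`: `lambda1_grid`,
#' `lambda2_grid` (each 1e-3..10), `zero_tol`.
#'
#' @param config path to a YAML config file, or an equivalent nested list.
#' @param out_dir optional override of `io$out_dir`.
#' @return Invisibly, a list of class `run_manifest` (also written to
#'   `manifest.json`) plus in-memory stage results in attribute `"stages"`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- read_config(config)
  if (!is.null(out_dir)) cfg$io$out_dir <- out_dir
  if (is.null(cfg$io$expression))
    stop("config must name the input expression table (io: expression:)",
         call. = FALSE)
  if (!file.exists(cfg$io$expression))
    stop("input expression file does not exist: ", cfg$io$expression,
         call. = FALSE)
  dir.create(cfg$io$out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(cfg$io$logfile)) {
    old_opt <- options(temponet.logfile = cfg$io$logfile)
    on.exit(options(old_opt))
  }
  started <- Sys.time()
  stage <- function(name, expr) {
    tn_log("stage %s: start", name)
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  tc <- stage("filter", {
    args <- list(path = cfg$io$expression, impute = cfg$filter$impute)
    if (!is.null(cfg$io$pattern)) args$pattern <- cfg$io$pattern
    if (!is.null(cfg$io$times)) args$times <- cfg$io$times
    ds <- do.call(read_expression, args)
    filter_fold_change(collapse_replicates(ds), cfg$filter$threshold)
  })
  write_tsv_num(data.frame(transcript_id = tc$transcript_ids,
                           signif(tc$values, 12), check.names = FALSE),
                file.path(cfg$io$out_dir, "filtered.tsv"))

  cl <- stage("cluster", {
    cr <- consensus_cluster(tc$values, k_range = cfg$cluster$k_range,
                            n_runs = cfg$cluster$runs,
                            sample_rate = cfg$cluster$sample_rate,
                            seed = cfg$cluster$seed)
    k <- if (!is.null(cfg$cluster$k)) as.integer(cfg$cluster$k)
    else as.integer(select_k(cr, cfg$cluster$delta_threshold))
    idx <- match(k, cr$k_range)
    ca <- if (!is.na(idx)) cr$assignments[[idx]]
          else kmeans_correlation(tc$values, k, seed = cfg$cluster$seed + 1L)
    list(cr = cr, k = k, ca = ca)
  })
  write_tsv_num(data.frame(K = cl$cr$k_range,
                           area = signif(cl$cr$area, 12),
                           delta_area = signif(cl$cr$delta_area, 12)),
                file.path(cfg$io$out_dir, "consensus_cdf.tsv"))
  write_tsv_num(data.frame(transcript_id = tc$transcript_ids,
                           cluster = cl$ca$labels),
                file.path(cfg$io$out_dir, "clusters.tsv"))

  tm <- stage("templates", build_templates(tc$values, cl$ca))
  write_tsv_num(data.frame(template = tm$template_ids,
                           signif(tm$V, 12), check.names = FALSE),
                file.path(cfg$io$out_dir, "templates.tsv"))
  pseudo <- stage("templates",
                  sample_pseudo_matrices(tc$values, cl$ca,
                                         N = cfg$infer$n_pseudo,
                                         seed = cfg$infer$seed))

  window <- tvnet_window(delta = cfg$infer$delta, decay = cfg$infer$decay,
                         sigma = cfg$infer$sigma)
  indicator <- tvnet_indicator(kind = cfg$infer$indicator,
                               radius = cfg$infer$radius, tau = cfg$infer$tau)
  sel <- NULL
  fit <- stage("select", {
    if (!is.null(cfg$infer$lambda1) && !is.null(cfg$infer$lambda2)) {
      tvnet(pseudo, lambda1 = cfg$infer$lambda1, lambda2 = cfg$infer$lambda2,
            window = window, indicator = indicator)
    } else {
      sel <- select_lambdas(pseudo, lambda1_grid = cfg$bic$lambda1_grid,
                             lambda2_grid = cfg$bic$lambda2_grid,
                             zero_tol = cfg$bic$zero_tol,
                             window = window, indicator = indicator)
      sel$fit
    }
  })
  if (!is.null(sel)) {
    tab <- sel$table
    for (cn in c("rss", "bic")) tab[[cn]] <- signif(tab[[cn]], 12)
    write_tsv_num(tab, file.path(cfg$io$out_dir, "bic_grid.tsv"))
  }
  for (t in seq_along(fit$W))
    write_tsv_num(as.data.frame(signif(fit$W[[t]], 12)),
                  file.path(cfg$io$out_dir, sprintf("W_t%d.tsv", t)),
                  row.names = TRUE)

  stage("export", {
    export_network(fit, file.path(cfg$io$out_dir, "edges.tsv"),
                   edge_threshold = cfg$infer$edge_threshold,
                   format = "edge_list")
    export_network(fit, file.path(cfg$io$out_dir, "network.sif"),
                   edge_threshold = cfg$infer$edge_threshold, format = "sif")
    export_network(fit, file.path(cfg$io$out_dir, "network.graphml"),
                   edge_threshold = cfg$infer$edge_threshold,
                   format = "graphml")
  })

  outputs <- list.files(cfg$io$out_dir, full.names = TRUE)
  outputs <- outputs[!grepl("manifest\\.json$", outputs)]
  manifest <- list(
    package = "temponet",
    version = as.character(utils::packageVersion("temponet")),
    config = cfg,
    seeds = list(cluster = cfg$cluster$seed, infer = cfg$infer$seed),
    selected_k = cl$k,
    lambda1 = fit$lambda1, lambda2 = fit$lambda2,
    hashes = as.list(tools::md5sum(sort(outputs))),
    started = format(started, "%Y-%m-%d %H:%M:%S"),
    finished = format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
  jsonlite::write_json(manifest, file.path(cfg$io$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  class(manifest) <- "run_manifest"
  attr(manifest, "stages") <- list(time_course = tc, consensus = cl$cr,
                                   assignment = cl$ca, templates = tm,
                                   bic = sel, fit = fit)
  invisible(manifest)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("temponet run: K = ", x$selected_k,
      sprintf(", lambda1 = %g, lambda2 = %g\n", x$lambda1, x$lambda2),
      sep = "")
  cat("  outputs: ", length(x$hashes), " files in ", x$config$io$out_dir,
      "\n", sep = "")
  invisible(x)
}

write_tsv_num <- function(df, path, row.names = FALSE) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = row.names, col.names = TRUE)
}
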