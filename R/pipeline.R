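#' Run the full scope-enumerate-analyse pipeline
#'
#' Ties the phases together under a single reproducible configuration:
#' reads one model (single-organism mode) or several (community mode, with
#' organism prefixes on all outputs), computes the seed scope, enumerates
#' pathways to the requested targets, and writes a scope report, one
#' pathway JSONL file per target, optional similarity and exchange reports,
#' and a run manifest. Re-running an identical configuration reproduces
#' byte-identical pathway output.
#'
#' Unreachable targets are a valid scientific result: they produce empty
#' outputs and explicit warnings, not an error.
#'
#' @param config a named list (or path to a YAML file holding one) with
#'   fields `models` (character vector of paths, >1 switches on community
#'   mode), `seeds` (seed file path) or `seed_ids` (character vector),
#'   `targets` (file path, character vector, or `"all-scope"`), `beta`
#'   (integer >= 1), `out_dir`, and optional `prune` (default TRUE),
#'   `max_pathways` (default 1e7), `similarity_bins` (break points; enables
#'   the similarity report), `exchanges` (logical), `labels` (organism
#'   labels), `rng_seed`.
#' @param ... fields overriding those in `config`.
#' @return invisibly, a list with the graph, scope, pathway table, the
#'   per-target pathway tibble, and the paths written.
#' @export
run_enumeration <- function(config, ...) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  config <- modifyList(config, list(...))
  defaults <- list(prune = TRUE, max_pathways = 1e7, exchanges = FALSE,
                   similarity_bins = NULL, labels = NULL, rng_seed = NULL)
  config <- modifyList(defaults, config)
  for (field in c("models", "beta", "out_dir")) {
    if (is.null(config[[field]])) abort(paste0("config field missing: ", field))
  }
  if (is.null(config$seeds) && is.null(config$seed_ids)) {
    abort("config needs 'seeds' (file) or 'seed_ids'")
  }
  if (config$beta < 1) abort("beta must be >= 1")
  absent <- config$models[!file.exists(config$models)]
  if (length(absent) > 0) {
    abort(paste0("model file(s) not found: ", paste(absent, collapse = ", ")))
  }
  if (!is.null(config$rng_seed)) set.seed(config$rng_seed)
  t0 <- Sys.time()
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  models <- lapply(config$models, read_model_auto)
  community <- length(models) > 1
  graph <- if (community) {
    build_community_graph(models, labels = config$labels)
  } else {
    build_graph(models[[1]])
  }
  seeds <- config$seed_ids %||% read_seeds(config$seeds)
  scope <- guided_bfs(graph, seeds)
  paths <- c(scope = file.path(config$out_dir, "scope_report.tsv"))
  write_scope_report(scope, paths[["scope"]])

  targets <- config$targets %||% "all-scope"
  if (identical(targets, "all-scope")) {
    targets <- setdiff(scope$scope, scope$seeds)
  } else if (length(targets) == 1 && file.exists(targets)) {
    targets <- read_seeds(targets)
  }
  reach <- reachable_targets(scope, targets, graph)
  if (any(!reach$reachable)) {
    warn(paste0("unreachable target(s), empty pathway output for: ",
                paste(reach$target[!reach$reachable], collapse = ", ")))
  }

  tab <- enumerate_pathways(graph, beta = config$beta, scope = scope,
                            prune = config$prune,
                            max_pathways = config$max_pathways)
  pw <- dplyr::bind_rows(lapply(sort(targets), function(tg) {
    p <- withCallingHandlers(pathways(tab, tg),
                             warning = function(w) invokeRestart("muffleWarning"))
    out <- file.path(config$out_dir,
                     paste0("pathways_", gsub("[^A-Za-z0-9_.-]", "_", tg), ".jsonl"))
    write_pathways_jsonl(p, out)
    p
  }))
  paths <- c(paths, pathways_dir = config$out_dir)

  if (!is.null(config$similarity_bins) && nrow(pw) >= 2) {
    spec <- similarity_spectrum(pw, bins = config$similarity_bins)
    paths <- c(paths, similarity = file.path(config$out_dir, "similarity.tsv"))
    write_report_tsv(spec, paths[["similarity"]])
    jsonlite::write_json(
      list(total_pairs = attr(spec, "total_pairs"),
           bins = as_tibble(spec)),
      file.path(config$out_dir, "similarity.json"), auto_unbox = TRUE)
  }
  exch <- NULL
  if (isTRUE(config$exchanges)) {
    if (!community) {
      warn("exchange analysis requested on a single-organism run; skipping")
    } else {
      exch <- find_exchanges(graph, pw, seeds = scope$seeds)
      paths <- c(paths, exchanges = file.path(config$out_dir, "exchanges.tsv"))
      write_report_tsv(exch, paths[["exchanges"]])
    }
  }

  manifest <- list(
    package = "metenum",
    version = as.character(utils::packageVersion("metenum")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config = config[order(names(config))],
    config_hash = rlang::hash(config[order(names(config))]),
    n_targets = length(targets),
    n_pathways = nrow(pw),
    wall_time_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(graph = graph, scope = scope, table = tab,
                 pathways = pw, exchanges = exch, paths = paths,
                 manifest = manifest))
}
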