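#' Run the full analysis pipeline
#'
#' Orchestrates load -> simulate -> metrics -> null-model inference with
#' reproducible seeding: every stochastic stage derives its seed
#' deterministically from the global seed and the stage name, so re-running
#' a config reproduces every numeric output exactly.
#'
#' @param config A named list, or a path to a YAML/JSON file holding one,
#'   with elements:
#'   \describe{
#'     \item{`network`}{Either a list `list(path =, format =)` for
#'       [read_network()], or one of the synthetic generators
#'       `list(synthetic = "funnel")` / `list(synthetic = "connectome")`.}
#'     \item{`params`}{Arguments for [sim_params()] (`lambda` required).}
#'     \item{`R`, `S`}{Ensemble sizes (default 20 and 20).}
#'     \item{`focal`}{Character vector of focal nodes (default: the funnel
#'       target when known, else the first node).}
#'     \item{`null`}{`list(kind =, fraction =)`; default rewired.}
#'     \item{`top_k`}{Edges to report (default 10).}
#'     \item{`phase_lambdas`}{Optional rate grid; when present a phase map
#'       is computed.}
#'     \item{`seed`}{Global seed (default 1).}
#'   }
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, a list with the in-memory results (`network`,
#'   `metrics`, `edge_traffic`, `reports`, `phase`, `manifest`). On disk:
#'   `node_metrics.csv` (ensemble means), `edge_traffic.csv`,
#'   `top_edges.csv`, `ranking_<metric>.csv`, one
#'   `null_report_<focal>.json` per focal node, optionally
#'   `phase_map.csv`, and `manifest.json`.
#' @export
run_pipeline <- function(config, out_dir) {
  config <- load_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)

  net <- resolve_network(config$network, seed)
  par_args <- config$params
  if (is.null(par_args$lambda)) abort("Config must set params$lambda.")
  params <- do.call(sim_params, par_args)
  R <- as.integer(config$R %||% 20L)
  S <- as.integer(config$S %||% 20L)
  top_k <- as.integer(config$top_k %||% 10L)
  null_cfg <- config$null %||% list(kind = "rewired")
  focal <- config$focal %||% default_focal(net)

  # ensemble of R runs on the empirical network
  runs <- purrr::map(seq_len(R), function(r) {
    simulate_traffic(net, params, seed = derive_seed(seed, paste0("empirical_", r)))
  })
  metric_mean <- purrr::map_dfr(runs, node_metrics) |>
    dplyr::group_by(.data$node) |>
    dplyr::summarise(dplyr::across(dplyr::everything(), mean), .groups = "drop") |>
    dplyr::arrange(match(.data$node, net$labels))
  traffic <- Reduce(`+`, purrr::map(runs, edge_traffic_matrix))

  readr::write_csv(metric_mean, file.path(out_dir, "node_metrics.csv"))
  edges_out <- tibble::tibble(
    from = rep(rownames(traffic), times = ncol(traffic)),
    to = rep(colnames(traffic), each = nrow(traffic)),
    count = as.vector(traffic)) |>
    dplyr::filter(.data$count > 0)
  readr::write_csv(edges_out, file.path(out_dir, "edge_traffic.csv"))
  readr::write_csv(top_k_edges(traffic, top_k), file.path(out_dir, "top_edges.csv"))
  for (m in c("arrivals", "mean_contents", "utilization")) {
    readr::write_csv(rank_nodes(metric_mean, m),
                     file.path(out_dir, sprintf("ranking_%s.csv", m)))
  }

  reports <- purrr::map(focal, function(f) {
    rep <- null_ensemble_report(
      net, params, f, kind = null_cfg$kind %||% "rewired",
      fraction = null_cfg$fraction %||% 1, R = R, S = S,
      seed = derive_seed(seed, paste0("null_", f)))
    jsonlite::write_json(
      list(focal = f, kind = rep$kind, fraction = rep$fraction,
           R = rep$R, S = rep$S, table = tidy(rep)),
      file.path(out_dir, sprintf("null_report_%s.json", gsub("[^A-Za-z0-9_-]", "_", f))),
      auto_unbox = TRUE, digits = NA)
    rep
  })
  names(reports) <- focal

  phase <- NULL
  if (!is.null(config$phase_lambdas)) {
    phase <- phase_map(net, sort(as.numeric(config$phase_lambdas)),
                       mu = params$mu, K = params$K,
                       T = config$phase_T %||% min(params$T, 2000),
                       seed = derive_seed(seed, "phase"))
    readr::write_csv(tidy(phase), file.path(out_dir, "phase_map.csv"))
  }

  config_echo <- config
  if (inherits(config_echo$network, "directed_network")) {
    config_echo$network <- list(
      in_memory = TRUE, n_nodes = n_nodes(config$network),
      n_edges = n_edges(config$network))
  }
  manifest <- list(
    config = config_echo, seed = seed,
    n_nodes = n_nodes(net), n_edges = n_edges(net),
    package_version = as.character(utils::packageVersion("queuenet")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)

  invisible(list(network = net, metrics = metric_mean,
                 edge_traffic = traffic, reports = reports, phase = phase,
                 manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

load_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) abort(sprintf("Config file not found: %s", config))
    config <- if (grepl("\\.ya?ml$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE)) {
        abort("YAML configs need the yaml package; use JSON instead.")
      }
      yaml::read_yaml(config)
    } else {
      jsonlite::read_json(config, simplifyVector = TRUE)
    }
  }
  if (!is.list(config)) abort("`config` must be a list or a config file path.")
  config
}

resolve_network <- function(net_cfg, seed) {
  if (inherits(net_cfg, "directed_network")) return(net_cfg)
  if (is.null(net_cfg)) abort("Config must describe the network.")
  if (!is.null(net_cfg$synthetic)) {
    return(switch(net_cfg$synthetic,
      funnel = funnel_network(seed = derive_seed(seed, "network")),
      connectome = synthetic_connectome(seed = derive_seed(seed, "network")),
      abort(sprintf("Unknown synthetic network '%s'.", net_cfg$synthetic))))
  }
  if (is.null(net_cfg$path)) abort("network config needs `path` or `synthetic`.")
  read_network(net_cfg$path, format = net_cfg$format %||% "edgelist",
               labels = net_cfg$labels)
}

default_focal <- function(net) {
  gt <- attr(net, "funnel")
  if (!is.null(gt)) return(gt$target)
  if ("CA1" %in% net$labels) return("CA1")
  net$labels[1]
}
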