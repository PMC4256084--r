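#' z-score of an empirical metric against a null distribution
#'
#' The ensemble inference statistic: the mean of the empirical sample is
#' expressed in units of the null distribution's standard deviation,
#' `z = (mean(empirical) - mean(null)) / sd(null)`, with a two-sided
#' normal-approximation p-value. An empirical (percentile) p-value is also
#' reported, since null distributions may be skewed.
#'
#' @param empirical Numeric vector of metric values from runs on the real
#'   network (length >= 2).
#' @param null Numeric vector of metric values from surrogate runs
#'   (length >= 2, positive standard deviation).
#' @return A one-row tibble: `empirical_mean`, `null_mean`, `null_sd`, `z`,
#'   `p` (normal), `p_empirical` (percentile).
#' @examples
#' zscore_vs_null(c(10, 10), c(0, 2))
#' @export
zscore_vs_null <- function(empirical, null) {
  if (length(empirical) < 2) abort("Need >= 2 empirical values.")
  if (length(null) < 2) abort("Need >= 2 null values.")
  s <- sd(null)
  if (!is.finite(s) || s == 0) {
    abort("Null distribution has zero variance; z-score undefined.")
  }
  m <- mean(empirical)
  z <- (m - mean(null)) / s
  p_emp <- 2 * min(mean(null >= m), mean(null <= m))
  tibble::tibble(
    empirical_mean = m, null_mean = mean(null), null_sd = s, z = z,
    p = 2 * pnorm(-abs(z)), p_empirical = min(1, p_emp))
}

#' Rank nodes by a communication metric
#'
#' Descending ranks (1 = highest value). Ties receive their average rank;
#' row order within a tie follows node label order, which is recorded
#' behaviour rather than an arbitrary sort.
#'
#' @param table A `metric_table` (or any data frame with a `node` column
#'   and the metric column).
#' @param metric One of `"arrivals"`, `"mean_contents"`, `"utilization"`.
#' @return The input rows sorted by rank with a `rank` column prepended.
#' @export
rank_nodes <- function(table, metric = c("arrivals", "mean_contents",
                                         "utilization")) {
  metric <- match.arg(metric)
  if (!metric %in% names(table)) {
    abort(sprintf("Column '%s' not found in the metric table.", metric))
  }
  if (nrow(table) == 0) abort("Empty metric table.")
  table |>
    dplyr::mutate(rank = rank(-.data[[metric]], ties.method = "average")) |>
    dplyr::arrange(.data$rank, .data$node) |>
    dplyr::relocate("rank")
}

#' Most-traversed directed connections
#'
#' @param traffic An edge-traffic table (`from`, `to`, `count`) or a dense
#'   traversal-count matrix with node-label dimnames.
#' @param k Number of edges to report. If `k` exceeds the number of edges
#'   with nonzero traffic, all of them are returned with a warning.
#' @return A tibble `from`, `to`, `count`, descending by count; ties broken
#'   by `(from, to)` label order.
#' @export
top_k_edges <- function(traffic, k = 10L) {
  if (!is.numeric(k) || length(k) != 1 || k < 1) abort("`k` must be >= 1.")
  if (is.matrix(traffic)) {
    idx <- which(traffic != 0, arr.ind = TRUE)
    traffic <- tibble::tibble(
      from = rownames(traffic)[idx[, 1]],
      to = colnames(traffic)[idx[, 2]],
      count = traffic[idx])
  }
  traffic <- dplyr::filter(tibble::as_tibble(traffic), .data$count > 0)
  if (nrow(traffic) < k) {
    warn(sprintf("Only %d edge(s) carry traffic; returning all of them.",
                 nrow(traffic)))
    k <- nrow(traffic)
  }
  traffic |>
    dplyr::arrange(dplyr::desc(.data$count), .data$from, .data$to) |>
    head(k)
}

#' Residual excess of a metric relative to in-degree
#'
#' Fits an ordinary least-squares regression of a communication metric on
#' in-degree and reports studentized residuals: nodes whose traffic exceeds
#' what their in-degree alone predicts. Nodes with `|residual|` above the
#' threshold are flagged as outliers (convergence-zone candidates when the
#' excess is positive).
#'
#' @param table A `metric_table`.
#' @param degrees A degree table from [node_degrees()].
#' @param metric Metric column to regress.
#' @param threshold Flagging threshold on `|studentized residual|`
#'   (default 3).
#' @return A tibble `node`, `k_in`, `value`, `residual`, `outlier`,
#'   in descending residual order.
#' @export
degree_outlier_scores <- function(table, degrees,
                                  metric = c("arrivals", "mean_contents",
                                             "utilization"),
                                  threshold = 3) {
  metric <- match.arg(metric)
  df <- dplyr::inner_join(
    dplyr::select(table, "node", value = dplyr::all_of(metric)),
    dplyr::select(degrees, "node", "k_in"), by = "node")
  if (nrow(df) < 3) abort("Need >= 3 nodes for the degree regression.")
  if (sd(df$k_in) == 0) abort("No variance in in-degree; regression degenerate.")
  fit <- lm(value ~ k_in, data = df)
  # an (almost) exact fit has no outliers: studentized residuals would be
  # ratios of numerical noise
  if (stats::sigma(fit) < 1e-10 * (sd(df$value) + abs(mean(df$value)) + 1)) {
    res <- rep(0, nrow(df))
  } else {
    res <- stats::rstudent(fit)
    # a point so extreme that the fit without it is (near) exact makes the
    # studentization degenerate: classify by the raw residual instead
    bad <- !is.finite(res)
    raw <- stats::resid(fit)
    res[bad] <- ifelse(abs(raw[bad]) > 1e-10 * (sd(df$value) + 1),
                       sign(raw[bad]) * 1e8, 0)
  }
  df |>
    dplyr::mutate(residual = unname(res),
                  outlier = abs(.data$residual) > threshold) |>
    dplyr::arrange(dplyr::desc(.data$residual))
}

#' Total network contents over time
#'
#' Sums the per-node contents step functions of a recorded run into one
#' step series for the whole network, the series whose stationarity
#' distinguishes the steady regime from the jammed one.
#'
#' @param result A `sim_result` recorded with `record_events = TRUE`.
#' @return A tibble `time`, `value` (step function starting at `(0, 0)`).
#' @export
total_contents_series <- function(result) {
  stopifnot(inherits(result, "sim_result"))
  if (is.null(result$trajectory)) {
    abort("Needs a run recorded with `record_events = TRUE`.")
  }
  tr <- result$trajectory
  if (nrow(tr) == 0) return(tibble::tibble(time = 0, value = 0))
  tr <- tr |>
    dplyr::group_by(.data$node) |>
    dplyr::mutate(delta = .data$n - dplyr::lag(.data$n, default = 0L)) |>
    dplyr::ungroup()
  # trajectory rows are appended in event order; within a node time is
  # non-decreasing, and cumulative deltas give the network total
  tibble::tibble(time = c(0, tr$time), value = c(0, cumsum(tr$delta)))
}

#' Map the steady/jammed phase boundary over arrival rates
#'
#' For each arrival rate, one recorded simulation is run and the total
#' network contents series is examined on the post-transient window. The
#' regime is `jammed` when the fitted ordinary-least-squares slope shows
#' drift over the window — `|slope| x window >= slope_tol x mean contents`
#' — or when a macroscopic fraction of generated units is ejected: with
#' finite buffers a saturated system stops drifting once its queues are
#' full and sheds the excess load as losses instead. `steady` otherwise.
#'
#' @param net A `directed_network`.
#' @param lambdas Increasing vector of arrival rates to probe.
#' @param mu,K,T,t_transient Simulation parameters as in [sim_params()].
#' @param seed Integer seed; one derived seed per rate.
#' @param slope_tol Stationarity tolerance (default 0.05); the drift over
#'   the whole window may be at most this fraction of the mean contents.
#' @param loss_tol Loss-fraction threshold (default 0.05): ejected/generated
#'   at or above it marks the jammed regime even without drift.
#' @param dt Resampling interval for the slope fit; default spans the
#'   window with 200 points.
#' @return A `phase_map`: tibble `lambda`, `slope`, `mean_contents`,
#'   `loss_frac`, `regime`.
#' @export
phase_map <- function(net, lambdas, mu = 1, K = 10L, T = 2000,
                      t_transient = 0.02 * T, seed = 1L, slope_tol = 0.05,
                      loss_tol = 0.05, dt = (T - t_transient) / 200) {
  stopifnot(inherits(net, "directed_network"))
  if (is.unsorted(lambdas, strictly = TRUE)) {
    abort("`lambdas` must be sorted ascending.")
  }
  rows <- purrr::map(seq_along(lambdas), function(i) {
    lam <- lambdas[i]
    res <- simulate_traffic(
      net, sim_params(lambda = lam, mu = mu, K = K, T = T,
                      t_transient = t_transient),
      seed = derive_seed(seed, paste0("phase_", i)), record_events = TRUE)
    series <- total_contents_series(res)
    samp <- resample_uniform(series, dt = dt, method = "hold", t_end = T)
    samp <- samp[samp$time > t_transient, ]
    m <- mean(samp$value)
    slope <- if (nrow(samp) >= 2 && sd(samp$value) > 0) {
      unname(coef(lm(value ~ time, data = samp))[2])
    } else 0
    # past the transition the bottleneck saturates: contents either still
    # drift upward within the window, or (buffers being finite) have
    # plateaued while a macroscopic fraction of units is ejected
    loss <- with(res$ledger, if (generated > 0) ejected / generated else 0)
    # drift must be non-negligible relative to the contents level, with a
    # floor of one signal unit so a near-empty system is never flagged on
    # relative noise alone
    drifting <- m > 0 && abs(slope) * (T - t_transient) >= slope_tol * max(m, 1)
    tibble::tibble(lambda = lam, slope = slope, mean_contents = m,
                   loss_frac = loss,
                   regime = if (drifting || loss >= loss_tol) "jammed"
                            else "steady")
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("phase_map", class(out))
  out
}

#' Compare a focal node's metrics against a surrogate ensemble
#'
#' The full inferential design: `R` simulations on the empirical network
#' against one simulation on each of `S` surrogate networks, summarized per
#' metric as a z-score of the empirical ensemble mean relative to the null
#' distribution.
#'
#' @param net A `directed_network`.
#' @param params A [sim_params()] object.
#' @param focal Focal node label.
#' @param kind Surrogate family: `"rewired"` (degree-preserving) or
#'   `"reversed"` (directional).
#' @param fraction Reversal fraction (reversed surrogates only).
#' @param R,S Ensemble sizes (empirical runs, surrogates).
#' @param seed Integer seed; all stage seeds derive from it.
#' @param n_attempts Swap budget for rewired surrogates.
#' @return A `null_ensemble_report`: list with `table` (per-metric tibble of
#'   means, sd, z, p), raw `empirical` and `null` draws, and the design
#'   parameters. Supports [tidy()], [glance()] and [autoplot()].
#' @export
null_ensemble_report <- function(net, params, focal,
                                 kind = c("rewired", "reversed"),
                                 fraction = 1, R = 20L, S = 20L, seed = 1L,
                                 n_attempts = NULL) {
  kind <- match.arg(kind)
  stopifnot(inherits(net, "directed_network"))
  if (!focal %in% net$labels) abort(sprintf("Unknown focal node '%s'.", focal))

  focal_metrics <- function(network, run_seed) {
    res <- simulate_traffic(network, params, seed = run_seed)
    node_metrics(res) |> dplyr::filter(.data$node == focal)
  }
  empirical <- purrr::map_dfr(seq_len(R), function(r) {
    focal_metrics(net, derive_seed(seed, paste0("empirical_", r))) |>
      dplyr::mutate(run = r)
  })
  surrogates <- surrogate_ensemble(net, S, kind = kind, fraction = fraction,
                                   n_attempts = n_attempts,
                                   seed = derive_seed(seed, "surrogates"))
  null <- purrr::map_dfr(seq_len(S), function(s) {
    focal_metrics(surrogates[[s]], derive_seed(seed, paste0("null_", s))) |>
      dplyr::mutate(run = s)
  })

  metrics <- c("arrivals", "mean_contents", "utilization")
  table <- purrr::map_dfr(metrics, function(m) {
    zscore_vs_null(empirical[[m]], null[[m]]) |>
      dplyr::mutate(metric = m, .before = 1)
  })
  structure(list(focal = focal, kind = kind, fraction = fraction,
                 R = R, S = S, seed = seed, params = params,
                 table = table,
                 empirical = tidyr::pivot_longer(
                   empirical, dplyr::all_of(metrics),
                   names_to = "metric", values_to = "value"),
                 null = tidyr::pivot_longer(
                   null, dplyr::all_of(metrics),
                   names_to = "metric", values_to = "value")),
            class = "null_ensemble_report")
}

#' @export
print.null_ensemble_report <- function(x, ...) {
  cat(sprintf("<null_ensemble_report> focal '%s' vs %s surrogates%s (R=%d, S=%d)\n",
              x$focal, x$kind,
              if (x$kind == "reversed") sprintf(" (fraction %g)", x$fraction) else "",
              x$R, x$S))
  print(x$table)
  invisible(x)
}
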