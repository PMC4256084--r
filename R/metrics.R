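#' Node-level communication metrics
#'
#' Reduces a `sim_result` to the three node-level metrics of the traffic
#' model, measured on the post-transient window:
#' * **arrivals** — total signal units arriving at the node (exogenous
#'   generations, hops from afferent projections and, by default,
#'   destination absorptions);
#' * **mean contents** — time-average of the node contents
#'   `n_i(t) = s_i(t) + q_i(t)`, the server indicator plus queue length;
#' * **utilization** — fraction of window time the server is busy.
#'
#' @param result A `sim_result` from [simulate_traffic()] or
#'   [scripted_simulate()].
#' @return A `metric_table`: tibble with columns `node`, `arrivals`,
#'   `mean_contents`, `utilization`, one row per node in network order.
#' @export
node_metrics <- function(result) {
  stopifnot(inherits(result, "sim_result"))
  w <- unname(result$window[["end"]] - result$window[["start"]])
  out <- tibble::tibble(
    node = result$nodes$node,
    arrivals = result$nodes$arrivals,
    mean_contents = if (w > 0) result$nodes$contents_integral / w else 0,
    utilization = if (w > 0) result$nodes$busy_time / w else 0)
  class(out) <- c("metric_table", class(out))
  out
}

#' Per-edge traversal counts
#'
#' `edge_traffic()` returns the post-transient count of service-completion
#' hops along each directed edge as a tidy table; `edge_traffic_matrix()`
#' as a dense N x N matrix, zero wherever there is no edge.
#'
#' @param result A `sim_result`.
#' @return A tibble `from`, `to`, `count` (one row per network edge), or an
#'   integer matrix with node labels as dimnames.
#' @export
edge_traffic <- function(result) {
  stopifnot(inherits(result, "sim_result"))
  result$edges
}

#' @rdname edge_traffic
#' @export
edge_traffic_matrix <- function(result) {
  stopifnot(inherits(result, "sim_result"))
  labels <- result$labels
  m <- matrix(0L, length(labels), length(labels),
              dimnames = list(labels, labels))
  e <- result$edges
  if (nrow(e) > 0) {
    m[cbind(match(e$from, labels), match(e$to, labels))] <- as.integer(e$count)
  }
  m
}

#' Contents trajectory of one node as a step function
#'
#' Requires a result recorded with `record_events = TRUE` (or a scripted
#' run). The series starts at `(0, 0)` — every run starts empty — and holds
#' each value until the next change.
#'
#' @param result A `sim_result` with a recorded trajectory.
#' @param node Node label.
#' @return A tibble `time`, `value`.
#' @export
node_trajectory <- function(result, node) {
  stopifnot(inherits(result, "sim_result"))
  if (is.null(result$trajectory)) {
    abort("No trajectory recorded; rerun with `record_events = TRUE`.")
  }
  if (!node %in% result$labels) abort(sprintf("Unknown node '%s'.", node))
  tr <- dplyr::filter(result$trajectory, .data$node == .env$node)
  tibble::tibble(time = c(0, tr$time), value = c(0L, tr$n))
}

#' Resample an event-stamped step function on a uniform grid
#'
#' System state changes at irregular event times; uniform resampling puts
#' replicate runs on a common grid. Zero-order hold (`"hold"`) is the
#' faithful reading of a step-valued state; `"linear"` interpolation
#' ("table lookup") is also provided. Beyond the last event the last value
#' is held.
#'
#' @param trajectory Data frame with columns `time` (increasing) and
#'   `value`; each value holds from its time until the next row.
#' @param dt Sampling interval, > 0.
#' @param method `"hold"` or `"linear"`.
#' @param t_end End of the sampling grid; defaults to the last event time.
#' @return A tibble `time`, `value` sampled at `t0, t0 + dt, ...` where
#'   `t0` is the trajectory's first time stamp.
#' @export
resample_uniform <- function(trajectory, dt, method = c("hold", "linear"),
                             t_end = NULL) {
  method <- match.arg(method)
  trajectory <- tibble::as_tibble(trajectory)
  if (!all(c("time", "value") %in% names(trajectory))) {
    abort("`trajectory` needs columns time and value.")
  }
  if (nrow(trajectory) == 0) abort("Empty trajectory.")
  if (!is.numeric(dt) || dt <= 0) abort("`dt` must be > 0.")
  if (is.null(t_end)) t_end <- max(trajectory$time)
  grid <- seq(min(trajectory$time), t_end, by = dt)
  # simultaneous events: the last value at a time stamp is the state
  trajectory <- trajectory |>
    dplyr::slice_tail(n = 1, by = "time")
  if (nrow(trajectory) == 1) {
    return(tibble::tibble(time = grid, value = trajectory$value[1]))
  }
  vals <- stats::approx(trajectory$time, trajectory$value, xout = grid,
                        method = if (method == "hold") "constant" else "linear",
                        f = 0, rule = 2)$y
  tibble::tibble(time = grid, value = vals)
}

#' Recompute a recorded run on a different post-transient window
#'
#' Re-derives every counter and time-average of a `sim_result` from its
#' event log and trajectories, restricted to `(t_transient, T]`. Requires a
#' run recorded with `record_events = TRUE`. The conservation ledger and
#' maximum queue lengths describe the whole run and are left untouched.
#'
#' @param result A recorded `sim_result`.
#' @param t_transient New transient cut, `0 <= t_transient < T`.
#' @return A `sim_result` with recomputed `nodes`, `edges` and `window`.
#' @export
remove_transient <- function(result, t_transient) {
  stopifnot(inherits(result, "sim_result"))
  if (is.null(result$events) || is.null(result$trajectory)) {
    abort("Recomputation needs a run recorded with `record_events = TRUE`.")
  }
  T_end <- unname(result$window[["end"]])
  if (t_transient < 0 || t_transient >= T_end) {
    abort("`t_transient` must satisfy 0 <= t_transient < T (empty window).")
  }
  count_del <- if (!is.null(result$params$count_deliveries)) {
    result$params$count_deliveries
  } else TRUE
  labels <- result$labels
  ev <- result$events

  in_window <- ev$time >= t_transient & ev$time <= T_end
  arr <- ev[in_window & ev$event == "arrive", ]
  if (!count_del) {
    del_key <- paste(ev$unit[ev$event == "deliver"],
                     ev$node[ev$event == "deliver"])
    arr <- arr[!paste(arr$unit, arr$node) %in% del_key, ]
  }
  arrivals <- as.integer(table(factor(arr$node, levels = labels)))

  busy <- busy_time_from_events(result, t_start = t_transient, t_end = T_end)
  cont <- purrr::map_dbl(labels, function(lbl) {
    step_integral(node_trajectory(result, lbl), t_transient, T_end)
  })

  hops <- edge_hops_from_events(result)
  hops <- hops[hops$time >= t_transient & hops$time <= T_end, ]
  counts <- dplyr::count(hops, .data$from, .data$to, name = "count")
  edges <- dplyr::left_join(
    dplyr::select(result$edges, "from", "to"), counts, by = c("from", "to"))
  edges$count <- as.integer(dplyr::coalesce(edges$count, 0L))

  out <- result
  out$nodes <- tibble::tibble(
    node = labels, arrivals = arrivals, busy_time = unname(busy),
    contents_integral = cont, max_queue = result$nodes$max_queue)
  out$edges <- edges
  out$window <- c(start = t_transient, end = T_end)
  out
}

# exact integral of a step function over (lo, hi]
step_integral <- function(trajectory, lo, hi) {
  t <- c(trajectory$time, Inf)
  v <- trajectory$value
  total <- 0
  for (k in seq_along(v)) {
    a <- max(t[k], lo); b <- min(t[k + 1], hi)
    if (b > a) total <- total + (b - a) * v[k]
  }
  total
}

#' Per-node busy time recomputed from the event log
#'
#' An independent accounting of server occupancy: busy intervals are
#' reconstructed from `start_service` / `complete` event pairs (a service
#' still open at the end of the run extends to `T`), then clipped to the
#' window. Used to cross-check the simulator's online busy-time counter.
#'
#' @param result A recorded `sim_result`.
#' @param t_start,t_end Window bounds; default the result's own window.
#' @return Named numeric vector of busy time per node, in node order.
#' @export
busy_time_from_events <- function(result, t_start = NULL, t_end = NULL) {
  stopifnot(inherits(result, "sim_result"))
  if (is.null(result$events)) {
    abort("Needs a run recorded with `record_events = TRUE`.")
  }
  if (is.null(t_start)) t_start <- unname(result$window[["start"]])
  if (is.null(t_end)) t_end <- unname(result$window[["end"]])
  ev <- result$events
  out <- purrr::map_dbl(result$labels, function(lbl) {
    e <- ev[ev$node == lbl & ev$event %in% c("start_service", "complete"), ]
    starts <- e$time[e$event == "start_service"]
    ends <- e$time[e$event == "complete"]
    if (length(ends) < length(starts)) ends <- c(ends, t_end)
    sum(pmax(0, pmin(ends, t_end) - pmax(starts, t_start)))
  })
  names(out) <- result$labels
  out
}

# one row per service-completion hop: (time, from, to, unit); pairs each
# `complete` with the same unit's arrival logged immediately after it
edge_hops_from_events <- function(result) {
  ev <- result$events
  comp <- which(ev$event == "complete")
  to <- character(length(comp))
  keep <- logical(length(comp))
  for (k in seq_along(comp)) {
    i <- comp[k]
    j <- i + 1L
    if (j <= nrow(ev) && ev$event[j] == "arrive" && ev$unit[j] == ev$unit[i] &&
        ev$time[j] == ev$time[i]) {
      to[k] <- ev$node[j]; keep[k] <- TRUE
    }
  }
  tibble::tibble(time = ev$time[comp], from = ev$node[comp], to = to,
                 unit = ev$unit[comp])[keep, ]
}

#' Estimate the initial transient from replicate runs
#'
#' The ensemble-average rule for transient identification: average the
#' replicate total-network-contents series point-wise, take the mean of the
#' terminal fraction of the averaged series as the stationary level, and
#' report the earliest grid time from which the averaged series stays
#' within `tolerance * stationary level` of that level for the rest of the
#' run. The tolerance is a free parameter of the rule, not a canonical
#' constant.
#'
#' @param series Replicate series on a common grid: a list of equal-length
#'   numeric vectors, or a matrix with one replicate per row.
#' @param times Grid times; defaults to `0, 1, 2, ...`.
#' @param tolerance Half-width of the stationarity band, as a fraction of
#'   the stationary level (default 0.05).
#' @param terminal_frac Fraction of the series tail used to estimate the
#'   stationary level (default 0.25).
#' @return The estimated transient length (a time on the grid; 0 when the
#'   ensemble average is stationary from the start).
#' @export
ensemble_transient_estimate <- function(series, times = NULL,
                                        tolerance = 0.05,
                                        terminal_frac = 0.25) {
  if (is.matrix(series)) series <- asplit(series, 1)
  if (length(series) < 2) abort("Need at least 2 replicate series.")
  lens <- lengths(series)
  if (length(unique(lens)) != 1) {
    abort("Replicates are on mismatched grids (unequal lengths).")
  }
  avg <- Reduce(`+`, lapply(series, as.numeric)) / length(series)
  n <- length(avg)
  if (is.null(times)) times <- seq_len(n) - 1
  if (length(times) != n) abort("`times` length must match the series.")
  tail_idx <- seq.int(max(1L, n - ceiling(terminal_frac * n) + 1L), n)
  level <- mean(avg[tail_idx])
  band <- tolerance * max(abs(level), .Machine$double.eps)
  inside <- abs(avg - level) <= band
  # earliest index from which the series never leaves the band
  ok_from <- rev(cumprod(rev(inside))) > 0
  if (!any(ok_from)) return(times[n])
  times[which(ok_from)[1]]
}
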