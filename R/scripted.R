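#' Build a deterministic simulation script
#'
#' A script replaces every stochastic draw of [simulate_traffic()] with
#' explicit values, so a walkthrough (such as the three-node two-pathway
#' schematic returned by [walkthrough_fixture()]) can be replayed exactly.
#'
#' @param generations Data frame with columns `time` (non-negative),
#'   `source`, `destination` (node labels, destination != source) and
#'   optionally `unit` (a label per signal unit; defaults to `u1, u2, ...`).
#'   Simultaneous generations are processed in row order.
#' @param service_times Numeric vector of service durations, consumed in
#'   the order service starts occur. If exhausted, further services never
#'   complete within the run (duration effectively infinite).
#' @param route_choices Integer vector; the k-th service completion hops
#'   along the `route_choices[k]`-th efferent edge of its node, efferents
#'   ordered by network node order. If exhausted, the first efferent is
#'   taken.
#' @return A list of class `traffic_script`.
#' @export
traffic_script <- function(generations, service_times = numeric(),
                           route_choices = integer()) {
  generations <- tibble::as_tibble(generations)
  req <- c("time", "source", "destination")
  if (!all(req %in% names(generations))) {
    abort("`generations` needs columns time, source, destination.")
  }
  if (nrow(generations) > 0 && any(generations$time < 0)) {
    abort("Generation times must be non-negative.")
  }
  if (!"unit" %in% names(generations)) {
    generations$unit <- paste0("u", seq_len(nrow(generations)))
  }
  if (any(generations$source == generations$destination)) {
    abort("A unit's destination must differ from its source.")
  }
  if (any(service_times < 0)) abort("Service durations must be non-negative.")
  structure(list(generations = generations,
                 service_times = as.numeric(service_times),
                 route_choices = as.integer(route_choices)),
            class = "traffic_script")
}

#' Replay a simulation from an explicit script
#'
#' Identical queueing mechanics to [simulate_traffic()] — destination
#' absorption on arrival, single non-preemptive server, K-slot
#' last-in-first-out buffer with displacement of the oldest queued unit on
#' overflow, uniform routing replaced by scripted choices — but every
#' stochastic draw is taken from `script`. Always records the full event log
#' and contents trajectories.
#'
#' Unlike the stochastic simulator, nodes with out-degree 0 are tolerated as
#' long as the script never requires routing from them.
#'
#' @param net A `directed_network`.
#' @param script A [traffic_script()].
#' @param K Buffer capacity (queue slots, server excluded).
#' @param T End of the run; defaults to the time of the last event.
#' @param t_transient Initial interval excluded from metrics.
#' @param count_deliveries As in [sim_params()].
#' @return A `sim_result` (see [simulate_traffic()]); `events$unit` holds
#'   the script's unit labels.
#' @examples
#' fx <- walkthrough_fixture()
#' res <- scripted_simulate(fx$network, fx$script, K = fx$K, T = fx$T)
#' res$ledger$ejected  # the displaced oldest unit
#' @export
scripted_simulate <- function(net, script, K = 10L, T = NULL,
                              t_transient = 0, count_deliveries = TRUE) {
  stopifnot(inherits(net, "directed_network"), inherits(script, "traffic_script"))
  labels <- net$labels
  gen <- script$generations
  bad <- setdiff(unique(c(gen$source, gen$destination)), labels)
  if (length(bad) > 0) {
    abort(paste0("Script references absent node(s): ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  n <- length(labels)
  adj <- net$adjacency
  nbrs <- lapply(seq_len(n), function(i) which(adj[i, ] == 1L))

  if (is.null(T)) T <- Inf   # resolved to the last event time afterwards

  # pending events: generations (type g) in row order, completions (type c)
  ev_t <- gen$time
  ev_seq <- seq_along(ev_t)
  ev_type <- rep("g", length(ev_t))
  ev_node <- rep(NA_integer_, length(ev_t))
  ev_unit <- seq_len(nrow(gen))
  seq_ctr <- length(ev_t)

  serving <- rep(NA_integer_, n)
  buf <- vector("list", n)          # [1] = back (oldest) ... end = front
  nq <- integer(n)
  maxq <- integer(n)
  last_t <- numeric(n)
  busy_int <- numeric(n)
  cont_int <- numeric(n)
  arrivals <- integer(n)
  edge_count <- matrix(0L, n, n)
  delivered <- 0L; ejected <- 0L
  svc_i <- 0L; route_i <- 0L
  dest_idx <- match(gen$destination, labels)

  log_rows <- list()
  traj_rows <- list()
  log_event <- function(t, type, node, unit) {
    log_rows[[length(log_rows) + 1L]] <<- list(
      time = t, event = type, node = labels[node], unit = gen$unit[unit])
  }
  log_traj <- function(t, i) {
    traj_rows[[length(traj_rows) + 1L]] <<- list(
      time = t, node = labels[i], n = nq[i])
  }
  acc <- function(i, t) {
    hi <- min(t, T); lo <- max(last_t[i], t_transient)
    if (hi > lo) {
      cont_int[i] <<- cont_int[i] + (hi - lo) * nq[i]
      if (!is.na(serving[i])) busy_int[i] <<- busy_int[i] + (hi - lo)
    }
    last_t[i] <<- t
  }
  push_event <- function(t, type, node, unit) {
    seq_ctr <<- seq_ctr + 1L
    ev_t <<- c(ev_t, t); ev_seq <<- c(ev_seq, seq_ctr)
    ev_type <<- c(ev_type, type); ev_node <<- c(ev_node, node)
    ev_unit <<- c(ev_unit, unit)
  }
  start_service <- function(i, t, u) {
    serving[i] <<- u
    svc_i <<- svc_i + 1L
    dur <- if (svc_i <= length(script$service_times))
      script$service_times[svc_i] else Inf
    if (is.finite(dur)) push_event(t + dur, "c", i, u)
    log_event(t, "start_service", i, u)
  }
  handle_arrival <- function(u, i, t) {
    if (t >= t_transient && t <= T &&
        (count_deliveries || dest_idx[u] != i)) {
      arrivals[i] <<- arrivals[i] + 1L
    }
    log_event(t, "arrive", i, u)
    if (dest_idx[u] == i) {
      delivered <<- delivered + 1L
      log_event(t, "deliver", i, u)
      return(invisible())
    }
    if (is.na(serving[i])) {
      acc(i, t); nq[i] <<- nq[i] + 1L
      start_service(i, t, u)
      log_traj(t, i)
    } else if (length(buf[[i]]) < K) {
      acc(i, t); nq[i] <<- nq[i] + 1L
      buf[[i]] <<- c(buf[[i]], u)
      maxq[i] <<- max(maxq[i], length(buf[[i]]))
      log_traj(t, i)
    } else {
      old <- buf[[i]][1]
      buf[[i]] <<- c(buf[[i]][-1], u)
      ejected <<- ejected + 1L
      log_event(t, "eject", i, old)
    }
    invisible()
  }
  handle_completion <- function(i, t, u) {
    k_out <- length(nbrs[[i]])
    route_i <<- route_i + 1L
    pick <- if (route_i <= length(script$route_choices))
      script$route_choices[route_i] else 1L
    if (k_out == 0L) {
      abort(sprintf("Unit completing at '%s' has no efferent edge to route along.",
                    labels[i]))
    }
    if (pick < 1L || pick > k_out) {
      abort(sprintf("Route choice %d out of range at node '%s' (out-degree %d).",
                    pick, labels[i], k_out))
    }
    j <- nbrs[[i]][pick]
    if (t >= t_transient && t <= T) edge_count[i, j] <<- edge_count[i, j] + 1L
    acc(i, t); nq[i] <<- nq[i] - 1L
    serving[i] <<- NA_integer_
    log_event(t, "complete", i, u)
    log_traj(t, i)
    handle_arrival(u, j, t)
    if (length(buf[[i]]) > 0 && is.na(serving[i])) {
      u2 <- buf[[i]][length(buf[[i]])]
      buf[[i]] <<- buf[[i]][-length(buf[[i]])]
      acc(i, t)
      start_service(i, t, u2)
    }
    invisible()
  }

  last_event_time <- 0
  while (length(ev_t) > 0) {
    k <- order(ev_t, ev_seq)[1]
    t <- ev_t[k]
    if (t > T) break
    type <- ev_type[k]; node <- ev_node[k]; unit <- ev_unit[k]
    ev_t <- ev_t[-k]; ev_seq <- ev_seq[-k]
    ev_type <- ev_type[-k]; ev_node <- ev_node[-k]; ev_unit <- ev_unit[-k]
    last_event_time <- t
    if (type == "g") {
      src <- match(gen$source[unit], labels)
      log_event(t, "generate", src, unit)
      handle_arrival(unit, src, t)
    } else {
      handle_completion(node, t, unit)
    }
  }
  if (!is.finite(T)) T <- last_event_time
  for (i in seq_len(n)) acc(i, T)

  residual <- sum(!is.na(serving)) + sum(lengths(buf))
  idx <- which(adj == 1L, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  out <- structure(list(
    nodes = tibble::tibble(
      node = labels, arrivals = arrivals, busy_time = busy_int,
      contents_integral = cont_int, max_queue = maxq),
    edges = tibble::tibble(from = labels[idx[, 1]], to = labels[idx[, 2]],
                           count = edge_count[idx]),
    ledger = list(generated = nrow(gen), delivered = delivered,
                  ejected = ejected, residual = residual),
    params = list(K = as.integer(K), T = T, t_transient = t_transient,
                  count_deliveries = count_deliveries, scripted = TRUE),
    seed = NULL,
    window = c(start = t_transient, end = T),
    labels = labels,
    events = if (length(log_rows)) dplyr::bind_rows(log_rows) else
      tibble::tibble(time = numeric(), event = character(),
                     node = character(), unit = character()),
    trajectory = if (length(traj_rows)) dplyr::bind_rows(traj_rows) else
      tibble::tibble(time = numeric(), node = character(), n = integer())),
    class = "sim_result")
  out
}
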