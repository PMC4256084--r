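#' Simulation parameters
#'
#' Bundles the parameters of one traffic simulation. Time is dimensionless
#' throughout; with the default `mu = 1` the time unit is one mean service.
#'
#' @param lambda Exogenous generation rate (signal units per time unit). By
#'   default one network-wide Poisson process with a uniformly random source
#'   per unit; with `per_node = TRUE`, `lambda` is instead read as a
#'   per-node rate (total rate `lambda * N`), an equivalent
#'   parameterization of the same process.
#' @param mu Service rate per node (completions per time unit).
#' @param K Buffer capacity: queue slots per node, excluding the server slot.
#' @param T Total simulated duration (time units).
#' @param t_transient Initial interval excluded from all metrics. Defaults
#'   to 2\% of `T`, which reproduces the conventional 40,000-unit cut at the
#'   full 2-million-unit study duration.
#' @param per_node Interpret `lambda` as a per-node rate.
#' @param count_deliveries Whether arrivals at a unit's destination count in
#'   the arrivals metric (default `TRUE`: exogenous generations, hops and
#'   destination absorptions are all arrivals to a node).
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(lambda, mu = 1, K = 10L, T = 2e6,
                       t_transient = 0.02 * T, per_node = FALSE,
                       count_deliveries = TRUE) {
  if (!is.numeric(lambda) || lambda <= 0) abort("`lambda` must be > 0.")
  if (!is.numeric(mu) || mu <= 0) abort("`mu` must be > 0.")
  if (!is.numeric(K) || K < 1 || K != round(K)) {
    abort("`K` must be an integer >= 1.")
  }
  if (!is.numeric(T) || T <= 0) abort("`T` must be > 0.")
  if (t_transient < 0 || t_transient >= T) {
    abort("`t_transient` must satisfy 0 <= t_transient < T.")
  }
  structure(list(lambda = lambda, mu = mu, K = as.integer(K), T = T,
                 t_transient = t_transient, per_node = isTRUE(per_node),
                 count_deliveries = isTRUE(count_deliveries)),
            class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat(sprintf(
    "<sim_params> lambda=%g%s mu=%g K=%d T=%g transient=%g%s\n",
    x$lambda, if (x$per_node) " (per node)" else "", x$mu, x$K, x$T,
    x$t_transient,
    if (x$count_deliveries) "" else " (deliveries excluded from arrivals)"))
  invisible(x)
}

#' Simulate signal traffic on a directed network
#'
#' Runs the discrete-event queueing model: signal units are generated by a
#' Poisson process with a uniformly random source and a uniformly random
#' destination among the other nodes; a unit arriving at its destination is
#' removed immediately; otherwise it is served (exponential service, one
#' non-preemptive server per node) or queued in a finite last-in-first-out
#' buffer of `K` slots, where on overflow the oldest queued unit is ejected
#' and the newcomer takes the front; on completing service a unit hops along
#' one efferent edge chosen uniformly at random. The run stops at time `T`;
#' units still in the system are counted as residual.
#'
#' Per-node counters and time-averages are accumulated on the post-transient
#' window `(t_transient, T]` only; the conservation ledger
#' (`generated = delivered + ejected + residual`) covers the whole run and
#' holds exactly.
#'
#' @param net A `directed_network` in which every node has out-degree >= 1.
#' @param params A [sim_params()] object.
#' @param seed Integer seed; the result is a deterministic function of
#'   `(net, params, seed)`. `NULL` uses (and advances) the session RNG.
#' @param record_events If `TRUE`, keep the full event log and per-node
#'   contents trajectories (memory scales with event count; intended for
#'   short runs, diagnostics and [remove_transient()]).
#' @return A `sim_result`: list with `nodes` (tibble: `node`, `arrivals`,
#'   `busy_time`, `contents_integral`, `max_queue`), `edges` (tibble:
#'   `from`, `to`, `count` for every edge of the network), `ledger`
#'   (generated / delivered / ejected / residual), `params`, `seed`,
#'   `window` (post-transient measurement window), and, when recorded,
#'   `events` and `trajectory` tibbles.
#' @examples
#' net <- generate_background(10, 0.3, seed = 1)
#' res <- simulate_traffic(net, sim_params(lambda = 0.5, T = 500), seed = 7)
#' node_metrics(res)
#' @export
simulate_traffic <- function(net, params, seed = NULL, record_events = FALSE) {
  stopifnot(inherits(net, "directed_network"), inherits(params, "sim_params"))
  kout <- rowSums(net$adjacency)
  if (any(kout == 0)) {
    abort(paste0("Simulation requires out-degree >= 1 at every node; ",
                 "0 at: ", paste(head(net$labels[kout == 0], 5), collapse = ", ")))
  }
  csr <- adjacency_to_csr(net)
  lambda_total <- if (params$per_node) params$lambda * n_nodes(net) else params$lambda
  runner <- function() {
    .des_run(csr$offsets, csr$targets, lambda_total, params$mu, params$K,
             params$T, params$t_transient, params$count_deliveries,
             record_events)
  }
  raw <- if (is.null(seed)) runner() else withr::with_seed(seed, runner())

  nodes <- tibble::tibble(
    node = net$labels,
    arrivals = as.integer(raw$arrivals),
    busy_time = raw$busy_time,
    contents_integral = raw$contents_integral,
    max_queue = raw$max_queue)
  edges <- tibble::tibble(
    from = net$labels[csr$from + 1L],
    to = net$labels[csr$targets + 1L],
    count = as.integer(raw$edge_count))
  out <- structure(list(
    nodes = nodes, edges = edges,
    ledger = lapply(raw$ledger, as.integer),
    params = params, seed = seed,
    window = c(start = params$t_transient, end = params$T),
    labels = net$labels), class = "sim_result")
  if (record_events) {
    out$events <- tibble::tibble(
      time = raw$events$time,
      event = c("generate", "arrive", "deliver", "eject", "start_service",
                "complete")[raw$events$type + 1L],
      node = net$labels[raw$events$node + 1L],
      unit = as.integer(raw$events$unit))
    out$trajectory <- tibble::tibble(
      time = raw$trajectory$time,
      node = net$labels[raw$trajectory$node + 1L],
      n = raw$trajectory$n)
  }
  out
}

#' @export
print.sim_result <- function(x, ...) {
  led <- x$ledger
  cat(sprintf(
    "<sim_result> %d nodes | window (%g, %g]\n  generated %d = delivered %d + ejected %d + residual %d\n",
    nrow(x$nodes), x$window[["start"]], x$window[["end"]],
    led$generated, led$delivered, led$ejected, led$residual))
  invisible(x)
}

# 0-based CSR out-adjacency; edge ids follow row-major adjacency order
adjacency_to_csr <- function(net) {
  a <- net$adjacency
  n <- nrow(a)
  kout <- rowSums(a)
  offsets <- c(0L, cumsum(as.integer(kout)))
  targets <- integer(sum(kout))
  from <- integer(sum(kout))
  pos <- 1L
  for (i in seq_len(n)) {
    nb <- which(a[i, ] == 1L)
    if (length(nb) > 0) {
      targets[pos:(pos + length(nb) - 1L)] <- nb - 1L
      from[pos:(pos + length(nb) - 1L)] <- i - 1L
      pos <- pos + length(nb)
    }
  }
  list(offsets = offsets, targets = targets, from = from)
}

#' Exponential variate by inverse transform
#'
#' The primitive used for every inter-arrival and service time:
#' `-log(u) / rate` maps a uniform variate `u` to an exponential one.
#'
#' @param rate Positive rate.
#' @param u Uniform variate strictly inside `(0, 1)`.
#' @return `-log(u) / rate`.
#' @examples
#' sample_exponential(1, exp(-1))  # exactly 1
#' @export
sample_exponential <- function(rate, u) {
  if (!is.numeric(rate) || any(rate <= 0)) abort("`rate` must be > 0.")
  if (!is.numeric(u) || any(u <= 0) || any(u >= 1)) {
    abort("`u` must lie strictly inside (0, 1).")
  }
  -log(u) / rate
}
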