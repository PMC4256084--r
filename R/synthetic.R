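#' Random directed background graph
#'
#' Directed Erdős–Rényi-style background: each ordered pair `(i, j)`,
#' `i != j`, carries an edge independently with probability `p`. The draw is
#' regenerated (bounded retries) until every node has out-degree >= 1 —
#' required by the traffic simulation — and in-degree >= 1, which
#' guarantees that full direction reversal also leaves every node routable
#' (reversal swaps the roles of in- and out-edges).
#'
#' @param N Number of nodes (>= 2); labels `n1 ... nN`.
#' @param p Edge probability in (0, 1).
#' @param seed Integer seed; the network is a deterministic function of
#'   `(N, p, seed)`.
#' @param max_retries Redraws allowed before giving up (relevant at very
#'   small `p`).
#' @return A `directed_network`.
#' @export
generate_background <- function(N, p, seed = NULL, max_retries = 100L) {
  if (!is.numeric(N) || N < 2) abort("`N` must be >= 2.")
  if (!is.numeric(p) || p <= 0 || p >= 1) abort("`p` must be in (0, 1).")
  draw <- function() {
    for (try in seq_len(max_retries)) {
      adj <- matrix(as.integer(runif(N * N) < p), N, N)
      diag(adj) <- 0L
      if (all(rowSums(adj) >= 1L) && all(colSums(adj) >= 1L)) return(adj)
    }
    abort(sprintf(
      "No draw with in- and out-degree >= 1 everywhere in %d retries; increase `p`.",
      max_retries))
  }
  adj <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  directed_network(adj, labels = paste0("n", seq_len(N)))
}

#' Specification of a planted funnel motif
#'
#' The structural ingredient behind traffic convergence: relay nodes with
#' many afferents but very few efferents, all of which point at (or
#' include) a single target. The archetype is a relay with 34 afferents and
#' a single efferent feeding the target — a severe degree imbalance.
#'
#' @param relays Labels of the relay nodes (default 2 relays).
#' @param target Label of the target node the relays converge on.
#' @param afferents_per_relay Integer vector (recycled to the number of
#'   relays): in-degree given to each relay.
#' @param relay_out_degree Integer vector (recycled): out-degree kept per
#'   relay; the target is always among the efferents.
#' @param seed Integer seed for the afferent/efferent draws.
#' @return A list of class `funnel_spec`.
#' @export
funnel_spec <- function(relays = c("relay1", "relay2"), target = "target",
                        afferents_per_relay = c(34L, 41L),
                        relay_out_degree = c(1L, 2L), seed = NULL) {
  n <- length(relays)
  afferents_per_relay <- rep_len(as.integer(afferents_per_relay), max(n, 1))
  relay_out_degree <- rep_len(as.integer(relay_out_degree), max(n, 1))
  if (n > 0 && any(afferents_per_relay < 1)) abort("Afferent counts must be >= 1.")
  if (n > 0 && any(relay_out_degree < 1)) abort("Relay out-degrees must be >= 1.")
  if (target %in% relays) abort("`target` cannot be one of the relays.")
  structure(list(relays = relays, target = target,
                 afferents_per_relay = afferents_per_relay,
                 relay_out_degree = relay_out_degree, seed = seed),
            class = "funnel_spec")
}

#' Plant a funnel motif in a directed network
#'
#' Rewrites the neighbourhoods of the spec's relay nodes: each relay
#' receives exactly `afferents_per_relay` incoming edges from distinct
#' random non-relay nodes and keeps exactly `relay_out_degree` efferents
#' with the target always included. All planted edges are forced
#' unidirectional (reciprocals removed), so the direction-reversal null
#' model acts on every one of them. Nodes left by the rewrite without
#' efferents — or without afferents, which would make them unroutable under
#' full direction reversal — are given one random replacement edge.
#'
#' @param net A `directed_network` containing the spec's relay and target
#'   labels.
#' @param spec A [funnel_spec()]. With zero relays the network is returned
#'   unchanged.
#' @return A `directed_network`; the planted ground truth is attached as
#'   attribute `funnel` (relays, target, planted efferent edges).
#' @export
plant_funnel <- function(net, spec) {
  stopifnot(inherits(net, "directed_network"), inherits(spec, "funnel_spec"))
  if (length(spec$relays) == 0) return(net)
  labels <- net$labels
  missing <- setdiff(c(spec$relays, spec$target), labels)
  if (length(missing) > 0) {
    abort(paste0("Network lacks node(s): ", paste(missing, collapse = ", ")))
  }
  build <- function() {
    adj <- net$adjacency
    n <- length(labels)
    ridx <- match(spec$relays, labels)
    tidx <- match(spec$target, labels)
    efferent_edges <- list()
    for (r in seq_along(ridx)) {
      i <- ridx[r]
      k_out <- spec$relay_out_degree[r]
      k_in <- spec$afferents_per_relay[r]
      # efferents: the target plus (k_out - 1) distinct others
      extra_pool <- setdiff(seq_len(n), c(i, ridx, tidx))
      if (k_out - 1 > length(extra_pool)) {
        abort("Not enough nodes for the requested relay out-degree.")
      }
      eff <- c(tidx, if (k_out > 1) sample_from(extra_pool, k_out - 1))
      # afferents: distinct sources; exclude relays, target and the relay's
      # own efferents so every planted edge can be made unidirectional
      aff_pool <- setdiff(seq_len(n), c(i, ridx, tidx, eff))
      if (k_in > length(aff_pool)) {
        abort("Not enough distinct nodes for the requested afferent count.")
      }
      aff <- sample_from(aff_pool, k_in)
      adj[i, ] <- 0L
      adj[, i] <- 0L
      adj[i, eff] <- 1L
      adj[aff, i] <- 1L
      adj[eff, i] <- 0L        # planted efferents unidirectional
      efferent_edges[[r]] <- tibble::tibble(from = labels[i], to = labels[eff])
    }
    # the rewrite can strip a background node of its last out-edge, or of
    # its last in-edge (which would leave it efferent-less under full
    # direction reversal); restore both
    fix <- setdiff(which(rowSums(adj) == 0L), ridx)
    for (u in fix) {
      pool <- setdiff(seq_len(n), c(u, ridx))
      pool <- pool[adj[u, pool] == 0L]
      adj[u, sample_from(pool, 1L)] <- 1L
    }
    fix_in <- setdiff(which(colSums(adj) == 0L), ridx)
    for (v in fix_in) {
      pool <- setdiff(seq_len(n), c(v, ridx))
      pool <- pool[adj[pool, v] == 0L]
      adj[sample_from(pool, 1L), v] <- 1L
    }
    list(adj = adj, eff = dplyr::bind_rows(efferent_edges))
  }
  built <- if (is.null(spec$seed)) build() else withr::with_seed(spec$seed, build())
  out <- directed_network(built$adj, labels = labels)
  attr(out, "funnel") <- list(relays = spec$relays, target = spec$target,
                              efferent_edges = built$eff)
  out
}

#' Synthetic network with a planted funnel motif
#'
#' Convenience wrapper: an Erdős–Rényi background with two relay nodes
#' mimicking the archetypal degree imbalance — 34 and 41 afferents against
#' out-degrees of 1 and 2 — converging on one target. The default size
#' (100 nodes, about five efferents per background node) keeps the motif
#' large relative to the background while the network stays small enough
#' for ensemble studies.
#'
#' @param N Nodes in total.
#' @param background_out_degree Mean efferents per background node; sets
#'   the edge probability `p = background_out_degree / (N - 1)` so the
#'   background density is size-independent.
#' @param p Background edge probability (overrides
#'   `background_out_degree` when given explicitly).
#' @param afferents_per_relay,relay_out_degree Per-relay degree targets.
#' @param seed Integer seed for background and planting.
#' @return A `directed_network` with the `funnel` ground-truth attribute;
#'   relays are labelled `relay1`, `relay2`, the target `target`.
#' @export
funnel_network <- function(N = 100L, background_out_degree = 5,
                           p = background_out_degree / (N - 1),
                           afferents_per_relay = c(34L, 41L),
                           relay_out_degree = c(1L, 2L), seed = 1L) {
  bg <- generate_background(N, p, seed = derive_seed(seed, "background"))
  labels <- bg$labels
  n_rel <- length(afferents_per_relay)
  rename <- stats::setNames(labels, labels)
  rename[1:n_rel] <- paste0("relay", seq_len(n_rel))
  rename[n_rel + 1] <- "target"
  bg$labels <- unname(rename)
  dimnames(bg$adjacency) <- list(bg$labels, bg$labels)
  spec <- funnel_spec(relays = paste0("relay", seq_len(n_rel)),
                      target = "target",
                      afferents_per_relay = afferents_per_relay,
                      relay_out_degree = relay_out_degree,
                      seed = derive_seed(seed, "plant"))
  plant_funnel(bg, spec)
}

#' Three-node walkthrough fixture
#'
#' The smallest instructive case: a chain `1 -> 2 -> 3` with two-slot
#' buffers and four scripted signal units (red and teal served in turn at
#' node 1; blue in service at node 2 with green queued behind it). Replayed
#' with [scripted_simulate()], the timeline exhibits every mechanic of the
#' model: LIFO insertion at the buffer front (red at time 2), displacement
#' and ejection of the oldest queued unit on overflow (green at time 4),
#' and onward hops on service completion (blue to node 3 at time 6).
#'
#' @return A list: `network`, `script` (a [traffic_script()]), buffer size
#'   `K = 2` and horizon `T = 8`.
#' @examples
#' fx <- walkthrough_fixture()
#' res <- scripted_simulate(fx$network, fx$script, K = fx$K, T = fx$T)
#' res$ledger
#' @export
walkthrough_fixture <- function() {
  adj <- rbind(c(0L, 1L, 0L), c(0L, 0L, 1L), c(0L, 0L, 0L))
  net <- directed_network(adj, labels = c("1", "2", "3"))
  generations <- tibble::tibble(
    time = c(0, 0, 0, 0),
    source = c("2", "2", "1", "1"),
    destination = c("1", "3", "3", "3"),
    unit = c("blue", "green", "red", "teal"))
  script <- traffic_script(
    generations = generations,
    # consumed at service starts: blue@2, red@1, teal@1, blue@3, teal@2
    service_times = c(6, 2, 2, 10, 10),
    # consumed at completions: red 1->2, teal 1->2, blue 2->3
    route_choices = c(1L, 1L, 1L))
  list(network = net, script = script, K = 2L, T = 8)
}

# size-safe uniform sampling without replacement (length-1 pools stay fixed)
sample_from <- function(x, k) x[sample.int(length(x), k)]
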