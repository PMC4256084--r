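# Independent oracles and fixture builders used across the suite.

# stationary distribution of the M/M/1/(cap) birth-death chain:
# up-rate lambda for states < cap, down-rate mu; returns utilization and
# mean number-in-system from the closed form p_n \propto rho^n
birth_death_stationary <- function(lambda, mu, cap) {
  rho <- lambda / mu
  n <- 0:cap
  pn <- if (abs(rho - 1) < 1e-12) rep(1 / (cap + 1), cap + 1) else
    rho^n * (1 - rho) / (1 - rho^(cap + 1))
  pn <- pn / sum(pn)
  list(utilization = 1 - pn[1], mean_contents = sum(n * pn))
}

# directed ring 1 -> 2 -> ... -> N -> 1
make_ring <- function(N) {
  adj <- matrix(0L, N, N)
  adj[cbind(seq_len(N), c(seq_len(N)[-1], 1L))] <- 1L
  directed_network(adj, labels = paste0("v", seq_len(N)))
}

# every node projects to the next k nodes around the ring: constant
# out-degree k, so scripted route choices in 1..k are always legal
make_regular_net <- function(N, k) {
  adj <- matrix(0L, N, N)
  for (s in seq_len(k)) {
    adj[cbind(seq_len(N), ((seq_len(N) - 1L + s) %% N) + 1L)] <- 1L
  }
  directed_network(adj, labels = paste0("v", seq_len(N)))
}

# random binary directed network (not necessarily routable)
make_random_net <- function(N, p, seed) {
  withr::with_seed(seed, {
    adj <- matrix(as.integer(runif(N * N) < p), N, N)
    diag(adj) <- 0L
    directed_network(adj, labels = paste0("v", seq_len(N)))
  })
}

# random deterministic script on a constant-out-degree network
make_random_script <- function(net, k_out, n_units, horizon, seed) {
  withr::with_seed(seed, {
    labels <- net$labels
    src <- sample(labels, n_units, replace = TRUE)
    dst <- vapply(src, function(s) sample(setdiff(labels, s), 1), character(1))
    traffic_script(
      generations = tibble::tibble(
        time = sort(runif(n_units, 0, horizon)),
        source = src, destination = unname(dst)),
      service_times = stats::rexp(n_units * 6, rate = 1),
      route_choices = sample.int(k_out, n_units * 6, replace = TRUE))
  })
}

# Straight-line reference interpreter for scripted runs: replays the same
# mechanics with flat loops and plain vectors, tracking only the ledger and
# per-node arrival counts. Kept deliberately simple and separate from the
# package implementation.
reference_scripted_ledger <- function(net, script, K, T) {
  labels <- net$labels
  n <- length(labels)
  adj <- net$adjacency
  gen <- script$generations
  n_units <- nrow(gen)
  src <- match(gen$source, labels)
  dst <- match(gen$destination, labels)

  # pending completion per node (Inf = idle), unit in service per node
  completes_at <- rep(Inf, n)
  in_service <- rep(NA_integer_, n)
  queues <- rep(list(integer()), n)   # element 1 = oldest
  next_gen <- 1L
  svc <- script$service_times
  rts <- script$route_choices
  svc_used <- 0L
  rts_used <- 0L
  arrivals <- integer(n)
  delivered <- 0L
  ejected <- 0L

  arrive <- function(u, node, t) {
    arrivals[node] <<- arrivals[node] + as.integer(t <= T)
    if (dst[u] == node) {
      delivered <<- delivered + 1L
      return(NULL)
    }
    if (is.na(in_service[node])) {
      in_service[node] <<- u
      svc_used <<- svc_used + 1L
      d <- if (svc_used <= length(svc)) svc[svc_used] else Inf
      completes_at[node] <<- t + d
    } else if (length(queues[[node]]) < K) {
      queues[[node]] <<- c(queues[[node]], u)
    } else {
      queues[[node]] <<- c(queues[[node]][-1], u)
      ejected <<- ejected + 1L
    }
    NULL
  }

  repeat {
    t_gen <- if (next_gen <= n_units) gen$time[next_gen] else Inf
    t_cmp <- min(completes_at)
    if (is.infinite(t_gen) && is.infinite(t_cmp)) break
    if (min(t_gen, t_cmp) > T) break
    if (t_gen <= t_cmp) {           # generations win ties (scheduled first)
      arrive(next_gen, src[next_gen], t_gen)
      next_gen <- next_gen + 1L
    } else {
      node <- which.min(completes_at)
      u <- in_service[node]
      nb <- which(adj[node, ] == 1L)
      rts_used <- rts_used + 1L
      pick <- if (rts_used <= length(rts)) rts[rts_used] else 1L
      in_service[node] <- NA_integer_
      completes_at[node] <- Inf
      arrive(u, nb[pick], t_cmp)
      if (length(queues[[node]]) > 0 && is.na(in_service[node])) {
        m <- length(queues[[node]])
        u2 <- queues[[node]][m]     # LIFO: newest first
        queues[[node]] <- queues[[node]][-m]
        in_service[node] <- u2
        svc_used <- svc_used + 1L
        d <- if (svc_used <= length(svc)) svc[svc_used] else Inf
        completes_at[node] <- t_cmp + d
      }
    }
  }
  residual <- sum(!is.na(in_service)) + sum(lengths(queues))
  list(ledger = list(generated = n_units, delivered = delivered,
                     ejected = ejected, residual = residual),
       arrivals = arrivals)
}

# Reconstructs the per-node contents sequence (server + queue occupancy)
# from the event log alone, for checking the contents identity
# n_i(t) = s_i(t) + q_i(t) against the recorded trajectory.
contents_from_events <- function(result) {
  ev <- result$events
  n_ev <- nrow(ev)
  s <- stats::setNames(integer(length(result$labels)), result$labels)
  q <- s
  rows <- list()
  for (i in seq_len(n_ev)) {
    e <- ev$event[i]
    node <- ev$node[i]
    if (e == "arrive") {
      nxt_e <- if (i < n_ev) ev$event[i + 1] else ""
      nxt_same_unit <- i < n_ev && ev$unit[i + 1] == ev$unit[i] &&
        ev$time[i + 1] == ev$time[i] && ev$node[i + 1] == node
      nxt_eject <- i < n_ev && ev$event[i + 1] == "eject" &&
        ev$time[i + 1] == ev$time[i] && ev$node[i + 1] == node
      if (nxt_same_unit && nxt_e %in% c("deliver", "start_service")) {
        # handled by the next record
      } else if (nxt_eject) {
        # displacement: one queued in, oldest out; contents unchanged
      } else {
        q[node] <- q[node] + 1L
        rows[[length(rows) + 1L]] <- list(time = ev$time[i], node = node,
                                          n = s[[node]] + q[[node]])
      }
    } else if (e == "start_service") {
      was_queued <- q[node] > 0L && !(i > 1 && ev$event[i - 1] == "arrive" &&
        ev$unit[i - 1] == ev$unit[i] && ev$time[i - 1] == ev$time[i])
      s[node] <- 1L
      if (was_queued) {
        q[node] <- q[node] - 1L     # dequeue: contents unchanged, no row
      } else {
        rows[[length(rows) + 1L]] <- list(time = ev$time[i], node = node,
                                          n = s[[node]] + q[[node]])
      }
    } else if (e == "complete") {
      s[node] <- 0L
      rows[[length(rows) + 1L]] <- list(time = ev$time[i], node = node,
                                        n = s[[node]] + q[[node]])
    }
  }
  dplyr::bind_rows(rows)
}

# independent exact integral of a step function over [lo, hi]
step_int_oracle <- function(traj, lo, hi) {
  ts <- c(traj$time, hi)
  total <- 0
  for (k in seq_len(nrow(traj))) {
    a <- max(ts[k], lo)
    b <- max(a, min(ts[k + 1], hi))
    total <- total + (b - a) * traj$value[k]
  }
  total
}
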