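test_that("node metrics reduce the walkthrough run to hand-computed values", {
  fx <- walkthrough_fixture()
  res <- scripted_simulate(fx$network, fx$script, K = fx$K, T = fx$T)
  m <- node_metrics(res)
  expect_s3_class(m, "metric_table")
  expect_equal(m$arrivals, c(2L, 4L, 1L))
  expect_equal(m$utilization, c(4, 8, 2) / 8)
  expect_equal(m$mean_contents, c(6, 20, 2) / 8)
  # a node never visited reports zeros
  iso <- scripted_simulate(
    fx$network,
    traffic_script(tibble::tibble(time = 0, source = "1", destination = "3"),
                   service_times = 100),
    K = 2, T = 10)
  expect_equal(node_metrics(iso)[3, ],
               tibble::tibble(node = "3", arrivals = 0L, mean_contents = 0,
                              utilization = 0),
               ignore_attr = TRUE)
  # a single unit in service for the whole window saturates utilization
  expect_equal(node_metrics(iso)$utilization[1], 1)
})

test_that("edge traffic counts service-completion hops only", {
  fx <- walkthrough_fixture()
  # one unit walks 1 -> 2 -> 3: exactly one traversal per edge
  walk <- traffic_script(
    tibble::tibble(time = 0, source = "1", destination = "3"),
    service_times = c(1, 1), route_choices = c(1L, 1L))
  res <- scripted_simulate(fx$network, walk, K = 2, T = 5)
  expect_equal(res$edges$count, c(1L, 1L))
  mat <- edge_traffic_matrix(res)
  expect_equal(unname(mat["1", "2"]), 1L)
  expect_equal(sum(mat), 2L)
  # matrix is zero wherever there is no edge
  expect_true(all(mat[fx$network$adjacency == 0L] == 0L))
  # no completions, no traffic
  idle <- scripted_simulate(
    fx$network,
    traffic_script(tibble::tibble(time = 0, source = "1", destination = "3"),
                   service_times = 100),
    K = 2, T = 10)
  expect_true(all(edge_traffic(idle)$count == 0L))
})

test_that("uniform resampling holds steps and converges to the exact integral", {
  const <- tibble::tibble(time = c(0, 3, 7), value = c(2, 2, 2))
  samp <- resample_uniform(const, dt = 0.5)
  expect_true(all(samp$value == 2))

  step <- tibble::tibble(time = c(0, 5), value = c(0, 1))
  expect_equal(resample_uniform(step, dt = 4.5)$value[2], 0)     # hold
  expect_equal(resample_uniform(step, dt = 4.5,
                                method = "linear")$value[2], 0.9)

  traj <- withr::with_seed(4, tibble::tibble(
    time = c(0, sort(runif(30, 0, 10))),
    value = c(0, sample(0:5, 30, replace = TRUE))))
  exact <- step_int_oracle(traj, 0, 10) / 10
  for (dt in c(0.1, 0.01)) {
    samp <- resample_uniform(traj, dt = dt, t_end = 10)
    expect_lt(abs(mean(samp$value) - exact), 6 * dt)
  }
  expect_error(resample_uniform(traj[0, ], dt = 1), "Empty")
})

test_that("transient removal recomputes counters on the retained window", {
  fx <- walkthrough_fixture()
  res <- scripted_simulate(fx$network, fx$script, K = fx$K, T = fx$T)

  # cut at zero: unchanged
  expect_equal(remove_transient(res, 0)$nodes, res$nodes)

  # cut at 3, hand-partitioned: teal and blue hops remain; red's do not
  cut <- remove_transient(res, 3)
  expect_equal(cut$nodes$arrivals, c(0L, 1L, 1L))
  expect_equal(cut$nodes$busy_time, c(1, 5, 2))
  expect_equal(cut$nodes$contents_integral, c(1, 13, 2))
  expect_equal(cut$edges$count, c(1L, 1L))
  expect_identical(cut$ledger, res$ledger)   # whole-run ledger untouched

  # a run whose only events precede the cut leaves zero counters
  early <- traffic_script(
    tibble::tibble(time = 0, source = "1", destination = "2"),
    service_times = 1, route_choices = 1L)
  res2 <- scripted_simulate(fx$network, early, K = 2, T = 10)
  late <- remove_transient(res2, 5)
  expect_true(all(late$nodes$arrivals == 0L))
  expect_true(all(late$nodes$busy_time == 0))
  expect_error(remove_transient(res2, 10), "empty window")
})

test_that("stochastic runs recount identically through the event log", {
  net <- generate_background(8, 0.4, seed = 12)
  p <- sim_params(lambda = 1.5, K = 3, T = 100, t_transient = 0)
  res <- simulate_traffic(net, p, seed = 21, record_events = TRUE)
  cut <- remove_transient(res, 20)
  # engine-side accumulation over the same window must agree exactly
  res2 <- simulate_traffic(net, sim_params(1.5, K = 3, T = 100,
                                           t_transient = 20),
                           seed = 21, record_events = TRUE)
  expect_equal(cut$nodes$arrivals, res2$nodes$arrivals)
  expect_equal(cut$nodes$busy_time, res2$nodes$busy_time, tolerance = 1e-12)
  expect_equal(cut$nodes$contents_integral, res2$nodes$contents_integral,
               tolerance = 1e-12)
  expect_equal(cut$edges, res2$edges)
})

test_that("busy time from the event log matches the online counter to 1e-9", {
  for (seed in c(31, 32)) {
    net <- generate_background(10, 0.35, seed = seed)
    res <- simulate_traffic(net, sim_params(2, K = 2, T = 150,
                                            t_transient = 10),
                            seed = seed, record_events = TRUE)
    indep <- busy_time_from_events(res)
    expect_equal(unname(indep), res$nodes$busy_time, tolerance = 1e-9)
  }
})

test_that("metrics are keyed by label, not by node position", {
  fx <- walkthrough_fixture()
  res <- scripted_simulate(fx$network, fx$script, K = fx$K, T = fx$T)
  # same network stored in permuted node order
  perm <- c(3, 1, 2)
  net_p <- directed_network(fx$network$adjacency[perm, perm],
                            labels = fx$network$labels[perm])
  res_p <- scripted_simulate(net_p, fx$script, K = fx$K, T = fx$T)
  a <- dplyr::arrange(node_metrics(res), node)
  b <- dplyr::arrange(node_metrics(res_p), node)
  expect_equal(a, b)
})

test_that("ensemble transient estimation finds the settling time", {
  # stationary replicates: no transient
  flat <- list(rep(3, 100), rep(3, 100))
  expect_equal(ensemble_transient_estimate(flat), 0)

  # exponential rise toward a plateau: analytic settling time tau*log(1/tol)
  tau <- 5; times <- seq(0, 60, by = 0.1)
  rise <- 1 - exp(-times / tau)
  est <- ensemble_transient_estimate(list(rise, rise), times = times,
                                     tolerance = 0.05, terminal_frac = 0.1)
  analytic <- tau * log(1 / 0.05)
  expect_lt(abs(est - analytic), 0.2 + 0.1)   # plateau bias + grid step

  expect_error(ensemble_transient_estimate(list(rise)), "at least 2")
  expect_error(ensemble_transient_estimate(list(1:5, 1:6)), "mismatched")
})
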