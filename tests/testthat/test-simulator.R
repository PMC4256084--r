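test_that("inverse-transform exponential sampling matches closed forms", {
  expect_equal(sample_exponential(1, exp(-1)), 1.0)
  expect_equal(sample_exponential(2, exp(-1)), 0.5)
  expect_error(sample_exponential(0, 0.5), "rate")
  expect_error(sample_exponential(1, 1), "inside")

  u <- withr::with_seed(1, runif(1e5))
  draws <- sample_exponential(4, u)
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - 0.25), 3 * se)
})

test_that("parameter validation rejects degenerate configurations", {
  expect_error(sim_params(lambda = 0), "lambda")
  expect_error(sim_params(lambda = 1, mu = -1), "mu")
  expect_error(sim_params(lambda = 1, K = 0), "K")
  expect_error(sim_params(lambda = 1, T = 100, t_transient = 100),
               "t_transient")
  # out-degree 0 rejected at simulate time, not at construction
  fx <- walkthrough_fixture()
  expect_error(simulate_traffic(fx$network, sim_params(1, T = 10)),
               "out-degree")
})

test_that("conservation and buffer bounds hold on every randomized run", {
  cases <- withr::with_seed(17, tibble::tibble(
    N = sample(3:10, 300, replace = TRUE),
    lambda = runif(300, 0.1, 5),
    mu = runif(300, 0.5, 2),
    K = sample(1:4, 300, replace = TRUE),
    T = runif(300, 20, 80),
    seed = sample.int(1e6, 300)))
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    net <- generate_background(cs$N, 0.5, seed = cs$seed)
    res <- simulate_traffic(
      net, sim_params(cs$lambda, cs$mu, cs$K, cs$T, t_transient = 0.1 * cs$T),
      seed = cs$seed)
    led <- res$ledger
    expect_identical(led$generated, led$delivered + led$ejected + led$residual)
    expect_true(all(res$nodes$max_queue <= cs$K))
    expect_true(all(res$nodes$busy_time <= 0.9 * cs$T + 1e-9))
    expect_true(all(res$nodes$contents_integral <= (cs$K + 1) * 0.9 * cs$T + 1e-9))
  }
})

test_that("identical (net, params, seed) give bit-identical results", {
  net <- generate_background(12, 0.3, seed = 2)
  p <- sim_params(lambda = 1, T = 200)
  a <- simulate_traffic(net, p, seed = 99, record_events = TRUE)
  b <- simulate_traffic(net, p, seed = 99, record_events = TRUE)
  expect_identical(a$nodes, b$nodes)
  expect_identical(a$edges, b$edges)
  expect_identical(a$ledger, b$ledger)
  expect_identical(a$events, b$events)
  c <- simulate_traffic(net, p, seed = 100)
  expect_false(identical(a$nodes, c$nodes))
})

test_that("the recorded contents trajectory obeys the server-plus-queue identity", {
  for (seed in c(5, 6)) {
    net <- generate_background(6, 0.5, seed = seed)
    res <- simulate_traffic(net, sim_params(lambda = 2, K = 2, T = 60),
                            seed = seed, record_events = TRUE)
    recon <- contents_from_events(res)
    expect_equal(nrow(recon), nrow(res$trajectory))
    expect_equal(recon$time, res$trajectory$time)
    expect_equal(recon$node, res$trajectory$node)
    expect_equal(recon$n, res$trajectory$n)
  }
})

test_that("two-node reciprocal traffic matches the birth-death closed form", {
  # each node is an M/M/1/(K+1) system with arrival rate lambda/2: arrivals
  # during a full buffer displace the oldest unit, leaving the count as is
  net <- directed_network(rbind(c(0, 1), c(1, 0)), c("a", "b"))
  lambda <- 1.2; K <- 4
  reps <- purrr::map_dfr(1:6, function(r) {
    res <- simulate_traffic(
      net, sim_params(lambda, mu = 1, K = K, T = 1e4, t_transient = 500),
      seed = 300 + r)
    m <- node_metrics(res)
    tibble::tibble(util = mean(m$utilization),
                   contents = mean(m$mean_contents))
  })
  theo <- birth_death_stationary(lambda / 2, 1, K + 1)
  se_u <- sd(reps$util) / sqrt(nrow(reps))
  se_c <- sd(reps$contents) / sqrt(nrow(reps))
  expect_lt(abs(mean(reps$util) - theo$utilization), 3 * se_u)
  expect_lt(abs(mean(reps$contents) - theo$mean_contents), 3 * se_c)
})

test_that("per-node metrics are exchangeable on an edge-transitive ring", {
  ring <- make_ring(4)
  utils <- purrr::map_dfr(1:24, function(r) {
    res <- simulate_traffic(ring, sim_params(0.5, T = 500), seed = 700 + r)
    node_metrics(res)
  }) |>
    dplyr::group_by(node) |>
    dplyr::summarise(util = mean(utilization), arr = mean(arrivals))
  # node means scatter around the grand mean within Monte-Carlo noise
  expect_lt(diff(range(utils$util)) / mean(utils$util), 0.2)
  expect_lt(diff(range(utils$arr)) / mean(utils$arr), 0.2)
})

test_that("per-node arrival-rate interpretation scales the global process", {
  net <- make_ring(5)
  res_total <- simulate_traffic(net, sim_params(2, T = 400), seed = 1)
  res_pernode <- simulate_traffic(
    net, sim_params(0.4, T = 400, per_node = TRUE), seed = 1)
  # identical seed and equal total rate: the two parameterizations coincide
  expect_identical(res_total$ledger, res_pernode$ledger)
})
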