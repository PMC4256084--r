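test_that("ensemble z-scores follow the defining arithmetic", {
  z <- zscore_vs_null(c(10, 10), c(0, 2))
  expect_equal(z$z, 9 / sd(c(0, 2)))
  expect_equal(z$z, 6.36396, tolerance = 1e-5)

  x <- withr::with_seed(8, rnorm(40))
  self <- zscore_vs_null(x, x)
  expect_equal(self$z, 0)
  expect_equal(self$p, 1)

  same <- zscore_vs_null(c(1, 1, 1), c(0.5, 1.5))
  expect_equal(same$z, 0)

  expect_error(zscore_vs_null(1, c(0, 2)), ">= 2")
  expect_error(zscore_vs_null(c(1, 2), c(3, 3)), "zero variance")
})

test_that("node ranking is a permutation with average ranks on ties", {
  tbl <- tibble::tibble(node = letters[1:5],
                        arrivals = c(10L, 30L, 20L, 30L, 5L))
  r <- rank_nodes(tbl, "arrivals")
  expect_setequal(r$rank, c(1.5, 1.5, 3, 4, 5))
  expect_equal(r$node[r$rank == 3], "c")
  expect_equal(sum(r$rank), sum(1:5))

  # all-equal values: everyone gets the average rank
  flat <- tibble::tibble(node = letters[1:4], arrivals = rep(7L, 4))
  expect_true(all(rank_nodes(flat, "arrivals")$rank == 2.5))

  # invariant to input row order, and matches an independent sort
  tbl2 <- withr::with_seed(2, tibble::tibble(
    node = paste0("n", 1:50), mean_contents = runif(50)))
  r1 <- rank_nodes(tbl2, "mean_contents")
  r2 <- rank_nodes(dplyr::slice_sample(tbl2, n = 50), "mean_contents")
  expect_equal(r1, r2)
  expect_equal(r1$node, tbl2$node[order(-tbl2$mean_contents)])

  expect_error(rank_nodes(tbl, "nope"))
  expect_error(rank_nodes(tbl[0, ], "arrivals"), "Empty")
})

test_that("top edges match a full-sort oracle and handle short tables", {
  m <- matrix(0L, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  m["a", "b"] <- 5L
  expect_warning(top <- top_k_edges(m, 10), "Only 1")
  expect_equal(nrow(top), 1L)

  traffic <- withr::with_seed(5, tibble::tibble(
    from = sample(letters[1:8], 40, replace = TRUE),
    to = sample(letters[1:8], 40, replace = TRUE),
    count = sample.int(500, 40))) |>
    dplyr::distinct(from, to, .keep_all = TRUE)
  top <- top_k_edges(traffic, 5)
  ref <- traffic[order(-traffic$count, traffic$from, traffic$to), ][1:5, ]
  expect_equal(top, ref, ignore_attr = TRUE)
  expect_error(top_k_edges(traffic, 0), ">= 1")
})

test_that("degree outlier scores vanish under an exact linear law", {
  deg <- tibble::tibble(node = paste0("n", 1:10), k_in = 1:10,
                        k_out = rep(2L, 10))
  tbl <- tibble::tibble(node = deg$node, arrivals = 2L * deg$k_in)
  sc <- degree_outlier_scores(tbl, deg, "arrivals")
  expect_true(all(abs(sc$residual) < 1e-8))
  expect_false(any(sc$outlier))

  # a planted excess is flagged
  tbl$arrivals[7] <- 200L
  sc2 <- degree_outlier_scores(tbl, deg, "arrivals")
  expect_equal(sc2$node[1], "n7")
  expect_true(sc2$outlier[1])

  expect_error(degree_outlier_scores(tbl[1:2, ], deg, "arrivals"), ">= 3")
  deg$k_in <- rep(3L, 10)
  expect_error(degree_outlier_scores(tbl, deg, "arrivals"), "variance")
})

test_that("phase map separates steady from jammed regimes", {
  ring <- make_ring(6)
  pm <- phase_map(ring, c(0.05, 8), mu = 1, K = 3, T = 400, seed = 5)
  expect_equal(pm$regime, c("steady", "jammed"))
  # the jammed system is loss-dominated and its buffers fill toward the
  # capacity bound N * (K + 1); the steady one is nearly empty
  expect_gt(pm$mean_contents[2], 0.5 * 6 * 4)
  expect_gt(pm$loss_frac[2], 0.5)
  expect_lt(pm$mean_contents[1], 2)
  expect_equal(pm$loss_frac[1], 0)
  # regimes are monotone along lambda
  pm2 <- phase_map(ring, c(0.05, 0.2, 4, 8), mu = 1, K = 3, T = 400, seed = 5)
  expect_equal(pm2$regime, sort(pm2$regime, decreasing = TRUE))
  expect_error(phase_map(ring, c(1, 0.5)), "ascending")
  g <- glance(pm)
  expect_equal(g$max_steady_lambda, 0.05)
  expect_equal(g$min_jammed_lambda, 8)
})

test_that("null-ensemble reports carry coherent z-tables and tidiers", {
  net <- funnel_network(N = 40, p = 0.1, afferents_per_relay = c(10, 12),
                        relay_out_degree = c(1, 2), seed = 3)
  p <- sim_params(lambda = 0.05, T = 600)
  rep <- null_ensemble_report(net, p, "target", kind = "rewired",
                              R = 4, S = 4, seed = 13)
  td <- tidy(rep)
  expect_equal(td$metric, c("arrivals", "mean_contents", "utilization"))
  expect_true(all(is.finite(td$z)))
  # z recomputed from the raw draws
  emp <- rep$empirical$value[rep$empirical$metric == "arrivals"]
  nul <- rep$null$value[rep$null$metric == "arrivals"]
  expect_equal(td$z[1], (mean(emp) - mean(nul)) / sd(nul))
  g <- glance(rep)
  expect_equal(g$R, 4L)
  expect_equal(g$focal, "target")
  expect_error(null_ensemble_report(net, p, "absent"), "Unknown focal")
})
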