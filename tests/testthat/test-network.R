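test_that("constructor validates shape, binarity, labels and self-loops", {
  adj <- rbind(c(0, 1), c(1, 0))
  net <- directed_network(adj, labels = c("a", "b"))
  expect_s3_class(net, "directed_network")
  expect_equal(n_edges(net), 2L)

  expect_error(directed_network(matrix(0, 2, 3)), "square")
  expect_error(directed_network(rbind(c(0, 2), c(1, 0))), "binary")
  expect_error(directed_network(adj, labels = c("a", "a")), "unique")
  expect_error(directed_network(adj, labels = "a"), "labels")

  loopy <- rbind(c(1, 1), c(0, 0))
  expect_error(directed_network(loopy, c("a", "b")), "Self-loops")
  expect_warning(net2 <- directed_network(loopy, c("a", "b"),
                                          drop_self_loops = TRUE),
                 "Dropped 1 self-loop")
  expect_equal(n_edges(net2), 1L)
})

test_that("degree sums always equal the edge count", {
  for (seed in 1:5) {
    net <- make_random_net(15, 0.25, seed)
    deg <- node_degrees(net)
    expect_identical(sum(deg$k_in), sum(deg$k_out))
    expect_identical(sum(deg$k_in), n_edges(net))
  }
  fx <- walkthrough_fixture()
  deg <- node_degrees(fx$network)
  expect_equal(deg[deg$node == "2", c("k_in", "k_out")],
               tibble::tibble(k_in = 1L, k_out = 1L))
})

test_that("unidirectional edges match an exhaustive pairwise scan", {
  # fully reciprocal network: none
  rec <- directed_network(matrix(1, 4, 4) - diag(4), letters[1:4])
  expect_equal(nrow(unidirectional_edges(rec)), 0L)
  expect_equal(nrow(reciprocal_pairs(rec)), 6L)

  fx <- walkthrough_fixture()
  expect_equal(unidirectional_edges(fx$network),
               tibble::tibble(from = c("1", "2"), to = c("2", "3")))

  net <- make_random_net(20, 0.2, seed = 42)
  got <- unidirectional_edges(net)
  a <- net$adjacency
  expected <- list()
  for (i in 1:20) for (j in 1:20) {
    if (a[i, j] == 1 && a[j, i] == 0) {
      expected[[length(expected) + 1]] <-
        tibble::tibble(from = net$labels[i], to = net$labels[j])
    }
  }
  expect_equal(got, dplyr::bind_rows(expected))
  # unidirectional edges + both directions of reciprocal pairs = all edges
  expect_identical(nrow(got) + 2L * nrow(reciprocal_pairs(net)), n_edges(net))
})

test_that("in-neighbour profiles equal hand enumeration", {
  # star: centre receives from k spokes, each spoke's only efferent is centre
  k <- 6
  adj <- matrix(0L, k + 1, k + 1)
  adj[2:(k + 1), 1] <- 1L
  star <- directed_network(adj, labels = c("centre", paste0("s", 1:k)))
  prof <- in_neighbour_profile(star, "centre")
  expect_equal(prof$n_in_neighbours, k)
  expect_equal(prof$nbr_mean_k_out, 1)
  expect_equal(prof$nbr_mean_k_in, 0)

  net <- make_random_net(15, 0.2, seed = 7)
  prof <- in_neighbour_profile(net)
  a <- net$adjacency
  for (j in seq_len(15)) {
    nbrs <- which(a[, j] == 1)
    row <- prof[prof$node == net$labels[j], ]
    if (length(nbrs) == 0) {
      expect_true(is.na(row$nbr_mean_k_in))
    } else {
      expect_equal(row$nbr_mean_k_in, mean(colSums(a)[nbrs]))
      expect_equal(row$nbr_mean_k_out, mean(rowSums(a)[nbrs]))
      expect_setequal(row$in_neighbours[[1]], net$labels[nbrs])
    }
  }
  expect_error(in_neighbour_profile(net, "nope"), "Unknown node")
})

test_that("assortativity profile covers all nodes and matches brute force", {
  ring <- make_ring(6)
  prof <- assortativity_profile(ring)
  expect_equal(prof$nbr_mean_k_in, rep(1, 6))
  expect_equal(prof$nbr_mean_k_out, rep(1, 6))

  net <- make_random_net(12, 0.3, seed = 3)
  prof <- assortativity_profile(net)
  expect_equal(nrow(prof), 12L)
  expect_equal(prof$node, net$labels)   # node order preserved
  ref <- in_neighbour_profile(net)
  expect_equal(prof$nbr_mean_k_out, ref$nbr_mean_k_out)
})

test_that("edge list and graphml IO round-trip exactly", {
  net <- make_random_net(12, 0.25, seed = 11)
  td <- withr::local_tempdir()

  csv <- file.path(td, "net.csv")
  lab <- file.path(td, "net.labels")
  write_network(net, csv, format = "edgelist", labels = lab)
  back <- read_network(csv, format = "edgelist", labels = lab)
  expect_identical(back$adjacency, net$adjacency)
  expect_identical(back$labels, net$labels)

  gml <- file.path(td, "net.graphml")
  write_network(net, gml, format = "graphml")
  back2 <- read_network(gml, format = "graphml")
  expect_identical(back2$adjacency, net$adjacency)

  # empty edge list with declared labels -> edgeless network
  readr::write_csv(tibble::tibble(source = character(), target = character()),
                   csv)
  readr::write_lines(c("x", "y", "z"), lab)
  empty <- read_network(csv, format = "edgelist", labels = lab)
  expect_equal(n_nodes(empty), 3L)
  expect_equal(n_edges(empty), 0L)

  expect_error(read_network(file.path(td, "absent.csv")), "not found")
})

test_that("MAT containers written by scipy load with labels in file order", {
  td <- withr::local_tempdir()
  matfile <- file.path(td, "net.mat")
  script <- file.path(td, "make.py")
  writeLines(c(
    "import numpy as np, scipy.io, sys",
    "A = np.zeros((3, 3)); A[0, 1] = 1; A[1, 2] = 1; A[2, 0] = 1; A[0, 2] = 1",
    "labels = np.array([['alpha'], ['beta'], ['gamma']], dtype=object)",
    "scipy.io.savemat(sys.argv[1],",
    "    {'CoCoMac_adjacency': A, 'Labels': labels})"
  ), script)
  status <- system2("python", c(script, matfile), stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(matfile))
  net <- read_network(matfile, format = "mat")
  expect_equal(net$labels, c("alpha", "beta", "gamma"))
  expect_equal(n_edges(net), 4L)
  expect_equal(unname(net$adjacency["alpha", "beta"]), 1L)
  expect_equal(unname(net$adjacency["gamma", "alpha"]), 1L)
})

test_that("strong connectivity is diagnosed, not enforced", {
  expect_true(is_strongly_connected(make_ring(5)))
  expect_false(is_strongly_connected(walkthrough_fixture()$network))
  # loading the chain works fine despite weak connectivity
  expect_s3_class(walkthrough_fixture()$network, "directed_network")
})
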