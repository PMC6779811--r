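test_that("regular digraph generation gives the exact degree sequence", {
  net <- generate_network(topology = "random_regular_directed", n_nodes = 20,
                          mean_degree = 2, seed = 1)
  expect_equal(sum(net$weights), 40) # N x out-degree directed edges
  expect_equal(unname(rowSums(net$weights)), rep(2, 20))
  expect_equal(unname(colSums(net$weights)), rep(2, 20))
  expect_true(net$directed)
  expect_error(
    generate_network(topology = "random_regular_directed", n_nodes = 5,
                     mean_degree = 2.5, seed = 1),
    "integer")
})

test_that("generation is deterministic under a fixed seed and varies across seeds", {
  for (topo in c("scale_free_static", "scale_free_ba",
                 "random_regular_directed", "random_undirected")) {
    a <- generate_network(topology = topo, n_nodes = 15, mean_degree = 2,
                          seed = 42)
    b <- generate_network(topology = topo, n_nodes = 15, mean_degree = 2,
                          seed = 42)
    c <- generate_network(topology = topo, n_nodes = 15, mean_degree = 2,
                          seed = 43)
    expect_identical(a$weights, b$weights)
    expect_false(identical(a$weights, c$weights))
  }
})

test_that("generator output satisfies network invariants over fuzzed configs", {
  topos <- c("scale_free_static", "scale_free_ba",
             "random_regular_directed", "random_undirected")
  set.seed(99)
  for (i in 1:100) {
    topo <- sample(topos, 1)
    n <- sample(5:25, 1)
    deg <- if (topo == "random_regular_directed") sample(1:3, 1)
    else runif(1, 1, 4)
    net <- generate_network(topology = topo, n_nodes = n, mean_degree = deg,
                            gamma = runif(1, 2.2, 4), seed = i)
    expect_silent(validate_network(net))
    expect_true(all(net$weights %in% c(0, 1))) # artificial nets are binary
  }
})

test_that("static-model degree distribution has the requested power-law tail", {
  # Hill (continuous MLE) tail-exponent estimate on a pooled ensemble
  degs <- unlist(lapply(1:3, function(s) {
    net <- generate_network(topology = "scale_free_static", n_nodes = 2000,
                            mean_degree = 4, gamma = 3, seed = s)
    colSums(net$weights) + rowSums(net$weights)
  }))
  xmin <- quantile(degs, 0.9) # estimate on the top-decile tail
  tail_deg <- degs[degs >= xmin]
  alpha_hat <- 1 + length(tail_deg) / sum(log(tail_deg / (xmin - 0.5)))
  expect_gt(alpha_hat, 2.4)
  expect_lt(alpha_hat, 3.6)
})

test_that("unsupported topologies and infeasible configurations are rejected", {
  expect_error(generate_network(topology = "small_world", n_nodes = 10,
                                mean_degree = 2), "unsupported topology")
  expect_error(generator_config("scale_free_static", 2, 1), "n_nodes")
  expect_error(generator_config("scale_free_static", 10, 12), "mean_degree")
  expect_error(generator_config("scale_free_static", 10, 2, gamma = 1.5),
               "gamma")
})

test_that("node removal zeroes rows and columns and composes as set union", {
  net <- chain_network(3)
  cut <- remove_nodes(net, 2)
  expect_equal(sum(cut$weights), 0) # 1->2->3 loses both edges
  expect_equal(remove_nodes(net, integer(0))$weights, net$weights)
  expect_equal(sum(remove_nodes(net, 1:3)$weights), 0)
  expect_error(remove_nodes(net, 4), "out of range")
  expect_error(remove_nodes(net, c(1, 1)), "distinct")
  for (i in 1:20) {
    net_i <- random_test_network(8, directed = TRUE, seed = i, weighted = TRUE)
    a <- sample(8, sample(0:3, 1))
    b <- sample(setdiff(1:8, a), sample(0:3, 1))
    expect_identical(remove_nodes(remove_nodes(net_i, a), b)$weights,
                     remove_nodes(net_i, union(a, b))$weights)
  }
})

test_that("betweenness, clustering and eigenvector match exhaustive oracles", {
  m <- node_metrics(path_network_undirected(3))
  expect_equal(m$betweenness, c(0, 1, 0))
  expect_equal(node_metrics(triangle_network())$clustering, rep(1, 3))
  st <- node_metrics(star_network(6))
  expect_equal(which.max(st$eigenvector), 1)
  expect_equal(st$eigenvector[1], 1)
  expect_true(all(st$eigenvector[2:6] < 1))

  for (i in 1:12) {
    directed <- i %% 2 == 0
    net <- random_test_network(sample(4:6, 1), directed = directed,
                               seed = 100 + i, weighted = i > 6)
    m <- suppressWarnings(node_metrics(net)) # sparse draws may be edgeless
    expect_true(all(is.finite(m$betweenness)))
    expect_true(all(m$clustering >= 0 & m$clustering <= 1))
    expect_equal(m$betweenness, oracle_betweenness(net), tolerance = 1e-8)
  }
})

test_that("eigenvector centrality is absent on directed and flagged on edgeless nets", {
  expect_false("eigenvector" %in% names(node_metrics(chain_network(4))))
  empty <- icto_network(matrix(0, 4, 4), directed = FALSE)
  expect_warning(m <- node_metrics(empty), "edgeless")
  expect_true(all(is.na(m$eigenvector)))
  expect_equal(m$degree_total, rep(0, 4))
})

test_that("set-average metric equals the brute-force mean", {
  net <- random_test_network(10, directed = FALSE, seed = 3)
  m <- node_metrics(net)
  expect_equal(set_average_metric(m, 4, "degree_total"), m$degree_total[4])
  m2 <- m
  m2$degree_total[1:2] <- c(2, 4)
  expect_equal(set_average_metric(m2, 1:2, "degree_total"), 3)
  for (i in 1:10) {
    x <- sample(10, sample(1:6, 1))
    acc <- 0
    for (j in x) acc <- acc + m$betweenness[j]
    expect_equal(set_average_metric(m, x, "betweenness"), acc / length(x))
  }
  expect_error(set_average_metric(node_metrics(chain_network(3)), 1,
                                  "eigenvector"), "not available")
})

test_that("network files round-trip exactly in both formats", {
  for (i in 1:4) {
    net <- random_test_network(7, directed = i %% 2 == 0, seed = i,
                               weighted = TRUE)
    for (fmt in c("csv-matrix", "edge-list")) {
      path <- withr::local_tempfile(fileext = ".csv")
      write_network(net, path, format = fmt)
      back <- read_network(path, format = fmt)
      expect_equal(back$weights, net$weights)
      expect_equal(back$directed, net$directed)
    }
  }
})

test_that("malformed network files are rejected with informative errors", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# nodes: 3", "source,target,weight", "0,1,-2"), p)
  expect_error(read_network(p, format = "edge-list"), "negative weight")
  writeLines(c("# nodes: 3", "source,target,weight", "0,1"), p)
  expect_error(read_network(p, format = "edge-list"), "line 1")
  writeLines(c("a,b,c", "1,0,1", "0,1,0"), p)
  expect_error(read_network(p, format = "csv-matrix"), "not square")
  writeLines(c("# nodes: 3", "source,target,weight"), p)
  empty <- read_network(p, format = "edge-list")
  expect_equal(n_nodes(empty), 3)
  expect_equal(sum(empty$weights), 0)
})

test_that("network ensembles are reproducible and pairwise distinct", {
  cfg <- generator_config("random_regular_directed", 20, 2, seed = 5)
  ens <- make_network_ensemble(cfg, 10)
  expect_length(ens, 10)
  for (net in ens) expect_equal(sum(net$weights), 40)
  keys <- vapply(ens, function(n) paste(n$weights, collapse = ""), character(1))
  expect_equal(anyDuplicated(keys), 0L)
  ens2 <- make_network_ensemble(cfg, 10)
  expect_identical(ens, ens2)
})
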