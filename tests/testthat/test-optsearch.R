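test_that("subset counting is exact and the budget refusal reports it", {
  expect_equal(count_subsets(3, 3), 7)
  expect_equal(count_subsets(20, 10), 616665)
  expect_equal(count_subsets(40, 40), 2^40 - 1)
  ev <- mock_evaluator(40, function(x) 0.5)
  err <- tryCatch(ground_truth_search(ev, max_size = 40, budget = 1e6),
                  error = function(e) e)
  expect_s3_class(err, "ictonet_budget_error")
  expect_equal(err$n_sets, 1099511627775)
  expect_match(conditionMessage(err), "1,099,511,627,775")
})

test_that("exhaustive search finds the per-size maxima of a known set function", {
  # synthetic SI: value of a set = normalized weight sum, known optimum
  v <- c(5, 1, 4, 2, 3, 1) / 16
  ev <- mock_evaluator(6, function(x) min(1, sum(v[x])))
  gt <- ground_truth_search(ev, max_size = 6, keep_all = TRUE)
  expect_equal(gt$per_size$si[1], 5 / 16)
  expect_equal(gt$per_size$set[[1]], 1L)
  expect_equal(gt$per_size$set[[2]], c(1L, 3L))
  expect_equal(nrow(gt$all), count_subsets(6, 6))
  # per-size maximum dominates every strategy at that size
  rs <- random_search(ev, budget = 30, max_size = 6, seed = 1)
  for (i in seq_len(nrow(rs$per_size))) {
    k <- rs$per_size$size[i]
    expect_lte(rs$per_size$si[i], gt$per_size$si[gt$per_size$size == k])
  }
})

test_that("simple ordering visits nodes by decreasing NI with index tie-break", {
  ni <- c(0.1, 0.9, 0.4)
  ev <- mock_evaluator(3, function(x) min(1, sum(ni[x])))
  res <- simple_ordering(ev, stop_si = 2) # never stop early
  expect_equal(res$order, c(2L, 3L, 1L))
  expect_equal(res$per_size$set[[1]], 2L)
  ni2 <- c(0.5, 0.5, 0.2)
  ev2 <- mock_evaluator(3, function(x) min(1, sum(ni2[x])))
  expect_equal(simple_ordering(ev2, stop_si = 2)$order[1], 1L) # tie -> lower index
})

test_that("orderings stop once SI exceeds the threshold", {
  ni <- c(0.6, 0.5, 0.1, 0.1)
  ev <- mock_evaluator(4, function(x) min(1, sum(ni[x])))
  res <- simple_ordering(ev, stop_si = 0.99)
  expect_equal(nrow(res$per_size), 2) # 0.6 then 1.1 -> capped at 1 > 0.99
  expect_equal(res$per_size$si[2], 1)
})

test_that("recurrent ordering diverges from simple ordering on a two-hub structure", {
  # hubs 1 and 2 drive overlapping halves: once hub 1 is removed, hub 2's
  # marginal contribution collapses below node 3's
  si_fun <- function(x) {
    has <- function(j) j %in% x
    s <- 0
    if (has(1)) s <- s + 0.5
    if (has(2)) s <- s + (if (has(1)) 0.05 else 0.45)
    if (has(3)) s <- s + 0.2
    if (has(4)) s <- s + 0.1
    min(1, s)
  }
  ev_s <- mock_evaluator(4, si_fun)
  ev_r <- mock_evaluator(4, si_fun)
  simple <- simple_ordering(ev_s, stop_si = 2)
  recur <- recurrent_ordering(ev_r, stop_si = 2)
  expect_equal(simple$order[1], recur$order[1]) # same initial NI ranking
  expect_equal(simple$order[2], 2L)
  expect_equal(recur$order[2], 3L) # re-scored after removing hub 1
  expect_gte(recur$per_size$si[2], simple$per_size$si[2])
})

test_that("recurrent ordering is at least as good as simple ordering on simulated networks", {
  diffs <- vapply(1:10, function(s) {
    net <- generate_network(topology = "scale_free_static", n_nodes = 10,
                            mean_degree = 2, seed = 200 + s)
    p <- fast_params(k = 100, n_steps = 5000, n_realizations = 1)
    ev <- make_si_evaluator(net, p)
    si_s <- simple_ordering(ev, stop_si = 2)$per_size$si
    si_r <- recurrent_ordering(ev, stop_si = 2)$per_size$si
    n <- min(length(si_s), length(si_r))
    mean(si_r[1:n] - si_s[1:n])
  }, numeric(1))
  expect_gte(median(diffs), 0)
})

test_that("random-search allocation is log-proportional, exact and reproducible", {
  alloc <- allocate_random_search(40, 20, 30000)
  expect_equal(sum(alloc), 30000)
  expect_identical(alloc, allocate_random_search(40, 20, 30000))
  # log-proportionality: compare two mid sizes with no full enumeration
  expect_equal(alloc[10] / alloc[5], log(choose(40, 10)) / log(choose(40, 5)),
               tolerance = 0.01)
  # small sizes fully enumerated when cheap: C(40,1) = 40 < its share
  expect_equal(alloc[1], 40)
  expect_error(allocate_random_search(10, 5, 3), "budget")

  ev <- mock_evaluator(12, function(x) min(1, sum(x) / 40))
  r1 <- random_search(ev, budget = 120, max_size = 4, seed = 9)
  ev2 <- mock_evaluator(12, function(x) min(1, sum(x) / 40))
  r2 <- random_search(ev2, budget = 120, max_size = 4, seed = 9)
  expect_identical(r1$per_size, r2$per_size)
  expect_equal(sum(r1$allocation), 120)
})

test_that("non-dominated sorting matches the brute-force oracle", {
  pts <- rbind(c(1, 0.5), c(2, 0.1), c(2, 0.6), c(3, 0.05))
  fr <- fast_nondominated_sort(pts)
  expect_equal(fr[[1]], c(1L, 2L, 4L))
  expect_equal(fr[[2]], 3L)
  expect_equal(fast_nondominated_sort(matrix(1, 4, 2))[[1]], 1:4)
  expect_equal(fast_nondominated_sort(rbind(c(1, 2)))[[1]], 1L)
  expect_equal(fast_nondominated_sort(matrix(numeric(0), 0, 2)), list())
  set.seed(21)
  for (i in 1:100) {
    m <- matrix(sample(1:8, 2 * sample(2:30, 1), replace = TRUE), ncol = 2)
    expect_identical(lapply(fast_nondominated_sort(m), sort),
                     lapply(oracle_nondominated_sort(m), sort))
  }
})

test_that("NSGA-II recovers exhaustive optima on an enumerable landscape", {
  v <- c(8, 6, 5, 3, 2, 2, 1, 1) / 28
  ev <- mock_evaluator(8, function(x) min(1, sum(v[x])))
  gt <- ground_truth_search(ev, max_size = 4)
  ga <- nsga2_search(ev, ga_config(population_size = 24, generations = 30,
                                   n_runs = 3, seed = 5))
  d <- delta_si(gt, ga)
  expect_true(all(d$delta_si <= 1e-12))
  # elitist archive: best SI per size never decreases within a run
  for (r in ga$runs) {
    for (k in seq_len(ncol(r$best_series))) {
      col <- r$best_series[, k]
      col <- col[!is.na(col)]
      if (length(col) > 1) expect_true(all(diff(col) >= 0))
    }
  }
})

test_that("NSGA-II honors forbidden nodes and the size cap", {
  v <- c(10, 6, 5, 3, 2, 2, 1, 1) / 28
  ev <- mock_evaluator(8, function(x) min(1, sum(v[x])))
  ga <- nsga2_search(ev, ga_config(population_size = 24, generations = 25,
                                   n_runs = 2, forbidden_nodes = 1L,
                                   seed = 3))
  for (i in seq_len(nrow(ga$front))) {
    expect_lte(ga$front$size[i], 4) # floor(8/2)
    for (s in ga$front$sets[[i]]) expect_false(1L %in% s)
  }
  expect_error(nsga2_search(ev, ga_config(population_size = 24,
                                          forbidden_nodes = 1:8)),
               "forbidden")
})

test_that("convergence report measures across-run spread and hypervolume", {
  v <- c(8, 6, 5, 3, 2, 2, 1, 1) / 28
  ev <- mock_evaluator(8, function(x) min(1, sum(v[x])))
  ga <- nsga2_search(ev, ga_config(population_size = 24, generations = 30,
                                   n_runs = 4, seed = 8))
  expect_true(all(ga$convergence$hypervolume >= 0))
  expect_lte(ga$convergence$max_spread, 0.05)
  expect_true(ga$convergence$converged)
  # hypervolume oracle on a tiny front
  hv <- ictonet:::hypervolume2d(rbind(c(1, 0.5), c(2, 0.2)), ref = c(3, 1.1))
  expect_equal(hv, (3 - 1) * (1.1 - 0.5) + (3 - 2) * (0.5 - 0.2))
})

test_that("delta-SI bookkeeping handles identity, sign and mismatched sizes", {
  a <- ictonet:::new_strategy_result("a", {
    d <- data.frame(size = 1:3, si = c(1, 0.8, 0.9))
    d$set <- list(1L, 1:2, 1:3)
    d
  }, 3, list())
  expect_true(all(delta_si(a, a)$delta_si == 0))
  b <- ictonet:::new_strategy_result("b", {
    d <- data.frame(size = 1:2, si = c(0.8, 0.8))
    d$set <- list(2L, 2:3)
    d
  }, 2, list())
  expect_warning(d <- delta_si(a, b), "skipped")
  expect_equal(d$delta_si, c(0.2, 0))
})

test_that("optimal-set extraction returns all minimal co-optimal sets", {
  ps <- data.frame(size = 1:3, si = c(0.7, 0.995, 1))
  ps$set <- list(1L, c(1L, 2L), 1:3)
  res <- ictonet:::new_strategy_result("x", ps, 3, list())
  opt <- optimal_set_extraction(res)
  expect_true(opt$found)
  expect_equal(opt$size, 2)
  expect_equal(opt$sets[[1]], c(1L, 2L))
  none <- ictonet:::new_strategy_result("x", {
    d <- data.frame(size = 1L, si = 0.4)
    d$set <- list(1L)
    d
  }, 1, list())
  miss <- optimal_set_extraction(none)
  expect_false(miss$found)
  expect_equal(miss$max_si, 0.4)
})
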