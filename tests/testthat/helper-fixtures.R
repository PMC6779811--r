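# shared fixtures and independent oracles, built in code at test time

chain_network <- function(n = 3) {
  w <- matrix(0, n, n)
  for (i in seq_len(n - 1)) w[i, i + 1] <- 1
  icto_network(w, directed = TRUE)
}

path_network_undirected <- function(n = 3) {
  w <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    w[i, i + 1] <- 1
    w[i + 1, i] <- 1
  }
  icto_network(w, directed = FALSE)
}

star_network <- function(n = 8, directed = FALSE) {
  w <- matrix(0, n, n)
  w[1, 2:n] <- 1
  if (!directed) w[2:n, 1] <- 1
  icto_network(w, directed = directed)
}

triangle_network <- function() {
  w <- matrix(1, 3, 3) - diag(3)
  icto_network(w, directed = FALSE)
}

# disjoint strongly coupled dyads: the planted-dependence fixture for
# network-inference validation (no indirect paths, so every dependence is a
# true edge)
dyads_network <- function(n_dyads = 4) {
  n <- 2 * n_dyads
  w <- matrix(0, n, n)
  for (i in seq(1, n, by = 2)) {
    w[i, i + 1] <- 1
    w[i + 1, i] <- 1
  }
  icto_network(w, directed = FALSE)
}

fast_params <- function(k = 0, n_steps = 2e4, seed = 1, n_realizations = 1,
                        ...) {
  theta_params(k = k, n_steps = n_steps, seed = seed,
               n_realizations = n_realizations, ...)
}

# ---- independent oracles -------------------------------------------------

# brute-force Pareto-front peeling by pairwise dominance (O(n^2) per front)
oracle_nondominated_sort <- function(points) {
  points <- as.matrix(points)
  idx <- seq_len(nrow(points))
  dominates_o <- function(a, b) all(a <= b) && any(a < b)
  fronts <- list()
  while (length(idx)) {
    nd <- idx[vapply(idx, function(p) {
      !any(vapply(idx, function(q)
        q != p && dominates_o(points[q, ], points[p, ]), logical(1)))
    }, logical(1))]
    fronts[[length(fronts) + 1L]] <- nd
    idx <- setdiff(idx, nd)
  }
  fronts
}

# exhaustive betweenness on a small weighted graph: enumerate all simple
# paths per ordered pair, keep shortest under distance 1/weight, split ties
oracle_betweenness <- function(net) {
  w <- net$weights
  n <- nrow(w)
  dist <- ifelse(w > 0, 1 / w, Inf)
  all_paths <- function(from, to) {
    out <- list()
    grow <- function(path) {
      last <- path[length(path)]
      if (last == to) {
        out[[length(out) + 1L]] <<- path
        return()
      }
      for (nxt in which(dist[last, ] < Inf)) {
        if (!(nxt %in% path)) grow(c(path, nxt))
      }
    }
    grow(from)
    out
  }
  btw <- numeric(n)
  for (s in seq_len(n)) {
    for (t in seq_len(n)) {
      if (s == t) next
      if (!net$directed && s > t) next
      paths <- all_paths(s, t)
      if (!length(paths)) next
      lens <- vapply(paths, function(p)
        sum(dist[cbind(p[-length(p)], p[-1])]), numeric(1))
      shortest <- paths[abs(lens - min(lens)) < 1e-12]
      for (p in shortest) {
        inner <- setdiff(p, c(s, t))
        btw[inner] <- btw[inner] + 1 / length(shortest)
      }
    }
  }
  btw
}

# exact rank-sum tail probability by enumerating all group assignments
oracle_rank_sum_p <- function(x, y, alternative = "greater") {
  n1 <- length(x)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n1)])
  combs <- combn(length(r), n1)
  w_all <- apply(combs, 2, function(ix) sum(r[ix]))
  if (alternative == "greater") mean(w_all >= w_obs) else mean(w_all <= w_obs)
}

random_test_network <- function(n, directed = TRUE, p = 0.3, seed = 1,
                                weighted = FALSE) {
  with_seed_local(seed, {
    w <- matrix((runif(n * n) < p) + 0, n, n)
    if (weighted) w <- w * matrix(runif(n * n, 0.2, 1.5), n, n)
    diag(w) <- 0
    if (!directed) w[lower.tri(w)] <- t(w)[lower.tri(w)]
    icto_network(w, directed = directed)
  })
}

with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# mock SI evaluator driven by an arbitrary set-function, for search-logic
# tests that need no simulation
mock_evaluator <- function(n, si_fun, k = 1) {
  ev <- new.env(parent = emptyenv())
  ev$net <- icto_network(matrix(0, n, n) + 1 - diag(n), directed = FALSE)
  ev$params <- theta_params(k = k, n_steps = 10L, seed = 1L)
  calls <- 0L
  cache <- new.env(parent = emptyenv())
  ev$si <- function(x) {
    x <- sort(as.integer(x))
    key <- paste0("s", paste(x, collapse = ","))
    if (is.null(cache[[key]])) {
      cache[[key]] <- si_fun(x)
      calls <<- calls + 1L
    }
    structure(list(x = x, si = cache[[key]], raw_si = cache[[key]],
                   bni_ref = 0.5, bni_perturbed = 0.5 * (1 - cache[[key]]),
                   k_used = k), class = "si_result")
  }
  ev$bni <- function(x) 0.5 * (1 - ev$si(x)$si)
  ev$bni_ref <- function() 0.5
  ev$n_evaluations <- function() calls
  ev$cache_size <- function() length(ls(cache))
  class(ev) <- "si_evaluator"
  ev
}
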