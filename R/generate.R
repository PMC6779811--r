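#' Generator configuration for artificial network topologies
#'
#' Bundles the parameters of [generate_network()]. Artificial networks are
#' binary (0/1 weights). Four topologies are available:
#'
#' * `scale_free_static`: the static model. Node `i` receives a weight
#'   proportional to `i^(-1/(gamma - 1))`; edge endpoints are drawn
#'   independently from this distribution (source and target draws for a
#'   directed network) and accepted until `round(n * mean_degree)` directed
#'   edges (or half that many undirected edges) exist, rejecting self-loops
#'   and duplicates. This yields a degree distribution with power-law tail
#'   exponent `gamma` at a fixed mean degree. Default for directed
#'   scale-free networks.
#' * `scale_free_ba`: Barabasi-Albert preferential attachment with
#'   `m = mean_degree / 2` edges per arriving node (tail exponent 3).
#' * `random_regular_directed`: a uniformly random simple digraph in which
#'   every node has in-degree and out-degree exactly `mean_degree`.
#' * `random_undirected`: an Erdos-Renyi G(n, m) graph with
#'   `m = round(n * mean_degree / 2)` edges.
#'
#' @param topology one of `"scale_free_static"`, `"scale_free_ba"`,
#'   `"random_regular_directed"`, `"random_undirected"`.
#' @param n_nodes number of nodes (at least 3).
#' @param mean_degree target mean degree; for directed topologies this is the
#'   mean (or, for the regular digraph, exact) in- and out-degree.
#' @param gamma power-law tail exponent for scale-free topologies (> 2).
#' @param directed logical; only some topologies support both modes.
#' @param seed integer seed; identical configurations with identical seeds
#'   produce byte-identical networks.
#' @return a list of class `generator_config`.
#' @export
generator_config <- function(topology, n_nodes, mean_degree, gamma = 3,
                             directed = NULL, seed = 1L) {
  topologies <- c("scale_free_static", "scale_free_ba",
                  "random_regular_directed", "random_undirected")
  if (!is.character(topology) || !(topology %in% topologies))
    stop("unsupported topology '", topology, "'; must be one of: ",
         paste(topologies, collapse = ", "))
  if (n_nodes < 3) stop("n_nodes must be >= 3")
  if (mean_degree <= 0 || mean_degree >= n_nodes)
    stop("mean_degree must be positive and smaller than n_nodes")
  if (startsWith(topology, "scale_free") && gamma <= 2)
    stop("gamma must be > 2 for scale-free topologies")
  if (is.null(directed))
    directed <- topology %in% c("scale_free_static", "random_regular_directed")
  if (topology == "random_regular_directed" && !directed)
    stop("random_regular_directed is a directed topology")
  if (topology == "random_undirected" && directed)
    stop("random_undirected is an undirected topology")
  structure(list(topology = topology, n_nodes = as.integer(n_nodes),
                 mean_degree = mean_degree, gamma = gamma,
                 directed = isTRUE(directed), seed = as.integer(seed)),
            class = "generator_config")
}

#' Generate an artificial network
#'
#' @param config a [generator_config()]; alternatively pass the same
#'   arguments directly via `...`.
#' @param ... arguments forwarded to [generator_config()] when `config` is
#'   not supplied.
#' @return an `icto_network` with binary weights.
#' @export
#' @examples
#' net <- generate_network(topology = "random_regular_directed",
#'                         n_nodes = 20, mean_degree = 2, seed = 1)
#' sum(net$weights) # exactly 40 directed edges
generate_network <- function(config = NULL, ...) {
  if (is.null(config)) config <- generator_config(...)
  stopifnot(inherits(config, "generator_config"))
  with_seed(config$seed, generate_network_impl(config))
}

generate_network_impl <- function(cfg) {
  n <- cfg$n_nodes
  w <- switch(cfg$topology,
    scale_free_static = static_model_matrix(n, cfg$mean_degree, cfg$gamma,
                                            cfg$directed),
    scale_free_ba = {
      m <- max(1L, round(cfg$mean_degree / 2))
      g <- igraph::sample_pa(n, power = 1, m = m, directed = cfg$directed)
      adj_matrix_binary(g)
    },
    random_regular_directed = {
      k <- cfg$mean_degree
      if (k != round(k))
        stop("regular digraph requires an integer in/out degree, got ", k)
      k <- as.integer(k)
      if (k >= n)
        stop(sprintf("in/out degree %d is not realizable on %d nodes", k, n))
      g <- regular_digraph(n, k)
      adj_matrix_binary(g)
    },
    random_undirected = {
      m <- round(n * cfg$mean_degree / 2)
      g <- igraph::sample_gnm(n, m, directed = FALSE)
      adj_matrix_binary(g)
    }
  )
  icto_network(w, directed = cfg$directed)
}

adj_matrix_binary <- function(g) {
  w <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
  mode(w) <- "double"
  w[w > 0] <- 1
  diag(w) <- 0
  w
}

# Uniform simple k-in/k-out-regular digraph; igraph's heuristic pairing can
# occasionally fail on tight instances, so retry with fresh draws.
regular_digraph <- function(n, k, max_tries = 100L) {
  for (i in seq_len(max_tries)) {
    g <- try(igraph::sample_degseq(rep(k, n), rep(k, n),
                                   method = "fast.heur.simple"), silent = TRUE)
    if (!inherits(g, "try-error") && igraph::is_simple(g)) return(g)
  }
  stop(sprintf("could not realize a simple %d-regular digraph on %d nodes", k, n))
}

# Static-model scale-free generator: endpoint i drawn with probability
# proportional to i^(-alpha), alpha = 1/(gamma - 1).
static_model_matrix <- function(n, mean_degree, gamma, directed) {
  alpha <- 1 / (gamma - 1)
  p <- (seq_len(n))^(-alpha)
  p <- p / sum(p)
  m_target <- if (directed) round(n * mean_degree) else round(n * mean_degree / 2)
  max_edges <- if (directed) n * (n - 1) else n * (n - 1) / 2
  if (m_target > max_edges)
    stop("mean_degree too large for a simple graph of this size")
  w <- matrix(0, n, n)
  m <- 0L
  guard <- 0L
  guard_max <- 2000L * m_target + 10000L
  while (m < m_target) {
    src <- sample.int(n, 1L, prob = p)
    tgt <- sample.int(n, 1L, prob = p)
    guard <- guard + 1L
    if (guard > guard_max)
      stop("static model failed to place the requested number of edges")
    if (src == tgt) next
    if (!directed && src > tgt) { tmp <- src; src <- tgt; tgt <- tmp }
    if (w[src, tgt] != 0) next
    w[src, tgt] <- 1
    if (!directed) w[tgt, src] <- 1
    m <- m + 1L
  }
  w
}

#' Generate an ensemble of networks
#'
#' Draws `n_realizations` independent networks from one configuration, using
#' sub-seeds derived from `config$seed` so the ensemble is reproducible and
#' each member differs.
#'
#' @param config a [generator_config()].
#' @param n_realizations ensemble size (default 10).
#' @return a list of `icto_network` objects.
#' @export
make_network_ensemble <- function(config, n_realizations = 10L) {
  stopifnot(inherits(config, "generator_config"), n_realizations >= 1)
  lapply(seq_len(n_realizations), function(i) {
    cfg <- config
    cfg$seed <- derive_seed(config$seed, "netgen-ensemble", i)
    generate_network(cfg)
  })
}
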