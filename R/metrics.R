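#' Per-node graph metrics
#'
#' Computes, for every node: in-, out- and total degree (weighted degree, i.e.
#' strength, which reduces to the edge count on binary networks), betweenness
#' centrality, clustering coefficient and (for undirected networks)
#' eigenvector centrality.
#'
#' Betweenness uses shortest paths under the affinity-to-distance convention
#' `distance = 1 / weight` and is reported unnormalized; node pairs with no
#' connecting path contribute nothing. Clustering is computed on the binarized
#' adjacency: the local transitivity for undirected networks and Fagiolo's
#' directed generalization otherwise; nodes with fewer than two neighbours get
#' 0. Eigenvector centrality (power iteration on the symmetric adjacency,
#' tolerance 1e-10, at most 1e4 iterations, normalized to maximum 1) is
#' undefined for directed networks and omitted; on an edgeless network it is
#' flagged as failed (all `NA`) with a warning.
#'
#' @param net an `icto_network`.
#' @return a data.frame with one row per node and columns `label`,
#'   `degree_in`, `degree_out`, `degree_total`, `betweenness`, `clustering`
#'   and, for undirected networks, `eigenvector`.
#' @export
node_metrics <- function(net) {
  validate_network(net)
  w <- net$weights
  n <- n_nodes(net)
  deg_in <- colSums(w)
  deg_out <- rowSums(w)
  deg_tot <- if (net$directed) deg_in + deg_out else deg_out
  g <- as_igraph(net)
  ew <- igraph::E(g)$weight
  btw <- if (length(ew)) {
    igraph::betweenness(g, directed = net$directed, weights = 1 / ew,
                        normalized = FALSE)
  } else rep(0, n)
  a <- (w > 0) + 0
  clus <- if (net$directed) fagiolo_clustering(a) else local_transitivity(a)
  out <- data.frame(label = net$labels, degree_in = deg_in,
                    degree_out = deg_out, degree_total = deg_tot,
                    betweenness = as.numeric(btw), clustering = clus,
                    row.names = NULL, stringsAsFactors = FALSE)
  if (!net$directed) {
    out$eigenvector <- eigenvector_power(a)
  }
  out
}

# Local clustering of an undirected binary adjacency; degree < 2 nodes get 0.
local_transitivity <- function(a) {
  deg <- rowSums(a)
  tri <- diag(a %*% a %*% a)
  denom <- deg * (deg - 1)
  ifelse(denom > 0, tri / denom, 0)
}

# Fagiolo's clustering coefficient for directed binary networks:
# C_i = (A + A^t)^3_ii / (2 * (d_tot (d_tot - 1) - 2 d_bi)),
# d_tot = in + out degree, d_bi = number of reciprocated partners.
fagiolo_clustering <- function(a) {
  s <- a + t(a)
  tri <- diag(s %*% s %*% s) / 2
  d_tot <- rowSums(a) + colSums(a)
  d_bi <- diag(a %*% a)
  denom <- d_tot * (d_tot - 1) - 2 * d_bi
  ifelse(denom > 0, tri / denom, 0)
}

# Power iteration for the leading eigenvector of a symmetric nonnegative
# adjacency; normalized so the maximum entry is 1.
eigenvector_power <- function(a, tol = 1e-10, max_iter = 1e4) {
  n <- nrow(a)
  if (all(a == 0)) {
    warning("eigenvector centrality undefined on an edgeless network")
    return(rep(NA_real_, n))
  }
  v <- rep(1 / sqrt(n), n)
  for (i in seq_len(max_iter)) {
    v_new <- as.numeric(a %*% v)
    # shift keeps the iteration from oscillating on bipartite structures
    v_new <- v_new + v * max(rowSums(a)) * 1e-3
    nrm <- sqrt(sum(v_new^2))
    if (nrm == 0) {
      warning("power iteration collapsed; eigenvector centrality flagged NA")
      return(rep(NA_real_, n))
    }
    v_new <- v_new / nrm
    if (max(abs(v_new - v)) < tol) {
      v <- v_new
      break
    }
    v <- v_new
  }
  v <- abs(v)
  v / max(v)
}

#' Average a metric over a node set
#'
#' Arithmetic mean of one per-node metric over the members of a set, as used
#' to relate removed-set composition to its ictogenicity.
#'
#' @param metrics output of [node_metrics()].
#' @param x nonempty integer vector of node indices.
#' @param which metric column name (e.g. `"degree_total"`, `"betweenness"`).
#' @return the mean metric value over `x`.
#' @export
set_average_metric <- function(metrics, x, which) {
  stopifnot(is.data.frame(metrics))
  x <- check_node_set(x, nrow(metrics), allow_empty = FALSE)
  if (!which %in% names(metrics))
    stop("metric '", which, "' not available",
         if (which == "eigenvector") " (undefined for directed networks)" else "")
  mean(metrics[[which]][x])
}
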