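#' Weighted network container
#'
#' A network is an `N x N` matrix of nonnegative edge weights `a[i, j]`
#' (weight of the edge from node `i` to node `j`), a vector of node labels and
#' a directedness flag. This is the substrate for the theta-model dynamics,
#' graph metrics and virtual resections. Self-loops are not allowed (zero
#' diagonal) and undirected networks must have a symmetric weight matrix.
#'
#' Node indices are 1-based throughout the R interface; on-disk edge lists use
#' 0-based indices (see [read_network()]).
#'
#' @param weights square numeric matrix of nonnegative, finite weights with a
#'   zero diagonal.
#' @param labels optional character vector of node labels; defaults to
#'   `"n1" ... "nN"` (or the matrix dimnames when present).
#' @param directed logical; when `NULL`, inferred from symmetry of `weights`.
#' @return an object of class `icto_network` with elements `weights`,
#'   `labels`, `directed`.
#' @export
#' @examples
#' w <- matrix(0, 3, 3); w[1, 2] <- 1; w[2, 3] <- 1
#' net <- icto_network(w)
#' net
icto_network <- function(weights, labels = NULL, directed = NULL) {
  weights <- as.matrix(weights)
  if (is.null(directed)) {
    directed <- !isSymmetric(unname(weights))
  }
  if (is.null(labels)) {
    labels <- rownames(weights)
    if (is.null(labels)) labels <- paste0("n", seq_len(nrow(weights)))
  }
  dimnames(weights) <- NULL
  net <- structure(
    list(weights = weights, labels = as.character(labels),
         directed = isTRUE(directed)),
    class = "icto_network"
  )
  validate_network(net)
  net
}

#' Validate network invariants
#'
#' Checks that a network satisfies its contract: square weight matrix, all
#' entries finite and nonnegative, zero diagonal, symmetric when undirected,
#' and labels matching the node count. Errors otherwise.
#'
#' @param net an `icto_network`.
#' @return `net`, invisibly.
#' @export
validate_network <- function(net) {
  stopifnot(inherits(net, "icto_network"))
  w <- net$weights
  if (!is.matrix(w) || !is.numeric(w) || nrow(w) != ncol(w))
    stop("network weights must be a square numeric matrix")
  if (anyNA(w) || any(!is.finite(w)))
    stop("network weights must all be finite")
  if (any(w < 0))
    stop("network weights must be nonnegative")
  if (any(diag(w) != 0))
    stop("network must have a zero diagonal (no self-loops)")
  if (!net$directed && !isSymmetric(unname(w)))
    stop("undirected network must have a symmetric weight matrix")
  if (length(net$labels) != nrow(w))
    stop("number of labels must equal the number of nodes")
  invisible(net)
}

#' @export
print.icto_network <- function(x, ...) {
  n <- n_nodes(x)
  ne <- if (x$directed) sum(x$weights != 0) else sum(x$weights != 0) / 2
  cat(sprintf("<icto_network> %d nodes, %g %s edges, %s\n", n, ne,
              if (all(x$weights %in% c(0, 1))) "binary" else "weighted",
              if (x$directed) "directed" else "undirected"))
  invisible(x)
}

#' Number of nodes of a network
#' @param net an `icto_network`.
#' @return integer node count.
#' @export
n_nodes <- function(net) nrow(net$weights)

#' Virtual resection: remove a set of nodes
#'
#' Removes nodes by zeroing all their incoming and outgoing connections,
#' keeping the node count fixed. This is the in-silico analogue of resecting
#' the tissue under the corresponding electrodes.
#'
#' @param net an `icto_network`.
#' @param x integer vector of distinct 1-based node indices (may be empty).
#' @return a new `icto_network`; the input is unmodified.
#' @export
#' @examples
#' w <- matrix(0, 3, 3); w[1, 2] <- 1; w[2, 3] <- 1
#' remove_nodes(icto_network(w), 2)
remove_nodes <- function(net, x) {
  validate_network(net)
  x <- check_node_set(x, n_nodes(net))
  if (length(x) == 0L) return(net)
  w <- net$weights
  w[x, ] <- 0
  w[, x] <- 0
  net$weights <- w
  net
}

# Normalize and validate a node-index set: integer, distinct, in range.
check_node_set <- function(x, n, allow_empty = TRUE) {
  if (length(x) == 0L) {
    if (!allow_empty) stop("node set must be nonempty")
    return(integer(0))
  }
  if (!is.numeric(x) || anyNA(x) || any(x != as.integer(x)))
    stop("node indices must be integers")
  x <- as.integer(x)
  if (any(x < 1L | x > n))
    stop(sprintf("node index out of range [1, %d]", n))
  if (anyDuplicated(x))
    stop("node indices must be distinct")
  sort(x)
}

#' Convert a network to an igraph graph
#'
#' Edge weights are carried in the `weight` edge attribute.
#'
#' @param net an `icto_network`.
#' @return an `igraph` object.
#' @export
as_igraph <- function(net) {
  validate_network(net)
  mode <- if (net$directed) "directed" else "undirected"
  g <- igraph::graph_from_adjacency_matrix(net$weights, mode = mode,
                                           weighted = TRUE)
  igraph::V(g)$name <- net$labels
  g
}

#' Read and write networks
#'
#' Two plain-text formats are supported. `csv-matrix` is a dense CSV adjacency
#' matrix with a header row of node labels. `edge-list` is a CSV with header
#' `source,target,weight` and 0-based node indices; the node count is carried
#' in a `# nodes: N` comment line so edgeless nodes survive the round trip.
#' Weights are written in full precision and `write_network()` followed by
#' [read_network()] round-trips exactly.
#'
#' @param path file path.
#' @param format `"csv-matrix"` or `"edge-list"`.
#' @param n_nodes node count, required for `edge-list` files lacking the
#'   `# nodes:` header.
#' @param directed directedness of the resulting network; when `NULL`,
#'   inferred (matrix symmetry, or the `# directed:` header of an edge list).
#' @return `read_network()` returns an `icto_network`; `write_network()`
#'   returns `path` invisibly.
#' @export
read_network <- function(path, format = c("csv-matrix", "edge-list"),
                         n_nodes = NULL, directed = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "csv-matrix") {
    df <- utils::read.csv(path, check.names = FALSE)
    w <- as.matrix(df)
    if (nrow(w) != ncol(w))
      stop(sprintf("adjacency matrix in %s is not square (%d x %d)",
                   path, nrow(w), ncol(w)))
    labels <- colnames(w)
    return(icto_network(w, labels = labels, directed = directed))
  }
  lines <- readLines(path)
  n_hdr <- grep("^#\\s*nodes:", lines, value = TRUE)
  d_hdr <- grep("^#\\s*directed:", lines, value = TRUE)
  if (length(n_hdr)) n_nodes <- as.integer(sub("^#\\s*nodes:\\s*", "", n_hdr[1]))
  if (is.null(directed) && length(d_hdr))
    directed <- as.logical(sub("^#\\s*directed:\\s*", "", d_hdr[1]))
  if (is.null(n_nodes)) stop("edge-list file lacks '# nodes:' header; pass n_nodes")
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) && grepl("^source", body[1])) body <- body[-1]
  w <- matrix(0, n_nodes, n_nodes)
  for (k in seq_along(body)) {
    parts <- strsplit(body[k], ",", fixed = TRUE)[[1]]
    if (length(parts) != 3L || anyNA(suppressWarnings(as.numeric(parts))))
      stop(sprintf("malformed edge-list line %d: '%s'", k, body[k]))
    src <- as.numeric(parts[1]); tgt <- as.numeric(parts[2])
    wt <- as.numeric(parts[3])
    if (src != floor(src) || tgt != floor(tgt) ||
        src < 0 || tgt < 0 || src >= n_nodes || tgt >= n_nodes)
      stop(sprintf("edge-list line %d: node index out of range: '%s'", k, body[k]))
    if (wt < 0)
      stop(sprintf("edge-list line %d: negative weight: '%s'", k, body[k]))
    w[src + 1, tgt + 1] <- wt
    if (isFALSE(directed)) w[tgt + 1, src + 1] <- wt
  }
  icto_network(w, directed = directed)
}

#' @param net an `icto_network`.
#' @rdname read_network
#' @export
write_network <- function(net, path, format = c("csv-matrix", "edge-list")) {
  validate_network(net)
  format <- match.arg(format)
  if (format == "csv-matrix") {
    w <- net$weights
    colnames(w) <- net$labels
    utils::write.table(format(w, digits = 17, scientific = FALSE, trim = TRUE),
                       path, sep = ",", row.names = FALSE, col.names = TRUE,
                       quote = FALSE)
  } else {
    idx <- which(net$weights != 0, arr.ind = TRUE)
    if (!net$directed) idx <- idx[idx[, 1] <= idx[, 2], , drop = FALSE]
    lines <- c(sprintf("# nodes: %d", n_nodes(net)),
               sprintf("# directed: %s", net$directed),
               "source,target,weight",
               sprintf("%d,%d,%s", idx[, 1] - 1L, idx[, 2] - 1L,
                       format(net$weights[idx], digits = 17,
                              scientific = FALSE, trim = TRUE)))
    writeLines(lines, path)
  }
  invisible(path)
}
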