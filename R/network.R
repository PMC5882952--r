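#' Construct a PPI network
#'
#' Builds an undirected protein-protein interaction network from an edge
#' table. Self-loops and duplicate edges (regardless of endpoint order) are
#' dropped with a warning, since the modularity formulas assume a simple
#' graph. Node identifiers are case-sensitive opaque strings; no identifier
#' mapping is attempted.
#'
#' @param edges a data.frame (or matrix) whose first two columns are the edge
#'   endpoints; an optional third column holds positive edge weights.
#' @param nodes optional character vector of node identifiers; nodes absent
#'   from `edges` are kept as isolated (degree-0) nodes. Endpoints of `edges`
#'   are always included.
#' @param weighted logical; if `TRUE` the third column of `edges` is used as
#'   edge weight (default 1 when missing), otherwise all weights are 1.
#' @return an object of class `ppi_network`: a list with elements `nodes`
#'   (character), `edges` (data.frame `from`, `to`, `weight`), `weighted`,
#'   plus precomputed adjacency and degree/strength tables used by the
#'   modularity routines.
#' @examples
#' net <- ppi_network(data.frame(from = c("a", "b"), to = c("b", "c")))
#' net
#' @export
ppi_network <- function(edges, nodes = NULL, weighted = FALSE) {
  if (is.matrix(edges)) edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  stopifnot(is.data.frame(edges))
  if (nrow(edges) > 0 && ncol(edges) < 2)
    stop("`edges` needs at least two columns (endpoints)")

  if (nrow(edges) == 0) {
    from <- character(0); to <- character(0); w <- numeric(0)
  } else {
    from <- as.character(edges[[1]])
    to   <- as.character(edges[[2]])
    if (weighted && ncol(edges) >= 3) {
      w <- as.numeric(edges[[3]])
      if (anyNA(w)) stop("non-numeric edge weight")
      if (any(w <= 0)) stop("edge weights must be positive")
    } else {
      w <- rep(1, length(from))
    }
  }

  loops <- from == to
  if (any(loops)) {
    warning(sprintf("dropped %d self-loop(s)", sum(loops)))
    from <- from[!loops]; to <- to[!loops]; w <- w[!loops]
  }
  # canonical endpoint order so "a b" and "b a" collide
  lo <- pmin(from, to); hi <- pmax(from, to)
  key <- paste(lo, hi, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    warning(sprintf("dropped %d duplicate edge(s)", sum(dup)))
    lo <- lo[!dup]; hi <- hi[!dup]; w <- w[!dup]
  }

  all_nodes <- unique(c(as.character(nodes), lo, hi))
  if (length(all_nodes) == 0) stop("network has no nodes")

  edf <- data.frame(from = lo, to = hi, weight = w, stringsAsFactors = FALSE)

  net <- structure(
    list(nodes = all_nodes, edges = edf, weighted = isTRUE(weighted)),
    class = "ppi_network"
  )
  net <- .index_network(net)
  net
}

# precompute adjacency list, degree and strength lookups
.index_network <- function(net) {
  nodes <- net$nodes
  edf <- net$edges
  adj <- vector("list", length(nodes))
  names(adj) <- nodes
  for (i in seq_along(adj)) adj[[i]] <- numeric(0)
  if (nrow(edf) > 0) {
    ends <- c(edf$from, edf$to)
    other <- c(edf$to, edf$from)
    wts <- c(edf$weight, edf$weight)
    sp <- split(seq_along(ends), ends)
    for (nm in names(sp)) {
      idx <- sp[[nm]]
      v <- wts[idx]
      names(v) <- other[idx]
      adj[[nm]] <- v
    }
  }
  degree <- vapply(adj, length, integer(1))
  strength <- vapply(adj, sum, numeric(1))
  net$adj <- adj
  net$degree <- degree          # unweighted degree
  net$strength <- strength      # weighted strength
  net$n_edges <- nrow(edf)
  net$total_weight <- sum(edf$weight)
  net
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("PPI network: %d nodes, %d edges (%s)\n",
              length(x$nodes), x$n_edges,
              if (x$weighted) "weighted" else "unweighted"))
  invisible(x)
}

#' Convert a PPI network to an igraph object
#'
#' @param network a [ppi_network()].
#' @return an undirected `igraph` graph with a `weight` edge attribute.
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "ppi_network"))
  g <- igraph::graph_from_data_frame(network$edges, directed = FALSE,
                                     vertices = network$nodes)
  g
}

#' Validate a partition against a network
#'
#' A partition assigns every network node to exactly one topological module:
#' modules are pairwise disjoint, non-empty, and their union is the full node
#' set (full coverage).
#'
#' @param partition named integer vector mapping node identifier to module
#'   index, or a list of node-id vectors (one per module).
#' @param network a [ppi_network()].
#' @return a validated named integer vector with compact module indices
#'   `1..H` (class `mtgo_partition`).
#' @export
as_partition <- function(partition, network) {
  stopifnot(inherits(network, "ppi_network"))
  if (is.list(partition)) {
    memb <- rep(seq_along(partition), lengths(partition))
    names(memb) <- unlist(partition, use.names = FALSE)
    partition <- memb
  }
  if (is.null(names(partition))) stop("partition must be named by node id")
  if (anyDuplicated(names(partition)))
    stop("partition assigns a node to more than one module")
  missing <- setdiff(network$nodes, names(partition))
  extra <- setdiff(names(partition), network$nodes)
  if (length(missing) > 0)
    stop(sprintf("partition does not cover %d node(s), e.g. '%s'",
                 length(missing), missing[1]))
  if (length(extra) > 0)
    stop(sprintf("partition contains %d unknown node(s), e.g. '%s'",
                 length(extra), extra[1]))
  p <- as.integer(factor(partition))     # compact 1..H, no empty module
  names(p) <- names(partition)
  p <- p[network$nodes]
  structure(p, class = "mtgo_partition")
}

#' Number of modules in a partition
#' @param partition a partition vector as returned by [as_partition()].
#' @return integer count of modules.
#' @export
n_modules <- function(partition) length(unique(unclass(partition)))

# list of node-id vectors, one per module index
.partition_modules <- function(partition) {
  split(names(partition), unclass(partition))
}
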