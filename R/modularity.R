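#' Newman modularity of a partition
#'
#' Computes Q = sum_h \[ e_h/W - (d_h/(2W))^2 \], where e_h is the
#' (weight-)sum of intra-module edges of module h, d_h the (strength-)sum of
#' node degrees in h, and W the total number of edges (or total edge weight
#' in the weighted case). Q ranges in \[-1, 1\]: positive when modules hold
#' more internal edges than expected under the degree-preserving null model.
#'
#' @param network a [ppi_network()].
#' @param partition a partition of the network nodes (see [as_partition()]).
#' @param use_weights logical; use edge weights and node strengths instead of
#'   counts and degrees. Defaults to the network's `weighted` flag.
#' @return the modularity value. A network with zero edges returns 0 with a
#'   warning.
#' @examples
#' tri2 <- ppi_network(data.frame(
#'   from = c("a", "b", "c", "d", "e", "f"),
#'   to   = c("b", "c", "a", "e", "f", "d")))
#' modularity_q(tri2, list(c("a", "b", "c"), c("d", "e", "f")))  # 0.5
#' @export
modularity_q <- function(network, partition, use_weights = network$weighted) {
  stopifnot(inherits(network, "ppi_network"))
  partition <- as_partition(partition, network)
  if (network$n_edges == 0) {
    warning("network has no edges; modularity defined as 0")
    return(0)
  }
  if (use_weights) {
    W <- network$total_weight
    ew <- network$edges$weight
    deg <- network$strength
  } else {
    W <- network$n_edges
    ew <- rep(1, network$n_edges)
    deg <- as.numeric(network$degree)
  }
  memb <- unclass(partition)
  mf <- memb[network$edges$from]
  mt <- memb[network$edges$to]
  intra <- mf == mt
  H <- max(memb)
  e_h <- vapply(seq_len(H), function(h) sum(ew[intra & mf == h]), numeric(1))
  d_h <- vapply(seq_len(H), function(h) sum(deg[memb == h]), numeric(1))
  sum(e_h / W - (d_h / (2 * W))^2)
}

#' Modularity variation of moving a node into a module
#'
#' Local gain in modularity from placing node `v` into module `c`:
#' `MV(c, v) = k_vc / W - d_v * d_c / (2 W^2)`, where `k_vc` is the
#' (weight-)sum of edges between `v` and the nodes of `c` (excluding `v`
#' itself), `d_v` the (strength-)degree of `v`, `d_c` the degree sum of `c`
#' excluding `v`, and `W` the total edge count (or weight). Ranking candidate
#' modules by MV is equivalent to ranking them by the full modularity of the
#' partition with `v` placed there.
#'
#' @param network a [ppi_network()].
#' @param partition current partition (see [as_partition()]).
#' @param node node identifier to (tentatively) move.
#' @param target_module module index, or `0` for a new empty module.
#' @param use_weights logical, as in [modularity_q()].
#' @return the MV value (0 for an empty target module or an isolated node
#'   paired with a degree-0 module).
#' @examples
#' path <- ppi_network(data.frame(from = c("a", "b"), to = c("b", "c")))
#' p <- as_partition(c(a = 1, b = 1, c = 2), path)
#' modularity_variation(path, p, "c", 1)  # 0.125
#' @export
modularity_variation <- function(network, partition, node, target_module,
                                 use_weights = network$weighted) {
  stopifnot(inherits(network, "ppi_network"))
  partition <- as_partition(partition, network)
  if (!node %in% network$nodes) stop(sprintf("node '%s' not in network", node))
  memb <- unclass(partition)
  if (target_module != 0 && !target_module %in% memb)
    stop(sprintf("module %s does not exist", target_module))
  members <- if (target_module == 0) character(0) else
    setdiff(names(memb)[memb == target_module], node)
  .mv(network, node, members, use_weights)
}

# MV against an explicit member set (node excluded by the caller)
.mv <- function(network, node, members, use_weights) {
  if (use_weights) {
    W <- network$total_weight
    d_v <- network$strength[[node]]
    d_c <- sum(network$strength[members])
    nb <- network$adj[[node]]
    k <- sum(nb[names(nb) %in% members])
  } else {
    W <- network$n_edges
    d_v <- network$degree[[node]]
    d_c <- sum(network$degree[members])
    nb <- network$adj[[node]]
    k <- sum(names(nb) %in% members)
  }
  if (W == 0) return(0)
  k / W - (d_v * d_c) / (2 * W^2)
}
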