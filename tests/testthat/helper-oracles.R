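# Independent oracles and small fixture builders used across the suite.

# naive O(N^2) modularity: double sum over node pairs of
# (A_ij - d_i d_j / 2W) / 2W restricted to same-module pairs
oracle_modularity <- function(network, partition, use_weights = FALSE) {
  nodes <- network$nodes
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (r in seq_len(nrow(network$edges))) {
    w <- if (use_weights) network$edges$weight[r] else 1
    A[network$edges$from[r], network$edges$to[r]] <- w
    A[network$edges$to[r], network$edges$from[r]] <- w
  }
  deg <- rowSums(A)
  W2 <- sum(deg)                      # 2W
  if (W2 == 0) return(0)
  memb <- unclass(mtgo::as_partition(partition, network))[nodes]
  total <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (memb[i] == memb[j])
      total <- total + (A[i, j] - deg[i] * deg[j] / W2) / W2
  }
  unname(total)
}

# exhaustive maximum weighted bipartite matching over injective assignments
oracle_mmr <- function(predicted, targets) {
  nt <- length(targets); np <- length(predicted)
  om <- outer(seq_len(nt), seq_len(np),
              Vectorize(function(i, j)
                mtgo::overlap_score(targets[[i]], predicted[[j]])))
  best <- 0
  # recursively match target i to an unused prediction or leave it unmatched
  rec <- function(i, used, acc) {
    if (i > nt) { best <<- max(best, acc); return(invisible()) }
    rec(i + 1, used, acc)
    for (j in seq_len(np)) if (!used[j])
      rec(i + 1, replace(used, j, TRUE), acc + om[i, j])
  }
  rec(1, rep(FALSE, np), 0)
  best / nt
}

# hypergeometric upper tail P(X >= x) by explicit PMF summation
oracle_hyper_tail <- function(x, white, black, drawn) {
  ks <- x:min(white, drawn)
  ks <- ks[drawn - ks <= black]
  if (length(ks) == 0) return(0)
  sum(choose(white, ks) * choose(black, drawn - ks) /
        choose(white + black, drawn))
}

# Erdos-Renyi random ppi_network with optional weights
random_network <- function(n, p = 0.3, weighted = FALSE) {
  nodes <- sprintf("v%02d", seq_len(n))
  pr <- utils::combn(n, 2)
  keep <- stats::runif(ncol(pr)) < p
  if (!any(keep)) keep[sample.int(ncol(pr), 1)] <- TRUE
  edges <- data.frame(from = nodes[pr[1, keep]], to = nodes[pr[2, keep]],
                      stringsAsFactors = FALSE)
  if (weighted) edges$weight <- stats::runif(nrow(edges), 0.2, 2)
  mtgo::ppi_network(edges, nodes = nodes, weighted = weighted)
}

random_partition_for <- function(network, h) {
  n <- length(network$nodes)
  memb <- sample.int(h, n, replace = TRUE)
  names(memb) <- network$nodes
  mtgo::as_partition(memb, network)
}

triangle_net <- function() {
  mtgo::ppi_network(data.frame(from = c("a", "b", "c"),
                               to = c("b", "c", "a")))
}

two_triangles_net <- function() {
  mtgo::ppi_network(data.frame(from = c("a", "b", "c", "d", "e", "f"),
                               to = c("b", "c", "a", "e", "f", "d")))
}

# random complex catalog over an alphabet of proteins
random_catalog <- function(n_complexes, alphabet, min_size = 2,
                           max_size = 5) {
  sets <- lapply(seq_len(n_complexes), function(i)
    sample(alphabet, sample(min_size:max_size, 1)))
  suppressWarnings(mtgo::complex_catalog(sets))
}
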