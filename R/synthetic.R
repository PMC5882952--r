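#' Generate a planted-partition benchmark network
#'
#' Planted-module (stochastic block model) graph: node pairs within a module
#' are connected with probability `p_in`, pairs across modules with `p_out`.
#' Optional edge weights are drawn uniformly from (0.5, 1.5). The ground
#' truth partition is returned alongside so recovery can be scored.
#'
#' @param module_sizes integer vector of module sizes (each >= 2).
#' @param p_in,p_out within- and between-module edge probabilities.
#' @param seed integer seed; the edge set is deterministic given it.
#' @param weighted logical; draw edge weights.
#' @return list with `network` (a [ppi_network()]) and `truth` (the planted
#'   partition, see [as_partition()]).
#' @examples
#' pl <- generate_planted_network(c(4, 4), p_in = 1, p_out = 0, seed = 1)
#' pl$network
#' @export
generate_planted_network <- function(module_sizes, p_in = 0.4, p_out = 0.02,
                                     seed = 42, weighted = FALSE) {
  stopifnot(all(module_sizes >= 2), p_in >= 0, p_in <= 1,
            p_out >= 0, p_out <= 1)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)

  n <- sum(module_sizes)
  nodes <- sprintf("p%03d", seq_len(n))
  block <- rep(seq_along(module_sizes), module_sizes)

  pairs <- utils::combn(n, 2)
  same <- block[pairs[1, ]] == block[pairs[2, ]]
  prob <- ifelse(same, p_in, p_out)
  keep <- stats::runif(ncol(pairs)) < prob
  from <- nodes[pairs[1, keep]]
  to <- nodes[pairs[2, keep]]
  edges <- if (weighted)
    data.frame(from = from, to = to,
               weight = stats::runif(sum(keep), 0.5, 1.5),
               stringsAsFactors = FALSE)
  else data.frame(from = from, to = to, stringsAsFactors = FALSE)

  network <- ppi_network(edges, nodes = nodes, weighted = weighted)
  truth <- as_partition(stats::setNames(block, nodes), network)
  list(network = network, truth = truth)
}

#' Generate GO-like annotations for a planted partition
#'
#' Emits one "true" term per planted module containing a `coverage` fraction
#' of its nodes; then deletes a `removal_fraction` of all (term, protein)
#' memberships uniformly at random, pooled across terms — emulating
#' increasingly degraded annotation quality (e.g. 25/50/75% perturbation).
#' Optionally adds decoy terms sampled uniformly from all nodes, providing a
#' null overlap structure.
#'
#' @param truth a planted partition (see [generate_planted_network()]).
#' @param coverage fraction of each module included in its true term.
#' @param removal_fraction fraction of memberships deleted.
#' @param n_decoy_terms number of decoy terms added.
#' @param decoy_size_range integer length-2 vector of decoy term sizes.
#' @param seed integer seed.
#' @return named list term_id -> protein vector, suitable for
#'   [build_term_set()] or [write_annotations()]. Terms emptied by removal
#'   are retained as empty vectors (downstream filtering drops them).
#' @export
generate_annotations <- function(truth, coverage = 1, removal_fraction = 0,
                                 n_decoy_terms = 0,
                                 decoy_size_range = c(3, 10), seed = 42) {
  stopifnot(coverage >= 0, coverage <= 1,
            removal_fraction >= 0, removal_fraction <= 1)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)

  mods <- split(names(truth), unclass(truth))
  terms <- lapply(mods, function(m) {
    k <- max(1, round(coverage * length(m)))
    sort(sample(m, k))
  })
  names(terms) <- sprintf("GO:TRUE%04d", as.integer(names(mods)))

  if (removal_fraction > 0) {
    pool <- data.frame(term = rep(names(terms), lengths(terms)),
                       protein = unlist(terms, use.names = FALSE),
                       stringsAsFactors = FALSE)
    n_remove <- round(removal_fraction * nrow(pool))
    if (n_remove > 0) {
      drop <- sample.int(nrow(pool), n_remove)
      pool <- pool[-drop, , drop = FALSE]
    }
    terms <- lapply(stats::setNames(names(terms), names(terms)),
                    function(tn) pool$protein[pool$term == tn])
  }

  if (n_decoy_terms > 0) {
    all_nodes <- names(truth)
    sizes <- sample(decoy_size_range[1]:decoy_size_range[2], n_decoy_terms,
                    replace = TRUE)
    decoys <- lapply(sizes, function(s) sort(sample(all_nodes,
                                                    min(s, length(all_nodes)))))
    names(decoys) <- sprintf("GO:DECOY%04d", seq_len(n_decoy_terms))
    terms <- c(terms, decoys)
  }
  terms
}

#' Normalized mutual information between two partitions
#'
#' Convenience wrapper scoring agreement between a recovered and a planted
#' partition (1 = identical up to relabeling, 0 = independent).
#'
#' @param p1,p2 named module vectors over the same node set.
#' @return NMI in \[0, 1\].
#' @export
partition_nmi <- function(p1, p2) {
  common <- intersect(names(p1), names(p2))
  stopifnot(length(common) == length(p1), length(common) == length(p2))
  igraph::compare(as.integer(factor(unclass(p1)[common])),
                  as.integer(factor(unclass(p2)[common])),
                  method = "nmi")
}
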