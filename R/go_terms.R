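#' Build the filtered GO term set for a network
#'
#' Restricts every raw term's protein set to the network nodes, removes terms
#' whose surviving protein set is empty or outside the \[`min_size`,
#' `max_size`\] bounds, and counts the GO-covered nodes (the union of all
#' surviving protein sets, N_GO, which normalizes the QGO functional).
#'
#' @param raw_terms a named list: term identifier -> character vector of
#'   protein identifiers. Optionally carries per-term metadata in attributes
#'   `term_names` and `categories` (named character vectors); the GAF reader
#'   supplies these.
#' @param network a [ppi_network()].
#' @param min_size,max_size inclusive bounds on the size of a term's protein
#'   set after intersection with the network (defaults 2 and 100).
#' @return an object of class `go_term_set`: list with `proteins` (named list
#'   of node-id vectors), `term_names`, `categories`, `n_go`, and
#'   `node_terms` (node -> integer indices of covering terms).
#' @examples
#' net <- ppi_network(data.frame(from = c("a", "a"), to = c("b", "c")))
#' ts <- build_term_set(list(t1 = c("a", "b"), t2 = c("a", "b", "c")), net)
#' ts$n_go  # 3
#' @export
build_term_set <- function(raw_terms, network, min_size = 2, max_size = 100) {
  stopifnot(inherits(network, "ppi_network"),
            min_size >= 1, min_size <= max_size)
  if (length(raw_terms) == 0 || is.null(names(raw_terms)))
    stop("`raw_terms` must be a non-empty named list")
  term_names <- attr(raw_terms, "term_names")
  categories <- attr(raw_terms, "categories")

  node_set <- network$nodes
  filtered <- lapply(raw_terms, function(p) unique(p[p %in% node_set]))
  sizes <- lengths(filtered)
  keep <- sizes >= min_size & sizes <= max_size
  filtered <- filtered[keep]
  if (length(filtered) == 0)
    stop("no GO term survives filtering; relax min_size/max_size or check ",
         "that protein identifiers match the network's node identifiers")
  filtered <- filtered[order(names(filtered))]

  covered <- unique(unlist(filtered, use.names = FALSE))
  node_terms <- vector("list", length(covered))
  names(node_terms) <- covered
  for (i in seq_along(filtered)) {
    for (nd in filtered[[i]]) node_terms[[nd]] <- c(node_terms[[nd]], i)
  }

  structure(
    list(
      proteins = filtered,
      term_names = if (!is.null(term_names)) term_names[names(filtered)],
      categories = if (!is.null(categories)) categories[names(filtered)],
      n_go = length(covered),
      node_terms = node_terms
    ),
    class = "go_term_set"
  )
}

#' @export
print.go_term_set <- function(x, ...) {
  cat(sprintf("GO term set: %d terms covering %d nodes (sizes %d-%d)\n",
              length(x$proteins), x$n_go,
              min(lengths(x$proteins)), max(lengths(x$proteins))))
  invisible(x)
}

#' Selection function gamma
#'
#' Counts the nodes outside the intersection of a topological module and a
#' candidate term's protein set: `|c U d| - |c n d|` (the size of the
#' symmetric difference). The best-fitting term for a module is the one
#' minimizing gamma.
#'
#' @param module_nodes character vector of the module's node identifiers.
#' @param term_proteins character vector of the candidate term's proteins.
#' @return non-negative integer count.
#' @examples
#' selection_gamma(c("a", "b", "c"), c("b", "c", "d"))  # 2
#' @export
selection_gamma <- function(module_nodes, term_proteins) {
  stopifnot(length(module_nodes) > 0, length(term_proteins) > 0)
  inter <- sum(term_proteins %in% module_nodes)
  length(module_nodes) + length(term_proteins) - 2L * inter
}

#' Select the best-describing GO term for a module
#'
#' Candidates are the terms sharing at least one protein with the module;
#' among those, the term minimizing [selection_gamma()] wins. Ties are broken
#' deterministically by larger intersection with the module, then by
#' lexicographically smallest term identifier. Returns `NA` when no term
#' intersects the module (the module stays unlabeled).
#'
#' @param module_nodes character vector of the module's node identifiers.
#' @param term_set a [build_term_set()] result.
#' @return integer index into `term_set$proteins`, or `NA_integer_`.
#' @export
select_best_term <- function(module_nodes, term_set) {
  stopifnot(inherits(term_set, "go_term_set"))
  cand <- unique(unlist(term_set$node_terms[
    names(term_set$node_terms) %in% module_nodes], use.names = FALSE))
  if (length(cand) == 0) return(NA_integer_)
  n_c <- length(module_nodes)
  inter <- vapply(term_set$proteins[cand],
                  function(p) sum(p %in% module_nodes), numeric(1))
  gam <- n_c + lengths(term_set$proteins[cand]) - 2 * inter
  best <- cand[gam == min(gam)]
  if (length(best) > 1) {
    bi <- inter[match(best, cand)]
    best <- best[bi == max(bi)]
    if (length(best) > 1)
      best <- best[order(names(term_set$proteins)[best])][1]
  }
  as.integer(best[1])
}
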