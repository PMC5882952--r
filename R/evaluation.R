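#' Construct a complex catalog
#'
#' A catalog of protein complexes — gold-standard targets or predictions.
#' Member lists are deduplicated; complexes with fewer than `min_size`
#' distinct members are excluded (the standard gold-standard convention drops
#' single-protein "complexes").
#'
#' @param sets list of character vectors (optionally named).
#' @param min_size minimum complex size kept (default 2).
#' @return a list of class `complex_catalog`.
#' @export
complex_catalog <- function(sets, min_size = 2) {
  stopifnot(is.list(sets))
  sets <- lapply(sets, function(s) unique(as.character(s)))
  if (length(sets) == 0)
    return(structure(list(), class = "complex_catalog"))
  if (is.null(names(sets)) || any(names(sets) == ""))
    names(sets) <- paste0("complex_", seq_along(sets))
  keep <- lengths(sets) >= min_size
  if (any(!keep))
    warning(sprintf("excluded %d complex(es) with fewer than %d members",
                    sum(!keep), min_size))
  structure(sets[keep], class = "complex_catalog")
}

#' @export
print.complex_catalog <- function(x, ...) {
  cat(sprintf("Complex catalog: %d complexes, sizes %s\n", length(x),
              if (length(x)) paste(range(lengths(x)), collapse = "-")
              else "-"))
  invisible(x)
}

#' Overlap (affinity) score between two protein sets
#'
#' `omega(A, B) = |A n B|^2 / (|A| * |B|)`, in \[0, 1\]; 1 iff the sets are
#' identical. The standard match criterion between predicted and target
#' complexes.
#'
#' @param a,b non-empty character vectors of protein identifiers.
#' @return numeric score.
#' @examples
#' overlap_score(c("a", "b", "c"), c("a", "b", "d", "e"))  # 1/3
#' @export
overlap_score <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (length(a) == 0 || length(b) == 0) stop("empty protein set")
  sum(a %in% b)^2 / (length(a) * length(b))
}

# omega matrix, targets in rows, predictions in columns
.omega_matrix <- function(predicted, targets) {
  outer(seq_along(targets), seq_along(predicted),
        Vectorize(function(i, j) overlap_score(targets[[i]], predicted[[j]])))
}

#' Matched complex counts at an overlap threshold
#'
#' @param predicted,targets [complex_catalog()] objects.
#' @param threshold minimum [overlap_score()] for a match (default 0.25).
#' @return list with `n_apc` (predictions matching at least one target) and
#'   `n_atc` (targets matched by at least one prediction).
#' @export
match_counts <- function(predicted, targets, threshold = 0.25) {
  stopifnot(threshold > 0, threshold <= 1)
  if (length(predicted) == 0 || length(targets) == 0)
    return(list(n_apc = 0L, n_atc = 0L))
  om <- .omega_matrix(predicted, targets)
  list(n_apc = sum(apply(om, 2, max) >= threshold),
       n_atc = sum(apply(om, 1, max) >= threshold))
}

#' Recall, Precision and F-measure of complex prediction
#'
#' Recall = N_ATC / |TC|, Precision = N_APC / |PC|, F = their harmonic mean
#' (0 when both vanish), with matches decided by the overlap score at
#' `threshold`.
#'
#' @inheritParams match_counts
#' @return named numeric vector `recall`, `precision`, `f`.
#' @export
recall_precision_f <- function(predicted, targets, threshold = 0.25) {
  if (length(targets) == 0) stop("empty target catalog")
  mc <- match_counts(predicted, targets, threshold)
  recall <- mc$n_atc / length(targets)
  precision <- if (length(predicted) == 0) 0 else mc$n_apc / length(predicted)
  f <- if (recall + precision == 0) 0 else
    2 * recall * precision / (recall + precision)
  c(recall = recall, precision = precision, f = f)
}

#' Clustering-wise Sensitivity, PPV and Accuracy
#'
#' Brohee-van Helden measures built from the overlap matrix
#' `t_ij = |target_i n predicted_j|`: Sn = sum_i max_j t_ij / sum_i
#' |target_i|; PPV = sum_j max_i t_ij / sum_ij t_ij; Accuracy is their
#' geometric mean.
#'
#' @inheritParams match_counts
#' @return named numeric vector `sn`, `ppv`, `accuracy`.
#' @export
sn_ppv_accuracy <- function(predicted, targets) {
  stopifnot(length(predicted) > 0, length(targets) > 0)
  t_ij <- outer(seq_along(targets), seq_along(predicted),
                Vectorize(function(i, j)
                  length(intersect(targets[[i]], predicted[[j]]))))
  sn <- sum(apply(t_ij, 1, max)) / sum(lengths(targets))
  tot <- sum(t_ij)
  if (tot == 0) {
    warning("no overlap between predictions and targets; Accuracy = 0")
    return(c(sn = sn, ppv = 0, accuracy = 0))
  }
  ppv <- sum(apply(t_ij, 2, max)) / tot
  c(sn = sn, ppv = ppv, accuracy = sqrt(sn * ppv))
}

#' Maximum Matching Ratio
#'
#' Builds the bipartite graph between targets and predictions weighted by the
#' overlap score, takes the maximum weighted matching, and divides its total
#' weight by the number of targets.
#'
#' @inheritParams match_counts
#' @return numeric MMR in \[0, 1\].
#' @examples
#' p <- complex_catalog(list(c("a", "b"), c("c", "d")))
#' t <- complex_catalog(list(c("a", "b"), c("c", "e")))
#' mmr(p, t)  # (1 + 0.25) / 2
#' @export
mmr <- function(predicted, targets) {
  stopifnot(length(targets) > 0)
  if (length(predicted) == 0) return(0)
  om <- .omega_matrix(predicted, targets)
  idx <- which(om > 0, arr.ind = TRUE)
  if (nrow(idx) == 0) return(0)
  nt <- length(targets)
  g <- igraph::make_bipartite_graph(
    c(rep(FALSE, nt), rep(TRUE, length(predicted))),
    edges = as.vector(t(cbind(idx[, 1], nt + idx[, 2]))),
    directed = FALSE)
  m <- igraph::max_bipartite_match(g, weights = om[idx])
  m$matching_weight / nt
}

#' Composite score
#'
#' Recall + Accuracy + MMR, the summary used to rank module-identification
#' algorithms; ranges over \[0, 3\].
#'
#' @inheritParams match_counts
#' @return numeric composite score.
#' @export
composite_score <- function(predicted, targets, threshold = 0.25) {
  if (length(predicted) == 0) return(0)
  r <- recall_precision_f(predicted, targets, threshold)[["recall"]]
  a <- sn_ppv_accuracy(predicted, targets)[["accuracy"]]
  r + a + mmr(predicted, targets)
}

#' Small-complex target subset
#'
#' Keeps the gold-standard complexes with 2 or 3 distinct members ("small"
#' complexes); sizes are counted after member deduplication.
#'
#' @param targets a [complex_catalog()].
#' @return a `complex_catalog` of the small complexes (empty with a warning
#'   if none qualify).
#' @export
derive_small_targets <- function(targets) {
  stopifnot(inherits(targets, "complex_catalog"))
  keep <- lengths(targets) >= 2 & lengths(targets) <= 3
  if (!any(keep)) warning("no complex with 2-3 members; empty target set")
  structure(unclass(targets)[keep], class = "complex_catalog")
}

#' Sparse-complex target subset relative to a network
#'
#' For each complex, members are first restricted to nodes present in the
#' network; with n >= 2 present members and e internal network edges, the
#' induced density is 2e / (n (n - 1)). Complexes with density below
#' `density_threshold` are kept; complexes with fewer than 2 present members
#' are dropped. The same catalog yields different sparse subsets against
#' different networks.
#'
#' @param targets a [complex_catalog()].
#' @param network a [ppi_network()].
#' @param density_threshold keep complexes with density strictly below this
#'   (default 0.5).
#' @return a `complex_catalog` of the sparse complexes (restricted to present
#'   members).
#' @export
derive_sparse_targets <- function(targets, network, density_threshold = 0.5) {
  stopifnot(inherits(targets, "complex_catalog"),
            inherits(network, "ppi_network"),
            density_threshold > 0, density_threshold <= 1)
  out <- list()
  for (nm in names(targets)) {
    present <- intersect(targets[[nm]], network$nodes)
    n <- length(present)
    if (n < 2) next
    e <- sum(network$edges$from %in% present & network$edges$to %in% present)
    density <- 2 * e / (n * (n - 1))
    if (density < density_threshold) out[[nm]] <- present
  }
  structure(out, class = "complex_catalog")
}

#' Significance of MTGO-assigned GO labels
#'
#' For every labeled module, a one-sided Fisher's exact test (hypergeometric
#' upper tail) of enrichment of the assigned term among the module's
#' GO-covered members, over the GO-covered network background. The Bonferroni
#' factor for a module is the number of candidate terms tested for it (terms
#' sharing at least one protein with the module). Reports, for each alpha,
#' the fraction of labeled modules whose corrected p-value is below it.
#'
#' @param result an [run_mtgo()] result.
#' @param term_set the [build_term_set()] used for the run.
#' @param network the [ppi_network()] analyzed.
#' @param alpha significance thresholds (default `c(1e-3, 1e-10)`).
#' @return list with `table` (data.frame: module, term_id, overlap,
#'   module_size, term_size, background, n_tests, raw_p, corrected_p, and one
#'   logical column per alpha) and `significant_fraction` (named numeric,
#'   fraction of labeled modules significant at each alpha).
#' @export
label_significance <- function(result, term_set, network,
                               alpha = c(1e-3, 1e-10)) {
  stopifnot(inherits(result, "mtgo_result"),
            inherits(term_set, "go_term_set"))
  asn <- result$final_assignment
  labeled <- asn[!is.na(asn$term_id), , drop = FALSE]
  if (nrow(labeled) == 0) stop("result has no labeled module")
  background <- names(term_set$node_terms)      # GO-covered nodes
  N <- length(background)
  mods <- .partition_modules(result$final_partition)

  rows <- lapply(seq_len(nrow(labeled)), function(i) {
    h <- as.character(labeled$module[i])
    members <- intersect(mods[[h]], background)
    delta <- intersect(term_set$proteins[[labeled$term_id[i]]], background)
    x <- length(intersect(members, delta))
    n_tests <- length(unique(unlist(
      term_set$node_terms[names(term_set$node_terms) %in% mods[[h]]],
      use.names = FALSE)))
    raw_p <- stats::phyper(x - 1, length(delta), N - length(delta),
                           length(members), lower.tail = FALSE)
    data.frame(module = labeled$module[i], term_id = labeled$term_id[i],
               overlap = x, module_size = length(members),
               term_size = length(delta), background = N,
               n_tests = n_tests, raw_p = raw_p,
               corrected_p = min(1, raw_p * n_tests),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  frac <- vapply(alpha, function(a) mean(tab$corrected_p < a), numeric(1))
  names(frac) <- format(alpha, scientific = TRUE)
  for (j in seq_along(alpha))
    tab[[paste0("sig_", format(alpha[j], scientific = TRUE))]] <-
      tab$corrected_p < alpha[j]
  list(table = tab, significant_fraction = frac)
}
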