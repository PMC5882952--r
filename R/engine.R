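#' MTGO run parameters
#'
#' @param min_size,max_size inclusive size bounds for GO term protein sets
#'   (defaults 2 and 100).
#' @param threshold convergence threshold on the successive differences of
#'   modularity Q and of the GO-agreement functional QGO (default 1e-4).
#' @param max_iterations hard cap on iterations (default 100); runs hitting
#'   the cap are reported with `converged = FALSE`.
#' @param seed integer seed driving all randomness of a run (initial random
#'   partition and the per-iteration module processing order).
#' @param use_weights logical; optimize the weighted modularity.
#' @return a list of class `mtgo_params`.
#' @export
mtgo_params <- function(min_size = 2, max_size = 100, threshold = 1e-4,
                        max_iterations = 100, seed = 42,
                        use_weights = FALSE) {
  stopifnot(min_size >= 1, min_size <= max_size, threshold > 0,
            max_iterations >= 1)
  structure(list(min_size = as.integer(min_size),
                 max_size = as.integer(max_size),
                 threshold = threshold,
                 max_iterations = as.integer(max_iterations),
                 seed = as.integer(seed),
                 use_weights = isTRUE(use_weights)),
            class = "mtgo_params")
}

#' Random initial partition
#'
#' Draws the starting partition: ceiling(sqrt(N)) modules, each node assigned
#' uniformly at random; empty modules are dropped and indices compacted.
#'
#' @param network a [ppi_network()].
#' @param seed integer seed (the partition is deterministic given it).
#' @return a partition vector (see [as_partition()]).
#' @export
initialize_partition <- function(network, seed) {
  stopifnot(inherits(network, "ppi_network"))
  N <- length(network$nodes)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  .random_partition(network)
}

.random_partition <- function(network) {
  N <- length(network$nodes)
  H0 <- ceiling(sqrt(N))
  memb <- sample.int(H0, N, replace = TRUE)
  names(memb) <- network$nodes
  as_partition(memb, network)
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Create an engine state from a partition
#'
#' Engine state is the partition plus the Temporary Node List (TNL), the
#' holding area for nodes evicted from their module in Step 1 and re-placed
#' in Step 2. At every iteration boundary the TNL is empty and the partition
#' covers all nodes.
#'
#' @param partition a partition vector (see [as_partition()]).
#' @param network a [ppi_network()].
#' @return a list of class `mtgo_state` with elements `memb` (named integer,
#'   `NA` while a node sits in the TNL) and `tnl` (character vector).
#' @export
new_engine_state <- function(partition, network) {
  partition <- as_partition(partition, network)
  structure(list(memb = unclass(partition), tnl = character(0)),
            class = "mtgo_state")
}

.state_members <- function(state, h) {
  names(state$memb)[!is.na(state$memb) & state$memb == h]
}
.state_module_ids <- function(state) {
  sort(unique(state$memb[!is.na(state$memb)]))
}

#' MTGO iteration Step 1: term-guided node redistribution
#'
#' Visits topological modules in a random order (drawn from the current RNG
#' stream). For each module with at least one intersecting term, the best
#' term is selected by [select_best_term()]; the module's nodes are then
#' split: nodes shared with the term stay (V_a), module nodes outside the
#' term go to the TNL (V_b), and term proteins living in other modules (V_c)
#' migrate in when the modularity variation toward this module strictly
#' exceeds the one toward their current module. Unlabeled modules are left
#' untouched. Modules emptied by migration disappear.
#'
#' @param state an `mtgo_state` (see [new_engine_state()]).
#' @param term_set a [build_term_set()] result.
#' @param network a [ppi_network()].
#' @param params an [mtgo_params()] object.
#' @return the updated `mtgo_state`.
#' @export
mtgo_step1 <- function(state, term_set, network, params) {
  ids <- .state_module_ids(state)
  order_ids <- ids[sample.int(length(ids))]
  for (h in order_ids) {
    members <- .state_members(state, h)
    if (length(members) == 0) next               # emptied by an earlier move
    ti <- select_best_term(members, term_set)
    if (is.na(ti)) next                          # unlabeled: untouched
    delta <- term_set$proteins[[ti]]
    v_b <- setdiff(members, delta)
    v_c <- setdiff(delta, members)
    if (length(v_b) > 0) {
      state$memb[v_b] <- NA_integer_
      state$tnl <- c(state$tnl, v_b)
    }
    for (v in v_c) {
      m <- state$memb[[v]]
      if (is.na(m)) next                         # already in the TNL
      members_h <- .state_members(state, h)
      members_m <- setdiff(.state_members(state, m), v)
      mv_h <- .mv(network, v, members_h, params$use_weights)
      mv_m <- .mv(network, v, members_m, params$use_weights)
      if (mv_h > mv_m) state$memb[[v]] <- h      # ties: node stays
    }
  }
  state
}

#' MTGO iteration Step 2: emptying the Temporary Node List
#'
#' TNL nodes covered by at least one GO term are grouped into a new module
#' c_TNL; each uncovered TNL node is placed in the pre-existing module
#' maximizing the modularity variation. c_TNL is then integrated by a single
#' re-run of the Step 1 rule restricted to it: its best term is selected, its
#' off-term nodes are routed to the MV-maximizing existing module, and the
#' term's proteins elsewhere migrate in under the usual MV comparison. On
#' return the TNL is empty and the partition covers every node.
#'
#' @inheritParams mtgo_step1
#' @return the updated `mtgo_state` with an empty TNL.
#' @export
mtgo_step2 <- function(state, term_set, network, params) {
  if (length(state$tnl) == 0) return(state)
  tnl <- state$tnl
  state$tnl <- character(0)
  covered <- tnl[tnl %in% names(term_set$node_terms)]
  uncovered <- setdiff(tnl, covered)

  existing <- .state_module_ids(state)
  tnl_id <- if (length(existing) > 0) max(existing) + 1L else 1L
  if (length(covered) > 0) state$memb[covered] <- tnl_id

  for (v in uncovered) {
    if (length(existing) == 0) {                 # degenerate: nothing to join
      fallback <- if (length(covered) > 0) tnl_id else tnl_id + 1L
      state$memb[[v]] <- fallback
      next
    }
    mv <- vapply(existing, function(h)
      .mv(network, v, .state_members(state, h), params$use_weights),
      numeric(1))
    state$memb[[v]] <- existing[which.max(mv)]   # ties: lowest module index
  }

  if (length(covered) > 0)
    state <- .integrate_ctnl(state, tnl_id, term_set, network, params)
  state
}

# single Step-1 pass restricted to c_TNL; evicted nodes go straight to the
# MV-best other module so the TNL is empty at the iteration boundary
.integrate_ctnl <- function(state, tnl_id, term_set, network, params) {
  members <- .state_members(state, tnl_id)
  if (length(members) == 0) return(state)
  ti <- select_best_term(members, term_set)
  if (is.na(ti)) return(state)                   # dispersed next iteration
  delta <- term_set$proteins[[ti]]
  v_b <- setdiff(members, delta)
  v_c <- setdiff(delta, members)
  for (v in v_b) {
    others <- setdiff(.state_module_ids(state), tnl_id)
    if (length(others) == 0) break
    mv <- vapply(others, function(h)
      .mv(network, v, .state_members(state, h), params$use_weights),
      numeric(1))
    state$memb[[v]] <- others[which.max(mv)]
  }
  for (v in v_c) {
    m <- state$memb[[v]]
    if (is.na(m) || m == tnl_id) next
    mv_h <- .mv(network, v, .state_members(state, tnl_id), params$use_weights)
    mv_m <- .mv(network, v, setdiff(.state_members(state, m), v),
                params$use_weights)
    if (mv_h > mv_m) state$memb[[v]] <- tnl_id
  }
  state
}

#' GO-agreement functional QGO
#'
#' QGO = sum_h |delta_B,h intersect c_h| / N_GO, where delta_B,h is the best
#' term selected for module h ([select_best_term()]) and N_GO the number of
#' network nodes covered by at least one term. Unlabeled modules contribute
#' 0. QGO lies in \[0, 1\] and equals 1 when every GO-covered node sits in
#' the intersection of its module with the module's term.
#'
#' @param partition a partition vector (see [as_partition()]).
#' @param term_set a [build_term_set()] result.
#' @param network a [ppi_network()].
#' @return list with `qgo` (numeric) and `assignment` (integer vector of term
#'   indices per module, `NA` for unlabeled modules).
#' @export
compute_qgo <- function(partition, term_set, network) {
  stopifnot(inherits(term_set, "go_term_set"))
  partition <- as_partition(partition, network)
  if (term_set$n_go == 0) stop("no annotated node (N_GO = 0)")
  mods <- .partition_modules(partition)
  sel <- vapply(mods, select_best_term, integer(1), term_set = term_set)
  overlap <- vapply(seq_along(mods), function(i) {
    if (is.na(sel[i])) return(0L)
    sum(term_set$proteins[[sel[i]]] %in% mods[[i]])
  }, integer(1))
  list(qgo = sum(overlap) / term_set$n_go, assignment = sel)
}

#' Run the MTGO algorithm
#'
#' Iteratively re-partitions a PPI network so that topological modules align
#' with GO-term protein sets, jointly tracking modularity Q and the
#' GO-agreement functional QGO. Each iteration applies [mtgo_step1()] then
#' [mtgo_step2()]; the run stops when both successive differences fall below
#' `params$threshold` (or at `params$max_iterations`), and the reported
#' solution is the iteration attaining the maximum QGO; ties on QGO are
#' broken by the higher modularity Q, then by the earlier iteration (QGO is
#' blind to a module splitting inside its term's protein set, so among
#' equally GO-consistent iterations the topologically best one is reported).
#'
#' @param network a [ppi_network()].
#' @param terms either a [build_term_set()] result or a named list of raw
#'   term protein sets (then filtered here with the bounds in `params`).
#' @param params an [mtgo_params()] object.
#' @return an object of class `mtgo_result`: `final_partition` (named module
#'   vector), `final_assignment` (data.frame module, term_id, term_name,
#'   size, term_size, overlap), `phi` (named list of the selected terms'
#'   protein sets), `trace` (data.frame k, Q, QGO, H), `converged`,
#'   `selected_iteration`, `n_go`, `params`.
#' @examples
#' net <- generate_planted_network(c(5, 5), p_in = 1, p_out = 0, seed = 1)
#' ts <- build_term_set(generate_annotations(net$truth, seed = 1),
#'                      net$network)
#' res <- run_mtgo(net$network, ts, mtgo_params(seed = 7))
#' res$trace
#' @export
run_mtgo <- function(network, terms, params = mtgo_params()) {
  stopifnot(inherits(network, "ppi_network"), inherits(params, "mtgo_params"))
  if (!inherits(terms, "go_term_set"))
    terms <- build_term_set(terms, network, params$min_size, params$max_size)

  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(params$seed)

  state <- new_engine_state(.random_partition(network), network)
  trace <- data.frame(k = integer(0), Q = numeric(0), QGO = numeric(0),
                      H = integer(0))
  best <- list(qgo = -Inf, q = -Inf, k = NA_integer_, partition = NULL,
               assignment = NULL)
  converged <- FALSE

  for (k in seq_len(params$max_iterations)) {
    state <- mtgo_step1(state, terms, network, params)
    state <- mtgo_step2(state, terms, network, params)
    stopifnot(length(state$tnl) == 0, !anyNA(state$memb))
    part <- as_partition(state$memb, network)
    q <- suppressWarnings(modularity_q(network, part, params$use_weights))
    qg <- compute_qgo(part, terms, network)
    trace <- rbind(trace, data.frame(k = k, Q = q, QGO = qg$qgo,
                                     H = n_modules(part)))
    if (qg$qgo > best$qgo || (qg$qgo == best$qgo && q > best$q)) {
      best <- list(qgo = qg$qgo, q = q, k = k, partition = part,
                   assignment = qg$assignment)
    }
    if (k >= 3 &&
        abs(trace$Q[k] - trace$Q[k - 1]) < params$threshold &&
        abs(trace$QGO[k - 1] - trace$QGO[k - 2]) < params$threshold) {
      converged <- TRUE
      break
    }
  }

  sel <- best$assignment
  mods <- .partition_modules(best$partition)
  term_ids <- ifelse(is.na(sel), NA_character_, names(terms$proteins)[sel])
  assignment <- data.frame(
    module = as.integer(names(mods)),
    term_id = term_ids,
    term_name = if (!is.null(terms$term_names))
      unname(terms$term_names[term_ids]) else NA_character_,
    size = lengths(mods),
    term_size = ifelse(is.na(sel), NA_integer_,
                       lengths(terms$proteins)[sel]),
    overlap = vapply(seq_along(mods), function(i) {
      if (is.na(sel[i])) return(NA_integer_)
      sum(terms$proteins[[sel[i]]] %in% mods[[i]])
    }, integer(1)),
    stringsAsFactors = FALSE
  )
  phi <- terms$proteins[sel[!is.na(sel)]]

  structure(
    list(final_partition = best$partition,
         final_assignment = assignment,
         phi = phi,
         trace = trace,
         converged = converged,
         selected_iteration = best$k,
         n_go = terms$n_go,
         params = params),
    class = "mtgo_result"
  )
}

#' @export
print.mtgo_result <- function(x, ...) {
  cat(sprintf(paste0(
    "MTGO result: %d modules (%d labeled), QGO = %.4f, Q = %.4f\n",
    "  %d iteration(s), %s, solution from iteration %d\n"),
    n_modules(x$final_partition),
    sum(!is.na(x$final_assignment$term_id)),
    x$trace$QGO[x$selected_iteration], x$trace$Q[x$selected_iteration],
    nrow(x$trace),
    if (x$converged) "converged" else "max iterations reached",
    x$selected_iteration))
  invisible(x)
}

#' Extract predicted complexes from an MTGO result
#'
#' Returns the topological modules as a complex catalog (the partition analog
#' of competitor algorithms' predicted clusters), or the overlapping
#' functional modules when `what = "functional"`. Modules below `min_size`
#' members are dropped, mirroring the target-side convention.
#'
#' @param result an [run_mtgo()] result.
#' @param what `"topological"` (default) or `"functional"`.
#' @param min_size drop predicted complexes smaller than this (default 2).
#' @return a [complex_catalog()].
#' @export
predicted_complexes <- function(result, what = c("topological", "functional"),
                                min_size = 2) {
  what <- match.arg(what)
  stopifnot(inherits(result, "mtgo_result"))
  sets <- if (what == "topological")
    .partition_modules(result$final_partition) else result$phi
  complex_catalog(sets, min_size = min_size)
}
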