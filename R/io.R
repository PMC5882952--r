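#' Read a PPI network from an edge list or SIF file
#'
#' Edge lists hold two whitespace/tab-separated columns (endpoints) and an
#' optional third column of positive weights. SIF rows are
#' `nodeA relation nodeB [nodeC ...]`, expanded to one edge per trailing
#' node; relation types are ignored. Self-loops and duplicate edges are
#' dropped with a warning.
#'
#' @param path file path.
#' @param weighted logical; read the third column as weight (edge-list
#'   format only).
#' @param format `"auto"` (SIF if the extension is `.sif`), `"edgelist"` or
#'   `"sif"`.
#' @return a [ppi_network()].
#' @export
read_network <- function(path, weighted = FALSE,
                         format = c("auto", "edgelist", "sif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (format == "auto")
    format <- if (grepl("\\.sif$", path, ignore.case = TRUE)) "sif"
              else "edgelist"
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop(sprintf("empty network file: %s", path))
  toks <- strsplit(trimws(lines), "[ \t]+")

  if (format == "edgelist") {
    bad <- which(lengths(toks) < 2)
    if (length(bad) > 0)
      stop(sprintf("malformed edge-list line %d in %s", bad[1], path))
    from <- vapply(toks, `[`, character(1), 1)
    to <- vapply(toks, `[`, character(1), 2)
    if (weighted) {
      w <- vapply(toks, function(t) if (length(t) >= 3) t[3] else "1",
                  character(1))
      wn <- suppressWarnings(as.numeric(w))
      if (anyNA(wn))
        stop(sprintf("non-numeric weight on line %d in %s",
                     which(is.na(wn))[1], path))
      edges <- data.frame(from = from, to = to, weight = wn,
                          stringsAsFactors = FALSE)
    } else {
      edges <- data.frame(from = from, to = to, stringsAsFactors = FALSE)
    }
  } else {
    # SIF: node [relation node node ...]; single-token rows = isolated nodes
    froms <- character(0); tos <- character(0); isolated <- character(0)
    for (i in seq_along(toks)) {
      t <- toks[[i]]
      if (length(t) == 1) { isolated <- c(isolated, t); next }
      if (length(t) == 2)
        stop(sprintf("malformed SIF line %d in %s", i, path))
      froms <- c(froms, rep(t[1], length(t) - 2))
      tos <- c(tos, t[-(1:2)])
    }
    edges <- data.frame(from = froms, to = tos, stringsAsFactors = FALSE)
    return(ppi_network(edges, nodes = isolated, weighted = FALSE))
  }
  ppi_network(edges, weighted = weighted)
}

#' Write a PPI network as an edge list
#'
#' @param network a [ppi_network()].
#' @param path output path. Weighted networks get a third column.
#' @export
write_network <- function(network, path) {
  stopifnot(inherits(network, "ppi_network"))
  e <- network$edges
  lines <- if (network$weighted)
    sprintf("%s\t%s\t%.10g", e$from, e$to, e$weight)
  else sprintf("%s\t%s", e$from, e$to)
  iso <- setdiff(network$nodes, unique(c(e$from, e$to)))
  writeLines(c(lines, iso), path)
  invisible(path)
}

#' Read GO annotations
#'
#' Supports GAF 2.x (`!`-prefixed comment lines skipped; the DB object ID
#' — column 2 — is the protein identifier, column 5 the GO ID, column 7 the
#' evidence code, column 9 the aspect) and a simple two-column tab-separated
#' `term_id<TAB>protein` format. Rows whose evidence code is not in
#' `evidence_filter` are dropped (GAF only). Duplicate (term, protein) rows
#' collapse to a single membership.
#'
#' @param path file path.
#' @param format `"two_column"` or `"gaf"`.
#' @param evidence_filter optional character vector of accepted evidence
#'   codes, e.g. `c("EXP", "IDA", "IPI", "IMP", "IGI", "IEP")`.
#' @return named list term_id -> character vector of proteins, with GAF
#'   aspect preserved in a `categories` attribute (named by term).
#' @export
read_annotations <- function(path, format = c("two_column", "gaf"),
                             evidence_filter = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]

  if (format == "two_column") {
    toks <- strsplit(lines, "\t")
    bad <- which(lengths(toks) < 2)
    if (length(bad) > 0)
      stop(sprintf("malformed two-column line %d in %s", bad[1], path))
    term <- vapply(toks, `[`, character(1), 1)
    prot <- vapply(toks, `[`, character(1), 2)
    aspect <- NULL
  } else {
    lines <- lines[!startsWith(lines, "!")]
    toks <- strsplit(lines, "\t")
    bad <- which(lengths(toks) < 9)
    if (length(bad) > 0)
      stop(sprintf("malformed GAF line %d in %s", bad[1], path))
    prot <- vapply(toks, `[`, character(1), 2)
    term <- vapply(toks, `[`, character(1), 5)
    evidence <- vapply(toks, `[`, character(1), 7)
    aspect <- vapply(toks, `[`, character(1), 9)
    if (!is.null(evidence_filter)) {
      keep <- evidence %in% evidence_filter
      prot <- prot[keep]; term <- term[keep]; aspect <- aspect[keep]
    }
  }
  if (length(term) == 0)
    stop(sprintf("no annotation row survives in %s", path))

  terms <- lapply(split(prot, term), unique)
  if (!is.null(aspect)) {
    cat_map <- c(P = "biological_process", F = "molecular_function",
                 C = "cellular_component")
    asp <- vapply(split(aspect, term), function(a) a[1], character(1))
    categories <- ifelse(asp %in% names(cat_map), cat_map[asp], NA_character_)
    names(categories) <- names(terms)
    attr(terms, "categories") <- categories
  }
  terms
}

#' Write annotations in the two-column format
#'
#' @param terms named list term_id -> protein vector.
#' @param path output path.
#' @export
write_annotations <- function(terms, path) {
  stopifnot(is.list(terms), !is.null(names(terms)))
  term <- rep(names(terms), lengths(terms))
  prot <- unlist(terms, use.names = FALSE)
  writeLines(paste(term, prot, sep = "\t"), path)
  invisible(path)
}

#' Read a complex catalog
#'
#' One complex per line, whitespace-separated protein identifiers, with an
#' optional leading `name<TAB>` field (CYC2008/CORUM-style exports).
#'
#' @param path file path.
#' @param min_size minimum complex size kept (default 2).
#' @return a [complex_catalog()].
#' @export
read_complexes <- function(path, min_size = 2) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (i in seq_along(lines)) {
    ln <- lines[i]
    nm <- NULL
    if (grepl("\t", ln)) {
      parts <- strsplit(ln, "\t")[[1]]
      first_members <- strsplit(trimws(parts[1]), "[ ]+")[[1]]
      if (length(parts) >= 2 && length(first_members) == 1 &&
          length(strsplit(trimws(parts[2]), "[ \t]+")[[1]]) >= 1) {
        nm <- parts[1]
        ln <- paste(parts[-1], collapse = " ")
      }
    }
    members <- strsplit(trimws(ln), "[ \t]+")[[1]]
    sets[[if (is.null(nm)) paste0("complex_", i) else nm]] <- members
  }
  complex_catalog(sets, min_size = min_size)
}

#' Write a complex catalog
#'
#' @param catalog a [complex_catalog()].
#' @param path output path; written as `name<TAB>member member ...`.
#' @export
write_complexes <- function(catalog, path) {
  stopifnot(inherits(catalog, "complex_catalog"))
  writeLines(paste(names(catalog),
                   vapply(catalog, paste, character(1), collapse = " "),
                   sep = "\t"), path)
  invisible(path)
}

#' Write an MTGO result to a directory
#'
#' Emits four tab-separated text files: `modules.tsv` (module, term id/name,
#' members), `membership.tsv` (node, module, whether the node belongs to the
#' module's selected term — the overlapping functional view),
#' `trace.tsv` (per-iteration k, Q, QGO, H) and `run_info.txt` (parameters,
#' seed, package version) so reruns are reproducible.
#'
#' @param result an [run_mtgo()] result.
#' @param out_dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_mtgo_result <- function(result, out_dir) {
  stopifnot(inherits(result, "mtgo_result"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  mods <- .partition_modules(result$final_partition)
  asn <- result$final_assignment

  modules_path <- file.path(out_dir, "modules.tsv")
  df <- data.frame(
    module = asn$module,
    term_id = ifelse(is.na(asn$term_id), "unlabeled", asn$term_id),
    term_name = ifelse(is.na(asn$term_name), "", asn$term_name),
    members = vapply(as.character(asn$module),
                     function(h) paste(sort(mods[[h]]), collapse = " "),
                     character(1)),
    stringsAsFactors = FALSE)
  utils::write.table(df, modules_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  membership_path <- file.path(out_dir, "membership.tsv")
  memb <- data.frame(node = names(result$final_partition),
                     module = as.integer(unclass(result$final_partition)),
                     stringsAsFactors = FALSE)
  memb$in_term <- vapply(seq_len(nrow(memb)), function(i) {
    tid <- asn$term_id[asn$module == memb$module[i]]
    if (length(tid) == 0 || is.na(tid)) return(FALSE)
    memb$node[i] %in% result$phi[[tid]]
  }, logical(1))
  utils::write.table(memb[order(memb$module, memb$node), ],
                     membership_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  trace_path <- file.path(out_dir, "trace.tsv")
  utils::write.table(result$trace, trace_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  info_path <- file.path(out_dir, "run_info.txt")
  p <- result$params
  writeLines(c(
    sprintf("package\tmtgo %s", as.character(utils::packageVersion("mtgo"))),
    sprintf("seed\t%d", p$seed),
    sprintf("min_size\t%d", p$min_size),
    sprintf("max_size\t%d", p$max_size),
    sprintf("threshold\t%g", p$threshold),
    sprintf("max_iterations\t%d", p$max_iterations),
    sprintf("use_weights\t%s", p$use_weights),
    sprintf("converged\t%s", result$converged),
    sprintf("selected_iteration\t%d", result$selected_iteration),
    sprintf("n_go\t%d", result$n_go)
  ), info_path)

  invisible(c(modules = modules_path, membership = membership_path,
              trace = trace_path, info = info_path))
}

#' Read back the modules file written by [write_mtgo_result()]
#'
#' @param path the `modules.tsv` path.
#' @return list with `partition` (named module vector) and `assignment`
#'   (data.frame module, term_id).
#' @export
read_mtgo_modules <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  members <- strsplit(df$members, " ")
  memb <- stats::setNames(rep(df$module, lengths(members)),
                          unlist(members, use.names = FALSE))
  list(partition = memb,
       assignment = df[, c("module", "term_id")])
}
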