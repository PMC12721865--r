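# Similarity scoring and graph-based dereplication.
#
# The pairwise score is the proportion of genes in the smaller
# neighbourhood (fewer genes) that have a reciprocal best hit in the
# larger one. Scores strictly above the user threshold become edges of the
# similarity graph, which is pruned by greedy maximum-degree deletion
# until no edge remains: every surviving pair is at most `threshold`
# similar.

#' Pairwise neighbourhood similarity
#'
#' `|RBH| / min(genes(a), genes(b))`: the proportion of genes in the
#' smaller neighbourhood with a reciprocal best hit in the larger one.
#' Because the RBH set is a matching, the score lies in `[0, 1]`.
#'
#' @param a,b [neighbourhood()] objects with at least one gene each.
#' @param rbh The RBH set for (a, b) from [reciprocal_best_hits()].
#' @return Numeric score in `[0, 1]`.
#' @export
similarity <- function(a, b, rbh) {
  stopifnot(inherits(a, "neighbourhood"), inherits(b, "neighbourhood"))
  m <- min(n_genes(a), n_genes(b))
  if (m < 1L) {
    abort_synsieve("similarity needs neighbourhoods with >= 1 gene",
                   "precondition")
  }
  k <- nrow(rbh)
  if (k > m) {
    abort_synsieve(
      sprintf("RBH count %d exceeds the smaller gene count %d: the matching property was violated upstream", k, m),
      "internal_consistency"
    )
  }
  k / m
}

#' Build the similarity graph
#'
#' All labels become nodes; an edge joins (i, j) iff `score(i, j) >
#' threshold` (strictly greater: a pair *exceeding* the threshold is
#' redundant). All non-zero scores, including sub-threshold ones, are
#' retained for the edge-weight histogram.
#'
#' @param labels Character vector of neighbourhood labels (unique).
#' @param pair_scores `data.frame` with columns `label_i`, `label_j`,
#'   `score` (one row per unordered pair; zero-score pairs may be
#'   omitted).
#' @param threshold Similarity threshold in `(0, 1]`.
#' @return A `similarity_graph`: igraph graph + threshold + the non-zero
#'   score table.
#' @export
build_graph <- function(labels, pair_scores, threshold) {
  if (!is_number(threshold) || threshold <= 0 || threshold > 1) {
    abort_synsieve("threshold must lie in (0, 1]", "validation")
  }
  if (anyDuplicated(labels)) {
    abort_synsieve("labels must be unique", "precondition")
  }
  if (nrow(pair_scores)) {
    bad <- pair_scores$label_i == pair_scores$label_j
    if (any(bad)) abort_synsieve("self-scores are not allowed", "precondition")
  }
  nonzero <- pair_scores[pair_scores$score > 0, , drop = FALSE]
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(labels), name = labels)
  above <- nonzero[nonzero$score > threshold, , drop = FALSE]
  if (nrow(above)) {
    g <- igraph::add_edges(
      g,
      as.vector(rbind(above$label_i, above$label_j)),
      weight = above$score
    )
  }
  structure(
    list(graph = g, threshold = threshold, edge_weights = nonzero),
    class = "similarity_graph"
  )
}

#' @export
print.similarity_graph <- function(x, ...) {
  cat(sprintf("<similarity_graph> %d nodes, %d edges above threshold %.2f\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph),
              x$threshold))
  invisible(x)
}

#' Prune the similarity graph
#'
#' Greedy maximum-degree deletion: while the graph has edges, remove the
#' node of maximal degree (ties: maximal sum of incident edge weights,
#' then lexicographically largest label) together with its edges. The
#' survivors therefore contain no pair whose similarity exceeds the
#' threshold, and removing high-degree hubs first retains as much
#' diversity as possible. Fully deterministic.
#'
#' Each removal records a *trigger neighbour*: the incident neighbour on
#' the heaviest edge (lexicographically smallest on ties) — the
#' neighbourhood most responsible for the removal.
#'
#' @param sg A [build_graph()] result.
#' @return A `sieve_report`: `kept` (lexicographically ordered labels),
#'   `removed` (`data.frame`: label, trigger_neighbour,
#'   degree_at_removal, in removal order) and `edge_weights`.
#' @export
prune <- function(sg) {
  stopifnot(inherits(sg, "similarity_graph"))
  g <- sg$graph
  removed <- list()
  while (igraph::ecount(g) > 0) {
    deg <- igraph::degree(g)
    cand <- names(deg)[deg == max(deg)]
    if (length(cand) > 1L) {
      strength <- igraph::strength(g, vids = cand, weights = igraph::E(g)$weight)
      cand <- names(strength)[strength == max(strength)]
    }
    victim <- sort(cand, decreasing = TRUE)[1]
    inc <- igraph::incident(g, victim)
    w <- igraph::E(g)$weight[as.integer(inc)]
    ends_mat <- igraph::ends(g, inc, names = TRUE)
    others <- ifelse(ends_mat[, 1] == victim, ends_mat[, 2], ends_mat[, 1])
    heaviest <- others[w == max(w)]
    trigger <- sort(heaviest)[1]
    removed[[length(removed) + 1L]] <- data.frame(
      label = victim, trigger_neighbour = trigger,
      degree_at_removal = as.integer(deg[victim]), stringsAsFactors = FALSE
    )
    g <- igraph::delete_vertices(g, victim)
  }
  structure(
    list(
      kept = sort(igraph::V(g)$name),
      removed = if (length(removed)) do.call(rbind, removed) else
        data.frame(label = character(), trigger_neighbour = character(),
                   degree_at_removal = integer(), stringsAsFactors = FALSE),
      edge_weights = sg$edge_weights,
      threshold = sg$threshold
    ),
    class = "sieve_report"
  )
}

#' @export
print.sieve_report <- function(x, ...) {
  cat(sprintf("<sieve_report> kept %d, removed %d (threshold %.2f)\n",
              length(x$kept), nrow(x$removed), x$threshold))
  invisible(x)
}

#' Score every neighbourhood pair
#'
#' Convenience wrapper: runs [all_vs_all()], then
#' [reciprocal_best_hits()] and [similarity()] for each unordered pair.
#'
#' @inheritParams all_vs_all
#' @return `data.frame` with columns `label_i`, `label_j`, `score`,
#'   `n_rbh` (labels ordered so `label_i < label_j`).
#' @export
score_pairs <- function(neighbourhoods, engine = builtin_engine(),
                        max_evalue = 1e-5, min_identity = 50,
                        work_dir = tempfile("synsieve_align_")) {
  hits <- all_vs_all(neighbourhoods, engine, max_evalue, min_identity,
                     work_dir)
  labels <- sort(vapply(neighbourhoods, function(n) n$label, character(1)))
  by_label <- stats::setNames(neighbourhoods,
                              vapply(neighbourhoods, function(n) n$label,
                                     character(1)))
  if (length(labels) < 2L) {
    abort_synsieve("need at least two neighbourhoods", "precondition")
  }
  combos <- utils::combn(labels, 2)
  rows <- lapply(seq_len(ncol(combos)), function(k) {
    a <- combos[1, k]
    b <- combos[2, k]
    rbh <- reciprocal_best_hits(hits, a, b)
    data.frame(
      label_i = a, label_j = b,
      score = similarity(by_label[[a]], by_label[[b]], rbh),
      n_rbh = nrow(rbh), stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Dereplicate a folder of GenBank neighbourhoods
#'
#' Reads every `.gbk`/`.gb`/`.gbff` file under `in_dir`, scores all pairs
#' ([score_pairs()]), builds and prunes the similarity graph, and copies
#' each surviving file byte-identically to `<out_dir>/kept/`. Also writes
#' `sieve_report.csv`, `edge_weights.csv`, the interactive graph HTML and
#' the edge-weight histogram into `out_dir`. Unreadable files are skipped
#' with a warning and counted in the report.
#'
#' @param in_dir Folder of GenBank neighbourhood files (>= 2 readable).
#' @param threshold Similarity above which a pair is redundant (default
#'   `0.7`).
#' @param max_evalue,min_identity Alignment hit filters (see
#'   [all_vs_all()]).
#' @param engine Alignment engine (default [builtin_engine()]).
#' @param out_dir Output folder (created if needed).
#' @return A `sieve_report` with extra elements `kept_paths`, `scores`
#'   and `n_skipped`.
#' @export
sieve <- function(in_dir, threshold = 0.7, max_evalue = 1e-5,
                  min_identity = 50, engine = builtin_engine(), out_dir) {
  if (!is_number(threshold) || threshold <= 0 || threshold > 1) {
    abort_synsieve("threshold must lie in (0, 1]", "validation")
  }
  files <- sort(list.files(in_dir, pattern = GB_EXT_PATTERN,
                           full.names = TRUE))
  nbs <- list()
  paths <- character()
  n_skipped <- 0L
  for (f in files) {
    nb <- tryCatch(read_neighbourhood(f), error = function(e) e)
    if (inherits(nb, "error")) {
      n_skipped <- n_skipped + 1L
      log_line("WARN", "sieve",
               sprintf("skipping unreadable neighbourhood '%s': %s",
                       f, conditionMessage(nb)))
      next
    }
    nbs[[length(nbs) + 1L]] <- nb
    paths[nb$label] <- f
  }
  if (length(nbs) < 2L) {
    abort_synsieve(
      sprintf("'%s' holds %d readable neighbourhood file(s); at least 2 required",
              in_dir, length(nbs)),
      "precondition"
    )
  }
  dir.create(file.path(out_dir, "kept"), recursive = TRUE,
             showWarnings = FALSE)

  scores <- score_pairs(nbs, engine, max_evalue, min_identity,
                        work_dir = file.path(out_dir, "alignment"))
  labels <- sort(vapply(nbs, function(n) n$label, character(1)))
  sg <- build_graph(labels, scores, threshold)
  report <- prune(sg)

  # safety: no surviving pair may exceed the threshold
  surviving <- scores$label_i %in% report$kept &
    scores$label_j %in% report$kept
  if (any(scores$score[surviving] > threshold)) {
    abort_synsieve("pruning left a pair above the threshold",
                   "internal_consistency")
  }

  kept_paths <- character()
  for (lab in report$kept) {
    dest <- file.path(out_dir, "kept", basename(paths[[lab]]))
    file.copy(paths[[lab]], dest, overwrite = TRUE, copy.date = FALSE)
    kept_paths[lab] <- dest
  }

  status <- rbind(
    data.frame(label = report$kept, outcome = "kept",
               trigger_neighbour = "", degree_at_removal = NA_integer_,
               stringsAsFactors = FALSE),
    if (nrow(report$removed)) data.frame(
      label = report$removed$label, outcome = "removed",
      trigger_neighbour = report$removed$trigger_neighbour,
      degree_at_removal = report$removed$degree_at_removal,
      stringsAsFactors = FALSE
    )
  )
  utils::write.csv(status, file.path(out_dir, "sieve_report.csv"),
                   row.names = FALSE)
  utils::write.csv(
    scores[scores$score > 0, c("label_i", "label_j", "score")],
    file.path(out_dir, "edge_weights.csv"), row.names = FALSE
  )

  organisms <- stats::setNames(
    vapply(nbs, function(n) n$organism, character(1)),
    vapply(nbs, function(n) n$label, character(1))
  )
  view <- graph_view(
    labels = labels,
    organisms = unname(organisms[labels]),
    kept = labels %in% report$kept,
    edges = scores[scores$score > threshold,
                   c("label_i", "label_j", "score")],
    threshold = threshold
  )
  write_graph_html(view, file.path(out_dir, "neighbourhood_graph.html"))
  write_edge_histogram(
    scores$score[scores$score > 0],
    file.path(out_dir, "edge_histogram.png"),
    threshold = threshold
  )

  report$kept_paths <- kept_paths
  report$scores <- scores
  report$n_skipped <- n_skipped
  log_line("INFO", "sieve",
           sprintf("kept %d of %d neighbourhoods (threshold %.2f)",
                   length(report$kept), length(nbs), threshold))
  report
}
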