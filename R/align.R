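# All-vs-all protein comparison and reciprocal best hits.
#
# An alignment engine is pluggable: `builtin_engine()` runs a deterministic
# Smith–Waterman in-process; `blast_engine()` / `diamond_engine()` shell out
# to the corresponding binary. Qualified protein ids are
# "<neighbourhoodLabel>::<geneId>" throughout.

# Karlin–Altschul constants for gapped BLOSUM62, gap open 11 / extend 1
# (the standard BLASTP parameterization for this matrix).
KA_LAMBDA <- 0.267
KA_K <- 0.041

#' Built-in deterministic alignment engine
#'
#' Smith–Waterman local alignment (BLOSUM62, gap open 11, gap extend 1)
#' via Biostrings, with bitscores from the standard Karlin–Altschul
#' constants for that matrix and e-values computed against the
#' concatenated subject-set size. Removes any external-binary dependency.
#'
#' @return An engine object for [all_vs_all()].
#' @export
builtin_engine <- function() {
  structure(list(name = "builtin"),
            class = c("synsieve_engine_builtin", "synsieve_engine"))
}

#' BLAST+ blastp alignment engine
#'
#' @param path Path to the `blastp` binary (`makeblastdb` must sit next to
#'   it on `PATH`).
#' @return An engine object for [all_vs_all()].
#' @export
blast_engine <- function(path = "blastp") {
  structure(list(name = "blast", path = path),
            class = c("synsieve_engine_blast", "synsieve_engine"))
}

#' DIAMOND blastp alignment engine
#'
#' @param path Path to the `diamond` binary.
#' @param sensitivity DIAMOND sensitivity flag (without leading dashes).
#' @return An engine object for [all_vs_all()].
#' @export
diamond_engine <- function(path = "diamond",
                           sensitivity = "very-sensitive") {
  structure(list(name = "diamond", path = path, sensitivity = sensitivity),
            class = c("synsieve_engine_diamond", "synsieve_engine"))
}

# Dispatch: every engine maps a protein table (qid, seq) to a data.frame
# (query_id, subject_id, pident, evalue, bitscore), one row per directed
# pair with a local alignment, self rows excluded.
run_engine <- function(engine, proteins, work_dir) {
  UseMethod("run_engine")
}

#' @export
run_engine.synsieve_engine_builtin <- function(engine, proteins, work_dir) {
  mat <- blosum62_matrix()
  n <- nrow(proteins)
  total_len <- sum(nchar(proteins$seq))
  aa <- Biostrings::AAStringSet(proteins$seq)
  names(aa) <- proteins$qid
  rows <- vector("list", n * (n - 1L))
  k <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      aln <- Biostrings::pairwiseAlignment(
        aa[[i]], aa[[j]], type = "local",
        substitutionMatrix = mat, gapOpening = 11, gapExtension = 1
      )
      s <- Biostrings::score(aln)
      if (s <= 0) next
      bit <- (KA_LAMBDA * s - log(KA_K)) / log(2)
      pid <- Biostrings::pid(aln, type = "PID1")
      e_ij <- nchar(proteins$seq[i]) * total_len * 2^(-bit)
      e_ji <- nchar(proteins$seq[j]) * total_len * 2^(-bit)
      k <- k + 1L
      rows[[k]] <- data.frame(
        query_id = c(proteins$qid[i], proteins$qid[j]),
        subject_id = c(proteins$qid[j], proteins$qid[i]),
        pident = pid, evalue = c(e_ij, e_ji), bitscore = bit,
        stringsAsFactors = FALSE
      )
    }
  }
  if (k == 0L) return(empty_hits())
  do.call(rbind, rows[seq_len(k)])
}

#' @export
run_engine.synsieve_engine_blast <- function(engine, proteins, work_dir) {
  faa <- write_protein_fasta(proteins, file.path(work_dir, "proteins.faa"))
  db <- file.path(work_dir, "proteins_db")
  out <- file.path(work_dir, "hits.tsv")
  mkdb <- sub("blastp", "makeblastdb", engine$path, fixed = TRUE)
  invoke_engine(mkdb, c("-in", faa, "-dbtype", "prot", "-out", db),
                work_dir)
  invoke_engine(engine$path, c(
    "-query", faa, "-db", db, "-out", out,
    "-outfmt", shQuote("6 qseqid sseqid pident evalue bitscore"),
    "-evalue", "10", "-max_hsps", "1"
  ), work_dir)
  parse_tabular_hits(out)
}

#' @export
run_engine.synsieve_engine_diamond <- function(engine, proteins, work_dir) {
  faa <- write_protein_fasta(proteins, file.path(work_dir, "proteins.faa"))
  db <- file.path(work_dir, "proteins_db")
  out <- file.path(work_dir, "hits.tsv")
  invoke_engine(engine$path, c("makedb", "--in", faa, "--db", db),
                work_dir)
  invoke_engine(engine$path, c(
    "blastp", "--query", faa, "--db", db, "--out", out,
    "--outfmt", "6", "qseqid", "sseqid", "pident", "evalue", "bitscore",
    paste0("--", engine$sensitivity), "--max-hsps", "1", "--evalue", "10"
  ), work_dir)
  parse_tabular_hits(out)
}

invoke_engine <- function(cmd, args, work_dir) {
  errf <- tempfile("engine_stderr_")
  on.exit(unlink(errf), add = TRUE)
  status <- suppressWarnings(
    system2(cmd, args, stdout = FALSE, stderr = errf)
  )
  if (!identical(status, 0L)) {
    diag <- if (file.exists(errf)) {
      paste(readLines(errf, warn = FALSE), collapse = "; ")
    } else {
      ""
    }
    abort_synsieve(
      sprintf("alignment engine '%s' failed (status %s): %s",
              cmd, status, diag),
      "engine"
    )
  }
  invisible(TRUE)
}

# FASTA headers are the qualified ids; the file stays in the run folder
# for audit alongside the raw tabular hits.
write_protein_fasta <- function(proteins, path) {
  aa <- Biostrings::AAStringSet(proteins$seq)
  names(aa) <- proteins$qid
  Biostrings::writeXStringSet(aa, path)
  path
}

parse_tabular_hits <- function(path) {
  if (!file.exists(path) || file.size(path) == 0) return(empty_hits())
  tab <- utils::read.table(
    path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
    col.names = c("query_id", "subject_id", "pident", "evalue", "bitscore"),
    colClasses = c("character", "character", "numeric", "numeric", "numeric")
  )
  tab <- tab[tab$query_id != tab$subject_id, , drop = FALSE]
  if (nrow(tab) == 0L) return(empty_hits())
  # keep the single best HSP line per directed pair
  ord <- order(tab$query_id, tab$subject_id, -tab$bitscore, -tab$pident)
  tab <- tab[ord, , drop = FALSE]
  tab <- tab[!duplicated(tab[c("query_id", "subject_id")]), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

empty_hits <- function() {
  data.frame(query_id = character(), subject_id = character(),
             pident = numeric(), evalue = numeric(), bitscore = numeric(),
             stringsAsFactors = FALSE)
}

blosum62_matrix <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

# Flatten a list of neighbourhoods into one protein table with qualified
# ids. Errors on duplicated labels or empty neighbourhoods.
protein_table <- function(neighbourhoods) {
  labels <- vapply(neighbourhoods, function(n) n$label, character(1))
  if (anyDuplicated(labels)) {
    abort_synsieve("duplicated neighbourhood labels", "precondition")
  }
  empty <- vapply(neighbourhoods, function(n) nrow(n$genes) == 0L,
                  logical(1))
  if (any(empty)) {
    abort_synsieve(
      sprintf("neighbourhood(s) with zero genes: %s",
              paste(labels[empty], collapse = ", ")),
      "precondition"
    )
  }
  do.call(rbind, lapply(neighbourhoods, function(n) {
    data.frame(
      qid = paste0(n$label, "::", n$genes$gene_id),
      label = n$label,
      gene_id = n$genes$gene_id,
      seq = n$genes$translation,
      stringsAsFactors = FALSE
    )
  }))
}

#' All-vs-all protein comparison across neighbourhoods
#'
#' Runs the alignment engine over every protein pair, then filters to
#' hits with `evalue <= max_evalue` and `pident >= min_identity`,
#' excludes same-neighbourhood comparisons, and returns the hits in a
#' deterministic order (query id, then subject id).
#'
#' @param neighbourhoods List of [neighbourhood()] objects (>= 2, each with
#'   at least one gene).
#' @param engine An engine from [builtin_engine()], [blast_engine()] or
#'   [diamond_engine()].
#' @param max_evalue Maximum e-value for a hit to pass (default `1e-5`).
#' @param min_identity Minimum percent identity (default `50`).
#' @param work_dir Folder where the engine's FASTA and raw tabular output
#'   are kept for audit.
#' @return A `data.frame` with columns `query_id`, `subject_id`,
#'   `query_label`, `subject_label`, `pident`, `evalue`, `bitscore`.
#' @export
all_vs_all <- function(neighbourhoods, engine = builtin_engine(),
                       max_evalue = 1e-5, min_identity = 50,
                       work_dir = tempfile("synsieve_align_")) {
  if (length(neighbourhoods) < 2L) {
    abort_synsieve("need at least two neighbourhoods", "precondition")
  }
  dir.create(work_dir, recursive = TRUE, showWarnings = FALSE)
  proteins <- protein_table(neighbourhoods)
  hits <- run_engine(engine, proteins, work_dir)
  lab <- stats::setNames(proteins$label, proteins$qid)
  hits$query_label <- unname(lab[hits$query_id])
  hits$subject_label <- unname(lab[hits$subject_id])
  if (anyNA(hits$query_label) || anyNA(hits$subject_label)) {
    abort_synsieve("engine returned ids not present in the input set",
                   "engine")
  }
  hits <- hits[
    hits$query_label != hits$subject_label &
      hits$evalue <= max_evalue &
      hits$pident >= min_identity, ,
    drop = FALSE
  ]
  hits <- hits[order(hits$query_id, hits$subject_id), , drop = FALSE]
  rownames(hits) <- NULL
  hits[c("query_id", "subject_id", "query_label", "subject_label",
         "pident", "evalue", "bitscore")]
}

#' Best hit per query gene, one direction
#'
#' For each gene of neighbourhood `a_label`, the subject gene in
#' `b_label` with maximal bitscore; ties broken by higher percent
#' identity, then by lexicographically smallest subject id. Genes with no
#' passing hit are absent.
#'
#' @param hits Output of [all_vs_all()].
#' @param a_label,b_label Neighbourhood labels (direction A -> B).
#' @return Named character vector: query id -> subject id.
#' @export
best_hits <- function(hits, a_label, b_label) {
  h <- hits[hits$query_label == a_label & hits$subject_label == b_label, ,
            drop = FALSE]
  if (nrow(h) == 0L) return(stats::setNames(character(), character()))
  ord <- order(h$query_id, -h$bitscore, -h$pident, h$subject_id)
  h <- h[ord, , drop = FALSE]
  h <- h[!duplicated(h$query_id), , drop = FALSE]
  stats::setNames(h$subject_id, h$query_id)
}

#' Reciprocal best hits between two neighbourhoods
#'
#' A pair (a, b) is reported iff b is a's best hit in B and a is b's best
#' hit in A. By construction the result is a partial matching: no gene id
#' appears twice. Labels are ordered so `gene_a` comes from the
#' lexicographically smaller label.
#'
#' @param hits Output of [all_vs_all()].
#' @param a_label,b_label The two neighbourhood labels.
#' @return `data.frame` with columns `gene_a`, `gene_b` (qualified ids),
#'   sorted by `gene_a`.
#' @export
reciprocal_best_hits <- function(hits, a_label, b_label) {
  if (a_label > b_label) {
    tmp <- a_label
    a_label <- b_label
    b_label <- tmp
  }
  fwd <- best_hits(hits, a_label, b_label)
  rev <- best_hits(hits, b_label, a_label)
  keep <- names(fwd)[!is.na(rev[fwd]) & rev[fwd] == names(fwd)]
  out <- data.frame(
    gene_a = keep,
    gene_b = unname(fwd[keep]),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$gene_a), , drop = FALSE]
  rownames(out) <- NULL
  out
}
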