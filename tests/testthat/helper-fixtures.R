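# Shared test helpers: in-code GenBank builders, random neighbourhoods,
# random score matrices on a dyadic grid, and an independent re-
# implementation of the greedy pruning rules used as an oracle.

# Build raw GenBank text for parser tests, with full control over the
# feature lines (so malformed/edge-case inputs can be constructed).
gbk_text <- function(sequence, feature_lines, organism = "Testus exampli",
                     accession = "TEST_1", locus_length = NULL) {
  len <- if (is.null(locus_length)) nchar(sequence) else locus_length
  seq_lines <- vapply(seq(1, nchar(sequence), by = 60), function(s) {
    chunk <- tolower(substr(sequence, s, min(s + 59, nchar(sequence))))
    groups <- substring(chunk, seq(1, nchar(chunk), 10),
                        pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    sprintf("%9d %s", s, paste(groups, collapse = " "))
  }, character(1))
  c(
    sprintf("LOCUS       %-16s %11d bp    DNA     linear   BCT 01-JAN-1980",
            accession, len),
    sprintf("ACCESSION   %s", accession),
    sprintf("SOURCE      %s", organism),
    sprintf("  ORGANISM  %s", organism),
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", nchar(sequence)),
    sprintf('                     /organism="%s"', organism),
    feature_lines,
    "ORIGIN",
    seq_lines,
    "//"
  )
}

write_gbk <- function(lines, dir = NULL, name = "test.gbk") {
  if (is.null(dir)) {
    dir <- tempfile("gbkdir")
    dir.create(dir)
  }
  path <- file.path(dir, name)
  writeLines(lines, path)
  path
}

# Access the internal raw-record parser (used to cross-check slicing).
read_genbank_record_for_test <- function(path) {
  synsieve:::read_genbank_record(path)
}

# A CDS feature block with a literal translation qualifier.
cds_lines <- function(start1, end1, strand = 1L, translation = NULL,
                      locus_tag = NULL, protein_id = NULL) {
  loc <- sprintf("%d..%d", start1, end1)
  if (strand == -1L) loc <- sprintf("complement(%s)", loc)
  out <- sprintf("     CDS             %s", loc)
  if (!is.null(protein_id)) {
    out <- c(out, sprintf('                     /protein_id="%s"', protein_id))
  }
  if (!is.null(locus_tag)) {
    out <- c(out, sprintf('                     /locus_tag="%s"', locus_tag))
  }
  if (!is.null(translation)) {
    text <- sprintf('/translation="%s"', translation)
    starts <- seq(1, nchar(text), by = 58)
    wrapped <- substring(text, starts, pmin(starts + 57, nchar(text)))
    out <- c(out, paste0(strrep(" ", 21), wrapped))
  }
  out
}

# Random in-memory neighbourhood for round-trip properties.
random_neighbourhood <- function(label = "rt", n_genes = NULL) {
  if (is.null(n_genes)) n_genes <- sample(1:6, 1)
  rows <- list()
  pos <- sample(0:40, 1)
  chunks <- strrep("A", pos)
  for (j in seq_len(n_genes)) {
    len_aa <- sample(30:80, 1)
    prot <- generate_family(len_aa)
    nt <- paste0(
      paste(c(A = "GCA", C = "TGC", D = "GAC", E = "GAA", F = "TTC",
              G = "GGA", H = "CAC", I = "ATC", K = "AAA", L = "CTG",
              M = "ATG", N = "AAC", P = "CCA", Q = "CAA", R = "AGA",
              S = "AGC", T = "ACA", V = "GTA", W = "TGG", Y = "TAC"
      )[strsplit(prot, "")[[1]]], collapse = ""),
      "TAA"
    )
    strand <- sample(c(1L, -1L), 1)
    placed <- if (strand == -1L) {
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(nt)))
    } else {
      nt
    }
    rows[[j]] <- data.frame(
      gene_id = sprintf("g%02d", j), start = pos, end = pos + nchar(nt),
      strand = strand, translation = prot, stringsAsFactors = FALSE
    )
    chunks <- c(chunks, placed)
    pos <- pos + nchar(nt) + 25L
    chunks <- c(chunks, strrep("A", 25L))
  }
  neighbourhood(
    source_accession = paste0("ACC_", label),
    organism = paste("Testus", label),
    sequence = paste(chunks, collapse = ""),
    genes = do.call(rbind, rows),
    label = label
  )
}

# Random symmetric score matrix on a dyadic grid (k/64), so that sums of
# edge weights are exact in floating point and tie-breaks are
# implementation-order independent.
random_score_matrix <- function(n, p_edge = 0.6) {
  labs <- sprintf("n%02d", seq_len(n))
  S <- matrix(0, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      if (stats::runif(1) < p_edge) {
        s <- sample.int(64, 1) / 64
        S[i, j] <- S[j, i] <- s
      }
    }
  }
  S
}

matrix_to_pair_scores <- function(S) {
  labs <- rownames(S)
  n <- length(labs)
  rows <- list()
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      rows[[length(rows) + 1L]] <- data.frame(
        label_i = labs[i], label_j = labs[j], score = S[i, j],
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

# Independent oracle: a literal, matrix-based transcription of the greedy
# pruning rules (max degree; ties by incident weight sum; ties by
# lexicographically largest label), kept deliberately separate from the
# igraph-based implementation in the package.
oracle_prune <- function(S, threshold) {
  alive <- rownames(S)
  removed <- character()
  repeat {
    A <- S[alive, alive, drop = FALSE] > threshold
    diag(A) <- FALSE
    if (!any(A)) break
    deg <- rowSums(A)
    cand <- alive[deg == max(deg)]
    if (length(cand) > 1) {
      W <- S[alive, alive, drop = FALSE] * A
      st <- rowSums(W)
      cand <- cand[st[cand] == max(st[cand])]
    }
    victim <- sort(cand, decreasing = TRUE)[1]
    removed <- c(removed, victim)
    alive <- setdiff(alive, victim)
  }
  list(kept = sort(alive), removed = removed)
}

# Standard 4-neighbourhood study set: three near-identical copies of one
# 5-family plan plus one unrelated 3-family plan.
study_fixture_spec <- function(seed = 101L, substitution_rate = 0.02) {
  family_spec(
    n_families = 8,
    plans = list(
      copy1 = 1:5, copy2 = 1:5, copy3 = 1:5,
      outsider = 6:8
    ),
    family_length = 100,
    substitution_rate = substitution_rate,
    seed = seed
  )
}
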