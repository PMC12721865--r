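# Synthetic neighbourhood generator.
#
# Neighbourhoods are assembled from "ancestral" protein families: every
# gene is a (lightly mutated) copy of a family sequence, so the expected
# RBH count between two neighbourhoods is the number of families they
# share, and the expected similarity score is shared / min(gene count).
# That makes every pipeline stage testable offline with known answers.

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Generate an ancestral protein family sequence
#'
#' Uniform-random sequence over the 20 standard residues, drawn from R's
#' current RNG stream (seed it for determinism).
#'
#' @param length Number of residues; at least 30 (shorter sequences make
#'   local-alignment behaviour unstable).
#' @return Character scalar amino-acid sequence.
#' @export
generate_family <- function(length) {
  if (!is_number(length) || length < 30) {
    abort_synsieve("family length must be >= 30 residues", "precondition")
  }
  paste(sample(AA_ALPHABET, length, replace = TRUE), collapse = "")
}

#' Mutate a protein sequence
#'
#' Each position is independently replaced by a uniformly chosen
#' *different* residue with probability `rate`, so the expected identity
#' to the input is `100 * (1 - rate)` percent.
#'
#' @param seq Amino-acid sequence.
#' @param rate Per-residue substitution probability in `[0, 1)`.
#' @return Mutated sequence.
#' @export
mutate_protein <- function(seq, rate) {
  stopifnot(is_number(rate), rate >= 0, rate < 1)
  if (rate == 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  hit <- stats::runif(length(chars)) < rate
  for (i in which(hit)) {
    chars[i] <- sample(setdiff(AA_ALPHABET, chars[i]), 1)
  }
  paste(chars, collapse = "")
}

# Fixed codon per residue: the lexicographically first table-11 codon, so
# back-translation (and hence the generated files) is deterministic.
backtranslate_codons <- function() {
  gc <- Biostrings::getGeneticCode("11")
  vapply(AA_ALPHABET, function(aa) sort(names(gc)[gc == aa])[1],
         character(1))
}

backtranslate <- function(seq) {
  codons <- backtranslate_codons()
  paste(codons[strsplit(seq, "")[[1]]], collapse = "")
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Specify a synthetic neighbourhood set
#'
#' @param n_families Number of ancestral protein families.
#' @param plans Named list: one entry per neighbourhood (name = label),
#'   each an integer vector of family indices in `1..n_families` (gene
#'   order), optionally with a `strands` attribute (`+1`/`-1` per gene;
#'   default all `+1`).
#' @param family_length Residues per family (default 100).
#' @param substitution_rate Per-residue substitution probability applied
#'   to every gene copy (default 0.02, i.e. ~98% identity between copies
#'   of one family).
#' @param seed RNG seed making the whole set reproducible.
#' @return A `family_spec` object for [build_neighbourhood_set()].
#' @export
family_spec <- function(n_families, plans, family_length = 100,
                        substitution_rate = 0.02, seed = 1L) {
  stopifnot(is_number(n_families), n_families >= 1,
            is.list(plans), length(names(plans)) == length(plans),
            is_number(substitution_rate),
            substitution_rate >= 0, substitution_rate < 1)
  for (lab in names(plans)) {
    idx <- as.integer(plans[[lab]])
    if (length(idx) && (any(idx < 1L) || any(idx > n_families))) {
      abort_synsieve(
        sprintf("plan '%s' references a family outside 1..%d",
                lab, n_families),
        "precondition"
      )
    }
  }
  structure(
    list(n_families = as.integer(n_families), plans = plans,
         family_length = as.integer(family_length),
         substitution_rate = substitution_rate, seed = as.integer(seed)),
    class = "family_spec"
  )
}

#' Build a synthetic neighbourhood set on disk
#'
#' Writes one GenBank file per planned neighbourhood into `out_dir`.
#' Genes are laid head-to-tail with 50 nt `A`-run spacers; each CDS is
#' the codon-wise back-translation of its (mutated) family protein plus a
#' TAA stop. A `manifest.json` records, for every neighbourhood pair, the
#' expected RBH count (shared families) and expected similarity score
#' (shared / min gene count) under the generator's construction.
#' Regenerating with the same spec yields byte-identical files.
#'
#' @param spec A [family_spec()].
#' @param out_dir Output directory (created if needed).
#' @return The manifest, invisibly the same as what `manifest.json`
#'   contains: `neighbourhoods` (label, n genes, families) and
#'   `expected_pairs` (label_i, label_j, expected_rbh, expected_score).
#' @export
build_neighbourhood_set <- function(spec, out_dir) {
  stopifnot(inherits(spec, "family_spec"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(spec$seed)
  families <- replicate(spec$n_families,
                        generate_family(spec$family_length))
  labels <- names(spec$plans)
  for (lab in labels) {
    idx <- as.integer(spec$plans[[lab]])
    strands <- attr(spec$plans[[lab]], "strands")
    if (is.null(strands)) strands <- rep(1L, length(idx))
    stopifnot(length(strands) == length(idx))
    chunks <- character()
    rows <- list()
    pos <- 0L
    for (j in seq_along(idx)) {
      chunks <- c(chunks, strrep("A", 50L))
      pos <- pos + 50L
      prot <- mutate_protein(families[[idx[j]]], spec$substitution_rate)
      nt <- paste0(backtranslate(prot), "TAA")
      placed <- if (strands[j] == -1L) revcomp_chr(nt) else nt
      rows[[j]] <- data.frame(
        gene_id = sprintf("gene%02d_fam%02d", j, idx[j]),
        start = pos, end = pos + nchar(nt),
        strand = as.integer(strands[j]), translation = prot,
        stringsAsFactors = FALSE
      )
      chunks <- c(chunks, placed)
      pos <- pos + nchar(nt)
    }
    chunks <- c(chunks, strrep("A", 50L))
    nb <- neighbourhood(
      source_accession = paste0("SYN_", lab),
      organism = sprintf("Synthetica exempli %s", lab),
      sequence = paste(chunks, collapse = ""),
      genes = if (length(rows)) do.call(rbind, rows) else data.frame(
        gene_id = character(), start = integer(), end = integer(),
        strand = integer(), translation = character(),
        stringsAsFactors = FALSE
      ),
      label = lab
    )
    write_neighbourhood(nb, out_dir)
  }

  pair_rows <- list()
  if (length(labels) >= 2L) {
    combos <- utils::combn(sort(labels), 2)
    for (k in seq_len(ncol(combos))) {
      a <- combos[1, k]
      b <- combos[2, k]
      fa <- as.integer(spec$plans[[a]])
      fb <- as.integer(spec$plans[[b]])
      shared <- length(intersect(fa, fb))
      pair_rows[[k]] <- data.frame(
        label_i = a, label_j = b, expected_rbh = shared,
        expected_score = if (min(length(fa), length(fb)) > 0)
          shared / min(length(fa), length(fb)) else 0,
        stringsAsFactors = FALSE
      )
    }
  }
  manifest <- list(
    seed = spec$seed,
    substitution_rate = spec$substitution_rate,
    neighbourhoods = data.frame(
      label = labels,
      n_genes = vapply(spec$plans, length, integer(1)),
      stringsAsFactors = FALSE
    ),
    expected_pairs = if (length(pair_rows)) do.call(rbind, pair_rows) else
      data.frame(label_i = character(), label_j = character(),
                 expected_rbh = integer(), expected_score = numeric(),
                 stringsAsFactors = FALSE)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest
}

#' Write a toy cblaster binary table for a folder of records
#'
#' Scans `records_dir` for GenBank files and emits one CSV row per
#' record, with the hit interval spanning the record's genes (1-based
#' inclusive, as cblaster prints) and a fixed score. Used to exercise the
#' collect stage against local fixtures.
#'
#' @param records_dir Folder of GenBank records.
#' @param path Output CSV path.
#' @return `path`.
#' @export
write_toy_binary <- function(records_dir, path) {
  files <- sort(list.files(records_dir, pattern = GB_EXT_PATTERN,
                           full.names = TRUE))
  rows <- lapply(files, function(f) {
    rec <- read_genbank_record(f)
    acc <- sub(GB_EXT_PATTERN, "", basename(f))
    g <- rec$genes
    if (nrow(g)) {
      data.frame(
        Organism = rec$organism, Scaffold = acc,
        Start = min(g$start) + 1L, End = max(g$end),
        Score = 50, Query1 = nrow(g), stringsAsFactors = FALSE
      )
    }
  })
  tab <- do.call(rbind, Filter(Negate(is.null), rows))
  utils::write.csv(tab, path, row.names = FALSE, quote = TRUE)
  path
}
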