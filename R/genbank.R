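# GenBank neighbourhood I/O.
#
# Coordinate convention: GenBank files are 1-based inclusive on disk; every
# internal coordinate in this package is 0-based half-open. The conversion
# happens here, at the I/O boundary, and nowhere else.

GB_EXT_PATTERN <- "\\.(gbk|gb|gbff)$"

#' Construct a neighbourhood object
#'
#' A neighbourhood is an annotated genomic interval: a nucleotide sequence
#' plus an ordered table of protein-coding genes. Gene coordinates are
#' 0-based half-open offsets into `sequence`; strand is `+1`/`-1`;
#' translations are uppercase amino-acid strings without a trailing stop.
#'
#' @param source_accession Accession of the record the interval came from.
#' @param organism Organism name (free text).
#' @param sequence Nucleotide sequence of the interval.
#' @param genes `data.frame` with columns `gene_id`, `start`, `end`,
#'   `strand`, `translation`. Rows are sorted by `start` (ties: `end`,
#'   then `gene_id`).
#' @param label File stem used for naming and as the graph node id.
#' @param contig_offset 0-based start of the interval on its source record.
#' @return An object of class `neighbourhood`.
#' @export
neighbourhood <- function(source_accession, organism, sequence, genes,
                          label, contig_offset = 0L) {
  genes <- validate_gene_table(genes, nchar(sequence))
  structure(
    list(
      source_accession = source_accession,
      organism = organism,
      contig_offset = as.integer(contig_offset),
      sequence = toupper(sequence),
      genes = genes,
      label = label
    ),
    class = "neighbourhood"
  )
}

#' @export
print.neighbourhood <- function(x, ...) {
  cat(sprintf("<neighbourhood> %s: %d bp, %d genes (%s)\n",
              x$label, nchar(x$sequence), nrow(x$genes), x$organism))
  invisible(x)
}

#' Number of genes in a neighbourhood
#' @param n A `neighbourhood`.
#' @return Integer gene count.
#' @export
n_genes <- function(n) nrow(n$genes)

# Sort by (start, end, gene_id) and enforce the invariants of the gene table.
validate_gene_table <- function(genes, seq_len) {
  needed <- c("gene_id", "start", "end", "strand", "translation")
  if (!all(needed %in% names(genes))) {
    abort_synsieve(
      paste0("gene table must have columns: ", paste(needed, collapse = ", ")),
      "format"
    )
  }
  genes <- genes[needed]
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)
  genes$strand <- as.integer(genes$strand)
  if (nrow(genes)) {
    if (any(genes$start >= genes$end)) {
      abort_synsieve("gene with start >= end", "format")
    }
    if (any(genes$start < 0L) || any(genes$end > seq_len)) {
      abort_synsieve("gene interval outside the neighbourhood sequence",
                     "format")
    }
    if (!all(genes$strand %in% c(1L, -1L))) {
      abort_synsieve("gene strand must be +1 or -1", "format")
    }
    if (anyDuplicated(genes$gene_id)) {
      abort_synsieve("duplicated gene_id within one neighbourhood", "format")
    }
    if (any(!nzchar(genes$translation))) {
      abort_synsieve("empty translation", "format")
    }
    genes <- genes[order(genes$start, genes$end, genes$gene_id), ,
                   drop = FALSE]
  }
  rownames(genes) <- NULL
  genes
}

#' Make a filesystem-safe label
#'
#' Replaces every character outside `[A-Za-z0-9._-]` with `_`, collapses
#' runs of `_`, and trims leading/trailing `_`. Idempotent.
#'
#' @param raw Non-empty character scalar (an accession or organism name).
#' @return Sanitized label.
#' @export
#' @examples
#' sanitize_label("Streptomyces coelicolor A3(2)")
sanitize_label <- function(raw) {
  if (!is_string(raw) || !nzchar(raw)) {
    abort_synsieve("label must be a non-empty string", "invalid_name")
  }
  x <- gsub("[^A-Za-z0-9._-]", "_", raw)
  x <- gsub("_+", "_", x)
  x <- gsub("^_+|_+$", "", x)
  if (!nzchar(x)) {
    abort_synsieve(
      sprintf("label '%s' contains no usable characters", raw),
      "invalid_name"
    )
  }
  x
}

# ---------------------------------------------------------------------------
# Reading

#' Read a GenBank neighbourhood file
#'
#' Parses a single-record GenBank flat file into a [neighbourhood()]. One
#' gene is produced per CDS feature. A CDS without a `/translation`
#' qualifier is translated from its nucleotide span with translation table
#' 11 when the span length is a multiple of 3 (trailing stop stripped),
#' otherwise it is skipped with a logged warning. Gene ids come from the
#' first available of `protein_id`, `locus_tag`, else `cds_<ordinal>`.
#' Non-CDS features (tRNA, rRNA, ...) are ignored: the downstream
#' similarity score is protein-based.
#'
#' @param path Path to a `.gbk`/`.gb`/`.gbff` file.
#' @return A `neighbourhood`; its `label` is the file stem.
#' @export
read_neighbourhood <- function(path) {
  rec <- read_genbank_record(path)
  if (nrow(rec$genes) == 0L) {
    abort_synsieve(
      sprintf("no scorable CDS features in '%s'", path),
      "empty_neighbourhood"
    )
  }
  neighbourhood(
    source_accession = rec$accession,
    organism = rec$organism,
    sequence = rec$sequence,
    genes = rec$genes,
    label = sub(GB_EXT_PATTERN, "", basename(path)),
    contig_offset = rec$region_offset
  )
}

# Parse a single-record GenBank flat file into its raw components.
# Used both by read_neighbourhood() and by the record fetchers.
read_genbank_record <- function(path) {
  if (!file.exists(path)) {
    abort_synsieve(sprintf("no such file: '%s'", path), "io")
  }
  lines <- readLines(path, warn = FALSE)
  locus_i <- grep("^LOCUS", lines)
  if (length(locus_i) == 0L) {
    abort_synsieve(sprintf("not a GenBank flat file: '%s'", path), "format")
  }
  locus_fields <- strsplit(trimws(lines[locus_i[1]]), "[[:space:]]+")[[1]]
  locus_name <- if (length(locus_fields) >= 2) locus_fields[2] else ""
  bp_i <- which(locus_fields == "bp")
  locus_length <- if (length(bp_i) && bp_i[1] > 1) {
    suppressWarnings(as.integer(locus_fields[bp_i[1] - 1]))
  } else {
    NA_integer_
  }

  feat_i <- grep("^FEATURES", lines)
  origin_i <- grep("^ORIGIN", lines)
  end_i <- grep("^//", lines)
  if (length(origin_i) == 0L) {
    abort_synsieve(sprintf("no ORIGIN section in '%s'", path), "format")
  }
  origin_i <- origin_i[1]
  stop_i <- if (length(end_i)) end_i[end_i > origin_i][1] else NA_integer_
  if (is.na(stop_i)) stop_i <- length(lines) + 1L

  seq_lines <- lines[seq.int(origin_i + 1L, stop_i - 1L)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (!nzchar(sequence)) {
    abort_synsieve(sprintf("empty sequence in '%s'", path), "format")
  }

  accession <- locus_name
  region_offset <- 0L
  acc_line <- grep("^ACCESSION", lines, value = TRUE)
  if (length(acc_line)) {
    acc <- strsplit(trimws(acc_line[1]), "[[:space:]]+")[[1]]
    if (length(acc) >= 2 && acc[2] != ".") accession <- acc[2]
    region <- regmatches(acc_line[1],
                         regexpr("REGION: [0-9]+\\.\\.[0-9]+", acc_line[1]))
    if (length(region)) {
      region_offset <- as.integer(sub("REGION: ([0-9]+)\\.\\..*", "\\1",
                                      region)) - 1L
    }
  }
  ver_line <- grep("^VERSION", lines, value = TRUE)
  if (length(ver_line)) {
    ver <- strsplit(trimws(ver_line[1]), "[[:space:]]+")[[1]]
    if (length(ver) >= 2 && ver[2] != ".") accession <- ver[2]
  }

  organism <- NA_character_
  org_i <- grep("^  ORGANISM", lines)
  if (length(org_i)) organism <- trimws(sub("^  ORGANISM", "", lines[org_i[1]]))

  features <- if (length(feat_i)) {
    parse_feature_table(lines[seq.int(feat_i[1] + 1L, origin_i - 1L)])
  } else {
    list()
  }

  if (is.na(organism) || !nzchar(organism)) {
    src <- Filter(function(f) f$key == "source", features)
    if (length(src) && !is.null(src[[1]]$qualifiers$organism)) {
      organism <- src[[1]]$qualifiers$organism
    } else {
      organism <- "unknown organism"
    }
  }

  genes <- features_to_genes(features, sequence, path)
  list(
    locus_name = locus_name,
    locus_length = locus_length,
    accession = accession,
    organism = organism,
    sequence = sequence,
    genes = genes,
    region_offset = region_offset
  )
}

# Split the FEATURES block into features; each is a key, a location string
# (possibly wrapped over several lines) and a named qualifier list.
parse_feature_table <- function(lines) {
  features <- list()
  cur <- NULL
  qual_key <- NULL
  for (line in lines) {
    if (!nzchar(trimws(line))) next
    key_field <- substr(line, 1, 20)
    content <- trimws(substr(line, 21, nchar(line)))
    if (nzchar(trimws(key_field)) && !startsWith(trimws(line), "/")) {
      # new feature
      if (!is.null(cur)) features[[length(features) + 1L]] <- cur
      cur <- list(key = trimws(key_field), location = content,
                  qualifiers = list())
      qual_key <- NULL
    } else if (is.null(cur)) {
      next
    } else if (startsWith(content, "/")) {
      eq <- regexpr("=", content, fixed = TRUE)
      if (eq > 0) {
        qual_key <- substr(content, 2, eq - 1)
        val <- substr(content, eq + 1, nchar(content))
        cur$qualifiers[[qual_key]] <- val
      } else {
        qual_key <- substring(content, 2)
        cur$qualifiers[[qual_key]] <- ""
      }
    } else if (!is.null(qual_key)) {
      # continuation of a (possibly wrapped) qualifier value
      sep <- if (identical(qual_key, "translation")) "" else " "
      cur$qualifiers[[qual_key]] <-
        paste(cur$qualifiers[[qual_key]], content, sep = sep)
    } else {
      # continuation of the location
      cur$location <- paste0(cur$location, content)
    }
  }
  if (!is.null(cur)) features[[length(features) + 1L]] <- cur
  for (i in seq_along(features)) {
    features[[i]]$qualifiers <- lapply(features[[i]]$qualifiers, strip_quotes)
  }
  features
}

strip_quotes <- function(x) gsub('^"|"$', "", x)

# Parse a GenBank location into outer 0-based half-open span + exon list.
# Handles complement(...), join(...)/order(...), per-exon complement, and
# partial markers (< >). Returns NULL for locations we cannot interpret.
parse_location <- function(loc) {
  loc <- gsub("[[:space:]<>]", "", loc)
  strand <- 1L
  if (grepl("^complement\\(", loc)) {
    strand <- -1L
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^(join|order)\\(", loc)) {
    loc <- sub("^(join|order)\\((.*)\\)$", "\\2", loc)
  }
  parts <- strsplit(loc, ",", fixed = TRUE)[[1]]
  exons <- lapply(parts, function(p) {
    s <- 1L
    if (grepl("^complement\\(", p)) {
      s <- -1L
      p <- sub("^complement\\((.*)\\)$", "\\1", p)
    }
    if (grepl("^[0-9]+\\.\\.[0-9]+$", p)) {
      ab <- as.integer(strsplit(p, "..", fixed = TRUE)[[1]])
    } else if (grepl("^[0-9]+$", p)) {
      ab <- c(as.integer(p), as.integer(p))
    } else {
      return(NULL)
    }
    list(start = ab[1] - 1L, end = ab[2], strand = s)
  })
  if (any(vapply(exons, is.null, logical(1)))) return(NULL)
  if (any(vapply(exons, function(e) e$strand, integer(1)) == -1L)) {
    strand <- -1L
  }
  starts <- vapply(exons, function(e) e$start, integer(1))
  ends <- vapply(exons, function(e) e$end, integer(1))
  list(start = min(starts), end = max(ends), strand = strand, exons = exons)
}

# Reduce the parsed features to the CDS gene table.
features_to_genes <- function(features, sequence, path) {
  rows <- list()
  ordinal <- 0L
  seen_ids <- character()
  for (f in features) {
    if (f$key != "CDS") next
    ordinal <- ordinal + 1L
    loc <- parse_location(f$location)
    if (is.null(loc)) {
      log_line("WARN", "read_neighbourhood",
               sprintf("%s: CDS %d has unsupported location '%s'; skipped",
                       path, ordinal, f$location))
      next
    }
    if (loc$end > nchar(sequence)) {
      log_line("WARN", "read_neighbourhood",
               sprintf("%s: CDS %d extends past the sequence; skipped",
                       path, ordinal))
      next
    }
    q <- f$qualifiers
    translation <- q$translation
    if (is.null(translation) || !nzchar(translation)) {
      translation <- translate_span(sequence, loc)
      if (is.null(translation)) {
        log_line("WARN", "read_neighbourhood",
                 sprintf(paste0("%s: CDS %d has no /translation and its span",
                                " is not a multiple of 3; skipped"),
                         path, ordinal))
        next
      }
    }
    translation <- toupper(sub("\\*$", "", translation))
    gene_id <- q$protein_id
    if (is.null(gene_id) || !nzchar(gene_id)) gene_id <- q$locus_tag
    if (is.null(gene_id) || !nzchar(gene_id)) {
      gene_id <- sprintf("cds_%d", ordinal)
    }
    if (gene_id %in% seen_ids) {
      k <- 1L
      while (sprintf("%s_%d", gene_id, k) %in% seen_ids) k <- k + 1L
      new_id <- sprintf("%s_%d", gene_id, k)
      log_line("WARN", "read_neighbourhood",
               sprintf("%s: duplicate gene id '%s' renamed to '%s'",
                       path, gene_id, new_id))
      gene_id <- new_id
    }
    seen_ids <- c(seen_ids, gene_id)
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = gene_id, start = loc$start, end = loc$end,
      strand = loc$strand, translation = translation,
      stringsAsFactors = FALSE
    )
  }
  genes <- if (length(rows)) do.call(rbind, rows) else data.frame(
    gene_id = character(), start = integer(), end = integer(),
    strand = integer(), translation = character(), stringsAsFactors = FALSE
  )
  if (nrow(genes)) {
    genes <- genes[order(genes$start, genes$end, genes$gene_id), ,
                   drop = FALSE]
    rownames(genes) <- NULL
  }
  genes
}

# Translate the (joined) exon sequence with table 11, or NULL when the
# coding span is not a multiple of 3. Trailing stop handling is the
# caller's job.
translate_span <- function(sequence, loc) {
  parts <- vapply(
    loc$exons,
    function(e) substr(sequence, e$start + 1L, e$end),
    character(1)
  )
  nt <- paste(parts, collapse = "")
  if (nchar(nt) %% 3L != 0L) return(NULL)
  dna <- Biostrings::DNAString(nt)
  if (loc$strand == -1L) dna <- Biostrings::reverseComplement(dna)
  aa <- Biostrings::translate(
    dna,
    genetic.code = Biostrings::getGeneticCode("11"),
    if.fuzzy.codon = "X"
  )
  as.character(aa)
}

# ---------------------------------------------------------------------------
# Writing

#' Write a neighbourhood as a GenBank file
#'
#' Serializes a [neighbourhood()] to `<directory>/<label>.gbk` as a
#' single-record GenBank flat file. Reading the file back reproduces the
#' gene count, intervals, strands and translations exactly. If a file with
#' the same label already exists, a `_1`, `_2`, ... suffix is appended and
#' the collision is logged.
#'
#' @param n A `neighbourhood`.
#' @param directory Existing, writable output directory.
#' @return The path written, invisibly-visible (returned).
#' @export
write_neighbourhood <- function(n, directory) {
  stopifnot(inherits(n, "neighbourhood"))
  if (!dir.exists(directory)) {
    abort_synsieve(sprintf("no such directory: '%s'", directory), "io")
  }
  label <- n$label
  path <- file.path(directory, paste0(label, ".gbk"))
  k <- 0L
  while (file.exists(path)) {
    k <- k + 1L
    path <- file.path(directory, sprintf("%s_%d.gbk", label, k))
  }
  if (k > 0L) {
    log_line("WARN", "write_neighbourhood",
             sprintf("label '%s' already on disk; writing '%s'",
                     label, basename(path)))
  }
  txt <- format_genbank(n, sub("\\.gbk$", "", basename(path)))
  ok <- tryCatch({
    writeLines(txt, path)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok || !file.exists(path)) {
    abort_synsieve(
      sprintf("cannot write to directory '%s'", directory), "io"
    )
  }
  path
}

# Build the GenBank text for one neighbourhood. The date field is fixed so
# regenerated fixtures are byte-identical.
format_genbank <- function(n, locus_name) {
  len <- nchar(n$sequence)
  out <- character()
  out <- c(out, sprintf(
    "LOCUS       %-16s %11d bp    DNA     linear   BCT 01-JAN-1980",
    gsub("[[:space:]]", "_", locus_name), len
  ))
  out <- c(out, sprintf("DEFINITION  %s neighbourhood.", n$organism))
  acc_line <- sprintf("ACCESSION   %s", n$source_accession)
  if (n$contig_offset > 0L) {
    # NCBI region notation: records where the slice sits on its source
    acc_line <- sprintf("%s REGION: %d..%d", acc_line,
                        n$contig_offset + 1L, n$contig_offset + len)
  }
  out <- c(out, acc_line)
  out <- c(out, sprintf("SOURCE      %s", n$organism))
  out <- c(out, sprintf("  ORGANISM  %s", n$organism))
  out <- c(out, "            .")
  out <- c(out, "FEATURES             Location/Qualifiers")
  out <- c(out, sprintf("     source          1..%d", len))
  out <- c(out, wrap_qualifier(sprintf('/organism="%s"', n$organism)))
  if (nrow(n$genes)) {
    for (i in seq_len(nrow(n$genes))) {
      g <- n$genes[i, ]
      loc <- sprintf("%d..%d", g$start + 1L, g$end)
      if (g$strand == -1L) loc <- sprintf("complement(%s)", loc)
      out <- c(out, sprintf("     CDS             %s", loc))
      out <- c(out, wrap_qualifier(sprintf('/locus_tag="%s"', g$gene_id)))
      out <- c(out, wrap_qualifier('/transl_table=11'))
      out <- c(out,
               wrap_qualifier(sprintf('/translation="%s"', g$translation)))
    }
  }
  out <- c(out, "ORIGIN")
  out <- c(out, format_origin(n$sequence))
  out <- c(out, "//")
  out
}

# Wrap a qualifier to the 80-column GenBank layout (text starts col 22).
wrap_qualifier <- function(text, width = 58L) {
  pieces <- substring(
    text,
    seq.int(1L, nchar(text), by = width),
    pmin(seq.int(width, nchar(text) + width - 1L, by = width), nchar(text))
  )
  paste0(strrep(" ", 21L), pieces)
}

format_origin <- function(sequence) {
  sequence <- tolower(sequence)
  len <- nchar(sequence)
  starts <- seq.int(1L, len, by = 60L)
  vapply(starts, function(s) {
    chunk <- substr(sequence, s, min(s + 59L, len))
    groups <- substring(
      chunk,
      seq.int(1L, nchar(chunk), by = 10L),
      pmin(seq.int(10L, nchar(chunk) + 9L, by = 10L), nchar(chunk))
    )
    sprintf("%9d %s", s, paste(groups, collapse = " "))
  }, character(1))
}
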