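# Collect: turn a cblaster binary hit table into centred, fixed-length,
# quality-filtered GenBank neighbourhood files.

#' Parse a cblaster binary hit table
#'
#' The binary table is delimited text with a header row; the delimiter is
#' auto-detected (tab if the header contains any tab, else comma). Columns
#' are mapped by position: organism, scaffold accession, hit start, hit
#' end, score, then one hit-count column per cblaster query. Printed
#' coordinates are 1-based inclusive and are converted to the package's
#' 0-based half-open convention.
#'
#' @param path Path to the table.
#' @return A `data.frame` with columns `organism`, `accession`, `start`,
#'   `end`, `score` and a list-column `query_counts`.
#' @export
parse_binary <- function(path) {
  if (!file.exists(path)) {
    abort_synsieve(sprintf("no such file: '%s'", path), "io")
  }
  header <- readLines(path, n = 1L, warn = FALSE)
  if (length(header) == 0L) {
    abort_synsieve(sprintf("'%s' is empty", path), "malformed_table")
  }
  delim <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  tab <- utils::read.table(
    path, sep = delim, header = TRUE, colClasses = "character",
    quote = "\"", comment.char = "", check.names = FALSE,
    stringsAsFactors = FALSE
  )
  if (ncol(tab) < 5L) {
    abort_synsieve(
      sprintf("'%s' has %d columns; at least 5 required", path, ncol(tab)),
      "malformed_table"
    )
  }
  n <- nrow(tab)
  starts <- suppressWarnings(as.numeric(tab[[3]]))
  ends <- suppressWarnings(as.numeric(tab[[4]]))
  bad <- which(is.na(starts) | is.na(ends))
  if (length(bad)) {
    abort_synsieve(
      sprintf("non-numeric hit interval in row %d of '%s'", bad[1], path),
      "malformed_table"
    )
  }
  start0 <- as.integer(starts) - 1L
  end0 <- as.integer(ends)
  if (any(start0 >= end0)) {
    abort_synsieve(
      sprintf("hit start >= end in row %d of '%s'",
              which(start0 >= end0)[1], path),
      "malformed_table"
    )
  }
  counts <- if (ncol(tab) > 5L) {
    lapply(seq_len(n), function(i) {
      suppressWarnings(as.integer(tab[i, 6:ncol(tab)]))
    })
  } else {
    rep(list(integer()), n)
  }
  out <- data.frame(
    organism = tab[[1]],
    accession = tab[[2]],
    start = start0,
    end = end0,
    score = suppressWarnings(as.numeric(tab[[5]])),
    stringsAsFactors = FALSE
  )
  out$query_counts <- counts
  out
}

#' Compute the centred neighbourhood span for one hit
#'
#' The span has length `neighbourhood_len` and is centred on the hit
#' interval's midpoint. Hits whose own interval is longer than
#' `neighbourhood_len` are rejected as `dispersed` (the clustered hits do
#' not fit the requested span). A span overhanging the contig is rejected
#' as `small` in strict mode; otherwise it is clamped to the contig,
#' provided the clamped span still covers the whole hit interval (else
#' `small`). Midpoint and half-length use `floor()`.
#'
#' @param hit_start,hit_end 0-based half-open hit interval.
#' @param neighbourhood_len Requested span length (bp), `>= 1`.
#' @param contig_len Length of the source contig (bp).
#' @param strict If `TRUE`, overhanging spans are rejected instead of
#'   clamped.
#' @return A list: either `list(outcome = "span", start, end)` or
#'   `list(outcome = "dispersed")` / `list(outcome = "small")`.
#' @export
compute_span <- function(hit_start, hit_end, neighbourhood_len, contig_len,
                         strict = FALSE) {
  stopifnot(is_number(neighbourhood_len), neighbourhood_len >= 1,
            hit_start < hit_end)
  if ((hit_end - hit_start) > neighbourhood_len) {
    return(list(outcome = "dispersed"))
  }
  mid <- (hit_start + hit_end) %/% 2
  raw_start <- mid - neighbourhood_len %/% 2
  raw_end <- raw_start + neighbourhood_len
  if (raw_start >= 0 && raw_end <= contig_len) {
    return(list(outcome = "span", start = raw_start, end = raw_end))
  }
  if (strict) return(list(outcome = "small"))
  cs <- max(0, raw_start)
  ce <- min(contig_len, raw_end)
  if (cs <= hit_start && ce >= hit_end) {
    list(outcome = "span", start = cs, end = ce)
  } else {
    list(outcome = "small")
  }
}

# ---------------------------------------------------------------------------
# Record fetchers. A fetcher is a function(accession) returning either
# list(ok = TRUE, record = <parsed record>) or
# list(ok = FALSE, reason = "not-found" | "network-failure" |
#      "malformed-record", detail = <text>).

#' Local-fixture record fetcher
#'
#' Resolves accessions against a directory of GenBank files named
#' `<accession>.gbk` (also `.gb`/`.gbff`). Never touches the network;
#' intended for tests and offline runs.
#'
#' @param dir Directory of GenBank records.
#' @return A fetcher function usable with [collect()].
#' @export
fixture_fetcher <- function(dir) {
  force(dir)
  function(accession) {
    for (ext in c(".gbk", ".gb", ".gbff")) {
      path <- file.path(dir, paste0(accession, ext))
      if (file.exists(path)) {
        rec <- tryCatch(read_genbank_record(path), error = function(e) e)
        if (inherits(rec, "error")) {
          return(list(ok = FALSE, reason = "malformed-record",
                      detail = conditionMessage(rec)))
        }
        if (!is.na(rec$locus_length) &&
            rec$locus_length != nchar(rec$sequence)) {
          return(list(
            ok = FALSE, reason = "malformed-record",
            detail = sprintf("LOCUS length %d != sequence length %d",
                             rec$locus_length, nchar(rec$sequence))
          ))
        }
        return(list(ok = TRUE, record = rec))
      }
    }
    list(ok = FALSE, reason = "not-found",
         detail = sprintf("no fixture for '%s' under '%s'", accession, dir))
  }
}

#' NCBI Entrez record fetcher
#'
#' Downloads full GenBank records (`rettype=gbwithparts`) from the NCBI
#' Entrez `efetch` endpoint, with up to `retries` attempts and exponential
#' backoff. NCBI asks for a contact e-mail with every request.
#'
#' @param email Contact e-mail passed to Entrez.
#' @param api_key Optional NCBI API key.
#' @param retries Maximum attempts per accession.
#' @return A fetcher function usable with [collect()].
#' @export
entrez_fetcher <- function(email, api_key = NULL, retries = 3L) {
  stopifnot(is_string(email), grepl("@", email))
  function(accession) {
    base <- "https://eutils.ncbi.nlm.nih.gov/entrez/eutils/efetch.fcgi"
    url <- sprintf(
      "%s?db=nuccore&id=%s&rettype=gbwithparts&retmode=text&tool=synsieve&email=%s",
      base, utils::URLencode(accession, reserved = TRUE),
      utils::URLencode(email, reserved = TRUE)
    )
    if (!is.null(api_key)) url <- paste0(url, "&api_key=", api_key)
    tmp <- tempfile(fileext = ".gbk")
    on.exit(unlink(tmp), add = TRUE)
    last <- "download failed"
    for (attempt in seq_len(retries)) {
      ok <- tryCatch({
        suppressWarnings(
          utils::download.file(url, tmp, quiet = TRUE, mode = "wb")
        )
        TRUE
      }, error = function(e) {
        last <<- conditionMessage(e)
        FALSE
      })
      if (ok && file.exists(tmp) && file.size(tmp) > 0) {
        rec <- tryCatch(read_genbank_record(tmp), error = function(e) e)
        if (inherits(rec, "error")) {
          return(list(ok = FALSE, reason = "malformed-record",
                      detail = conditionMessage(rec)))
        }
        return(list(ok = TRUE, record = rec))
      }
      Sys.sleep(2^attempt)
    }
    list(ok = FALSE, reason = "network-failure", detail = last)
  }
}

# ---------------------------------------------------------------------------

#' Collect neighbourhoods from a cblaster binary table
#'
#' For every row of the table: compute the centred span ([compute_span()]),
#' fetch the source record through `fetcher`, slice the record to the span
#' (CDS features fully inside the span are kept with coordinates shifted;
#' features straddling a span boundary are dropped and logged), and write
#' the slice as `<out_dir>/neighbourhood/<label>.gbk` where the label is
#' the sanitized accession or organism. Rows are never fatal to the batch:
#' each ends up in exactly one of the report's four buckets.
#'
#' @param binary_path Path to the cblaster binary table.
#' @param neighbourhood_len Span length in bp.
#' @param naming_mode `"accession"` or `"organism"`.
#' @param strict Passed to [compute_span()].
#' @param fetcher A record fetcher ([fixture_fetcher()],
#'   [entrez_fetcher()], or any function honouring the contract).
#' @param out_dir Output directory (created if needed); neighbourhood files
#'   go to `<out_dir>/neighbourhood/`, the run summary to
#'   `<out_dir>/collect_report.csv`.
#' @return A `collect_report` with elements `written` (data.frame:
#'   accession, path), `rejected_dispersed`, `rejected_small` (character),
#'   `fetch_failures` (data.frame: accession, reason) and `n_rows`.
#' @export
collect <- function(binary_path, neighbourhood_len,
                    naming_mode = c("accession", "organism"),
                    strict = FALSE, fetcher, out_dir) {
  naming_mode <- match.arg(naming_mode)
  stopifnot(is_number(neighbourhood_len), neighbourhood_len >= 1)
  hits <- parse_binary(binary_path)
  nbh_dir <- file.path(out_dir, "neighbourhood")
  dir.create(nbh_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(nbh_dir)) {
    abort_synsieve(sprintf("cannot create output directory '%s'", nbh_dir),
                   "io")
  }
  probe <- file.path(nbh_dir, ".write_probe")
  if (!isTRUE(suppressWarnings(file.create(probe)))) {
    abort_synsieve(sprintf("output directory '%s' is not writable", nbh_dir),
                   "io")
  }
  unlink(probe)

  cache <- new.env(parent = emptyenv())
  written <- list()
  dispersed <- character()
  small <- character()
  failures <- list()
  report_rows <- list()
  note <- function(i, acc, org, outcome, detail = "") {
    report_rows[[length(report_rows) + 1L]] <<- data.frame(
      row_index = i, accession = acc, organism = org,
      outcome = outcome, detail = detail, stringsAsFactors = FALSE
    )
  }

  for (i in seq_len(nrow(hits))) {
    acc <- hits$accession[i]
    org <- hits$organism[i]
    if ((hits$end[i] - hits$start[i]) > neighbourhood_len) {
      dispersed <- c(dispersed, acc)
      log_line("INFO", "collect",
               sprintf("row %d (%s): hit span exceeds neighbourhood length; dispersed",
                       i, acc))
      note(i, acc, org, "rejected_dispersed")
      next
    }
    fetched <- if (exists(acc, envir = cache)) {
      get(acc, envir = cache)
    } else {
      res <- fetcher(acc)
      assign(acc, res, envir = cache)
      res
    }
    if (!isTRUE(fetched$ok)) {
      failures[[length(failures) + 1L]] <- data.frame(
        accession = acc, reason = fetched$reason, stringsAsFactors = FALSE
      )
      log_line("WARN", "collect",
               sprintf("row %d (%s): fetch failed (%s)", i, acc,
                       fetched$reason))
      note(i, acc, org, "fetch_failure", fetched$reason)
      next
    }
    rec <- fetched$record
    span <- compute_span(hits$start[i], hits$end[i], neighbourhood_len,
                         nchar(rec$sequence), strict = strict)
    if (span$outcome != "span") {
      small <- c(small, acc)
      log_line("INFO", "collect",
               sprintf("row %d (%s): span overhangs the contig; rejected as small",
                       i, acc))
      note(i, acc, org, "rejected_small")
      next
    }
    nb <- slice_record(rec, span$start, span$end,
                       organism = if (nzchar(org)) org else rec$organism)
    nb$label <- sanitize_label(
      if (naming_mode == "accession") acc else nb$organism
    )
    path <- write_neighbourhood(nb, nbh_dir)
    written[[length(written) + 1L]] <- data.frame(
      accession = acc, path = path, stringsAsFactors = FALSE
    )
    note(i, acc, org, "written", basename(path))
  }

  report <- structure(
    list(
      written = if (length(written)) do.call(rbind, written) else
        data.frame(accession = character(), path = character(),
                   stringsAsFactors = FALSE),
      rejected_dispersed = dispersed,
      rejected_small = small,
      fetch_failures = if (length(failures)) do.call(rbind, failures) else
        data.frame(accession = character(), reason = character(),
                   stringsAsFactors = FALSE),
      n_rows = nrow(hits)
    ),
    class = "collect_report"
  )
  stopifnot(
    nrow(report$written) + length(dispersed) + length(small) +
      nrow(report$fetch_failures) == nrow(hits)
  )
  utils::write.csv(do.call(rbind, report_rows),
                   file.path(out_dir, "collect_report.csv"),
                   row.names = FALSE)
  report
}

#' @export
print.collect_report <- function(x, ...) {
  cat(sprintf(
    "<collect_report> %d rows: %d written, %d dispersed, %d small, %d fetch failures\n",
    x$n_rows, nrow(x$written), length(x$rejected_dispersed),
    length(x$rejected_small), nrow(x$fetch_failures)
  ))
  invisible(x)
}

# Cut [start, end) out of a parsed record: subsequence plus the CDS
# features lying entirely inside the span, shifted to span coordinates.
# Straddling features are dropped and logged.
slice_record <- function(rec, start, end, organism = rec$organism) {
  genes <- rec$genes
  inside <- genes$start >= start & genes$end <= end
  straddle <- !inside & genes$end > start & genes$start < end
  if (any(straddle)) {
    log_line("INFO", "collect",
             sprintf("%s: dropped %d gene(s) straddling the span boundary (%s)",
                     rec$accession, sum(straddle),
                     paste(genes$gene_id[straddle], collapse = ", ")))
  }
  kept <- genes[inside, , drop = FALSE]
  kept$start <- kept$start - as.integer(start)
  kept$end <- kept$end - as.integer(start)
  neighbourhood(
    source_accession = rec$accession,
    organism = organism,
    sequence = substr(rec$sequence, start + 1L, end),
    genes = kept,
    label = rec$accession,
    contig_offset = start
  )
}
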