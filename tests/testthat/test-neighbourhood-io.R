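# GenBank neighbourhood reading/writing and label sanitization.

test_that("sanitize_label applies the replacement, collapse and trim rules", {
  expect_identical(sanitize_label("Streptomyces coelicolor A3(2)"),
                   "Streptomyces_coelicolor_A3_2")
  expect_identical(sanitize_label("NZ_CP023689.1"), "NZ_CP023689.1")
  expect_error(sanitize_label("///"), class = "synsieve_invalid_name_error")
  expect_error(sanitize_label(""), class = "synsieve_invalid_name_error")
})

test_that("sanitize_label is idempotent on arbitrary input", {
  set.seed(42)
  pool <- c(LETTERS, letters, 0:9, ".", "-", "_", " ", "(", ")", "/", "#",
            ",", "'")
  for (i in 1:50) {
    raw <- paste(sample(pool, sample(1:30, 1), replace = TRUE),
                 collapse = "")
    once <- tryCatch(sanitize_label(raw), error = function(e) NULL)
    if (is.null(once)) next
    expect_identical(sanitize_label(once), once)
  }
})

test_that("a file with translated CDS features parses in coordinate order", {
  prot <- strrep("MAD", 10)
  # features deliberately out of coordinate order
  feats <- c(
    cds_lines(201, 292, strand = -1L, translation = prot,
              locus_tag = "late"),
    cds_lines(11, 102, translation = prot, protein_id = "early",
              locus_tag = "ignored_in_favour_of_protein_id"),
    cds_lines(401, 492, translation = prot, locus_tag = "last")
  )
  path <- write_gbk(gbk_text(strrep("ACGT", 150), feats))
  nb <- read_neighbourhood(path)
  expect_equal(n_genes(nb), 3L)
  expect_identical(nb$genes$gene_id, c("early", "late", "last"))
  expect_identical(nb$genes$start, c(10L, 200L, 400L))
  expect_identical(nb$genes$end, c(102L, 292L, 492L))
  expect_identical(nb$genes$strand, c(1L, -1L, 1L))
  expect_identical(nb$organism, "Testus exampli")
})

test_that("a CDS without /translation is translated with table 11, stop stripped", {
  # ATG GCT GAC GAA GGT CAC ATC AAA CTG TAA -> MADEGHIKL + stop
  coding <- "ATGGCTGACGAAGGTCACATCAAACTGTAA"
  sequence <- paste0(strrep("A", 50), coding, strrep("A", 40))
  feats <- c("     CDS             51..80",
             '                     /locus_tag="untranslated"')
  nb <- read_neighbourhood(write_gbk(gbk_text(sequence, feats)))
  expect_identical(nb$genes$translation, "MADEGHIKL")
  expect_identical(nchar(nb$genes$translation), 9L)
})

test_that("a CDS on the minus strand without /translation uses the reverse complement", {
  coding <- "ATGGCTGACGAAGGTCACATCAAACTGTAA"
  rc <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(coding))
  )
  sequence <- paste0(strrep("A", 50), rc, strrep("A", 40))
  feats <- "     CDS             complement(51..80)"
  nb <- read_neighbourhood(write_gbk(gbk_text(sequence, feats)))
  expect_identical(nb$genes$translation, "MADEGHIKL")
  expect_identical(nb$genes$strand, -1L)
})

test_that("a joined CDS keeps the outer span but translates the exons", {
  # exon1 MADE, exon2 GHIKL + stop; intron of 38 nt between them
  exon1 <- "ATGGCTGACGAA"
  exon2 <- "GGTCACATCAAACTGTAA"
  sequence <- paste0(strrep("A", 50), exon1, strrep("C", 38), exon2,
                     strrep("A", 40))
  feats <- c("     CDS             join(51..62,101..118)",
             '                     /locus_tag="joined"')
  nb <- read_neighbourhood(write_gbk(gbk_text(sequence, feats)))
  expect_identical(nb$genes$translation, "MADEGHIKL")
  expect_identical(nb$genes$start, 50L)
  expect_identical(nb$genes$end, 118L)
})

test_that("CDS with a non-codon span and no translation is skipped with a warning", {
  sequence <- paste0(strrep("A", 50), "ATGGCTGACGAAGGTCACATCAAACTGTAA",
                     strrep("A", 40))
  feats <- c(
    "     CDS             51..80",
    "     CDS             85..98"  # 14 nt, not a codon multiple
  )
  msgs <- capture_messages(nb <- read_neighbourhood(write_gbk(gbk_text(sequence, feats))))
  expect_equal(n_genes(nb), 1L)
  expect_match(paste(msgs, collapse = "\n"), "not a multiple of 3")
})

test_that("records without CDS features raise an empty-neighbourhood error", {
  path <- write_gbk(gbk_text(strrep("ACGT", 50), character()))
  expect_error(read_neighbourhood(path),
               class = "synsieve_empty_neighbourhood_error")
})

test_that("unparsable files raise a format error naming the path", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "junk.gbk")
  writeLines(c("this is", "not genbank"), path)
  err <- expect_error(read_neighbourhood(path),
                      class = "synsieve_format_error")
  expect_match(conditionMessage(err), "junk.gbk")
  expect_error(read_neighbourhood(file.path(dir, "missing.gbk")),
               class = "synsieve_io_error")
})

test_that("write -> read round-trips the gene table exactly", {
  set.seed(7)
  dir <- withr::local_tempdir()
  for (i in 1:30) {
    nb <- random_neighbourhood(label = sprintf("rt%03d", i))
    path <- write_neighbourhood(nb, dir)
    back <- read_neighbourhood(path)
    expect_identical(back$genes, nb$genes)
    expect_identical(back$sequence, nb$sequence)
    expect_identical(back$organism, nb$organism)
    expect_identical(back$source_accession, nb$source_accession)
  }
})

test_that("label collisions on disk get numbered suffixes", {
  set.seed(8)
  dir <- withr::local_tempdir()
  nb <- random_neighbourhood(label = "same")
  p1 <- write_neighbourhood(nb, dir)
  p2 <- suppressMessages(write_neighbourhood(nb, dir))
  p3 <- suppressMessages(write_neighbourhood(nb, dir))
  expect_identical(basename(p1), "same.gbk")
  expect_identical(basename(p2), "same_1.gbk")
  expect_identical(basename(p3), "same_2.gbk")
})

test_that("writing into a nonexistent directory is an I/O error", {
  set.seed(9)
  nb <- random_neighbourhood()
  err <- expect_error(write_neighbourhood(nb, "/no/such/dir/anywhere"),
                      class = "synsieve_io_error")
  expect_match(conditionMessage(err), "/no/such/dir/anywhere")
})

test_that("written files agree with an independent GenBank parser", {
  # Biopython (shipped with the environment's python) re-reads the file
  # and must recover the identical gene table and translations.
  set.seed(10)
  dir <- withr::local_tempdir()
  nb <- random_neighbourhood(label = "oracle", n_genes = 4)
  path <- write_neighbourhood(nb, dir)
  script <- file.path(dir, "check.py")
  writeLines(c(
    "import sys, json",
    "from Bio import SeqIO",
    "rec = SeqIO.read(sys.argv[1], 'genbank')",
    "rows = []",
    "for f in rec.features:",
    "    if f.type != 'CDS':",
    "        continue",
    "    rows.append([f.qualifiers['locus_tag'][0], int(f.location.start),",
    "                 int(f.location.end), int(f.location.strand),",
    "                 f.qualifiers['translation'][0]])",
    "print(json.dumps(sorted(rows, key=lambda r: (r[1], r[2], r[0]))))"
  ), script)
  out <- system2("python", c(script, path), stdout = TRUE)
  parsed <- jsonlite::fromJSON(paste(out, collapse = ""),
                               simplifyMatrix = FALSE)
  expect_equal(length(parsed), n_genes(nb))
  for (i in seq_along(parsed)) {
    expect_identical(as.character(parsed[[i]][[1]]), nb$genes$gene_id[i])
    expect_equal(as.integer(parsed[[i]][[2]]), nb$genes$start[i])
    expect_equal(as.integer(parsed[[i]][[3]]), nb$genes$end[i])
    expect_equal(as.integer(parsed[[i]][[4]]), nb$genes$strand[i])
    expect_identical(as.character(parsed[[i]][[5]]), nb$genes$translation[i])
  }
})
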