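# Similarity scoring, graph construction and greedy pruning.

stub_neighbourhood <- function(label, n) {
  prot <- strrep("MADEGHIKL", 5)
  genes <- data.frame(
    gene_id = sprintf("g%d", seq_len(n)),
    start = seq(0L, by = 100L, length.out = n),
    end = seq(90L, by = 100L, length.out = n),
    strand = 1L, translation = prot, stringsAsFactors = FALSE
  )
  neighbourhood(label, paste("Testus", label),
                strrep("A", 100L * n + 10L), genes, label)
}

rbh_stub <- function(k) {
  data.frame(gene_a = sprintf("a::g%d", seq_len(k)),
             gene_b = sprintf("b::g%d", seq_len(k)),
             stringsAsFactors = FALSE)[seq_len(k), , drop = FALSE]
}

test_that("similarity is the RBH share of the smaller neighbourhood", {
  a5 <- stub_neighbourhood("a", 5)
  b5 <- stub_neighbourhood("b", 5)
  expect_equal(similarity(a5, b5, rbh_stub(5)), 1.0)
  expect_equal(similarity(stub_neighbourhood("a", 4),
                          stub_neighbourhood("b", 6), rbh_stub(3)), 0.75)
  expect_equal(similarity(a5, b5, rbh_stub(0)), 0.0)
  expect_error(similarity(stub_neighbourhood("a", 2), b5, rbh_stub(3)),
               class = "synsieve_internal_consistency_error")
})

test_that("graph edges require scores strictly above the threshold", {
  scores <- data.frame(
    label_i = c("a", "a"), label_j = c("b", "c"),
    score = c(0.9, 0.7), stringsAsFactors = FALSE
  )
  sg <- build_graph(c("a", "b", "c"), scores, threshold = 0.7)
  expect_equal(igraph::ecount(sg$graph), 1L)
  ends <- igraph::ends(sg$graph, igraph::E(sg$graph), names = TRUE)
  expect_setequal(as.vector(ends), c("a", "b"))
  # all non-zero scores retained for the histogram regardless of threshold
  expect_equal(nrow(sg$edge_weights), 2L)

  sg1 <- build_graph(c("a", "b", "c"), scores, threshold = 1.0)
  expect_equal(igraph::ecount(sg1$graph), 0L)

  sg_empty <- build_graph(c("a", "b", "c"),
                          scores[0, , drop = FALSE], threshold = 0.5)
  expect_equal(igraph::vcount(sg_empty$graph), 3L)
  expect_equal(igraph::ecount(sg_empty$graph), 0L)
  expect_error(build_graph("a", scores[0, ], threshold = 0),
               class = "synsieve_validation_error")
})

test_that("prune follows the greedy degree/weight/label rules", {
  two <- build_graph(c("a", "b"),
                     data.frame(label_i = "a", label_j = "b", score = 0.9),
                     threshold = 0.7)
  rep2 <- prune(two)
  expect_identical(rep2$kept, "a")
  expect_identical(rep2$removed$label, "b")
  expect_identical(rep2$removed$trigger_neighbour, "a")
  expect_identical(rep2$removed$degree_at_removal, 1L)

  path3 <- build_graph(
    c("a", "b", "c"),
    data.frame(label_i = c("a", "b"), label_j = c("b", "c"),
               score = c(0.9, 0.8)),
    threshold = 0.7
  )
  rep3 <- prune(path3)
  expect_identical(rep3$removed$label, "b")
  expect_identical(rep3$kept, c("a", "c"))

  edgeless <- build_graph(c("x", "y", "z"),
                          data.frame(label_i = character(),
                                     label_j = character(),
                                     score = numeric()), 0.7)
  repe <- prune(edgeless)
  expect_identical(repe$kept, c("x", "y", "z"))
  expect_equal(nrow(repe$removed), 0L)
})

test_that("prune agrees with an independent transcription of the rules", {
  set.seed(51)
  for (case in 1:300) {
    n <- sample(3:7, 1)
    S <- random_score_matrix(n)
    threshold <- sample(1:63, 1) / 64
    sg <- build_graph(rownames(S), matrix_to_pair_scores(S), threshold)
    got <- prune(sg)
    want <- oracle_prune(S, threshold)
    expect_identical(got$kept, want$kept)
    expect_identical(got$removed$label, want$removed)
  }
})

test_that("pruning is safe and idempotent on random score matrices", {
  set.seed(52)
  for (case in 1:60) {
    n <- sample(3:15, 1)
    S <- random_score_matrix(n)
    threshold <- sample(1:63, 1) / 64
    scores <- matrix_to_pair_scores(S)
    rep1 <- prune(build_graph(rownames(S), scores, threshold))
    kept <- rep1$kept
    # safety: no kept pair exceeds the threshold
    sub <- scores[scores$label_i %in% kept & scores$label_j %in% kept, ]
    expect_true(all(sub$score <= threshold))
    # idempotence: pruning the kept subgraph removes nothing
    rep2 <- prune(build_graph(kept, sub, threshold))
    expect_identical(rep2$kept, kept)
    expect_equal(nrow(rep2$removed), 0L)
  }
})

test_that("non-transitive similarity keeps both distant endpoints", {
  scores <- data.frame(
    label_i = c("a", "b", "a"), label_j = c("b", "c", "c"),
    score = c(0.9, 0.9, 0.1), stringsAsFactors = FALSE
  )
  report <- prune(build_graph(c("a", "b", "c"), scores, 0.7))
  expect_identical(report$kept, c("a", "c"))
  expect_identical(report$removed$label, "b")
})

test_that("sieve keeps two of four on the redundant study fixture", {
  dir <- tempfile("sieve_fix")
  build_neighbourhood_set(study_fixture_spec(seed = 101L), dir)
  out <- tempfile("sieve_out")
  report <- suppressMessages(sieve(dir, threshold = 0.7, out_dir = out))

  expect_equal(length(report$kept), 2L)
  expect_true("outsider" %in% report$kept)
  kept_files <- list.files(file.path(out, "kept"), full.names = TRUE)
  expect_equal(length(kept_files), 2L)
  # kept files are byte-identical copies of their inputs
  for (f in kept_files) {
    src <- file.path(dir, basename(f))
    expect_identical(readLines(f), readLines(src))
  }
  expect_true(file.exists(file.path(out, "sieve_report.csv")))
  expect_true(file.exists(file.path(out, "edge_weights.csv")))
  expect_true(file.exists(file.path(out, "neighbourhood_graph.html")))
  expect_true(file.exists(file.path(out, "edge_histogram.png")))
})

test_that("re-sieving its own output removes nothing", {
  dir <- tempfile("sieve_fix2")
  build_neighbourhood_set(study_fixture_spec(seed = 102L), dir)
  out1 <- tempfile(); out2 <- tempfile()
  rep1 <- suppressMessages(sieve(dir, threshold = 0.7, out_dir = out1))
  rep2 <- suppressMessages(
    sieve(file.path(out1, "kept"), threshold = 0.7, out_dir = out2)
  )
  expect_identical(rep2$kept, rep1$kept)
  expect_equal(nrow(rep2$removed), 0L)
})

test_that("the kept set does not depend on file enumeration order", {
  dir <- tempfile("sieve_fix3")
  build_neighbourhood_set(study_fixture_spec(seed = 103L), dir)
  files <- list.files(dir, pattern = "gbk$", full.names = TRUE)
  # same content under names that reverse the lexicographic file order,
  # while keeping the record labels themselves stable inside sieve by
  # scoring the neighbourhoods directly in shuffled order
  nbs <- lapply(files, read_neighbourhood)
  for (perm in list(c(2, 4, 1, 3), c(4, 3, 2, 1))) {
    scores <- score_pairs(nbs[perm])
    labels <- sort(vapply(nbs, function(n) n$label, character(1)))
    report <- prune(build_graph(labels, scores, 0.7))
    baseline <- prune(build_graph(labels, score_pairs(nbs), 0.7))
    expect_identical(report$kept, baseline$kept)
  }
})

test_that("sieve needs at least two readable neighbourhoods", {
  dir <- tempfile("sieve_one")
  dir.create(dir)
  set.seed(60)
  write_neighbourhood(random_neighbourhood("solo"), dir)
  writeLines("garbage", file.path(dir, "broken.gbk"))
  expect_error(
    suppressMessages(sieve(dir, out_dir = tempfile())),
    class = "synsieve_precondition_error"
  )
})

test_that("a threshold above every score keeps everything unchanged", {
  dir <- tempfile("sieve_fix4")
  build_neighbourhood_set(study_fixture_spec(seed = 104L), dir)
  out <- tempfile()
  report <- suppressMessages(sieve(dir, threshold = 1.0, out_dir = out))
  expect_equal(length(report$kept), 4L)
  kept_files <- sort(list.files(file.path(out, "kept")))
  expect_identical(kept_files, sort(list.files(dir, pattern = "gbk$")))
})
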