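write_hits <- function(hits, path = tempfile(fileext = ".tsv")) {
  write_blast_tabular(hits, path)
  path
}

test_that("blast tabular parsing maps fields and flags format errors", {
  p <- tempfile()
  writeLines(c("# comment",
               "q1\ts1\t98.0\t150\t3\t0\t101\t250\t1\t150\t1e-50\t280"), p)
  h <- parse_blast_tabular(p, "forward")
  expect_equal(nrow(h), 1)
  expect_equal(h$qstart, 101L)
  expect_equal(h$qend, 250L)
  expect_equal(h$sstart, 1L)
  expect_equal(h$send, 150L)
  expect_equal(h$bitscore, 280)

  empty <- tempfile(); file.create(empty)
  expect_equal(nrow(parse_blast_tabular(empty, "forward")), 0)

  bad <- tempfile()
  writeLines(c("q1\ts1\t98.0\t150", ""), bad)
  expect_error(parse_blast_tabular(bad, "forward"), "line 1",
               class = "corexpr_format_error")
  bad2 <- tempfile()
  writeLines("q1\ts1\t98.0\t150\t3\t0\tXX\t250\t1\t150\t1e-50\t280", bad2)
  expect_error(parse_blast_tabular(bad2, "forward"), "non-numeric",
               class = "corexpr_format_error")
})

test_that("parse then re-serialize is field-identical on generated tables", {
  tx <- simulate_ortholog_transcriptomes(12, seed = 2)
  bt <- simulate_blast_tables(tx$truth, seed = 2)
  p1 <- write_hits(bt$forward)
  parsed <- parse_blast_tabular(p1, "forward")
  p2 <- write_hits(parsed)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("trinity gene ids strip only the isoform suffix", {
  expect_equal(trinity_gene_of("TRINITY_DN1000_c0_g1_i3"),
               "TRINITY_DN1000_c0_g1")
  expect_equal(trinity_gene_of("NM_000123.4"), "NM_000123.4")
  expect_equal(trinity_gene_of("SIM_DN7_c0_g1_i12"), "SIM_DN7_c0_g1")
})

test_that("best hit per query follows the ranking chain", {
  hits <- tibble::tibble(
    qseqid = c("q1", "q1"), sseqid = c("s1", "s2"),
    pident = 95, length = c(100L, 100L), mismatch = 0L, gapopen = 0L,
    qstart = 1L, qend = 100L, sstart = 1L, send = 100L,
    evalue = c(1e-50, 1e-50), bitscore = c(300, 200))
  expect_equal(best_hit_per_query(hits)$subject_id, "s1")

  # cutoff: a 1e-4 hit is absent at cutoff 1e-5
  hits$evalue <- c(1e-4, 1e-4)
  expect_equal(nrow(best_hit_per_query(hits, 1e-5)), 0)

  # tie on bitscore and evalue: longer alignment wins
  tie <- tibble::tibble(
    qseqid = "q1", sseqid = c("sA", "sB"), pident = 95,
    length = c(120L, 150L), mismatch = 0L, gapopen = 0L,
    qstart = 1L, qend = 100L, sstart = 1L, send = 100L,
    evalue = 1e-30, bitscore = 250)
  expect_equal(best_hit_per_query(tie)$subject_id, "sB")

  # exhaustive comparator over the full ranking chain on a random table
  set.seed(17)
  rnd <- tibble::tibble(
    qseqid = "q1", sseqid = sample(c("s1", "s2", "s3"), 12, replace = TRUE),
    pident = 95, length = sample(c(100L, 150L), 12, replace = TRUE),
    mismatch = 0L, gapopen = 0L, qstart = 1L, qend = 100L,
    sstart = 1L, send = 100L,
    evalue = sample(c(1e-30, 1e-40), 12, replace = TRUE),
    bitscore = sample(c(200, 250), 12, replace = TRUE))
  got <- best_hit_per_query(rnd)
  agg <- lapply(split(rnd, rnd$sseqid), function(d) {
    c(sum(d$bitscore), min(d$evalue), sum(d$length))
  })
  ord <- names(agg)[order(-vapply(agg, `[`, 0, 1),
                          vapply(agg, `[`, 0, 2),
                          -vapply(agg, `[`, 0, 3), names(agg))]
  expect_equal(got$subject_id, ord[1])
})

test_that("gene-level reciprocity accepts and rejects per the stated rule", {
  row <- function(q, s, bits, ev = 1e-40) {
    tibble::tibble(qseqid = q, sseqid = s, pident = 95, length = 100L,
                   mismatch = 0L, gapopen = 0L, qstart = 1L, qend = 100L,
                   sstart = 1L, send = 100L, evalue = ev, bitscore = bits)
  }
  fwd <- dplyr::bind_rows(row("gA_i1", "NM_1", 300), row("gA_i2", "NM_1", 250))
  rev_ <- row("NM_1", "gA_i2", 280)       # reverse best is another isoform
  orth <- reciprocal_best_hits(fwd, rev_)
  expect_equal(nrow(orth), 1)
  expect_setequal(orth$isoforms_a[[1]], c("gA_i1", "gA_i2"))

  rev_bad <- row("NM_1", "gB_i1", 280)    # reverse lands on a different gene
  expect_equal(nrow(reciprocal_best_hits(fwd, rev_bad)), 0)

  # overlapping namespaces
  expect_error(reciprocal_best_hits(row("x_i1", "x_i1", 10),
                                    row("x_i1", "x_i1", 10)),
               class = "corexpr_validation_error")
})

test_that("RBH on fixtures equals the brute-force oracle across seeds", {
  for (seed in 1:5) {
    tx <- simulate_ortholog_transcriptomes(50, isoforms_per_gene = 1:3,
                                           divergence = 0.05, seed = seed)
    bt <- simulate_blast_tables(tx$truth, split_prob = 0.5,
                                decoy_rate = 0.2, seed = seed)
    orth <- reciprocal_best_hits(bt$forward, bt$reverse)
    oracle <- brute_rbh(bt$forward, bt$reverse)
    expect_identical(orth$gene_a, sort(oracle$gene_a))
    expect_identical(orth$transcript_b[order(orth$gene_a)],
                     oracle$transcript_b[order(oracle$gene_a)])
    # fixtures recover the planted truth exactly
    expect_setequal(paste(orth$gene_a, orth$transcript_b),
                    paste(tx$truth$pairs$gene_a,
                          tx$truth$pairs$transcript_b))
  }
})

test_that("RBH output is invariant to row order and monotone in the cutoff", {
  tx <- simulate_ortholog_transcriptomes(25, divergence = 0.05, seed = 13)
  bt <- simulate_blast_tables(tx$truth, decoy_rate = 0.3, seed = 13)
  orth <- reciprocal_best_hits(bt$forward, bt$reverse)
  set.seed(1)
  shuf <- reciprocal_best_hits(bt$forward[sample(nrow(bt$forward)), ],
                               bt$reverse[sample(nrow(bt$reverse)), ])
  expect_identical(orth, shuf)
  # raising the cutoff never removes an accepted pair
  strict <- reciprocal_best_hits(bt$forward, bt$reverse,
                                 evalue_cutoff = 1e-60)
  expect_true(all(paste(strict$gene_a, strict$gene_b) %in%
                    paste(orth$gene_a, orth$gene_b)))
})

test_that("zero-divergence fixtures without decoys recover exactly truth", {
  tx <- simulate_ortholog_transcriptomes(20, divergence = 0, indel_rate = 0,
                                         seed = 21)
  bt <- simulate_blast_tables(tx$truth, decoy_rate = 0, seed = 21)
  orth <- reciprocal_best_hits(bt$forward, bt$reverse)
  expect_setequal(paste(orth$gene_a, orth$transcript_b),
                  paste(tx$truth$pairs$gene_a, tx$truth$pairs$transcript_b))
})

test_that("ortholog tables round-trip through TSV", {
  tx <- simulate_ortholog_transcriptomes(10, seed = 30)
  bt <- simulate_blast_tables(tx$truth, seed = 30)
  orth <- reciprocal_best_hits(bt$forward, bt$reverse)
  p <- tempfile(fileext = ".tsv")
  write_ortholog_table(orth, p)
  back <- read_ortholog_table(p)
  expect_equal(back$gene_a, orth$gene_a)
  expect_equal(back$isoforms_a, orth$isoforms_a)
  expect_equal(back$bitscore, orth$bitscore, tolerance = 1e-6)
})
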