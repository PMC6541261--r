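test_that("transcriptome simulation is deterministic and honors divergence", {
  tx1 <- simulate_ortholog_transcriptomes(10, divergence = 0.05,
                                          indel_rate = 0, seed = 7)
  tx2 <- simulate_ortholog_transcriptomes(10, divergence = 0.05,
                                          indel_rate = 0, seed = 7)
  f1 <- tempfile(fileext = ".fasta"); f2 <- tempfile(fileext = ".fasta")
  Biostrings::writeXStringSet(tx1$seqs_a, f1)
  Biostrings::writeXStringSet(tx2$seqs_a, f2)
  expect_identical(readLines(f1), readLines(f2))

  # zero divergence: identical sequences, one truth pair
  tx0 <- simulate_ortholog_transcriptomes(1, isoforms_per_gene = 1,
                                          divergence = 0, indel_rate = 0,
                                          seed = 1)
  expect_identical(as.character(tx0$seqs_a[[1]]),
                   as.character(tx0$seqs_b[[1]]))
  expect_equal(nrow(tx0$truth$pairs), 1)

  # observed identity ~ 1 - 0.75 * divergence, by direct mismatch count
  tx <- simulate_ortholog_transcriptomes(50, isoforms_per_gene = 1,
                                         divergence = 0.08, indel_rate = 0,
                                         seed = 11)
  mism <- vapply(seq_len(50), function(g) {
    a <- strsplit(as.character(tx$seqs_a[[g]]), "")[[1]]
    b <- strsplit(as.character(tx$seqs_b[[g]]), "")[[1]]
    mean(a != b)
  }, numeric(1))
  expect_lt(abs(mean(mism) - 0.75 * 0.08), 0.01)

  expect_error(simulate_ortholog_transcriptomes(5, divergence = 0.5),
               class = "corexpr_parameter_error")
})

test_that("sim truth tables round-trip byte-identically", {
  tx <- simulate_ortholog_transcriptomes(8, seed = 3)
  p1 <- tempfile(fileext = ".tsv"); p2 <- tempfile(fileext = ".tsv")
  write_sim_truth(tx$truth, p1)
  write_sim_truth(read_sim_truth(p1), p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("blast tables respect construction guarantees and bounds", {
  tx <- simulate_ortholog_transcriptomes(30, divergence = 0.05, seed = 5)
  bt <- simulate_blast_tables(tx$truth, split_prob = 1, decoy_rate = 0,
                              seed = 5)
  # decoy_rate 0: forward best hit of every isoform is its true partner
  best <- best_hit_per_query(bt$forward, 1)
  truth_map <- tx$truth$isoforms |>
    dplyr::left_join(tx$truth$pairs, by = "gene_a")
  expect_identical(best$subject_id[match(truth_map$transcript,
                                         best$query_id)],
                   truth_map$transcript_b)
  # split_prob 1: every alignment reported as >= 2 HSPs (where long enough)
  n_hsp <- table(paste(bt$forward$qseqid, bt$forward$sseqid))
  long <- truth_map$length >= 60
  expect_true(all(n_hsp[paste(truth_map$transcript,
                              truth_map$transcript_b)][long] >= 2))

  # coordinate bounds, brute-force scan over every row
  bt2 <- simulate_blast_tables(tx$truth, split_prob = 0.5, decoy_rate = 0.5,
                               seed = 6)
  qlen <- setNames(tx$truth$isoforms$length, tx$truth$isoforms$transcript)
  slen <- setNames(tx$truth$transcripts_b$length,
                   tx$truth$transcripts_b$transcript)
  for (tab in bt2) {
    dir_q <- if (all(tab$qseqid %in% names(qlen))) qlen else slen
    dir_s <- if (all(tab$sseqid %in% names(slen))) slen else qlen
    ok <- logical(nrow(tab))
    for (i in seq_len(nrow(tab))) {
      ok[i] <- tab$qstart[i] >= 1 && tab$qend[i] <= dir_q[tab$qseqid[i]] &&
        max(tab$sstart[i], tab$send[i]) <= dir_s[tab$sseqid[i]] &&
        min(tab$sstart[i], tab$send[i]) >= 1
    }
    expect_true(all(ok))
  }
  # some minus-strand subject HSPs are emitted
  expect_gt(sum(bt2$forward$sstart > bt2$forward$send), 0)
})

test_that("count simulation matches planted means in the small-phi limit", {
  cs <- simulate_counts(400, n_rep = 4, dispersion = 1e-8, frac_de = 0,
                        seed = 9)
  expect_true(all(cs$truth$lfc == 0))
  m <- corexpr:::as_count_matrix(cs$counts)
  # per-group means track planted means * sample scale within Poisson error
  grp <- split(cs$samples$sample_id,
               paste(cs$samples$species, cs$samples$day))
  for (g in grp) {
    gm <- rowMeans(m[, g])
    rel <- gm / cs$truth$base_mean
    # scale factors are within 2^(+-0.5); group mean of 4 draws
    expect_true(all(rel > 0.4 & rel < 2.5))
  }
  # determinism
  cs2 <- simulate_counts(400, n_rep = 4, dispersion = 1e-8, frac_de = 0,
                         seed = 9)
  expect_identical(cs$counts, cs2$counts)
  expect_error(simulate_counts(10, dispersion = 0),
               class = "corexpr_parameter_error")
})

test_that("coexpression simulation plants modules at the target correlation", {
  one <- simulate_coexpression(n_modules = 1, module_sizes = 5,
                               within_r = 0.99, n_background = 10,
                               star_sizes = integer(0), n_samples = 50,
                               seed = 2)
  rho <- spearman_matrix(one$expr)
  genes <- one$truth$gene[!is.na(one$truth$module) & one$truth$module == 1]
  sub <- abs(rho[genes, genes])
  expect_true(all(sub[upper.tri(sub)] >= 0.9))   # 5-clique at 0.9

  sim <- simulate_coexpression(seed = 4)
  rho <- spearman_matrix(sim$expr)
  mt <- sim$truth[!is.na(sim$truth$module) & sim$truth$module > 0, ]
  within <- unlist(lapply(split(mt$gene, mt$module), function(g) {
    s <- rho[g, g]; s[upper.tri(s)]
  }))
  expect_lt(abs(mean(within) - 0.92), 0.01)

  sim2 <- simulate_coexpression(seed = 4)
  expect_identical(sim$expr, sim2$expr)
  expect_error(simulate_coexpression(within_r = 1.2),
               class = "corexpr_parameter_error")
})

test_that("background-only correlations match the permutation null", {
  noise <- simulate_coexpression(n_modules = 0, module_sizes = integer(0),
                                 star_sizes = integer(0),
                                 n_background = 40, n_samples = 30,
                                 seed = 8)
  rho <- spearman_matrix(noise$expr)
  n_edges <- sum(abs(rho[upper.tri(rho)]) >= 0.6)
  # permutation null for P(|rho| >= 0.6) at n = 30
  set.seed(1)
  null_p <- mean(replicate(4000, {
    abs(cor(sample(30), sample(30), method = "spearman")) >= 0.6
  }))
  expected <- choose(40, 2) * null_p
  expect_lt(abs(n_edges - expected), 3 * sqrt(max(expected, 1)) + 3)
})

test_that("discrete power-law sampler is zeta-normalized and deterministic", {
  x <- simulate_powerlaw_degrees(2.5, 1, 1e5, seed = 4)
  expect_true(all(x >= 1))
  expect_lt(abs(mean(x == 1) - 1 / hurwitz_zeta(2.5, 1)), 0.01)
  expect_identical(x, simulate_powerlaw_degrees(2.5, 1, 1e5, seed = 4))
  x3 <- simulate_powerlaw_degrees(3.0, 5, 1000, seed = 1)
  expect_true(all(x3 >= 5))
  expect_error(simulate_powerlaw_degrees(0.9, 1, 10),
               class = "corexpr_parameter_error")
})
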