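#' Simulate a pair of ortholog transcriptomes
#'
#' Generates a de novo style transcriptome for species A (one or more isoforms
#' per gene, Trinity-style ids `SIM_DN<g>_c0_g1_i<k>`) and a reference
#' transcriptome for species B (one transcript per gene), where each A isoform
#' is derived from its B ortholog by random substitution and single-base
#' indels. Substituted bases are drawn uniformly from all four nucleotides
#' (Jukes-Cantor-style), so the expected observed mismatch rate is
#' `0.75 * divergence`.
#'
#' @param n_genes Number of ortholog pairs to simulate.
#' @param isoforms_per_gene Integer vector; the number of A isoforms per gene
#'   is drawn uniformly from this set.
#' @param mean_len Mean transcript length in bp (lengths vary uniformly
#'   within +/-30%).
#' @param divergence Per-base substitution rate in `[0, 0.3)`.
#' @param indel_rate Per-base single-base indel rate.
#' @param seed Integer seed; identical seeds give byte-identical output.
#' @return A list with `seqs_a`, `seqs_b` ([Biostrings::DNAStringSet]) and
#'   `truth`, a `sim_truth` list holding the true pairs, the isoform table
#'   with lengths, and the simulation parameters.
#' @export
simulate_ortholog_transcriptomes <- function(n_genes,
                                             isoforms_per_gene = 1:3,
                                             mean_len = 500,
                                             divergence = 0.05,
                                             indel_rate = 0.002,
                                             seed = 1) {
  check_scalar(n_genes, "n_genes", lower = 1, integerish = TRUE)
  check_scalar(divergence, "divergence", lower = 0, upper = 0.3 - 1e-12)
  check_scalar(indel_rate, "indel_rate", lower = 0, upper = 0.1)
  check_scalar(mean_len, "mean_len", lower = 100)
  withr::local_seed(seed)

  bases <- c("A", "C", "G", "T")
  gene_a <- sprintf("SIM_DN%d_c0_g1", seq_len(n_genes))
  gene_b <- sprintf("Gene%04d", seq_len(n_genes))
  tx_b <- sprintf("NM_%06d.1", seq_len(n_genes))
  len_b <- pmax(100L, as.integer(round(runif(n_genes, 0.7, 1.3) * mean_len)))
  n_iso <- sample(as.integer(isoforms_per_gene), n_genes, replace = TRUE)

  seq_b <- vapply(len_b, function(L) paste(sample(bases, L, replace = TRUE),
                                           collapse = ""), character(1))

  iso_rows <- vector("list", n_genes)
  seqs_a <- character(0)
  for (g in seq_len(n_genes)) {
    ref <- strsplit(seq_b[g], "", fixed = TRUE)[[1]]
    ids <- sprintf("%s_i%d", gene_a[g], seq_len(n_iso[g]))
    seqs <- vapply(seq_len(n_iso[g]), function(k) {
      x <- ref
      sub_at <- runif(length(x)) < divergence
      if (any(sub_at)) x[sub_at] <- sample(bases, sum(sub_at), replace = TRUE)
      if (indel_rate > 0) {
        ind_at <- which(runif(length(x)) < indel_rate)
        for (i in rev(ind_at)) {             # apply right-to-left, indices stay valid
          if (runif(1) < 0.5) {
            x <- x[-i]                       # deletion
          } else {
            x <- append(x, sample(bases, 1), after = i)
          }
        }
      }
      paste(x, collapse = "")
    }, character(1))
    names(seqs) <- ids
    seqs_a <- c(seqs_a, seqs)
    iso_rows[[g]] <- tibble(transcript = ids, gene_a = gene_a[g],
                            length = nchar(seqs))
  }

  truth <- structure(list(
    pairs = tibble(gene_a = gene_a, gene_b = gene_b, transcript_b = tx_b),
    isoforms = bind_rows(iso_rows),
    transcripts_b = tibble(transcript = tx_b, gene_b = gene_b, length = len_b),
    divergence = divergence,
    seed = seed
  ), class = "sim_truth")

  list(seqs_a = Biostrings::DNAStringSet(seqs_a),
       seqs_b = Biostrings::DNAStringSet(setNames(seq_b, tx_b)),
       truth = truth)
}

#' Write / read a simulated ortholog truth table
#'
#' One TSV row per A isoform with its true ortholog pair and both transcript
#' lengths; `read_sim_truth()` reconstructs the `sim_truth` object so that
#' write -> read -> write is byte-identical.
#'
#' @param truth A `sim_truth` object from [simulate_ortholog_transcriptomes()].
#' @param path Output TSV path.
#' @export
write_sim_truth <- function(truth, path) {
  tab <- truth$isoforms |>
    left_join(truth$pairs, by = "gene_a") |>
    left_join(rename(truth$transcripts_b, length_b = "length"),
              by = c("gene_b", "transcript_b" = "transcript")) |>
    rename(length_a = "length") |>
    mutate(divergence = truth$divergence, seed = truth$seed)
  readr::write_tsv(tab, path)
  invisible(path)
}

#' @rdname write_sim_truth
#' @export
read_sim_truth <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  structure(list(
    pairs = distinct(tab, .data$gene_a, .data$gene_b, .data$transcript_b),
    isoforms = tab |> select("transcript", "gene_a", length = "length_a"),
    transcripts_b = distinct(tab, transcript = .data$transcript_b,
                             .data$gene_b, length = .data$length_b),
    divergence = tab$divergence[1],
    seed = tab$seed[1]
  ), class = "sim_truth")
}

#' Simulate reciprocal BLAST tabular hit files
#'
#' Emits outfmt-6-style forward (A isoforms vs B reference) and reverse
#' (B reference vs A isoforms) hit tables for a simulated truth set. True-pair
#' alignments may be split into 2-3 HSPs; decoy cross-gene hits carry summed
#' bitscores strictly below 0.8x the true pair's, so reciprocal-best-hit
#' ground truth is unambiguous. A fraction of subject intervals are emitted
#' minus-strand (`sstart > send`).
#'
#' @param truth A `sim_truth` object.
#' @param split_prob Probability that a true alignment is reported as 2-3 HSPs.
#' @param decoy_rate Per-query probability of a spurious cross-gene hit.
#' @param seed Integer seed.
#' @return A list of tibbles `forward` and `reverse` with the 12 standard
#'   columns (qseqid sseqid pident length mismatch gapopen qstart qend sstart
#'   send evalue bitscore).
#' @export
simulate_blast_tables <- function(truth, split_prob = 0.5, decoy_rate = 0.2,
                                  seed = 1) {
  stopifnot(inherits(truth, "sim_truth"))
  if (nrow(truth$pairs) == 0) abort("`truth` has no ortholog pairs.")
  check_scalar(split_prob, "split_prob", lower = 0, upper = 1)
  check_scalar(decoy_rate, "decoy_rate", lower = 0, upper = 1)
  withr::local_seed(seed)

  iso <- truth$isoforms |>
    left_join(truth$pairs, by = "gene_a") |>
    left_join(rename(truth$transcripts_b, length_b = "length"),
              by = c("gene_b", "transcript_b" = "transcript"))
  pident_true <- 100 * (1 - 0.75 * truth$divergence)

  # one true alignment (possibly split into HSPs) covering most of both seqs
  true_rows <- function(qid, sid, qlen, slen, minus_ok) {
    aln <- min(qlen, slen)
    total_bits <- round(1.8 * aln * pident_true / 100, 1)
    k <- if (runif(1) < split_prob && aln >= 60) sample(2:3, 1) else 1L
    cuts <- sort(sample(seq(20, aln - 20), k - 1))
    lo <- c(1L, cuts + 1L)
    hi <- c(cuts, aln)
    # trim a small unaligned gap from internal boundaries
    if (k > 1) {
      gap <- pmin(5L, (hi - lo) %/% 4L)
      hi[-k] <- hi[-k] - gap[-k]
      lo[-1] <- lo[-1] + gap[-1]
    }
    minus <- minus_ok && runif(1) < 0.1
    sstart <- lo
    send <- hi
    if (minus) {
      sstart <- slen - lo + 1L
      send <- slen - hi + 1L
    }
    w <- (hi - lo + 1) / aln
    bits <- round(total_bits * w, 1)
    pid <- round(pmin(100, pident_true + rnorm(k, 0, 0.5)), 2)
    tibble(qseqid = qid, sseqid = sid, pident = pid,
           length = hi - lo + 1L,
           mismatch = as.integer(round((hi - lo + 1) * (1 - pid / 100))),
           gapopen = 0L, qstart = lo, qend = hi,
           sstart = sstart, send = send,
           evalue = signif(10^-pmin(180, bits / 2), 3), bitscore = bits)
  }

  decoy_rows <- function(qid, qlen, subj_pool, true_bits) {
    j <- sample(nrow(subj_pool), 1)
    slen <- subj_pool$length[j]
    aln <- max(30L, as.integer(round(0.3 * min(qlen, slen))))
    aln <- min(aln, qlen, slen)
    bits <- round(runif(1, 0.2, 0.75) * true_bits, 1)
    q0 <- sample(seq_len(qlen - aln + 1), 1)
    s0 <- sample(seq_len(slen - aln + 1), 1)
    pid <- round(runif(1, 70, 85), 2)
    minus <- runif(1) < 0.3
    tibble(qseqid = qid, sseqid = subj_pool$transcript[j], pident = pid,
           length = aln,
           mismatch = as.integer(round(aln * (1 - pid / 100))),
           gapopen = sample(0:2, 1),
           qstart = q0, qend = q0 + aln - 1L,
           sstart = if (minus) s0 + aln - 1L else s0,
           send = if (minus) s0 else s0 + aln - 1L,
           evalue = signif(10^-pmin(180, bits / 2), 3), bitscore = bits)
  }

  fwd <- vector("list", nrow(iso))
  rev_ <- list()
  for (i in seq_len(nrow(iso))) {
    r <- true_rows(iso$transcript[i], iso$transcript_b[i],
                   iso$length[i], iso$length_b[i], minus_ok = TRUE)
    rows <- list(r)
    if (runif(1) < decoy_rate) {
      pool <- filter(truth$transcripts_b, .data$gene_b != iso$gene_b[i])
      if (nrow(pool) > 0) {
        rows <- c(rows, list(decoy_rows(iso$transcript[i], iso$length[i],
                                        pool, sum(r$bitscore))))
      }
    }
    fwd[[i]] <- bind_rows(rows)
  }

  iso_pool <- select(truth$isoforms, transcript = "transcript",
                     gene_a = "gene_a", length = "length")
  for (g in seq_len(nrow(truth$pairs))) {
    tb <- truth$pairs$transcript_b[g]
    blen <- truth$transcripts_b$length[match(tb, truth$transcripts_b$transcript)]
    members <- filter(iso, .data$gene_a == truth$pairs$gene_a[g])
    rows <- lapply(seq_len(nrow(members)), function(i) {
      true_rows(tb, members$transcript[i], blen, members$length[i],
                minus_ok = TRUE)
    })
    best_bits <- max(vapply(rows, function(r) sum(r$bitscore), numeric(1)))
    if (runif(1) < decoy_rate) {
      pool <- filter(iso_pool, .data$gene_a != truth$pairs$gene_a[g])
      if (nrow(pool) > 0) rows <- c(rows, list(decoy_rows(tb, blen, pool,
                                                          best_bits)))
    }
    rev_[[g]] <- bind_rows(rows)
  }

  list(forward = bind_rows(fwd), reverse = bind_rows(rev_))
}

#' Write a hit table as a BLAST outfmt-6 TSV (no header)
#' @param hits A hit tibble with the 12 standard columns.
#' @param path Output path.
#' @export
write_blast_tabular <- function(hits, path) {
  readr::write_tsv(hits[, blast6_cols], path, col_names = FALSE)
  invisible(path)
}

#' Simulate single-end transcriptome alignments as SAM text
#'
#' Places a known fraction of reads wholly inside the species-A CORE intervals
#' of each ortholog pair and the remainder wholly outside them (on off-target
#' reference sequences absent from the BED set), so the downstream filter's
#' retained fraction is known exactly. Truth counts per gene are recorded in
#' `@CO` header lines and returned as a tibble.
#'
#' @param core A `core_regions` object (see [build_core_beds()]).
#' @param reads_per_gene Reads simulated per ortholog pair.
#' @param off_target_frac Fraction of each gene's reads placed outside COREs.
#' @param read_len Read length in bp; must fit inside at least one CORE
#'   interval of every pair.
#' @param transcript_lengths Optional named integer vector of species-A
#'   transcript lengths for the SAM header; defaults to max interval end + 100.
#' @param seed Integer seed.
#' @return A list with `sam` (character vector of SAM lines) and `truth`
#'   (tibble with gene, n_in, n_out).
#' @export
simulate_alignments <- function(core, reads_per_gene = 50,
                                off_target_frac = 0, read_len = 50,
                                transcript_lengths = NULL, seed = 1) {
  stopifnot(inherits(core, "core_regions"))
  if (nrow(core$intervals_a) == 0) abort("`core` has no species-A intervals.")
  check_scalar(off_target_frac, "off_target_frac", lower = 0, upper = 1)
  check_scalar(read_len, "read_len", lower = 1, integerish = TRUE)
  withr::local_seed(seed)

  iv <- core$intervals_a |>
    left_join(core$pair_index, by = "pair_id") |>
    mutate(width = .data$end - .data$start)
  if (max(iv$width) < read_len) {
    abort("`read_len` is longer than every CORE interval.",
          class = "corexpr_parameter_error")
  }
  genes <- split(iv, iv$gene_b)

  if (is.null(transcript_lengths)) {
    transcript_lengths <- tapply(iv$end, iv$transcript, max) + 100
  }
  sq <- sprintf("@SQ\tSN:%s\tLN:%d", names(transcript_lengths),
                as.integer(transcript_lengths))

  n_in_per <- as.integer(round(reads_per_gene * (1 - off_target_frac)))
  rec <- list()
  truth <- list()
  decoy_sq <- character(0)
  for (g in names(genes)) {
    giv <- filter(genes[[g]], .data$width >= read_len)
    if (nrow(giv) == 0) {
      abort(sprintf("no CORE interval of gene %s can hold a %d bp read.",
                    g, read_len), class = "corexpr_parameter_error")
    }
    n_in <- n_in_per
    n_out <- reads_per_gene - n_in
    rows <- character(0)
    if (n_in > 0) {
      pick <- sample(nrow(giv), n_in, replace = TRUE)
      pos <- giv$start[pick] +
        floor(runif(n_in) * (giv$width[pick] - read_len + 1)) + 1L
      rows <- sprintf("rd_%s_in_%04d\t0\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t%s",
                      g, seq_len(n_in), giv$transcript[pick], as.integer(pos),
                      read_len, strrep("A", read_len), strrep("I", read_len))
    }
    if (n_out > 0) {
      decoy <- sprintf("OFFTARGET_%s", g)
      decoy_sq <- c(decoy_sq,
                    sprintf("@SQ\tSN:%s\tLN:%d", decoy, read_len + 100L))
      pos <- sample(101L, n_out, replace = TRUE)
      rows <- c(rows, sprintf(
        "rd_%s_out_%04d\t0\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t%s",
        g, seq_len(n_out), decoy, pos, read_len,
        strrep("A", read_len), strrep("I", read_len)))
    }
    rec[[g]] <- rows
    truth[[g]] <- tibble(gene = g, n_in = n_in, n_out = n_out)
  }

  truth <- bind_rows(truth)
  header <- c("@HD\tVN:1.6\tSO:unknown", sq, decoy_sq,
              sprintf("@CO\ttruth gene=%s in=%d out=%d",
                      truth$gene, truth$n_in, truth$n_out))
  list(sam = c(header, unlist(rec, use.names = FALSE)), truth = truth)
}

#' Simulate a negative-binomial count matrix with a planted species-by-time
#' interaction
#'
#' Counts follow NB(mu, phi) with `var = mu + phi * mu^2`. A fraction of genes
#' carry `interaction_lfc` (log2) on species A at days > 0 only, so the
#' planted effect lies purely on the species-by-time interaction contrast.
#' Per-sample library scale factors vary at most 2-fold.
#'
#' @param n_genes Number of genes.
#' @param groups Tibble of (species, day) cells; must contain both species at
#'   day 0 and at least one later day.
#' @param n_rep Replicates per group (>= 2).
#' @param dispersion NB dispersion phi (> 0).
#' @param frac_de Fraction of genes with a planted interaction effect.
#' @param interaction_lfc Planted interaction effect in log2 units.
#' @param seed Integer seed.
#' @return A list with `counts` (tibble, gene x samples), `samples`
#'   (sample_id, species, day, replicate) and `truth` (gene, lfc).
#' @export
simulate_counts <- function(n_genes,
                            groups = tidyr::crossing(species = c("A", "B"),
                                                     day = c(0, 7, 14)),
                            n_rep = 4, dispersion = 0.1, frac_de = 0.1,
                            interaction_lfc = 2, seed = 1) {
  check_scalar(n_genes, "n_genes", lower = 1, integerish = TRUE)
  check_scalar(n_rep, "n_rep", lower = 2, integerish = TRUE)
  check_scalar(dispersion, "dispersion", lower = 0, strict_lower = TRUE)
  check_scalar(frac_de, "frac_de", lower = 0, upper = 1)
  groups <- as_tibble(groups)
  for (sp in unique(groups$species)) {
    if (!0 %in% groups$day[groups$species == sp])
      abort("every species needs a day-0 group.")
  }
  if (length(unique(groups$species)) < 2 || max(groups$day) <= 0)
    abort("`groups` must include two species and a post-baseline day.")
  withr::local_seed(seed)

  genes <- sprintf("G%05d", seq_len(n_genes))
  mu0 <- 2^runif(n_genes, 4, 11)
  lfc <- numeric(n_genes)
  n_de <- round(frac_de * n_genes)
  if (n_de > 0) lfc[sample(n_genes, n_de)] <- interaction_lfc

  samples <- groups |>
    tidyr::crossing(replicate = seq_len(n_rep)) |>
    mutate(sample_id = sprintf("%s_d%d_r%d", .data$species, .data$day,
                               .data$replicate)) |>
    select("sample_id", "species", "day", "replicate")
  scale_j <- 2^runif(nrow(samples), -0.5, 0.5)

  counts <- matrix(0L, n_genes, nrow(samples),
                   dimnames = list(genes, samples$sample_id))
  for (j in seq_len(nrow(samples))) {
    bump <- if (samples$species[j] == "A" && samples$day[j] > 0) 2^lfc else 1
    mu <- mu0 * bump * scale_j[j]
    counts[, j] <- rnbinom(n_genes, size = 1 / dispersion, mu = mu)
  }

  list(counts = count_matrix_to_tibble(counts), samples = samples,
       truth = tibble(gene = genes, lfc = lfc, base_mean = mu0))
}

#' Simulate an expression matrix with planted co-expression modules
#'
#' Genes inside a module load on a shared latent factor; the loading is
#' chosen so the pairwise Spearman correlation is `within_r` (via the
#' Gaussian rank-correlation relation rho_S = (6/pi) asin(rho_P / 2)), and
#' the per-module noise vectors are orthonormalized against the factor in
#' sample space, so the realized within-module Pearson correlation is exact
#' and only the rank-conversion wobble (~1/sqrt(n_samples)) remains. Three
#' further populations shape the thresholded graph: hub-and-spoke "star"
#' groups whose hub-leaf correlation sits just above `within_r` while
#' leaf-leaf correlations sit well below it (leaves supply the degree-1
#' mass and star hubs the heavy upper tail, so the degree distribution
#' decays like k^-2 across the threshold band, as in real co-expression
#' data); bridge hub genes connecting pairs of larger modules through
#' correlated factors; and independent background noise genes. The default
#' module-size profile continues the k^-2 line over degrees 2-6.
#'
#' @param n_modules Number of modules; defaults to `length(module_sizes)`.
#' @param module_sizes Integer vector of module sizes (recycled to
#'   `n_modules`).
#' @param within_r Target within-module Spearman correlation in (0, 1).
#' @param n_background Number of independent background genes.
#' @param star_sizes Integer vector of leaf counts, one star per entry;
#'   `integer(0)` for none.
#' @param n_samples Number of samples (>= 10; blocks are exact only when
#'   `n_samples` exceeds the largest block by 2).
#' @param seed Integer seed.
#' @return A list with `expr` (tibble, gene x samples) and `truth`
#'   (gene, module; 0 denotes bridge hubs, -1 star genes, NA background).
#' @export
simulate_coexpression <- function(n_modules = NULL,
                                  module_sizes = rep(3:7, c(25, 8, 4, 2, 1)),
                                  within_r = 0.92, n_background = 100,
                                  star_sizes = rep(c(7:14, 16, 18, 21, 25),
                                                   c(6, 4, 3, 3, 2, 2, 1, 1,
                                                     1, 1, 1, 1)),
                                  n_samples = 500, seed = 1) {
  if (within_r <= 0 || within_r >= 1) {
    abort("`within_r` must lie in (0, 1).", class = "corexpr_parameter_error")
  }
  check_scalar(n_samples, "n_samples", lower = 10, integerish = TRUE)
  if (is.null(n_modules)) n_modules <- length(module_sizes)
  module_sizes <- rep_len(as.integer(module_sizes), n_modules)
  withr::local_seed(seed)

  pearson_r <- 2 * sin(pi * within_r / 6)   # invert rho_S = (6/pi) asin(r/2)
  a <- sqrt(pearson_r)

  # exact-correlation block: first column of Q spans the (centered) factor,
  # remaining columns are sample-orthonormal noise directions
  exact_block <- function(factor, k) {
    M <- cbind(factor, matrix(rnorm(n_samples * k), n_samples, k))
    M <- scale(M, center = TRUE, scale = FALSE)
    qr.Q(qr(M))
  }

  # bridge pairs of larger modules through correlated factors; the bridge
  # hub (a near-noiseless copy of the normalized factor sum) correlates
  # with members of both modules while cross-module member pairs stay below
  # the threshold band
  fc <- 0.87
  z <- matrix(rnorm(n_samples * max(n_modules, 1)), n_samples,
              max(n_modules, 1))
  hub_latent <- list()
  if (n_modules >= 2) {
    for (m in seq(2, n_modules, by = 2)) {
      if (min(module_sizes[m - 1], module_sizes[m]) < 5) next
      z[, m] <- fc * z[, m - 1] + sqrt(1 - fc^2) * z[, m]
      hub_latent[[length(hub_latent) + 1]] <-
        (z[, m - 1] + z[, m]) / sqrt(2 * (1 + fc))
    }
  }

  expr <- list()
  truth <- list()
  for (m in seq_len(n_modules)) {
    s <- module_sizes[m]
    Q <- exact_block(z[, m], s)
    for (i in seq_len(s)) {
      gid <- sprintf("M%02dg%02d", m, i)
      expr[[gid]] <- a * Q[, 1] + sqrt(1 - a^2) * Q[, i + 1]
      truth[[gid]] <- tibble(gene = gid, module = m)
    }
  }
  for (h in seq_along(hub_latent)) {
    gid <- sprintf("HUB%02d", h)
    expr[[gid]] <- 0.998 * hub_latent[[h]] +
      sqrt(1 - 0.998^2) * rnorm(n_samples)
    truth[[gid]] <- tibble(gene = gid, module = 0L)
  }

  # stars: hub-leaf Spearman ~ within_r + 0.015, leaf-leaf = (hub-leaf)^2 on
  # the Pearson scale, comfortably below the threshold band
  if (length(star_sizes) > 0) {
    a_s <- 2 * sin(pi * min(within_r + 0.015, 0.985) / 6)
    for (st in seq_along(star_sizes)) {
      d <- star_sizes[st]
      Q <- exact_block(rnorm(n_samples), d)
      hid <- sprintf("STAR%02dhub", st)
      expr[[hid]] <- Q[, 1]
      truth[[hid]] <- tibble(gene = hid, module = -1L)
      for (i in seq_len(d)) {
        gid <- sprintf("STAR%02dleaf%02d", st, i)
        expr[[gid]] <- a_s * Q[, 1] + sqrt(1 - a_s^2) * Q[, i + 1]
        truth[[gid]] <- tibble(gene = gid, module = -1L)
      }
    }
  }

  for (b in seq_len(n_background)) {
    gid <- sprintf("BG%03d", b)
    expr[[gid]] <- rnorm(n_samples)
    truth[[gid]] <- tibble(gene = gid, module = NA_integer_)
  }

  mat <- t(vapply(expr, identity, numeric(n_samples)))
  colnames(mat) <- sprintf("S%03d", seq_len(n_samples))
  list(expr = count_matrix_to_tibble(mat), truth = bind_rows(truth))
}

# inverse-CDF sampler for the zeta-normalized discrete power law (no seed)
sample_discrete_powerlaw <- function(n, alpha, xmin) {
  u <- runif(n)
  z0 <- hurwitz_zeta(alpha, xmin)
  tail_needed <- 1 - max(u)
  K <- xmin
  while (hurwitz_zeta(alpha, K + 1) / z0 >= tail_needed) {
    K <- K * 2
    if (K > 5e7) abort("power-law tail too heavy to tabulate; raise alpha.")
  }
  k <- seq(xmin, K)
  cdf <- cumsum(k^(-alpha) / z0)
  as.integer(xmin + findInterval(u, cdf))
}

#' Draw from a discrete power-law distribution
#'
#' i.i.d. sample from `p_k = k^-alpha / zeta(alpha, xmin)` for
#' `k >= xmin`, via inverse-CDF on the Hurwitz-zeta-normalized pmf.
#'
#' @param alpha Exponent (> 1; the distribution is non-normalizable
#'   otherwise).
#' @param xmin Lower support bound (integer >= 1).
#' @param n Sample size.
#' @param seed Integer seed.
#' @return Integer vector of length `n`, all values `>= xmin`.
#' @export
simulate_powerlaw_degrees <- function(alpha, xmin = 1, n, seed = 1) {
  check_scalar(alpha, "alpha", lower = 1, strict_lower = TRUE)
  check_scalar(xmin, "xmin", lower = 1, integerish = TRUE)
  check_scalar(n, "n", lower = 1, integerish = TRUE)
  withr::local_seed(seed)
  sample_discrete_powerlaw(n, alpha, as.integer(xmin))
}
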