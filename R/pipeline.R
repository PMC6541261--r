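stage_hash <- function(params, inputs) {
  md5 <- if (length(inputs)) unname(tools::md5sum(inputs)) else character(0)
  digest_input <- paste(c(jsonlite::toJSON(params, auto_unbox = TRUE,
                                           digits = NA), md5),
                        collapse = "|")
  # md5 of the serialized parameters + input hashes, via a temp file
  tf <- tempfile()
  writeLines(digest_input, tf)
  on.exit(unlink(tf))
  unname(tools::md5sum(tf))
}

#' Run the CORE pipeline end to end
#'
#' Executes the stages simulate (optional) -> orthologs -> core-bed ->
#' filter-count -> de -> network -> subnet (optional) -> metrics in
#' dependency order, writing every artifact under `out_dir`. Each stage is
#' idempotent and resumable: a JSON manifest records a hash of the stage
#' parameters and input files, and unchanged stages are skipped on re-run.
#' All randomness derives from the single `seed` in the config.
#'
#' @param config A YAML file path or an equivalent nested list. Recognized
#'   sections: `out_dir`, `seed`, `simulate` (n_genes, divergence,
#'   decoy_rate, split_prob, reads_per_gene, off_target_frac, read_len,
#'   n_rep, dispersion, frac_de, interaction_lfc), `orthologs`
#'   (forward/reverse TSV paths when not simulating, evalue_cutoff), `de`
#'   (min_cpm, min_samples), `network` (grid_start, grid_stop, grid_step,
#'   n_boot), `subnet` (regulators: TSV paths, min_size), `counts` /
#'   `samples` paths when not simulating.
#' @param force Re-run all stages even when the manifest says they are
#'   current.
#' @return Invisibly, a list with the manifest and the log lines.
#' @export
run_core_pipeline <- function(config, force = FALSE) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  out_dir <- cfg$out_dir %||% abort("config needs `out_dir`.")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- cfg$seed %||% 1
  manifest_path <- file.path(out_dir, "manifest.json")
  manifest <- if (file.exists(manifest_path)) {
    jsonlite::read_json(manifest_path)
  } else list()
  log_lines <- character(0)
  say <- function(...) {
    line <- sprintf(...)
    log_lines <<- c(log_lines, line)
    inform(line)
  }

  run_stage <- function(name, params, inputs, outputs, fun) {
    h <- stage_hash(params, inputs)
    cur <- manifest[[name]]
    if (!force && !is.null(cur) && identical(cur$hash, h) &&
        all(file.exists(unlist(outputs)))) {
      say("stage %s: up to date, skipped", name)
      return(invisible())
    }
    say("stage %s: running", name)
    fun()
    missing <- outputs[!file.exists(unlist(outputs))]
    if (length(missing) > 0) {
      abort(sprintf("stage %s did not produce: %s", name,
                    paste(unlist(missing), collapse = ", ")))
    }
    manifest[[name]] <<- list(hash = h, outputs = outputs,
                              completed = format(Sys.time(), tz = "UTC"),
                              version = as.character(
                                utils::packageVersion("corexpr")))
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         pretty = TRUE)
  }
  path <- function(...) file.path(out_dir, ...)

  sim <- cfg$simulate
  if (!is.null(sim)) {
    run_stage("simulate", c(sim, seed = seed), character(0),
              list(path("truth.tsv"), path("forward.tsv"),
                   path("reverse.tsv"), path("counts.tsv"),
                   path("samples.tsv")), function() {
      tx <- simulate_ortholog_transcriptomes(
        n_genes = sim$n_genes %||% 50,
        divergence = sim$divergence %||% 0.05,
        seed = seed)
      write_sim_truth(tx$truth, path("truth.tsv"))
      Biostrings::writeXStringSet(tx$seqs_a, path("species_a.fasta"))
      Biostrings::writeXStringSet(tx$seqs_b, path("species_b.fasta"))
      bt <- simulate_blast_tables(tx$truth,
                                  split_prob = sim$split_prob %||% 0.5,
                                  decoy_rate = sim$decoy_rate %||% 0.2,
                                  seed = seed + 1)
      write_blast_tabular(bt$forward, path("forward.tsv"))
      write_blast_tabular(bt$reverse, path("reverse.tsv"))
      cs <- simulate_counts(n_genes = sim$n_counts_genes %||% 2000,
                            n_rep = sim$n_rep %||% 4,
                            dispersion = sim$dispersion %||% 0.1,
                            frac_de = sim$frac_de %||% 0.1,
                            interaction_lfc = sim$interaction_lfc %||% 2,
                            seed = seed + 2)
      write_counts(cs$counts, path("counts.tsv"))
      write_samples(cs$samples, path("samples.tsv"))
      readr::write_tsv(cs$truth, path("counts_truth.tsv"))
    })
  }

  fwd_path <- if (!is.null(sim)) path("forward.tsv") else
    cfg$orthologs$forward
  rev_path <- if (!is.null(sim)) path("reverse.tsv") else
    cfg$orthologs$reverse
  ecut <- cfg$orthologs$evalue_cutoff %||% 1e-5
  run_stage("orthologs", list(evalue_cutoff = ecut),
            c(fwd_path, rev_path), list(path("orthologs.tsv")), function() {
    fwd <- parse_blast_tabular(fwd_path, "forward")
    rev_ <- parse_blast_tabular(rev_path, "reverse")
    orth <- reciprocal_best_hits(fwd, rev_, evalue_cutoff = ecut)
    say("orthologs: %d pairs accepted", nrow(orth))
    write_ortholog_table(orth, path("orthologs.tsv"))
  })

  run_stage("core_bed", list(), c(fwd_path, path("orthologs.tsv")),
            list(path("core_a.bed"), path("core_b.bed"),
                 path("gene_map.tsv")), function() {
    orth <- read_ortholog_table(path("orthologs.tsv"))
    fwd <- parse_blast_tabular(fwd_path, "forward")
    core <- build_core_beds(orth, fwd)
    write_core_beds(core, path("core_a.bed"), path("core_b.bed"))
    write_gene_map(build_gene_transcript_map(orth), path("gene_map.tsv"))
  })

  fc <- cfg$filter_count %||% list()
  run_stage("filter_count",
            list(min_overlap = fc$min_overlap %||% 1,
                 min_overlap_frac = fc$min_overlap_frac %||% 0,
                 reads_per_gene = fc$reads_per_gene %||% 50,
                 off_target_frac = fc$off_target_frac %||% 0.2,
                 seed = seed),
            c(path("core_a.bed"), path("gene_map.tsv")),
            list(path("filtered_counts.tsv"),
                 path("filter_summary.json")), function() {
    orth <- read_ortholog_table(path("orthologs.tsv"))
    fwd <- parse_blast_tabular(fwd_path, "forward")
    core <- build_core_beds(orth, fwd)
    sam <- simulate_alignments(core,
                               reads_per_gene = fc$reads_per_gene %||% 50,
                               off_target_frac = fc$off_target_frac %||% 0.2,
                               read_len = fc$read_len %||% 50, seed = seed)
    sam_path <- path("alignments_a.sam")
    writeLines(sam$sam, sam_path)
    flt <- filter_alignments(sam_path, core$intervals_a,
                             min_overlap = fc$min_overlap %||% 1,
                             min_overlap_frac = fc$min_overlap_frac %||% 0)
    map <- read_gene_map(path("gene_map.tsv"))
    iso_map <- core$intervals_a |>
      distinct(transcript = .data$transcript, .data$pair_id) |>
      left_join(core$pair_index, by = "pair_id") |>
      select("transcript", gene = "gene_b")
    cnt <- count_genes(flt, iso_map, sample_id = "filtered")
    say("filter-count: kept %d of %d records",
        sum(flt$records$kept), nrow(flt$records))
    readr::write_tsv(cnt, path("filtered_counts.tsv"))
    jsonlite::write_json(flt$summary, path("filter_summary.json"),
                         auto_unbox = TRUE)
  })

  counts_path <- if (!is.null(sim)) path("counts.tsv") else cfg$counts
  samples_path <- if (!is.null(sim)) path("samples.tsv") else cfg$samples
  de_cfg <- cfg$de %||% list()
  run_stage("de", list(min_cpm = de_cfg$min_cpm %||% 10,
                       min_samples = de_cfg$min_samples %||% 3),
            c(counts_path, samples_path),
            list(path("logcpm.tsv")), function() {
    counts <- read_counts(counts_path)
    samples <- read_samples(samples_path)
    de <- run_de(counts, samples, min_cpm = de_cfg$min_cpm %||% 10,
                 min_samples = de_cfg$min_samples %||% 3)
    for (nm in names(de$results)) {
      de_table(de$results[[nm]], path = path(sprintf("de_%s.tsv", nm)))
    }
    say("de: %d genes tested, %d contrasts", nrow(de$voom$E),
        length(de$results))
    write_counts(de$voom$E, path("logcpm.tsv"))
  })

  nw <- cfg$network %||% list()
  run_stage("network", list(grid_start = nw$grid_start %||% 0.99,
                            grid_stop = nw$grid_stop %||% 0.70,
                            grid_step = nw$grid_step %||% 0.002,
                            n_boot = nw$n_boot %||% 200, seed = seed),
            path("logcpm.tsv"),
            list(path("threshold_report.tsv"),
                 path("powerlaw.json")), function() {
    expr <- read_counts(path("logcpm.tsv"))
    rho <- spearman_matrix(expr)
    sel <- select_threshold(rho, grid = seq(nw$grid_start %||% 0.99,
                                            nw$grid_stop %||% 0.70,
                                            by = -(nw$grid_step %||% 0.002)))
    readr::write_tsv(sel$report, path("threshold_report.tsv"))
    pl <- list(status = sel$status, threshold = sel$threshold)
    if (sel$status == "ok") {
      net <- network_at_threshold(rho, sel$threshold)
      write_edge_list(net, path("edges.tsv"))
      deg <- igraph::degree(as_igraph(net))
      fit <- tryCatch(powerlaw_bootstrap(deg, n_boot = nw$n_boot %||% 200,
                                         seed = seed),
                      error = function(e) NULL)
      if (!is.null(fit)) {
        pl <- c(pl, list(alpha = fit$alpha, xmin = fit$xmin, ks = fit$ks,
                         p_value = fit$p_value))
      }
      say("network: threshold %.3f, %d nodes, %d edges", sel$threshold,
          length(net$nodes), nrow(net$edges))
    } else {
      say("network: no passing threshold")
    }
    jsonlite::write_json(pl, path("powerlaw.json"), auto_unbox = TRUE,
                         digits = NA)
  })

  sn <- cfg$subnet
  if (!is.null(sn) && file.exists(path("edges.tsv"))) {
    run_stage("subnet", list(min_size = sn$min_size %||% 10),
              c(path("edges.tsv"), unlist(sn$regulators)),
              list(path("subnetworks.tsv")), function() {
      net <- read_edge_list(path("edges.tsv"))
      allowed <- load_regulator_targets(unlist(sn$regulators),
                                        symbol_col = sn$symbol_col %||%
                                          "symbol")
      subs <- enumerate_subnetworks(net, allowed,
                                    min_size = sn$min_size %||% 10)
      readr::write_tsv(select(subs, -"subnetwork"), path("subnetworks.tsv"))
      say("subnet: %d subnetworks, %d flagged", nrow(subs),
          sum(subs$flagged))
    })
  }

  if (!is.null(sim)) {
    run_stage("metrics", list(), path("truth.tsv"),
              list(path("exn50.tsv")), function() {
      truth <- read_sim_truth(path("truth.tsv"))
      lens <- truth$isoforms$length
      counts <- read_counts(path("counts.tsv"))
      say("metrics: N50 = %d over %d transcripts", n50(lens), length(lens))
      # uniform expression proxy over simulated isoforms
      readr::write_tsv(exn50(rep(1, length(lens)), lens,
                             truth$isoforms$transcript),
                       path("exn50.tsv"))
    })
  }

  writeLines(log_lines, path("pipeline.log"))
  invisible(list(manifest = manifest, log = log_lines))
}
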