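#' Filter transcriptome alignments to CORE intervals
#'
#' Keeps primary, mapped, non-supplementary single-end records whose aligned
#' reference span (from the CIGAR; M/D/N/=/X consume reference) overlaps the
#' union of that transcript's CORE intervals by at least `min_overlap` bases
#' and at least `min_overlap_frac` of the aligned length. Records on
#' reference sequences absent from the interval set are dropped and counted,
#' not errors.
#'
#' @param path A SAM or BAM file (SAM is converted on the fly).
#' @param intervals One side of a `core_regions` object: tibble with
#'   transcript, start, end (0-based half-open).
#' @param min_overlap Minimum overlap in bp (default 1).
#' @param min_overlap_frac Minimum overlap as a fraction of the aligned
#'   reference length (default 0).
#' @return A list with `records` (tibble: qname, transcript, start, end,
#'   overlap, kept, reason) and `summary` (tibble of kept/dropped counts by
#'   reason).
#' @export
filter_alignments <- function(path, intervals, min_overlap = 1,
                              min_overlap_frac = 0) {
  check_scalar(min_overlap, "min_overlap", lower = 0)
  check_scalar(min_overlap_frac, "min_overlap_frac", lower = 0, upper = 1)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  rec <- Rsamtools::scanBam(
    bam, param = Rsamtools::ScanBamParam(
      what = c("qname", "flag", "rname", "pos", "cigar")))[[1]]
  n <- length(rec$qname)
  if (n == 0) {
    return(list(records = tibble(qname = character(), transcript = character(),
                                 start = integer(), end = integer(),
                                 overlap = integer(), kept = logical(),
                                 reason = character()),
                summary = tibble(reason = character(), n = integer())))
  }
  flag <- rec$flag
  if (any(bitwAnd(flag, 1L) > 0)) {
    warn("paired-end records found; mates are treated as independent single-end reads.")
  }
  unmapped <- bitwAnd(flag, 4L) > 0
  secondary <- bitwAnd(flag, 256L) > 0
  supplementary <- bitwAnd(flag, 2048L) > 0
  width <- rep(NA_integer_, n)
  ok <- !unmapped & !is.na(rec$cigar)
  width[ok] <- GenomicAlignments::cigarWidthAlongReferenceSpace(rec$cigar[ok])
  start <- rec$pos
  end <- start + width - 1L        # 1-based closed span

  # union of intervals per transcript, as 1-based closed IRanges
  merged <- merge_intervals(select(intervals, "transcript", "start", "end"))
  bed_gr <- GenomicRanges::GRanges(merged$transcript,
                                   IRanges::IRanges(merged$start + 1L,
                                                    merged$end))
  overlap <- integer(n)
  in_bed <- !is.na(rec$rname) & as.character(rec$rname) %in% merged$transcript
  idx <- which(ok & in_bed)
  if (length(idx) > 0) {
    read_gr <- GenomicRanges::GRanges(as.character(rec$rname)[idx],
                                      IRanges::IRanges(start[idx], end[idx]))
    hits <- GenomicRanges::findOverlaps(read_gr, bed_gr)
    if (length(hits) > 0) {
      ww <- IRanges::width(IRanges::pintersect(
        IRanges::ranges(read_gr)[S4Vectors::queryHits(hits)],
        IRanges::ranges(bed_gr)[S4Vectors::subjectHits(hits)]))
      ov <- tapply(ww, S4Vectors::queryHits(hits), sum)
      overlap[idx[as.integer(names(ov))]] <- as.integer(ov)
    }
  }

  reason <- rep("kept", n)
  reason[overlap < max(min_overlap, 1e-9) |
           overlap < min_overlap_frac * width] <- "low_overlap"
  reason[!in_bed] <- "reference_not_in_bed"
  reason[supplementary] <- "supplementary"
  reason[secondary] <- "secondary"
  reason[unmapped] <- "unmapped"
  kept <- reason == "kept"

  records <- tibble(qname = rec$qname,
                    transcript = as.character(rec$rname),
                    start = start, end = end, overlap = overlap,
                    kept = kept, reason = reason)
  list(records = records,
       summary = records |> count(.data$reason, name = "n") |>
         arrange(desc(.data$n)))
}

#' Aggregate retained alignments to gene-level counts
#'
#' One count per gene label = number of retained primary records whose
#' reference transcript maps to that gene through the gene-transcript map.
#' Records on transcripts with no map entry are tallied separately and
#' reported via the `n_unassigned` attribute.
#'
#' @param filtered Result of [filter_alignments()] (or its `records` tibble).
#' @param map Gene-transcript map tibble (transcript, gene).
#' @param sample_id Optional sample name for the count column.
#' @return Tibble with `gene` and one count column.
#' @export
count_genes <- function(filtered, map, sample_id = "count") {
  records <- if (is.data.frame(filtered)) filtered else filtered$records
  kept <- filter(records, .data$kept)
  joined <- left_join(kept, map, by = "transcript")
  n_unassigned <- sum(is.na(joined$gene))
  if (n_unassigned > 0) {
    inform(sprintf("%d retained record(s) map to no gene; excluded.",
                   n_unassigned))
  }
  out <- joined |>
    filter(!is.na(.data$gene)) |>
    count(.data$gene, name = sample_id) |>
    arrange(.data$gene)
  attr(out, "n_unassigned") <- n_unassigned
  out
}

#' Assemble the combined two-species count matrix
#'
#' Joins per-species gene-level count tables on the shared reference gene
#' labels; the row universe is the intersection of labels present on both
#' sides (the ortholog-labelled genes). Columns are ordered species A samples
#' then species B samples.
#'
#' @param counts_a,counts_b Tibbles with a `gene` column and one column per
#'   sample.
#' @return Tibble with `gene` and all sample columns.
#' @export
combine_species_counts <- function(counts_a, counts_b) {
  sa <- setdiff(names(counts_a), "gene")
  sb <- setdiff(names(counts_b), "gene")
  if (anyDuplicated(c(sa, sb))) {
    abort("duplicate sample ids across species.",
          class = "corexpr_validation_error")
  }
  dropped <- length(union(counts_a$gene, counts_b$gene)) -
    length(intersect(counts_a$gene, counts_b$gene))
  if (dropped > 0) {
    inform(sprintf("%d gene(s) present on one side only; dropped.", dropped))
  }
  inner_join(counts_a, counts_b, by = "gene") |> arrange(.data$gene)
}

#' Write / read a genes-by-samples count TSV
#' @param counts Tibble with `gene` plus sample columns (or matrix).
#' @param path TSV path.
#' @export
write_counts <- function(counts, path) {
  if (is.matrix(counts)) counts <- count_matrix_to_tibble(counts)
  readr::write_tsv(counts, path)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Write / read the sample metadata TSV
#' @param samples Tibble with sample_id, species, day, replicate.
#' @param path TSV path.
#' @export
write_samples <- function(samples, path) {
  readr::write_tsv(samples, path)
  invisible(path)
}

#' @rdname write_samples
#' @export
read_samples <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(sample_id = "c", species = "c"))
}
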