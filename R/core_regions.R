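#' Convert HSP coordinates to BED-style intervals
#'
#' BLAST coordinates are 1-based inclusive; BED intervals are 0-based
#' half-open. The query interval is `(qstart - 1, qend)`; the subject
#' interval is `(min(sstart, send) - 1, max(sstart, send))` with strand
#' `"-"` iff `sstart > send`.
#'
#' @param hsps An HSP tibble (one or more rows) with qseqid, qstart, qend,
#'   sseqid, sstart, send.
#' @return A tibble with query (transcript, start, end) and subject
#'   (transcript, start, end, strand) interval columns, one row per HSP.
#' @export
hsp_to_bed_intervals <- function(hsps) {
  if (any(hsps$qend < hsps$qstart)) {
    abort("invalid HSP: qend < qstart.", class = "corexpr_validation_error")
  }
  tibble(
    q_transcript = hsps$qseqid,
    q_start = hsps$qstart - 1L, q_end = hsps$qend,
    s_transcript = hsps$sseqid,
    s_start = pmin(hsps$sstart, hsps$send) - 1L,
    s_end = pmax(hsps$sstart, hsps$send),
    s_strand = ifelse(hsps$sstart > hsps$send, "-", "+")
  )
}

#' Merge 0-based half-open intervals
#'
#' Computes the union within each group (any columns besides start/end),
#' coalescing overlapping and book-ended (`[a,b) [b,c)`) intervals; output is
#' sorted. Merging is idempotent.
#'
#' @param intervals Tibble with `start`, `end` (0-based half-open) and any
#'   number of grouping columns (e.g. transcript, pair_id).
#' @return Tibble with the grouping columns and merged `start`, `end`.
#' @export
merge_intervals <- function(intervals) {
  grp_cols <- setdiff(names(intervals), c("start", "end"))
  merged <- intervals |>
    group_by(across(all_of(grp_cols))) |>
    dplyr::group_modify(function(d, key) {
      # IRanges is 1-based closed: [start+1, end]; min.gapwidth = 1 also
      # coalesces book-ended intervals
      r <- IRanges::reduce(IRanges::IRanges(d$start + 1L, d$end),
                           min.gapwidth = 1L)
      tibble(start = IRanges::start(r) - 1L, end = IRanges::end(r))
    }) |>
    ungroup()
  arrange(merged, across(all_of(grp_cols)), .data$start)
}

#' Build the paired CORE interval sets for accepted ortholog pairs
#'
#' Isolates, from the forward hit table, the HSPs that connect an accepted
#' isoform of each ortholog pair to its paired reference transcript, converts
#' them to BED intervals and merges them per (transcript, pair) independently
#' on each species side. Subject-side intervals from different A isoforms of
#' the same pair are merged together, since downstream counting is
#' gene-level.
#'
#' @param orthologs Tibble from [reciprocal_best_hits()].
#' @param forward_hits The forward HSP tibble the orthologs were derived
#'   from.
#' @param transcript_lengths_a,transcript_lengths_b Optional named integer
#'   vectors used to validate that intervals stay within transcript bounds.
#' @return A `core_regions` object: list with `intervals_a` and
#'   `intervals_b` tibbles (transcript, start, end, pair_id, strand) and
#'   `pair_index` (pair_id, gene_a, gene_b).
#' @export
build_core_beds <- function(orthologs, forward_hits,
                            transcript_lengths_a = NULL,
                            transcript_lengths_b = NULL) {
  pair_index <- orthologs |>
    mutate(pair_id = sprintf("CORE_%05d", row_number())) |>
    select("pair_id", "gene_a", "gene_b", "transcript_b")

  link <- orthologs |>
    mutate(pair_id = pair_index$pair_id) |>
    select("pair_id", "transcript_b", "isoforms_a") |>
    tidyr::unnest_longer("isoforms_a", values_to = "isoform_a")

  hsps <- forward_hits |>
    inner_join(link, by = c(qseqid = "isoform_a", sseqid = "transcript_b"),
               relationship = "many-to-many")
  missing <- anti_join(link, hsps,
                       by = c(pair_id = "pair_id"))
  if (nrow(missing) > 0) {
    miss_pairs <- setdiff(link$pair_id, hsps$pair_id)
    if (length(miss_pairs) > 0) {
      abort(sprintf("ortholog pair(s) with no HSPs in the forward table: %s",
                    paste(miss_pairs, collapse = ", ")),
            class = "corexpr_consistency_error")
    }
  }

  iv <- hsp_to_bed_intervals(hsps) |> mutate(pair_id = hsps$pair_id)

  intervals_a <- iv |>
    select(transcript = "q_transcript", start = "q_start", end = "q_end",
           "pair_id") |>
    merge_intervals() |>
    mutate(strand = "+") |>
    select("transcript", "start", "end", "pair_id", "strand")

  strand_b <- iv |>
    group_by(transcript = .data$s_transcript, pair_id = .data$pair_id) |>
    summarise(strand = if (dplyr::n_distinct(.data$s_strand) == 1)
      .data$s_strand[1] else ".", .groups = "drop")
  intervals_b <- iv |>
    select(transcript = "s_transcript", start = "s_start", end = "s_end",
           "pair_id") |>
    merge_intervals() |>
    left_join(strand_b, by = c("transcript", "pair_id")) |>
    select("transcript", "start", "end", "pair_id", "strand")

  check_bounds <- function(ivs, lens, side) {
    if (is.null(lens)) return(invisible())
    known <- ivs$transcript %in% names(lens)
    over <- known & ivs$end > unname(lens[ivs$transcript])
    if (any(ivs$start < 0) || any(over, na.rm = TRUE)) {
      abort(sprintf("CORE intervals exceed %s transcript bounds.", side),
            class = "corexpr_consistency_error")
    }
  }
  check_bounds(intervals_a, transcript_lengths_a, "species-A")
  check_bounds(intervals_b, transcript_lengths_b, "species-B")

  structure(list(intervals_a = intervals_a, intervals_b = intervals_b,
                 pair_index = select(pair_index, "pair_id", "gene_a",
                                     "gene_b")),
            class = "core_regions")
}

#' @export
print.core_regions <- function(x, ...) {
  cat(sprintf(
    "CORE region set: %d pairs; %d A-side and %d B-side intervals\n",
    nrow(x$pair_index), nrow(x$intervals_a), nrow(x$intervals_b)))
  invisible(x)
}

#' Write the two species-specific CORE BED6 files
#'
#' chrom = transcript id, name = pair id, score = 0; coordinates are 0-based
#' half-open as in standard BED.
#'
#' @param core A `core_regions` object.
#' @param path_a,path_b Output BED paths for the species A and B sides.
#' @export
write_core_beds <- function(core, path_a, path_b) {
  bed <- function(iv, path) {
    readr::write_tsv(tibble(iv$transcript, iv$start, iv$end, iv$pair_id,
                            0L, iv$strand),
                     path, col_names = FALSE)
  }
  bed(core$intervals_a, path_a)
  bed(core$intervals_b, path_b)
  invisible(c(path_a, path_b))
}

#' Read one side of a CORE BED6 file back into an interval tibble
#' @param path BED6 path written by [write_core_beds()].
#' @export
read_core_bed <- function(path) {
  readr::read_tsv(path, col_names = c("transcript", "start", "end",
                                      "pair_id", "score", "strand"),
                  show_col_types = FALSE,
                  col_types = "ciicic") |>
    select("transcript", "start", "end", "pair_id", "strand")
}

#' Build the gene-transcript map
#'
#' Ortholog isoforms map to their reference gene label (combined analysis).
#' With `augment = TRUE` every remaining transcript of the supplied universe
#' maps to its Trinity gene id, so that all transcripts are quantified
#' (per se mode); with `augment = FALSE` unmatched transcripts are absent.
#' A transcript claimed by two reference genes is resolved by the larger
#' bitscore, with a message.
#'
#' @param orthologs Tibble from [reciprocal_best_hits()].
#' @param all_transcripts Optional character vector of the full species-A
#'   transcript universe (required when `augment = TRUE`).
#' @param augment Add Trinity-gene rows for unmatched transcripts?
#' @return Tibble with `transcript`, `gene`.
#' @export
build_gene_transcript_map <- function(orthologs, all_transcripts = NULL,
                                      augment = FALSE) {
  rows <- orthologs |>
    select("gene_b", "isoforms_a", "bitscore") |>
    tidyr::unnest_longer("isoforms_a", values_to = "transcript") |>
    select("transcript", gene = "gene_b", "bitscore")
  dup <- rows |> count(.data$transcript) |> filter(.data$n > 1)
  if (nrow(dup) > 0) {
    inform(sprintf(
      "%d transcript(s) claimed by multiple reference genes; keeping the best bitscore.",
      nrow(dup)))
    rows <- rows |>
      group_by(.data$transcript) |>
      arrange(desc(.data$bitscore), .data$gene, .by_group = TRUE) |>
      slice(1) |>
      ungroup()
  }
  rows <- select(rows, "transcript", "gene")
  if (augment) {
    if (is.null(all_transcripts)) {
      abort("`all_transcripts` is required when `augment = TRUE`.")
    }
    orphan <- setdiff(all_transcripts, rows$transcript)
    rows <- bind_rows(rows, tibble(transcript = orphan,
                                   gene = trinity_gene_of(orphan)))
  }
  arrange(rows, .data$transcript)
}

#' Write / read the 2-column gene-transcript map TSV
#' @param map Tibble with transcript, gene.
#' @param path TSV path.
#' @export
write_gene_map <- function(map, path) {
  readr::write_tsv(map, path)
  invisible(path)
}

#' @rdname write_gene_map
#' @export
read_gene_map <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, col_types = "cc")
}
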