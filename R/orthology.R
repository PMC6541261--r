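blast6_cols <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                 "gapopen", "qstart", "qend", "sstart", "send",
                 "evalue", "bitscore")

#' Parse a BLAST tabular (outfmt 6) hit file
#'
#' Reads the 12-column tab-separated format (qseqid sseqid pident length
#' mismatch gapopen qstart qend sstart send evalue bitscore). Comment lines
#' starting with `#` are skipped; row order is preserved. `sstart > send`
#' marks a minus-strand subject interval.
#'
#' @param path Path to the TSV file.
#' @param direction `"forward"` (A vs B) or `"reverse"` (B vs A); recorded as
#'   an attribute for downstream bookkeeping.
#' @return A tibble of HSPs with the 12 standard columns.
#' @export
parse_blast_tabular <- function(path, direction = c("forward", "reverse")) {
  direction <- match.arg(direction)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readr::read_lines(path)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  data_lines <- lines[keep]
  line_no <- which(keep)
  if (length(data_lines) == 0) {
    out <- tibble(qseqid = character(), sseqid = character(),
                  pident = double(), length = integer(),
                  mismatch = integer(), gapopen = integer(),
                  qstart = integer(), qend = integer(),
                  sstart = integer(), send = integer(),
                  evalue = double(), bitscore = double())
    attr(out, "direction") <- direction
    return(out)
  }
  fields <- strsplit(data_lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12L)) {
    bad <- which(nf != 12L)[1]
    abort(sprintf("line %d of %s has %d tab-separated fields; expected 12.",
                  line_no[bad], path, nf[bad]),
          class = "corexpr_format_error")
  }
  m <- do.call(rbind, fields)
  num <- function(col, ix, int = FALSE) {
    v <- suppressWarnings(as.numeric(m[, ix]))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1]
      abort(sprintf("line %d of %s: non-numeric value '%s' in column %s.",
                    line_no[bad], path, m[bad, ix], col),
            class = "corexpr_format_error")
    }
    if (int) as.integer(v) else v
  }
  out <- tibble(
    qseqid = m[, 1], sseqid = m[, 2],
    pident = num("pident", 3), length = num("length", 4, int = TRUE),
    mismatch = num("mismatch", 5, int = TRUE),
    gapopen = num("gapopen", 6, int = TRUE),
    qstart = num("qstart", 7, int = TRUE), qend = num("qend", 8, int = TRUE),
    sstart = num("sstart", 9, int = TRUE), send = num("send", 10, int = TRUE),
    evalue = num("evalue", 11), bitscore = num("bitscore", 12)
  )
  attr(out, "direction") <- direction
  out
}

#' Trinity gene id of a transcript id
#'
#' Strips a trailing `_i<digits>` isoform suffix if present; ids without the
#' suffix (e.g. RefSeq accessions) are returned unchanged.
#'
#' @param transcript_id Character vector of transcript ids.
#' @return Character vector of gene ids.
#' @export
trinity_gene_of <- function(transcript_id) {
  sub("_i\\d+$", "", transcript_id)
}

#' Best subject hit per query
#'
#' Applies the E-value cutoff, sums bitscores over all HSPs of each
#' (query, subject) pair (a single HSP understates split alignments), and
#' picks the best subject per query by: max summed bitscore, then min
#' E-value, then max total aligned length, then lexicographically smallest
#' subject id. Queries with no surviving hit are absent from the result.
#'
#' @param hits An HSP tibble from [parse_blast_tabular()].
#' @param evalue_cutoff Maximum E-value for an HSP to be considered.
#' @return Tibble with query_id, subject_id, bitscore (summed), evalue (min),
#'   aln_len (summed).
#' @export
best_hit_per_query <- function(hits, evalue_cutoff = 1e-5) {
  hits <- filter(hits, .data$evalue <= evalue_cutoff)
  if (nrow(hits) == 0) {
    return(tibble(query_id = character(), subject_id = character(),
                  bitscore = double(), evalue = double(),
                  aln_len = integer()))
  }
  hits |>
    group_by(query_id = .data$qseqid, subject_id = .data$sseqid) |>
    summarise(bitscore = sum(.data$bitscore), evalue = min(.data$evalue),
              aln_len = sum(.data$length), .groups = "drop") |>
    group_by(.data$query_id) |>
    arrange(desc(.data$bitscore), .data$evalue, desc(.data$aln_len),
            .data$subject_id, .by_group = TRUE) |>
    slice(1) |>
    ungroup()
}

#' Gene-level reciprocal best-hit orthologs
#'
#' Accepts a pair (geneA, geneB) when (i) some isoform of the Trinity gene
#' geneA has its best forward hit on a transcript of geneB and (ii) that
#' transcript's best reverse hit lands on any isoform of the same geneA
#' (gene-level reciprocity; multiple A isoforms may hit one reference
#' transcript). `isoforms_a` collects all isoforms of geneA whose best hit is
#' that transcript. A reference gene claimed by several Trinity genes is kept
#' and flagged via `shared_reference`. If one Trinity gene reciprocates with
#' two reference transcripts, the pair with the larger summed supporting
#' bitscore is kept (then min evalue, then smallest geneB).
#'
#' @param forward HSP tibble, species A transcripts vs species B reference.
#' @param reverse HSP tibble, species B reference vs species A transcripts.
#' @param evalue_cutoff Maximum E-value for an HSP to be considered.
#' @param subject_genes Optional named character vector mapping reference
#'   transcript ids to reference gene labels; by default each reference
#'   transcript is its own gene.
#' @return Tibble with gene_a, gene_b, transcript_b, isoforms_a (list
#'   column), n_isoforms, bitscore, evalue, shared_reference.
#' @export
reciprocal_best_hits <- function(forward, reverse, evalue_cutoff = 1e-5,
                                 subject_genes = NULL) {
  a_ids <- unique(c(forward$qseqid, reverse$sseqid))
  b_ids <- unique(c(forward$sseqid, reverse$qseqid))
  if (length(intersect(a_ids, b_ids)) > 0) {
    abort("query and subject id namespaces overlap between species.",
          class = "corexpr_validation_error")
  }
  gene_b_of <- function(tx) {
    if (is.null(subject_genes)) tx else unname(subject_genes[tx])
  }

  fwd <- best_hit_per_query(forward, evalue_cutoff) |>
    mutate(gene_a = trinity_gene_of(.data$query_id),
           gene_b = gene_b_of(.data$subject_id))
  rev_best <- best_hit_per_query(reverse, evalue_cutoff) |>
    mutate(rev_gene_a = trinity_gene_of(.data$subject_id)) |>
    select(transcript_b = "query_id", "rev_gene_a")

  cand <- fwd |>
    left_join(rev_best, by = c(subject_id = "transcript_b")) |>
    filter(!is.na(.data$rev_gene_a), .data$rev_gene_a == .data$gene_a)
  if (nrow(cand) == 0) {
    return(tibble(gene_a = character(), gene_b = character(),
                  transcript_b = character(), isoforms_a = list(),
                  n_isoforms = integer(), bitscore = double(),
                  evalue = double(), shared_reference = logical()))
  }
  cand <- cand |>
    group_by(gene_a = .data$gene_a, gene_b = .data$gene_b,
             transcript_b = .data$subject_id)

  # isoforms supporting a candidate = all isoforms of geneA whose best hit is
  # that transcript (not only those that themselves reciprocate)
  support <- fwd |>
    select("query_id", "gene_a", "subject_id", "bitscore", "evalue",
           "aln_len")
  pairs <- cand |>
    summarise(.groups = "drop") |>
    left_join(support, by = c("gene_a", transcript_b = "subject_id"),
              relationship = "many-to-many") |>
    group_by(.data$gene_a, .data$gene_b, .data$transcript_b) |>
    summarise(isoforms_a = list(sort(.data$query_id)),
              n_isoforms = dplyr::n_distinct(.data$query_id),
              support_bitscore = sum(.data$bitscore),
              bitscore = max(.data$bitscore), evalue = min(.data$evalue),
              .groups = "drop")

  # enforce "each geneA at most once"
  pairs <- pairs |>
    group_by(.data$gene_a) |>
    arrange(desc(.data$support_bitscore), .data$evalue, .data$gene_b,
            .by_group = TRUE) |>
    slice(1) |>
    ungroup() |>
    group_by(.data$gene_b) |>
    mutate(shared_reference = n() > 1) |>
    ungroup() |>
    arrange(.data$gene_a) |>
    select("gene_a", "gene_b", "transcript_b", "isoforms_a", "n_isoforms",
           "bitscore", "evalue", "shared_reference")
  pairs
}

#' Write an ortholog table as TSV
#'
#' Isoforms are comma-joined; the list column round-trips through
#' [read_ortholog_table()].
#' @param orthologs Tibble from [reciprocal_best_hits()].
#' @param path Output path.
#' @export
write_ortholog_table <- function(orthologs, path) {
  tab <- orthologs |>
    mutate(isoforms_a = map_chr(.data$isoforms_a, paste, collapse = ","))
  readr::write_tsv(tab, path)
  invisible(path)
}

#' @rdname write_ortholog_table
#' @export
read_ortholog_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(gene_a = "c", gene_b = "c",
                                          transcript_b = "c")) |>
    mutate(isoforms_a = strsplit(.data$isoforms_a, ",", fixed = TRUE))
}
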