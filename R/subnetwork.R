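#' Load regulator / target gene lists
#'
#' Reads one or more TSV exports (e.g. from a pathway tool's regulatory
#' effects analysis), takes the union of gene symbols, uppercases them for
#' case-insensitive matching across species symbol conventions, and records
#' a role and source label per file.
#'
#' @param paths TSV paths.
#' @param symbol_col Name of the gene-symbol column (default "symbol").
#' @param roles Optional character vector (recycled) of roles, e.g.
#'   "regulator" / "target".
#' @return Tibble with symbol (uppercased), role, source; duplicates
#'   collapsed.
#' @export
load_regulator_targets <- function(paths, symbol_col = "symbol",
                                   roles = NULL) {
  if (is.null(roles)) roles <- rep("regulator", length(paths))
  roles <- rep_len(roles, length(paths))
  out <- purrr::map2(paths, roles, function(p, role) {
    tab <- readr::read_tsv(p, show_col_types = FALSE)
    if (!symbol_col %in% names(tab)) {
      abort(sprintf("file %s lacks a '%s' column.", p, symbol_col),
            class = "corexpr_format_error")
    }
    tibble(symbol = toupper(tab[[symbol_col]]), role = role,
           source = basename(p))
  }) |> bind_rows() |> distinct(.data$symbol, .keep_all = TRUE)
  if (nrow(out) == 0) abort("no gene symbols loaded.")
  out
}

#' Extract the subnetwork centered on one gene
#'
#' Members are the center plus its direct network neighbors that appear in
#' the allowed regulator/target set (case-insensitive symbol match); edges
#' are the induced edges among members present in the parent network.
#'
#' @param net A `core_network` object.
#' @param center Center gene id (must be a network node).
#' @param allowed Regulator set tibble from [load_regulator_targets()], or a
#'   character vector of symbols.
#' @return A `core_subnetwork` object: list with center, members, edges.
#' @export
extract_subnetwork <- function(net, center, allowed) {
  stopifnot(inherits(net, "core_network"))
  if (!center %in% net$nodes) {
    abort(sprintf("center gene '%s' is not a network node.", center),
          class = "corexpr_lookup_error")
  }
  symbols <- if (is.data.frame(allowed)) allowed$symbol else allowed
  symbols <- toupper(symbols)
  e <- net$edges
  nbr <- unique(c(e$gene_b[e$gene_a == center], e$gene_a[e$gene_b == center]))
  members <- c(center, sort(nbr[toupper(nbr) %in% symbols]))
  edges <- filter(e, .data$gene_a %in% members & .data$gene_b %in% members)
  structure(list(center = center, members = members, edges = edges),
            class = "core_subnetwork")
}

#' @export
print.core_subnetwork <- function(x, ...) {
  cat(sprintf("subnetwork centered on %s: %d members, %d edges\n",
              x$center, length(x$members), nrow(x$edges)))
  invisible(x)
}

#' Enumerate regulator-centered subnetworks
#'
#' One subnetwork per allowed gene present in the network, sorted by size
#' descending; those with at least `min_size` members are flagged as of
#' particular interest.
#'
#' @inheritParams extract_subnetwork
#' @param min_size Size at which a subnetwork is flagged (default 10).
#' @return Tibble with center, size, flagged, subnetwork (list column).
#' @export
enumerate_subnetworks <- function(net, allowed, min_size = 10) {
  symbols <- if (is.data.frame(allowed)) allowed$symbol else allowed
  centers <- net$nodes[toupper(net$nodes) %in% toupper(symbols)]
  subs <- map(centers, extract_subnetwork, net = net, allowed = allowed)
  tibble(center = centers,
         size = map_int(subs, ~ length(.x$members)),
         flagged = map_int(subs, ~ length(.x$members)) >= min_size,
         subnetwork = subs) |>
    arrange(desc(.data$size), .data$center)
}

#' Group means of log2(expression + 1) with t-based confidence intervals
#'
#' For each requested gene and species-by-day group: the mean of
#' `log2(x + 1)`, the number of samples, and the 95% confidence half-width
#' `t(0.975, n-1) * s / sqrt(n)` (undefined and flagged when `n = 1`).
#'
#' @param expr Expression tibble with `gene` column (natural scale), or
#'   matrix.
#' @param genes Genes to summarize.
#' @param samples Sample metadata tibble (sample_id, species, day).
#' @param conf_level Confidence level (default 0.95).
#' @return Tibble with gene, species, day, n, mean, ci_lo, ci_hi.
#' @export
factor_plot_data <- function(expr, genes, samples, conf_level = 0.95) {
  m <- as_expr_matrix(expr)
  missing <- setdiff(genes, rownames(m))
  if (length(missing) > 0) {
    abort(sprintf("gene(s) not in expression matrix: %s",
                  paste(missing, collapse = ", ")),
          class = "corexpr_lookup_error")
  }
  long <- as_tibble(m[genes, , drop = FALSE], rownames = "gene") |>
    tidyr::pivot_longer(-"gene", names_to = "sample_id",
                        values_to = "value") |>
    inner_join(samples, by = "sample_id") |>
    mutate(log_expr = log2(.data$value + 1))
  out <- long |>
    group_by(.data$gene, .data$species, .data$day) |>
    summarise(n = n(), mean = mean(.data$log_expr),
              half_width = if (n() > 1) {
                qt(1 - (1 - conf_level) / 2, n() - 1) *
                  sd(.data$log_expr) / sqrt(n())
              } else NA_real_,
              .groups = "drop") |>
    mutate(ci_lo = .data$mean - .data$half_width,
           ci_hi = .data$mean + .data$half_width)
  if (any(out$n == 1)) {
    warn("group(s) with a single sample: confidence interval undefined.")
  }
  out
}

#' Write the membership and edge tables of a subnetwork
#' @param sub A `core_subnetwork` object.
#' @param edges_path,members_path Output TSV paths.
#' @export
write_subnetwork <- function(sub, edges_path, members_path) {
  readr::write_tsv(sub$edges, edges_path)
  readr::write_tsv(tibble(gene = sub$members,
                          is_center = sub$members == sub$center),
                   members_path)
  invisible(c(edges_path, members_path))
}
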