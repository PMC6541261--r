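#' @importFrom rlang abort warn inform %||%
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   left_join inner_join anti_join bind_rows bind_cols distinct slice n
#'   row_number desc across all_of rename count pull first lag
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom purrr map map_dbl map_int map_chr map2 pmap imap keep
#' @importFrom stats cor lowess approxfun optimize lm pt qt sd var median
#'   quantile rnorm runif rbinom rnbinom p.adjust setNames complete.cases
#' @importFrom utils head tail
NULL

# numeric scalar check with informative error
check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         integerish = FALSE, strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single non-missing number.", name),
          class = "corexpr_parameter_error")
  }
  ok_low <- if (strict_lower) x > lower else x >= lower
  if (!ok_low || x > upper) {
    abort(sprintf("`%s` = %s is outside its allowed range %s%s, %s].",
                  name, format(x), if (strict_lower) "(" else "[",
                  format(lower), format(upper)),
          class = "corexpr_parameter_error")
  }
  if (integerish && x != round(x)) {
    abort(sprintf("`%s` must be a whole number.", name),
          class = "corexpr_parameter_error")
  }
  invisible(x)
}

# counts can arrive as a tibble with a `gene` column or as a numeric matrix
as_count_matrix <- function(counts) {
  if (is.matrix(counts)) {
    if (is.null(rownames(counts))) {
      abort("count matrix must have gene ids as rownames.")
    }
    return(counts)
  }
  if (is.data.frame(counts)) {
    gene_col <- if ("gene" %in% names(counts)) "gene" else names(counts)[1]
    m <- as.matrix(counts[setdiff(names(counts), gene_col)])
    rownames(m) <- as.character(counts[[gene_col]])
    storage.mode(m) <- "double"
    return(m)
  }
  abort("`counts` must be a data frame with a `gene` column or a matrix.")
}

count_matrix_to_tibble <- function(m) {
  bind_cols(tibble(gene = rownames(m)), as_tibble(m))
}

# expression matrix (possibly non-integer) with gene ids
as_expr_matrix <- function(expr) as_count_matrix(expr)
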