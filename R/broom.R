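#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a differential-expression result
#'
#' The per-gene table (gene, logFC, AveExpr, t, p_value, fdr) as a plain
#' tibble, sorted by p-value.
#' @param x A `core_de_result`.
#' @param ... Unused.
#' @export
tidy.core_de_result <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "core_de_result")
  arrange(out, .data$p_value)
}

#' @rdname tidy.core_de_result
#' @export
glance.core_de_result <- function(x, ...) {
  tibble(n_genes = nrow(x), d0 = attr(x, "d0"), s02 = attr(x, "s02"),
         df_total = attr(x, "df_total"),
         n_signif_fdr05 = sum(x$fdr < 0.05),
         contrast = attr(x, "contrast_name") %||% NA_character_)
}

#' Summaries of a moderated fit
#'
#' `glance()` reports the empirical-Bayes prior (d0, s02), residual df and
#' gene count; `tidy()` returns per-gene residual variances.
#' @param x A `core_de_fit`.
#' @param ... Unused.
#' @export
glance.core_de_fit <- function(x, ...) {
  tibble(n_genes = nrow(x$coefficients), df_resid = x$df_resid,
         d0 = x$d0, s02 = x$s02)
}

#' @rdname glance.core_de_fit
#' @export
tidy.core_de_fit <- function(x, ...) {
  tibble(gene = rownames(x$coefficients), sigma2 = x$sigma2,
         s2_post = x$s2_post)
}

#' Tidy a power-law fit
#'
#' `tidy()` returns the bootstrap replicates (when present); `glance()` the
#' point estimates, KS distance and bootstrap p-value.
#' @param x A `core_powerlaw_fit`.
#' @param ... Unused.
#' @export
tidy.core_powerlaw_fit <- function(x, ...) {
  if (is.null(x$boot)) {
    tibble(alpha = x$alpha, xmin = x$xmin, ks = x$ks)
  } else x$boot
}

#' @rdname tidy.core_powerlaw_fit
#' @export
glance.core_powerlaw_fit <- function(x, ...) {
  tibble(alpha = x$alpha, xmin = x$xmin, n_tail = x$n_tail, ks = x$ks,
         p_value = x$p_value %||% NA_real_,
         ci_alpha_lo = if (is.null(x$ci_alpha)) NA_real_ else x$ci_alpha[1],
         ci_alpha_hi = if (is.null(x$ci_alpha)) NA_real_ else x$ci_alpha[2])
}

#' Tidy threshold-selection output
#'
#' `tidy()` returns the per-threshold report; `glance()` the selected
#' threshold and status.
#' @param x A `core_threshold`.
#' @param ... Unused.
#' @export
tidy.core_threshold <- function(x, ...) x$report

#' @rdname tidy.core_threshold
#' @export
glance.core_threshold <- function(x, ...) {
  tibble(threshold = x$threshold, status = x$status,
         n_candidates = nrow(x$report), n_passing = sum(x$report$pass))
}

#' Tidy a network into its edge list
#' @param x A `core_network`.
#' @param ... Unused.
#' @export
tidy.core_network <- function(x, ...) x$edges

#' @rdname tidy.core_network
#' @export
glance.core_network <- function(x, ...) {
  tibble(n_nodes = length(x$nodes), n_edges = nrow(x$edges),
         threshold = x$threshold, n_input = x$n_input,
         pct_used = 100 * length(x$nodes) / x$n_input)
}
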