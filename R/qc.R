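#' Assembly N50
#'
#' The smallest length L such that transcripts of length >= L contain at
#' least half the assembled bases (descending-sort cumulative convention).
#'
#' @param lengths Positive transcript lengths in bp.
#' @return N50 in bp.
#' @export
n50 <- function(lengths) {
  if (length(lengths) == 0 || any(lengths <= 0) || anyNA(lengths)) {
    abort("`lengths` must be a nonempty vector of positive values.",
          class = "corexpr_validation_error")
  }
  s <- sort(lengths, decreasing = TRUE)
  s[match(TRUE, cumsum(s) >= sum(s) / 2)]
}

#' Expression-weighted N50 (ExN50) table
#'
#' Transcripts are sorted by normalized expression, descending (ties broken
#' by longer length, then id); for each Ex in 1..100 the minimal prefix
#' whose expression reaches Ex% of the total is taken and the N50 of that
#' prefix's lengths reported. ExN50 at high Ex summarizes contiguity of the
#' transcripts that carry most of the expression.
#'
#' @param expression Non-negative per-transcript normalized expression.
#' @param lengths Transcript lengths, aligned with `expression`.
#' @param ids Optional transcript ids for tie-breaking (defaults to index).
#' @return Tibble with Ex (1..100), N50 (bp), n_transcripts.
#' @export
exn50 <- function(expression, lengths, ids = NULL) {
  if (length(expression) != length(lengths)) {
    abort("`expression` and `lengths` must be aligned.")
  }
  if (any(expression < 0)) abort("`expression` must be non-negative.")
  total <- sum(expression)
  if (total <= 0) {
    abort("total expression is zero.", class = "corexpr_validation_error")
  }
  if (is.null(ids)) ids <- as.character(seq_along(expression))
  ord <- order(-expression, -lengths, ids)
  cum <- cumsum(expression[ord]) / total
  rows <- lapply(1:100, function(ex) {
    k <- match(TRUE, cum >= ex / 100)
    tibble(Ex = ex, N50 = n50(lengths[ord][seq_len(k)]), n_transcripts = k)
  })
  bind_rows(rows)
}
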