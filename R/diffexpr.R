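#' Remove genes below a CPM threshold
#'
#' Keeps genes whose counts reach `min_cpm` counts-per-million, judged
#' against the average library size, in at least `min_samples` samples: the
#' CPM cutoff is converted to a count cutoff
#' `min_cpm * mean(lib_size) / 1e6` and applied per sample.
#'
#' @param counts Tibble with a `gene` column plus sample columns, or matrix.
#' @param min_cpm CPM threshold (default 10).
#' @param min_samples Minimum number of samples reaching the threshold
#'   (default 3; use 4 for a deeper-replicated per se design).
#' @return Filtered counts in the same form as the input.
#' @export
filter_low_expression <- function(counts, min_cpm = 10, min_samples = 3) {
  m <- as_count_matrix(counts)
  check_scalar(min_samples, "min_samples", lower = 1, upper = ncol(m),
               integerish = TRUE)
  cutoff <- min_cpm * mean(colSums(m)) / 1e6
  keep <- rowSums(m >= cutoff) >= min_samples
  if (!any(keep)) warn("no genes pass the expression filter.")
  out <- m[keep, , drop = FALSE]
  if (is.matrix(counts)) out else count_matrix_to_tibble(out)
}

# TMM factor of one sample against the reference (doubly trimmed,
# precision-weighted mean of M values)
tmm_one <- function(obs, ref, n_obs, n_ref, logratio_trim, sum_trim,
                    a_cutoff) {
  logR <- log2((obs / n_obs) / (ref / n_ref))
  absE <- (log2(obs / n_obs) + log2(ref / n_ref)) / 2
  v <- (n_obs - obs) / n_obs / obs + (n_ref - ref) / n_ref / ref
  fin <- is.finite(logR) & is.finite(absE) & (absE > a_cutoff)
  if (!any(fin)) {
    warn("no genes shared with the reference sample; factor set to 1.")
    return(1)
  }
  logR <- logR[fin]; absE <- absE[fin]; v <- v[fin]
  if (max(abs(logR)) < 1e-6) return(1)
  n <- length(logR)
  loL <- floor(n * logratio_trim) + 1
  hiL <- n + 1 - loL
  loS <- floor(n * sum_trim) + 1
  hiS <- n + 1 - loS
  keep <- rank(logR) >= loL & rank(logR) <= hiL &
    rank(absE) >= loS & rank(absE) <= hiS
  f <- sum(logR[keep] / v[keep], na.rm = TRUE) /
    sum(1 / v[keep], na.rm = TRUE)
  if (is.na(f)) f <- 0
  2^f
}

#' TMM normalization factors
#'
#' Trimmed mean of M-values between-sample normalization. The reference
#' sample is the one whose upper-quartile count fraction is closest to the
#' mean; per sample, genes absent in either sample or reference are
#' excluded, log-ratios are doubly trimmed (30% on M, 5% on A by default)
#' and averaged with precision (inverse asymptotic variance) weights; the
#' factors are rescaled so their geometric mean is 1.
#'
#' @param counts Tibble with `gene` column or matrix.
#' @param logratio_trim Two-sided trim fraction on M values.
#' @param sum_trim Two-sided trim fraction on A values.
#' @param a_cutoff Lower cutoff on A values.
#' @return Tibble with sample_id, lib_size, norm_factor (geometric mean 1).
#' @export
tmm_factors <- function(counts, logratio_trim = 0.3, sum_trim = 0.05,
                        a_cutoff = -1e10) {
  m <- as_count_matrix(counts)
  if (ncol(m) < 2) abort("TMM needs at least two samples.")
  lib <- colSums(m)
  if (any(lib == 0)) abort("a sample has zero total counts.")
  f75 <- apply(m, 2, quantile, p = 0.75) / lib
  ref <- which.min(abs(f75 - mean(f75)))
  f <- vapply(seq_len(ncol(m)), function(j) {
    tmm_one(m[, j], m[, ref], lib[j], lib[ref],
            logratio_trim, sum_trim, a_cutoff)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  tibble(sample_id = colnames(m), lib_size = unname(lib),
         norm_factor = unname(f))
}

#' Group-means design matrix for a species-by-day layout
#'
#' One indicator column per species-by-day cell, labelled `<species>_d<day>`
#' (cell-means coding; contrasts are explicit vectors over these columns).
#'
#' @param samples Tibble with sample_id, species, day.
#' @return Numeric design matrix, rows aligned with `samples`.
#' @export
design_group_means <- function(samples) {
  grp <- factor(sprintf("%s_d%s", samples$species, samples$day))
  X <- stats::model.matrix(~ 0 + grp)
  colnames(X) <- levels(grp)
  rownames(X) <- samples$sample_id
  X
}

#' Pairwise and species-by-time interaction contrasts
#'
#' `contrast_pairwise()` is `day - ref` within one cell pair (e.g. the per se
#' day7 - day0 comparison); `contrast_interaction()` is the
#' difference-of-differences `(A_day - A_d0) - (B_day - B_d0)` that compares
#' the two species' time responses directly.
#'
#' @param design Design matrix from [design_group_means()].
#' @param level,ref Column labels of the two cells to contrast.
#' @return Named numeric contrast vector over the design columns.
#' @export
contrast_pairwise <- function(design, level, ref) {
  cols <- colnames(design)
  if (!all(c(level, ref) %in% cols)) {
    abort(sprintf("contrast levels not in design columns: %s",
                  paste(setdiff(c(level, ref), cols), collapse = ", ")))
  }
  ct <- setNames(numeric(length(cols)), cols)
  ct[level] <- 1
  ct[ref] <- -1
  ct
}

#' @rdname contrast_pairwise
#' @param day Post-baseline day of the interaction.
#' @param ref_day Baseline day (default 0).
#' @param species_a,species_b Species labels; the sign convention is
#'   species-A-relative.
#' @export
contrast_interaction <- function(design, day, ref_day = 0,
                                 species_a = "A", species_b = "B") {
  ca <- contrast_pairwise(design, sprintf("%s_d%s", species_a, day),
                          sprintf("%s_d%s", species_a, ref_day))
  cb <- contrast_pairwise(design, sprintf("%s_d%s", species_b, day),
                          sprintf("%s_d%s", species_b, ref_day))
  ca - cb
}

#' Log-CPM transformation with precision weights
#'
#' Transforms counts to `log2((count + 0.5) / (lib * factor + 1) * 1e6)`,
#' fits each gene's logCPM on the design by ordinary least squares, smooths
#' sqrt(residual sd) against mean log2 count with lowess, and converts the
#' predicted sd at each fitted value into an inverse-variance observation
#' weight (`predicted^-4`), clipped to a positive floor.
#'
#' @param counts Filtered counts (tibble with `gene` column or matrix).
#' @param design Design matrix (full column rank).
#' @param factors Normalization factors from [tmm_factors()] (or NULL for
#'   library size only).
#' @param span Lowess span (default 0.5).
#' @param weight_floor Lower clip for weights (default 1e-6).
#' @return A `core_voom` object: list with `E` (logCPM matrix), `weights`,
#'   `design`, `trend` (the lowess curve), `lib_size` (effective sizes).
#' @export
voom_transform <- function(counts, design, factors = NULL, span = 0.5,
                           weight_floor = 1e-6) {
  m <- as_count_matrix(counts)
  if (qr(design)$rank < ncol(design)) {
    abort("design matrix is rank-deficient.",
          class = "corexpr_validation_error")
  }
  lib <- colSums(m)
  nf <- rep(1, ncol(m))
  if (!is.null(factors)) {
    nf <- factors$norm_factor[match(colnames(m), factors$sample_id)]
    if (anyNA(nf)) abort("`factors` does not cover all samples.")
  }
  eff_lib <- lib * nf
  E <- t(log2(t(m + 0.5) / (eff_lib + 1) * 1e6))

  fit <- stats::lm.fit(design, t(E))
  df_resid <- nrow(design) - ncol(design)
  if (df_resid < 1) abort("no residual degrees of freedom.")
  sigma <- sqrt(colSums(as.matrix(fit$residuals)^2) / df_resid)

  amean <- rowMeans(E)
  sx <- amean + mean(log2(eff_lib + 1)) - log2(1e6)   # mean log2 count
  sy <- sqrt(sigma)
  l <- lowess(sx, sy, f = span)
  trend_fun <- approxfun(l, rule = 2, ties = list("ordered", mean))

  fitted_logcpm <- t(design %*% fit$coefficients)     # genes x samples
  fitted_logcount <- t(t(fitted_logcpm) + log2(eff_lib + 1)) - log2(1e6)
  w <- pmax(1 / trend_fun(fitted_logcount)^4, weight_floor)
  dim(w) <- dim(fitted_logcount)
  dimnames(w) <- dimnames(E)

  structure(list(E = E, weights = w, design = design,
                 trend = list(x = l$x, y = l$y, span = span),
                 lib_size = eff_lib, amean = amean),
            class = "core_voom")
}

# limma-style Newton solve of trigamma(y) = x
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2)
    y <- y + dif
    if (-dif / y < 1e-8) break
  }
  y
}

# moments-of-log fit of the scaled inverse-chi-square prior to sigma^2
fit_variance_prior <- function(s2, df) {
  z <- log(pmax(s2, 1e-300))
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- var(e) - trigamma(df / 2)
  if (is.na(evar) || evar <= 0) {
    return(list(d0 = Inf, s02 = exp(emean)))
  }
  d0 <- 2 * trigamma_inverse(evar)
  list(d0 = d0, s02 = exp(emean + digamma(d0 / 2) - log(d0 / 2)))
}

#' Gene-wise weighted fits with empirical-Bayes variance moderation
#'
#' Fits each gene's logCPM on the design by weighted least squares with the
#' voom precision weights, then fits a scaled inverse-chi-square prior to the
#' residual variances by matching the moments of log s^2 (digamma/trigamma
#' inversion), yielding prior degrees of freedom `d0` and prior variance
#' `s02`. The posterior variance is `(d0 s02 + dg sg^2) / (d0 + dg)`. When
#' all variances are equal the prior is degenerate (`d0 = Inf`) and every
#' gene shares `s02`.
#'
#' @param voom A `core_voom` object.
#' @param prior_df Optional override for `d0` (0 recovers the ordinary
#'   t-statistic; Inf pools all genes).
#' @return A `core_de_fit` object.
#' @export
fit_and_moderate <- function(voom, prior_df = NULL) {
  stopifnot(inherits(voom, "core_voom"))
  E <- voom$E
  W <- voom$weights
  X <- voom$design
  G <- nrow(E)
  p <- ncol(X)
  df_resid <- nrow(X) - p
  if (df_resid < 1) abort("at least one residual degree of freedom required.")

  beta <- matrix(NA_real_, G, p, dimnames = list(rownames(E), colnames(X)))
  s2 <- numeric(G)
  cov_arr <- array(NA_real_, c(p, p, G))
  for (g in seq_len(G)) {
    w <- W[g, ]
    y <- E[g, ]
    xw <- X * w
    xtwx <- crossprod(X, xw)
    xtwy <- crossprod(xw, y)
    ci <- chol2inv(chol(xtwx))
    b <- drop(ci %*% xtwy)
    r <- y - drop(X %*% b)
    beta[g, ] <- b
    s2[g] <- sum(w * r^2) / df_resid
    cov_arr[, , g] <- ci
  }

  prior <- fit_variance_prior(s2, df_resid)
  if (!is.null(prior_df)) prior$d0 <- prior_df
  d0 <- prior$d0
  s2_post <- if (is.infinite(d0)) rep(prior$s02, G) else
    (d0 * prior$s02 + df_resid * s2) / (d0 + df_resid)

  structure(list(coefficients = beta, sigma2 = s2, s2_post = s2_post,
                 cov_unscaled = cov_arr, df_resid = df_resid,
                 d0 = d0, s02 = prior$s02, design = X,
                 amean = voom$amean),
            class = "core_de_fit")
}

#' Test a contrast and assemble the differential-expression table
#'
#' Computes `logFC = c' beta`, the moderated t-statistic
#' `logFC / (s_post * se_c)`, two-sided p-values on `d0 + dg` degrees of
#' freedom (capped at the pooled residual df) and Benjamini-Hochberg FDR.
#'
#' @param fit A `core_de_fit` object.
#' @param contrast Numeric contrast vector over the design columns.
#' @param name Optional contrast label stored as an attribute.
#' @return A `core_de_result` tibble: gene, logFC, AveExpr, t, p_value, fdr.
#' @export
apply_contrast <- function(fit, contrast, name = NULL) {
  stopifnot(inherits(fit, "core_de_fit"))
  if (length(contrast) != ncol(fit$coefficients)) {
    abort("contrast length must equal the number of design columns.",
          class = "corexpr_validation_error")
  }
  if (all(contrast == 0)) {
    abort("contrast vector is all zero.", class = "corexpr_validation_error")
  }
  G <- nrow(fit$coefficients)
  logfc <- unname(drop(fit$coefficients %*% contrast))
  se_unscaled <- vapply(seq_len(G), function(g) {
    sqrt(drop(crossprod(contrast, fit$cov_unscaled[, , g] %*% contrast)))
  }, numeric(1))
  tstat <- logfc / (sqrt(fit$s2_post) * se_unscaled)
  df_total <- min(fit$d0 + fit$df_resid, G * fit$df_resid)
  p <- 2 * pt(-abs(tstat), df = df_total)
  out <- tibble(gene = rownames(fit$coefficients), logFC = logfc,
                AveExpr = unname(fit$amean), t = tstat, p_value = p,
                fdr = bh_adjust(p))
  class(out) <- c("core_de_result", class(out))
  attr(out, "contrast") <- contrast
  attr(out, "contrast_name") <- name
  attr(out, "d0") <- fit$d0
  attr(out, "s02") <- fit$s02
  attr(out, "df_total") <- df_total
  out
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Adjusted FDR values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    abort("p-values must lie in [0, 1].", class = "corexpr_validation_error")
  }
  p.adjust(p, method = "BH")
}

#' Export a DE result as a ranked table
#'
#' Columns: signed fold change (`2^|logFC|` carrying the sign of logFC),
#' gene symbol/name if provided, FDR, logFC, AveExpr, t, p; rows sorted by
#' p-value.
#'
#' @param result A `core_de_result` tibble.
#' @param annotations Optional tibble (gene, symbol, name).
#' @param path Optional TSV output path.
#' @return The formatted tibble (invisibly writes `path` if given).
#' @export
de_table <- function(result, annotations = NULL, path = NULL) {
  tab <- result |>
    mutate(FC = sign(.data$logFC) * 2^abs(.data$logFC)) |>
    as_tibble()
  if (!is.null(annotations)) {
    tab <- left_join(tab, annotations, by = "gene")
  } else {
    tab <- mutate(tab, symbol = .data$gene, name = NA_character_)
  }
  tab <- tab |>
    select("FC", "symbol", "name", FDR = "fdr", "logFC", "AveExpr", "t",
           p = "p_value", "gene") |>
    arrange(.data$p)
  if (!is.null(path)) readr::write_tsv(tab, path)
  tab
}

#' Run the full DE engine on a count matrix
#'
#' Convenience wrapper: expression filter, TMM, voom transform, moderated
#' fits, and one result tibble per contrast.
#'
#' @param counts Tibble with `gene` column (or matrix).
#' @param samples Sample metadata tibble (sample_id, species, day).
#' @param contrasts Named list of contrast vectors, or NULL to build the
#'   built-in set (per se day contrasts per species plus the species-by-time
#'   interactions for every post-baseline day).
#' @param min_cpm,min_samples Expression filter parameters.
#' @return List with `fit` (core_de_fit), `voom`, `factors`, and `results`
#'   (named list of core_de_result tibbles).
#' @export
run_de <- function(counts, samples, contrasts = NULL, min_cpm = 10,
                   min_samples = 3) {
  kept <- filter_low_expression(counts, min_cpm, min_samples)
  m <- as_count_matrix(kept)
  samples <- samples[match(colnames(m), samples$sample_id), ]
  design <- design_group_means(samples)
  factors <- tmm_factors(m)
  v <- voom_transform(m, design, factors)
  fit <- fit_and_moderate(v)
  if (is.null(contrasts)) {
    contrasts <- list()
    days <- sort(setdiff(unique(samples$day), 0))
    for (sp in sort(unique(samples$species))) {
      for (d in days) {
        lv <- sprintf("%s_d%s", sp, d)
        rf <- sprintf("%s_d%s", sp, 0)
        if (all(c(lv, rf) %in% colnames(design))) {
          contrasts[[sprintf("%s_d%s_vs_d0", sp, d)]] <-
            contrast_pairwise(design, lv, rf)
        }
      }
    }
    if (length(unique(samples$species)) == 2) {
      sps <- sort(unique(samples$species))
      for (d in days) {
        contrasts[[sprintf("interaction_d%s", d)]] <-
          contrast_interaction(design, d, species_a = sps[1],
                               species_b = sps[2])
      }
    }
  }
  results <- imap(contrasts, function(ct, nm) apply_contrast(fit, ct, nm))
  list(fit = fit, voom = v, factors = factors, results = results)
}
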