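#' Spearman correlation matrix of a gene-by-sample expression matrix
#'
#' Pearson correlation of average-ranked data (ties receive average ranks);
#' the diagonal is 1. A constant gene has zero rank variance; its
#' correlations are defined as 0, with a message.
#'
#' @param expr Tibble with `gene` column plus sample columns, or matrix.
#' @return Symmetric correlation matrix with gene dimnames.
#' @export
spearman_matrix <- function(expr) {
  m <- as_expr_matrix(expr)
  if (ncol(m) < 3) abort("need at least 3 samples.")
  if (anyNA(m)) abort("missing values are not allowed; impute or drop first.")
  constant <- apply(m, 1, function(x) length(unique(x)) == 1)
  rho <- suppressWarnings(cor(t(m), method = "spearman"))
  if (any(constant)) {
    inform(sprintf("%d constant gene(s); their correlations are set to 0.",
                   sum(constant)))
    rho[constant, ] <- 0
    rho[, constant] <- 0
  }
  diag(rho) <- 1
  rho
}

#' Threshold a correlation matrix into a co-expression network
#'
#' Genes i != j are connected iff `|rho| >= tau` (or `rho >= tau` with
#' `absolute = FALSE`). Genes with no edge are excluded from the node set
#' (they are "unused").
#'
#' @param corr Symmetric correlation matrix.
#' @param tau Threshold in (0, 1].
#' @param absolute Use `|rho|` (default) or signed rho.
#' @return A `core_network` object: list with `nodes`, `edges` (tibble:
#'   gene_a, gene_b, rho), `threshold`, `n_input`.
#' @export
network_at_threshold <- function(corr, tau, absolute = TRUE) {
  check_scalar(tau, "tau", lower = 0, upper = 1, strict_lower = TRUE)
  v <- if (absolute) abs(corr) else corr
  diag(v) <- -Inf
  idx <- which(upper.tri(v) & v >= tau, arr.ind = TRUE)
  genes <- rownames(corr)
  edges <- tibble(gene_a = genes[idx[, 1]], gene_b = genes[idx[, 2]],
                  rho = corr[idx])
  structure(list(nodes = sort(unique(c(edges$gene_a, edges$gene_b))),
                 edges = edges, threshold = tau, n_input = nrow(corr)),
            class = "core_network")
}

#' @export
print.core_network <- function(x, ...) {
  cat(sprintf("co-expression network: %d nodes, %d edges (threshold %.3f, %d input genes)\n",
              length(x$nodes), nrow(x$edges), x$threshold, x$n_input))
  invisible(x)
}

#' Convert a core network to an igraph graph
#' @param net A `core_network` object.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "core_network"))
  igraph::graph_from_data_frame(net$edges[, c("gene_a", "gene_b")],
                                directed = FALSE,
                                vertices = net$nodes)
}

#' Least-squares fit of the log-log degree distribution
#'
#' Regresses `log(p_k)` on `log(k)` over the observed nonzero degree
#' frequencies (no binning) and returns the exponent as the negated slope,
#' so a scale-free fit has `a` in (1, 3).
#'
#' @param degrees Vector of positive integer degrees.
#' @return List with `a` (negated slope), `intercept`, `r_squared`,
#'   `n_distinct`.
#' @export
degree_loglog_fit <- function(degrees) {
  degrees <- degrees[degrees > 0]
  tab <- table(degrees)
  if (length(tab) < 3) {
    abort("need at least 3 distinct degree values for the log-log fit.",
          class = "corexpr_undefined_fit_error")
  }
  k <- as.numeric(names(tab))
  pk <- as.numeric(tab) / sum(tab)
  f <- lm(log(pk) ~ log(k))
  # an exactly linear log-log profile is a legitimate input; silence the
  # perfect-fit note from summary.lm
  r2 <- suppressWarnings(summary(f)$r.squared)
  list(a = -unname(stats::coef(f)[2]), intercept = unname(stats::coef(f)[1]),
       r_squared = r2, n_distinct = length(tab))
}

#' Small-world statistics with random-graph baselines
#'
#' Mean local clustering coefficient over all nodes (nodes of degree < 2
#' contribute 0) and mean shortest-path length over connected pairs within
#' the largest component, with Erdos-Renyi baselines of equal size and mean
#' degree: `CC_rand = kbar / n`, `Path_rand = ln(n) / ln(kbar)` (undefined
#' and flagged when `kbar <= 1`).
#'
#' @param net A `core_network` object or igraph graph.
#' @return List with mean_cc, mean_path, cc_rand, path_rand, n, mean_degree.
#' @export
smallworld_stats <- function(net) {
  g <- if (inherits(net, "igraph")) net else as_igraph(net)
  n <- igraph::vcount(g)
  if (n == 0) abort("network is empty.")
  cc <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  cc[is.nan(cc)] <- 0   # degree-1 vertices
  mean_cc <- mean(cc)
  comp <- igraph::components(g)
  big <- which.max(comp$csize)
  sub <- igraph::induced_subgraph(g, which(comp$membership == big))
  mean_path <- if (igraph::vcount(sub) > 1) {
    igraph::mean_distance(sub, directed = FALSE)
  } else 0
  kbar <- mean(igraph::degree(g))
  list(mean_cc = mean_cc, mean_path = mean_path,
       cc_rand = kbar / n,
       path_rand = if (kbar > 1) log(n) / log(kbar) else NA_real_,
       n = n, mean_degree = kbar)
}

#' Dynamic scale-free / small-world threshold selection
#'
#' Evaluates every candidate threshold: a candidate passes when the log-log
#' degree-fit exponent lies in `slope_range`, its R^2 reaches `r2_min`, the
#' mean clustering coefficient is at least `cc_ratio` times the random
#' baseline and the mean path length is at most `path_ratio` times the
#' random baseline. The selected threshold is the lowest passing one
#' (maximizing the fraction of genes used), or the highest with
#' `rule = "highest"`. The full per-threshold report is always returned.
#'
#' @param corr Symmetric correlation matrix.
#' @param grid Candidate thresholds (evaluated in descending order).
#' @param r2_min Minimum R^2 of the degree fit.
#' @param cc_ratio Minimum MeanCC / CC_rand.
#' @param path_ratio Maximum MeanPath / Path_rand.
#' @param slope_range Interval for the degree exponent.
#' @param rule `"lowest"` (default) or `"highest"` passing threshold.
#' @param absolute Use `|rho|` for edges.
#' @return A `core_threshold` object: list with `threshold` (NA when
#'   nothing passes), `status`, and `report`, a tibble with columns
#'   threshold, r_squared, slope, mean_cc, mean_path, cc_rand, path_rand,
#'   pct_used, pct_big_comp, pass.
#' @export
select_threshold <- function(corr, grid = seq(0.99, 0.70, by = -0.002),
                             r2_min = 0.80, cc_ratio = 2, path_ratio = 1,
                             slope_range = c(1, 3), rule = c("lowest",
                                                             "highest"),
                             absolute = TRUE) {
  rule <- match.arg(rule)
  if (any(grid <= 0 | grid >= 1)) abort("grid thresholds must lie in (0,1).")
  grid <- sort(grid, decreasing = TRUE)
  n_input <- nrow(corr)
  rows <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    tau <- grid[i]
    net <- network_at_threshold(corr, tau, absolute = absolute)
    row <- tibble(threshold = tau, r_squared = NA_real_, slope = NA_real_,
                  mean_cc = NA_real_, mean_path = NA_real_,
                  cc_rand = NA_real_, path_rand = NA_real_,
                  pct_used = 100 * length(net$nodes) / n_input,
                  pct_big_comp = NA_real_, pass = FALSE)
    if (length(net$nodes) >= 3 && nrow(net$edges) >= 2) {
      g <- as_igraph(net)
      deg <- igraph::degree(g)
      sw <- smallworld_stats(g)
      comp <- igraph::components(g)
      row$mean_cc <- sw$mean_cc
      row$mean_path <- sw$mean_path
      row$cc_rand <- sw$cc_rand
      row$path_rand <- sw$path_rand
      row$pct_big_comp <- 100 * max(comp$csize) / length(net$nodes)
      fit <- tryCatch(degree_loglog_fit(deg), error = function(e) NULL)
      if (!is.null(fit)) {
        row$slope <- fit$a
        row$r_squared <- fit$r_squared
        row$pass <- fit$a > slope_range[1] && fit$a < slope_range[2] &&
          fit$r_squared >= r2_min &&
          sw$mean_cc >= cc_ratio * sw$cc_rand &&
          !is.na(sw$path_rand) && sw$mean_path <= path_ratio * sw$path_rand
      }
    }
    rows[[i]] <- row
  }
  report <- bind_rows(rows)
  passing <- report$threshold[report$pass]
  tau_star <- if (length(passing) == 0) NA_real_ else
    if (rule == "lowest") min(passing) else max(passing)
  structure(list(threshold = tau_star,
                 status = if (is.na(tau_star)) "no_passing_threshold" else "ok",
                 report = report, criteria = list(
                   r2_min = r2_min, cc_ratio = cc_ratio,
                   path_ratio = path_ratio, slope_range = slope_range)),
            class = "core_threshold")
}

#' @export
print.core_threshold <- function(x, ...) {
  if (is.na(x$threshold)) {
    cat(sprintf("threshold selection: no passing threshold among %d candidates\n",
                nrow(x$report)))
  } else {
    cat(sprintf("selected threshold %.3f (%d of %d candidates pass)\n",
                x$threshold, sum(x$report$pass), nrow(x$report)))
  }
  invisible(x)
}

#' Write a network edge list as TSV
#' @param net A `core_network` object.
#' @param path Output path.
#' @export
write_edge_list <- function(net, path) {
  readr::write_tsv(net$edges, path)
  invisible(path)
}

#' Read an edge list TSV back into a `core_network`
#' @param path Edge-list TSV (gene_a, gene_b, rho).
#' @param threshold Threshold to record on the object.
#' @export
read_edge_list <- function(path, threshold = NA_real_) {
  edges <- readr::read_tsv(path, show_col_types = FALSE,
                           col_types = readr::cols(gene_a = "c",
                                                   gene_b = "c"))
  structure(list(nodes = sort(unique(c(edges$gene_a, edges$gene_b))),
                 edges = edges, threshold = threshold,
                 n_input = length(unique(c(edges$gene_a, edges$gene_b)))),
            class = "core_network")
}
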