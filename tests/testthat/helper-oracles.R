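# independent brute-force oracles used across test files; these deliberately
# avoid the package's own interval / graph / ranking code paths

# exhaustive reciprocal-best-hit search over raw hit tibbles
brute_rbh <- function(forward, reverse, cutoff = 1e-5) {
  best_of <- function(tab, q) {
    rows <- tab[tab$qseqid == q & tab$evalue <= cutoff, ]
    if (nrow(rows) == 0) return(NA_character_)
    agg <- list()
    for (i in seq_len(nrow(rows))) {
      s <- rows$sseqid[i]
      cur <- if (is.null(agg[[s]])) c(0, Inf, 0) else agg[[s]]
      agg[[s]] <- c(cur[1] + rows$bitscore[i],
                    min(cur[2], rows$evalue[i]),
                    cur[3] + rows$length[i])
    }
    subjects <- names(agg)
    best <- subjects[1]
    for (s in subjects[-1]) {
      a <- agg[[s]]; b <- agg[[best]]
      better <- (a[1] > b[1]) ||
        (a[1] == b[1] && a[2] < b[2]) ||
        (a[1] == b[1] && a[2] == b[2] && a[3] > b[3]) ||
        (a[1] == b[1] && a[2] == b[2] && a[3] == b[3] && s < best)
      if (better) best <- s
    }
    best
  }
  pairs <- list()
  for (q in unique(forward$qseqid)) {
    tb <- best_of(forward, q)
    if (is.na(tb)) next
    back <- best_of(reverse, tb)
    if (is.na(back)) next
    ga <- trinity_gene_of(q)
    if (trinity_gene_of(back) == ga) {
      pairs[[paste(ga, tb)]] <- c(gene_a = ga, transcript_b = tb)
    }
  }
  out <- unique(do.call(rbind, pairs))
  if (is.null(out)) return(tibble::tibble(gene_a = character(),
                                          transcript_b = character()))
  tibble::as_tibble(out)
}

# per-base union of 0-based half-open intervals
brute_union_bases <- function(starts, ends) {
  covered <- integer(0)
  for (i in seq_along(starts)) {
    if (ends[i] > starts[i]) covered <- union(covered,
                                              seq(starts[i], ends[i] - 1))
  }
  sort(covered)
}

# per-record overlap of a 1-based closed span with 0-based half-open intervals
brute_overlap_bp <- function(span_start, span_end, iv_starts, iv_ends) {
  bases <- seq(span_start, span_end)          # 1-based positions
  hit <- logical(length(bases))
  for (i in seq_along(iv_starts)) {
    hit <- hit | (bases > iv_starts[i] & bases <= iv_ends[i])
  }
  sum(hit)
}

# clustering coefficient and mean path by direct enumeration (<= 30 nodes)
brute_graph_stats <- function(adj) {
  n <- nrow(adj)
  cc <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(adj[v, ] > 0)
    k <- length(nb)
    if (k < 2) { cc[v] <- 0; next }
    links <- 0
    for (i in seq_along(nb)) for (j in seq_len(i - 1)) {
      links <- links + adj[nb[i], nb[j]]
    }
    cc[v] <- 2 * links / (k * (k - 1))
  }
  # BFS all-pairs shortest paths
  dist <- matrix(Inf, n, n)
  diag(dist) <- 0
  for (s in seq_len(n)) {
    frontier <- s; d <- 0
    while (length(frontier) > 0) {
      d <- d + 1
      nxt <- integer(0)
      for (v in frontier) {
        for (w in which(adj[v, ] > 0)) {
          if (dist[s, w] > d) { dist[s, w] <- d; nxt <- c(nxt, w) }
        }
      }
      frontier <- unique(nxt)
    }
  }
  # largest component
  comp <- rep(NA_integer_, n)
  cid <- 0
  for (v in seq_len(n)) {
    if (is.na(comp[v])) {
      cid <- cid + 1
      comp[is.finite(dist[v, ])] <- cid
    }
  }
  big <- which(comp == which.max(tabulate(comp)))
  dsub <- dist[big, big, drop = FALSE]
  pairs <- dsub[upper.tri(dsub)]
  list(mean_cc = mean(cc),
       mean_path = if (length(pairs) > 0) mean(pairs[is.finite(pairs)])
       else 0)
}

# AUC of score ranking positives above negatives
rank_auc <- function(score, positive) {
  r <- rank(score)
  np <- sum(positive); nn <- sum(!positive)
  (sum(r[positive]) - np * (np + 1) / 2) / (np * nn)
}

# build a core_network directly from an adjacency-defining edge tibble
toy_network <- function(edges, nodes) {
  structure(list(nodes = nodes, edges = edges, threshold = 0.9,
                 n_input = length(nodes)),
            class = "core_network")
}
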