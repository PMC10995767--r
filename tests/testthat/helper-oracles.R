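# Independent brute-force oracles: plain per-observation loops that restate
# each calling rule directly, kept deliberately separate from the package's
# vectorized implementations.

oracle_lncpm <- function(vals, thr = 2.5) {
  out <- character(ncol(vals))
  for (j in seq_len(ncol(vals))) {
    cd94 <- vals["KLRD1", j] >= thr
    a <- vals["KLRC1", j] >= thr
    c_ <- vals["KLRC2", j] >= thr
    out[j] <- if (cd94 && a && c_) "DOUBLE_POS"
    else if (cd94 && a) "NKG2A_POS"
    else if (cd94 && c_) "NKG2C_POS"
    else "UNASSIGNED"
  }
  out
}

oracle_zscore <- function(vals, margin = 1) {
  out <- character(ncol(vals))
  for (j in seq_len(ncol(vals))) {
    d <- vals["KLRC1", j] - vals["KLRC2", j]
    out[j] <- if (d >= margin) "NKG2A_POS"
    else if (d <= -margin) "NKG2C_POS"
    else "UNASSIGNED"
  }
  out
}

oracle_pentile <- function(scores, frac = 0.2) {
  n <- length(scores)
  k <- floor(frac * n)
  out <- rep("UNASSIGNED", n)
  out[order(-scores)[seq_len(k)]] <- "NKG2A_POS"
  out[order(scores)[seq_len(k)]] <- "NKG2C_POS"
  out
}

oracle_spatial_cd8 <- function(vals) {
  out <- character(ncol(vals))
  for (j in seq_len(ncol(vals))) {
    t_pos <- mean(vals[c("CD3D", "CD3E", "CD3G"), j]) > 0
    cd8_pos <- t_pos && mean(vals[c("CD8A", "CD8B"), j]) > 0
    out[j] <- if (!cd8_pos) "OTHER"
    else if (vals["KLRC1", j] > 0) "NKG2A_CD8T" else "NKG2A_NEG_CD8T"
  }
  out
}

# Multi-source breadth-first search over an adjacency list.
oracle_bfs <- function(adjacency, sources) {
  n <- length(adjacency)
  dist <- rep(Inf, n)
  dist[sources] <- 0
  queue <- sources
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adjacency[[v]]) {
      if (dist[w] > dist[v] + 1) {
        dist[w] <- dist[v] + 1
        queue <- c(queue, w)
      }
    }
  }
  dist
}

# Pairwise AUROC: wins plus half-ties over all positive/negative pairs.
oracle_auroc <- function(labels, scores) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Exact hypergeometric tail by combinatorial enumeration.
oracle_hyper_ge <- function(k, N, m, n) {
  lo <- max(0, m + n - N)
  hi <- min(m, n)
  if (k > hi) return(0)
  i <- max(k, lo):hi
  sum(choose(m, i) * choose(N - m, n - i)) / choose(N, n)
}

# Two-pass HVG statistics with explicit loops.
oracle_hvg <- function(vals, n_bins = 20) {
  vals <- vals[rowSums(vals) > 0, , drop = FALSE]
  G <- nrow(vals)
  mu <- disp <- numeric(G)
  for (g in seq_len(G)) {
    mu[g] <- mean(vals[g, ])
    disp[g] <- var(vals[g, ]) / mu[g]
  }
  bin <- ceiling(rank(mu, ties.method = "average") / (G / n_bins))
  bin <- pmin(pmax(bin, 1L), n_bins)
  nd <- numeric(G)
  for (g in seq_len(G)) {
    d_bin <- disp[bin == bin[g]]
    m <- median(d_bin); s <- mad(d_bin)
    nd[g] <- if (s > 0) (disp[g] - m) / s else 0
  }
  sel <- mu > 0.5 & mu < 7.5 & nd >= 0.5 & disp > 0
  list(gene = rownames(vals), mean = mu, dispersion = disp,
       bin = as.integer(bin), norm_dispersion = nd, selected = sel)
}

rand_expr <- function(n_obs, genes = c("KLRD1", "KLRC1", "KLRC2"),
                      normalization = "ln_cpm1", gen = function(n) 5 * runif(n)) {
  vals <- matrix(gen(length(genes) * n_obs), length(genes), n_obs,
                 dimnames = list(genes, paste0("obs", seq_len(n_obs))))
  expression_matrix(vals, normalization)
}
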