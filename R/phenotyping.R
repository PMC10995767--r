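#' Dispersion-based highly-variable-gene selection
#'
#' Mean/dispersion HVG selection on ln(CPM+1) expression, in the style of
#' the original Seurat `mean.var.plot` procedure: genes with zero total
#' expression are removed first; per-gene dispersion is variance/mean;
#' genes are placed into equal-frequency bins by mean expression; the
#' normalized dispersion is the gene's dispersion centered by its bin
#' median and scaled by the bin median absolute deviation. A gene is
#' selected when its mean lies strictly between 0.5 and 7.5 (dropping
#' constantly lowly and constantly highly expressed genes) and its
#' normalized dispersion is at least 0.5.
#'
#' @param expr `ExpressionMatrix` with normalization `"ln_cpm1"`.
#' @param n_bins number of equal-frequency mean bins (default 20).
#' @param mean_bounds open interval of admissible means.
#' @param min_norm_dispersion selection threshold on the normalized
#'   dispersion.
#' @return data.frame of class `HVGResult`, one row per retained gene:
#'   `gene`, `mean`, `dispersion`, `bin`, `norm_dispersion`, `selected`.
#' @export
select_hvg <- function(expr, n_bins = 20, mean_bounds = c(0.5, 7.5),
                       min_norm_dispersion = 0.5) {
  vals <- expr$values
  vals <- vals[rowSums(vals) > 0, , drop = FALSE]
  if (nrow(vals) < n_bins)
    stop("fewer genes (", nrow(vals), ") than bins (", n_bins, ")")
  mu <- rowMeans(vals)
  v <- apply(vals, 1, stats::var)
  disp <- v / mu
  # equal-frequency bins by mean: rank-based cut keeps bins balanced
  bin <- ceiling(rank(mu, ties.method = "average") / (length(mu) / n_bins))
  bin <- pmin(pmax(bin, 1L), n_bins)
  med <- tapply(disp, bin, stats::median)
  madv <- tapply(disp, bin, stats::mad)
  nd <- (disp - med[as.character(bin)]) / madv[as.character(bin)]
  nd[!is.finite(nd)] <- 0   # zero-MAD bins carry no dispersion signal
  sel <- mu > mean_bounds[1] & mu < mean_bounds[2] &
    nd >= min_norm_dispersion & disp > 0
  out <- data.frame(gene = rownames(vals), mean = mu, dispersion = disp,
                    bin = as.integer(bin), norm_dispersion = unname(nd),
                    selected = unname(sel),
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("HVGResult", "data.frame")
  out
}

#' Default marker rules for CD8 T cell phenotype annotation
#'
#' Ordered literature-derived marker rules: proliferation via MKI67, MAIT
#' via KLRB1, SLEC-like (short-lived effector) via CD57 (B3GAT1) together
#' with IFN-gamma (IFNG), memory via IL7R, and effector via GZMB. The
#' order encodes precedence: SLEC-like is tested before effector because
#' effector cells are defined as non-SLEC-like cells still expressing
#' GZMB.
#'
#' @return data.frame with `label` and list-column `genes`.
#' @export
marker_rules <- function() {
  out <- data.frame(label = c("proliferation", "MAIT", "SLEC-like",
                              "memory", "effector"),
                    stringsAsFactors = FALSE)
  out$genes <- list("MKI67", "KLRB1", c("B3GAT1", "IFNG"), "IL7R", "GZMB")
  out
}

#' Annotate clusters by marker rules
#'
#' For each cluster, a marker gene is "high" when the cluster's mean
#' expression exceeds the across-cluster average of cluster means for that
#' gene. The first rule (in the fixed precedence order) whose required
#' genes are all high wins; clusters matching no rule are "unlabeled".
#' This is a reproducible proxy for annotation by inspection.
#'
#' @param cluster_means matrix of cluster mean expression, genes in rows,
#'   clusters in columns (ln(CPM+1) scale).
#' @param rules rule table from [marker_rules()].
#' @return named character vector: label per cluster.
#' @export
annotate_clusters <- function(cluster_means, rules = marker_rules()) {
  need <- normalize_symbols(unique(unlist(rules$genes)))
  rn <- normalize_symbols(rownames(cluster_means))
  miss <- setdiff(need, rn)
  if (length(miss)) stop("rule gene(s) absent from cluster means: ",
                         paste(miss, collapse = ", "))
  rownames(cluster_means) <- rn
  high <- cluster_means > rowMeans(cluster_means)
  labels <- apply(high, 2, function(h) {
    for (i in seq_len(nrow(rules))) {
      gs <- normalize_symbols(rules$genes[[i]])
      if (all(h[gs])) return(rules$label[i])
    }
    "unlabeled"
  })
  stats::setNames(labels, colnames(cluster_means))
}

#' Cluster mean expression table
#'
#' @param expr `ExpressionMatrix`.
#' @param clusters cluster id per observation (in column order).
#' @return matrix of cluster means, genes in rows, clusters in columns.
#' @export
cluster_means <- function(expr, clusters) {
  if (length(clusters) != ncol(expr$values))
    stop("one cluster id per observation required")
  cl <- factor(clusters)
  sums <- expr$values %*% stats::model.matrix(~ cl - 1)
  out <- sweep(sums, 2, table(cl), "/")
  colnames(out) <- levels(cl)
  as.matrix(out)
}
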