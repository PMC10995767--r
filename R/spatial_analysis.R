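#' Density diffusion from positive spots
#'
#' Diffuses each positive spot outwards over the spot neighbor graph to
#' delineate regions occupied by NKG2A+ or NKG2C+ spots — the spatial
#' analogue of embedding-density plots. The density at a spot is
#' `alpha^d`, with `d` the breadth-first graph distance to the nearest
#' positive spot: 1 at positive spots, decaying geometrically, and 0 beyond
#' the cutoff radius or for spots unreachable from any positive spot.
#'
#' @param grid a `SpatialGrid`.
#' @param positives character vector of positive spot ids (e.g. from
#'   [call_spatial_single_marker()]).
#' @param alpha decay per graph step, in (0, 1); default 0.5.
#' @param cutoff maximum graph distance receiving nonzero density
#'   (default 6).
#' @return named numeric vector of densities in [0, 1], one per spot.
#' @export
density_diffusion <- function(grid, positives, alpha = 0.5, cutoff = 6) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  ids <- grid$spots$spot_id
  src <- match(positives, ids)
  if (anyNA(src))
    stop("positive spot(s) not in grid: ",
         paste(positives[is.na(src)], collapse = ", "))
  dens <- stats::setNames(rep(0, length(ids)), ids)
  if (length(src) == 0) {
    warning("empty positive set; all densities are zero")
    return(dens)
  }
  # multi-source BFS via igraph shortest paths from the positive set
  edges <- do.call(rbind, lapply(seq_along(grid$adjacency), function(i) {
    nb <- grid$adjacency[[i]]
    nb <- nb[nb > i]
    if (length(nb)) cbind(i, nb) else NULL
  }))
  g <- if (is.null(edges)) {
    igraph::make_empty_graph(length(ids), directed = FALSE)
  } else {
    igraph::add_vertices(igraph::graph_from_edgelist(edges, directed = FALSE),
                         max(0, length(ids) - max(edges)))
  }
  d <- igraph::distances(g, v = src)
  dmin <- apply(d, 2, min)
  reach <- is.finite(dmin) & dmin <= cutoff
  dens[reach] <- alpha^dmin[reach]
  dens
}

#' Ligand-receptor pair list
#'
#' @param pair_id identifiers.
#' @param ligand,receptor lists (or pipe-joined strings) of gene symbols;
#'   multi-subunit complexes give several components per side.
#' @return data.frame of class `LRPairs` with list-columns
#'   `ligand_components`, `receptor_components`.
#' @export
lr_pairs <- function(pair_id, ligand, receptor) {
  split_side <- function(x) {
    if (is.list(x)) lapply(x, as.character)
    else strsplit(as.character(x), "|", fixed = TRUE)
  }
  lig <- split_side(ligand); rec <- split_side(receptor)
  if (any(lengths(lig) == 0) || any(lengths(rec) == 0))
    stop("every pair needs at least one ligand and one receptor component")
  out <- data.frame(pair_id = as.character(pair_id),
                    stringsAsFactors = FALSE)
  out$ligand_components <- lig
  out$receptor_components <- rec
  class(out) <- c("LRPairs", "data.frame")
  out
}

#' Read a ligand-receptor pair list from CSV
#'
#' Columns: `pair_id`, `ligand_components`, `receptor_components`, the
#' component columns pipe-joined for complexes.
#'
#' @param path CSV path.
#' @return an `LRPairs` data.frame.
#' @export
read_lr_pairs <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("pair_id", "ligand_components", "receptor_components")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("pair list missing column(s): ",
                         paste(miss, collapse = ", "))
  lr_pairs(tab$pair_id, tab$ligand_components, tab$receptor_components)
}

#' Spot-level ligand-receptor interaction scores
#'
#' For each (spot, pair), the product of a ligand summary and a receptor
#' summary. Each side of a pair is summarized by the minimum over its
#' components (limiting-subunit convention for complexes) of the mean
#' expression across the neighborhood: the spot alone (default) or the
#' spot plus its graph neighbors for juxtacrine signaling that spans
#' adjacent spots. Pairs with missing component genes are dropped with a
#' warning.
#'
#' @param expr `ExpressionMatrix` of spot expression.
#' @param grid `SpatialGrid` matching the observation columns (only needed
#'   for `neighborhood = "spot_neighbors"`).
#' @param pairs an `LRPairs` table.
#' @param neighborhood `"spot"` or `"spot_neighbors"`.
#' @return matrix of scores, pairs in rows, spots in columns.
#' @export
lr_scores <- function(expr, pairs, grid = NULL,
                      neighborhood = c("spot", "spot_neighbors")) {
  neighborhood <- match.arg(neighborhood)
  vals <- expr$values
  if (neighborhood == "spot_neighbors") {
    if (is.null(grid)) stop("neighborhood mode requires a SpatialGrid")
    idx <- match(colnames(vals), grid$spots$spot_id)
    if (anyNA(idx)) stop("expression columns missing from grid")
    sm <- vals
    for (j in seq_len(ncol(vals))) {
      nb <- c(idx[j], grid$adjacency[[idx[j]]])
      cols <- match(grid$spots$spot_id[nb], colnames(vals))
      cols <- cols[!is.na(cols)]
      sm[, j] <- rowMeans(vals[, cols, drop = FALSE])
    }
    vals <- sm
  }
  have <- function(gs) all(gs %in% rownames(vals))
  keep <- vapply(seq_len(nrow(pairs)), function(i)
    have(pairs$ligand_components[[i]]) && have(pairs$receptor_components[[i]]),
    logical(1))
  if (!all(keep))
    warning("dropping pair(s) with missing genes: ",
            paste(pairs$pair_id[!keep], collapse = ", "))
  if (!any(keep)) stop("all ligand-receptor pairs dropped")
  pairs <- pairs[keep, , drop = FALSE]
  side_min <- function(gs) {
    m <- vals[gs, , drop = FALSE]
    apply(m, 2, min)
  }
  sc <- matrix(0, nrow(pairs), ncol(vals),
               dimnames = list(pairs$pair_id, colnames(vals)))
  for (i in seq_len(nrow(pairs)))
    sc[i, ] <- side_min(pairs$ligand_components[[i]]) *
      side_min(pairs$receptor_components[[i]])
  sc
}

#' Differential ligand-receptor statistic between spot classes
#'
#' Per pair, a two-sided Mann-Whitney test of per-spot interaction scores
#' between two spot classes (NKG2A+ CD8 T cell spots versus NKG2A- CD8 T
#' cell spots), the log2 fold change of class means (pseudocount 1e-9),
#' and the composite `rank_weight = log2fc * (-log10 p)` used to rank
#' pairs — the product of the volcano-plot axes.
#'
#' @param scores pair-by-spot score matrix from [lr_scores()].
#' @param class_a,class_b character vectors of spot ids for the two
#'   classes (both non-empty).
#' @return data.frame per pair: `pair_id`, `p`, `log2fc`, `rank_weight`,
#'   ordered as in `scores`.
#' @export
differential_lr <- function(scores, class_a, class_b) {
  a <- intersect(class_a, colnames(scores))
  b <- intersect(class_b, colnames(scores))
  if (length(a) == 0 || length(b) == 0)
    stop("both spot classes must be non-empty")
  eps <- 1e-9
  out <- lapply(rownames(scores), function(pid) {
    xa <- scores[pid, a]; xb <- scores[pid, b]
    if (stats::sd(c(xa, xb)) == 0) {
      p <- 1  # constant pair carries no signal
    } else {
      p <- mwu(xa, xb)$p
    }
    lfc <- log2((mean(xa) + eps) / (mean(xb) + eps))
    data.frame(pair_id = pid, p = p, log2fc = lfc,
               rank_weight = lfc * (-log10(p)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
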