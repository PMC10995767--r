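#' @keywords internal
"_PACKAGE"

# Bias labels used across all modalities.
BIAS_LEVELS <- c("NKG2A_POS", "NKG2C_POS", "DOUBLE_POS", "UNASSIGNED")

# Protein-name aliases for the receptor genes; the literature mixes protein
# and gene nomenclature, so lookups try the symbol first and then the alias.
GENE_ALIASES <- c(
  CD94  = "KLRD1",
  NKG2A = "KLRC1",
  NKG2C = "KLRC2",
  CD57  = "B3GAT1",
  CD56  = "NCAM1",
  "IFNγ" = "IFNG"
)

#' Normalize protein aliases to gene symbols
#'
#' Maps the handful of protein names used interchangeably with gene symbols
#' (CD94, NKG2A, NKG2C, CD57, CD56, IFN-gamma) onto their HGNC symbols.
#' Unknown symbols pass through untouched; matching is case-sensitive.
#'
#' @param symbols character vector of gene symbols or protein names.
#' @return character vector of the same length with aliases replaced.
#' @export
#' @examples
#' normalize_symbols(c("CD94", "NKG2A", "CD8A"))
normalize_symbols <- function(symbols) {
  hit <- symbols %in% names(GENE_ALIASES)
  symbols[hit] <- unname(GENE_ALIASES[symbols[hit]])
  symbols
}

#' Construct an expression matrix
#'
#' A validated genes-by-observations matrix carrying a normalization tag.
#' The tag governs which bias-calling rule is legal: threshold calls require
#' `ln_cpm1`, margin calls require `zscore`, bulk scoring requires
#' `bulk_norm`, and spatial positivity requires `spatial_counts`.
#'
#' @param values numeric matrix, genes in rows, observations in columns.
#'   Row and column names are required and must be unique.
#' @param normalization one of `"ln_cpm1"`, `"zscore"`, `"bulk_norm"`,
#'   `"spatial_counts"`.
#' @return an object of class `ExpressionMatrix` (a list with elements
#'   `values` and `normalization`).
#' @export
#' @examples
#' m <- matrix(rexp(6), 3, 2,
#'             dimnames = list(c("KLRD1", "KLRC1", "KLRC2"), c("c1", "c2")))
#' expression_matrix(m, "ln_cpm1")
expression_matrix <- function(values,
                              normalization = c("ln_cpm1", "zscore",
                                                "bulk_norm", "spatial_counts")) {
  normalization <- match.arg(normalization)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix requires gene (row) and observation (column) names")
  if (anyDuplicated(rownames(values)))
    stop("duplicated gene ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicated observation ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  bad <- !is.finite(values)
  if (any(bad)) {
    genes <- rownames(values)[unique(which(bad, arr.ind = TRUE)[, 1])]
    stop("non-finite expression values for gene(s): ",
         paste(genes, collapse = ", "))
  }
  if (normalization == "zscore") {
    mu <- rowMeans(values)
    sdv <- apply(values, 1, stats::sd)
    varying <- sdv > 0
    if (any(abs(mu[varying]) > 1e-6) ||
        any(abs(sdv[varying] - 1) > 1e-6))
      stop("zscore matrix must have per-gene mean 0 and sd 1 ",
           "(within 1e-6) over genes with nonzero variance")
  }
  structure(list(values = values, normalization = normalization),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d observations [%s]\n",
              nrow(x$values), ncol(x$values), x$normalization))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

# Locate a gene row, trying the symbol then its protein alias.
# Returns the row index or NA.
.gene_row <- function(expr, symbol) {
  rn <- rownames(expr$values)
  i <- match(normalize_symbols(symbol), normalize_symbols(rn))
  if (is.na(i)) i <- match(symbol, rn)
  i
}

# Fetch one gene's expression vector; hard error naming the gene if absent.
.gene_values <- function(expr, symbol) {
  i <- .gene_row(expr, symbol)
  if (is.na(i)) stop("required gene absent from matrix: ", symbol)
  expr$values[i, ]
}

.has_gene <- function(expr, symbol) !is.na(.gene_row(expr, symbol))

#' Bias-calling parameters
#'
#' Bundles the constants behind every calling rule: the ln(CPM+1) positivity
#' threshold (2.5 on both CD94/KLRD1 and the receptor), the Z-score margin
#' (1 standard deviation between the NKG2A and NKG2C scores), the pentile
#' fraction for bulk calls (top/bottom 20%), the patient-level count-ratio
#' factors (NK cells need three times more NKG2A+ than NKG2C+ cells; CD8 T
#' cells simply more), pseudocounts, and the expressed-gene filters used by
#' the set-overlap analyses.
#'
#' @param lncpm_threshold positivity threshold on the ln(CPM+1) scale.
#' @param zscore_margin required difference between NKG2A and NKG2C Z-scores.
#' @param pentile fraction labelled at each pole of the bulk score; must be
#'   in (0, 0.5).
#' @param nk_ratio_factor,cd8_ratio_factor patient bias requires
#'   `n_A > factor * n_C` (strict) for the given cell type.
#' @param bulk_epsilon pseudocount added to the CD94 x receptor products
#'   before taking log2, so zero expression never yields +/-Inf.
#' @param count_pseudocount pseudocount for the continuous A:C cell ratio.
#' @param expressed_top_fraction expressed-gene filter for infection
#'   contexts: top fraction of genes by mean expression.
#' @param expressed_min_mean expressed-gene filter for the cancer context:
#'   minimum mean expression.
#' @return a list of class `BiasCallingParams`.
#' @export
bias_params <- function(lncpm_threshold = 2.5,
                        zscore_margin = 1.0,
                        pentile = 0.20,
                        nk_ratio_factor = 3.0,
                        cd8_ratio_factor = 1.0,
                        bulk_epsilon = 1e-9,
                        count_pseudocount = 1.0,
                        expressed_top_fraction = 0.10,
                        expressed_min_mean = 0.01) {
  p <- list(lncpm_threshold = lncpm_threshold,
            zscore_margin = zscore_margin,
            pentile = pentile,
            nk_ratio_factor = nk_ratio_factor,
            cd8_ratio_factor = cd8_ratio_factor,
            bulk_epsilon = bulk_epsilon,
            count_pseudocount = count_pseudocount,
            expressed_top_fraction = expressed_top_fraction,
            expressed_min_mean = expressed_min_mean)
  num <- vapply(p, is.numeric, logical(1))
  if (!all(num) || any(unlist(p) <= 0))
    stop("all bias-calling parameters must be strictly positive numbers")
  if (pentile >= 0.5) stop("pentile must lie in (0, 0.5)")
  structure(p, class = "BiasCallingParams")
}

#' Construct a gene set
#'
#' @param name set name.
#' @param symbols character vector of gene symbols; duplicates are dropped.
#' @return list of class `GeneSet` with elements `name` and `symbols`.
#' @export
gene_set <- function(name, symbols) {
  symbols <- unique(as.character(symbols))
  if (length(symbols) == 0) stop("gene set '", name, "' is empty")
  structure(list(name = name, symbols = symbols), class = "GeneSet")
}

#' Construct a TCR-beta repertoire
#'
#' A repertoire is the set of unique TCR-beta chains observed in one sample,
#' each chain identified by the triple (CDR3 amino-acid sequence, V gene,
#' J gene). Rows are de-duplicated on the triple.
#'
#' @param sample_id,patient_id identifiers.
#' @param chains data.frame with columns `cdr3_aa`, `v_gene`, `j_gene`.
#' @return list of class `Repertoire`.
#' @export
repertoire <- function(sample_id, patient_id, chains) {
  need <- c("cdr3_aa", "v_gene", "j_gene")
  miss <- setdiff(need, names(chains))
  if (length(miss)) stop("repertoire table missing column(s): ",
                         paste(miss, collapse = ", "))
  bad <- grepl("[^ACDEFGHIKLMNPQRSTVWY]", chains$cdr3_aa)
  if (any(bad))
    stop("cdr3_aa contains non-standard residues in: ",
         paste(utils::head(chains$cdr3_aa[bad], 3), collapse = ", "))
  key <- paste(chains$cdr3_aa, chains$v_gene, chains$j_gene, sep = "|")
  chains <- chains[!duplicated(key), need, drop = FALSE]
  rownames(chains) <- NULL
  structure(list(sample_id = sample_id, patient_id = patient_id,
                 chains = chains),
            class = "Repertoire")
}

#' @export
print.Repertoire <- function(x, ...) {
  cat(sprintf("Repertoire %s (patient %s): %d unique TCR-beta chains\n",
              x$sample_id, x$patient_id, nrow(x$chains)))
  invisible(x)
}

# Internal key used for exact triple matching.
.chain_key <- function(chains)
  paste(chains$cdr3_aa, chains$v_gene, chains$j_gene, sep = "|")
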