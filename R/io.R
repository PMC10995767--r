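#' Read an expression matrix
#'
#' Supports dense TSV (genes in rows, first column the gene symbol, header
#' row of observation ids) and Matrix Market triplets with `genes.tsv` /
#' `barcodes.tsv` sidecars next to the `.mtx` file. The normalization tag is
#' supplied by the caller, never guessed from the data.
#'
#' @param path file path (`.tsv` for dense, `.mtx` for Matrix Market).
#' @param format `"tsv"` or `"mtx"`; inferred from the extension by default.
#' @param normalization normalization tag; see [expression_matrix()].
#' @return an `ExpressionMatrix`.
#' @export
read_expression <- function(path, format = c("auto", "tsv", "mtx"),
                            normalization = "ln_cpm1") {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.mtx$", path)) "mtx" else "tsv"
  if (format == "tsv") {
    tab <- utils::read.delim(path, check.names = FALSE,
                             stringsAsFactors = FALSE)
    genes <- as.character(tab[[1]])
    if (anyDuplicated(genes))
      stop("duplicated gene ids in ", path, ": ",
           paste(unique(genes[duplicated(genes)]), collapse = ", "))
    m <- as.matrix(tab[, -1, drop = FALSE])
    mode(m) <- "numeric"
    rownames(m) <- genes
  } else {
    dir <- dirname(path)
    m <- as.matrix(Matrix::readMM(path))
    genes <- utils::read.delim(file.path(dir, "genes.tsv"), header = FALSE,
                               stringsAsFactors = FALSE)[[1]]
    obs <- utils::read.delim(file.path(dir, "barcodes.tsv"), header = FALSE,
                             stringsAsFactors = FALSE)[[1]]
    if (length(genes) != nrow(m) || length(obs) != ncol(m))
      stop("sidecar gene/barcode files do not match matrix dimensions")
    dimnames(m) <- list(genes, obs)
  }
  expression_matrix(m, normalization)
}

#' Write an expression matrix
#'
#' Inverse of [read_expression()]; dense TSV or Matrix Market triplet with
#' `genes.tsv`/`barcodes.tsv` sidecars.
#'
#' @param expr an `ExpressionMatrix`.
#' @param path output path (`.tsv` or `.mtx`).
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  if (grepl("\\.mtx$", path)) {
    dir <- dirname(path)
    Matrix::writeMM(Matrix::Matrix(expr$values, sparse = TRUE), path)
    utils::write.table(rownames(expr$values), file.path(dir, "genes.tsv"),
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    utils::write.table(colnames(expr$values), file.path(dir, "barcodes.tsv"),
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  } else {
    tab <- data.frame(gene = rownames(expr$values), expr$values,
                      check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read a clinical table
#'
#' Expects a CSV with columns `patient_id`, `sex`, `age_years`,
#' `severity_wos`, `deceased` and optionally `cmv_positive` plus any number
#' of `symptom_*` / `comorbidity_*` binary columns. Sex is recoded so that
#' female is 1 and male is 0; severity stays on the raw WHO Ordinal Scale
#' (the severe-disease binarization at WOS >= 5 is derived downstream, never
#' stored).
#'
#' @param path CSV path.
#' @param sex_coding named map from the file's sex codes to {0,1}.
#' @return data.frame of patient records with a `sex_female` column.
#' @export
read_clinical <- function(path,
                          sex_coding = c(F = 1, M = 0, female = 1, male = 0)) {
  # sex read as character so "F"/"T" codes survive type conversion
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(sex = "character"))
  need <- c("patient_id", "sex", "age_years", "severity_wos", "deceased")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("clinical table missing column(s): ",
                         paste(miss, collapse = ", "))
  sx <- sex_coding[as.character(tab$sex)]
  if (any(is.na(sx)))
    stop("unrecognized sex value(s): ",
         paste(unique(tab$sex[is.na(sx)]), collapse = ", "))
  tab$sex_female <- as.integer(sx)
  if (!all(tab$deceased %in% c(0, 1)))
    stop("deceased must be binary; offending patient(s): ",
         paste(tab$patient_id[!tab$deceased %in% c(0, 1)], collapse = ", "))
  if (any(tab$age_years < 0))
    stop("negative age for patient(s): ",
         paste(tab$patient_id[tab$age_years < 0], collapse = ", "))
  tab
}

#' Read a TCR-beta repertoire table
#'
#' immunoSEQ-style TSV with columns `cdr3_aa`, `v_gene`, `j_gene`; rows are
#' de-duplicated on the triple.
#'
#' @param path TSV path.
#' @param sample_id,patient_id identifiers; default to the file name.
#' @return a [repertoire()].
#' @export
read_repertoire <- function(path, sample_id = basename(path),
                            patient_id = sample_id) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  repertoire(sample_id, patient_id, tab)
}

#' Write a repertoire table
#' @param rep a `Repertoire`.
#' @param path TSV output path.
#' @return `path`, invisibly.
#' @export
write_repertoire <- function(rep, path) {
  utils::write.table(rep$chains, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read Visium-style tissue positions
#'
#' CSV in the tissue-positions dialect: `barcode`, `in_tissue`, `array_row`,
#' `array_col` (pixel coordinate columns are ignored). Builds the hex
#' neighbor graph over in-tissue spots.
#'
#' @param path CSV path.
#' @param layout grid layout passed to [spatial_grid()].
#' @param header whether the file carries a header row (Space Ranger wrote
#'   both dialects).
#' @return a `SpatialGrid` over the in-tissue spots.
#' @export
read_positions <- function(path, layout = "hex", header = TRUE) {
  tab <- utils::read.csv(path, header = header, stringsAsFactors = FALSE)
  if (!header)
    names(tab)[1:4] <- c("barcode", "in_tissue", "array_row", "array_col")
  need <- c("barcode", "in_tissue", "array_row", "array_col")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("positions table missing column(s): ",
                         paste(miss, collapse = ", "))
  spots <- data.frame(spot_id = tab$barcode,
                      array_row = as.integer(tab$array_row),
                      array_col = as.integer(tab$array_col),
                      in_tissue = as.integer(tab$in_tissue),
                      stringsAsFactors = FALSE)
  spatial_grid(spots[spots$in_tissue == 1L, , drop = FALSE], layout)
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then tab-separated gene symbols.
#'
#' @param path GMT path.
#' @return list of [gene_set()] objects, named by set.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3)
      stop("GMT line with no genes: ", parts[1])
    gene_set(parts[1], parts[-(1:2)])
  })
  stats::setNames(sets, vapply(sets, `[[`, character(1), "name"))
}

#' Write gene sets in GMT format
#' @param sets list of `GeneSet` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(sets, function(s)
    paste(c(s$name, "na", s$symbols), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}
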