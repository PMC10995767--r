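#' Call NKG2A+/NKG2C+ cells from ln(CPM+1) expression
#'
#' A cell is NKG2A+ when both CD94 (KLRD1) and NKG2A (KLRC1) are at or above
#' the positivity threshold (default 2.5 on the ln(CPM+1) scale) while NKG2C
#' (KLRC2) is below it; NKG2C+ symmetrically. Cells clearing the threshold
#' on CD94 and both receptors are flagged DOUBLE_POS; everything else is
#' UNASSIGNED. CD94 co-expression is required because it heterodimerizes
#' with both receptors to permit their surface expression.
#'
#' @param expr `ExpressionMatrix` with normalization `"ln_cpm1"`, containing
#'   KLRD1, KLRC1 and KLRC2 (protein aliases accepted).
#' @param params [bias_params()].
#' @return factor of bias labels, one per observation, levels
#'   `NKG2A_POS`, `NKG2C_POS`, `DOUBLE_POS`, `UNASSIGNED`.
#' @export
#' @examples
#' m <- matrix(c(3, 2.6, 0, 3, 0, 2.6), 3,
#'             dimnames = list(c("KLRD1", "KLRC1", "KLRC2"), c("a", "c")))
#' call_cells_lncpm(expression_matrix(m, "ln_cpm1"))
call_cells_lncpm <- function(expr, params = bias_params()) {
  if (expr$normalization != "ln_cpm1")
    stop("threshold calling requires ln_cpm1 normalization, got ",
         expr$normalization)
  thr <- params$lncpm_threshold
  cd94 <- .gene_values(expr, "KLRD1") >= thr
  a <- .gene_values(expr, "KLRC1") >= thr
  c_ <- .gene_values(expr, "KLRC2") >= thr
  lab <- rep("UNASSIGNED", ncol(expr$values))
  lab[cd94 & a & !c_] <- "NKG2A_POS"
  lab[cd94 & c_ & !a] <- "NKG2C_POS"
  lab[cd94 & a & c_] <- "DOUBLE_POS"
  factor(stats::setNames(lab, colnames(expr$values)), levels = BIAS_LEVELS)
}

#' Call NKG2A+/NKG2C+ cells from Z-scored expression
#'
#' For matrices normalized to per-gene Z-scores, absolute thresholds are
#' meaningless; instead a cell is NKG2A+ when its NKG2A (KLRC1) Z-score
#' exceeds its NKG2C (KLRC2) Z-score by at least the margin (default 1),
#' and NKG2C+ symmetrically. The two margins cannot hold simultaneously, so
#' DOUBLE_POS is unreachable in this mode.
#'
#' @inheritParams call_cells_lncpm
#' @return factor of bias labels as in [call_cells_lncpm()].
#' @export
call_cells_zscore <- function(expr, params = bias_params()) {
  if (expr$normalization != "zscore")
    stop("margin calling requires zscore normalization, got ",
         expr$normalization)
  d <- .gene_values(expr, "KLRC1") - .gene_values(expr, "KLRC2")
  lab <- rep("UNASSIGNED", ncol(expr$values))
  lab[d >= params$zscore_margin] <- "NKG2A_POS"
  lab[-d >= params$zscore_margin] <- "NKG2C_POS"
  factor(stats::setNames(lab, colnames(expr$values)), levels = BIAS_LEVELS)
}

#' Score bulk samples for NKG2A:NKG2C bias
#'
#' Per sample, the log2 fold change between the CD94 x NKG2A and
#' CD94 x NKG2C products of normalized expression:
#' `log2(KLRD1*KLRC1 + eps) - log2(KLRD1*KLRC2 + eps)`. The pseudocount
#' keeps zero expression finite.
#'
#' @param expr `ExpressionMatrix` with nonnegative bulk-normalized values
#'   (normalization `"bulk_norm"`).
#' @param params [bias_params()].
#' @return named numeric vector of scores, one per sample.
#' @export
score_bulk <- function(expr, params = bias_params()) {
  if (any(expr$values < 0))
    stop("bulk scoring requires nonnegative expression")
  eps <- params$bulk_epsilon
  cd94 <- .gene_values(expr, "KLRD1")
  a <- .gene_values(expr, "KLRC1")
  c_ <- .gene_values(expr, "KLRC2")
  log2(cd94 * a + eps) - log2(cd94 * c_ + eps)
}

#' Assign bulk pentile labels from bias scores
#'
#' Ranks samples by score (descending) and labels the top `floor(0.2 n)` as
#' NKG2A_POS, the bottom `floor(0.2 n)` as NKG2C_POS, and the remainder
#' UNASSIGNED. Ties are broken by stable input order.
#'
#' @param scores numeric vector of bias scores (named or not).
#' @param params [bias_params()].
#' @return factor of labels with levels `NKG2A_POS`, `NKG2C_POS`,
#'   `UNASSIGNED`, in input order.
#' @export
call_bulk_pentiles <- function(scores, params = bias_params()) {
  n <- length(scores)
  if (n < 10) stop("pentile calling needs at least 10 samples, got ", n)
  k <- floor(params$pentile * n)
  ord_desc <- order(-scores)           # stable: ties keep input order
  ord_asc <- order(scores)
  lab <- rep("UNASSIGNED", n)
  lab[ord_desc[seq_len(k)]] <- "NKG2A_POS"
  # bottom pole skips spots the top pole already claimed under ties
  bottom <- setdiff(ord_asc, ord_desc[seq_len(k)])
  lab[bottom[seq_len(k)]] <- "NKG2C_POS"
  factor(stats::setNames(lab, names(scores)),
         levels = c("NKG2A_POS", "NKG2C_POS", "UNASSIGNED"))
}

#' Call a patient's NKG2A+ bias from per-cell labels
#'
#' Within one cell type, a timepoint is biased when the NKG2A+ cell count
#' strictly exceeds `factor` times the NKG2C+ count, with `factor` 3 for NK
#' cells (their constitutive NKG2A+ skew) and 1 for CD8 T cells. DOUBLE_POS
#' and UNASSIGNED cells enter neither count. The patient is biased when any
#' acute timepoint is biased; the continuous A:C ratio
#' `(n_A + 1)/(n_C + 1)` pools counts over acute timepoints.
#'
#' @param cells data.frame of cell records for one patient with columns
#'   `cell_type`, `bias`, and optionally `timepoint` (single timepoint
#'   assumed when absent) and `phase` (all acute assumed when absent).
#' @param cell_type `"NK"` or `"CD8T"`.
#' @param params [bias_params()].
#' @param patient_id identifier copied into the result.
#' @return data.frame with one row: `patient_id`, `cell_type`, `n_a`, `n_c`
#'   (pooled acute counts), `biased` (0/1, NA when no cells of the type),
#'   `ac_ratio`, `n_cells`.
#' @export
call_patient_bias <- function(cells, cell_type = c("NK", "CD8T"),
                              params = bias_params(), patient_id = NA) {
  cell_type <- match.arg(cell_type)
  factor_ <- if (cell_type == "NK") params$nk_ratio_factor else
    params$cd8_ratio_factor
  sub <- cells[cells$cell_type == cell_type, , drop = FALSE]
  if (!is.null(sub$phase))
    sub <- sub[sub$phase == "acute", , drop = FALSE]
  if (nrow(sub) == 0) {
    warning("no acute ", cell_type, " cells for patient ", patient_id,
            "; bias unassigned")
    return(data.frame(patient_id = patient_id, cell_type = cell_type,
                      n_a = 0L, n_c = 0L, biased = NA_integer_,
                      ac_ratio = NA_real_, n_cells = 0L,
                      stringsAsFactors = FALSE))
  }
  tp <- if (is.null(sub$timepoint)) rep("t0", nrow(sub)) else
    as.character(sub$timepoint)
  n_a_t <- tapply(sub$bias == "NKG2A_POS", tp, sum)
  n_c_t <- tapply(sub$bias == "NKG2C_POS", tp, sum)
  biased <- as.integer(any(n_a_t > factor_ * n_c_t))
  n_a <- sum(n_a_t); n_c <- sum(n_c_t)
  pc <- params$count_pseudocount
  data.frame(patient_id = patient_id, cell_type = cell_type,
             n_a = as.integer(n_a), n_c = as.integer(n_c), biased = biased,
             ac_ratio = (n_a + pc) / (n_c + pc), n_cells = nrow(sub),
             stringsAsFactors = FALSE)
}

#' Call patient bias for every patient in a cell table
#'
#' Vectorized driver over [call_patient_bias()]: one row per patient for the
#' requested cell type.
#'
#' @param cells data.frame with at least `patient_id`, `cell_type`, `bias`.
#' @inheritParams call_patient_bias
#' @return data.frame, one row per patient.
#' @export
call_cohort_bias <- function(cells, cell_type = c("NK", "CD8T"),
                             params = bias_params()) {
  cell_type <- match.arg(cell_type)
  factor_ <- if (cell_type == "NK") params$nk_ratio_factor else
    params$cd8_ratio_factor
  patients <- unique(cells$patient_id)
  sub <- cells[cells$cell_type == cell_type, , drop = FALSE]
  if (!is.null(sub$phase)) sub <- sub[sub$phase == "acute", , drop = FALSE]
  pid <- factor(sub$patient_id, levels = patients)
  tp <- if (is.null(sub$timepoint)) factor(rep("t0", nrow(sub))) else
    factor(sub$timepoint)
  n_a_pt <- tapply(sub$bias == "NKG2A_POS", list(pid, tp), sum)
  n_c_pt <- tapply(sub$bias == "NKG2C_POS", list(pid, tp), sum)
  biased_pt <- n_a_pt > factor_ * n_c_pt
  biased <- as.integer(apply(biased_pt, 1, function(r) any(r, na.rm = TRUE)))
  n_a <- rowSums(n_a_pt, na.rm = TRUE)
  n_c <- rowSums(n_c_pt, na.rm = TRUE)
  n_cells <- as.integer(table(pid))
  empty <- n_cells == 0
  if (any(empty)) {
    warning("no acute ", cell_type, " cells for patient(s): ",
            paste(patients[empty], collapse = ", "), "; bias unassigned")
    biased[empty] <- NA_integer_
  }
  pc <- params$count_pseudocount
  out <- data.frame(patient_id = patients, cell_type = cell_type,
                    n_a = as.integer(n_a), n_c = as.integer(n_c),
                    biased = biased,
                    ac_ratio = (n_a + pc) / (n_c + pc), n_cells = n_cells,
                    stringsAsFactors = FALSE)
  out$ac_ratio[empty] <- NA_real_
  rownames(out) <- NULL
  out
}

#' Classify spatial spots as NKG2A+/- CD8 T cell spots
#'
#' Nested marker rule on spot expression: T-cell-positive when the mean of
#' CD3D, CD3E and CD3G is above zero; within those, CD8-positive when the
#' mean of CD8A and CD8B is above zero; within CD8-positive spots, split on
#' NKG2A (KLRC1) expression into NKG2A_CD8T and NKG2A_NEG_CD8T. All other
#' spots are OTHER. Positivity is literal `> 0` because spatial counts are
#' sparse.
#'
#' @param expr `ExpressionMatrix` of nonnegative spot expression containing
#'   CD3D, CD3E, CD3G, CD8A, CD8B, KLRC1.
#' @param params [bias_params()] (unused thresholds kept for signature
#'   symmetry).
#' @return factor per spot with levels `NKG2A_CD8T`, `NKG2A_NEG_CD8T`,
#'   `OTHER`.
#' @export
call_spatial_cd8 <- function(expr, params = bias_params()) {
  if (any(expr$values < 0))
    stop("spatial calling requires nonnegative expression")
  t_score <- (.gene_values(expr, "CD3D") + .gene_values(expr, "CD3E") +
                .gene_values(expr, "CD3G")) / 3
  cd8_score <- (.gene_values(expr, "CD8A") + .gene_values(expr, "CD8B")) / 2
  nkg2a <- .gene_values(expr, "KLRC1")
  lab <- rep("OTHER", ncol(expr$values))
  cd8t <- t_score > 0 & cd8_score > 0
  lab[cd8t & nkg2a > 0] <- "NKG2A_CD8T"
  lab[cd8t & nkg2a <= 0] <- "NKG2A_NEG_CD8T"
  factor(stats::setNames(lab, colnames(expr$values)),
         levels = c("NKG2A_CD8T", "NKG2A_NEG_CD8T", "OTHER"))
}

#' Single-marker positive spots
#'
#' A spot is positive for the receptor when its expression is above zero —
#' the sparse-counts reading used for single-sample spatial slides.
#'
#' @param expr `ExpressionMatrix` of spot expression.
#' @param marker `"KLRC1"` or `"KLRC2"` (protein aliases accepted).
#' @return character vector of positive spot ids.
#' @export
call_spatial_single_marker <- function(expr, marker = c("KLRC1", "KLRC2")) {
  marker <- normalize_symbols(match.arg(normalize_symbols(marker),
                                        c("KLRC1", "KLRC2")))
  v <- .gene_values(expr, marker)
  colnames(expr$values)[v > 0]
}
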