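test_that("ln(CPM+1) threshold rule matches its stated examples", {
  m <- matrix(c(3.0, 2.6, 0.0,
                2.4, 5.0, 5.0,
                3.0, 2.6, 2.7,
                3.0, 0.0, 2.6), 3,
              dimnames = list(c("KLRD1", "KLRC1", "KLRC2"), paste0("c", 1:4)))
  labs <- call_cells_lncpm(expression_matrix(m, "ln_cpm1"))
  expect_equal(as.character(labs),
               c("NKG2A_POS", "UNASSIGNED", "DOUBLE_POS", "NKG2C_POS"))
  expect_error(call_cells_lncpm(rand_expr(5, normalization = "bulk_norm",
                                          gen = runif)),
               "ln_cpm1")
  expect_error(call_cells_lncpm(rand_expr(5, genes = c("KLRD1", "KLRC1"))),
               "KLRC2")
})

test_that("zscore margin rule matches its stated examples and is exclusive", {
  # build a unit-variance zero-mean gene vector whose first entries are the
  # example z-values exactly, padded with adjusted filler cells
  zvec <- function(v, n = 200, seed = 1) {
    set.seed(seed)
    m <- n - length(v)
    u <- rnorm(m); u0 <- u - mean(u)
    b <- -sum(v) / m
    a <- sqrt(((n - 1) - sum(v^2) - m * b^2) / sum(u0^2))
    c(v, a * u0 + b)
  }
  vals <- rbind(KLRC1 = zvec(c(1.2, 0.5, -1.5), seed = 1),
                KLRC2 = zvec(c(0.1, 0.1, 0.2), seed = 2))
  colnames(vals) <- paste0("c", seq_len(ncol(vals)))
  labs <- call_cells_zscore(expression_matrix(vals, "zscore"))
  expect_equal(as.character(labs[1:3]),
               c("NKG2A_POS", "UNASSIGNED", "NKG2C_POS"))
  # exclusivity: margins cannot both hold
  set.seed(4)
  vals <- matrix(rnorm(400), 2, 200)
  vals <- t(scale(t(vals)))
  dimnames(vals) <- list(c("KLRC1", "KLRC2"), paste0("c", 1:200))
  labs <- call_cells_zscore(expression_matrix(vals, "zscore"))
  expect_false(any(labs == "DOUBLE_POS"))
})

test_that("cell calls equal the direct per-cell rule loop on random input", {
  set.seed(11)
  for (rep in 1:5) {
    em <- rand_expr(500)
    expect_equal(as.character(call_cells_lncpm(em)), oracle_lncpm(em$values))
  }
  for (rep in 1:5) {
    vals <- matrix(rnorm(3 * 300), 3, 300)
    vals <- t(scale(t(vals)))
    dimnames(vals) <- list(c("KLRD1", "KLRC1", "KLRC2"), paste0("c", 1:300))
    em <- expression_matrix(vals, "zscore")
    expect_equal(as.character(call_cells_zscore(em)), oracle_zscore(vals))
  }
})

test_that("every observation receives exactly one label", {
  set.seed(12)
  em <- rand_expr(400)
  labs <- call_cells_lncpm(em)
  expect_equal(length(labs), 400)
  expect_false(anyNA(labs))
  expect_equal(sum(table(labs)), 400)
})

test_that("bulk score follows the CD94-product log2 fold change", {
  m <- matrix(c(2, 4, 1), 3,
              dimnames = list(c("KLRD1", "KLRC1", "KLRC2"), "s1"))
  s <- score_bulk(expression_matrix(m, "bulk_norm"),
                  bias_params(bulk_epsilon = 1e-300))
  expect_equal(unname(s), 2.0)  # log2(8) - log2(2)
  # symmetry: equal receptor levels give score 0
  m2 <- matrix(c(5, 3, 3), 3,
               dimnames = list(c("KLRD1", "KLRC1", "KLRC2"), "s1"))
  expect_equal(unname(score_bulk(expression_matrix(m2, "bulk_norm"))), 0)
  # brute-force recomputation on random samples
  set.seed(13)
  em <- rand_expr(100, normalization = "bulk_norm", gen = function(n) rexp(n))
  eps <- bias_params()$bulk_epsilon
  direct <- vapply(seq_len(100), function(j) {
    v <- em$values[, j]
    log2(v["KLRD1"] * v["KLRC1"] + eps) - log2(v["KLRD1"] * v["KLRC2"] + eps)
  }, numeric(1))
  expect_equal(unname(score_bulk(em)), unname(direct))
  neg <- em; neg$values[1, 1] <- -1
  expect_error(score_bulk(neg), "nonnegative")
})

test_that("pentile calls take floor(0.2 n) at each pole with stable ties", {
  set.seed(14)
  s <- rnorm(10)
  labs <- call_bulk_pentiles(s)
  expect_equal(sum(labs == "NKG2A_POS"), 2)
  expect_equal(sum(labs == "NKG2C_POS"), 2)
  expect_error(call_bulk_pentiles(rnorm(9)), "at least 10")
  # all-equal scores: first floor(0.2 n) by input order at each pole
  tied <- call_bulk_pentiles(rep(1, 10))
  expect_equal(which(tied == "NKG2A_POS"), 1:2)
  expect_equal(which(tied == "NKG2C_POS"), 3:4)
  # sort-based oracle on many random scores
  s <- rnorm(1000)
  expect_equal(as.character(call_bulk_pentiles(s)), oracle_pentile(s))
  # invariance under strictly monotone transform
  expect_equal(call_bulk_pentiles(exp(s)), call_bulk_pentiles(s))
  expect_equal(call_bulk_pentiles(rank(s)), call_bulk_pentiles(s))
})

test_that("patient rule applies strict count inequalities per cell type", {
  mk <- function(n_a, n_c, type) {
    data.frame(cell_type = type,
               bias = c(rep("NKG2A_POS", n_a), rep("NKG2C_POS", n_c)),
               stringsAsFactors = FALSE)
  }
  expect_equal(call_patient_bias(mk(10, 3, "NK"), "NK")$biased, 1L)
  expect_equal(call_patient_bias(mk(9, 3, "NK"), "NK")$biased, 0L)
  expect_equal(call_patient_bias(mk(5, 4, "CD8T"), "CD8T")$biased, 1L)
  expect_equal(call_patient_bias(mk(4, 4, "CD8T"), "CD8T")$biased, 0L)
  # pseudocount ratio
  expect_equal(call_patient_bias(mk(6, 2, "CD8T"), "CD8T")$ac_ratio, 7 / 3)
  # double-positive and unassigned cells enter neither count
  cells <- rbind(mk(5, 4, "CD8T"),
                 data.frame(cell_type = "CD8T",
                            bias = c("DOUBLE_POS", "UNASSIGNED")))
  res <- call_patient_bias(cells, "CD8T")
  expect_equal(c(res$n_a, res$n_c), c(5L, 4L))
  expect_equal(res$n_cells, 11L)
})

test_that("a patient is biased when any acute timepoint is biased", {
  cells <- data.frame(
    cell_type = "CD8T",
    timepoint = c(rep("T1", 5), rep("T2", 4)),
    phase = "acute",
    bias = c(rep("NKG2A_POS", 3), rep("NKG2C_POS", 2),   # T1 biased
             rep("NKG2C_POS", 4)),                        # T2 not
    stringsAsFactors = FALSE)
  expect_equal(call_patient_bias(cells, "CD8T")$biased, 1L)
  # post-acute cells are excluded from the call
  cells$phase <- c(rep("post_acute", 5), rep("acute", 4))
  expect_equal(call_patient_bias(cells, "CD8T")$biased, 0L)
  # zero cells of the requested type: warning + unassigned
  expect_warning(res <- call_patient_bias(cells, "NK", patient_id = "P1"),
                 "no acute NK")
  expect_true(is.na(res$biased))
})

test_that("patient bias is monotone in the cell counts", {
  set.seed(15)
  for (i in 1:50) {
    n_a <- rpois(1, 5); n_c <- rpois(1, 5)
    cells <- data.frame(cell_type = "NK",
                        bias = c(rep("NKG2A_POS", n_a),
                                 rep("NKG2C_POS", n_c)),
                        stringsAsFactors = FALSE)
    base <- suppressWarnings(call_patient_bias(cells, "NK")$biased)
    plus_a <- suppressWarnings(call_patient_bias(
      rbind(cells, data.frame(cell_type = "NK", bias = "NKG2A_POS")),
      "NK")$biased)
    plus_c <- suppressWarnings(call_patient_bias(
      rbind(cells, data.frame(cell_type = "NK", bias = "NKG2C_POS")),
      "NK")$biased)
    if (!is.na(base)) {
      if (base == 1) expect_equal(plus_a, 1L)   # adding A never flips 1 -> 0
      if (base == 0) expect_equal(plus_c, 0L)   # adding C never flips 0 -> 1
    }
  }
})

test_that("cohort driver agrees with the single-patient reference", {
  set.seed(16)
  cells <- data.frame(
    cell_id = paste0("c", 1:600),
    patient_id = sample(paste0("P", 1:20), 600, replace = TRUE),
    cell_type = sample(c("NK", "CD8T"), 600, replace = TRUE),
    timepoint = sample(c("T1", "T2"), 600, replace = TRUE),
    phase = sample(c("acute", "post_acute"), 600, replace = TRUE,
                   prob = c(0.8, 0.2)),
    bias = sample(c("NKG2A_POS", "NKG2C_POS", "DOUBLE_POS", "UNASSIGNED"),
                  600, replace = TRUE),
    stringsAsFactors = FALSE)
  for (ct in c("NK", "CD8T")) {
    fast <- suppressWarnings(call_cohort_bias(cells, ct))
    for (p in unique(cells$patient_id)) {
      ref <- suppressWarnings(
        call_patient_bias(cells[cells$patient_id == p, ], ct,
                          patient_id = p))
      row <- fast[fast$patient_id == p, ]
      expect_equal(row$biased, ref$biased)
      expect_equal(row$n_a, ref$n_a)
      expect_equal(row$n_c, ref$n_c)
      expect_equal(row$ac_ratio, ref$ac_ratio)
    }
  }
})

test_that("spatial CD8 classification follows the nested marker rule", {
  genes <- c("CD3D", "CD3E", "CD3G", "CD8A", "CD8B", "KLRC1")
  mk <- function(...) {
    v <- matrix(c(...), length(genes),
                dimnames = list(genes, paste0("s", seq_len(length(c(...)) /
                                                             length(genes)))))
    expression_matrix(v, "spatial_counts")
  }
  # T-positive but CD8-negative -> OTHER
  expect_equal(as.character(call_spatial_cd8(mk(1, 0, 0, 0, 0, 0))), "OTHER")
  # T+, CD8 mean 0.5, KLRC1 0.5 -> NKG2A+ CD8 T spot
  expect_equal(as.character(call_spatial_cd8(mk(1, 0, 0, 1, 0, 0.5))),
               "NKG2A_CD8T")
  expect_equal(as.character(call_spatial_cd8(mk(1, 1, 1, 1, 1, 0))),
               "NKG2A_NEG_CD8T")
  # random grid equals the nested-rule oracle
  set.seed(17)
  em <- rand_expr(300, genes = genes, normalization = "spatial_counts",
                  gen = function(n) rbinom(n, 2, 0.3))
  expect_equal(as.character(call_spatial_cd8(em)),
               oracle_spatial_cd8(em$values))
  expect_error(call_spatial_cd8(rand_expr(5, genes = genes[-6],
                                          normalization = "spatial_counts")),
               "KLRC1")
})

test_that("single-marker spot positivity is literal > 0", {
  genes <- c("KLRC1", "KLRC2")
  v <- matrix(c(0, 0.2, 0.01, 0, 0, 0), 2,
              dimnames = list(genes, c("s1", "s2", "s3")))
  em <- expression_matrix(v, "spatial_counts")
  expect_equal(call_spatial_single_marker(em, "KLRC1"), "s2")
  expect_equal(call_spatial_single_marker(em, "KLRC2"), "s1")
  expect_error(call_spatial_single_marker(
    expression_matrix(v[1, , drop = FALSE], "spatial_counts"), "KLRC2"),
    "KLRC2")
})
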