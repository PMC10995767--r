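test_that("intercept-only logit recovers the closed-form log odds", {
  y <- c(rep(1, 30), rep(0, 70))
  fit <- fit_logit(y)
  expect_equal(fit$coefficients$estimate[1], log(30 / 70),
               tolerance = 1e-7)
  # fitted probabilities average to the event rate (intercept present)
  set.seed(20)
  fit2 <- fit_logit(y, data.frame(x = rnorm(100)))
  expect_equal(mean(fit2$fitted), 0.3, tolerance = 1e-8)
})

test_that("logit rejects degenerate designs and separation", {
  y <- rep(c(0, 1), 25)
  expect_error(fit_logit(y, data.frame(x = rep(1, 50))), "constant")
  expect_error(fit_logit(c(y, 2), data.frame(x = rnorm(51))), "binary")
  # perfectly separating predictor
  x <- c(rnorm(25, -5), rnorm(25, 5))
  ys <- c(rep(0, 25), rep(1, 25))
  expect_error(fit_logit(ys, data.frame(x = x)), "separation")
  # aliased duplicate column
  z <- rnorm(50)
  expect_error(fit_logit(y, data.frame(a = z, b = z)), "rank-deficient")
})

test_that("logit recovers a planted bias effect through the full pipeline", {
  cfg <- sim_config(seed = 21, n_patients = 800, true_lnOR_bias = -1)
  co <- simulate_cohort(cfg)
  co$cells$bias <- as.character(call_cells_lncpm(co$expr))
  pb <- call_cohort_bias(co$cells, "CD8T")
  pat <- co$patients[match(pb$patient_id, co$patients$patient_id), ]
  fit <- fit_logit(pat$deceased,
                   data.frame(bias = pb$biased, sex = pat$sex_female,
                              age = pat$age_std))
  est <- fit$coefficients[fit$coefficients$term == "bias", ]
  expect_lt(abs(est$estimate - (-1)), 1.96 * est$se * 1.5)
  expect_true(est$ci_lo < est$estimate && est$estimate < est$ci_hi)
})

test_that("KM equals the empirical survival function without censoring", {
  res <- km_logrank(times = c(1:5, 1:5), events = rep(1, 10),
                    groups = rep(c("a", "b"), each = 5))
  a <- res$km[res$km$group == "a", ]
  expect_equal(a$surv, c(0.8, 0.6, 0.4, 0.2, 0))
  expect_equal(a$n_risk, 5:1)
})

test_that("log-rank detects a planted hazard ratio and rejects degenerates", {
  cfg <- sim_config(seed = 22, n_bulk = 500, bulk_hazard_ratio = 3)
  bk <- simulate_bulk(cfg)
  two <- bk$samples[bk$samples$pentile != "UNASSIGNED", ]
  res <- km_logrank(two$time, two$event, two$pentile)
  expect_lt(res$p, 0.001)
  expect_gt(res$median_survival["NKG2A_POS"],
            res$median_survival["NKG2C_POS"])
  expect_error(km_logrank(c(1, 2), c(1, 1), c("a", "a")), "two")
  expect_error(km_logrank(rep(1, 6), rep(0, 6), rep(c("a", "b"), 3)),
               "undefined")
  expect_error(km_logrank(c(-1, 2), c(1, 1), c("a", "b")), "negative")
})

test_that("hypergeometric overlap matches exact enumeration", {
  # universe 10, |A| = |B| = 5, full overlap: P = 1/C(10,5)
  u <- letters[1:10]
  res <- hypergeom_overlap(u[1:5], u[1:5], u)
  expect_equal(res$p_ge, 1 / choose(10, 5), tolerance = 1e-12)
  # zero overlap is never surprising
  res0 <- hypergeom_overlap(u[1:5], u[6:10], u)
  expect_equal(res0$p_ge, 1)
  expect_equal(res0$k, 0)
  # complement identity holds exactly
  expect_identical(res$p_ge + res$p_lt, 1)
  # literal 1 - CDF(k) variant excludes the observed value
  lit <- hypergeom_overlap(u[1:5], u[1:5], u, literal_one_minus_cdf = TRUE)
  expect_equal(lit$p_ge, 0)
  expect_error(hypergeom_overlap(c(u[1], "zz"), u[1:2], u), "zz")
})

test_that("p_ge is non-increasing in observed overlap for fixed margins", {
  u <- paste0("g", 1:40)
  p <- vapply(0:10, function(k) {
    A <- u[1:10]
    B <- c(u[seq_len(k)], u[11:(20 - k)])
    hypergeom_overlap(A, B, u)$p_ge
  }, numeric(1))
  expect_true(all(diff(p) <= 1e-12))
})

test_that("expressed-gene filters apply the context thresholds", {
  set.seed(23)
  em <- rand_expr(20, genes = paste0("g", 1:100))
  inf <- expressed_genes(em, "infection_top_fraction")
  expect_length(inf$symbols, 10)
  mu <- rowMeans(em$values)
  expect_setequal(inf$symbols, names(sort(mu, decreasing = TRUE))[1:10])
  # cancer context: strict mean threshold (0.005 below, 0.5 above)
  vals <- matrix(rep(c(rep(0.005, 4), rep(0.5, 6)), 2), 10, 2,
                 dimnames = list(paste0("g", 1:10), c("s1", "s2")))
  can <- expressed_genes(expression_matrix(vals, "bulk_norm"),
                         "cancer_min_mean")
  expect_setequal(can$symbols, paste0("g", 5:10))
  expect_warning(
    expressed_genes(expression_matrix(vals * 0 + 0.001, "bulk_norm"),
                    "cancer_min_mean"), "no genes")
})

test_that("antibody gene filter equals the prefix oracle", {
  expect_setequal(antibody_genes(c("IGHG1", "IGKC", "IGLV1-40", "CD8A"))$symbols,
                  c("IGHG1", "IGKC", "IGLV1-40"))
  expect_length(antibody_genes(character(0))$symbols, 0)
  set.seed(24)
  syms <- paste0(sample(c("IGH", "IGK", "IGL", "CD", "KLR", "TRBV"),
                        1000, replace = TRUE),
                 sample(LETTERS, 1000, replace = TRUE))
  got <- antibody_genes(syms)$symbols
  want <- unique(syms[substr(syms, 1, 3) %in% c("IGH", "IGK", "IGL")])
  expect_setequal(got, want)
})

test_that("Mann-Whitney U follows the stated conventions", {
  x <- c(1, 2, 3, 4)
  expect_equal(mwu(x, x)$U, length(x)^2 / 2)   # identical samples
  # exact small-sample p equals full enumeration: complete separation
  res <- mwu(11:20, 1:10)
  expect_equal(res$p, 2 / choose(20, 10), tolerance = 1e-12)
  expect_error(mwu(numeric(0), 1:3), "empty")
})

test_that("correlations match the standard contracts", {
  set.seed(25)
  x <- rnorm(30)
  expect_equal(correlate(x, exp(x), "spearman")$r, 1.0)   # monotone
  expect_equal(correlate(x, 2 * x + 1, "pearson")$r, 1.0)
  expect_error(correlate(x, rep(1, 30)), "constant")
  # spearman is pearson on average ranks
  y <- rnorm(30)
  expect_equal(correlate(x, y, "spearman")$r,
               cor(rank(x), rank(y)))
})

test_that("differential features require both significance and direction", {
  set.seed(26)
  a <- matrix(rnorm(10 * 10, 5), 10, dimnames = list(paste0("f", 1:10)))
  b <- matrix(rnorm(10 * 10, 5), 10, dimnames = list(paste0("f", 1:10)))
  # plant one fully separated upregulated feature and one downregulated
  a["f1", ] <- 10 + runif(10); b["f1", ] <- runif(10)
  a["f2", ] <- runif(10); b["f2", ] <- 10 + runif(10)
  res <- differential_features(a, b)
  expect_true(res$selected[res$feature == "f1"])
  expect_equal(res$p[res$feature == "f1"], 2 / choose(20, 10),
               tolerance = 1e-12)
  # significant but wrong direction is excluded
  f2 <- res[res$feature == "f2", ]
  expect_lt(f2$p, 0.05)
  expect_false(f2$selected)
  expect_error(differential_features(a, b[1:5, ]), "match")
})

test_that("multi-timepoint compilation keeps features passing everywhere", {
  set.seed(27)
  mk <- function(planted) {
    a <- matrix(rnorm(5 * 12, 5), 5, dimnames = list(paste0("f", 1:5)))
    b <- matrix(rnorm(5 * 12, 5), 5, dimnames = list(paste0("f", 1:5)))
    for (f in planted) a[f, ] <- a[f, ] + 8
    list(a = a, b = b)
  }
  pairs <- list(mk(c("f1", "f2")), mk(c("f1", "f3")), mk("f1"))
  expect_equal(differential_features_all_timepoints(pairs), "f1")
})
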