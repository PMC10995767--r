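#' Covariate-adjusted log-odds model
#'
#' Maximum-likelihood logistic regression of a binary patient outcome on an
#' immune-bias indicator plus clinical covariates, reported as ln(odds
#' ratio) with Wald 95% confidence intervals — the quantities drawn on a
#' forest plot. Conventions: female sex is coded 1, age enters in years,
#' and severe disease is the WHO Ordinal Scale binarized at >= 5 (use
#' [severe_wos()]).
#'
#' @param outcome binary 0/1 vector.
#' @param predictors data.frame of numeric predictors (one column per
#'   covariate); an intercept is always added. NULL fits the
#'   intercept-only model.
#' @return list of class `LogitResult`: `coefficients` data.frame with
#'   `term`, `estimate` (ln OR), `se`, `ci_lo`, `ci_hi`, `p`; plus `n`,
#'   `converged`, `null_deviance`, `deviance`.
#' @export
fit_logit <- function(outcome, predictors = NULL) {
  if (!all(outcome %in% c(0, 1)))
    stop("outcome must be binary 0/1")
  if (is.null(predictors))
    predictors <- data.frame(row.names = seq_along(outcome))
  predictors <- as.data.frame(predictors)
  if (nrow(predictors) != length(outcome))
    stop("outcome and predictors disagree on n")
  const <- vapply(predictors, function(v) stats::var(v) == 0, logical(1))
  if (any(const))
    stop("rank-deficient design: constant predictor(s): ",
         paste(names(predictors)[const], collapse = ", "))
  dat <- cbind(.y = outcome, predictors)
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    stats::glm(.y ~ ., data = dat, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep_warn <<- TRUE
      invokeRestart("muffleWarning")
    })
  co <- stats::coef(fit)
  if (anyNA(co))
    stop("rank-deficient design: aliased term(s): ",
         paste(names(co)[is.na(co)], collapse = ", "))
  if (sep_warn)
    stop("perfect separation detected (diverging coefficients); ",
         "consider a penalized fit")
  sm <- summary(fit)$coefficients
  res <- data.frame(term = rownames(sm),
                    estimate = sm[, 1], se = sm[, 2],
                    ci_lo = sm[, 1] - 1.96 * sm[, 2],
                    ci_hi = sm[, 1] + 1.96 * sm[, 2],
                    p = sm[, 4],
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(coefficients = res, n = length(outcome),
                 converged = fit$converged,
                 null_deviance = fit$null.deviance,
                 deviance = fit$deviance,
                 fitted = stats::fitted(fit)),
            class = "LogitResult")
}

#' @export
print.LogitResult <- function(x, ...) {
  cat(sprintf("Logit model (n = %d, converged = %s)\n", x$n, x$converged))
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Binarize WHO Ordinal Scale severity
#'
#' Severe disease is WOS greater than or equal to 5.
#'
#' @param wos integer vector of WHO Ordinal Scale values (0-8).
#' @return integer 0/1 vector.
#' @export
severe_wos <- function(wos) as.integer(wos >= 5)

#' Kaplan-Meier curves and log-rank test
#'
#' Product-limit survival estimate per group and the log-rank chi-square
#' test across groups (hypergeometric variance, chi-square with
#' groups - 1 degrees of freedom). Used to compare survival of bulk
#' samples in the top versus bottom pentile of the NKG2A:NKG2C bias score.
#'
#' @param times nonnegative follow-up times.
#' @param events event indicator, 1 = death observed, 0 = censored.
#' @param groups group labels (two or more non-empty groups).
#' @return list of class `SurvivalResult`: `km` data.frame (`group`,
#'   `time`, `n_risk`, `n_event`, `surv`), `chisq`, `df`, `p`,
#'   `median_survival` per group.
#' @export
km_logrank <- function(times, events, groups) {
  if (any(times < 0)) stop("negative survival times")
  if (!all(events %in% c(0, 1))) stop("events must be binary 0/1")
  groups <- factor(groups)
  groups <- droplevels(groups)
  if (nlevels(groups) < 2)
    stop("log-rank requires at least two non-empty groups")
  if (sum(events) == 0)
    stop("no observed events; survival is 1 throughout and the ",
         "log-rank test is undefined")
  sf <- survival::survfit(survival::Surv(times, events) ~ groups)
  strata <- rep(names(sf$strata), sf$strata)
  km <- data.frame(group = sub("^groups=", "", strata),
                   time = sf$time, n_risk = sf$n.risk,
                   n_event = sf$n.event, surv = sf$surv,
                   stringsAsFactors = FALSE)
  sd_ <- survival::survdiff(survival::Surv(times, events) ~ groups)
  df <- nlevels(groups) - 1
  med <- summary(sf)$table[, "median"]
  names(med) <- sub("^groups=", "", names(med))
  structure(list(km = km, chisq = unname(sd_$chisq), df = df,
                 p = stats::pchisq(sd_$chisq, df, lower.tail = FALSE),
                 median_survival = med),
            class = "SurvivalResult")
}

#' @export
print.SurvivalResult <- function(x, ...) {
  cat(sprintf("Log-rank chi-square = %.3f (df = %d), p = %.3g\n",
              x$chisq, x$df, x$p))
  invisible(x)
}

#' Hypergeometric set-overlap test
#'
#' Tests whether two gene sets drawn from a common universe overlap as much
#' as observed or more. With `k` the observed intersection size and
#' `X ~ Hypergeometric(|universe|, |A|, |B|)`, the enrichment p-value is
#' `p_ge = P(X >= k)` (the survival function at `k - 1`) and the depletion
#' probability is its exact complement `p_lt = P(X < k) = 1 - p_ge`. A
#' literal "1 - CDF at k" variant (`P(X > k)`, which excludes the observed
#' value) is exposed for audit.
#'
#' @param setA,setB character vectors (or `GeneSet`s) of symbols.
#' @param universe character vector containing both sets.
#' @param literal_one_minus_cdf if TRUE report `P(X > k)` instead of
#'   `P(X >= k)`.
#' @return list of class `OverlapResult`: `k`, `n_a`, `n_b`, `n_universe`,
#'   `p_ge`, `p_lt`.
#' @export
hypergeom_overlap <- function(setA, setB, universe,
                              literal_one_minus_cdf = FALSE) {
  if (inherits(setA, "GeneSet")) setA <- setA$symbols
  if (inherits(setB, "GeneSet")) setB <- setB$symbols
  setA <- unique(setA); setB <- unique(setB); universe <- unique(universe)
  strays <- c(setdiff(setA, universe), setdiff(setB, universe))
  if (length(strays))
    stop("set member(s) outside the universe: ",
         paste(unique(strays), collapse = ", "))
  k <- length(intersect(setA, setB))
  N <- length(universe); m <- length(setA); n <- length(setB)
  q <- if (literal_one_minus_cdf) k else k - 1
  p_ge <- stats::phyper(q, m, N - m, n, lower.tail = FALSE)
  structure(list(k = k, n_a = m, n_b = n, n_universe = N,
                 p_ge = p_ge, p_lt = 1 - p_ge,
                 literal = literal_one_minus_cdf),
            class = "OverlapResult")
}

#' Expressed-gene filter
#'
#' Confidently expressed genes for set-overlap analyses: in infection
#' contexts the top 10% of genes by mean expression; in the cancer context
#' genes with mean expression above 0.01.
#'
#' @param expr `ExpressionMatrix`.
#' @param context `"infection_top_fraction"` or `"cancer_min_mean"`.
#' @param params [bias_params()].
#' @return a `GeneSet` named after the context.
#' @export
expressed_genes <- function(expr,
                            context = c("infection_top_fraction",
                                        "cancer_min_mean"),
                            params = bias_params()) {
  context <- match.arg(context)
  mu <- rowMeans(expr$values)
  genes <- if (context == "infection_top_fraction") {
    k <- max(1L, floor(params$expressed_top_fraction * length(mu)))
    rownames(expr$values)[order(-mu)[seq_len(k)]]
  } else {
    rownames(expr$values)[mu > params$expressed_min_mean]
  }
  if (length(genes) == 0) {
    warning("expressed-gene filter returned no genes")
    return(structure(list(name = context, symbols = character(0)),
                     class = "GeneSet"))
  }
  gene_set(context, genes)
}

#' Antibody gene set from candidate symbols
#'
#' Retains immunoglobulin heavy-chain genes and kappa/lambda light-chain
#' genes: symbols with prefix IGH, IGK or IGL.
#'
#' @param symbols character vector of candidate gene symbols.
#' @return a `GeneSet` (possibly empty `symbols`).
#' @export
antibody_genes <- function(symbols) {
  keep <- unique(symbols[grepl("^(IGH|IGK|IGL)", symbols)])
  structure(list(name = "antibody", symbols = keep), class = "GeneSet")
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test. For combined sample size at most 20 (and no
#' ties) the exact null enumeration is used; otherwise the normal
#' approximation with tie correction and continuity correction.
#'
#' @param x,y numeric samples.
#' @return list with `U` (the statistic for `x`, average ranks for ties)
#'   and `p`.
#' @export
mwu <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) stop("empty sample")
  exact <- (length(x) + length(y)) <= 20
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = !exact))
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Correlation with test
#'
#' Pearson or Spearman correlation; Spearman is Pearson on average ranks,
#' suited to rank-based quantities like tumor immunogenicity orderings.
#'
#' @param x,y numeric vectors.
#' @param method `"pearson"` or `"spearman"`.
#' @return list with `r` and `p`.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for a constant vector")
  ct <- suppressWarnings(stats::cor.test(x, y, method = method))
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Differential feature selection
#'
#' Per feature, compares group A against group B by two-sided Mann-Whitney
#' U test and the log2 fold change of group means (pseudocount 1e-9). A
#' feature is retained as upregulated in A when p < alpha and the log2 fold
#' change is strictly positive. No multiple-testing correction is applied
#' by default, matching raw-p reporting; Benjamini-Hochberg is available.
#'
#' @param mat_a,mat_b numeric matrices, features in rows (shared rownames),
#'   observations in columns.
#' @param alpha significance level (default 0.05).
#' @param adjust if TRUE, apply Benjamini-Hochberg to the p-values before
#'   thresholding.
#' @return data.frame per feature: `feature`, `p`, `log2fc`, `selected`.
#' @export
differential_features <- function(mat_a, mat_b, alpha = 0.05,
                                  adjust = FALSE) {
  if (!identical(rownames(mat_a), rownames(mat_b)))
    stop("feature sets of the two groups must match")
  eps <- 1e-9
  p <- vapply(seq_len(nrow(mat_a)), function(i)
    mwu(mat_a[i, ], mat_b[i, ])$p, numeric(1))
  lfc <- log2((rowMeans(mat_a) + eps) / (rowMeans(mat_b) + eps))
  p_use <- if (adjust) stats::p.adjust(p, "BH") else p
  data.frame(feature = rownames(mat_a), p = p, log2fc = lfc,
             selected = p_use < alpha & lfc > 0,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Features upregulated at every timepoint
#'
#' Compiles the differential features detected at each of several
#' timepoints and keeps those passing at all of them — the rule used to
#' nominate persistently elevated plasma proteins.
#'
#' @param pairs list of `list(a = matrix, b = matrix)` per timepoint.
#' @param alpha significance level.
#' @return character vector of features selected at every timepoint.
#' @export
differential_features_all_timepoints <- function(pairs, alpha = 0.05) {
  sel <- lapply(pairs, function(pr) {
    df <- differential_features(pr$a, pr$b, alpha)
    df$feature[df$selected]
  })
  Reduce(intersect, sel)
}
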