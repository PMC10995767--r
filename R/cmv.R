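#' Extract CMV classifier features from a repertoire
#'
#' The two features of the published serostatus classifier: the number of
#' reference CMV-associated TCR-beta chains detected in the repertoire
#' (exact match on the CDR3 amino-acid sequence / V gene / J gene triple)
#' and the total number of unique TCR-betas in the repertoire.
#'
#' @param rep a [repertoire()].
#' @param ref data.frame of reference chains (`cdr3_aa`, `v_gene`,
#'   `j_gene`) or a `Repertoire`.
#' @return list with `n_matched` and `n_unique`.
#' @export
extract_features <- function(rep, ref) {
  if (inherits(ref, "Repertoire")) ref <- ref$chains
  if (nrow(rep$chains) == 0) stop("empty repertoire: ", rep$sample_id)
  ref_key <- unique(.chain_key(ref))
  n_matched <- sum(.chain_key(rep$chains) %in% ref_key)
  list(n_matched = n_matched, n_unique = nrow(rep$chains))
}

#' Feature table for a list of repertoires
#'
#' @param reps list of `Repertoire` objects.
#' @param ref reference chain table as in [extract_features()].
#' @return data.frame with `sample_id`, `patient_id`, `n_matched`,
#'   `n_unique`.
#' @export
extract_feature_table <- function(reps, ref) {
  rows <- lapply(reps, function(r) {
    f <- extract_features(r, ref)
    data.frame(sample_id = r$sample_id, patient_id = r$patient_id,
               n_matched = f$n_matched, n_unique = f$n_unique,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

# Stratified fold assignment: labels split separately, folds seeded.
.stratified_folds <- function(labels, k, seed) {
  folds <- integer(length(labels))
  set.seed(seed)
  for (cls in unique(labels)) {
    i <- which(labels == cls)
    folds[i] <- sample(rep_len(seq_len(k), length(i)))
  }
  folds
}

#' Train the CMV serostatus classifier
#'
#' Maximum-margin linear classifier (linear-kernel support vector machine)
#' on the two standardized repertoire features, with the regularization
#' cost chosen by stratified 6-fold cross-validation maximizing mean
#' held-out AUROC. Standardization matters: the unique-chain count is
#' orders of magnitude larger than the matched-chain count.
#'
#' @param features data.frame or matrix with columns `n_matched`,
#'   `n_unique`.
#' @param labels binary vector (1 = CMV positive).
#' @param costs candidate SVM costs searched by cross-validation.
#' @param n_folds number of CV folds (default 6).
#' @param seed seed for the stratified fold assignment.
#' @return list of class `CMVModel`: the fitted `svm`, `cost`,
#'   `cv_auroc` (mean held-out AUROC per candidate cost), `fold_auroc`
#'   for the chosen cost, and the feature scaling.
#' @export
cmv_train <- function(features, labels, costs = 10^(-2:2), n_folds = 6,
                      seed = 1L) {
  feats <- as.data.frame(features)[, c("n_matched", "n_unique")]
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2)
    stop("training requires both CMV classes")
  if (length(labels) < 2 * n_folds)
    stop("need at least ", 2 * n_folds, " labeled subjects")
  folds <- .stratified_folds(labels, n_folds, seed)
  cv_auroc <- vapply(costs, function(cost) {
    aucs <- vapply(seq_len(n_folds), function(f) {
      tr <- folds != f; te <- !tr
      if (length(unique(labels[te])) < 2) return(NA_real_)
      fit <- e1071::svm(x = as.matrix(feats[tr, ]),
                        y = factor(labels[tr], levels = c(0, 1)),
                        kernel = "linear", cost = cost, scale = TRUE)
      sc <- .svm_scores(fit, as.matrix(feats[te, ]))
      auroc(labels[te], sc)
    }, numeric(1))
    mean(aucs, na.rm = TRUE)
  }, numeric(1))
  best <- costs[which.max(cv_auroc)]
  fit <- e1071::svm(x = as.matrix(feats), y = factor(labels, levels = c(0, 1)),
                    kernel = "linear", cost = best, scale = TRUE)
  fold_auroc <- vapply(seq_len(n_folds), function(f) {
    tr <- folds != f; te <- !tr
    if (length(unique(labels[te])) < 2) return(NA_real_)
    m <- e1071::svm(x = as.matrix(feats[tr, ]),
                    y = factor(labels[tr], levels = c(0, 1)),
                    kernel = "linear", cost = best, scale = TRUE)
    auroc(labels[te], .svm_scores(m, as.matrix(feats[te, ])))
  }, numeric(1))
  structure(list(fit = fit, cost = best,
                 cv_auroc = stats::setNames(cv_auroc, costs),
                 fold_auroc = fold_auroc, n = length(labels)),
            class = "CMVModel")
}

# Decision scores oriented so that larger means more likely CMV positive.
# libsvm orients decision values by the first training label; flip so
# positive scores mean class "1".
.svm_scores <- function(fit, x) {
  dv <- attr(stats::predict(fit, x, decision.values = TRUE),
             "decision.values")
  if (colnames(dv)[1] == "0/1") -dv[, 1] else dv[, 1]
}

#' @export
print.CMVModel <- function(x, ...) {
  cat(sprintf(
    "CMV serostatus classifier: linear SVM, cost = %g, mean CV AUROC = %.3f\n",
    x$cost, mean(x$fold_auroc, na.rm = TRUE)))
  invisible(x)
}

#' Predict CMV serostatus
#'
#' Per-sample label from the sign of the decision score; a patient is
#' labeled CMV positive when any of their samples is predicted positive.
#'
#' @param model a `CMVModel`.
#' @param features data.frame with `n_matched`, `n_unique` and
#'   `sample_id`; `patient_id` optional (defaults to sample ids).
#' @return list with `samples` (data.frame `sample_id`, `score`,
#'   `predicted`) and `patients` (data.frame `patient_id`, `cmv_positive`).
#' @export
cmv_predict <- function(model, features) {
  feats <- as.data.frame(features)
  x <- as.matrix(feats[, c("n_matched", "n_unique")])
  score <- .svm_scores(model$fit, x)
  pred <- as.integer(score > 0)
  pid <- if (is.null(feats$patient_id)) feats$sample_id else feats$patient_id
  if (anyNA(pid)) stop("unknown patient id for sample(s): ",
                       paste(feats$sample_id[is.na(pid)], collapse = ", "))
  pat <- tapply(pred, pid, function(v) as.integer(any(v == 1)))
  list(samples = data.frame(sample_id = feats$sample_id, score = score,
                            predicted = pred, stringsAsFactors = FALSE),
       patients = data.frame(patient_id = names(pat),
                             cmv_positive = as.integer(pat),
                             row.names = NULL, stringsAsFactors = FALSE))
}

#' Area under the ROC curve
#'
#' Computed through the Mann-Whitney identity: the rank-sum of the positive
#' class scores, with average ranks for ties, normalized by
#' `n_pos * n_neg`. Equals the probability a random positive outscores a
#' random negative, counting ties as one half.
#'
#' @param labels binary vector (1 = positive class).
#' @param scores numeric decision scores.
#' @return AUROC in [0, 1].
#' @export
auroc <- function(labels, scores) {
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0)
    stop("AUROC requires both classes")
  r <- rank(scores)                          # average ranks for ties
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Generate a synthetic CMV reference chain list
#'
#' A stand-in for the published list of 164 CMV-associated TCR-beta chains
#' (which is not redistributed here): unique random triples drawn from the
#' same alphabet as the repertoire simulator.
#'
#' @param n number of chains (default 164, the published list size).
#' @param seed integer seed.
#' @return data.frame with `cdr3_aa`, `v_gene`, `j_gene`.
#' @export
synthetic_cmv_reference <- function(n = 164, seed = 1L) {
  set.seed(seed)
  .random_chains(n)
}

# Unique random TCR-beta triples. CDR3s are C...F amino-acid strings of
# length 10-16; V/J genes drawn from plausible TRBV/TRBJ symbols.
.random_chains <- function(n) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  v_genes <- paste0("TRBV", c(2, 4, 5, 6, 7, 9, 10, 11, 12, 15, 19, 20, 27,
                              28, 29, 30))
  j_genes <- paste0("TRBJ", c("1-1", "1-2", "1-3", "1-4", "1-5", "1-6",
                              "2-1", "2-2", "2-3", "2-5", "2-7"))
  out <- NULL
  while (is.null(out) || nrow(out) < n) {
    m <- n - if (is.null(out)) 0 else nrow(out)
    maxlen <- 12L  # variable part of the CDR3 (total length 10-16)
    chars <- matrix(sample(aa, m * maxlen, replace = TRUE), m, maxlen)
    body <- do.call(paste0, as.data.frame(chars, stringsAsFactors = FALSE))
    lens <- sample(6:12, m, replace = TRUE)
    cdr3 <- paste0("CAS", substr(body, 1, lens), "F")
    new <- data.frame(cdr3_aa = cdr3,
                      v_gene = sample(v_genes, m, replace = TRUE),
                      j_gene = sample(j_genes, m, replace = TRUE),
                      stringsAsFactors = FALSE)
    out <- rbind(out, new)
    out <- out[!duplicated(.chain_key(out)), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}
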