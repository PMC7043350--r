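#' Deterministic train/test split
#'
#' @param samples character vector of sample ids.
#' @param fraction training fraction (default 0.8).
#' @param seed integer seed.
#' @param stratify optional vector (same length) of class labels; the split
#'   then preserves the class mix within +/- 1 sample per class.
#' @return list with `train` and `test` id vectors (disjoint, exhaustive).
#' @export
split_train_test <- function(samples, fraction = 0.8, seed = 1L,
                             stratify = NULL) {
  stopifnot(fraction > 0, fraction < 1)
  n <- length(samples)
  if (n < 10L) fu_stop("need at least 10 samples to split")
  if (is.null(stratify)) {
    train <- with_seed(seed, sample(samples, ceiling(fraction * n)))
  } else {
    stopifnot(length(stratify) == n)
    idx <- with_seed(seed, {
      unlist(lapply(split(seq_len(n), stratify), function(i)
        sample(i, round(fraction * length(i)))), use.names = FALSE)
    })
    train <- samples[idx]
  }
  test <- setdiff(samples, train)
  if (!length(test) || !length(train)) fu_stop("degenerate split")
  if (!is.null(stratify)) {
    tr_cls <- unique(stratify[samples %in% train])
    te_cls <- unique(stratify[samples %in% test])
    if (!setequal(tr_cls, te_cls))
      fu_stop("a class is absent from one side of the stratified split")
  }
  list(train = train, test = test)
}

#' Cross-validated penalty selection (lambda.min)
#'
#' K-fold cross-validation over a shared descending lambda path; returns the
#' lambda minimizing mean deviance (logistic) or mean squared error
#' (linear). Folds are seeded and, for the logistic family, stratified by
#' outcome so no fold loses a class.
#'
#' @inheritParams fit_lasso
#' @param K number of folds (default 10).
#' @param seed integer seed for fold assignment.
#' @return the selected `lambda.min` (scalar).
#' @export
cv_lambda <- function(x, y, covars = NULL, family = c("linear", "logistic"),
                      K = 10, seed = 1L, alpha = 1, standardize = TRUE) {
  family <- match.arg(family)
  y <- as.numeric(y)
  n <- length(y)
  stopifnot(K >= 2, n >= 2 * K || K == n)
  d <- build_design(x, covars)
  foldid <- with_seed(seed, {
    if (family == "logistic") {
      f <- integer(n)
      for (cls in unique(y)) {
        i <- which(y == cls)
        f[i] <- sample(rep_len(seq_len(K), length(i)))
      }
      f
    } else {
      sample(rep_len(seq_len(K), n))
    }
  })
  if (family == "logistic" &&
      any(tapply(y, foldid, function(z) length(unique(z))) < 2L) && K < n)
    fu_warn("a CV fold contains a single outcome class")
  cv <- glmnet::cv.glmnet(d$X, y, family = glmnet_family(family),
                          alpha = alpha, penalty.factor = d$pf,
                          standardize = standardize, foldid = foldid,
                          type.measure = if (family == "linear") "mse" else "deviance")
  cv$lambda.min
}

#' Area under the ROC curve (Mann-Whitney estimator)
#'
#' `P(score_case > score_control) + 0.5 * P(tie)`, computed from average
#' ranks. Invariant under strictly monotone score transforms.
#'
#' @param scores numeric prediction scores.
#' @param labels binary 0/1 labels.
#' @return AUC in `[0, 1]`.
#' @export
#' @examples
#' auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))  # 0.75
auc <- function(scores, labels) {
  labels <- as.numeric(labels)
  if (!all(labels %in% c(0, 1))) fu_stop("labels must be binary 0/1")
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) fu_stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Compare set-based and single-SNP predictors by test-set AUC
#'
#' The predictive-accuracy protocol: one stratified 80/20 split fixed before
#' any fitting; per FU, a LASSO on the FU's SNP dosages plus covariates with
#' lambda tuned by K-fold CV on the training set (`lambda.min`), scored on
#' the test set by linear predictor; per GWAS hit SNP, a covariate-adjusted
#' logistic/linear model on the training set, scored on the test set. SNPs
#' that are both dSNPs and hits get a paired AUC comparison.
#'
#' @param genotypes a [genotype_matrix()].
#' @param phenotypes a [phenotype_table()] (logistic family for AUC).
#' @param fu_sets a [build_fu_sets()] result or named list of sets.
#' @param gwas_hits character vector of hit variant ids for the univariate
#'   arm.
#' @param covariates covariate columns (see [covariate_matrix()]).
#' @param fraction training fraction (default 0.8).
#' @param K CV folds for lambda tuning.
#' @param seed integer seed (split, folds).
#' @param catalog optional `fuwas` catalog used to pair dSNPs with hits.
#' @return list of class `auc_comparison`: `fu_auc` (per-FU AUC table),
#'   `snp_auc` (per-hit table), `paired` (dSNP-and-hit table), `split`.
#' @export
predictive_comparison <- function(genotypes, phenotypes, fu_sets, gwas_hits,
                                  covariates = NULL, fraction = 0.8, K = 10,
                                  seed = 1L, catalog = NULL) {
  sets <- if (inherits(fu_sets, "fu_sets")) fu_sets$sets else fu_sets
  al <- align_samples(genotypes, phenotypes)
  dosage <- impute_dosage(al$genotypes$dosage)
  ph <- al$phenotypes
  family <- attr(ph, "family")
  if (family != "logistic") fu_stop("AUC comparison needs a binary outcome")
  y <- as.numeric(ph[[attr(ph, "outcome")]])
  covars <- covariate_matrix(ph, covariates)
  ids <- sample_ids(al$genotypes)
  sp <- split_train_test(ids, fraction, seed, stratify = y)
  tr <- match(sp$train, ids); te <- match(sp$test, ids)
  seeds <- child_seeds(seed, length(sets) + 1L)
  covars_or_null <- function(i) if (ncol(covars)) covars[i, , drop = FALSE] else NULL

  fu_rows <- lapply(seq_along(sets), function(k) {
    fu <- names(sets)[k]
    vids <- intersect(sets[[fu]], colnames(dosage))
    if (!length(vids)) return(NULL)
    xtr <- dosage[tr, vids, drop = FALSE]
    lam <- tryCatch(cv_lambda(xtr, y[tr], covars_or_null(tr), "logistic",
                              K = K, seed = seeds[k]),
                    error = function(e) NA_real_)
    if (is.na(lam)) return(NULL)
    fit <- fit_lasso(xtr, y[tr], covars_or_null(tr), "logistic", lambda = lam)
    nz <- sum(fit$beta[fit$penalized] != 0)
    cols <- names(fit$beta)
    Xte <- cbind(if (ncol(covars)) covars[te, , drop = FALSE],
                 dosage[te, vids, drop = FALSE])[, cols, drop = FALSE]
    scores <- fit$intercept + as.numeric(Xte %*% fit$beta)
    data.frame(model_id = fu, auc = auc(scores, y[te]), n_test = length(te),
               lambda = lam, n_selected = nz,
               covariate_only = nz == 0L, stringsAsFactors = FALSE)
  })
  fu_auc <- do.call(rbind, Filter(Negate(is.null), fu_rows))

  snp_rows <- lapply(intersect(gwas_hits, colnames(dosage)), function(v) {
    df_tr <- data.frame(y = y[tr], snp = dosage[tr, v])
    if (ncol(covars)) df_tr <- cbind(df_tr, as.data.frame(covars[tr, , drop = FALSE]))
    fit <- tryCatch(suppressWarnings(glm(y ~ ., data = df_tr, family = binomial())),
                    error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    df_te <- data.frame(snp = dosage[te, v])
    if (ncol(covars)) df_te <- cbind(df_te, as.data.frame(covars[te, , drop = FALSE]))
    scores <- predict(fit, newdata = df_te, type = "link")
    data.frame(model_id = v, auc = auc(scores, y[te]), n_test = length(te),
               stringsAsFactors = FALSE)
  })
  snp_auc <- do.call(rbind, Filter(Negate(is.null), snp_rows))

  paired <- NULL
  if (!is.null(catalog) && !is.null(fu_auc) && !is.null(snp_auc)) {
    both <- intersect(unique(catalog$variant_id), snp_auc$model_id)
    paired <- do.call(rbind, lapply(both, function(v) {
      fus <- catalog$fu_id[catalog$variant_id == v]
      fa <- fu_auc$auc[fu_auc$model_id %in% fus]
      if (!length(fa)) return(NULL)
      sa <- snp_auc$auc[snp_auc$model_id == v]
      data.frame(variant_id = v, best_fu_auc = max(fa), snp_auc = sa,
                 winner = if (max(fa) >= sa) "fu_model" else "single_snp",
                 stringsAsFactors = FALSE)
    }))
  }
  structure(list(fu_auc = fu_auc, snp_auc = snp_auc, paired = paired,
                 split = sp, seed = seed),
            class = "auc_comparison")
}

#' @export
print.auc_comparison <- function(x, ...) {
  if (!is.null(x$fu_auc))
    cat(sprintf("FU models: %d, AUC range %.3f-%.3f\n", nrow(x$fu_auc),
                min(x$fu_auc$auc), max(x$fu_auc$auc)))
  if (!is.null(x$snp_auc))
    cat(sprintf("single-SNP models: %d, AUC range %.3f-%.3f\n",
                nrow(x$snp_auc), min(x$snp_auc$auc), max(x$snp_auc$auc)))
  if (!is.null(x$paired))
    cat(sprintf("paired comparisons: %d (FU model wins %d)\n",
                nrow(x$paired), sum(x$paired$winner == "fu_model")))
  invisible(x)
}
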