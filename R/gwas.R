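#' Univariate SNP association with covariate adjustment
#'
#' Classical per-SNP test: maximum-likelihood fit of
#' `y ~ intercept + covars + dosage` with a two-sided Wald test on the
#' dosage term.
#'
#' @param x dosage vector for one SNP.
#' @param y outcome vector.
#' @param covars optional covariate matrix.
#' @param family `"linear"` or `"logistic"`.
#' @return one-row data frame: `beta`, `se`, `p`, `n`, `converged`. A
#'   non-converged logistic fit yields `NA` statistics with
#'   `converged = FALSE` rather than an error.
#' @export
univariate_assoc <- function(x, y, covars = NULL,
                             family = c("linear", "logistic")) {
  family <- match.arg(family)
  x <- as.numeric(x)
  if (sd(x, na.rm = TRUE) == 0 || all(is.na(x)))
    fu_stop("constant dosage vector: no association test possible")
  df <- data.frame(y = as.numeric(y), snp = x)
  if (!is.null(covars) && ncol(as.matrix(covars)) > 0L)
    df <- cbind(df, as.data.frame(as.matrix(covars)))
  df <- df[complete.cases(df), , drop = FALSE]
  n <- nrow(df)
  fam <- if (family == "linear") gaussian() else binomial()
  fit <- tryCatch(glm(y ~ ., data = df, family = fam), warning = function(w) w,
                  error = function(e) e)
  flagged <- data.frame(beta = NA_real_, se = NA_real_, p = NA_real_, n = n,
                        converged = FALSE)
  if (inherits(fit, "condition")) return(flagged)
  if (!fit$converged) return(flagged)
  sm <- summary(fit)$coefficients
  if (!"snp" %in% rownames(sm)) return(flagged)
  beta <- sm["snp", 1L]; se <- sm["snp", 2L]
  # two-sided normal reference (Wald), the GWAS convention
  p <- 2 * pnorm(-abs(beta / se))
  data.frame(beta = beta, se = se, p = p, n = n, converged = TRUE)
}

#' Genome-wide univariate association scan
#'
#' Runs [univariate_assoc()] for every variant in the genotype matrix.
#' Constant variants and non-converged fits are reported with `NA`
#' statistics.
#'
#' @param genotypes a [genotype_matrix()].
#' @param phenotypes a [phenotype_table()].
#' @param covariates covariate columns (see [covariate_matrix()]).
#' @return data frame with one row per variant: `variant_id`, `beta`, `se`,
#'   `p`, `n`, `converged`.
#' @export
gwas_scan <- function(genotypes, phenotypes, covariates = NULL) {
  al <- align_samples(genotypes, phenotypes)
  dosage <- impute_dosage(al$genotypes$dosage)
  ph <- al$phenotypes
  y <- as.numeric(ph[[attr(ph, "outcome")]])
  family <- attr(ph, "family")
  covars <- covariate_matrix(ph, covariates)
  if (ncol(covars) == 0L) covars <- NULL
  rows <- lapply(colnames(dosage), function(v) {
    st <- tryCatch(univariate_assoc(dosage[, v], y, covars, family),
                   error = function(e)
                     data.frame(beta = NA_real_, se = NA_real_, p = NA_real_,
                                n = length(y), converged = FALSE))
    cbind(data.frame(variant_id = v, stringsAsFactors = FALSE), st)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Inverse-variance fixed-effects meta-analysis
#'
#' Combines per-cohort association statistics with weights `1/se^2`:
#' `beta = sum(w * beta_i) / sum(w)`, `se = 1 / sqrt(sum(w))`, two-sided
#' normal p-value. A single cohort passes through unchanged (with a note).
#'
#' @param stats data frame with columns `beta` and `se` (one row per
#'   cohort); an optional `n` column is summed.
#' @return one-row data frame: `beta`, `se`, `p`, `n`, `k` (cohorts).
#' @export
#' @examples
#' fixed_effects_meta(data.frame(beta = c(1, 3), se = c(1, 1)))
fixed_effects_meta <- function(stats) {
  stopifnot(is.data.frame(stats), all(c("beta", "se") %in% names(stats)))
  ok <- is.finite(stats$beta) & is.finite(stats$se) & stats$se > 0
  stats <- stats[ok, , drop = FALSE]
  k <- nrow(stats)
  if (k == 0L) fu_stop("no cohort with finite beta and se")
  if (k == 1L) fu_log("fixed_effects_meta: single cohort, passing through")
  w <- 1 / stats$se^2
  beta <- sum(w * stats$beta) / sum(w)
  se <- 1 / sqrt(sum(w))
  n <- if ("n" %in% names(stats)) sum(stats$n) else NA_integer_
  data.frame(beta = beta, se = se, p = 2 * pnorm(-abs(beta / se)), n = n, k = k)
}

#' Tier dSNPs by their (proxy-expanded) GWAS significance
#'
#' For every dSNP in the catalog, looks up its own GWAS p-value and the
#' p-values of its LD proxies, and classifies the best of them against the
#' genome-wide and nominal thresholds.
#'
#' @param catalog `fuwas` catalog (or any data frame with a `variant_id`
#'   column).
#' @param gwas data frame with `variant_id` and `p` (e.g. [gwas_scan()]).
#' @param proxies optional proxy map from [find_proxies()] (data frame
#'   `target_id`, `proxy_id`, `r2`); `NULL` means self-only.
#' @param genome_wide genome-wide significance threshold (default `5e-8`).
#' @param nominal nominal threshold (default `0.05`).
#' @return object of class `overlap_report`: data frame per dSNP (`own_p`,
#'   `best_p`, `best_variant`, `tier`) with a `counts` attribute.
#' @export
overlap_report <- function(catalog, gwas, proxies = NULL,
                           genome_wide = 5e-8, nominal = 0.05) {
  ds <- unique(as.character(catalog$variant_id))
  if (!length(ds)) fu_stop("no dSNPs in catalog")
  pv <- setNames(gwas$p, gwas$variant_id)
  rows <- lapply(ds, function(v) {
    own <- unname(pv[v])
    prox <- if (is.null(proxies)) v else
      unique(c(v, proxies$proxy_id[proxies$target_id == v]))
    cand <- pv[intersect(prox, names(pv))]
    cand <- cand[is.finite(cand)]
    if (!length(cand)) {
      fu_log("overlap_report: dSNP %s absent from GWAS table and proxy-less", v)
      return(data.frame(variant_id = v, own_p = NA_real_, best_p = NA_real_,
                        best_variant = NA_character_, tier = "none",
                        stringsAsFactors = FALSE))
    }
    best <- which.min(cand)
    bp <- unname(cand[best])
    tier <- if (bp < genome_wide) "genome_wide" else
      if (bp < nominal) "nominal" else "none"
    data.frame(variant_id = v, own_p = if (is.null(own)) NA_real_ else own,
               best_p = bp, best_variant = names(cand)[best], tier = tier,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  counts <- table(factor(out$tier, levels = c("genome_wide", "nominal", "none")))
  structure(out, class = c("overlap_report", "data.frame"), counts = counts)
}

#' @export
print.overlap_report <- function(x, ...) {
  cat("dSNP vs GWAS overlap:\n")
  print(attr(x, "counts"))
  NextMethod()
  invisible(x)
}
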