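# Penalized-regression core. All models share one design-matrix convention:
# forced (unpenalized) columns first -- intercept is implicit, covariates get
# penalty factor 0 -- then the penalized SNP dosage columns. The objective is
# glmnet's: (1/n) * NLL (gaussian: 1/(2n) * RSS) + lambda * sum|beta_pen|,
# with the elastic-net mixing alpha applied to penalized columns only.

# internal: assemble design, penalty factors and drop constant penalized cols
build_design <- function(x, covars) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("snp_", seq_len(ncol(x)))
  if (!is.null(covars) && ncol(as.matrix(covars)) > 0L) {
    covars <- as.matrix(covars)
    if (is.null(colnames(covars)))
      colnames(covars) <- paste0("covar_", seq_len(ncol(covars)))
  } else {
    covars <- matrix(numeric(0), nrow = nrow(x), ncol = 0L)
  }
  keep <- apply(x, 2L, function(col) sd(col) > 0)
  if (!all(keep)) {
    fu_warn("dropping %d constant penalized column(s): %s", sum(!keep),
            paste(head(colnames(x)[!keep], 3L), collapse = ", "))
    x <- x[, keep, drop = FALSE]
  }
  if (ncol(x) == 0L) fu_stop("no non-constant penalized columns left")
  # glmnet requires >= 2 columns; pad with an all-zero dummy if needed
  pad <- ncol(covars) + ncol(x) < 2L
  if (pad) x <- cbind(x, .pad. = 0)
  list(X = cbind(covars, x), penalized = colnames(x)[colnames(x) != ".pad."],
       forced = colnames(covars),
       pf = c(rep(0, ncol(covars)), rep(1, ncol(x))), padded = pad)
}

glmnet_family <- function(family) {
  switch(family, linear = "gaussian", logistic = "binomial",
         fu_stop("unknown family '%s'", family))
}

# internal: descending lambda sequence from the data-driven lambda_max down to
# (and including) target; 100 log-spaced points, min ratio 1e-3 (1e-2 if n<p)
lambda_sequence <- function(fit_max, target, n, p, nlambda = 100) {
  lmax <- fit_max
  if (target >= lmax) return(sort(unique(c(lmax * 1.001, target)), decreasing = TRUE))
  ratio <- if (n < p) 1e-2 else 1e-3
  floor_l <- max(target, lmax * ratio * 1e-2, lmax * 1e-8)
  seq_l <- exp(seq(log(lmax), log(floor_l), length.out = nlambda))
  sort(unique(c(seq_l, target)), decreasing = TRUE)
}

#' Fit an L1-penalized (LASSO / elastic-net) regression at a given lambda
#'
#' Fits `y ~ intercept + covars + x` where the intercept and covariate
#' coefficients are never shrunk and the SNP-dosage columns in `x` carry the
#' L1 penalty (mixed with an L2 term when `alpha < 1`). The solver is
#' coordinate descent over a descending lambda path ending at the requested
#' value; coefficients are reported on the original predictor scale.
#'
#' @param x numeric matrix of penalized predictors (samples x SNPs).
#' @param y outcome vector (0/1 for `"logistic"`).
#' @param covars optional numeric matrix of forced, unpenalized covariates.
#' @param family `"linear"` or `"logistic"`.
#' @param lambda nonnegative penalty strength.
#' @param alpha elastic-net mixing in (0, 1]; 1 is the LASSO.
#' @param standardize standardize penalized columns inside the solver
#'   (coefficients are back-transformed).
#' @param penalize_covars penalize the covariates too (off by default:
#'   adjustment variables are forced).
#' @return object of class `lasso_fit`: `intercept`, `beta` (named, all
#'   columns), `lambda`, `alpha`, `family`, `penalized`, `forced`,
#'   `objective`.
#' @export
fit_lasso <- function(x, y, covars = NULL, family = c("linear", "logistic"),
                      lambda, alpha = 1, standardize = TRUE,
                      penalize_covars = FALSE) {
  family <- match.arg(family)
  stopifnot(length(lambda) == 1L, lambda >= 0, alpha > 0, alpha <= 1)
  y <- as.numeric(y)
  if (anyNA(y)) fu_stop("NA in outcome")
  d <- build_design(x, covars)
  if (anyNA(d$X)) fu_stop("NA in design matrix")
  n <- nrow(d$X)
  if (n < 2L) fu_stop("need at least 2 samples")
  if (length(y) != n) fu_stop("length(y) != nrow(x)")
  pf <- if (penalize_covars) rep(1, ncol(d$X)) else d$pf
  fam <- glmnet_family(family)
  probe <- glmnet::glmnet(d$X, y, family = fam, alpha = alpha,
                          penalty.factor = pf, standardize = standardize,
                          nlambda = 5)
  lseq <- lambda_sequence(probe$lambda[1], lambda, n, length(d$penalized))
  fit <- glmnet::glmnet(d$X, y, family = fam, alpha = alpha,
                        penalty.factor = pf, standardize = standardize,
                        lambda = lseq, thresh = 1e-12, maxit = 1e6)
  cf <- as.numeric(coef(fit, s = lambda, exact = FALSE))
  names(cf) <- c("(Intercept)", colnames(d$X))
  beta <- cf[-1L]
  beta <- beta[names(beta) != ".pad."]
  if (family == "logistic" && lambda == 0 && max(abs(beta)) > 50)
    fu_warn("very large coefficients at lambda = 0; possible separation, consider lambda > 0")
  eta <- cf[1L] + as.numeric(d$X[, names(beta), drop = FALSE] %*% beta)
  loss <- if (family == "linear") mean((y - eta)^2) / 2 else
    mean(log(1 + exp(eta)) - y * eta)
  bpen <- beta[d$penalized]
  obj <- loss + lambda * (alpha * sum(abs(bpen)) + (1 - alpha) / 2 * sum(bpen^2))
  structure(list(intercept = unname(cf[1L]), beta = beta, lambda = lambda,
                 alpha = alpha, family = family, penalized = d$penalized,
                 forced = d$forced, objective = obj),
            class = "lasso_fit")
}

#' @export
print.lasso_fit <- function(x, ...) {
  nz <- sum(x$beta[x$penalized] != 0)
  cat(sprintf("lasso_fit (%s): lambda = %.4g, %d/%d penalized coefficients nonzero\n",
              x$family, x$lambda, nz, length(x$penalized)))
  invisible(x)
}

#' @export
coef.lasso_fit <- function(object, ...) c("(Intercept)" = object$intercept, object$beta)

#' Per-subsample selection count from the stability-selection error bound
#'
#' Given `p` candidate variables, a selection-frequency cutoff and a target
#' per-family error rate (PFER, the expected number of false selections per
#' model), returns the largest number `q` of variables each subsample fit may
#' select such that the Meinshausen-Buhlmann bound
#' `PFER <= q^2 / ((2 * cutoff - 1) * p)` still controls the PFER:
#' `q = floor(sqrt(PFER * (2 * cutoff - 1) * p))`, capped at `p`.
#'
#' @param p number of penalized candidate variables.
#' @param cutoff selection-frequency cutoff in (0.5, 1].
#' @param PFER target per-family error rate (> 0; may exceed 1).
#' @return integer `q >= 1`.
#' @export
#' @examples
#' compute_q(1000, 0.7, 1.0)  # 20
compute_q <- function(p, cutoff, PFER) {
  stopifnot(p >= 1, cutoff > 0.5, cutoff <= 1, PFER > 0)
  q <- floor(sqrt(PFER * (2 * cutoff - 1) * p) + 1e-8)
  if (q < 1) fu_stop("FU too small for requested error control (p = %d gives q < 1)", p)
  as.integer(min(q, p))
}

#' First q variables to enter the regularization path
#'
#' Computes a descending lambda path from the smallest lambda at which every
#' penalized coefficient is zero, and returns the penalized variables active
#' when the active set first reaches size `q` (all variables that ever
#' activate, if fewer). When a path step jumps past `q`, variables are ranked
#' by entry order, ties by coefficient magnitude at the jump.
#'
#' @inheritParams fit_lasso
#' @param q maximum number of penalized variables to return.
#' @param nlambda path resolution.
#' @return character vector of at most `q` penalized column names.
#' @export
first_q_active <- function(x, y, covars = NULL,
                           family = c("linear", "logistic"), q, alpha = 1,
                           standardize = TRUE, nlambda = 100) {
  family <- match.arg(family)
  stopifnot(q >= 1)
  d <- build_design(x, covars)
  n <- nrow(d$X); p <- length(d$penalized)
  ratio <- if (n < p) 1e-2 else 1e-3
  fit <- glmnet::glmnet(d$X, as.numeric(y), family = glmnet_family(family),
                        alpha = alpha, penalty.factor = d$pf,
                        standardize = standardize, nlambda = nlambda,
                        lambda.min.ratio = ratio,
                        pmax = min(ncol(d$X), q + length(d$forced) + 2L),
                        maxit = 1e6)
  B <- as.matrix(fit$beta)[d$penalized, , drop = FALSE]
  active <- B != 0
  counts <- colSums(active)
  if (max(counts) == 0L) {
    fu_warn("no penalized variable entered the path")
    return(character(0))
  }
  k <- which(counts >= q)[1]
  if (is.na(k)) {  # never reaches q: everything that ever activated
    return(rownames(B)[rowSums(active) > 0])
  }
  vars <- which(active[, k])
  if (length(vars) <= q) return(rownames(B)[vars])
  entry <- apply(active[vars, seq_len(k), drop = FALSE], 1L,
                 function(z) which(z)[1])
  mag <- abs(B[vars, k])
  ord <- order(entry, -mag)
  rownames(B)[vars[ord[seq_len(q)]]]
}
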