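# independent oracles ---------------------------------------------------

# soft-thresholding closed form for orthonormal designs
soft <- function(b, lam) sign(b) * pmax(abs(b) - lam, 0)

# design whose centered columns satisfy (1/n) X'X = I
orthonormal_design <- function(n, p, seed = 1) {
  set.seed(seed)
  M <- cbind(1, matrix(rnorm(n * p), n, p))
  Q <- qr.Q(qr(M))[, -1, drop = FALSE]
  X <- sqrt(n) * Q
  colnames(X) <- paste0("x", seq_len(p))
  X
}

test_that("orthonormal-design solutions equal the soft-thresholding closed form", {
  n <- 64; p <- 6
  X <- orthonormal_design(n, p)
  set.seed(3)
  beta_true <- c(1.0, -0.8, 0.5, 0.2, 0, 0)
  y <- as.numeric(X %*% beta_true) + rnorm(n, 0, 0.3)
  b_ols <- as.numeric(crossprod(X, y - mean(y))) / n
  for (lam in c(0, 0.1, 0.3, 0.7)) {
    fit <- fit_lasso(X, y, family = "linear", lambda = lam,
                     standardize = FALSE)
    expect_equal(unname(fit$beta[colnames(X)]), soft(b_ols, lam),
                 tolerance = 1e-6)
  }
  # the classic single-predictor case: OLS coefficient 1 shrinks to 1 - lambda
  x1 <- X[, 1, drop = FALSE]
  y1 <- as.numeric(x1) * 1.0
  fit1 <- fit_lasso(x1, y1, family = "linear", lambda = 0.3,
                    standardize = FALSE)
  expect_equal(unname(fit1$beta["x1"]), 0.7, tolerance = 1e-6)
})

test_that("lambda = 0 agrees with the unpenalized MLE oracle", {
  set.seed(4)
  n <- 300
  X <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("s", 1:4)))
  covars <- cbind(sex = rbinom(n, 1, 0.5), age = rnorm(n))
  eta <- 0.3 + 0.5 * X[, 1] - 0.4 * X[, 3] + 0.2 * covars[, "sex"]
  # linear family vs lm
  y <- eta + rnorm(n)
  fit <- fit_lasso(X, y, covars, "linear", lambda = 0)
  oracle <- lm(y ~ covars + X)
  expect_equal(unname(fit$beta[paste0("s", 1:4)]),
               unname(coef(oracle)[paste0("Xs", 1:4)]), tolerance = 1e-5)
  expect_equal(fit$intercept, unname(coef(oracle)[1]), tolerance = 1e-5)
  # logistic family vs glm
  yb <- rbinom(n, 1, 1 / (1 + exp(-eta)))
  fitb <- fit_lasso(X, yb, covars, "logistic", lambda = 0)
  orb <- glm(yb ~ covars + X, family = binomial())
  expect_equal(unname(fitb$beta[paste0("s", 1:4)]),
               unname(coef(orb)[paste0("Xs", 1:4)]), tolerance = 1e-4)
})

test_that("full shrinkage leaves forced covariates at their covariate-only MLE", {
  set.seed(5)
  n <- 200
  X <- matrix(rnorm(n * 10), n, 10)
  covars <- cbind(sex = rbinom(n, 1, 0.5), age = rnorm(n))
  y <- rbinom(n, 1, plogis(0.4 * covars[, "sex"] - 0.2))
  fit <- fit_lasso(X, y, covars, "logistic", lambda = 10)
  expect_true(all(fit$beta[fit$penalized] == 0))
  oracle <- glm(y ~ covars, family = binomial())
  expect_equal(unname(fit$beta[c("sex", "age")]),
               unname(coef(oracle)[c("covarssex", "covarsage")]),
               tolerance = 1e-4)
  expect_equal(fit$intercept, unname(coef(oracle)[1]), tolerance = 1e-4)
})

test_that("the l1 norm of penalized coefficients shrinks monotonically in lambda", {
  set.seed(6)
  n <- 150; p <- 20
  X <- matrix(rnorm(n * p), n, p)
  y <- X[, 1] - 0.5 * X[, 2] + rnorm(n)
  lams <- c(0.01, 0.05, 0.1, 0.2, 0.5, 1)
  norms <- vapply(lams, function(l) {
    f <- fit_lasso(X, y, family = "linear", lambda = l)
    sum(abs(f$beta[f$penalized]))
  }, numeric(1))
  expect_true(all(diff(norms) <= 1e-8))
})

test_that("constant penalized columns are dropped with a warning", {
  set.seed(7)
  X <- cbind(a = rnorm(50), b = rep(1, 50), c = rnorm(50))
  y <- X[, "a"] + rnorm(50)
  expect_warning(fit <- fit_lasso(X, y, family = "linear", lambda = 0.01),
                 "constant")
  expect_false("b" %in% names(fit$beta))
})

test_that("the subsample selection count obeys the error-control bound", {
  expect_equal(compute_q(1000, 0.7, 1.0), 20L)  # floor(sqrt(0.4 * 1000))
  expect_error(compute_q(1, 0.7, 1.0), "too small")
  expect_equal(compute_q(10, 1.0, 10), 10L)     # capped at p
  # exhaustive check of the bound over a grid
  for (p in c(5, 50, 500)) for (pf in c(0.5, 1, 2)) for (ct in c(0.6, 0.7, 0.9)) {
    q <- tryCatch(compute_q(p, ct, pf), error = function(e) NA_integer_)
    if (!is.na(q)) {
      expect_lte(q^2, pf * (2 * ct - 1) * p + 1e-6)
      if (q < p) expect_gt((q + 1)^2, pf * (2 * ct - 1) * p)
    }
  }
})

test_that("the first path entrant maximizes correlation with the response", {
  set.seed(8)
  n <- 400; p <- 30
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("v", 1:p)))
  y <- 1.2 * X[, 17] + rnorm(n)
  sel <- first_q_active(X, y, family = "linear", q = 1, standardize = FALSE)
  # oracle: with standardized columns the first entrant has maximal
  # |correlation| with the centered response
  cors <- abs(cor(X, y))
  expect_identical(sel, rownames(cors)[which.max(cors)])
  expect_identical(sel, "v17")
  # q >= p returns everything that ever activates; never more than q
  sel_all <- first_q_active(X, y, family = "linear", q = p)
  expect_lte(length(sel_all), p)
  expect_true("v17" %in% sel_all)
  set.seed(9)
  ynull <- rnorm(n)
  sel2 <- first_q_active(X, ynull, family = "linear", q = 2)
  expect_lte(length(sel2), 2)
})

test_that("elastic-net mixing and covariate penalization are available switches", {
  set.seed(10)
  n <- 120
  X <- matrix(rnorm(n * 8), n, 8)
  covars <- cbind(age = rnorm(n))
  y <- X[, 1] + 0.5 * covars[, 1] + rnorm(n)
  f_en <- fit_lasso(X, y, covars, "linear", lambda = 0.2, alpha = 0.5)
  f_l1 <- fit_lasso(X, y, covars, "linear", lambda = 0.2, alpha = 1)
  expect_gte(sum(f_en$beta[f_en$penalized] != 0),
             sum(f_l1$beta[f_l1$penalized] != 0))
  f_pen <- fit_lasso(X, y, covars, "linear", lambda = 5, penalize_covars = TRUE)
  expect_equal(unname(f_pen$beta["age"]), 0)
})
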