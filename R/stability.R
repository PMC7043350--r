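#' Stability-selection configuration
#'
#' Defaults follow the standard FU-wide analysis settings: selection-frequency
#' cutoff 0.7, per-family error rate 1.0, 100 subsamples of size
#' `floor(n/2)` drawn without replacement, LASSO (`alpha = 1`) as the
#' per-subsample fit.
#'
#' @param cutoff selection-frequency threshold in (0.5, 1].
#' @param PFER target per-family error rate (expected false selections per
#'   model; may exceed 1).
#' @param B number of subsamples.
#' @param seed integer seed governing all subsampling.
#' @param alpha elastic-net mixing for the per-subsample fits (1 = LASSO).
#' @param standardize standardize penalized columns in the solver.
#' @return list of class `stability_config`.
#' @export
stability_config <- function(cutoff = 0.7, PFER = 1.0, B = 100, seed = 1L,
                             alpha = 1, standardize = TRUE) {
  stopifnot(cutoff > 0.5, cutoff <= 1, PFER > 0, B >= 2)
  structure(list(cutoff = cutoff, PFER = PFER, B = as.integer(B),
                 seed = as.integer(seed), alpha = alpha,
                 standardize = standardize),
            class = "stability_config")
}

#' Stability selection for one SNP set
#'
#' Draws `B` subsamples of size `floor(n/2)` without replacement, runs the
#' penalized fit on each subsample keeping the first `q` variables to enter
#' the regularization path (with `q` from [compute_q()] so the
#' Meinshausen-Buhlmann bound controls the PFER), and selects the variables
#' whose selection frequency reaches the cutoff. Deterministic given the
#' config seed.
#'
#' @param x dosage matrix for the SNP set (samples x SNPs, named columns).
#' @param y outcome vector.
#' @param covars forced covariate matrix (may be `NULL`).
#' @param family `"linear"` or `"logistic"`.
#' @param config a [stability_config()].
#' @return object of class `stabsel_fit`: `pi` (named selection
#'   frequencies), `selected`, `q`, `B`, `B_effective`, plus the
#'   configuration used.
#' @export
stability_selection <- function(x, y, covars = NULL,
                                family = c("linear", "logistic"),
                                config = stability_config()) {
  family <- match.arg(family)
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("snp_", seq_len(ncol(x)))
  n <- nrow(x)
  if (n < 10L) fu_stop("stability selection needs at least 10 samples")
  p <- ncol(x)
  if (p < 1L) fu_stop("empty SNP set")
  q <- compute_q(p, config$cutoff, config$PFER)
  m <- n %/% 2L
  subsamples <- with_seed(config$seed,
                          replicate(config$B, sample.int(n, m), simplify = FALSE))
  counts <- setNames(numeric(p), colnames(x))
  b_eff <- 0L
  for (idx in subsamples) {
    sel <- tryCatch(
      suppressWarnings(first_q_active(x[idx, , drop = FALSE], y[idx],
                                      covars = if (is.null(covars)) NULL else
                                        covars[idx, , drop = FALSE],
                                      family = family, q = q,
                                      alpha = config$alpha,
                                      standardize = config$standardize)),
      error = function(e) NULL)
    if (is.null(sel)) next
    b_eff <- b_eff + 1L
    counts[sel] <- counts[sel] + 1
  }
  if (b_eff == 0L) fu_stop("all %d subsample fits failed", config$B)
  if (b_eff < config$B)
    fu_log("stability_selection: %d of %d subsample fits failed and were skipped",
           config$B - b_eff, config$B)
  pi_hat <- counts / b_eff
  structure(list(pi = pi_hat, selected = names(pi_hat)[pi_hat >= config$cutoff],
                 q = q, B = config$B, B_effective = b_eff,
                 cutoff = config$cutoff, PFER = config$PFER,
                 seed = config$seed, n = n, p = p, family = family),
            class = "stabsel_fit")
}

#' @export
print.stabsel_fit <- function(x, ...) {
  cat(sprintf("stabsel_fit (%s): %d candidates, q = %d, B = %d, cutoff = %.2f, PFER = %.2f\n",
              x$family, x$p, x$q, x$B, x$cutoff, x$PFER))
  if (length(x$selected)) {
    cat("selected:\n")
    print(round(x$pi[x$selected], 3))
  } else cat("selected: none\n")
  invisible(x)
}

#' Plot selection frequencies of a stability-selection fit
#'
#' @param x a `stabsel_fit`.
#' @param top number of variables to show, by decreasing frequency.
#' @param ... passed to [graphics::barplot()].
#' @return invisibly, the plotted frequencies.
#' @export
plot.stabsel_fit <- function(x, top = 20, ...) {
  p <- sort(x$pi, decreasing = TRUE)
  p <- head(p, top)
  graphics::barplot(p, las = 2, ylim = c(0, 1),
                    ylab = "selection frequency", ...)
  graphics::abline(h = x$cutoff, lty = 2)
  invisible(p)
}

#' Functional-unit-wide association study
#'
#' The core model: for every functional unit's regulatory SNP set, fits an
#' L1-penalized regression of the outcome on the set's dosages plus forced
#' covariates, under stability selection with per-family error-rate control,
#' and calls as dSNPs the variants whose selection frequency reaches the
#' cutoff in at least one FU model.
#'
#' FUs whose sets are empty, whose SNPs are all absent from the genotype
#' matrix, or that are too small for the requested error control are skipped
#' with a logged reason. One master seed fans out to independent per-FU
#' seeds, so results are reproducible FU by FU.
#'
#' @param genotypes a [genotype_matrix()].
#' @param phenotypes a [phenotype_table()]; its `family` attribute picks the
#'   model family.
#' @param fu_sets a [build_fu_sets()] result, or a named list of variant-id
#'   vectors.
#' @param covariates covariate columns for [covariate_matrix()] (default:
#'   all standard ones present).
#' @param config a [stability_config()].
#' @return object of class `fuwas`: `catalog` (data frame of dSNP calls:
#'   `variant_id`, `fu_id`, `selection_frequency`, `q`, `n_snps_in_fu`),
#'   `results` (per-FU `stabsel_fit`s), `skipped`, `config`, `family`.
#' @export
fuwas <- function(genotypes, phenotypes, fu_sets, covariates = NULL,
                  config = stability_config()) {
  sets <- if (inherits(fu_sets, "fu_sets")) fu_sets$sets else fu_sets
  stopifnot(is.list(sets), !is.null(names(sets)))
  if (!any(lengths(sets) > 0L)) fu_stop("all FU sets are empty")
  al <- align_samples(genotypes, phenotypes)
  dosage <- impute_dosage(al$genotypes$dosage)
  ph <- al$phenotypes
  family <- attr(ph, "family")
  y <- as.numeric(ph[[attr(ph, "outcome")]])
  covars <- covariate_matrix(ph, covariates)
  if (ncol(covars) == 0L) covars <- NULL
  fus <- names(sets)
  seeds <- child_seeds(config$seed, length(fus))
  results <- list()
  skipped <- data.frame(fu_id = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  skip <- function(fu, why) {
    skipped[nrow(skipped) + 1L, ] <<- list(fu, why)
    fu_log("fuwas: skipping FU %s (%s)", fu, why)
  }
  for (i in seq_along(fus)) {
    fu <- fus[i]
    vids <- intersect(sets[[fu]], colnames(dosage))
    n_absent <- length(sets[[fu]]) - length(vids)
    if (length(sets[[fu]]) == 0L) { skip(fu, "empty set"); next }
    if (length(vids) == 0L) { skip(fu, "no set member present in genotypes"); next }
    if (n_absent > 0L)
      fu_log("fuwas: FU %s: %d set member(s) absent from genotypes", fu, n_absent)
    cfg_i <- config
    cfg_i$seed <- seeds[i]
    fit <- tryCatch(
      stability_selection(dosage[, vids, drop = FALSE], y, covars,
                          family = family, config = cfg_i),
      error = function(e) conditionMessage(e))
    if (is.character(fit)) { skip(fu, fit); next }
    results[[fu]] <- fit
  }
  if (!length(results)) fu_stop("no FU model could be fitted")
  rows <- lapply(names(results), function(fu) {
    r <- results[[fu]]
    if (!length(r$selected)) return(NULL)
    data.frame(variant_id = r$selected, fu_id = fu,
               selection_frequency = unname(r$pi[r$selected]),
               q = r$q, n_snps_in_fu = r$p, stringsAsFactors = FALSE)
  })
  catalog <- do.call(rbind, c(Filter(Negate(is.null), rows),
                              list(make.row.names = FALSE)))
  if (is.null(catalog))
    catalog <- data.frame(variant_id = character(0), fu_id = character(0),
                          selection_frequency = numeric(0), q = integer(0),
                          n_snps_in_fu = integer(0), stringsAsFactors = FALSE)
  structure(list(catalog = catalog, results = results, skipped = skipped,
                 config = config, family = family, n = length(y),
                 call = match.call()),
            class = "fuwas")
}

#' @export
print.fuwas <- function(x, ...) {
  cat(sprintf("fuwas fit (%s family): %d FU models, %d skipped, n = %d\n",
              x$family, length(x$results), nrow(x$skipped), x$n))
  cat(sprintf("dSNP calls: %d (%d unique variants across %d FUs)\n",
              nrow(x$catalog), length(unique(x$catalog$variant_id)),
              length(unique(x$catalog$fu_id))))
  invisible(x)
}

#' @export
summary.fuwas <- function(object, ...) {
  per_fu <- vapply(object$results, function(r) length(r$selected), integer(1))
  out <- list(n_models = length(object$results),
              n_skipped = nrow(object$skipped),
              n_calls = nrow(object$catalog),
              n_dsnps = length(unique(object$catalog$variant_id)),
              dsnps_per_fu = table(per_fu),
              config = object$config)
  class(out) <- "summary.fuwas"
  out
}

#' @export
print.summary.fuwas <- function(x, ...) {
  cat(sprintf("FU models fitted: %d (skipped: %d)\n", x$n_models, x$n_skipped))
  cat(sprintf("dSNP calls: %d rows, %d unique dSNPs\n", x$n_calls, x$n_dsnps))
  cat("dSNPs per FU model:\n")
  print(x$dsnps_per_fu)
  invisible(x)
}

#' @export
coef.fuwas <- function(object, ...) object$catalog

#' @export
as.data.frame.fuwas <- function(x, ...) x$catalog

#' Unique dSNP identifiers of a fit
#' @param fit a `fuwas` object.
#' @return character vector of distinct selected variant ids.
#' @export
dsnps <- function(fit) unique(fit$catalog$variant_id)

#' Single penalized model over the whole regulatory universe
#'
#' The ungrouped comparison model: stability selection applied once to the
#' union of all regulatory SNPs instead of per-FU sets.
#'
#' @inheritParams fuwas
#' @param universe character vector of variant ids (e.g. `fu_sets$universe`).
#' @return a `stabsel_fit`.
#' @export
single_lasso_all <- function(genotypes, phenotypes, universe,
                             covariates = NULL, config = stability_config()) {
  if (!length(universe)) fu_stop("empty regulatory universe")
  al <- align_samples(genotypes, phenotypes)
  dosage <- impute_dosage(al$genotypes$dosage)
  vids <- intersect(universe, colnames(dosage))
  if (!length(vids)) fu_stop("no universe variant present in genotypes")
  ph <- al$phenotypes
  covars <- covariate_matrix(ph, covariates)
  if (ncol(covars) == 0L) covars <- NULL
  stability_selection(dosage[, vids, drop = FALSE],
                      as.numeric(ph[[attr(ph, "outcome")]]), covars,
                      family = attr(ph, "family"), config = config)
}

#' Write the dSNP catalog as TSV
#' @param fit a `fuwas` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_dsnp_catalog <- function(fit, path) {
  write.table(fit$catalog, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a structured JSON run log
#'
#' Records the seed and configuration, per-FU set sizes and q, and every
#' skipped FU with its reason.
#'
#' @param fit a `fuwas` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_run_log <- function(fit, path) {
  log <- list(config = unclass(fit$config), family = fit$family, n = fit$n,
              fus = lapply(fit$results, function(r)
                list(p = r$p, q = r$q, B_effective = r$B_effective,
                     n_selected = length(r$selected))),
              skipped = fit$skipped)
  jsonlite::write_json(log, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
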