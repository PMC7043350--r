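#' Simulation configuration
#'
#' Defines the synthetic study conditions: LD-block genotypes from a latent
#' AR(1) Gaussian haplotype model, FU-structured regulatory scores with
#' planted significant e-values, and phenotypes from the additive
#' dosage model with covariate effects. Defaults describe the reference
#' desk-scale study: n = 1,000 samples, 20 LD blocks of 20 SNPs, one
#' 10-member FU per block with 2 causal SNPs at standardized effect 0.5, a
#' one-million-variant e-value background, and a continuous outcome. The
#' default FU size and the additive (linear) default link are chosen so
#' that, under the package's error-control defaults, the planted signal is
#' recoverable: the per-subsample selection bound q grows only as the
#' square root of the FU size, while every planted causal SNP across all
#' FUs feeds the same phenotype, so large FU sets and the extra
#' effect-attenuation of the logistic link both erode per-SNP selection
#' frequencies.
#'
#' @param n_samples number of samples.
#' @param n_blocks number of independent LD blocks.
#' @param snps_per_block SNPs per block.
#' @param rho AR(1) LD parameter in `[0, 1)`.
#' @param maf_range minor-allele-frequency range, inside `(0, 0.5]`.
#' @param n_fus number of functional units (FU k draws its members from
#'   block `((k - 1) %% n_blocks) + 1`).
#' @param snps_per_fu members per FU (at most `snps_per_block`).
#' @param causal_per_fu causal SNPs planted per FU.
#' @param causal_beta effect size per causal SNP on the standardized-dosage
#'   scale (signs alternate), so signal strength is MAF-independent.
#' @param family `"logistic"` or `"linear"`.
#' @param sigma residual SD for the linear family.
#' @param intercept linear-predictor intercept.
#' @param covar_coefs named effects of the standardized covariates
#'   (`sex`, `age`, `cohort`, `mds`).
#' @param n_mds number of simulated ancestry components.
#' @param background_n background variants per FU for e-values.
#' @param evalue_cutoff e-value cutoff the planted members must beat.
#' @param seed master seed; fans out to per-stage child seeds.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 1000, n_blocks = 20, snps_per_block = 20,
                       rho = 0.5, maf_range = c(0.05, 0.5), n_fus = 20,
                       snps_per_fu = 10, causal_per_fu = 2,
                       causal_beta = 0.5, family = c("linear", "logistic"),
                       sigma = 1, intercept = 0,
                       covar_coefs = c(sex = 0.25, age = 0.25, cohort = 0.25,
                                       mds = 0.1),
                       n_mds = 2, background_n = 1e6, evalue_cutoff = 5e-5,
                       seed = 1L) {
  family <- match.arg(family)
  stopifnot(rho >= 0, rho < 1, maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2], snps_per_fu <= snps_per_block,
            causal_per_fu <= snps_per_fu, n_samples >= 10)
  structure(list(n_samples = n_samples, n_blocks = n_blocks,
                 snps_per_block = snps_per_block, rho = rho,
                 maf_range = maf_range, n_fus = n_fus,
                 snps_per_fu = snps_per_fu, causal_per_fu = causal_per_fu,
                 causal_beta = causal_beta, family = family, sigma = sigma,
                 intercept = intercept, covar_coefs = covar_coefs,
                 n_mds = n_mds, background_n = background_n,
                 evalue_cutoff = evalue_cutoff, seed = as.integer(seed)),
            class = "sim_config")
}

# internal: one block of haplotype pairs from a latent AR(1) Gaussian
sim_block <- function(n, m, rho, mafs) {
  hap <- function() {
    z <- matrix(rnorm(n * m), n, m)
    if (m > 1L && rho > 0) {
      for (j in 2:m) z[, j] <- rho * z[, j - 1L] + sqrt(1 - rho^2) * z[, j]
    }
    # allele = 1 where the latent Gaussian falls below the MAF quantile
    sweep(z, 2L, qnorm(mafs), `<`) * 1
  }
  hap() + hap()
}

#' Simulate LD-structured genotypes
#'
#' Each block draws two haplotypes per sample from a latent AR(1) Gaussian
#' with parameter `rho`, thresholded at each SNP's MAF quantile; the dosage
#' is the haplotype sum. Blocks are independent; within a block, adjacent-
#' pair correlation rises with `rho`. Blocks sit on chromosome 1 at 10-Mb
#' intervals with 1-kb SNP spacing. Deterministic given the config seed.
#'
#' @param config a [sim_config()].
#' @return a [genotype_matrix()].
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  seed <- child_seeds(config$seed, 3L)[1L]
  n <- config$n_samples; m <- config$snps_per_block
  with_seed(seed, {
    blocks <- vector("list", config$n_blocks)
    mafs_all <- vector("list", config$n_blocks)
    for (b in seq_len(config$n_blocks)) {
      mafs <- runif(m, config$maf_range[1], config$maf_range[2])
      for (attempt in 1:10) {
        d <- sim_block(n, m, config$rho, mafs)
        if (all(apply(d, 2L, sd) > 0)) break
        if (attempt == 10) fu_stop("block %d monomorphic after 10 redraws", b)
      }
      blocks[[b]] <- d
      mafs_all[[b]] <- mafs
    }
    dosage <- do.call(cbind, blocks)
    ids <- unlist(lapply(seq_len(config$n_blocks), function(b)
      sprintf("snp_%d_%d", b, seq_len(m))))
    pos <- unlist(lapply(seq_len(config$n_blocks), function(b)
      (b - 1L) * 1e7 + 1 + (seq_len(m) - 1L) * 1000))
    colnames(dosage) <- ids
    rownames(dosage) <- sprintf("sample_%04d", seq_len(n))
    variants <- data.frame(id = ids, chrom = "1", pos = as.integer(pos),
                           ref = "A", alt = "G", maf = unlist(mafs_all),
                           stringsAsFactors = FALSE)
    genotype_matrix(dosage, variants)
  })
}

#' Simulate FU-structured regulatory scores and backgrounds
#'
#' Draws a per-FU background of effect magnitudes (Beta-distributed in
#' (0, 1)), plants FU members above the background maximum so they survive
#' the e-value filter with certainty, and draws non-member effects from the
#' same background law so they pass only at roughly the cutoff rate. Effects
#' are encoded as allele-probability pairs symmetric around 0.5, so the
#' `abs_diff` metric recovers them exactly.
#'
#' @param config a [sim_config()].
#' @param variants variant table (e.g. `genotypes$variants`).
#' @return list: `scores` (data frame `variant_id`, `fu_id`, `p_ref`,
#'   `p_alt`), `backgrounds` (per-FU [background_distribution()]),
#'   `memberships` (data frame `variant_id`, `fu_id` of planted members).
#' @export
simulate_scores <- function(config, variants) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_fus > 0L && config$snps_per_fu > nrow(variants))
    fu_stop("snps_per_fu exceeds the number of variants")
  if (config$n_fus == 0L)
    return(list(scores = data.frame(variant_id = character(0),
                                    fu_id = character(0), p_ref = numeric(0),
                                    p_alt = numeric(0)),
                backgrounds = list(),
                memberships = data.frame(variant_id = character(0),
                                         fu_id = character(0))))
  seed <- child_seeds(config$seed, 3L)[2L]
  with_seed(seed, {
    fu_ids <- sprintf("CL%d:TF%d", ((seq_len(config$n_fus) - 1L) %% 5L) + 1L,
                      seq_len(config$n_fus))
    scores <- list(); backgrounds <- list(); members <- list()
    for (k in seq_len(config$n_fus)) {
      bg <- rbeta(config$background_n, 1.2, 8)
      backgrounds[[fu_ids[k]]] <- background_distribution(fu_ids[k], bg)
      blk <- ((k - 1L) %% config$n_blocks) + 1L
      blk_ids <- variants$id[grepl(sprintf("^snp_%d_", blk), variants$id)]
      if (!length(blk_ids)) blk_ids <- variants$id  # free-form variant tables
      mem <- sort(sample(blk_ids, config$snps_per_fu))
      mx <- max(bg)
      eff_m <- mx + (1 - mx) * runif(length(mem), 0.5, 0.9)
      non <- setdiff(variants$id, mem)
      eff_n <- rbeta(length(non), 1.2, 8)
      eff <- c(eff_m, eff_n)
      scores[[k]] <- data.frame(variant_id = c(mem, non), fu_id = fu_ids[k],
                                p_ref = 0.5 - eff / 2, p_alt = 0.5 + eff / 2,
                                stringsAsFactors = FALSE)
      members[[k]] <- data.frame(variant_id = mem, fu_id = fu_ids[k],
                                 stringsAsFactors = FALSE)
    }
    list(scores = do.call(rbind, scores), backgrounds = backgrounds,
         memberships = do.call(rbind, members))
  })
}

#' Simulate a phenotype from the additive dosage model
#'
#' Builds the linear predictor as the sum of causal standardized dosages
#' times their effects plus standardized covariate effects and the
#' intercept; the linear family adds Gaussian noise, the logistic family
#' draws Bernoulli outcomes through the expit link. Covariates: sex ~
#' Bernoulli(0.5), age ~ Uniform(20, 80), a two-level cohort, and Gaussian
#' ancestry components.
#'
#' @param genotypes a [genotype_matrix()].
#' @param config a [sim_config()].
#' @param causal data frame `variant_id`, `beta` (standardized scale);
#'   `NULL` means no genetic effect.
#' @return a [phenotype_table()] with attribute `eta` (the noiseless linear
#'   predictor).
#' @export
simulate_phenotype <- function(genotypes, config, causal = NULL) {
  stopifnot(inherits(config, "sim_config"))
  seed <- child_seeds(config$seed, 3L)[3L]
  n <- nrow(genotypes$dosage)
  with_seed(seed, {
    sex <- rbinom(n, 1, 0.5)
    age <- runif(n, 20, 80)
    cohort <- sample(c("cohort_a", "cohort_b"), n, replace = TRUE)
    mds <- matrix(rnorm(n * config$n_mds), n,
                  dimnames = list(NULL, paste0("mds_", seq_len(config$n_mds))))
    cc <- config$covar_coefs
    eta <- rep(config$intercept, n) +
      cc[["sex"]] * (sex - 0.5) / 0.5 +
      cc[["age"]] * scale(age)[, 1L] +
      cc[["cohort"]] * (cohort == "cohort_b") +
      mds %*% rep(cc[["mds"]], config$n_mds)
    eta <- as.numeric(eta)
    if (!is.null(causal) && nrow(causal)) {
      miss <- setdiff(causal$variant_id, colnames(genotypes$dosage))
      if (length(miss)) fu_stop("causal variants absent from genotypes: %s",
                                paste(head(miss, 3L), collapse = ", "))
      Xc <- scale(genotypes$dosage[, causal$variant_id, drop = FALSE])
      eta <- eta + as.numeric(Xc %*% causal$beta)
    }
    y <- if (config$family == "linear") {
      eta + rnorm(n, 0, config$sigma)
    } else {
      out <- rbinom(n, 1, 1 / (1 + exp(-eta)))
      if (length(unique(out)) == 1L) {
        # recenter once, then give up
        out <- rbinom(n, 1, 1 / (1 + exp(-(eta - mean(eta)))))
        if (length(unique(out)) == 1L)
          fu_stop("degenerate binary outcome; adjust the intercept")
      }
      out
    }
    tab <- data.frame(sample_id = rownames(genotypes$dosage), y = y,
                      sex = sex, age = age, cohort = cohort, mds,
                      stringsAsFactors = FALSE)
    ph <- phenotype_table(tab, "y",
                          if (config$family == "linear") "linear" else "logistic")
    attr(ph, "eta") <- eta
    ph
  })
}

#' Simulate a complete study with known ground truth
#'
#' Chains [simulate_genotypes()], [simulate_scores()] (picking
#' `causal_per_fu` causal members per FU with alternating effect signs) and
#' [simulate_phenotype()], then runs [build_fu_sets()] on the simulated
#' scores.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_study`: `genotypes`, `phenotypes`, `scores`,
#'   `backgrounds`, `fu_sets`, `truth` (causal triples, memberships,
#'   covariate coefficients), `config`.
#' @export
simulate_study <- function(config = sim_config()) {
  geno <- simulate_genotypes(config)
  sc <- simulate_scores(config, geno$variants)
  causal <- NULL
  if (config$causal_per_fu > 0L && nrow(sc$memberships)) {
    pick_seed <- child_seeds(config$seed, 4L)[4L]
    causal <- with_seed(pick_seed, {
      by_fu <- split(sc$memberships$variant_id, sc$memberships$fu_id)
      rows <- lapply(names(by_fu), function(fu) {
        v <- sort(sample(by_fu[[fu]], config$causal_per_fu))
        data.frame(variant_id = v, fu_id = fu,
                   beta = config$causal_beta *
                     rep_len(c(1, -1), length(v)),
                   stringsAsFactors = FALSE)
      })
      do.call(rbind, rows)
    })
  }
  causal_unique <- if (is.null(causal)) NULL else
    causal[!duplicated(causal$variant_id), c("variant_id", "beta")]
  ph <- simulate_phenotype(geno, config, causal_unique)
  sets <- suppressWarnings(build_fu_sets(sc$scores, sc$backgrounds,
                                         cutoff = config$evalue_cutoff))
  structure(list(genotypes = geno, phenotypes = ph, scores = sc$scores,
                 backgrounds = sc$backgrounds, fu_sets = sets,
                 truth = list(causal = causal, memberships = sc$memberships,
                              covar_coefs = config$covar_coefs),
                 config = config),
            class = "sim_study")
}

#' @export
print.sim_study <- function(x, ...) {
  cat(sprintf("sim_study: %d samples, %d variants, %d FUs, %d causal rows\n",
              nrow(x$genotypes$dosage), ncol(x$genotypes$dosage),
              length(x$fu_sets$sets),
              if (is.null(x$truth$causal)) 0L else nrow(x$truth$causal)))
  invisible(x)
}

#' Write a simulated study bundle to disk
#'
#' Emits the plain-text input bundle every reader in the package accepts:
#' dosage TSV, phenotype TSV, score TSV, background TSV and a ground-truth
#' JSON. Intended for small configurations (the background TSV holds
#' `n_fus * background_n` rows).
#'
#' @param study a [simulate_study()] result.
#' @param dir output directory (created if absent).
#' @return named vector of file paths, invisibly.
#' @export
write_study <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(genotypes = file.path(dir, "genotypes.tsv"),
             phenotypes = file.path(dir, "phenotypes.tsv"),
             scores = file.path(dir, "scores.tsv"),
             backgrounds = file.path(dir, "backgrounds.tsv"),
             truth = file.path(dir, "truth.json"))
  write_dosage_tsv(study$genotypes, paths["genotypes"])
  write.table(as.data.frame(study$phenotypes), paths["phenotypes"],
              sep = "\t", quote = FALSE, row.names = FALSE, na = ".")
  write.table(study$scores, paths["scores"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  bg <- do.call(rbind, lapply(study$backgrounds, function(b)
    data.frame(fu_id = b$fu_id, effect = b$effects)))
  write.table(bg, paths["backgrounds"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(study$truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
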