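#' Encode genotype probabilities as an allele dosage
#'
#' Computes the additive-model dosage `2 * p_hom_alt + p_het`, the expected
#' count of the alternative (minor) allele given genotype probabilities, and
#' clips the result to `[0, 2]`.
#'
#' @param p_hom_alt probability of the homozygous-alternative genotype
#'   (vectorized).
#' @param p_het probability of the heterozygous genotype.
#' @param tol tolerance for probability-sum validation.
#' @param id optional variant/sample label used in error messages.
#' @return numeric dosage vector in `[0, 2]`.
#' @export
#' @examples
#' encode_dosage(1, 0)       # certain homozygote -> 2
#' encode_dosage(0.25, 0.5)  # -> 1
encode_dosage <- function(p_hom_alt, p_het, tol = 1e-6, id = NULL) {
  bad <- which(p_hom_alt < -tol | p_het < -tol | p_hom_alt + p_het > 1 + tol)
  if (length(bad)) {
    where <- if (is.null(id)) paste(head(bad, 3L), collapse = ", ") else
      paste(head(id[bad], 3L), collapse = ", ")
    fu_stop("invalid genotype probabilities (negative or sum > 1) at: %s", where)
  }
  pmin(2, pmax(0, 2 * p_hom_alt + p_het))
}

#' Construct a genotype dosage matrix
#'
#' Bundles a samples x variants dosage matrix with its variant table. Dosages
#' must lie in `[0, 2]`; missing values are allowed and flagged.
#'
#' @param dosage numeric matrix, rows = samples, columns = variants; must
#'   carry row and column names.
#' @param variants data frame with columns `id`, `chrom`, `pos`, `ref`, `alt`;
#'   `id` must match `colnames(dosage)`.
#' @return an object of class `genotype_matrix` with elements `dosage` and
#'   `variants`.
#' @export
genotype_matrix <- function(dosage, variants) {
  stopifnot(is.matrix(dosage), is.data.frame(variants))
  need <- c("id", "chrom", "pos", "ref", "alt")
  miss <- setdiff(need, names(variants))
  if (length(miss)) fu_stop("variant table lacks columns: %s", paste(miss, collapse = ", "))
  if (anyDuplicated(variants$id)) fu_stop("duplicate variant ids")
  if (is.null(rownames(dosage)) || is.null(colnames(dosage)))
    fu_stop("dosage matrix needs sample row names and variant column names")
  if (!identical(colnames(dosage), as.character(variants$id)))
    fu_stop("dosage column names do not match variant ids")
  if (any(variants$pos < 1)) fu_stop("variant positions must be >= 1")
  if (any(variants$ref == variants$alt)) fu_stop("ref and alt alleles must differ")
  rng <- range(dosage, na.rm = TRUE)
  if (rng[1] < -1e-9 || rng[2] > 2 + 1e-9)
    fu_stop("dosages outside [0, 2]: range %.4g..%.4g", rng[1], rng[2])
  variants$chrom <- as.character(variants$chrom)
  variants$pos <- as.integer(variants$pos)
  structure(list(dosage = dosage, variants = variants),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d variants\n",
              nrow(x$dosage), ncol(x$dosage)))
  nmiss <- sum(is.na(x$dosage))
  if (nmiss) cat(sprintf("  missing dosages: %d\n", nmiss))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Sample ids of a genotype matrix
#' @param geno a `genotype_matrix`.
#' @return character vector of sample ids.
#' @export
sample_ids <- function(geno) rownames(geno$dosage)

#' Read genotype dosages from VCF or a dosage TSV
#'
#' For VCF input the genotype representation is chosen per the imputed-data
#' convention: a `DS` dosage FORMAT field is used if present, else `GP`
#' genotype probabilities (converted via [encode_dosage()]), else hard `GT`
#' calls (alt-allele count). Multi-allelic records are rejected. For
#' `dosage_tsv` input the file has a header of sample ids and a first column
#' of variant ids formatted `chrom:pos:ref:alt` (or a plain id with companion
#' columns `chrom`, `pos`, `ref`, `alt`).
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"vcf"` or `"dosage_tsv"`.
#' @return a [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "dosage_tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) fu_stop("file not found: %s", path)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "dosage_tsv"
  }
  if (format == "vcf") read_genotypes_vcf(path) else read_genotypes_tsv(path)
}

read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (any(grepl(",", fix$ALT, fixed = TRUE)))
    fu_stop("multi-allelic VCF records not supported; split them upstream")
  ids <- fix$ID
  no_id <- is.na(ids) | ids == "."
  ids[no_id] <- paste(fix$CHROM, fix$POS, fix$REF, fix$ALT, sep = ":")[no_id]
  if (anyDuplicated(ids)) fu_stop("duplicate variant id in VCF: %s",
                                  ids[duplicated(ids)][1])
  fmt_keys <- unique(unlist(strsplit(v@gt[, "FORMAT"], ":", fixed = TRUE)))
  if ("DS" %in% fmt_keys) {
    ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  } else if ("GP" %in% fmt_keys) {
    gp <- vcfR::extract.gt(v, element = "GP")
    sp <- strsplit(gp, ",", fixed = TRUE)
    ok <- lengths(sp) == 3L
    if (!all(ok)) fu_stop("GP field without 3 probabilities at record %d",
                          which(!ok)[1])
    num <- matrix(as.numeric(unlist(sp)), ncol = 3L, byrow = TRUE)
    # GP order per VCF spec: P(ref/ref), P(ref/alt), P(alt/alt)
    ds <- matrix(encode_dosage(num[, 3L], num[, 2L],
                               id = rep(ids, times = ncol(gp))),
                 nrow = nrow(gp), dimnames = dimnames(gp))
  } else if ("GT" %in% fmt_keys) {
    gt <- vcfR::extract.gt(v, element = "GT")
    cnt <- function(g) {
      if (is.na(g)) return(NA_real_)
      al <- strsplit(g, "[/|]")[[1]]
      if (any(al == ".")) return(NA_real_)
      sum(al != "0")
    }
    ds <- matrix(vapply(gt, cnt, numeric(1)), nrow = nrow(gt),
                 dimnames = dimnames(gt))
  } else {
    fu_stop("VCF carries none of DS, GP or GT genotype representations")
  }
  rownames(ds) <- ids
  variants <- data.frame(id = ids, chrom = fix$CHROM, pos = as.integer(fix$POS),
                         ref = fix$REF, alt = fix$ALT,
                         stringsAsFactors = FALSE)
  genotype_matrix(t(ds), variants)
}

read_genotypes_tsv <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", na.strings = ".",
                    check.names = FALSE, stringsAsFactors = FALSE)
  id_col <- names(tab)[1]
  ids <- as.character(tab[[id_col]])
  if (anyDuplicated(ids)) fu_stop("duplicate variant id in %s", path)
  meta_cols <- intersect(c("chrom", "pos", "ref", "alt"), names(tab))
  sample_cols <- setdiff(names(tab), c(id_col, meta_cols))
  if (!length(sample_cols)) fu_stop("no sample columns in %s", path)
  m <- as.matrix(tab[, sample_cols, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (length(meta_cols) == 4L) {
    variants <- data.frame(id = ids, chrom = as.character(tab$chrom),
                           pos = as.integer(tab$pos), ref = tab$ref,
                           alt = tab$alt, stringsAsFactors = FALSE)
  } else {
    parts <- strsplit(ids, ":", fixed = TRUE)
    if (any(lengths(parts) != 4L))
      fu_stop("variant ids must be chrom:pos:ref:alt or provide chrom/pos/ref/alt columns")
    variants <- data.frame(id = ids,
                           chrom = vapply(parts, `[`, "", 1L),
                           pos = as.integer(vapply(parts, `[`, "", 2L)),
                           ref = vapply(parts, `[`, "", 3L),
                           alt = vapply(parts, `[`, "", 4L),
                           stringsAsFactors = FALSE)
  }
  genotype_matrix(t(m), variants)
}

#' Write a genotype matrix as a dosage TSV
#'
#' Emits the transposed layout read by [read_genotypes()]: one row per
#' variant, header = sample ids, missing dosages as `.`.
#'
#' @param geno a `genotype_matrix`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_dosage_tsv <- function(geno, path) {
  m <- t(geno$dosage)
  out <- data.frame(variant_id = rownames(m),
                    chrom = geno$variants$chrom, pos = geno$variants$pos,
                    ref = geno$variants$ref, alt = geno$variants$alt,
                    m, check.names = FALSE, stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = ".")
  invisible(path)
}

#' Build a phenotype/covariate table
#'
#' @param data data frame with one row per sample, a `sample_id` column, the
#'   outcome column, and any covariates (`sex`, `age`, `cohort`, `mds_1`...).
#' @param outcome name of the outcome column.
#' @param family `"logistic"` (binary 0/1 outcome) or `"linear"`.
#' @return object of class `phenotype_table` (a data frame with attributes
#'   `outcome` and `family`).
#' @export
phenotype_table <- function(data, outcome, family = c("logistic", "linear")) {
  family <- match.arg(family)
  stopifnot(is.data.frame(data))
  if (!"sample_id" %in% names(data)) fu_stop("data needs a sample_id column")
  if (!outcome %in% names(data)) fu_stop("outcome column '%s' not found", outcome)
  if (anyDuplicated(data$sample_id)) fu_stop("duplicate sample ids")
  y <- data[[outcome]]
  if (family == "logistic" && !all(y[!is.na(y)] %in% c(0, 1)))
    fu_stop("logistic family requires a binary 0/1 outcome")
  if (family == "linear" && !is.numeric(y))
    fu_stop("linear family requires a numeric outcome")
  data$sample_id <- as.character(data$sample_id)
  structure(data, class = c("phenotype_table", "data.frame"),
            outcome = outcome, family = family)
}

#' Read a phenotype/covariate TSV
#'
#' @param path tab-delimited file with a `sample_id` column; `.` denotes
#'   missing values.
#' @inheritParams phenotype_table
#' @return a [phenotype_table()].
#' @export
read_phenotypes <- function(path, outcome, family = c("logistic", "linear")) {
  tab <- read.table(path, header = TRUE, sep = "\t", na.strings = ".",
                    stringsAsFactors = FALSE)
  phenotype_table(tab, outcome, match.arg(family))
}

#' Align genotypes and phenotypes to their shared samples
#'
#' Restricts both inputs to the intersection of their sample ids, in the
#' genotype matrix's order, and reports how many samples were dropped from
#' each side. Idempotent.
#'
#' @param genotypes a `genotype_matrix`.
#' @param phenotypes a `phenotype_table`.
#' @return list with elements `genotypes` and `phenotypes`.
#' @export
align_samples <- function(genotypes, phenotypes) {
  gs <- sample_ids(genotypes)
  ps <- phenotypes$sample_id
  shared <- gs[gs %in% ps]
  if (length(shared) < 2L) fu_stop("fewer than 2 shared samples between genotypes and phenotypes")
  drop_g <- length(gs) - length(shared)
  drop_p <- length(ps) - length(shared)
  if (drop_g || drop_p)
    fu_log("align_samples: dropped %d genotype-only and %d phenotype-only samples; %d retained",
           drop_g, drop_p, length(shared))
  geno <- genotype_matrix(genotypes$dosage[shared, , drop = FALSE],
                          genotypes$variants)
  ph <- phenotypes[match(shared, ps), , drop = FALSE]
  rownames(ph) <- NULL
  ph <- structure(ph, class = class(phenotypes),
                  outcome = attr(phenotypes, "outcome"),
                  family = attr(phenotypes, "family"))
  list(genotypes = geno, phenotypes = ph)
}

#' Choose the number of ancestry components to carry as covariates
#'
#' Two conventions: `cumulative_80` takes the smallest k whose normalized
#' cumulative variance reaches 80%; `scree` (Cattell) takes the elbow,
#' operationalized as the largest drop between consecutive components (ties
#' broken toward fewer components).
#'
#' @param variance_explained nonnegative vector of per-component variances,
#'   in component order.
#' @param strategy `"cumulative_80"` or `"scree"`.
#' @return integer count of components to keep.
#' @export
#' @examples
#' select_ancestry_components(c(0.5, 0.3, 0.1, 0.1), "cumulative_80")  # 2
select_ancestry_components <- function(variance_explained,
                                       strategy = c("cumulative_80", "scree")) {
  strategy <- match.arg(strategy)
  v <- as.numeric(variance_explained)
  if (!length(v)) fu_stop("variance_explained is empty")
  if (any(v < 0)) fu_stop("variance_explained must be nonnegative")
  if (is.unsorted(rev(v), strictly = FALSE) && any(diff(v) > 0))
    fu_warn("variance_explained is not nonincreasing")
  if (strategy == "cumulative_80") {
    cum <- cumsum(v) / sum(v)
    return(which(cum >= 0.80)[1])
  }
  if (length(v) == 1L) return(1L)
  drops <- -diff(v)
  which.max(drops)  # first index of the maximal drop = smaller k on ties
}

#' Expand phenotype covariates into a numeric design block
#'
#' Builds the unpenalized covariate matrix used in every model: `sex` and
#' `age` as-is, `cohort` as K-1 indicator columns against the first-observed
#' level, and all `mds_*` columns.
#'
#' @param phenotypes a `phenotype_table`.
#' @param covariates covariate column names to use; default every available
#'   one of `sex`, `age`, `cohort`, `mds_*`.
#' @return numeric matrix with one row per sample (may have zero columns).
#' @export
covariate_matrix <- function(phenotypes, covariates = NULL) {
  std <- c("sex", "age", "cohort", grep("^mds_", names(phenotypes), value = TRUE))
  if (is.null(covariates)) covariates <- intersect(std, names(phenotypes))
  miss <- setdiff(covariates, names(phenotypes))
  if (length(miss)) fu_stop("covariates not in phenotype table: %s",
                            paste(miss, collapse = ", "))
  blocks <- lapply(covariates, function(cv) {
    x <- phenotypes[[cv]]
    if (cv == "cohort" || is.character(x) || is.factor(x)) {
      f <- factor(x, levels = unique(as.character(x)))
      if (nlevels(f) < 2L) return(NULL)
      mm <- model.matrix(~f)[, -1L, drop = FALSE]
      colnames(mm) <- paste0(cv, "_", levels(f)[-1L])
      mm
    } else {
      matrix(as.numeric(x), ncol = 1L, dimnames = list(NULL, cv))
    }
  })
  blocks <- Filter(Negate(is.null), blocks)
  if (!length(blocks))
    return(matrix(numeric(0), nrow = nrow(phenotypes), ncol = 0L))
  out <- do.call(cbind, blocks)
  rownames(out) <- phenotypes$sample_id
  out
}

# internal: mean-impute missing dosages per variant (imputed data are normally
# complete; this keeps design matrices dense when they are not)
impute_dosage <- function(dosage) {
  nmiss <- sum(is.na(dosage))
  if (nmiss == 0L) return(dosage)
  fu_log("mean-imputing %d missing dosages", nmiss)
  mu <- colMeans(dosage, na.rm = TRUE)
  idx <- which(is.na(dosage), arr.ind = TRUE)
  dosage[idx] <- mu[idx[, 2L]]
  dosage
}
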