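#' Molecular trait matrix (expression or methylation)
#'
#' @param values numeric matrix, rows = samples (named), columns = traits
#'   (named: genes or CpGs).
#' @param positions data frame `trait_id`, `chrom`, `pos` for every trait.
#' @param kind `"expression"` or `"methylation"`.
#' @return object of class `trait_matrix`.
#' @export
trait_matrix <- function(values, positions,
                         kind = c("expression", "methylation")) {
  kind <- match.arg(kind)
  stopifnot(is.matrix(values), is.data.frame(positions))
  if (!all(c("trait_id", "chrom", "pos") %in% names(positions)))
    fu_stop("positions need trait_id, chrom, pos")
  miss <- setdiff(colnames(values), positions$trait_id)
  if (length(miss)) fu_stop("traits without positions: %s",
                            paste(head(miss, 3L), collapse = ", "))
  positions <- positions[match(colnames(values), positions$trait_id), ]
  positions$chrom <- as.character(positions$chrom)
  structure(list(values = values, positions = positions, kind = kind),
            class = "trait_matrix")
}

#' Enumerate cis variant-trait pairs
#'
#' All same-chromosome pairs whose positions are within `window_bp` of each
#' other (boundary inclusive).
#'
#' @param variants data frame `id`, `chrom`, `pos` (e.g.
#'   `genotypes$variants`).
#' @param traits a [trait_matrix()] or a data frame `trait_id`, `chrom`,
#'   `pos`.
#' @param window_bp window in base pairs (default 1 Mb; 250 kb is the other
#'   common methylation convention).
#' @return data frame `variant_id`, `trait_id`, `distance`.
#' @export
cis_pairs <- function(variants, traits, window_bp = 1e6) {
  tp <- if (inherits(traits, "trait_matrix")) traits$positions else traits
  rows <- lapply(seq_len(nrow(variants)), function(i) {
    j <- which(tp$chrom == variants$chrom[i] &
                 abs(tp$pos - variants$pos[i]) <= window_bp)
    if (!length(j)) return(NULL)
    data.frame(variant_id = variants$id[i], trait_id = tp$trait_id[j],
               distance = tp$pos[j] - variants$pos[i],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  if (is.null(out))
    out <- data.frame(variant_id = character(0), trait_id = character(0),
                      distance = integer(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment with monotonicity enforcement; `q` lies in
#' `[p, 1]`.
#'
#' @param pvals p-values in `[0, 1]`.
#' @return q-values of the same length.
#' @export
bh_fdr <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    fu_stop("p-values must lie in [0, 1]")
  p.adjust(pvals, method = "BH")
}

#' Cis-window QTL scan
#'
#' For each (variant, trait) pair, a linear model of the trait on intercept,
#' covariates and dosage with a t-type test on the dosage term, followed by
#' BH adjustment across all tested pairs. Significance convention:
#' `fdr_q < 0.05`.
#'
#' @param pairs a [cis_pairs()] result (or any data frame `variant_id`,
#'   `trait_id`, optionally `distance`).
#' @param genotypes a [genotype_matrix()].
#' @param traits a [trait_matrix()]; samples are aligned to the genotype
#'   matrix by row name.
#' @param covars optional covariate matrix (rows matching genotype samples).
#' @param fdr significance threshold on q (default 0.05).
#' @return data frame of `qtl_records`: `variant_id`, `trait_id`, `beta`,
#'   `se`, `p`, `fdr_q`, `distance`, `significant`.
#' @export
qtl_scan <- function(pairs, genotypes, traits, covars = NULL, fdr = 0.05) {
  stopifnot(inherits(traits, "trait_matrix"))
  shared <- intersect(sample_ids(genotypes), rownames(traits$values))
  if (length(shared) < 10L) fu_stop("fewer than 10 shared samples for the QTL scan")
  dosage <- impute_dosage(genotypes$dosage[shared, , drop = FALSE])
  tv <- traits$values[shared, , drop = FALSE]
  cv <- if (!is.null(covars)) as.matrix(covars)[shared, , drop = FALSE] else NULL
  rows <- lapply(seq_len(nrow(pairs)), function(k) {
    v <- pairs$variant_id[k]; t <- pairs$trait_id[k]
    if (!v %in% colnames(dosage) || !t %in% colnames(tv)) return(NULL)
    yt <- tv[, t]
    if (sd(yt, na.rm = TRUE) == 0) {
      fu_log("qtl_scan: constant trait %s skipped", t)
      return(NULL)
    }
    st <- tryCatch(univariate_assoc(dosage[, v], yt, cv, "linear"),
                   error = function(e) NULL)
    if (is.null(st)) return(NULL)
    data.frame(variant_id = v, trait_id = t, beta = st$beta, se = st$se,
               p = st$p,
               distance = if ("distance" %in% names(pairs)) pairs$distance[k]
                          else NA_integer_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  if (is.null(out)) fu_stop("no testable pair")
  out$fdr_q <- bh_fdr(out$p)
  out$significant <- !is.na(out$fdr_q) & out$fdr_q < fdr
  rownames(out) <- NULL
  out
}

#' Permutation enrichment of dSNPs in an annotation set
#'
#' Counts the dSNPs whose proxy-expanded set intersects the annotation, and
#' compares against `n_perm` equally-sized variant sets drawn without
#' replacement from the regulatory universe (each proxy-expanded the same
#' way). Fold = observed / mean(null); the p-value uses the add-one
#' estimator `(1 + #\{null >= observed\}) / (1 + n_perm)`, so it is never
#' exactly zero.
#'
#' @param dsnps character vector of selected variant ids (must lie in
#'   `universe`).
#' @param universe character vector: the regulatory variant pool.
#' @param annotation character vector of annotated variant ids.
#' @param proxies optional proxy map ([find_proxies()] data frame); `NULL`
#'   means no expansion.
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed.
#' @return object of class `enrichment_result`: `observed`, `null_mean`,
#'   `fold`, `p`, `n_perm`, `n_sets`.
#' @export
permutation_enrichment <- function(dsnps, universe, annotation,
                                   proxies = NULL, n_perm = 1000, seed = 1L) {
  dsnps <- unique(dsnps); universe <- unique(universe)
  if (!all(dsnps %in% universe)) fu_stop("dsnps must be a subset of the universe")
  if (n_perm < 100) fu_stop("n_perm must be >= 100")
  if (length(universe) < length(dsnps)) fu_stop("universe smaller than the dSNP set")
  ann <- unique(annotation)
  expand <- if (is.null(proxies)) {
    function(v) v
  } else {
    prox_by_target <- split(proxies$proxy_id, proxies$target_id)
    function(v) unique(c(v, unlist(prox_by_target[v], use.names = FALSE)))
  }
  # per-variant hit indicator precomputed once over the universe: a variant
  # "hits" if itself or any proxy is annotated
  hits <- vapply(universe, function(v) any(expand(v) %in% ann), logical(1))
  observed <- sum(hits[dsnps])
  k <- length(dsnps)
  null_counts <- with_seed(seed, vapply(seq_len(n_perm), function(i)
    sum(hits[sample.int(length(universe), k)]), numeric(1)))
  null_mean <- mean(null_counts)
  fold <- if (null_mean > 0) observed / null_mean else {
    fu_warn("null mean overlap is zero; fold reported as Inf")
    if (observed > 0) Inf else NaN
  }
  p <- (1 + sum(null_counts >= observed)) / (1 + n_perm)
  structure(list(observed = observed, null_mean = null_mean, fold = fold,
                 p = p, n_perm = n_perm, n_sets = k, seed = seed),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("enrichment: observed %d / null mean %.2f = %.2f-fold, permutation p = %.4g (%d permutations of %d-variant sets)\n",
              x$observed, x$null_mean, x$fold, x$p, x$n_perm, x$n_sets))
  invisible(x)
}

#' Write QTL records as TSV
#' @param records a [qtl_scan()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_qtl_records <- function(records, path) {
  write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an enrichment result as JSON
#' @param result an [permutation_enrichment()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_enrichment_json <- function(result, path) {
  jsonlite::write_json(unclass(result), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
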