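#' Pairwise linkage disequilibrium from dosages
#'
#' Squared Pearson correlation of dosage vectors (composite LD; no phasing
#' assumed).
#'
#' @param x_a,x_b dosage vectors of equal length >= 3.
#' @return r-squared in `[0, 1]`, or `NA` (with a warning) for a constant
#'   vector.
#' @export
#' @examples
#' ld_r2(c(0, 1, 2, 0), c(0, 1, 1, 0))  # 0.9
ld_r2 <- function(x_a, x_b) {
  stopifnot(length(x_a) == length(x_b), length(x_a) >= 3L)
  if (sd(x_a, na.rm = TRUE) == 0 || sd(x_b, na.rm = TRUE) == 0) {
    fu_warn("constant dosage vector: LD undefined")
    return(NA_real_)
  }
  cor(x_a, x_b, use = "complete.obs")^2
}

# internal: minor allele frequency from dosages
maf_of <- function(x) {
  f <- mean(x, na.rm = TRUE) / 2
  min(f, 1 - f)
}

#' Windowed LD pruning of a genotype matrix
#'
#' Greedy sliding-window pruning in the indep-pairwise style: within each
#' window of `window_snps` consecutive variants (per chromosome,
#' position-sorted), every pair with r-squared strictly above `r2_thresh`
#' loses its lower-MAF member (ties: the later-position variant is removed);
#' the window then slides by `step` variants. On return no surviving
#' within-window pair exceeds the threshold. The window is counted in SNPs,
#' the command's native unit.
#'
#' @param genotypes a [genotype_matrix()].
#' @param window_snps window size in variants (default 50).
#' @param step slide in variants (default 5).
#' @param r2_thresh strict r-squared threshold (default 0.5).
#' @param sort_variants if variants are not position-sorted, sort them with
#'   a warning (`TRUE`, default) or error (`FALSE`).
#' @return character vector of kept variant ids (a subset of the input, in
#'   input order).
#' @export
ld_prune <- function(genotypes, window_snps = 50, step = 5, r2_thresh = 0.5,
                     sort_variants = TRUE) {
  v <- genotypes$variants
  ord <- order(v$chrom, v$pos)
  if (!identical(ord, seq_len(nrow(v)))) {
    if (!sort_variants) fu_stop("variants are not position-sorted")
    fu_warn("variants not position-sorted; sorting for pruning")
  }
  dosage <- impute_dosage(genotypes$dosage)
  removed <- character(0)
  for (chr in unique(v$chrom)) {
    ids <- v$id[ord][v$chrom[ord] == chr]
    if (length(ids) < 2L) next
    mafs <- vapply(ids, function(i) maf_of(dosage[, i]), numeric(1))
    start <- 1L
    repeat {
      win <- ids[start:min(start + window_snps - 1L, length(ids))]
      win <- setdiff(win, removed)
      if (length(win) >= 2L) {
        repeat {
          dropped <- FALSE
          for (a in seq_len(length(win) - 1L)) {
            for (b in (a + 1L):length(win)) {
              r2 <- suppressWarnings(ld_r2(dosage[, win[a]], dosage[, win[b]]))
              if (!is.na(r2) && r2 > r2_thresh) {
                # remove the lower-MAF member; on a tie the later position
                loser <- if (mafs[win[a]] < mafs[win[b]]) win[a] else
                  if (mafs[win[b]] < mafs[win[a]]) win[b] else win[b]
                removed <- c(removed, loser)
                win <- setdiff(win, loser)
                dropped <- TRUE
                break
              }
            }
            if (dropped) break
          }
          if (!dropped || length(win) < 2L) break
        }
      }
      if (start + window_snps - 1L >= length(ids)) break
      start <- start + step
    }
  }
  setdiff(v$id, removed)
}

#' Find LD proxies for target variants
#'
#' For each target, every variant in the genotype matrix on the same
#' chromosome within `window_bp` whose r-squared with the target is at least
#' `r2_thresh` (inclusive). A variant is always its own proxy (r2 = 1);
#' targets absent from the matrix get a logged self-only entry.
#'
#' @param targets character vector of target variant ids.
#' @param genotypes a [genotype_matrix()] providing the proxy universe.
#' @param r2_thresh inclusive threshold (default 0.5).
#' @param window_bp search distance in base pairs (default 1 Mb).
#' @return data frame (`proxy_map`): `target_id`, `proxy_id`, `r2`.
#' @export
find_proxies <- function(targets, genotypes, r2_thresh = 0.5,
                         window_bp = 1e6) {
  v <- genotypes$variants
  dosage <- impute_dosage(genotypes$dosage)
  rows <- lapply(unique(targets), function(t) {
    self <- data.frame(target_id = t, proxy_id = t, r2 = 1,
                       stringsAsFactors = FALSE)
    i <- match(t, v$id)
    if (is.na(i)) {
      fu_log("find_proxies: target %s absent from genotype matrix; self-only", t)
      return(self)
    }
    near <- which(v$chrom == v$chrom[i] & abs(v$pos - v$pos[i]) <= window_bp &
                    v$id != t)
    if (!length(near)) return(self)
    r2 <- vapply(near, function(j)
      suppressWarnings(ld_r2(dosage[, i], dosage[, j])), numeric(1))
    hit <- which(!is.na(r2) & r2 >= r2_thresh)
    if (!length(hit)) return(self)
    rbind(self, data.frame(target_id = t, proxy_id = v$id[near[hit]],
                           r2 = r2[hit], stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("proxy_map", "data.frame")
  out
}

#' Write a proxy map as TSV
#' @param proxies a [find_proxies()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_proxy_map <- function(proxies, path) {
  write.table(proxies, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
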