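# Fixture builders shared across test files. Everything is generated in code;
# no binary data.

# tiny deterministic genotype matrix with explicit coordinates
tiny_genotypes <- function() {
  dosage <- rbind(
    sample_1 = c(0, 1, 2, 0.5, 1.3),
    sample_2 = c(1, 1, 0, 1.5, 0.0),
    sample_3 = c(2, 0, 1, 0.2, 1.9),
    sample_4 = c(0, 2, 1, 1.0, 0.4)
  )
  colnames(dosage) <- paste0("rs", 1:5)
  variants <- data.frame(id = paste0("rs", 1:5), chrom = c("1", "1", "1", "2", "2"),
                         pos = c(100L, 5000L, 900000L, 100L, 2000L),
                         ref = "A", alt = "G", stringsAsFactors = FALSE)
  genotype_matrix(dosage, variants)
}

tiny_phenotypes <- function(family = "logistic") {
  df <- data.frame(sample_id = paste0("sample_", 1:4),
                   y = if (family == "logistic") c(0, 1, 0, 1) else c(0.2, 1.4, -0.3, 2.2),
                   sex = c(0, 1, 1, 0), age = c(30, 45, 52, 38),
                   cohort = c("a", "a", "b", "b"),
                   mds_1 = c(0.1, -0.2, 0.05, 0.3),
                   stringsAsFactors = FALSE)
  phenotype_table(df, "y", family)
}

# write a minimal single-sample-block VCF; `mode` picks the genotype field
write_tiny_vcf <- function(path, mode = c("DS", "GP", "GT")) {
  mode <- match.arg(mode)
  hdr <- c("##fileformat=VCFv4.2",
           sprintf('##FORMAT=<ID=%s,Number=.,Type=%s,Description="x">',
                   mode, if (mode == "GT") "String" else "Float"),
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", "FORMAT", "s1", "s2", "s3", sep = "\t"))
  body <- switch(mode,
    DS = c("1\t100\trs1\tA\tG\t.\t.\t.\tDS\t1.3\t0.0\t2.0",
           "1\t200\trs2\tC\tT\t.\t.\t.\tDS\t0.5\t1.0\t0.2"),
    GP = c("1\t100\trs1\tA\tG\t.\t.\t.\tGP\t0.25,0.50,0.25\t1,0,0\t0,0,1",
           "1\t200\trs2\tC\tT\t.\t.\t.\tGP\t0.1,0.8,0.1\t0.5,0.5,0\t0,1,0"),
    GT = c("1\t100\trs1\tA\tG\t.\t.\t.\tGT\t0/1\t0/0\t1/1",
           "1\t200\trs2\tC\tT\t.\t.\t.\tGT\t1|1\t0/1\t./."))
  writeLines(c(hdr, body), path)
  path
}

# quick simulated study used by several tests
small_study <- function(seed = 7, n = 300, causal_beta = 0.8,
                        background_n = 2000) {
  cfg <- sim_config(n_samples = n, n_blocks = 5, snps_per_block = 10,
                    n_fus = 5, snps_per_fu = 10, causal_per_fu = 1,
                    causal_beta = causal_beta, background_n = background_n,
                    family = "logistic", seed = seed)
  suppressWarnings(simulate_study(cfg))
}

# independent brute-force BH step-up: q_(i) = min(1, min_{j>=i} p_(j) * m / j)
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  out <- numeric(m)
  out[o] <- vapply(seq_len(m), function(i) min(1, min(ps[i:m] * m / (i:m))),
                   numeric(1))
  out
}

# independent brute-force AUC: all case-control pairs, ties count half
brute_auc <- function(scores, labels) {
  cases <- scores[labels == 1]; ctrls <- scores[labels == 0]
  tot <- 0
  for (a in cases) for (b in ctrls) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(cases) * length(ctrls))
}

# brute-force within-window LD check used to verify pruning output
windows_clean <- function(geno, kept, window_snps, r2_thresh) {
  v <- geno$variants[geno$variants$id %in% kept, ]
  for (chr in unique(v$chrom)) {
    ids <- v$id[v$chrom == chr][order(v$pos[v$chrom == chr])]
    # kept variants occupying the same original window must all be below
    # the threshold pairwise; scan every contiguous run of window size
    all_ids <- geno$variants$id[geno$variants$chrom == chr]
    all_ids <- all_ids[order(geno$variants$pos[geno$variants$chrom == chr])]
    for (start in seq_len(max(1, length(all_ids) - window_snps + 1))) {
      win <- all_ids[start:min(start + window_snps - 1, length(all_ids))]
      wk <- intersect(win, kept)
      if (length(wk) < 2) next
      for (a in seq_len(length(wk) - 1)) for (b in (a + 1):length(wk)) {
        r2 <- suppressWarnings(ld_r2(geno$dosage[, wk[a]], geno$dosage[, wk[b]]))
        if (!is.na(r2) && r2 > r2_thresh) return(FALSE)
      }
    }
  }
  TRUE
}
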