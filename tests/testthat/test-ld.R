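test_that("dosage LD equals squared Pearson correlation and is symmetric", {
  expect_equal(ld_r2(c(0, 1, 2, 0), c(0, 1, 2, 0)), 1)
  expect_equal(ld_r2(c(0, 1, 2, 0), 2 - c(0, 1, 2, 0)), 1)  # perfect negative
  # hand computation: cov = 1.5, var_a = 2.75, var_b = 1 -> r^2 = 0.8182
  expect_equal(ld_r2(c(0, 1, 2, 0), c(0, 1, 1, 0)), 1.5^2 / 2.75,
               tolerance = 1e-12)
  set.seed(111)
  a <- rbinom(50, 2, 0.3); b <- rbinom(50, 2, 0.4)
  expect_equal(ld_r2(a, b), ld_r2(b, a))
  expect_warning(r <- ld_r2(rep(1, 10), rbinom(10, 2, 0.5)), "constant")
  expect_true(is.na(r))
})

test_that("pruning removes duplicates, keeps independents, and clears every window", {
  # duplicate pair: exactly one kept, the earlier position on the MAF tie
  dup <- matrix(rep(c(0, 1, 2, 1, 0, 2, 1, 1), 2), ncol = 2,
                dimnames = list(paste0("s", 1:8), c("a", "b")))
  gd <- genotype_matrix(dup, data.frame(id = c("a", "b"), chrom = "1",
                                        pos = c(100L, 200L), ref = "A", alt = "G"))
  expect_identical(ld_prune(gd), "a")
  # mutually uncorrelated variants all survive
  set.seed(112)
  ind <- sapply(1:6, function(i) rbinom(400, 2, 0.4))
  colnames(ind) <- paste0("v", 1:6); rownames(ind) <- paste0("s", 1:400)
  gi <- genotype_matrix(ind, data.frame(id = paste0("v", 1:6), chrom = "1",
                                        pos = seq(100L, 600L, 100L),
                                        ref = "A", alt = "G"))
  expect_setequal(ld_prune(gi), paste0("v", 1:6))
  # crafted 20-variant LD fixture verified by exhaustive window scan
  cfg <- sim_config(n_samples = 500, n_blocks = 2, snps_per_block = 10,
                    rho = 0.9, n_fus = 0, snps_per_fu = 1, causal_per_fu = 0,
                    seed = 5)
  g20 <- simulate_genotypes(cfg)
  kept <- ld_prune(g20, window_snps = 10, step = 2, r2_thresh = 0.5)
  expect_true(length(kept) < 20)
  expect_true(all(kept %in% g20$variants$id))
  expect_true(windows_clean(g20, kept, 10, 0.5))
  # idempotent: pruning the pruned set changes nothing
  gk <- genotype_matrix(g20$dosage[, kept, drop = FALSE],
                        g20$variants[g20$variants$id %in% kept, ])
  expect_setequal(ld_prune(gk, window_snps = 10, step = 2, r2_thresh = 0.5),
                  kept)
})

test_that("proxy search is windowed, inclusive at the threshold, and self-containing", {
  set.seed(113)
  base <- rbinom(600, 2, 0.3)
  d <- cbind(t1 = base, p_same = base,
             p_far = base,                      # same haplotype but 2 Mb away
             p_unrelated = rbinom(600, 2, 0.3))
  rownames(d) <- paste0("s", 1:600)
  v <- data.frame(id = colnames(d), chrom = "1",
                  pos = c(1000000L, 1010000L, 3200000L, 1020000L),
                  ref = "A", alt = "G")
  g <- genotype_matrix(d, v)
  pm <- find_proxies("t1", g, r2_thresh = 0.5, window_bp = 1e6)
  expect_true(all(c("t1", "p_same") %in% pm$proxy_id))
  expect_false("p_far" %in% pm$proxy_id)        # outside the window
  expect_false("p_unrelated" %in% pm$proxy_id)  # below threshold
  expect_equal(pm$r2[pm$proxy_id == "t1"], 1)
  # brute-force r2 scan over a crafted block
  cfg <- sim_config(n_samples = 400, n_blocks = 1, snps_per_block = 5,
                    rho = 0.8, n_fus = 0, snps_per_fu = 1, causal_per_fu = 0,
                    seed = 6)
  gb <- simulate_genotypes(cfg)
  t <- gb$variants$id[1]
  pm2 <- find_proxies(t, gb)
  brute <- c(t, gb$variants$id[-1][vapply(gb$variants$id[-1], function(v)
    suppressWarnings(ld_r2(gb$dosage[, t], gb$dosage[, v])) >= 0.5,
    logical(1))])
  expect_setequal(pm2$proxy_id, brute)
  # absent target: logged self-only entry
  expect_message(pm3 <- find_proxies("ghost", gb), "self-only")
  expect_identical(pm3$proxy_id, "ghost")
})

test_that("adjacent-pair LD rises with the simulator's rho", {
  r2_mean <- function(rho, seed) {
    cfg <- sim_config(n_samples = 2000, n_blocks = 2, snps_per_block = 10,
                      rho = rho, n_fus = 0, snps_per_fu = 1,
                      causal_per_fu = 0, seed = seed)
    g <- simulate_genotypes(cfg)
    v <- g$variants
    mean(unlist(lapply(split(v$id, sub("_[0-9]+$", "", v$id)), function(ids) {
      vapply(seq_len(length(ids) - 1), function(j)
        ld_r2(g$dosage[, ids[j]], g$dosage[, ids[j + 1]]), numeric(1))
    })))
  }
  m0 <- r2_mean(0, 7); m5 <- r2_mean(0.5, 7); m95 <- r2_mean(0.95, 7)
  expect_lt(m0, 0.02)   # independence limit
  # thresholding the latent Gaussian attenuates r^2 below the latent rho^2,
  # so 0.95 latent correlation yields dosage r^2 well under 0.9
  expect_gt(m95, 0.35)  # strong LD induction
  expect_true(m0 < m5 && m5 < m95)
})
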