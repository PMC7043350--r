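test_that("dosage encoding follows the additive-model formula and validates inputs", {
  expect_equal(encode_dosage(1.0, 0.0), 2.0)
  expect_equal(encode_dosage(0.0, 0.0), 0.0)
  expect_equal(encode_dosage(0.25, 0.50), 1.0)
  expect_equal(encode_dosage(c(0.1, 0.4), c(0.2, 0.2)), c(0.4, 1.0))
  expect_error(encode_dosage(-0.1, 0.5), "invalid genotype probabilities")
  expect_error(encode_dosage(0.8, 0.5), "invalid genotype probabilities")
  # clipping keeps tolerated rounding inside [0, 2]
  expect_lte(encode_dosage(1 + 1e-7, 0), 2)
})

test_that("VCF genotype representations are read with dosage > probabilities > hard calls priority", {
  for (mode in c("DS", "GP", "GT")) {
    path <- withr::local_tempfile(fileext = ".vcf")
    write_tiny_vcf(path, mode)
    g <- read_genotypes(path, "vcf")
    expect_s3_class(g, "genotype_matrix")
    expect_equal(dim(g), c(3L, 2L))
    expect_identical(g$variants$id, c("rs1", "rs2"))
  }
  path <- withr::local_tempfile(fileext = ".vcf")
  write_tiny_vcf(path, "DS")
  g <- read_genotypes(path, "vcf")
  expect_equal(unname(g$dosage["s1", "rs1"]), 1.3)  # DS passes through
  write_tiny_vcf(path, "GP")
  g <- read_genotypes(path, "vcf")
  expect_equal(unname(g$dosage["s1", "rs1"]), 2 * 0.25 + 0.5)
  write_tiny_vcf(path, "GT")
  g <- read_genotypes(path, "vcf")
  expect_equal(unname(g$dosage["s1", "rs1"]), 1)    # 0/1 het
  expect_equal(unname(g$dosage["s1", "rs2"]), 2)    # 1|1 phased hom
  expect_true(is.na(g$dosage["s3", "rs2"]))         # ./. missing
})

test_that("dosage TSV round-trips through write and read to 6 decimals", {
  g <- tiny_genotypes()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_dosage_tsv(g, path)
  g2 <- read_genotypes(path, "dosage_tsv")
  expect_equal(g2$dosage, g$dosage, tolerance = 1e-6)
  expect_identical(g2$variants$id, g$variants$id)
  expect_identical(g2$variants$pos, g$variants$pos)
  # hand-written 3-sample, 2-variant fixture parsed field by field
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("variant_id\ts1\ts2\ts3",
               "1:100:A:G\t0\t1.5\t.",
               "1:200:C:T\t2\t0.25\t1"), tsv)
  g3 <- read_genotypes(tsv)
  expect_equal(dim(g3), c(3L, 2L))
  expect_equal(unname(g3$dosage[, "1:100:A:G"]), c(0, 1.5, NA))
  expect_equal(g3$variants$pos, c(100L, 200L))
  expect_equal(g3$variants$ref, c("A", "C"))
})

test_that("construction rejects out-of-range dosages and duplicate ids", {
  d <- matrix(c(0, 1, 2, 3), 2, 2,
              dimnames = list(c("a", "b"), c("v1", "v2")))
  v <- data.frame(id = c("v1", "v2"), chrom = "1", pos = c(1L, 2L),
                  ref = "A", alt = "G")
  expect_error(genotype_matrix(d, v), "outside")
  d[2, 2] <- 1
  expect_silent(genotype_matrix(d, v))
  v2 <- v; v2$id <- c("v1", "v1"); colnames(d) <- c("v1", "v1")
  expect_error(genotype_matrix(d, v2), "duplicate")
})

test_that("sample alignment intersects, reorders, logs drops, and is idempotent", {
  g <- tiny_genotypes()
  ph <- tiny_phenotypes()
  ph2 <- ph[c(3, 1, 2), ]
  ph2$sample_id <- c("sample_3", "sample_1", "sample_9")
  ph2 <- phenotype_table(ph2, "y", "logistic")
  expect_message(al <- align_samples(g, ph2), "dropped")
  expect_identical(sample_ids(al$genotypes), c("sample_1", "sample_3"))
  expect_identical(al$phenotypes$sample_id, c("sample_1", "sample_3"))
  al2 <- align_samples(al$genotypes, al$phenotypes)
  expect_identical(al2$genotypes$dosage, al$genotypes$dosage)
  expect_identical(al2$phenotypes$sample_id, al$phenotypes$sample_id)
  # disjoint sets error
  ph3 <- ph; ph3$sample_id <- paste0("x", 1:4)
  ph3 <- phenotype_table(ph3, "y", "logistic")
  expect_error(align_samples(g, ph3), "shared")
})

test_that("ancestry-component selection implements both conventions", {
  expect_equal(select_ancestry_components(c(0.5, 0.3, 0.1, 0.1), "cumulative_80"), 2L)
  expect_equal(select_ancestry_components(c(1.0), "cumulative_80"), 1L)
  expect_equal(select_ancestry_components(c(0.4, 0.39, 0.01, 0.01), "scree"), 2L)
  # largest-drop oracle by exhaustive scan on random nonincreasing vectors
  set.seed(42)
  for (i in 1:20) {
    v <- sort(runif(sample(3:8, 1)), decreasing = TRUE)
    drops <- v[-length(v)] - v[-1]
    expect_equal(select_ancestry_components(v, "scree"),
                 which(drops == max(drops))[1])
    cum <- cumsum(v) / sum(v)
    expect_equal(select_ancestry_components(v, "cumulative_80"),
                 which(cum >= 0.8)[1])
  }
  expect_error(select_ancestry_components(numeric(0)), "empty")
  expect_warning(select_ancestry_components(c(0.1, 0.5), "cumulative_80"),
                 "nonincreasing")
})

test_that("covariate matrix expands cohort to reference-coded indicators", {
  ph <- tiny_phenotypes()
  cm <- covariate_matrix(ph)
  expect_true(all(c("sex", "age", "cohort_b", "mds_1") %in% colnames(cm)))
  expect_equal(unname(cm[, "cohort_b"]), c(0, 0, 1, 1))
  expect_error(covariate_matrix(ph, "bmi"), "not in phenotype table")
})
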