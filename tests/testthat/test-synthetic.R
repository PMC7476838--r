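test_that("simulation is deterministic given seed and truth", {
  truth <- small_truth(seed = 13L)
  a <- simulate_cohort(truth)
  b <- simulate_cohort(truth)
  expect_identical(a$pileup, b$pileup)
  c <- simulate_cohort(truth, seed = 14L)
  expect_false(identical(a$pileup, c$pileup))
  expect_identical(a$tumor_variants, c$tumor_variants)
})

test_that("generated tables satisfy every allele-count invariant", {
  ds <- simulate_cohort(small_truth(seed = 2L, n_error_sites = 80))
  pu <- ds$pileup
  expect_silent(validate_pileup(pu))
  expect_true(all(pu$alt_reads <= pu$depth))
  expect_true(all(pu$alt_fwd + pu$alt_rev == pu$alt_reads))
  expect_true(all(pu$alt_artifact_reads <= pu$alt_reads))
  expect_true(all(pu$role %in% c("cfdna", "buffy_matched", "tumor")))
  # every sample is genotyped at every non-tumor site
  n_sites <- nrow(ds$sites)
  per_sample <- table(pu$sample_id[pu$role != "tumor"])
  expect_true(all(per_sample == n_sites))
})

test_that("counts follow the binomial shedding model", {
  set.seed(501)
  # no error, VAF 0.10, fixed depth 1000: alt ~ Binomial(1000, 0.10)
  x <- simulate_allele_counts(2000, 1000, 0.10)
  se <- sqrt(1000 * 0.1 * 0.9) / sqrt(2000)
  expect_lt(abs(mean(x$alt_reads) - 100), 3 * se)
  expect_true(all(x$depth == 1000))
  # all-zero truth and zero error: no alt reads anywhere
  x0 <- simulate_allele_counts(200, 1500, 0)
  expect_true(all(x0$alt_reads == 0))
  # germline heterozygote concentrates near 0.5
  xh <- simulate_allele_counts(500, 1000, 0.5)
  se_h <- sqrt(0.5 * 0.5 / 1000 / 500)
  expect_lt(abs(mean(xh$alt_reads / xh$depth) - 0.5), 3 * se_h + 1e-3)
})

test_that("error-only sites carry the per-allele error rate", {
  set.seed(77)
  e <- 6e-4
  x <- simulate_allele_counts(4000, 1500, 0, error_rate = e)
  emp <- mean(x$alt_reads / x$depth)
  se <- sqrt((e / 3) / 1500 / 4000)
  expect_lt(abs(emp - e / 3), 4 * se)
  # artifact flags only ever sit on error-origin reads
  xa <- simulate_allele_counts(2000, 1500, 0.05, error_rate = 0,
                               artifact_rate = 1)
  expect_true(all(xa$alt_artifact_reads == 0))
})

test_that("truth validation rejects inconsistent cohorts", {
  tv <- data.frame(patient_id = "S01", chrom = "chr13", pos = 48877900L,
                   ref = "C", alt = "T", true_cfdna_vaf = 1.2,
                   is_germline = FALSE, stringsAsFactors = FALSE)
  expect_error(cohort_truth(tv), "true_cfdna_vaf")
  tv$true_cfdna_vaf <- 0.4
  tv$is_germline <- TRUE
  expect_error(cohort_truth(tv), "0.5")
  tv$is_germline <- FALSE
  tv$seeded_below <- "nope"
  expect_error(cohort_truth(tv), "seeded_below")
})

test_that("the reference cohort encodes the intended study shape", {
  truth <- rb1_reference_cohort()
  expect_identical(truth, rb1_reference_cohort())   # versioned constants
  tv <- truth$variants
  somatic <- tv[!tv$is_germline, ]
  expect_equal(nrow(somatic), 13L)
  expect_equal(length(unique(tv$patient_id)), 10L)
  expect_equal(sum(tv$is_germline), 1L)
  detectable <- somatic$true_cfdna_vaf[somatic$seeded_below == "none" &
                                         somatic$true_cfdna_vaf > 0]
  expect_equal(length(detectable), 10L)
  expect_equal(median(detectable), 0.049)
  expect_equal(mean(somatic$true_cfdna_vaf), 0.0378, tolerance = 0.01)
  expect_equal(sum(truth$patients$n_replicates == 2L), 5L)
  # one patient sheds nothing, one carries two subthreshold variants
  expect_equal(somatic$patient_id[somatic$true_cfdna_vaf == 0], "P19")
  expect_equal(sort(somatic$patient_id[somatic$seeded_below != "none"]),
               c("P16", "P16"))
  # panel has 27 non-overlapping exons on chr13 containing every variant
  panel <- truth$panel
  expect_equal(nrow(panel), 27L)
  expect_true(all(panel$start < panel$end))
  expect_true(all(panel$end[-27] < panel$start[-1]))
  expect_true(all(in_panel(tv$chrom, tv$pos, panel)))
})

test_that("truth objects and datasets round-trip through disk", {
  truth <- small_truth(seed = 8L, n_error_sites = 10)
  dir <- tempfile()
  ds <- simulate_cohort(truth, out_dir = dir)
  expect_true(all(file.exists(file.path(
    dir, c("pileup.tsv", "panel.bed", "truth.json")))))
  back <- read_truth(file.path(dir, "truth.json"))
  expect_equal(back$variants, truth$variants)
  expect_equal(back$error_rate, truth$error_rate)
  expect_equal(back$panel[, c("chrom", "start", "end")],
               truth$panel[, c("chrom", "start", "end")])
  expect_identical(read_pileup(file.path(dir, "pileup.tsv")), ds$pileup)
  tv <- read_tumor_vcfs(file.path(dir, "tumor"))
  expect_equal(tv[order(tv$patient_id, tv$pos), c("patient_id", "pos", "ref", "alt")],
               ds$tumor_variants[order(ds$tumor_variants$patient_id,
                                       ds$tumor_variants$pos),
                                 c("patient_id", "pos", "ref", "alt")],
               ignore_attr = TRUE)
})

test_that("pipeline scoring recovers construction-time performance", {
  truth <- small_truth(vafs = c(0.05, 0.10, 0.08, 0.12), seed = 55L)
  truth$patients$n_replicates <- c(2L, 2L, 1L, 1L)
  ds <- simulate_cohort(truth)
  geno <- genotype_cohort(ds$tumor_variants, ds$pileup)
  dn <- call_denovo_cohort(ds$pileup, truth$panel,
                           tumor_variants = ds$tumor_variants)
  met <- score_pipeline(truth, geno, dn)
  expect_equal(met$sensitivity_genotyping, 1)
  expect_equal(met$sensitivity_denovo, 1)
  expect_equal(met$n_false_denovo_calls, 0L)
  expect_lt(met$vaf_mae, 0.02)
  expect_true(is.na(met$replicate_r2) || met$replicate_r2 <= 1)
  # truth/results mismatch is a hard error
  other <- small_truth(vafs = c(0.05, 0.10), seed = 56L)
  other$variants$pos <- other$variants$pos + 1L
  expect_error(score_pipeline(other, geno), "mismatch")
})
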