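denovo_buffy <- function(alt, depth) {
  ac(alt, depth, sample = "PA.buffy", role = "buffy_matched")
}

test_that("candidate scanning is gated by panel regions", {
  regions <- panel_regions("chr13", 48941600L, 48941700L, "exon")
  inside <- ac(15L, 1400L)                      # pos 48941648, inside
  outside <- ac(15L, 1400L, pos = 48950000L)
  cand <- scan_candidates(rbind(inside, outside), regions)
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$pos, 48941648L)
  # non-cfdna rows and alt 0 rows never become candidates
  pu <- rbind(ac(0L, 1400L), denovo_buffy(20L, 1400L))
  expect_equal(nrow(scan_candidates(pu, regions)), 0L)
  # candidate count equals a direct row scan on a dense pileup
  set.seed(9)
  pos <- 48941601L + sample(0:99, 60)
  alt <- rbinom(60, 1400, 0.001)
  dense <- ac(alt, 1400L, pos = pos)
  want <- sum(alt >= 1)
  expect_equal(nrow(scan_candidates(dense, regions)), want)
})

test_that("de novo filters reproduce the boundary cases", {
  v <- vk()
  m <- clean_model(v)
  cand <- function(alt, depth, ...) {
    regions <- panel_regions("chr13", 48941600L, 48941700L, "exon")
    scan_candidates(ac(alt, depth, ...), regions)
  }
  # 10/1000 = 1.0% with clean buffy and panel: called
  r <- filter_denovo(cand(10L, 1000L), denovo_buffy(0L, 1500L), m)
  expect_true(r$called)
  expect_equal(r$filters_failed, "")
  # 9 alt reads fail the count floor regardless of VAF
  r <- filter_denovo(cand(9L, 500L), denovo_buffy(0L, 1500L), m)
  expect_false(r$called)
  expect_match(r$filters_failed, "low_alt_reads")
  # 12/3000 = 0.4% fails the VAF floor
  r <- filter_denovo(cand(12L, 3000L), denovo_buffy(0L, 1500L), m)
  expect_match(r$filters_failed, "low_vaf")
  # VAF exactly 0.5% is not > 0.5%
  r <- filter_denovo(cand(10L, 2000L), denovo_buffy(0L, 1500L), m)
  expect_match(r$filters_failed, "low_vaf")
  # cfDNA VAF exactly 2x the buffy VAF passes the ratio ("at least 2 times")
  r <- filter_denovo(cand(30L, 1500L), denovo_buffy(15L, 1500L), m)
  expect_false(grepl("buffy_ratio", r$filters_failed))
  r <- filter_denovo(cand(29L, 1500L), denovo_buffy(15L, 1500L), m)
  expect_match(r$filters_failed, "buffy_ratio")
  # artifact majority fails
  r <- filter_denovo(cand(12L, 1000L, artifact = 7L), denovo_buffy(0L, 1500L), m)
  expect_match(r$filters_failed, "artifact")
  # all-one-strand support with >= 10 reads trips the strand-bias screen
  r <- filter_denovo(cand(14L, 1000L, fwd = 14L, rev = 0L),
                     denovo_buffy(0L, 1500L), m)
  expect_match(r$filters_failed, "strand_bias")
  r <- filter_denovo(cand(14L, 1000L, fwd = 7L, rev = 7L),
                     denovo_buffy(0L, 1500L), m)
  expect_false(grepl("strand_bias", r$filters_failed))
  expect_error(filter_denovo(cand(10L, 1000L),
                             denovo_buffy(0L, 1500L)[, ] |>
                               transform(pos = 1L), m), "variant")
})

test_that("filter decisions equal brute-force evaluation on a grid", {
  v <- vk()
  regions <- panel_regions("chr13", 48941600L, 48941700L, "exon")
  panel_cfgs <- list(
    list(alts = rep(0L, 9), depths = rep(1500L, 9)),
    list(alts = c(rep(0L, 8), 4L), depths = rep(1000L, 9))
  )
  for (pc in panel_cfgs) {
    m <- build_background(v, panel_counts(pc$alts, pc$depths))
    for (alt in c(0L, 1L, 5L, 9L, 10L, 11L, 16L, 25L)) {
      for (depth in c(800L, 1500L, 2500L, 3300L)) {
        for (bv in list(c(0L, 1500L), c(2L, 1500L), c(8L, 1500L),
                        c(750L, 1500L))) {
          if (alt == 0L) next  # never a candidate
          pu <- ac(alt, depth, fwd = alt, rev = 0L)
          cand <- scan_candidates(pu, regions)
          r <- filter_denovo(cand, denovo_buffy(bv[1], bv[2]), m)
          want <- oracle_denovo_filters(
            alt, depth, 0L, alt, 0L, bv[1], bv[2], pc$alts, pc$depths,
            cand$strand_bias_p)
          got <- sort(setdiff(strsplit(r$filters_failed, ",")[[1]], ""))
          expect_identical(got, want)
        }
      }
    }
  }
})

test_that("calls are invariant to pileup and region ordering", {
  truth <- small_truth(vafs = c(0.05, 0.09), n_error_sites = 40, seed = 19L)
  ds <- simulate_cohort(truth)
  dn1 <- call_denovo_cohort(ds$pileup, truth$panel,
                            tumor_variants = ds$tumor_variants)
  set.seed(1)
  shuffled <- ds$pileup[sample(nrow(ds$pileup)), , drop = FALSE]
  regions_rev <- truth$panel[rev(seq_len(nrow(truth$panel))), , drop = FALSE]
  dn2 <- call_denovo_cohort(shuffled, regions_rev,
                            tumor_variants = ds$tumor_variants)
  keyf <- function(d) sort(paste(d$patient_id, d$chrom, d$pos, d$ref, d$alt))
  expect_identical(keyf(dn1$calls), keyf(dn2$calls))
})

test_that("de novo VCF output round-trips and concordance classifies correctly", {
  truth <- small_truth(vafs = c(0.08, 0.002), seed = 23L)
  ds <- simulate_cohort(truth)
  dn <- call_denovo_cohort(ds$pileup, truth$panel,
                           tumor_variants = ds$tumor_variants)
  # S01's 8% variant is callable, S02's 0.2% is not
  expect_equal(dn$summary$calls_total, 1L)
  expect_equal(dn$calls$patient_id, "S01")
  cls <- dn$concordance
  expect_equal(cls$class[cls$patient_id == "S01"], "concordant")
  expect_equal(cls$class[cls$patient_id == "S02"], "tumor_only")

  dir <- tempfile()
  write_denovo_vcfs(dn, dir)
  back <- read_variants(file.path(dir, "S01.denovo.vcf"))
  expect_equal(back[, c("chrom", "pos", "ref", "alt")],
               dn$calls[, c("chrom", "pos", "ref", "alt")],
               ignore_attr = TRUE)
})

test_that("every de novo call is detected by genotyping of the same variant", {
  for (seed in c(3L, 17L)) {
    truth <- small_truth(vafs = c(0.006, 0.012, 0.03, 0.11),
                         n_error_sites = 60, seed = seed)
    ds <- simulate_cohort(truth)
    geno <- genotype_cohort(ds$tumor_variants, ds$pileup)
    dn <- call_denovo_cohort(ds$pileup, truth$panel,
                             tumor_variants = ds$tumor_variants)
    key <- function(d) paste(d$patient_id, d$chrom, d$pos, d$ref, d$alt)
    prim <- geno$results[geno$results$primary, ]
    detected <- key(prim[prim$status == "detected", ])
    shared_calls <- dn$calls[key(dn$calls) %in% key(ds$tumor_variants), ]
    expect_true(all(key(shared_calls) %in% detected))
  }
})
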