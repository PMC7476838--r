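test_that("genotyping criteria reproduce the known worked cases", {
  v <- vk()
  buffy0 <- ac(0L, 1500L, sample = "PA.buffy", role = "buffy_matched")
  m <- clean_model(v)

  # 2 supporting reads in 2286: below the 3-read floor, subthreshold evidence
  r <- genotype_variant(v, ac(2L, 2286L), buffy0, m)
  expect_equal(r$status, "not_detected")
  expect_false(r$pass_min_reads)
  expect_true(r$pass_buffy && r$pass_background && r$pass_artifact)
  expect_true(r$subthreshold_evidence)

  # 5 supporting reads in 5666 clears the read floor
  r <- genotype_variant(v, ac(5L, 5666L), buffy0, m)
  expect_true(r$pass_min_reads)

  # clear detection: 100 alt reads at 1500x over a clean background
  r <- genotype_variant(v, ac(100L, 1500L), buffy0, m)
  expect_equal(r$status, "detected")
  expect_false(r$subthreshold_evidence)

  # artifact rule: 5 of 8 alt reads flagged (62.5% > 50%) kills the call
  r <- genotype_variant(v, ac(8L, 1500L, artifact = 5L), buffy0, m)
  expect_equal(r$status, "not_detected")
  expect_false(r$pass_artifact)
  # exactly 50% flagged passes
  r <- genotype_variant(v, ac(8L, 1500L, artifact = 4L), buffy0, m)
  expect_true(r$pass_artifact)
})

test_that("depth-0 cfDNA fails every criterion except the artifact rule", {
  v <- vk()
  r <- genotype_variant(v, ac(0L, 0L),
                        ac(0L, 1500L, sample = "PA.buffy",
                           role = "buffy_matched"), clean_model(v))
  expect_false(r$pass_min_reads || r$pass_buffy || r$pass_background)
  expect_true(r$pass_artifact)
  expect_equal(r$status, "not_detected")
  expect_false(r$subthreshold_evidence)
})

test_that("mismatched inputs are rejected", {
  v <- vk()
  m <- clean_model(v)
  buffy_other <- ac(0L, 1500L, sample = "PX.buffy", role = "buffy_matched")
  expect_error(genotype_variant(v, ac(5L, 1500L), buffy_other, m),
               "different patient")
  buffy_wrong_site <- ac(0L, 1500L, sample = "PA.buffy",
                         role = "buffy_matched", pos = 42L)
  expect_error(genotype_variant(v, ac(5L, 1500L), buffy_wrong_site, m),
               "match")
  expect_error(genotype_variant(v, ac(5L, 1500L), NULL, m), "buffy")
  # background panel containing the case patient is refused
  leaky <- build_background(v, panel_counts(rep(0L, 3), rep(1500L, 3)))
  leaky$panel_samples[1] <- "PA.buffy"
  expect_error(genotype_variant(
    v, ac(5L, 1500L),
    ac(0L, 1500L, sample = "PA.buffy", role = "buffy_matched"), leaky),
    "case patient")
})

test_that("verdicts equal brute-force enumeration on all small instances", {
  v <- vk()
  configs <- list(
    list(buffy = c(0L, 1500L), panel_alts = rep(0L, 9),
         panel_depths = rep(1500L, 9)),
    list(buffy = c(1L, 1500L), panel_alts = rep(0L, 9),
         panel_depths = rep(1500L, 9)),
    list(buffy = c(0L, 1000L), panel_alts = c(rep(0L, 8), 4L),
         panel_depths = rep(1000L, 9)),
    list(buffy = c(0L, 0L), panel_alts = rep(1L, 3),
         panel_depths = rep(1000L, 3)),
    list(buffy = c(150L, 1500L), panel_alts = c(0L, 0L, 3L),
         panel_depths = rep(1000L, 3))
  )
  for (cfg in configs) {
    buffy <- ac(cfg$buffy[1], cfg$buffy[2], sample = "PA.buffy",
                role = "buffy_matched")
    m <- build_background(v, panel_counts(cfg$panel_alts, cfg$panel_depths))
    for (depth in c(0L, 1L, 5L, 10L, 20L, 30L)) {
      for (alt in 0:depth) {
        art <- alt %/% 3L   # sweep a sub-50% artifact load as well
        r <- genotype_variant(v, ac(alt, depth, artifact = art), buffy, m)
        want <- oracle_genotype(alt, depth, art, cfg$buffy[1], cfg$buffy[2],
                                cfg$panel_alts, cfg$panel_depths)
        expect_identical(r$status == "detected", want)
      }
    }
  }
})

test_that("detection is monotone in alt reads at fixed depth", {
  v <- vk()
  buffy <- ac(1L, 1500L, sample = "PA.buffy", role = "buffy_matched")
  m <- build_background(v, panel_counts(c(0L, 0L, 2L), rep(1500L, 3)))
  status <- vapply(0:60, function(alt) {
    genotype_variant(v, ac(alt, 1500L), buffy, m)$status == "detected"
  }, logical(1))
  expect_true(all(diff(status) >= 0))  # never flips detected -> not
})

test_that("cohort genotyping handles replicates, missing counts and summaries", {
  truth <- small_truth(vafs = c(0.06, 0.10), seed = 31L)
  ds <- simulate_cohort(truth)
  g <- genotype_cohort(ds$tumor_variants, ds$pileup)
  expect_equal(g$summary$mutations_total, 2L)
  expect_equal(g$summary$mutations_detected, 2L)
  expect_equal(g$summary$patients_detected, 2L)
  expect_true(all(g$results$primary))

  # drop one patient's pileup entirely: warned, reported not_detected
  pu <- ds$pileup[sample_patient(ds$pileup$sample_id) != "S02", , drop = FALSE]
  w <- capture_warnings(g2 <- genotype_cohort(ds$tumor_variants, pu))
  expect_true(any(grepl("S02", w)))
  s2 <- g2$results[g2$results$patient_id == "S02", ]
  expect_equal(s2$status, "not_detected")
  expect_equal(s2$depth, 0L)

  # empty cohort: empty results, zero counts
  g0 <- genotype_cohort(ds$tumor_variants[0, ], ds$pileup)
  expect_equal(nrow(g0$results), 0L)
  expect_equal(g0$summary$mutations_total, 0L)
})

test_that("theoretical detection limit is the read floor over coverage", {
  expect_equal(theoretical_detection_limit(3, 1596), 3 / 1596)
  expect_equal(theoretical_detection_limit(3, 3), 1)
  expect_equal(theoretical_detection_limit(10, 2000), 0.005)
  expect_error(theoretical_detection_limit(3, 0), "coverage")
})
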