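# Independent brute-force oracles and small constructors shared by tests.
# The oracles re-derive the detection rules from first principles (naive
# arithmetic, explicit loops) and stay independent of the package code
# paths they check.

ac <- function(alt, depth, sample = "PA.cfdna", role = "cfdna",
               chrom = "chr13", pos = 48941648L, ref = "C", altb = "T",
               artifact = 0L, fwd = NULL, rev = NULL) {
  allele_count(sample, role, chrom, pos, ref, altb, depth, alt,
               alt_artifact_reads = artifact, alt_fwd = fwd, alt_rev = rev)
}

vk <- function(chrom = "chr13", pos = 48941648L, ref = "C", alt = "T") {
  variant_key(chrom, pos, ref, alt)
}

# panel of unmatched buffy counts from alt/depth vectors, patients PB1..PBn
panel_counts <- function(alts, depths, pos = 48941648L, ref = "C",
                         alt = "T") {
  do.call(rbind, lapply(seq_along(alts), function(i) {
    ac(alts[i], depths[i], sample = sprintf("PB%02d.buffy", i),
       role = "buffy_unmatched", pos = pos, ref = ref, altb = alt)
  }))
}

# two-pass mean/SD/threshold from first principles
oracle_background <- function(alts, depths, k) {
  vafs <- ifelse(depths == 0, 0, alts / depths)
  n <- length(vafs)
  m <- sum(vafs) / n
  s <- if (n > 1) sqrt(sum((vafs - m)^2) / (n - 1)) else 0
  list(mean = m, sd = s, threshold = m + k * s)
}

# criteria (a)-(c) + artifact rule, enumerated directly
oracle_genotype <- function(alt, depth, artifact, buffy_alt, buffy_depth,
                            panel_alts, panel_depths, k = 2, min_reads = 3,
                            artifact_frac = 0.5) {
  cf_vaf <- if (depth == 0) 0 else alt / depth
  bc_vaf <- if (buffy_depth == 0) 0 else buffy_alt / buffy_depth
  thr <- oracle_background(panel_alts, panel_depths, k)$threshold
  a <- alt >= min_reads
  b <- cf_vaf > bc_vaf
  c <- cf_vaf > thr
  art_ok <- if (alt == 0) TRUE else artifact <= artifact_frac * alt
  a && b && c && art_ok
}

# the six de novo filters, evaluated independently
oracle_denovo_filters <- function(alt, depth, artifact, fwd, rev,
                                  buffy_alt, buffy_depth, panel_alts,
                                  panel_depths, sb_p, k = 2) {
  cf_vaf <- if (depth == 0) 0 else alt / depth
  bc_vaf <- if (buffy_depth == 0) 0 else buffy_alt / buffy_depth
  thr <- oracle_background(panel_alts, panel_depths, k)$threshold
  failed <- character(0)
  if (!(cf_vaf > 0.005)) failed <- c(failed, "low_vaf")
  if (alt < 10) failed <- c(failed, "low_alt_reads")
  if (cf_vaf < 2 * bc_vaf) failed <- c(failed, "buffy_ratio")
  if (!(cf_vaf > thr)) failed <- c(failed, "background")
  if (alt > 0 && artifact > 0.5 * alt) failed <- c(failed, "artifact")
  if (min(fwd, rev) == 0 && alt >= 10 && sb_p < 0.005) {
    failed <- c(failed, "strand_bias")
  }
  sort(failed)
}

# independent trim-based normalization (index arithmetic on substrings)
oracle_normalize <- function(pos, ref, alt) {
  while (nchar(ref) > 1 && nchar(alt) > 1 &&
         substr(ref, nchar(ref), nchar(ref)) ==
           substr(alt, nchar(alt), nchar(alt))) {
    ref <- substr(ref, 1, nchar(ref) - 1)
    alt <- substr(alt, 1, nchar(alt) - 1)
  }
  while (nchar(ref) > 1 && nchar(alt) > 1 &&
         substr(ref, 1, 1) == substr(alt, 1, 1)) {
    ref <- substr(ref, 2, nchar(ref))
    alt <- substr(alt, 2, nchar(alt))
    pos <- pos + 1
  }
  list(pos = pos, ref = ref, alt = alt)
}

# exact two-sided binomial p at p0 = 0.5 by direct tail summation
oracle_binom_p <- function(x, n) {
  d <- dbinom(0:n, n, 0.5)
  sum(d[d <= dbinom(x, n, 0.5) * (1 + 1e-7)])
}

# germline rule re-derived from the stated constants
oracle_germline_verdict <- function(alt, depth) {
  bvaf <- if (depth == 0) 0 else alt / depth
  p <- if (depth > 0) oracle_binom_p(alt, depth) else NA
  if (!is.na(p) && p >= 0.01 && bvaf >= 0.30) return("germline")
  if (alt <= 3 || bvaf < 0.02) return("somatic")
  "ambiguous"
}

clean_model <- function(v = vk()) {
  build_background(v, panel_counts(rep(0L, 9), rep(1500L, 9)))
}

# small two-patient truth used by several property tests
small_truth <- function(vafs = c(0.05, 0.12), n_error_sites = 20,
                        seed = 11L, ...) {
  panel <- rb1_panel()
  variants <- data.frame(
    patient_id = rep(c("S01", "S02"), length.out = length(vafs)),
    chrom = "chr13",
    pos = as.integer(panel$start[seq_along(vafs)] + 10L),
    ref = "C", alt = "T", label = NA_character_,
    true_cfdna_vaf = vafs, is_germline = FALSE, stringsAsFactors = FALSE)
  patients <- data.frame(patient_id = c("S01", "S02", "S03", "S04"),
                         n_replicates = 1L, stringsAsFactors = FALSE)
  cohort_truth(variants, patients, n_error_sites = n_error_sites,
               seed = seed, panel = panel, ...)
}
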