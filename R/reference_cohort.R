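#' Synthetic 27-exon RB1 capture panel
#'
#' A deterministic, synthetic stand-in for the footprint of a hybrid-capture
#' panel targeting the 27 exons of *RB1* on chromosome 13 (the gene spans
#' roughly chr13:48.88-49.06 Mb on GRCh37). Exon sizes and spacing are
#' plausible but synthetic; the detection statistics depend only on counts
#' at sites, never on true genomic coordinates.
#'
#' @return panel region data.frame (`chrom, start, end, name`), 0-based
#'   half-open.
#' @export
rb1_panel <- function() {
  exon_len <- c(200L, 120L, 110L, 100L, 90L, 80L, 130L, 95L, 85L, 105L,
                75L, 115L, 90L, 100L, 80L, 140L, 195L, 85L, 150L, 145L,
                160L, 185L, 165L, 110L, 120L, 95L, 1900L)
  gap <- as.integer(round(6500 + 400 * (seq_len(26L) %% 7L)))
  start <- integer(27L)
  start[1L] <- 48877887L
  for (i in 2:27) start[i] <- start[i - 1L] + exon_len[i - 1L] + gap[i - 1L]
  panel_regions("chr13", start, start + exon_len,
                sprintf("RB1_exon_%02d", 1:27))
}

#' Reference ten-patient cohort truth
#'
#' A fixed, versioned truth object emulating the design of a ten-patient
#' advanced intraocular unilateral retinoblastoma cfDNA study: 13 somatic
#' *RB1* mutations across 10 patients plus one germline heterozygote, mean
#' unique coverage ~1530x, per-base error 5e-4, and five patients with
#' technical replicates. The construction encodes:
#'
#' * ten variants detectable by tumor-guided genotyping (median true VAF
#'   0.049), of which exactly seven also clear the stricter de novo floors;
#'   the other three sit at true VAF 0.003 on deeply captured sites
#'   (~6000x), safely above the 3-read genotyping floor but below the 0.5%
#'   de novo VAF floor;
#' * two variants in one patient (P16 analogue) seeded below threshold: a
#'   recurrent buffy-coat artifact at those sites (panel VAF ~0.4%) puts
#'   the background threshold far above their faint cfDNA signal, leaving
#'   only subthreshold evidence;
#' * one patient (P19 analogue, treated with chemotherapy before blood
#'   draw) whose mutation sheds nothing (true cfDNA VAF 0);
#' * one patient (P01 analogue) carrying a germline heterozygote alongside
#'   a distinct somatic mutation at VAF 0.0137.
#'
#' The mean of the 13 somatic true VAFs is ~0.0378 and the median of the
#' ten detectable ones 0.049. The object is identical across calls.
#'
#' @return an [cohort_truth()] object (default seed 20200707).
#' @export
rb1_reference_cohort <- function() {
  panel <- rb1_panel()
  # site = exon index, off = offset into the exon
  site_pos <- function(exon, off) as.integer(panel$start[exon] + off)
  v <- function(pid, exon, off, ref, alt, label, vaf, germ = FALSE,
                below = "none", dmult = 1, perr = 0) {
    data.frame(patient_id = pid, chrom = "chr13",
               pos = site_pos(exon, off), ref = ref, alt = alt,
               label = label, true_cfdna_vaf = vaf, is_germline = germ,
               seeded_below = below, depth_mult = dmult,
               panel_error_vaf = perr, stringsAsFactors = FALSE)
  }
  variants <- rbind(
    v("P23", 3L, 40L, "C", "T", "p.R320*",      0.126),
    v("P11", 8L, 25L, "CA", "C", "p.E492fs",    0.081),
    v("P01", 11L, 30L, "G", "T", "p.E580*",     0.0137, dmult = 2.5),
    v("P01", 4L, 18L, "C", "T", "c.1072C>T",    0.5, germ = TRUE),
    v("P03", 14L, 55L, "G", "A", "p.W99*",      0.044),
    v("P03", 6L, 12L, "C", "A", "p.S149*",      0.003, dmult = 3.92),
    v("P21", 17L, 80L, "A", "T", "p.K652*",     0.003, dmult = 3.92),
    v("P22", 19L, 33L, "G", "C", "X405_splice", 0.054),
    v("P22", 21L, 61L, "C", "T", "p.R556*",     0.063),
    v("P26", 23L, 90L, "T", "A", "p.L688*",     0.099),
    v("P24", 25L, 44L, "G", "T", "p.E748*",     0.003, dmult = 3.92),
    v("P16", 20L, 70L, "A", "G", "X702_splice", 0.0009, below = "background",
      dmult = 3.70, perr = 0.004),
    v("P16", 22L, 15L, "C", "T", "p.Q736*",     0.0004,
      below = "genotyping_floor", dmult = 1.49, perr = 0.004),
    v("P19", 9L, 28L, "C", "G", "p.S567*",      0)
  )
  variants$depth_mult[variants$patient_id == "P19" &
                        !variants$is_germline] <- 1.043
  patients <- data.frame(
    patient_id = c("P01", "P03", "P11", "P16", "P19", "P21", "P22", "P23",
                   "P24", "P26"),
    n_replicates = c(1L, 2L, 2L, 1L, 1L, 1L, 2L, 2L, 1L, 2L),
    stringsAsFactors = FALSE)
  cohort_truth(variants, patients, panel = panel, seed = 20200707L)
}
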