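#' Tumor-guided genotyping of one known variant in cfDNA
#'
#' Applies the four genotyping criteria to a mutation already known from the
#' patient's tumor:
#'
#' 1. `pass_min_reads`: at least `min_alt_reads_genotyping` (default 3)
#'    cfDNA reads support the alternative allele;
#' 2. `pass_buffy`: cfDNA VAF strictly above the matched buffy-coat VAF;
#' 3. `pass_background`: cfDNA VAF strictly above the unmatched-panel
#'    threshold (mean + k SD, see [build_background()]);
#' 4. `pass_artifact`: at most `artifact_max_fraction` (default 50%) of
#'    alt-supporting reads are artifact-flagged (vacuously true with zero
#'    alt reads).
#'
#' `status` is `"detected"` iff all four pass. `subthreshold_evidence` marks
#' undetected variants that still show at least one supporting read.
#'
#' @param variant single variant key.
#' @param cfdna cfDNA allele count for this variant (1-row pileup).
#' @param buffy_matched matched buffy-coat allele count (required: the
#'   buffy comparison is undefined without it).
#' @param model `rb_background` for the same variant, built from a panel
#'   excluding this patient.
#' @param thresholds an [detection_thresholds()] object.
#' @return 1-row data.frame (a detection result): variant fields,
#'   `patient_id`, `sample_id`, `track`, VAFs, threshold, the four `pass_*`
#'   flags, `status`, `subthreshold_evidence`, `alt_reads`, `depth`.
#' @export
genotype_variant <- function(variant, cfdna, buffy_matched, model,
                             thresholds = detection_thresholds()) {
  stopifnot(inherits(model, "rb_background"))
  if (is.null(buffy_matched) || nrow(buffy_matched) != 1L) {
    stop("genotyping requires exactly one matched buffy-coat count for ",
         variant_id(variant))
  }
  if (nrow(cfdna) != 1L) stop("cfdna must be a single allele-count row")
  for (x in list(cfdna, buffy_matched)) {
    if (!same_variant(x, variant) || !same_variant(model$variant, variant)) {
      stop("allele counts/background do not match variant ",
           variant_id(variant))
    }
  }
  patient <- sample_patient(cfdna$sample_id)
  if (sample_patient(buffy_matched$sample_id) != patient) {
    stop("matched buffy coat belongs to a different patient than the cfDNA")
  }
  if (patient %in% sample_patient(model$panel_samples)) {
    stop("background panel for ", variant_id(variant),
         " includes the case patient ", patient)
  }

  cf_vaf <- vaf(cfdna$alt_reads, cfdna$depth)
  bc_vaf <- vaf(buffy_matched$alt_reads, buffy_matched$depth)
  pass_min_reads <- cfdna$alt_reads >= thresholds$min_alt_reads_genotyping
  pass_buffy <- cf_vaf > bc_vaf
  pass_background <- exceeds_background(cf_vaf, model)
  pass_artifact <- cfdna$alt_reads == 0L ||
    cfdna$alt_artifact_reads <= thresholds$artifact_max_fraction * cfdna$alt_reads
  detected <- pass_min_reads && pass_buffy && pass_background && pass_artifact

  data.frame(
    patient_id = patient,
    sample_id = cfdna$sample_id,
    track = "tumor_guided",
    chrom = variant$chrom, pos = variant$pos, ref = variant$ref,
    alt = variant$alt,
    label = if ("label" %in% names(variant)) variant$label else NA_character_,
    depth = cfdna$depth, alt_reads = cfdna$alt_reads,
    cfdna_vaf = cf_vaf, buffy_vaf = bc_vaf,
    background_threshold = model$threshold,
    pass_min_reads = pass_min_reads, pass_buffy = pass_buffy,
    pass_background = pass_background, pass_artifact = pass_artifact,
    status = if (detected) "detected" else "not_detected",
    subthreshold_evidence = !detected && cfdna$alt_reads >= 1L,
    stringsAsFactors = FALSE
  )
}

#' Genotype every tumor mutation of a cohort in cfDNA
#'
#' For each patient and each tumor variant, genotypes every cfDNA sample of
#' that patient (technical replicates are analyzed separately; the
#' lexicographically first cfDNA sample per patient is flagged `primary` and
#' used for cohort summaries). The background null is built leave-one-out
#' from all other patients' buffy coats. Missing counts (patient absent
#' from the pileup, or no row at a variant) are treated as depth 0 with a
#' warning, and such variants come out `not_detected`.
#'
#' @param tumor_variants data.frame with a `patient_id` column plus variant
#'   key columns — one row per (patient, tumor mutation).
#' @param pileup full cohort pileup table (all samples, all sites).
#' @param thresholds an [detection_thresholds()] object.
#' @return list with `results` (one detection-result row per
#'   patient/variant/cfDNA sample, plus `primary` flag) and `summary`
#'   (see [cohort_summary()], computed on primary rows).
#' @export
genotype_cohort <- function(tumor_variants, pileup,
                            thresholds = detection_thresholds()) {
  validate_pileup(pileup)
  patients <- unique(tumor_variants$patient_id)
  out <- list()
  for (p in patients) {
    pv <- tumor_variants[tumor_variants$patient_id == p, , drop = FALSE]
    prows <- pileup[sample_patient(pileup$sample_id) == p, , drop = FALSE]
    cf_samples <- sort(unique(prows$sample_id[prows$role == "cfdna"]))
    bc_samples <- sort(unique(prows$sample_id[prows$role == "buffy_matched"]))
    if (!length(cf_samples)) {
      warning("patient ", p, " has no cfDNA sample in the pileup; ",
              "variants reported not_detected at depth 0")
      cf_samples <- paste0(p, ".cfdna")
    }
    if (!length(bc_samples)) {
      warning("patient ", p, " has no matched buffy coat in the pileup; ",
              "using zero-depth counts")
      bc_samples <- paste0(p, ".buffy")
    }
    for (i in seq_len(nrow(pv))) {
      v <- pv[i, , drop = FALSE]
      model <- build_background(v, unmatched_panel(pileup, v, p),
                                k = thresholds$background_k)
      bc <- pileup_at(prows[prows$sample_id == bc_samples[1L], , drop = FALSE], v)
      if (nrow(bc) == 0L) {
        warning("no matched buffy count at ", variant_id(v), " for ", p,
                "; using depth 0")
        bc <- zero_count(bc_samples[1L], "buffy_matched", v)
      }
      for (s in cf_samples) {
        cf <- pileup_at(prows[prows$sample_id == s, , drop = FALSE], v)
        if (nrow(cf) == 0L) {
          warning("no cfDNA count at ", variant_id(v), " for sample ", s,
                  "; using depth 0")
          cf <- zero_count(s, "cfdna", v)
        }
        res <- genotype_variant(v, cf, bc, model, thresholds)
        res$primary <- s == cf_samples[1L]
        out[[length(out) + 1L]] <- res
      }
    }
  }
  results <- if (length(out)) do.call(rbind, out) else empty_results()
  rownames(results) <- NULL
  list(results = results,
       summary = cohort_summary(results[results$primary, , drop = FALSE]))
}

empty_results <- function() {
  data.frame(
    patient_id = character(0), sample_id = character(0), track = character(0),
    chrom = character(0), pos = integer(0), ref = character(0),
    alt = character(0), label = character(0), depth = integer(0),
    alt_reads = integer(0), cfdna_vaf = numeric(0), buffy_vaf = numeric(0),
    background_threshold = numeric(0), pass_min_reads = logical(0),
    pass_buffy = logical(0), pass_background = logical(0),
    pass_artifact = logical(0), status = character(0),
    subthreshold_evidence = logical(0), primary = logical(0),
    stringsAsFactors = FALSE)
}

#' Summarize detection results across a cohort
#'
#' @param results detection-result rows (typically primary samples only).
#' @return list: `mutations_detected`, `mutations_total`,
#'   `patients_detected`, `patients_total`, and median / min / max of
#'   detected-variant cfDNA VAFs (NA when nothing was detected).
#' @export
cohort_summary <- function(results) {
  det <- results[results$status == "detected", , drop = FALSE]
  list(
    mutations_detected = nrow(det),
    mutations_total = nrow(results),
    patients_detected = length(unique(det$patient_id)),
    patients_total = length(unique(results$patient_id)),
    detected_vaf_median = if (nrow(det)) median(det$cfdna_vaf) else NA_real_,
    detected_vaf_min = if (nrow(det)) min(det$cfdna_vaf) else NA_real_,
    detected_vaf_max = if (nrow(det)) max(det$cfdna_vaf) else NA_real_
  )
}

#' Theoretical detection limit of a read-count floor
#'
#' The smallest VAF observable at a given unique coverage when a detection
#' rule demands `min_reads` supporting reads: `min_reads / coverage` (e.g.
#' 3 reads at 1596x unique coverage gives 0.0018797, i.e. just under 0.19%).
#'
#' @param min_reads integer read floor (>= 1).
#' @param coverage unique coverage at the site (>= 1).
#' @return fraction `min_reads / coverage`.
#' @export
theoretical_detection_limit <- function(min_reads, coverage) {
  if (any(coverage < 1)) stop("coverage must be >= 1")
  if (any(min_reads < 1)) stop("min_reads must be >= 1")
  min_reads / coverage
}
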