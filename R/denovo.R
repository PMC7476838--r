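DENOVO_FILTERS <- c("low_vaf", "low_alt_reads", "buffy_ratio", "background",
                    "artifact", "strand_bias")

#' Scan a cfDNA pileup for candidate variants inside the panel
#'
#' Every (site, non-reference allele) with at least one supporting read that
#' falls inside a panel region becomes a candidate; sites outside the panel
#' are ignored. Candidates are sorted by (chrom, pos, alt). A two-sided
#' exact strand-bias p-value is attached: Fisher's test of
#' (alt_fwd, alt_rev) against the reference reads, whose strand split is
#' not carried by the pileup dialect and is taken as even (the screen only
#' ever acts on all-one-strand support, where this convention is
#' immaterial).
#'
#' @param pileup pileup rows (only `role == "cfdna"` rows are scanned).
#' @param regions panel region data.frame (see [panel_regions()]).
#' @return data.frame of candidates: pileup columns plus `strand_bias_p`.
#' @export
scan_candidates <- function(pileup, regions) {
  validate_pileup(pileup)
  cf <- pileup[pileup$role == "cfdna", , drop = FALSE]
  cf <- cf[cf$alt_reads >= 1L & in_panel(cf$chrom, cf$pos, regions), ,
           drop = FALSE]
  cf <- cf[order(cf$chrom, cf$pos, cf$alt, cf$sample_id), , drop = FALSE]
  cf$strand_bias_p <- vapply(seq_len(nrow(cf)), function(i) {
    strand_bias_p(cf$alt_fwd[i], cf$alt_rev[i], cf$depth[i] - cf$alt_reads[i])
  }, numeric(1))
  rownames(cf) <- NULL
  cf
}

strand_bias_p <- function(alt_fwd, alt_rev, ref_reads) {
  ref_fwd <- ceiling(ref_reads / 2)
  ref_rev <- ref_reads - ref_fwd
  fisher.test(matrix(c(alt_fwd, alt_rev, ref_fwd, ref_rev), nrow = 2L))$p.value
}

#' Apply the de novo filter cascade to one candidate
#'
#' The stricter de novo criteria, evaluated against the matched buffy coat
#' and the unmatched-panel background null:
#'
#' * `low_vaf`: cfDNA VAF not strictly above `denovo_min_vaf` (0.5%);
#' * `low_alt_reads`: fewer than `denovo_min_alt_reads` (10) alt reads;
#' * `buffy_ratio`: cfDNA VAF below `denovo_buffy_ratio` (2) times the
#'   matched buffy VAF ("at least 2 times" — equality passes; a clean buffy
#'   coat at VAF 0 passes any positive cfDNA VAF);
#' * `background`: cfDNA VAF not strictly above the panel threshold;
#' * `artifact`: more than `artifact_max_fraction` of alt reads flagged;
#' * `strand_bias`: all alt reads on one strand with >=
#'   `denovo_min_alt_reads` of them and exact-test p below `strand_bias_p`.
#'
#' The artifact and strand-bias screens are the automated surrogate for
#' manual review of alignments.
#'
#' @param candidate 1-row candidate from [scan_candidates()].
#' @param buffy_matched matched buffy allele count at the same variant.
#' @param model `rb_background` for the same variant.
#' @param thresholds an [detection_thresholds()] object.
#' @return the candidate row annotated with `buffy_vaf`,
#'   `background_threshold`, `filters_failed` (comma-joined, `""` when
#'   clean) and `called` (TRUE iff no filter failed).
#' @export
filter_denovo <- function(candidate, buffy_matched, model,
                          thresholds = detection_thresholds()) {
  stopifnot(inherits(model, "rb_background"))
  if (!same_variant(candidate, model$variant) ||
      !same_variant(candidate, buffy_matched)) {
    stop("candidate, buffy count and background model must share a variant")
  }
  cf_vaf <- vaf(candidate$alt_reads, candidate$depth)
  bc_vaf <- vaf(buffy_matched$alt_reads, buffy_matched$depth)
  failed <- character(0)
  if (!(cf_vaf > thresholds$denovo_min_vaf)) failed <- c(failed, "low_vaf")
  if (candidate$alt_reads < thresholds$denovo_min_alt_reads) {
    failed <- c(failed, "low_alt_reads")
  }
  if (cf_vaf < thresholds$denovo_buffy_ratio * bc_vaf) {
    failed <- c(failed, "buffy_ratio")
  }
  if (!exceeds_background(cf_vaf, model)) failed <- c(failed, "background")
  if (candidate$alt_reads > 0L &&
      candidate$alt_artifact_reads >
        thresholds$artifact_max_fraction * candidate$alt_reads) {
    failed <- c(failed, "artifact")
  }
  if (min(candidate$alt_fwd, candidate$alt_rev) == 0L &&
      candidate$alt_reads >= thresholds$denovo_min_alt_reads &&
      candidate$strand_bias_p < thresholds$strand_bias_p) {
    failed <- c(failed, "strand_bias")
  }
  candidate$cfdna_vaf <- cf_vaf
  candidate$buffy_vaf <- bc_vaf
  candidate$background_threshold <- model$threshold
  candidate$filters_failed <- paste(failed, collapse = ",")
  candidate$called <- length(failed) == 0L
  candidate
}

#' De novo variant calling across a cohort
#'
#' Scans the primary cfDNA sample of each patient for candidates inside the
#' panel, applies [filter_denovo()] to each with the patient's matched
#' buffy coat and a leave-one-out background null, and (when a tumor
#' variant list is supplied) classifies every call and tumor variant as
#' `concordant`, `cfdna_only` or `tumor_only`.
#'
#' @param pileup full cohort pileup.
#' @param regions panel regions.
#' @param thresholds an [detection_thresholds()] object.
#' @param tumor_variants optional data.frame of tumor mutations with a
#'   `patient_id` column, for the concordance table.
#' @return list: `candidates` (annotated candidates for every patient),
#'   `calls` (passing candidates only), `concordance` (or NULL), and
#'   `summary` (patients with >= 1 call, total calls, and — when tumor
#'   variants are given — calls matching a tumor mutation).
#' @export
call_denovo_cohort <- function(pileup, regions,
                               thresholds = detection_thresholds(),
                               tumor_variants = NULL) {
  validate_pileup(pileup)
  cf_all <- pileup[pileup$role == "cfdna", , drop = FALSE]
  patients <- sort(unique(sample_patient(cf_all$sample_id)))
  ann <- list()
  for (p in patients) {
    prim <- sort(unique(cf_all$sample_id[sample_patient(cf_all$sample_id) == p]))[1L]
    cand <- scan_candidates(cf_all[cf_all$sample_id == prim, , drop = FALSE],
                            regions)
    bc_rows <- pileup[pileup$role == "buffy_matched" &
                        sample_patient(pileup$sample_id) == p, , drop = FALSE]
    for (i in seq_len(nrow(cand))) {
      v <- cand[i, c("chrom", "pos", "ref", "alt"), drop = FALSE]
      model <- build_background(v, unmatched_panel(pileup, v, p),
                                k = thresholds$background_k)
      bc <- pileup_at(bc_rows, v)
      if (nrow(bc) == 0L) {
        warning("no matched buffy count at ", variant_id(v), " for ", p,
                "; using depth 0")
        bc <- zero_count(paste0(p, ".buffy"), "buffy_matched", v)
      }
      out <- filter_denovo(cand[i, , drop = FALSE], bc[1L, , drop = FALSE],
                           model, thresholds)
      out$patient_id <- p
      ann[[length(ann) + 1L]] <- out
    }
  }
  candidates <- if (length(ann)) do.call(rbind, ann) else NULL
  calls <- if (!is.null(candidates)) {
    candidates[candidates$called, , drop = FALSE]
  } else NULL
  concordance <- NULL
  n_concordant <- NA_integer_
  if (!is.null(tumor_variants)) {
    concordance <- denovo_concordance(calls, tumor_variants)
    n_concordant <- sum(concordance$class == "concordant")
  }
  n_calls <- if (is.null(calls)) 0L else nrow(calls)
  list(
    candidates = candidates, calls = calls, concordance = concordance,
    summary = list(
      calls_total = n_calls,
      patients_with_call = if (n_calls) length(unique(calls$patient_id)) else 0L,
      patients_total = length(patients),
      calls_concordant_with_tumor = n_concordant
    )
  )
}

# One row per (patient, variant) in calls-union-tumor list, classified.
denovo_concordance <- function(calls, tumor_variants) {
  key <- function(df) paste(df$patient_id, df$chrom, df$pos, df$ref, df$alt)
  ck <- if (is.null(calls) || !nrow(calls)) character(0) else key(calls)
  tk <- key(tumor_variants)
  all_keys <- unique(c(ck, tk))
  take <- function(k) {
    src <- if (k %in% ck) calls[match(k, ck), , drop = FALSE]
      else tumor_variants[match(k, tk), , drop = FALSE]
    src[, c("patient_id", "chrom", "pos", "ref", "alt"), drop = FALSE]
  }
  out <- do.call(rbind, lapply(all_keys, take))
  out$class <- ifelse(all_keys %in% ck & all_keys %in% tk, "concordant",
                      ifelse(all_keys %in% ck, "cfdna_only", "tumor_only"))
  rownames(out) <- NULL
  out
}

#' Write per-patient de novo calls as annotated VCFs
#'
#' One VCF 4.2 file per patient (`<patient>.denovo.vcf`), PASS records for
#' calls with `VAF`, `ALTREADS` and `BGTHRESH` INFO keys. When
#' `include_filtered` is TRUE, failing candidates are written too with
#' their filter names in FILTER.
#'
#' @param denovo result of [call_denovo_cohort()].
#' @param dir output directory (created if needed).
#' @param include_filtered also write failing candidates.
#' @return character vector of written paths, invisibly.
#' @export
write_denovo_vcfs <- function(denovo, dir, include_filtered = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  src <- if (include_filtered) denovo$candidates else denovo$calls
  hdr <- c(
    '##INFO=<ID=VAF,Number=1,Type=Float,Description="cfDNA variant allele frequency">',
    '##INFO=<ID=ALTREADS,Number=1,Type=Integer,Description="cfDNA alt-supporting reads">',
    '##INFO=<ID=BGTHRESH,Number=1,Type=Float,Description="Unmatched-panel background threshold (mean + k SD)">',
    sprintf('##FILTER=<ID=%s,Description="De novo filter">', DENOVO_FILTERS)
  )
  paths <- character(0)
  patients <- if (is.null(src)) character(0) else unique(src$patient_id)
  for (p in patients) {
    rec <- src[src$patient_id == p, , drop = FALSE]
    rec$filter <- ifelse(rec$filters_failed == "", "PASS",
                         gsub(",", ";", rec$filters_failed))
    rec$info <- sprintf("VAF=%.6g;ALTREADS=%d;BGTHRESH=%.6g",
                        rec$cfdna_vaf, rec$alt_reads, rec$background_threshold)
    path <- file.path(dir, paste0(p, ".denovo.vcf"))
    write_variants(rec, path, info_header = hdr)
    paths <- c(paths, path)
  }
  invisible(paths)
}
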