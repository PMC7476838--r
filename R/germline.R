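#' Classify a variant as germline, somatic or ambiguous from the buffy coat
#'
#' Germline heterozygotes are present in every nucleated cell and therefore
#' sit near 50% VAF in the buffy coat, whereas tumor-derived somatic
#' variants are absent from it. The rule, with constants from
#' [detection_thresholds()]:
#'
#' * **germline** — the exact two-sided binomial test of the buffy alt
#'   count against `germline_vaf_center` (0.5) is *not* rejected at level
#'   `germline_alpha` (0.01) and the buffy VAF is at least
#'   `germline_min_vaf` (0.30);
#' * **somatic** — the buffy coat is essentially clean: alt reads at or
#'   below `germline_somatic_max_reads` (3) or buffy VAF below
#'   `germline_somatic_max_vaf` (0.02);
#' * **ambiguous** — anything in between (e.g. mosaic-like intermediate
#'   VAFs), deliberately never auto-resolved.
#'
#' The verdict depends only on the buffy coat; the cfDNA VAF is carried as
#' reporting context.
#'
#' @param variant single variant key.
#' @param buffy matched buffy-coat allele count (1 row).
#' @param cfdna cfDNA allele count (1 row), context only.
#' @param thresholds an [detection_thresholds()] object.
#' @return 1-row data.frame: variant fields, `patient_id`, `buffy_vaf`,
#'   `cfdna_vaf`, `binomial_p`, `verdict`.
#' @export
classify_germline <- function(variant, buffy, cfdna,
                              thresholds = detection_thresholds()) {
  stopifnot(nrow(buffy) == 1L, nrow(cfdna) == 1L)
  if (!same_variant(buffy, variant) || !same_variant(cfdna, variant)) {
    stop("allele counts do not match variant ", variant_id(variant))
  }
  bc_vaf <- vaf(buffy$alt_reads, buffy$depth)
  p <- if (buffy$depth > 0L) {
    binom.test(buffy$alt_reads, buffy$depth,
               p = thresholds$germline_vaf_center)$p.value
  } else NA_real_
  verdict <- if (!is.na(p) && p >= thresholds$germline_alpha &&
                 bc_vaf >= thresholds$germline_min_vaf) {
    "germline"
  } else if (buffy$alt_reads <= thresholds$germline_somatic_max_reads ||
             bc_vaf < thresholds$germline_somatic_max_vaf) {
    "somatic"
  } else {
    "ambiguous"
  }
  data.frame(
    patient_id = sample_patient(buffy$sample_id),
    chrom = variant$chrom, pos = variant$pos, ref = variant$ref,
    alt = variant$alt,
    buffy_vaf = bc_vaf, cfdna_vaf = vaf(cfdna$alt_reads, cfdna$depth),
    binomial_p = p, verdict = verdict, stringsAsFactors = FALSE
  )
}

#' Classify every tumor variant of a cohort
#'
#' Runs [classify_germline()] for each (patient, variant) using the
#' matched buffy coat and primary cfDNA counts from the pileup (depth 0
#' when absent).
#'
#' @param tumor_variants data.frame with `patient_id` + variant key columns.
#' @param pileup cohort pileup table.
#' @param thresholds an [detection_thresholds()] object.
#' @return data.frame of germline calls, one row per (patient, variant).
#' @export
classify_germline_cohort <- function(tumor_variants, pileup,
                                     thresholds = detection_thresholds()) {
  validate_pileup(pileup)
  out <- list()
  for (i in seq_len(nrow(tumor_variants))) {
    v <- tumor_variants[i, , drop = FALSE]
    p <- v$patient_id
    prows <- pileup[sample_patient(pileup$sample_id) == p, , drop = FALSE]
    get1 <- function(role, suffix) {
      rows <- pileup_at(prows[prows$role == role, , drop = FALSE], v)
      if (nrow(rows)) {
        rows[order(rows$sample_id), , drop = FALSE][1L, , drop = FALSE]
      } else zero_count(paste0(p, suffix), role, v)
    }
    out[[i]] <- classify_germline(v, get1("buffy_matched", ".buffy"),
                                  get1("cfdna", ".cfdna"), thresholds)
  }
  if (!length(out)) {
    return(data.frame(patient_id = character(0), chrom = character(0),
                      pos = integer(0), ref = character(0),
                      alt = character(0), buffy_vaf = numeric(0),
                      cfdna_vaf = numeric(0), binomial_p = numeric(0),
                      verdict = character(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Partition detection results into somatic-reported and germline-excluded
#'
#' Results whose germline call is `germline` are removed from the somatic
#' report and listed separately; `ambiguous` results stay in the somatic
#' report flagged `germline_flag = "ambiguous"`. Results without a matching
#' germline call (e.g. clean buffy coat, never classified) are retained
#' unflagged.
#'
#' @param results detection-result rows ([genotype_cohort()] output).
#' @param calls germline calls ([classify_germline_cohort()] output).
#' @return list with `somatic` (retained rows plus `germline_flag`) and
#'   `germline` (excluded rows).
#' @export
filter_germline <- function(results, calls) {
  key <- function(df) paste(df$patient_id, df$chrom, df$pos, df$ref, df$alt)
  verdict <- calls$verdict[match(key(results), key(calls))]
  verdict[is.na(verdict)] <- "somatic"
  somatic <- results[verdict != "germline", , drop = FALSE]
  somatic$germline_flag <- ifelse(
    verdict[verdict != "germline"] == "ambiguous", "ambiguous", "")
  germline <- results[verdict == "germline", , drop = FALSE]
  rownames(somatic) <- rownames(germline) <- NULL
  list(somatic = somatic, germline = germline)
}
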