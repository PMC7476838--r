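#' Detection thresholds for both calling tracks
#'
#' All numeric criteria used by tumor-guided genotyping, de novo filtering
#' and germline classification live here; nothing is hard-coded elsewhere.
#' Defaults are the study criteria:
#'
#' * genotyping: >= 3 alt reads; cfDNA VAF strictly above the matched buffy
#'   coat; cfDNA VAF strictly above mean + 2 SD across unmatched buffy
#'   coats; at most 50% of alt reads artifact-flagged.
#' * de novo: VAF > 0.5% with >= 10 alt reads; cfDNA VAF at least 2x the
#'   matched buffy coat (ties pass); same background null and artifact rule;
#'   plus an extreme strand-bias screen standing in for manual review.
#' * germline: buffy-coat counts compatible with a heterozygote (exact
#'   binomial test against 0.5 not rejected at `germline_alpha` and buffy
#'   VAF >= `germline_min_vaf`); somatic when the buffy coat is essentially
#'   clean (<= `germline_somatic_max_reads` alt reads or VAF below
#'   `germline_somatic_max_vaf`); ambiguous (possible mosaicism) otherwise.
#'
#' @param min_alt_reads_genotyping minimum alt reads, genotyping track.
#' @param background_k number of SDs above the unmatched-buffy mean VAF.
#' @param denovo_min_vaf de novo VAF floor (strict `>`).
#' @param denovo_min_alt_reads de novo alt-read floor.
#' @param denovo_buffy_ratio required cfDNA/buffy VAF multiple (`>=` passes).
#' @param artifact_max_fraction maximum artifact fraction of alt reads.
#' @param germline_vaf_center expected germline heterozygote VAF.
#' @param germline_alpha two-sided binomial test level for the het model.
#' @param germline_min_vaf minimum buffy VAF for a germline verdict.
#' @param germline_somatic_max_vaf buffy VAF below which a variant is
#'   called somatic.
#' @param germline_somatic_max_reads buffy alt reads at or below which a
#'   variant is called somatic.
#' @param strand_bias_p p-value floor of the strand-bias screen.
#' @return object of class `rb_thresholds` (a named list).
#' @export
detection_thresholds <- function(min_alt_reads_genotyping = 3L,
                                 background_k = 2,
                                 denovo_min_vaf = 0.005,
                                 denovo_min_alt_reads = 10L,
                                 denovo_buffy_ratio = 2,
                                 artifact_max_fraction = 0.5,
                                 germline_vaf_center = 0.5,
                                 germline_alpha = 0.01,
                                 germline_min_vaf = 0.30,
                                 germline_somatic_max_vaf = 0.02,
                                 germline_somatic_max_reads = 3L,
                                 strand_bias_p = 0.005) {
  th <- list(
    min_alt_reads_genotyping = as.integer(min_alt_reads_genotyping),
    background_k = as.numeric(background_k),
    denovo_min_vaf = as.numeric(denovo_min_vaf),
    denovo_min_alt_reads = as.integer(denovo_min_alt_reads),
    denovo_buffy_ratio = as.numeric(denovo_buffy_ratio),
    artifact_max_fraction = as.numeric(artifact_max_fraction),
    germline_vaf_center = as.numeric(germline_vaf_center),
    germline_alpha = as.numeric(germline_alpha),
    germline_min_vaf = as.numeric(germline_min_vaf),
    germline_somatic_max_vaf = as.numeric(germline_somatic_max_vaf),
    germline_somatic_max_reads = as.integer(germline_somatic_max_reads),
    strand_bias_p = as.numeric(strand_bias_p)
  )
  counts <- c("min_alt_reads_genotyping", "denovo_min_alt_reads",
              "germline_somatic_max_reads")
  if (any(unlist(th[counts]) < 1L)) stop("count thresholds must be >= 1")
  fracs <- c("denovo_min_vaf", "artifact_max_fraction", "germline_vaf_center",
             "germline_alpha", "germline_min_vaf", "germline_somatic_max_vaf",
             "strand_bias_p")
  fr <- unlist(th[fracs])
  if (any(fr <= 0 | fr > 1)) stop("fraction thresholds must lie in (0, 1]")
  if (th$background_k < 0) stop("background_k must be >= 0")
  if (th$denovo_buffy_ratio < 1) stop("denovo_buffy_ratio must be >= 1")
  structure(th, class = "rb_thresholds")
}

#' @export
print.rb_thresholds <- function(x, ...) {
  cat("Detection thresholds:\n")
  for (nm in names(x)) cat(sprintf("  %-26s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
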