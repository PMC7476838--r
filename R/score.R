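#' Score pipeline output against a simulation truth
#'
#' Computes stage-level performance metrics against the ground truth the
#' data were generated from:
#'
#' * genotyping sensitivity: fraction of shedding somatic truth variants
#'   (true cfDNA VAF > 0, not germline) detected in the primary cfDNA
#'   sample;
#' * de novo sensitivity: same denominator, called de novo;
#' * de novo false calls: calls that match no truth variant at all
#'   (error-site artifacts surviving the filters);
#' * VAF recovery: mean signed bias and mean absolute error of the
#'   estimated VAF over detected shedding variants;
#' * replicate concordance: Pearson r^2 of the VAF pairs of variants
#'   detected in both technical replicates of the replicated patients.
#'
#' @param truth the [cohort_truth()] the dataset was generated from.
#' @param genotype result of [genotype_cohort()] on that dataset.
#' @param denovo optional result of [call_denovo_cohort()].
#' @return named list of metrics (NA where not computable).
#' @export
score_pipeline <- function(truth, genotype, denovo = NULL) {
  stopifnot(inherits(truth, "rb_cohort_truth"))
  res <- genotype$results
  tv <- truth$variants
  key <- function(df) paste(df$patient_id, df$chrom, df$pos, df$ref, df$alt)
  if (!all(key(tv[!tv$is_germline, ]) %in% key(res))) {
    stop("genotyping results do not cover the truth cohort; ",
         "truth/results mismatch")
  }
  shed <- tv[!tv$is_germline & tv$true_cfdna_vaf > 0, , drop = FALSE]
  prim <- res[res$primary, , drop = FALSE]
  m <- match(key(shed), key(prim))
  det <- !is.na(m) & prim$status[m] == "detected"

  sens_geno <- mean(det)
  vaf_err <- prim$cfdna_vaf[m][det] - shed$true_cfdna_vaf[det]

  sens_denovo <- NA_real_
  n_false_calls <- NA_integer_
  if (!is.null(denovo)) {
    calls <- denovo$calls
    ck <- if (is.null(calls) || !nrow(calls)) character(0) else key(calls)
    sens_denovo <- mean(key(shed) %in% ck)
    n_false_calls <- sum(!ck %in% key(tv))
  }

  list(
    sensitivity_genotyping = sens_geno,
    sensitivity_denovo = sens_denovo,
    n_detected_genotyping = sum(det),
    n_shedding_somatic = nrow(shed),
    n_false_denovo_calls = n_false_calls,
    vaf_bias = if (length(vaf_err)) mean(vaf_err) else NA_real_,
    vaf_mae = if (length(vaf_err)) mean(abs(vaf_err)) else NA_real_,
    replicate_r2 = replicate_r2(res)
  )
}

#' Pearson r^2 between technical-replicate VAF pairs
#'
#' For each patient with two or more cfDNA samples in the results, variants
#' detected in both the first and second replicate contribute their VAF
#' pair; the squared Pearson correlation is computed across all pairs
#' (NA with fewer than 3 pairs).
#'
#' @param results detection-result rows from [genotype_cohort()].
#' @return squared Pearson correlation, or NA.
#' @export
replicate_r2 <- function(results) {
  pairs <- replicate_vaf_pairs(results)
  if (nrow(pairs) < 3L) return(NA_real_)
  cor(pairs$vaf_rep1, pairs$vaf_rep2)^2
}

replicate_vaf_pairs <- function(results) {
  out <- data.frame(vaf_rep1 = numeric(0), vaf_rep2 = numeric(0))
  for (p in unique(results$patient_id)) {
    pr <- results[results$patient_id == p, , drop = FALSE]
    reps <- sort(unique(pr$sample_id))
    if (length(reps) < 2L) next
    a <- pr[pr$sample_id == reps[1L], , drop = FALSE]
    b <- pr[pr$sample_id == reps[2L], , drop = FALSE]
    k <- function(df) paste(df$chrom, df$pos, df$ref, df$alt)
    m <- match(k(a), k(b))
    both <- !is.na(m) & a$status == "detected" & b$status[m] == "detected"
    if (any(both)) {
      out <- rbind(out, data.frame(vaf_rep1 = a$cfdna_vaf[both],
                                   vaf_rep2 = b$cfdna_vaf[m][both]))
    }
  }
  out
}
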