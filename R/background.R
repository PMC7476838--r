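#' Build the per-variant empirical background null
#'
#' The chance of seeing a given variant as a sequencing/process artifact is
#' estimated from the buffy coats of *other* patients in the cohort, where
#' the somatic mutation cannot be present. The null is simply the per-sample
#' VAF distribution at that variant: its arithmetic mean and sample standard
#' deviation (n-1 denominator; 0 when only one panel sample) give the
#' detection threshold `mean + k * SD`. A case VAF must exceed the threshold
#' strictly to count as above background.
#'
#' Panel samples with zero coverage at the variant enter as VAF 0 (with a
#' message); the methods vignette discusses this convention.
#'
#' @param variant a single variant key (1-row data.frame).
#' @param panel pileup rows for this variant from unmatched buffy coats.
#' @param k number of standard deviations above the mean (default 2).
#' @return object of class `rb_background`: list with `variant`,
#'   `panel_vafs`, `mean_vaf`, `sd_vaf`, `threshold`, `n_panel`, `k`.
#' @export
build_background <- function(variant, panel, k = 2) {
  if (is.null(panel) || nrow(panel) == 0L) {
    stop("cannot build a background null from an empty unmatched panel for ",
         variant_id(variant))
  }
  if (!all(panel$chrom == variant$chrom & panel$pos == variant$pos &
             panel$ref == variant$ref & panel$alt == variant$alt)) {
    stop("panel rows do not all match variant ", variant_id(variant))
  }
  if (!all(panel$role %in% c("buffy_unmatched", "buffy_matched"))) {
    stop("background panel must consist of buffy-coat samples")
  }
  if (any(panel$depth == 0L)) {
    message(sum(panel$depth == 0L), " unmatched panel sample(s) with zero ",
            "coverage at ", variant_id(variant), " enter the null as VAF 0")
  }
  vafs <- vaf(panel$alt_reads, panel$depth)
  m <- mean(vafs)
  s <- if (length(vafs) > 1L) sd(vafs) else 0
  structure(
    list(variant = variant, panel_vafs = vafs, mean_vaf = m, sd_vaf = s,
         threshold = m + k * s, n_panel = length(vafs), k = k,
         panel_samples = panel$sample_id),
    class = "rb_background"
  )
}

#' Compare a case VAF against the background threshold
#'
#' Strict inequality: a VAF exactly equal to `mean + k * SD` does not exceed
#' the background.
#'
#' @param case_vaf numeric VAF(s) observed in the case sample.
#' @param model an `rb_background` object for the same variant.
#' @return logical vector.
#' @export
exceeds_background <- function(case_vaf, model) {
  stopifnot(inherits(model, "rb_background"))
  case_vaf > model$threshold
}

#' @export
print.rb_background <- function(x, ...) {
  cat(sprintf(
    "Background null for %s: n=%d, mean=%.3g, sd=%.3g, threshold=%.3g (k=%g)\n",
    variant_id(x$variant), x$n_panel, x$mean_vaf, x$sd_vaf, x$threshold, x$k))
  invisible(x)
}

# Assemble the leave-one-out unmatched panel for `patient` at `variant`:
# all other patients' buffy-coat rows, relabelled buffy_unmatched. If the
# pileup carries no row for a panel sample at this variant, zero-depth
# counts are synthesized for every other-patient buffy sample (warning).
unmatched_panel <- function(pileup, variant, patient) {
  buffy <- pileup[pileup$role %in% c("buffy_matched", "buffy_unmatched"), ,
                  drop = FALSE]
  buffy <- buffy[sample_patient(buffy$sample_id) != patient, , drop = FALSE]
  rows <- pileup_at(buffy, variant)
  if (nrow(rows) == 0L && nrow(buffy) > 0L) {
    warning("no unmatched-panel counts at ", variant_id(variant),
            " for patient ", patient, "; using zero-depth counts")
    samples <- unique(buffy$sample_id)
    rows <- do.call(rbind, lapply(samples, function(s)
      zero_count(s, "buffy_unmatched", variant)))
  }
  if (nrow(rows)) rows$role <- "buffy_unmatched"
  rows
}
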