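#' Draw allele counts under the count-level sequencing model
#'
#' The generator works at count level: per observation, depth is drawn from
#' a negative binomial around its mean (overdispersion via `size =
#' depth_dispersion`; `Inf` gives fixed depth), then reads are partitioned
#' multinomially into true-variant reads (probability
#' `true_vaf * (1 - error_rate)`), error reads supporting this specific
#' allele (`(1 - true_vaf) * error_rate_allele + extra_error_vaf`), and
#' reference reads. Artifact flags are Bernoulli(`artifact_rate`) on
#' error-origin reads only; the strand split of alt reads is
#' Binomial(alt, 0.5).
#'
#' @param n number of observations to draw.
#' @param depth mean depth (vector recycled to `n`).
#' @param true_vaf true variant allele fraction(s).
#' @param error_rate total per-base substitution error probability; a
#'   specific alternative allele receives `error_rate / 3` of it unless
#'   `error_rate_allele` is given explicitly (e.g. for indel errors).
#' @param artifact_rate probability an error-origin alt read is flagged.
#' @param extra_error_vaf additional per-allele error VAF (site- and
#'   library-specific recurrent artifacts).
#' @param depth_dispersion negative-binomial size; `Inf` = fixed depth.
#' @param error_rate_allele per-allele error probability override.
#' @return data.frame with `depth, alt_reads, alt_artifact_reads, alt_fwd,
#'   alt_rev` (n rows), satisfying all allele-count invariants.
#' @export
simulate_allele_counts <- function(n, depth, true_vaf, error_rate = 0,
                                   artifact_rate = 0, extra_error_vaf = 0,
                                   depth_dispersion = Inf,
                                   error_rate_allele = error_rate / 3) {
  depth <- rep_len(depth, n)
  v <- rep_len(true_vaf, n)
  e_tot <- rep_len(error_rate, n)
  e_all <- rep_len(error_rate_allele, n)
  extra <- rep_len(extra_error_vaf, n)
  art <- rep_len(artifact_rate, n)
  dd <- if (is.finite(depth_dispersion)) {
    rnbinom(n, mu = depth, size = depth_dispersion)
  } else round(depth)
  p_true <- v * (1 - e_tot)
  p_err <- pmin((1 - v) * e_all + extra, 1 - p_true)
  alt_true <- rbinom(n, dd, p_true)
  # conditional binomial == multinomial split of the remaining reads
  alt_err <- rbinom(n, dd - alt_true, ifelse(p_true < 1, p_err / (1 - p_true), 0))
  alt <- alt_true + alt_err
  artifact <- rbinom(n, alt_err, art)
  fwd <- rbinom(n, alt, 0.5)
  data.frame(depth = dd, alt_reads = alt, alt_artifact_reads = artifact,
             alt_fwd = fwd, alt_rev = alt - fwd)
}

#' Define a synthetic cohort (ground truth)
#'
#' A cohort truth fixes everything the generator needs: the per-patient
#' variants with their true cfDNA VAFs and germline status, the error and
#' artifact model, the depth model, and which patients carry technical
#' replicates. Germline variants have true VAF 0.5 in both buffy coat and
#' cfDNA; somatic variants have buffy-coat true VAF 0.
#'
#' @param variants data.frame with columns `patient_id, chrom, pos, ref,
#'   alt, label, true_cfdna_vaf, is_germline`, and optionally `seeded_below`
#'   (`"none"`, `"genotyping_floor"`, `"background"`), `depth_mult`
#'   (site-level capture-depth multiplier, default 1) and `panel_error_vaf`
#'   (recurrent buffy-coat artifact VAF at the site, default 0).
#' @param patients optional data.frame `patient_id, n_replicates`; defaults
#'   to one cfDNA sample per patient seen in `variants`.
#' @param error_rate per-base per-read substitution error (default 5e-4).
#' @param indel_error_rate per-allele indel error probability (default 5e-5).
#' @param depth_mean mean unique coverage (default 1530).
#' @param depth_dispersion negative-binomial size (default 60, mild).
#' @param artifact_rate artifact-flag probability on error reads.
#' @param n_error_sites error-only panel sites to scatter per cohort.
#' @param panel panel regions the cohort is captured on.
#' @param seed default RNG seed for [simulate_cohort()].
#' @return object of class `rb_cohort_truth`.
#' @export
cohort_truth <- function(variants, patients = NULL, error_rate = 5e-4,
                         indel_error_rate = 5e-5, depth_mean = 1530,
                         depth_dispersion = 60, artifact_rate = 0.1,
                         n_error_sites = 150, panel = rb1_panel(),
                         seed = 20200707) {
  need <- c("patient_id", "chrom", "pos", "ref", "alt", "true_cfdna_vaf",
            "is_germline")
  miss <- setdiff(need, names(variants))
  if (length(miss)) stop("truth variants missing column(s): ",
                         paste(miss, collapse = ", "))
  if (!"label" %in% names(variants)) variants$label <- NA_character_
  variants$label <- as.character(variants$label)
  if (!"seeded_below" %in% names(variants)) variants$seeded_below <- "none"
  if (!"depth_mult" %in% names(variants)) variants$depth_mult <- 1
  if (!"panel_error_vaf" %in% names(variants)) variants$panel_error_vaf <- 0
  if (any(variants$true_cfdna_vaf < 0 | variants$true_cfdna_vaf > 1)) {
    stop("true_cfdna_vaf must lie in [0, 1]")
  }
  if (any(variants$is_germline & variants$true_cfdna_vaf != 0.5)) {
    stop("germline variants must have true VAF 0.5")
  }
  if (!all(variants$seeded_below %in% c("none", "genotyping_floor",
                                        "background"))) {
    stop("seeded_below must be none, genotyping_floor or background")
  }
  if (is.null(patients)) {
    patients <- data.frame(patient_id = unique(variants$patient_id),
                           n_replicates = 1L, stringsAsFactors = FALSE)
  }
  if (error_rate < 0 || error_rate >= 1) stop("error_rate out of range")
  if (depth_mean < 1) stop("depth_mean must be >= 1")
  structure(
    list(variants = variants, patients = patients, error_rate = error_rate,
         indel_error_rate = indel_error_rate, depth_mean = depth_mean,
         depth_dispersion = depth_dispersion, artifact_rate = artifact_rate,
         n_error_sites = as.integer(n_error_sites), panel = panel,
         seed = as.integer(seed)),
    class = "rb_cohort_truth"
  )
}

#' @export
print.rb_cohort_truth <- function(x, ...) {
  cat(sprintf(
    "Synthetic cohort truth: %d patients, %d variants (%d germline), %s",
    nrow(x$patients), nrow(x$variants), sum(x$variants$is_germline),
    sprintf("~%dx mean coverage, error %.2g, seed %d\n",
            round(x$depth_mean), x$error_rate, x$seed)))
  invisible(x)
}

#' Simulate a cohort dataset from a truth object
#'
#' Produces the full pileup table (cfDNA samples including replicates,
#' matched buffy coats, tumor samples at each patient's own variants) over
#' all truth variants plus `n_error_sites` error-only sites scattered
#' across the panel, together with per-patient tumor variant lists.
#' Every sample is genotyped at every site (so the unmatched buffy coats of
#' other patients are available to build the background null for each
#' variant). Recurrent site artifacts (`panel_error_vaf`) are applied to
#' buffy-coat libraries. Output is deterministic given (truth, seed).
#'
#' @param truth an [cohort_truth()] object.
#' @param seed RNG seed (defaults to `truth$seed`).
#' @param out_dir optional directory: writes `pileup.tsv`, `panel.bed`,
#'   `truth.json`, and `tumor/<patient>.vcf`.
#' @return list with `pileup`, `tumor_variants`, `sites`, `truth`.
#' @export
simulate_cohort <- function(truth, seed = truth$seed, out_dir = NULL) {
  stopifnot(inherits(truth, "rb_cohort_truth"))
  set.seed(seed)
  sites <- truth_sites(truth)

  pats <- truth$patients
  samples <- list()
  for (i in seq_len(nrow(pats))) {
    p <- pats$patient_id[i]
    nr <- pats$n_replicates[i]
    cf <- if (nr > 1L) paste0(p, ".cfdna.r", seq_len(nr)) else paste0(p, ".cfdna")
    samples[[i]] <- data.frame(
      sample_id = c(cf, paste0(p, ".buffy"), paste0(p, ".tumor")),
      role = c(rep("cfdna", nr), "buffy_matched", "tumor"),
      patient_id = p, stringsAsFactors = FALSE)
  }
  samples <- do.call(rbind, samples)

  grid <- merge(samples, sites, by = NULL)  # cartesian sample x site
  grid <- grid[grid$role != "tumor" | (!is.na(grid$owner) &
                                         grid$owner == grid$patient_id), ,
               drop = FALSE]
  grid <- grid[order(grid$sample_id, grid$chrom, grid$pos, grid$alt), ,
               drop = FALSE]
  own <- !is.na(grid$owner) & grid$owner == grid$patient_id
  v <- numeric(nrow(grid))
  v[own & grid$role == "cfdna"] <- grid$true_cfdna_vaf[own & grid$role == "cfdna"]
  is_germ <- own & grid$is_germline
  v[is_germ & grid$role != "cfdna"] <- 0.5
  v[own & !grid$is_germline & grid$role == "tumor"] <- 0.45
  v[is_germ & grid$role == "cfdna"] <- 0.5
  mu <- ifelse(grid$role == "tumor", 600, truth$depth_mean * grid$depth_mult)
  extra <- ifelse(grid$role == "buffy_matched", grid$panel_error_vaf, 0)

  cnt <- simulate_allele_counts(
    n = nrow(grid), depth = mu, true_vaf = v,
    error_rate = grid$err_total, artifact_rate = truth$artifact_rate,
    extra_error_vaf = extra, depth_dispersion = truth$depth_dispersion,
    error_rate_allele = grid$err_allele)

  pileup <- cbind(grid[, c("sample_id", "role", "chrom", "pos", "ref", "alt")],
                  cnt)
  rownames(pileup) <- NULL
  pileup <- validate_pileup(pileup)

  tumor_variants <- truth$variants[, c("patient_id", "chrom", "pos", "ref",
                                       "alt", "label"), drop = FALSE]
  out <- list(pileup = pileup, tumor_variants = tumor_variants,
              sites = sites, truth = truth)
  if (!is.null(out_dir)) write_cohort(out, out_dir)
  out
}

# Site table: truth variants (owner = patient) + error-only sites.
truth_sites <- function(truth) {
  tv <- truth$variants
  sites <- data.frame(
    chrom = tv$chrom, pos = as.integer(tv$pos), ref = tv$ref, alt = tv$alt,
    owner = tv$patient_id, true_cfdna_vaf = tv$true_cfdna_vaf,
    is_germline = tv$is_germline, depth_mult = tv$depth_mult,
    panel_error_vaf = tv$panel_error_vaf,
    err_total = truth$error_rate, err_allele = truth$error_rate / 3,
    stringsAsFactors = FALSE)
  n_err <- truth$n_error_sites
  if (n_err > 0L) {
    panel <- truth$panel
    w <- panel$end - panel$start
    reg <- sample.int(nrow(panel), n_err, replace = TRUE, prob = w)
    pos <- panel$start[reg] + 1L +
      vapply(w[reg], function(x) sample.int(x, 1L) - 1L, integer(1))
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n_err, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))
    is_indel <- seq_len(n_err) %% 10L == 0L
    ref[is_indel] <- paste0(ref[is_indel],
                            sample(bases, sum(is_indel), replace = TRUE))
    alt[is_indel] <- substr(ref[is_indel], 1L, 1L)
    err <- data.frame(
      chrom = panel$chrom[reg], pos = as.integer(pos), ref = ref, alt = alt,
      owner = NA_character_, true_cfdna_vaf = 0, is_germline = FALSE,
      depth_mult = 1, panel_error_vaf = 0,
      err_total = ifelse(is_indel, truth$indel_error_rate, truth$error_rate),
      err_allele = ifelse(is_indel, truth$indel_error_rate,
                          truth$error_rate / 3),
      stringsAsFactors = FALSE)
    # drop error sites colliding with truth variants or with each other
    err <- err[!paste(err$chrom, err$pos) %in% paste(sites$chrom, sites$pos), ,
               drop = FALSE]
    err <- err[!duplicated(paste(err$chrom, err$pos, err$ref, err$alt)), ,
               drop = FALSE]
    sites <- rbind(sites, err)
  }
  sites
}

#' Write a simulated cohort dataset to a directory
#'
#' @param dataset result of [simulate_cohort()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_pileup(dataset$pileup, file.path(dir, "pileup.tsv"))
  write_panel(dataset$truth$panel, file.path(dir, "panel.bed"))
  write_truth(dataset$truth, file.path(dir, "truth.json"))
  tdir <- file.path(dir, "tumor")
  dir.create(tdir, showWarnings = FALSE)
  tv <- dataset$tumor_variants
  for (p in unique(tv$patient_id)) {
    write_variants(tv[tv$patient_id == p, , drop = FALSE],
                   file.path(tdir, paste0(p, ".vcf")))
  }
  invisible(dir)
}

#' Serialize / restore a cohort truth as JSON
#'
#' @param truth an `rb_cohort_truth` object.
#' @param path file path.
#' @return `path` invisibly / the restored truth object.
#' @export
write_truth <- function(truth, path) {
  x <- unclass(truth)
  jsonlite::write_json(x, path, dataframe = "rows", digits = NA,
                       auto_unbox = TRUE, pretty = TRUE, na = "null")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cohort_truth(
    variants = x$variants, patients = x$patients, error_rate = x$error_rate,
    indel_error_rate = x$indel_error_rate, depth_mean = x$depth_mean,
    depth_dispersion = x$depth_dispersion, artifact_rate = x$artifact_rate,
    n_error_sites = x$n_error_sites,
    panel = panel_regions(x$panel$chrom, x$panel$start, x$panel$end,
                          x$panel$name),
    seed = x$seed)
}

#' Read per-patient tumor VCFs from a directory
#'
#' Each `<patient>.vcf` contributes its variants tagged with that patient
#' id (file base name).
#'
#' @param dir directory of per-patient VCF files.
#' @return data.frame with `patient_id` + variant key columns.
#' @export
read_tumor_vcfs <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.vcf$", full.names = TRUE))
  if (!length(files)) stop("no .vcf files found in ", dir)
  out <- lapply(files, function(f) {
    v <- read_variants(f)
    if (nrow(v)) v$patient_id <- sub("\\.vcf$", "", basename(f))
    v
  })
  out <- out[vapply(out, nrow, integer(1)) > 0]
  if (!length(out)) {
    return(data.frame(patient_id = character(0), chrom = character(0),
                      pos = integer(0), ref = character(0),
                      alt = character(0), label = character(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("patient_id", "chrom", "pos", "ref", "alt", "label")]
}
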