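#' Assemble a run configuration
#'
#' Orchestration for the three pipeline stages. A config is a plain named
#' list (serializable to/from YAML with [read_run_config()]); every run
#' echoes its effective configuration into the output directory.
#'
#' @param data directory holding a simulated or imported dataset
#'   (`pileup.tsv`, `panel.bed`, `tumor/<patient>.vcf`, optional
#'   `truth.json`).
#' @param out output directory for reports.
#' @param seed integer RNG seed (used by `run_simulate`).
#' @param reference use the built-in reference cohort truth
#'   ([rb1_reference_cohort()]) for simulation.
#' @param truth path to a truth JSON for simulation (ignored when
#'   `reference` is TRUE).
#' @param replicate_handling `"separate"` (default: replicates analyzed
#'   independently, the first is primary) or `"merged"` (replicate counts
#'   summed into one cfDNA sample per patient).
#' @param thresholds named list of [detection_thresholds()] overrides.
#' @return config list of class `rb_run_config`.
#' @export
run_config <- function(data = NULL, out = NULL, seed = 20200707L,
                       reference = FALSE, truth = NULL,
                       replicate_handling = c("separate", "merged"),
                       thresholds = list()) {
  replicate_handling <- match.arg(replicate_handling)
  structure(list(data = data, out = out, seed = as.integer(seed),
                 reference = reference, truth = truth,
                 replicate_handling = replicate_handling,
                 thresholds = thresholds),
            class = "rb_run_config")
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file path.
#' @return an `rb_run_config` (read) or `path` invisibly (write).
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(run_config, x[intersect(names(x), names(formals(run_config)))])
}

#' @rdname read_run_config
#' @param config an `rb_run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

config_thresholds <- function(config) {
  do.call(detection_thresholds, config$thresholds)
}

prepare_out <- function(config, stage) {
  if (is.null(config$out)) stop("config$out (output directory) is required")
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  write_run_config(config, file.path(config$out,
                                     paste0(stage, ".config.yaml")))
  config$out
}

load_dataset <- function(config) {
  if (is.null(config$data)) stop("config$data (dataset directory) is required")
  pfile <- file.path(config$data, "pileup.tsv")
  if (!file.exists(pfile)) stop("missing input file: ", pfile)
  pileup <- read_pileup(pfile)
  if (config$replicate_handling == "merged") pileup <- merge_replicates(pileup)
  bed <- file.path(config$data, "panel.bed")
  panel <- if (file.exists(bed)) read_panel(bed) else NULL
  tdir <- file.path(config$data, "tumor")
  tumor <- if (dir.exists(tdir)) read_tumor_vcfs(tdir) else NULL
  list(pileup = pileup, panel = panel, tumor = tumor)
}

#' Sum technical-replicate cfDNA counts into one sample per patient
#'
#' Used by `replicate_handling = "merged"`: all cfDNA rows of a patient are
#' collapsed per variant by summing depth, alt, artifact and strand counts,
#' under sample id `<patient>.cfdna`.
#'
#' @param pileup pileup table.
#' @return pileup table with merged cfDNA samples.
#' @export
merge_replicates <- function(pileup) {
  cf <- pileup[pileup$role == "cfdna", , drop = FALSE]
  rest <- pileup[pileup$role != "cfdna", , drop = FALSE]
  if (!nrow(cf)) return(pileup)
  keyv <- paste(sample_patient(cf$sample_id), cf$chrom, cf$pos, cf$ref, cf$alt)
  agg <- lapply(split(cf, keyv), function(g) {
    out <- g[1L, , drop = FALSE]
    out$sample_id <- paste0(sample_patient(g$sample_id[1L]), ".cfdna")
    for (cl in c("depth", "alt_reads", "alt_artifact_reads", "alt_fwd",
                 "alt_rev")) {
      out[[cl]] <- sum(g[[cl]])
    }
    out
  })
  out <- rbind(rest, do.call(rbind, agg))
  rownames(out) <- NULL
  validate_pileup(out)
}

#' Run the simulation stage
#'
#' Generates a dataset directory from the reference truth or a truth JSON.
#'
#' @param config an `rb_run_config` or path to a YAML config.
#' @return the dataset (invisibly); files under `config$out`.
#' @export
run_simulate <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  truth <- if (isTRUE(config$reference)) {
    rb1_reference_cohort()
  } else if (!is.null(config$truth)) {
    read_truth(config$truth)
  } else {
    stop("run_simulate needs reference = TRUE or a truth JSON path")
  }
  out <- prepare_out(config, "simulate")
  ds <- simulate_cohort(truth, seed = config$seed, out_dir = out)
  message("simulated ", nrow(ds$pileup), " pileup rows for ",
          nrow(truth$patients), " patients into ", out)
  invisible(ds)
}

#' Run the tumor-guided genotyping stage
#'
#' Genotypes every tumor mutation in every patient's cfDNA, classifies
#' germline status from the matched buffy coat, excludes germline variants
#' from the somatic report, and writes: `detection_results.tsv` (every
#' result with per-criterion flags), `germline_report.tsv`,
#' `background_summary.tsv` (the per-variant null), and `summary.json`
#' (cohort counts over the somatic-reported primary results).
#'
#' @param config an `rb_run_config` or path to a YAML config.
#' @return list (invisibly): `results`, `somatic`, `germline_excluded`,
#'   `germline_calls`, `summary`.
#' @export
run_genotype <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  ds <- load_dataset(config)
  if (is.null(ds$tumor)) stop("missing tumor VCF directory under ",
                              config$data)
  out <- prepare_out(config, "genotype")
  th <- config_thresholds(config)
  geno <- genotype_cohort(ds$tumor, ds$pileup, th)
  gl <- classify_germline_cohort(ds$tumor, ds$pileup, th)
  part <- filter_germline(geno$results, gl)
  summary <- cohort_summary(part$somatic[part$somatic$primary, , drop = FALSE])

  write.table(geno$results, file.path(out, "detection_results.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(gl, file.path(out, "germline_report.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_background_summary(ds$tumor, ds$pileup, th,
                           file.path(out, "background_summary.tsv"))
  jsonlite::write_json(summary, file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(results = geno$results, somatic = part$somatic,
                 germline_excluded = part$germline, germline_calls = gl,
                 summary = summary))
}

write_background_summary <- function(tumor_variants, pileup, thresholds,
                                     path) {
  if (!nrow(tumor_variants)) return(invisible(path))
  rows <- lapply(seq_len(nrow(tumor_variants)), function(i) {
    v <- tumor_variants[i, , drop = FALSE]
    m <- build_background(v, unmatched_panel(pileup, v, v$patient_id),
                          k = thresholds$background_k)
    data.frame(patient_id = v$patient_id, chrom = v$chrom, pos = v$pos,
               ref = v$ref, alt = v$alt, n_panel = m$n_panel,
               mean_vaf = m$mean_vaf, sd_vaf = m$sd_vaf,
               threshold = m$threshold, stringsAsFactors = FALSE)
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Run the de novo calling stage
#'
#' Scans every patient's primary cfDNA sample across the panel, applies the
#' de novo filter cascade, and writes per-patient annotated VCFs, the full
#' candidate table with failed filters (`denovo_candidates.tsv`), the
#' concordance table against the tumor mutations when available
#' (`concordance.tsv`), and `summary.json`.
#'
#' @param config an `rb_run_config` or path to a YAML config.
#' @return the [call_denovo_cohort()] result, invisibly.
#' @export
run_denovo <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  ds <- load_dataset(config)
  if (is.null(ds$panel)) stop("missing panel.bed under ", config$data)
  out <- prepare_out(config, "denovo")
  th <- config_thresholds(config)
  dn <- call_denovo_cohort(ds$pileup, ds$panel, th, tumor_variants = ds$tumor)
  write_denovo_vcfs(dn, file.path(out, "denovo_vcf"))
  if (!is.null(dn$candidates)) {
    write.table(dn$candidates, file.path(out, "denovo_candidates.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(dn$concordance)) {
    write.table(dn$concordance, file.path(out, "concordance.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(dn$summary, file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dn)
}

#' Run the scoring stage
#'
#' Re-runs genotyping and de novo calling in memory on a dataset that
#' carries its `truth.json`, scores them with [score_pipeline()], and
#' writes `metrics.json`.
#'
#' @param config an `rb_run_config` or path to a YAML config.
#' @return the metrics list, invisibly.
#' @export
run_score <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  tfile <- file.path(config$data, "truth.json")
  if (!file.exists(tfile)) stop("missing input file: ", tfile)
  truth <- read_truth(tfile)
  ds <- load_dataset(config)
  out <- prepare_out(config, "score")
  th <- config_thresholds(config)
  geno <- genotype_cohort(ds$tumor, ds$pileup, th)
  dn <- call_denovo_cohort(ds$pileup, ds$panel, th, tumor_variants = ds$tumor)
  metrics <- score_pipeline(truth, geno, dn)
  jsonlite::write_json(metrics, file.path(out, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(metrics)
}
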