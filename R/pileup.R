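PILEUP_COLS <- c("sample_id", "role", "chrom", "pos", "ref", "alt",
                 "depth", "alt_reads", "alt_artifact_reads", "alt_fwd",
                 "alt_rev")

PILEUP_ROLES <- c("cfdna", "buffy_matched", "buffy_unmatched", "tumor")

#' Construct per-sample per-variant allele counts
#'
#' An allele count is one sample's observation at one variant: total
#' qualifying depth, alt-supporting reads, how many of those were flagged as
#' artifact, and the forward/reverse strand split of the alt reads. Depth
#' counts only qualifying (deduplicated, quality-filtered) reads; the pileup
#' producer owns those floors.
#'
#' @param sample_id sample identifiers. By convention
#'   `<patient>.<role>[.r<k>]`; the token before the first `.` is the
#'   patient id (see [sample_patient()]).
#' @param role one of `"cfdna"`, `"buffy_matched"`, `"buffy_unmatched"`,
#'   `"tumor"`.
#' @param chrom,pos,ref,alt the variant key fields (1-based `pos`).
#' @param depth total qualifying reads (>= 0).
#' @param alt_reads alt-supporting reads (`0 <= alt_reads <= depth`).
#' @param alt_artifact_reads alt reads flagged artifact (<= `alt_reads`).
#' @param alt_fwd,alt_rev strand split (`alt_fwd + alt_rev == alt_reads`).
#' @return validated data.frame with the pileup columns.
#' @export
allele_count <- function(sample_id, role, chrom, pos, ref, alt, depth,
                         alt_reads, alt_artifact_reads = 0L,
                         alt_fwd = NULL, alt_rev = NULL) {
  n <- max(length(sample_id), length(chrom), length(pos), length(depth),
           length(alt_reads))
  if (is.null(alt_fwd)) {
    alt_fwd <- rep_len(as.integer(alt_reads), n) %/% 2L
  }
  alt_fwd <- rep_len(as.integer(alt_fwd), n)
  if (is.null(alt_rev)) alt_rev <- rep_len(as.integer(alt_reads), n) - alt_fwd
  df <- data.frame(
    sample_id = rep_len(as.character(sample_id), n),
    role = rep_len(as.character(role), n),
    chrom = rep_len(as.character(chrom), n),
    pos = rep_len(as.integer(pos), n),
    ref = rep_len(as.character(ref), n),
    alt = rep_len(as.character(alt), n),
    depth = rep_len(as.integer(depth), n),
    alt_reads = rep_len(as.integer(alt_reads), n),
    alt_artifact_reads = rep_len(as.integer(alt_artifact_reads), n),
    alt_fwd = alt_fwd,
    alt_rev = rep_len(as.integer(alt_rev), n),
    stringsAsFactors = FALSE
  )
  validate_pileup(df)
}

#' Validate a pileup table against the allele-count invariants
#'
#' Hard errors (naming the offending row) on: missing columns, unknown role,
#' negative counts, `alt_reads > depth`, `alt_artifact_reads > alt_reads`,
#' or `alt_fwd + alt_rev != alt_reads`.
#'
#' @param pileup data.frame with the pileup columns.
#' @return the validated data.frame, invisibly usable downstream.
#' @export
validate_pileup <- function(pileup) {
  missing_cols <- setdiff(PILEUP_COLS, names(pileup))
  if (length(missing_cols)) {
    stop("pileup table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  bad_role <- !pileup$role %in% PILEUP_ROLES
  if (any(bad_role)) {
    stop("unknown role '", pileup$role[which(bad_role)[1]], "' in pileup row ",
         which(bad_role)[1])
  }
  num <- c("pos", "depth", "alt_reads", "alt_artifact_reads", "alt_fwd",
           "alt_rev")
  for (cl in num) pileup[[cl]] <- as.integer(pileup[[cl]])
  chk <- function(bad, what) {
    if (any(bad)) stop(what, " in pileup row ", which(bad)[1])
  }
  chk(pileup$depth < 0L | pileup$alt_reads < 0L |
        pileup$alt_artifact_reads < 0L | pileup$alt_fwd < 0L |
        pileup$alt_rev < 0L, "negative count")
  chk(pileup$alt_reads > pileup$depth, "alt_reads > depth")
  chk(pileup$alt_artifact_reads > pileup$alt_reads,
      "alt_artifact_reads > alt_reads")
  chk(pileup$alt_fwd + pileup$alt_rev != pileup$alt_reads,
      "alt_fwd + alt_rev != alt_reads")
  pileup
}

#' Read an allele-count pileup table
#'
#' Tab-separated with a header row and columns exactly
#' `sample_id role chrom pos ref alt depth alt_reads alt_artifact_reads
#' alt_fwd alt_rev`; lines starting with `#` are ignored. All allele-count
#' invariants are enforced on load.
#'
#' @param path path to the TSV file.
#' @return validated pileup data.frame.
#' @export
read_pileup <- function(path) {
  if (!file.exists(path)) stop("pileup file not found: ", path)
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                   check.names = FALSE,
                   colClasses = c(sample_id = "character",
                                  role = "character", chrom = "character",
                                  ref = "character", alt = "character"))
  validate_pileup(df)
}

#' Write an allele-count pileup table
#'
#' @param pileup pileup data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pileup <- function(pileup, path) {
  validate_pileup(pileup)
  write.table(pileup[, PILEUP_COLS], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Variant allele frequency
#'
#' `alt_reads / depth`, defined as 0 at depth 0 so that a site with no
#' coverage can never satisfy a strict detection inequality.
#'
#' @param alt_reads,depth integer vectors.
#' @return numeric vector of fractions in `[0, 1]`.
#' @examples
#' vaf(2, 2286)   # 0.000875
#' vaf(0, 0)      # 0
#' @export
vaf <- function(alt_reads, depth) {
  ifelse(depth == 0, 0, alt_reads / depth)
}

#' Patient id encoded in a sample id
#'
#' Sample ids follow `<patient>.<role>[.r<k>]`; the patient id is the token
#' before the first dot (the whole id when there is no dot).
#'
#' @param sample_id character vector.
#' @return character vector of patient ids.
#' @export
sample_patient <- function(sample_id) {
  sub("\\..*$", "", sample_id)
}

# Rows of `pileup` for one variant; zero-row result allowed.
pileup_at <- function(pileup, variant) {
  pileup[pileup$chrom == variant$chrom & pileup$pos == variant$pos &
           pileup$ref == variant$ref & pileup$alt == variant$alt, ,
         drop = FALSE]
}

# Synthesize a depth-0 allele count for a missing observation.
zero_count <- function(sample_id, role, variant) {
  allele_count(sample_id, role, variant$chrom, variant$pos, variant$ref,
               variant$alt, depth = 0L, alt_reads = 0L)
}
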