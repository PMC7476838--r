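#' Construct a table of normalized variant keys
#'
#' A variant key identifies a genomic variant by `(chrom, pos, ref, alt)`
#' with `pos` the 1-based position of the first reference base. Keys are
#' normalized on construction: shared trailing bases are trimmed, then
#' shared leading bases (advancing `pos`), always keeping at least one base
#' of each allele so indels retain their single anchor base. `label` is an
#' optional human-readable annotation (e.g. `"p.Q736*"`, `"X702_splice"`)
#' and never enters variant identity.
#'
#' @param chrom chromosome names.
#' @param pos 1-based integer positions (>= 1).
#' @param ref,alt non-empty uppercase A/C/G/T allele strings; `ref != alt`.
#' @param label optional annotation strings (recycled; `NA` allowed).
#' @return data.frame with columns `chrom, pos, ref, alt, label`.
#' @examples
#' variant_key("chr13", 48941648, "C", "T")
#' variant_key("chr13", 100, "ACC", "AC")  # normalized to pos 100 AC>A
#' @export
variant_key <- function(chrom, pos, ref, alt, label = NA_character_) {
  n <- max(length(chrom), length(pos), length(ref), length(alt))
  v <- data.frame(
    chrom = rep_len(as.character(chrom), n),
    pos = rep_len(as.integer(pos), n),
    ref = toupper(rep_len(as.character(ref), n)),
    alt = toupper(rep_len(as.character(alt), n)),
    label = rep_len(as.character(label), n),
    stringsAsFactors = FALSE
  )
  bad <- !grepl("^[ACGT]+$", v$ref) | !grepl("^[ACGT]+$", v$alt)
  if (any(bad)) {
    stop("ref/alt alleles must be non-empty A/C/G/T strings (records ",
         paste(which(bad), collapse = ", "), ")")
  }
  if (any(v$pos < 1L)) stop("pos must be >= 1")
  v <- normalize_variants(v)
  if (any(v$ref == v$alt)) stop("ref and alt must differ after normalization")
  v
}

#' Normalize variant alleles (trim to parsimonious representation)
#'
#' Removes bases shared between `ref` and `alt` at the right end, then at the
#' left end (incrementing `pos` for each left-trimmed base), keeping at least
#' one base per allele as the indel anchor. Normalization is idempotent.
#' Full left-alignment across repeat tracts requires the reference sequence
#' and is out of scope; keys are assumed to come from a consistent caller.
#'
#' @param variants data.frame with `pos`, `ref`, `alt` columns.
#' @return the same data.frame with normalized `pos`, `ref`, `alt`.
#' @export
normalize_variants <- function(variants) {
  for (i in seq_len(nrow(variants))) {
    nm <- normalize_allele_pair(variants$pos[i], variants$ref[i], variants$alt[i])
    variants$pos[i] <- nm$pos
    variants$ref[i] <- nm$ref
    variants$alt[i] <- nm$alt
  }
  variants
}

normalize_allele_pair <- function(pos, ref, alt) {
  r <- strsplit(ref, "", fixed = TRUE)[[1]]
  a <- strsplit(alt, "", fixed = TRUE)[[1]]
  # trim shared trailing bases
  while (length(r) > 1L && length(a) > 1L && r[length(r)] == a[length(a)]) {
    r <- r[-length(r)]
    a <- a[-length(a)]
  }
  # trim shared leading bases, advancing pos
  while (length(r) > 1L && length(a) > 1L && r[1L] == a[1L]) {
    r <- r[-1L]
    a <- a[-1L]
    pos <- pos + 1L
  }
  list(pos = as.integer(pos), ref = paste(r, collapse = ""),
       alt = paste(a, collapse = ""))
}

variant_id <- function(v) paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")

same_variant <- function(a, b) {
  identical(as.character(a$chrom), as.character(b$chrom)) &&
    a$pos == b$pos && a$ref == b$ref && a$alt == b$alt
}

#' Read a variant list from a VCF file
#'
#' One variant key is produced per (record, alt allele); multi-allelic
#' records are split. Keys are normalized and duplicates (same chrom, pos,
#' ref, alt) collapsed, preserving first-seen order. The VCF `ID` field, when
#' not `"."`, is kept as the `label`.
#'
#' Records whose REF or ALT contains characters outside A/C/G/T (symbolic
#' alleles, breakends, `*`) are dropped with a warning.
#'
#' @param path path to a VCF 4.x file.
#' @return data.frame of variant keys (see [variant_key()]).
#' @export
read_variants <- function(path) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  vcf <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) stop("VCF parse error in ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  fix <- vcfR::getFIX(vcf)
  if (!is.null(fix) && !is.matrix(fix)) fix <- t(fix)  # single-record VCF
  if (is.null(fix) || nrow(fix) == 0L) {
    return(variant_key(character(), integer(), character(), character())[0, ])
  }
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  out <- vector("list", nrow(fix))
  for (i in seq_len(nrow(fix))) {
    ref <- toupper(fix$REF[i])
    alts <- toupper(strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]])
    if (!grepl("^[ACGT]+$", ref)) {
      warning("dropping VCF record ", i, " (", fix$CHROM[i], ":", fix$POS[i],
              "): REF allele '", fix$REF[i], "' is not plain A/C/G/T")
      next
    }
    keep <- grepl("^[ACGT]+$", alts)
    if (any(!keep)) {
      warning("dropping non-ACGT alt allele(s) in VCF record ", i, " (",
              fix$CHROM[i], ":", fix$POS[i], ")")
    }
    alts <- alts[keep]
    if (!length(alts)) next
    lab <- if (!is.na(fix$ID[i]) && fix$ID[i] != ".") fix$ID[i] else NA_character_
    out[[i]] <- variant_key(fix$CHROM[i], as.integer(fix$POS[i]), ref, alts, lab)
  }
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out)) {
    return(variant_key(character(), integer(), character(), character())[0, ])
  }
  out <- out[!duplicated(variant_id(out)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a variant table as VCF 4.2
#'
#' Used for tumor mutation lists and for de novo call sets; optional `filter`
#' and `info` columns carry per-record FILTER strings and pre-formatted INFO
#' fields (e.g. `"VAF=0.05;ALTREADS=75"`). Output round-trips through
#' [read_variants()] to the identical key set.
#'
#' @param variants variant key data.frame; may carry `filter`/`info` columns.
#' @param path output path.
#' @param info_header character vector of extra `##INFO`/`##FILTER` header
#'   lines (without trailing newline).
#' @return `path`, invisibly.
#' @export
write_variants <- function(variants, path, info_header = character()) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##source=rbcfdna-%s", as.character(utils::packageVersion("rbcfdna"))),
    info_header,
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          sep = "\t")
  )
  rows <- character(0)
  if (nrow(variants)) {
    id <- if ("label" %in% names(variants)) variants$label else NA_character_
    id[is.na(id) | id == ""] <- "."
    filt <- if ("filter" %in% names(variants)) variants$filter else "."
    filt[is.na(filt) | filt == ""] <- "."
    info <- if ("info" %in% names(variants)) variants$info else "."
    info[is.na(info) | info == ""] <- "."
    rows <- paste(variants$chrom, variants$pos, id, variants$ref,
                  variants$alt, ".", filt, info, sep = "\t")
  }
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read targeted-panel regions from a BED file
#'
#' BED is 0-based half-open; that convention is kept in the returned table
#' (`start` 0-based inclusive, `end` exclusive). Overlapping or bookended
#' regions on the same chromosome are merged; the merged region keeps the
#' first constituent's name.
#'
#' @param path path to a BED file (3+ columns).
#' @return data.frame with columns `chrom, start, end, name`.
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  gr <- rtracklayer::import(path, format = "BED")
  nm <- if (!is.null(gr$name)) as.character(gr$name) else
    sprintf("region_%03d", seq_along(gr))
  panel_regions(as.character(GenomicRanges::seqnames(gr)),
                GenomicRanges::start(gr) - 1L,
                GenomicRanges::end(gr), nm)
}

#' Construct (and merge) panel regions
#'
#' @param chrom chromosome names.
#' @param start 0-based inclusive starts.
#' @param end 0-based exclusive ends (`end > start`).
#' @param name region labels.
#' @return data.frame `chrom, start, end, name`, sorted, non-overlapping.
#' @export
panel_regions <- function(chrom, start, end, name = NULL) {
  start <- as.integer(start)
  end <- as.integer(end)
  if (any(end <= start)) stop("panel regions require start < end")
  if (is.null(name)) name <- sprintf("region_%03d", seq_along(chrom))
  df <- data.frame(chrom = as.character(chrom), start = start, end = end,
                   name = as.character(name), stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  out <- df[0, ]
  for (i in seq_len(nrow(df))) {
    n <- nrow(out)
    if (n > 0L && out$chrom[n] == df$chrom[i] && df$start[i] <= out$end[n]) {
      out$end[n] <- max(out$end[n], df$end[i])
    } else {
      out <- rbind(out, df[i, ])
    }
  }
  rownames(out) <- NULL
  out
}

#' Write panel regions as BED
#'
#' @param regions panel region data.frame (see [panel_regions()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(regions, path) {
  write.table(regions[, c("chrom", "start", "end", "name")], path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Test whether 1-based positions fall inside panel regions
#'
#' @param chrom,pos vectors of chromosome names and 1-based positions.
#' @param regions panel region data.frame.
#' @return logical vector.
#' @export
in_panel <- function(chrom, pos, regions) {
  res <- logical(length(pos))
  for (i in seq_len(nrow(regions))) {
    res <- res | (chrom == regions$chrom[i] &
                    pos > regions$start[i] & pos <= regions$end[i])
  }
  res
}
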