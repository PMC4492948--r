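# ---- shared VCF line machinery -----------------------------------------------

# Split VCF body lines into a character matrix of fields. VCF is tab-delimited;
# hand-written fixtures with single-space separation are tolerated.
split_vcf_fields <- function(lines, line_no, min_fields) {
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(fields) < min_fields
  if (any(short)) {
    fields[short] <- strsplit(trimws(lines[short]), "[ \t]+")
  }
  bad <- lengths(fields) < min_fields
  if (any(bad)) {
    stop(sprintf("malformed VCF line %d: expected >= %d fields, found %d",
                 line_no[bad][1], min_fields, lengths(fields)[bad][1]))
  }
  fields
}

parse_info_field <- function(info) {
  # -> named character vector; flags get NA values
  if (is.na(info) || info == "." || !nzchar(info)) return(character(0))
  parts <- strsplit(info, ";", fixed = TRUE)[[1]]
  eq <- regexpr("=", parts, fixed = TRUE)
  keys <- ifelse(eq > 0, substr(parts, 1, eq - 1), parts)
  vals <- ifelse(eq > 0, substring(parts, eq + 1), NA_character_)
  names(vals) <- keys
  vals
}

dot_na <- function(x) ifelse(x == ".", NA_character_, x)

num_or_na <- function(x) suppressWarnings(as.numeric(x))

# Per-record FORMAT/sample lookup: returns character vector of the sample
# value of `key` for each record (NA where absent or ".").
format_value <- function(fmt, sample, key) {
  out <- rep(NA_character_, length(fmt))
  has <- !is.na(fmt) & !is.na(sample)
  if (!any(has)) return(out)
  fk <- strsplit(fmt[has], ":", fixed = TRUE)
  sv <- strsplit(sample[has], ":", fixed = TRUE)
  out[has] <- mapply(function(k, v) {
    i <- match(key, k)
    if (is.na(i) || i > length(v)) NA_character_ else v[i]
  }, fk, sv, USE.NAMES = FALSE)
  dot_na(out)
}

vcf_header_lines <- function(lines) startsWith(lines, "#")

# ---- gVCF --------------------------------------------------------------------

#' Parse gVCF text into a record table
#'
#' Reads VCF 4.x text using the gVCF block extension: non-variant stretches are
#' encoded as block records with ALT `.`, an `END` coordinate and block-level
#' quality summaries (`GQX`, `MIN_DP`). Every body line maps to exactly one
#' record. `MIN_DP` and `GQX` are accepted from either the INFO column or the
#' FORMAT/sample columns (callers differ on where they put them).
#'
#' @param lines Character vector of gVCF lines (header plus body), e.g. from
#'   [readLines()].
#' @return A data frame of class `gvcf_records`, one row per body line, with
#'   columns `contig`, `pos`, `id`, `ref`, `alt` (comma-joined alternate
#'   alleles, `NA` for blocks), `qual`, `filter`, `kind` (`"VARIANT"` or
#'   `"BLOCK"`), `end` (1-based inclusive; for blocks from `END`, for variants
#'   `pos + nchar(ref) - 1`), `gt`, `gqx`, `dp`, `min_dp`. The header lines are
#'   kept in attribute `"header"`.
#' @details Records must be sorted by contig (in order of first appearance)
#'   then position; `END < POS` or a malformed line is an error carrying the
#'   offending line number.
#' @seealso [read_gvcf()], [write_gvcf()], [index_gvcf()]
#' @export
#' @examples
#' g <- parse_gvcf(c(
#'   "##fileformat=VCFv4.1",
#'   "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
#'   "chr1\t100\t.\tA\t.\t.\tPASS\tEND=199\tGT:GQX:DP:MIN_DP\t0/0:50:32:30",
#'   "chr1\t1500\trs1\tA\tG\t120\tPASS\t.\tGT:GQX\t0/1:110"
#' ))
#' g$kind
parse_gvcf <- function(lines) {
  hdr <- vcf_header_lines(lines)
  header <- lines[hdr]
  body <- lines[!hdr]
  body_no <- which(!hdr)
  body_keep <- nzchar(trimws(body))
  body <- body[body_keep]
  body_no <- body_no[body_keep]
  if (length(body) == 0) {
    rec <- empty_gvcf_records()
    attr(rec, "header") <- header
    return(rec)
  }
  f <- split_vcf_fields(body, body_no, 8L)
  get <- function(i) vapply(f, function(x) if (length(x) >= i) x[i] else NA_character_,
                            character(1))
  contig <- get(1)
  pos <- suppressWarnings(as.integer(get(2)))
  if (anyNA(pos)) {
    stop(sprintf("malformed VCF line %d: non-numeric POS", body_no[which(is.na(pos))[1]]))
  }
  id <- dot_na(get(3))
  ref <- get(4)
  alt_raw <- get(5)
  if (any(ref == "." | !nzchar(ref))) {
    stop(sprintf("malformed VCF line %d: missing REF",
                 body_no[which(ref == "." | !nzchar(ref))[1]]))
  }
  qual <- num_or_na(dot_na(get(6)))
  filter <- dot_na(get(7))
  info <- get(8)
  fmt <- if (any(lengths(f) >= 10)) get(9) else rep(NA_character_, length(f))
  smp <- if (any(lengths(f) >= 10)) get(10) else rep(NA_character_, length(f))

  kind <- ifelse(alt_raw == "." | !nzchar(alt_raw), "BLOCK", "VARIANT")
  alt <- ifelse(kind == "BLOCK", NA_character_, alt_raw)

  info_list <- lapply(info, parse_info_field)
  info_get <- function(key) {
    vapply(info_list, function(v) if (key %in% names(v)) v[[key]] else NA_character_,
           character(1))
  }
  end_info <- suppressWarnings(as.integer(info_get("END")))
  end <- ifelse(kind == "BLOCK",
                ifelse(is.na(end_info), pos, end_info),
                pos + nchar(ref) - 1L)
  bad_end <- which(end < pos)
  if (length(bad_end) > 0) {
    stop(sprintf("invalid record at line %d: END (%d) < POS (%d)",
                 body_no[bad_end[1]], end[bad_end[1]], pos[bad_end[1]]))
  }

  gt <- format_value(fmt, smp, "GT")
  gqx <- num_or_na(ifelse(is.na(format_value(fmt, smp, "GQX")),
                          info_get("GQX"), format_value(fmt, smp, "GQX")))
  dp <- suppressWarnings(as.integer(ifelse(is.na(format_value(fmt, smp, "DP")),
                                           info_get("DP"), format_value(fmt, smp, "DP"))))
  min_dp_chr <- format_value(fmt, smp, "MIN_DP")
  min_dp <- suppressWarnings(as.integer(ifelse(is.na(min_dp_chr), info_get("MIN_DP"),
                                               min_dp_chr)))

  # ordering: contigs grouped in first-appearance order, positions sorted within
  contig_rank <- match(contig, unique(contig))
  if (is.unsorted(contig_rank)) {
    i <- which(diff(contig_rank) < 0)[1] + 1L
    stop(sprintf("ordering error at line %d: contig %s appears after a later contig",
                 body_no[i], contig[i]))
  }
  ooo <- which(diff(pos) < 0 & diff(contig_rank) == 0)
  if (length(ooo) > 0) {
    i <- ooo[1] + 1L
    stop(sprintf("ordering error at line %d: position %d before previous record",
                 body_no[i], pos[i]))
  }

  rec <- data.frame(
    contig = contig, pos = pos, id = id, ref = ref, alt = alt,
    qual = qual, filter = filter, kind = kind, end = as.integer(end),
    gt = gt, gqx = gqx, dp = dp, min_dp = min_dp,
    stringsAsFactors = FALSE
  )
  class(rec) <- c("gvcf_records", "data.frame")
  attr(rec, "header") <- header
  rec
}

empty_gvcf_records <- function() {
  rec <- data.frame(
    contig = character(0), pos = integer(0), id = character(0),
    ref = character(0), alt = character(0), qual = numeric(0),
    filter = character(0), kind = character(0), end = integer(0),
    gt = character(0), gqx = numeric(0), dp = integer(0), min_dp = integer(0),
    stringsAsFactors = FALSE
  )
  class(rec) <- c("gvcf_records", "data.frame")
  rec
}

#' Read a gVCF file
#'
#' @param path Path to a gVCF text file.
#' @return See [parse_gvcf()].
#' @export
read_gvcf <- function(path) parse_gvcf(readLines(path))

fmt_num <- function(x) {
  out <- rep(".", length(x))
  ok <- !is.na(x)
  out[ok] <- format(x[ok], trim = TRUE, scientific = FALSE, digits = 15)
  out
}

fmt_chr <- function(x) ifelse(is.na(x) | !nzchar(x), ".", x)

# Serialize gvcf_records rows back to VCF body lines (gvcftools convention:
# GQX/DP/MIN_DP in FORMAT, END in INFO for blocks).
format_gvcf_body <- function(rec, extra_info = NULL) {
  info <- ifelse(rec$kind == "BLOCK", paste0("END=", rec$end), ".")
  if (!is.null(extra_info)) {
    info <- ifelse(nzchar(extra_info),
                   ifelse(info == ".", extra_info, paste(info, extra_info, sep = ";")),
                   info)
  }
  fmt <- character(nrow(rec))
  smp <- character(nrow(rec))
  for (i in seq_len(nrow(rec))) {
    keys <- "GT"
    vals <- fmt_chr(rec$gt[i])
    if (!is.na(rec$gqx[i])) { keys <- c(keys, "GQX"); vals <- c(vals, fmt_num(rec$gqx[i])) }
    if (!is.na(rec$dp[i]))  { keys <- c(keys, "DP");  vals <- c(vals, fmt_num(rec$dp[i])) }
    if (!is.na(rec$min_dp[i])) { keys <- c(keys, "MIN_DP"); vals <- c(vals, fmt_num(rec$min_dp[i])) }
    fmt[i] <- paste(keys, collapse = ":")
    smp[i] <- paste(vals, collapse = ":")
  }
  paste(rec$contig, rec$pos, fmt_chr(rec$id), rec$ref, fmt_chr(rec$alt),
        fmt_num(rec$qual), fmt_chr(rec$filter), info, fmt, smp, sep = "\t")
}

gvcf_standard_header <- function(sample = "SAMPLE", extra = character(0),
                                 contigs = character(0)) {
  c("##fileformat=VCFv4.1",
    sprintf("##contig=<ID=%s>", contigs),
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position of the non-variant block\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GQX,Number=1,Type=Float,Description=\"Genotype quality floor over the record\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=MIN_DP,Number=1,Type=Integer,Description=\"Minimum depth over the block\">",
    extra,
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample, sep = "\t"))
}

#' Write gVCF records
#'
#' Serializes a `gvcf_records` table (see [parse_gvcf()]) to gVCF text with
#' `END` in INFO for block records and `GT:GQX:DP:MIN_DP` in the sample column.
#' `parse_gvcf(write_gvcf(x))` reproduces `x` field by field.
#'
#' @param rec `gvcf_records` data frame.
#' @param path Optional file path; when `NULL` the lines are returned.
#' @param sample Sample name for the header line.
#' @return Invisibly (or visibly when `path` is `NULL`) the character vector
#'   of file lines.
#' @export
write_gvcf <- function(rec, path = NULL, sample = "SAMPLE") {
  lines <- c(gvcf_standard_header(sample, contigs = unique(rec$contig)),
             format_gvcf_body(rec))
  if (is.null(lines)) lines <- character(0)
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

# ---- sites-only VCF (dbSNP / ClinVar style catalogs) -------------------------

#' Parse a sites-only VCF catalog
#'
#' Reads a dbSNP- or ClinVar-style sites-only VCF into a site table. One row
#' is produced per ALT-bearing line; multiallelic lines keep their full
#' comma-joined ALT list on one row. Lines with ALT `.` carry no allele to
#' genotype and are skipped (counted in attribute `"n_skipped"`). Duplicate
#' `(contig, pos, ref, id)` combinations are kept and flagged in the
#' `duplicate` column.
#'
#' @param lines Character vector of VCF lines.
#' @param freq_key INFO key carrying allele frequencies. dbSNP's `CAF`
#'   convention (reference frequency first, then one value per ALT) is
#'   detected by length; a key listing only per-ALT frequencies (e.g. `AF`)
#'   also works.
#' @param sig_key INFO key carrying clinical significance labels.
#' @return Data frame of class `site_records` with columns `contig`, `pos`,
#'   `rsid`, `ref`, `alt` (comma-joined), `alt_freqs` (comma-joined numbers or
#'   `NA`), `clnsig`, `duplicate`.
#' @export
parse_site_vcf <- function(lines, freq_key = "CAF", sig_key = "CLNSIG") {
  hdr <- vcf_header_lines(lines)
  body <- lines[!hdr]
  body_no <- which(!hdr)
  keep <- nzchar(trimws(body))
  body <- body[keep]
  body_no <- body_no[keep]
  if (length(body) == 0) {
    out <- empty_site_records()
    attr(out, "n_skipped") <- 0L
    return(out)
  }
  f <- split_vcf_fields(body, body_no, 8L)
  get <- function(i) vapply(f, `[`, character(1), i)
  contig <- get(1)
  pos <- suppressWarnings(as.integer(get(2)))
  rsid <- dot_na(get(3))
  ref <- get(4)
  alt <- get(5)
  info <- get(8)
  if (any(is.na(ref) | ref == "." | !nzchar(ref))) {
    stop(sprintf("parse error at line %d: missing REF",
                 body_no[which(is.na(ref) | ref == "." | !nzchar(ref))[1]]))
  }
  if (any(is.na(alt) | !nzchar(alt))) {
    stop(sprintf("parse error at line %d: missing ALT",
                 body_no[which(is.na(alt) | !nzchar(alt))[1]]))
  }
  skip <- alt == "."
  n_skipped <- sum(skip)
  contig <- contig[!skip]; pos <- pos[!skip]; rsid <- rsid[!skip]
  ref <- ref[!skip]; alt <- alt[!skip]; info <- info[!skip]

  info_list <- lapply(info, parse_info_field)
  alt_freqs <- vapply(seq_along(info_list), function(i) {
    v <- info_list[[i]]
    if (!(freq_key %in% names(v)) || is.na(v[[freq_key]])) return(NA_character_)
    vals <- suppressWarnings(as.numeric(split_csv(v[[freq_key]])))
    n_alt <- length(split_csv(alt[i]))
    if (length(vals) == n_alt + 1L) vals <- vals[-1L]  # CAF: drop leading ref freq
    if (length(vals) != n_alt) return(NA_character_)
    paste(fmt_num(vals), collapse = ",")
  }, character(1))
  clnsig <- vapply(info_list, function(v) {
    if (sig_key %in% names(v)) v[[sig_key]] else NA_character_
  }, character(1))

  key <- paste(contig, pos, ref, rsid, sep = "\r")
  out <- data.frame(
    contig = contig, pos = pos, rsid = rsid, ref = ref, alt = alt,
    alt_freqs = alt_freqs, clnsig = clnsig,
    duplicate = duplicated(key) | duplicated(key, fromLast = TRUE),
    stringsAsFactors = FALSE
  )
  class(out) <- c("site_records", "data.frame")
  attr(out, "n_skipped") <- n_skipped
  out
}

empty_site_records <- function() {
  out <- data.frame(
    contig = character(0), pos = integer(0), rsid = character(0),
    ref = character(0), alt = character(0), alt_freqs = character(0),
    clnsig = character(0), duplicate = logical(0), stringsAsFactors = FALSE
  )
  class(out) <- c("site_records", "data.frame")
  out
}

#' Read a sites-only VCF catalog file
#' @param path File path.
#' @inheritParams parse_site_vcf
#' @return See [parse_site_vcf()].
#' @export
read_site_vcf <- function(path, freq_key = "CAF", sig_key = "CLNSIG") {
  parse_site_vcf(readLines(path), freq_key = freq_key, sig_key = sig_key)
}

#' Write a sites-only VCF catalog
#'
#' Companion writer to [parse_site_vcf()], used mainly by the synthetic-data
#' generator.
#'
#' @param sites `site_records` data frame.
#' @param path Optional output path.
#' @param freq_key INFO key used for frequencies (written in the dbSNP `CAF`
#'   convention: reference frequency first).
#' @param sig_key INFO key for clinical significance.
#' @return The file lines (invisibly when `path` is given).
#' @export
write_site_vcf <- function(sites, path = NULL, freq_key = "CAF", sig_key = "CLNSIG") {
  info <- vapply(seq_len(nrow(sites)), function(i) {
    parts <- character(0)
    fq <- suppressWarnings(as.numeric(split_csv(sites$alt_freqs[i])))
    if (length(fq) > 0 && !anyNA(fq)) {
      parts <- c(parts, paste0(freq_key, "=",
                               paste(fmt_num(c(1 - sum(fq), fq)), collapse = ",")))
    }
    if (!is.na(sites$clnsig[i])) parts <- c(parts, paste0(sig_key, "=", sites$clnsig[i]))
    if (length(parts) == 0) "." else paste(parts, collapse = ";")
  }, character(1))
  body <- paste(sites$contig, sites$pos, fmt_chr(sites$rsid), sites$ref,
                sites$alt, ".", ".", info, sep = "\t")
  lines <- c("##fileformat=VCFv4.1",
             sprintf("##INFO=<ID=%s,Number=.,Type=Float,Description=\"Allele frequencies (reference first)\">", freq_key),
             sprintf("##INFO=<ID=%s,Number=.,Type=String,Description=\"Clinical significance\">", sig_key),
             paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", sep = "\t"),
             body)
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
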