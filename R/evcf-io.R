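# eVCF: a standard VCF of the caller's variant records plus one explicit
# genotype record per catalog site (hom-ref as ALT "." / GT 0/0, no-call as
# GT ./.), with catalog provenance in the header and clinical annotations in
# INFO.

EVCF_INFO_KEYS <- c(
  known      = "##INFO=<ID=known,Number=0,Type=Flag,Description=\"Site present in the site catalog\">",
  gwascat_id = "##INFO=<ID=gwascat_id,Number=.,Type=String,Description=\"GWAS catalog association identifiers\">",
  odds_ratio = "##INFO=<ID=odds_ratio,Number=.,Type=Float,Description=\"Odds ratios aligned to gwascat_id\">",
  clnsig     = "##INFO=<ID=clnsig,Number=.,Type=String,Description=\"Clinical significance labels\">",
  conflict   = "##INFO=<ID=conflict,Number=0,Type=Flag,Description=\"Catalog REF disagrees with the gVCF at this site\">"
)

#' eVCF header provenance
#'
#' Describes the site catalog and confidence policy that produced an eVCF;
#' rendered into the file header by [write_evcf()].
#'
#' @param catalog_name,catalog_version Catalog identity (e.g. a dbSNP build).
#'   Both must be non-empty whenever catalog site records are written.
#' @param source_gvcf Name of the gVCF the genotypes were resolved from.
#' @param policy Optional [confidence_policy()] rendered into the header.
#' @param extra_info_keys Named character vector of INFO declarations; the
#'   standard `known`, `gwascat_id`, `odds_ratio`, `clnsig` and `conflict`
#'   keys are always declared.
#' @return An object of class `evcf_header_meta`.
#' @export
evcf_header_meta <- function(catalog_name = "", catalog_version = "",
                             source_gvcf = NA_character_, policy = NULL,
                             extra_info_keys = character(0)) {
  structure(list(
    catalog_name = catalog_name,
    catalog_version = catalog_version,
    source_gvcf = source_gvcf,
    policy = policy,
    extra_info_keys = c(EVCF_INFO_KEYS, extra_info_keys)
  ), class = "evcf_header_meta")
}

evcf_records_template <- function(n) {
  data.frame(
    contig = character(n), pos = integer(n), id = rep(NA_character_, n),
    ref = character(n), alt = rep(NA_character_, n), qual = rep(NA_real_, n),
    filter = rep(NA_character_, n), kind = character(n), end = integer(n),
    gt = rep(NA_character_, n), gqx = rep(NA_real_, n), dp = rep(NA_integer_, n),
    min_dp = rep(NA_integer_, n),
    known = rep(NA, n), clnsig = rep(NA_character_, n),
    gwascat_id = rep(NA_character_, n), odds_ratio = rep(NA_character_, n),
    conflict = rep(NA, n), call_class = rep(NA_character_, n),
    source = rep(NA_character_, n),
    stringsAsFactors = FALSE
  )
}

is_catalog_record <- function(rec) {
  (!is.na(rec$known) & rec$known) |
    (!is.na(rec$source) & rec$source %in% c("BLOCK", "NONE"))
}

check_record_order <- function(rec, what = "records") {
  if (nrow(rec) < 2) return(invisible(TRUE))
  r <- match(rec$contig, unique(rec$contig))
  if (is.unsorted(r) || any(diff(rec$pos) < 0 & diff(r) == 0)) {
    stop("ordering error: ", what, " are not sorted by contig then position")
  }
  invisible(TRUE)
}

#' Write an eVCF file
#'
#' Serializes variant and catalog-site records to VCF 4.x text. Catalog
#' hom-ref sites are written with ALT `.` and GT `0/0`; no-call sites with GT
#' `./.`. The header carries one `##siteCatalog=<name=...,version=...>`
#' provenance line plus the confidence policy, and declares every INFO key
#' used in the body.
#'
#' @param rec An eVCF record table (as produced by [build_evcf()], or a
#'   `gvcf_records` table of plain variant records).
#' @param meta [evcf_header_meta()] provenance. `catalog_name` and
#'   `catalog_version` must be non-empty when any catalog site record is
#'   present.
#' @param path Optional output path.
#' @param sample Sample name for the column header.
#' @return The file lines (invisibly when `path` is given).
#' @export
write_evcf <- function(rec, meta, path = NULL, sample = "SAMPLE") {
  rec <- as_evcf_records(rec)
  check_record_order(rec, "eVCF records")
  has_catalog <- any(is_catalog_record(rec))
  if (has_catalog && (!nzchar(meta$catalog_name) || !nzchar(meta$catalog_version))) {
    stop("catalog records present but catalog_name/catalog_version empty in header meta")
  }
  used <- c("known", "clnsig", "gwascat_id", "odds_ratio", "conflict")[c(
    any(rec$known %in% TRUE), any(!is.na(rec$clnsig)),
    any(!is.na(rec$gwascat_id)), any(!is.na(rec$odds_ratio)),
    any(rec$conflict %in% TRUE))]
  undeclared <- setdiff(used, names(meta$extra_info_keys))
  if (length(undeclared) > 0) {
    stop("serialization error: INFO key(s) not declared in header meta: ",
         paste(undeclared, collapse = ", "))
  }

  info <- vapply(seq_len(nrow(rec)), function(i) {
    parts <- character(0)
    if (rec$known[i] %in% TRUE) parts <- c(parts, "known")
    if (!is.na(rec$gwascat_id[i])) parts <- c(parts, paste0("gwascat_id=", rec$gwascat_id[i]))
    if (!is.na(rec$odds_ratio[i])) parts <- c(parts, paste0("odds_ratio=", rec$odds_ratio[i]))
    if (!is.na(rec$clnsig[i])) parts <- c(parts, paste0("clnsig=", rec$clnsig[i]))
    if (rec$conflict[i] %in% TRUE) parts <- c(parts, "conflict")
    if (length(parts) == 0) "" else paste(parts, collapse = ";")
  }, character(1))

  base <- rec[, c("contig", "pos", "id", "ref", "alt", "qual", "filter", "kind",
                  "end", "gt", "gqx", "dp", "min_dp")]
  class(base) <- c("gvcf_records", "data.frame")
  body <- format_gvcf_body(base, extra_info = info)

  hdr <- c(
    "##fileformat=VCFv4.1",
    sprintf("##contig=<ID=%s>", unique(rec$contig)),
    if (has_catalog) sprintf("##siteCatalog=<name=%s,version=%s>",
                             meta$catalog_name, meta$catalog_version),
    if (!is.na(meta$source_gvcf)) sprintf("##sourceGvcf=%s", meta$source_gvcf),
    if (!is.null(meta$policy)) sprintf(
      "##confidencePolicy=<min_gqx=%s,min_dp=%s,require_pass=%s>",
      fmt_num(meta$policy$min_gqx), fmt_num(meta$policy$min_dp),
      tolower(meta$policy$require_pass)),
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position of the non-variant block\">",
    unname(meta$extra_info_keys),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GQX,Number=1,Type=Float,Description=\"Genotype quality floor\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=MIN_DP,Number=1,Type=Integer,Description=\"Minimum depth over the block\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample, sep = "\t")
  )
  lines <- c(hdr, body)
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

# Coerce a gvcf_records table (possibly without annotation columns) to the
# full eVCF column set.
as_evcf_records <- function(rec) {
  need <- c("known", "clnsig", "gwascat_id", "odds_ratio", "conflict",
            "call_class", "source")
  for (col in need) {
    if (!col %in% names(rec)) {
      rec[[col]] <- if (col %in% c("known", "conflict")) {
        rep(NA, nrow(rec))
      } else {
        rep(NA_character_, nrow(rec))
      }
    }
  }
  class(rec) <- c("evcf_records", "gvcf_records", "data.frame")
  rec
}

gt_call_class <- function(gt) {
  idx <- strsplit(ifelse(is.na(gt), "./.", gsub("|", "/", gt, fixed = TRUE)),
                  "/", fixed = TRUE)
  i1 <- suppressWarnings(as.integer(vapply(idx, `[`, character(1), 1)))
  i2 <- suppressWarnings(as.integer(vapply(idx, function(x) {
    if (length(x) >= 2) x[2] else x[1]
  }, character(1))))
  classify_gt_indices(i1, i2)
}

#' Parse eVCF text
#'
#' Re-reads an eVCF written by [write_evcf()]: the standard record fields plus
#' the `known` / `gwascat_id` / `odds_ratio` / `clnsig` / `conflict` INFO
#' annotations and a `call_class` derived from GT. Header provenance is kept
#' in attributes `"catalog_name"` / `"catalog_version"`.
#'
#' @param lines Character vector of eVCF lines.
#' @return Data frame of class `evcf_records`.
#' @export
parse_evcf <- function(lines) {
  rec <- parse_gvcf(lines)
  rec <- as_evcf_records(rec)
  header <- attr(rec, "header")
  hdr <- lines[vcf_header_lines(lines)]
  body <- lines[!vcf_header_lines(lines)]
  body <- body[nzchar(trimws(body))]
  if (nrow(rec) > 0) {
    f <- split_vcf_fields(body, seq_along(body), 8L)
    info_list <- lapply(vapply(f, `[`, character(1), 8), parse_info_field)
    rec$known <- vapply(info_list, function(v) "known" %in% names(v), logical(1))
    rec$conflict <- vapply(info_list, function(v) "conflict" %in% names(v), logical(1))
    pick <- function(key) vapply(info_list, function(v) {
      if (key %in% names(v)) v[[key]] else NA_character_
    }, character(1))
    rec$gwascat_id <- pick("gwascat_id")
    rec$odds_ratio <- pick("odds_ratio")
    rec$clnsig <- pick("clnsig")
    rec$call_class <- gt_call_class(rec$gt)
  }
  cat_line <- grep("^##siteCatalog=", hdr, value = TRUE)
  if (length(cat_line) == 1) {
    m <- regmatches(cat_line, regexec("name=([^,>]*),version=([^,>]*)", cat_line))[[1]]
    attr(rec, "catalog_name") <- m[2]
    attr(rec, "catalog_version") <- m[3]
  }
  attr(rec, "header") <- header
  rec
}

#' Read an eVCF file
#' @param path File path.
#' @return See [parse_evcf()].
#' @export
read_evcf <- function(path) parse_evcf(readLines(path))

# ---- annotation-table (ANNOVAR-style) export ---------------------------------

# One ref/alt pair -> (start, end, reference_observed, sample_observed) in the
# annotation-table dialect: SNVs as-is; deletions drop the left anchor base and
# observe "-"; insertions anchor at the last shared base with reference "-".
annovar_coords <- function(pos, ref, alt) {
  if (nchar(ref) == 1 && nchar(alt) == 1) {
    return(list(start = pos, end = pos, ref = ref, obs = alt))
  }
  if (nchar(ref) > nchar(alt) && startsWith(ref, alt)) {         # deletion
    return(list(start = pos + nchar(alt), end = pos + nchar(ref) - 1L,
                ref = substring(ref, nchar(alt) + 1), obs = "-"))
  }
  if (nchar(alt) > nchar(ref) && startsWith(alt, ref)) {         # insertion
    return(list(start = pos + nchar(ref) - 1L, end = pos + nchar(ref) - 1L,
                ref = "-", obs = substring(alt, nchar(ref) + 1)))
  }
  # block substitution: trim the shared leading prefix
  k <- 0L
  n <- min(nchar(ref), nchar(alt)) - 1L
  while (k < n && substr(ref, k + 1, k + 1) == substr(alt, k + 1, k + 1)) k <- k + 1L
  list(start = pos + k, end = pos + nchar(ref) - 1L,
       ref = substring(ref, k + 1), obs = substring(alt, k + 1))
}

#' Export eVCF records as an annotation table
#'
#' Converts resolved genotype records to the five-column tabular dialect used
#' by annotation engines (contig, start, end, reference observed, sample
#' observed): heterozygous and homozygous alternate genotypes produce one row
#' per distinct alternate allele, hom-ref sites produce one row with the
#' reference observed on both sides, deletions drop the left anchor base
#' (observed `-`), insertions anchor on the last reference base.
#'
#' @param rec eVCF record table with resolved genotypes.
#' @param skip_nocalls Drop records whose genotype is missing (`TRUE`,
#'   default; the number dropped is in attribute `"n_skipped"`). When `FALSE`,
#'   no-call records are exported with sample observed `.`.
#' @return Data frame with columns `contig`, `start`, `end`,
#'   `reference_observed`, `sample_observed`.
#' @export
export_annotation_table <- function(rec, skip_nocalls = TRUE) {
  rec <- as_evcf_records(rec)
  rows <- vector("list", nrow(rec))
  n_skipped <- 0L
  for (i in seq_len(nrow(rec))) {
    gt <- rec$gt[i]
    cls <- gt_call_class(gt)
    if (cls == "NO_CALL") {
      if (skip_nocalls) { n_skipped <- n_skipped + 1L; next }
      rows[[i]] <- data.frame(contig = rec$contig[i], start = rec$pos[i],
                              end = rec$pos[i] + nchar(rec$ref[i]) - 1L,
                              reference_observed = rec$ref[i],
                              sample_observed = ".", stringsAsFactors = FALSE)
      next
    }
    if (cls == "HOM_REF") {
      rows[[i]] <- data.frame(contig = rec$contig[i], start = rec$pos[i],
                              end = rec$pos[i] + nchar(rec$ref[i]) - 1L,
                              reference_observed = rec$ref[i],
                              sample_observed = rec$ref[i], stringsAsFactors = FALSE)
      next
    }
    alts <- split_csv(rec$alt[i])
    idx <- suppressWarnings(as.integer(strsplit(gsub("|", "/", gt, fixed = TRUE),
                                                "/", fixed = TRUE)[[1]]))
    alt_idx <- sort(unique(idx[idx > 0]))
    sub <- lapply(alt_idx, function(ai) {
      a <- annovar_coords(rec$pos[i], rec$ref[i], alts[ai])
      data.frame(contig = rec$contig[i], start = a$start, end = a$end,
                 reference_observed = a$ref, sample_observed = a$obs,
                 stringsAsFactors = FALSE)
    })
    rows[[i]] <- do.call(rbind, sub)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(contig = character(0), start = integer(0), end = integer(0),
                      reference_observed = character(0),
                      sample_observed = character(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "n_skipped") <- n_skipped
  out
}
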