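# Genotyping-array report ingestion: a minimal five-column TSV (marker id,
# chromosome, position, two called alleles), the level at which array exports
# are consumed here. Array no-calls arrive as "-" or "--".

#' Parse a genotyping-array report
#'
#' @param lines Character vector of TSV lines with a header row, or a data
#'   frame already read from one.
#' @param expected_sites Optional `site_records` table; markers whose id (or
#'   `(contig, pos)`) is absent from it are retained but flagged
#'   `unmatched = TRUE`.
#' @param cols Named character vector mapping the roles `marker`, `contig`,
#'   `pos`, `allele_a`, `allele_b` to the report's column names.
#' @return Data frame of class `array_genotypes` with columns `marker_id`,
#'   `contig`, `pos` (1-based), `allele_a`, `allele_b` (NA for array
#'   no-calls), `unmatched`.
#' @details Alleles must be A/C/G/T or the no-call markers `-` / `--`;
#'   anything else (e.g. `N`) is a parse error.
#' @export
parse_array_report <- function(lines, expected_sites = NULL,
                               cols = c(marker = "marker_id", contig = "contig",
                                        pos = "pos", allele_a = "allele_a",
                                        allele_b = "allele_b")) {
  tab <- if (is.data.frame(lines)) {
    lines
  } else {
    utils::read.delim(text = lines, header = TRUE, sep = "\t",
                      colClasses = "character", check.names = FALSE)
  }
  missing_cols <- setdiff(unname(cols), names(tab))
  if (length(missing_cols) > 0) {
    stop("array report lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  norm_allele <- function(x) {
    x <- toupper(trimws(as.character(x)))
    x[x %in% c("-", "--", "")] <- NA_character_
    bad <- !is.na(x) & !x %in% c("A", "C", "G", "T")
    if (any(bad)) {
      stop("parse error: non-ACGT array allele(s): ",
           paste(unique(x[bad]), collapse = ", "))
    }
    x
  }
  out <- data.frame(
    marker_id = as.character(tab[[cols[["marker"]]]]),
    contig = as.character(tab[[cols[["contig"]]]]),
    pos = as.integer(tab[[cols[["pos"]]]]),
    allele_a = norm_allele(tab[[cols[["allele_a"]]]]),
    allele_b = norm_allele(tab[[cols[["allele_b"]]]]),
    stringsAsFactors = FALSE
  )
  # one missing allele only happens on malformed exports; treat as full no-call
  half <- xor(is.na(out$allele_a), is.na(out$allele_b))
  out$allele_a[half] <- NA_character_
  out$allele_b[half] <- NA_character_
  if (!is.null(expected_sites)) {
    out$unmatched <- !(out$marker_id %in% expected_sites$rsid |
                         paste(out$contig, out$pos) %in%
                           paste(expected_sites$contig, expected_sites$pos))
  } else {
    out$unmatched <- FALSE
  }
  class(out) <- c("array_genotypes", "data.frame")
  out
}

#' Read a genotyping-array report file
#' @param path TSV file path.
#' @inheritParams parse_array_report
#' @return See [parse_array_report()].
#' @export
read_array_report <- function(path, expected_sites = NULL,
                              cols = c(marker = "marker_id", contig = "contig",
                                       pos = "pos", allele_a = "allele_a",
                                       allele_b = "allele_b")) {
  parse_array_report(readLines(path), expected_sites = expected_sites, cols = cols)
}

#' Write a genotyping-array report
#' @param ag `array_genotypes` data frame.
#' @param path Optional output path.
#' @return The file lines (invisibly when `path` is given).
#' @export
write_array_report <- function(ag, path = NULL) {
  body <- paste(ag$marker_id, ag$contig, ag$pos,
                ifelse(is.na(ag$allele_a), "-", ag$allele_a),
                ifelse(is.na(ag$allele_b), "-", ag$allele_b), sep = "\t")
  lines <- c(paste("marker_id", "contig", "pos", "allele_a", "allele_b", sep = "\t"),
             body)
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
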