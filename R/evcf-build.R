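# Core genotype resolution: a catalog site is genotyped from a variant record
# when one sits at its position, from covering high-confidence non-variant
# blocks (hom-ref) otherwise, and is a no-call when neither route passes the
# confidence policy. This is what lets a gVCF distinguish "clearly homozygous
# reference" from "cannot be called" -- the distinction a variant-only VCF
# erases.

#' Confidence policy for non-variant blocks
#'
#' The thresholds a non-variant block must meet before it may assert a
#' homozygous-reference genotype: a genotype-quality floor (`GQX`), a minimum
#' block depth (`MIN_DP`), and the FILTER status. Variant records are exempt
#' -- they carry the caller's own FILTER, which is copied through.
#'
#' @param min_gqx Minimum block GQX (default 20, a conventional Q20 floor).
#'   A block with missing GQX fails any finite threshold.
#' @param min_dp Minimum block depth (default 5, matching the read-depth floor
#'   used in the coverage QC). `MIN_DP` is used when present, `DP` otherwise;
#'   both missing fails.
#' @param require_pass Require FILTER to be `PASS` on blocks (default TRUE).
#' @return Object of class `confidence_policy`.
#' @export
confidence_policy <- function(min_gqx = 20, min_dp = 5, require_pass = TRUE) {
  stopifnot(min_gqx >= 0, min_dp >= 0)
  structure(list(min_gqx = min_gqx, min_dp = as.integer(min_dp),
                 require_pass = isTRUE(require_pass)),
            class = "confidence_policy")
}

#' @export
print.confidence_policy <- function(x, ...) {
  cat(sprintf("Confidence policy: GQX >= %s, depth >= %d, PASS filter %s\n",
              fmt_num(x$min_gqx), x$min_dp,
              if (x$require_pass) "required" else "not required"))
  invisible(x)
}

#' Build an interval index over gVCF records
#'
#' Per-contig interval lookup: a point (or span) query returns every record
#' whose `[pos, end]` intersects it. Overlapping block records are an error;
#' a variant record co-located with a block is tolerated with a warning (the
#' variant takes precedence during resolution).
#'
#' @param rec `gvcf_records` table.
#' @return Object of class `gvcf_index`.
#' @export
index_gvcf <- function(rec) {
  by_contig <- split(seq_len(nrow(rec)), rec$contig)
  idx <- lapply(by_contig, function(rows) {
    sub <- rec[rows, ]
    blk <- sub$kind == "BLOCK"
    if (sum(blk) > 1) {
      o <- order(sub$pos[blk])
      bp <- sub$pos[blk][o]; be <- sub$end[blk][o]
      ov <- which(bp[-1] <= be[-length(be)])
      if (length(ov) > 0) {
        stop(sprintf(
          "overlap error: block records %s:%d-%d and %s:%d-%d overlap",
          sub$contig[1], bp[ov[1]], be[ov[1]],
          sub$contig[1], bp[ov[1] + 1], be[ov[1] + 1]))
      }
    }
    if (any(blk) && any(!blk)) {
      vb <- IRanges::findOverlaps(
        IRanges::IRanges(sub$pos[!blk], sub$end[!blk]),
        IRanges::IRanges(sub$pos[blk], sub$end[blk]))
      if (length(vb) > 0) {
        warning(sprintf(
          "%d variant record(s) on %s overlap non-variant blocks; variant records take precedence",
          length(unique(S4Vectors::queryHits(vb))), sub$contig[1]))
      }
    }
    list(rows = rows, ranges = IRanges::IRanges(sub$pos, sub$end))
  })
  structure(list(records = rec, contigs = idx), class = "gvcf_index")
}

#' Query a gVCF index
#'
#' @param index A [index_gvcf()] result.
#' @param contig Contig name.
#' @param start,end 1-based inclusive query span (a point when `end = start`).
#' @return Integer row indices into the indexed record table, in record order
#'   (empty when nothing covers the span).
#' @export
query_gvcf_index <- function(index, contig, start, end = start) {
  ci <- index$contigs[[contig]]
  if (is.null(ci)) return(integer(0))
  hits <- IRanges::findOverlaps(IRanges::IRanges(start, end), ci$ranges)
  sort(ci$rows[S4Vectors::subjectHits(hits)])
}

block_passes <- function(rec, policy) {
  cov_dp <- ifelse(!is.na(rec$min_dp), rec$min_dp, rec$dp)
  ok <- rec$kind == "BLOCK" &
    !is.na(rec$gqx) & rec$gqx >= policy$min_gqx &
    !is.na(cov_dp) & cov_dp >= policy$min_dp
  if (policy$require_pass) ok <- ok & !is.na(rec$filter) & rec$filter == "PASS"
  ok
}

empty_calls <- function() {
  data.frame(contig = character(0), pos = integer(0), rsid = character(0),
             ref = character(0), alt = character(0), call_class = character(0),
             alleles = character(0), source = character(0), gqx = numeric(0),
             dp = numeric(0), conflict = logical(0), stringsAsFactors = FALSE)
}

#' Resolve genotypes at catalog sites from a gVCF
#'
#' For each site: a variant record at `(contig, pos)` supplies the genotype
#' directly from its GT (allele indices 0/0 hom-ref, 0/x het, x/x hom-alt,
#' x/y het-alt); otherwise, when every base of the site's REF span is covered
#' by non-variant blocks passing the [confidence_policy()], the site is
#' homozygous reference with the minimum GQX/depth over the covering blocks;
#' otherwise it is a no-call. A variant record whose REF disagrees with the
#' catalog REF yields a no-call flagged `conflict`. Every site resolves to
#' exactly one call.
#'
#' @param sites `site_records` catalog.
#' @param gvcf `gvcf_records` table or a prebuilt [index_gvcf()].
#' @param policy A [confidence_policy()].
#' @return Data frame of genotype calls aligned to `sites`: `contig`, `pos`,
#'   `rsid`, `ref`, `alt`, `call_class` (one of [CALL_CLASSES]), `alleles`
#'   (normalized `"A/G"`, NA for no-calls), `source` (`VARIANT_RECORD`,
#'   `BLOCK` or `NONE`), `gqx`, `dp`, `conflict`.
#' @export
resolve_genotypes <- function(sites, gvcf, policy = confidence_policy()) {
  index <- if (inherits(gvcf, "gvcf_index")) gvcf else index_gvcf(gvcf)
  rec <- index$records
  n <- nrow(sites)
  if (n == 0) return(empty_calls())

  out <- data.frame(
    contig = sites$contig, pos = sites$pos, rsid = sites$rsid,
    ref = sites$ref, alt = sites$alt,
    call_class = rep("NO_CALL", n), alleles = rep(NA_character_, n),
    source = rep("NONE", n), gqx = rep(NA_real_, n), dp = rep(NA_real_, n),
    conflict = rep(FALSE, n), stringsAsFactors = FALSE
  )

  # 1) variant records at the site position
  var <- which(rec$kind == "VARIANT")
  m <- match(paste(sites$contig, sites$pos, sep = "\r"),
             paste(rec$contig[var], rec$pos[var], sep = "\r"))
  hit <- which(!is.na(m))
  for (i in hit) {
    r <- var[m[i]]
    if (!identical(rec$ref[r], sites$ref[i])) {
      out$conflict[i] <- TRUE           # catalog REF disagrees with the caller
      next
    }
    gt <- rec$gt[r]
    idx <- suppressWarnings(as.integer(strsplit(
      gsub("|", "/", if (is.na(gt)) "." else gt, fixed = TRUE), "/", fixed = TRUE)[[1]]))
    if (length(idx) == 1) idx <- rep(idx, 2)
    if (anyNA(idx)) {
      out$source[i] <- "VARIANT_RECORD"   # explicit ./. in the caller output
      next
    }
    alleles_all <- c(rec$ref[r], split_csv(rec$alt[r]))
    out$call_class[i] <- classify_gt_indices(idx[1], idx[2])
    out$alleles[i] <- format_alleles(alleles_all[idx[1] + 1], alleles_all[idx[2] + 1])
    out$source[i] <- "VARIANT_RECORD"
    out$gqx[i] <- rec$gqx[r]
    out$dp[i] <- rec$dp[r]
  }

  # 2) hom-ref via policy-passing block coverage of the full REF span
  todo <- which(out$source == "NONE" & !out$conflict)
  pass <- which(block_passes(rec, policy))
  if (length(pass) > 0 && length(todo) > 0) {
    span_end <- sites$pos + nchar(sites$ref) - 1L
    for (ct in unique(sites$contig[todo])) {
      si <- todo[sites$contig[todo] == ct]
      bi <- pass[rec$contig[pass] == ct]
      if (length(bi) == 0) next
      qr <- IRanges::IRanges(sites$pos[si], span_end[si])
      br <- IRanges::IRanges(rec$pos[bi], rec$end[bi])
      ov <- IRanges::findOverlaps(qr, br)
      if (length(ov) == 0) next
      q <- S4Vectors::queryHits(ov); s <- S4Vectors::subjectHits(ov)
      covered_w <- pmin(IRanges::end(qr)[q], IRanges::end(br)[s]) -
        pmax(IRanges::start(qr)[q], IRanges::start(br)[s]) + 1L
      tot <- tapply(covered_w, q, sum)
      full <- as.integer(names(tot))[tot == IRanges::width(qr)[as.integer(names(tot))]]
      if (length(full) == 0) next
      keep <- q %in% full
      gq <- tapply(rec$gqx[bi][s[keep]], q[keep], min)
      dpv <- tapply(ifelse(!is.na(rec$min_dp[bi]), rec$min_dp[bi],
                           rec$dp[bi])[s[keep]], q[keep], min)
      ord <- match(as.character(full), names(gq))
      rows <- si[full]
      out$call_class[rows] <- "HOM_REF"
      out$alleles[rows] <- paste(sites$ref[rows], sites$ref[rows], sep = "/")
      out$source[rows] <- "BLOCK"
      out$gqx[rows] <- as.numeric(gq)[ord]
      out$dp[rows] <- as.numeric(dpv)[ord]
    }
  }
  out
}

#' Resolve one site
#'
#' Single-site convenience wrapper around [resolve_genotypes()].
#'
#' @param site One-row `site_records` data frame.
#' @param index [index_gvcf()] result (or `gvcf_records`).
#' @param policy A [confidence_policy()].
#' @return One-row genotype call data frame.
#' @export
resolve_genotype <- function(site, index, policy = confidence_policy()) {
  resolve_genotypes(site[1, , drop = FALSE], index, policy)
}

#' Summarize catalog-site calls
#'
#' @param calls Data frame from [resolve_genotypes()].
#' @param n_variant_records_passthrough Count of caller variant records copied
#'   into the eVCF.
#' @return Object of class `call_summary`: `n_sites` and the five class
#'   counts (which always sum to `n_sites`), the passthrough count, and
#'   `n_conflicts`.
#' @export
call_summary <- function(calls, n_variant_records_passthrough = NA_integer_) {
  counts <- table(factor(calls$call_class, levels = CALL_CLASSES))
  structure(list(
    n_sites = nrow(calls),
    n_hom_ref = unname(counts[["HOM_REF"]]),
    n_het = unname(counts[["HET"]]),
    n_hom_alt = unname(counts[["HOM_ALT"]]),
    n_het_alt = unname(counts[["HET_ALT"]]),
    n_no_call = unname(counts[["NO_CALL"]]),
    n_variant_records_passthrough = n_variant_records_passthrough,
    n_conflicts = sum(calls$conflict)
  ), class = "call_summary")
}

#' @export
print.call_summary <- function(x, ...) {
  cat("Catalog-site call summary\n")
  cat(sprintf("  sites:        %d\n", x$n_sites))
  cat(sprintf("  hom-ref:      %d\n", x$n_hom_ref))
  cat(sprintf("  het:          %d\n", x$n_het))
  cat(sprintf("  hom-alt:      %d\n", x$n_hom_alt))
  cat(sprintf("  het-alt:      %d\n", x$n_het_alt))
  cat(sprintf("  no-call:      %d\n", x$n_no_call))
  if (!is.na(x$n_variant_records_passthrough)) {
    cat(sprintf("  caller variant records passed through: %d\n",
                x$n_variant_records_passthrough))
  }
  if (x$n_conflicts > 0) {
    cat(sprintf("  catalog/caller REF conflicts: %d\n", x$n_conflicts))
  }
  invisible(x)
}

#' Assemble an eVCF from a gVCF and a site catalog
#'
#' The eVCF contains (a) every variant record of the input gVCF, annotated
#' where it matches a catalog site, and (b) one explicit record per catalog
#' site not already covered by a variant record: hom-ref records always
#' (ALT `.`, GT `0/0`), no-call records (GT `./.`) when `emit_nocalls` is on.
#' A catalog site whose REF conflicts with the caller's record is emitted as
#' a no-call with the `conflict` INFO flag rather than aborting the run.
#'
#' @param gvcf `gvcf_records` table.
#' @param catalog `site_records` catalog (sorted or sortable).
#' @param annotations Optional [annotate_sites()] data frame aligned to
#'   `catalog`.
#' @param policy A [confidence_policy()].
#' @param emit_nocalls Emit explicit no-call records (default TRUE: silently
#'   omitting them would re-create the hom-ref/no-call ambiguity the format
#'   exists to remove).
#' @return List of class `evcf_build` with elements `records` (sorted
#'   `evcf_records`), `summary` ([call_summary()]) and `calls` (per-site
#'   genotype calls).
#' @export
build_evcf <- function(gvcf, catalog, annotations = NULL,
                       policy = confidence_policy(), emit_nocalls = TRUE) {
  ord <- order(match(catalog$contig, unique(catalog$contig)), catalog$pos)
  catalog <- catalog[ord, , drop = FALSE]
  if (!is.null(annotations)) annotations <- annotations[ord, , drop = FALSE]
  index <- index_gvcf(gvcf)
  calls <- resolve_genotypes(catalog, index, policy)

  variants <- gvcf[gvcf$kind == "VARIANT", ]
  ev <- as_evcf_records(variants)
  if (nrow(ev) > 0) {
    ev$call_class <- gt_call_class(ev$gt)
    ev$source <- "VARIANT_RECORD"
  }
  # annotate passthrough variants that coincide with catalog sites
  if (nrow(ev) > 0 && nrow(catalog) > 0) {
    m <- match(paste(ev$contig, ev$pos, ev$ref, sep = "\r"),
               paste(catalog$contig, catalog$pos, catalog$ref, sep = "\r"))
    hit <- which(!is.na(m))
    ev$known[hit] <- TRUE
    ev$id[hit] <- ifelse(is.na(ev$id[hit]), catalog$rsid[m[hit]], ev$id[hit])
    if (!is.null(annotations)) {
      ev$known[hit] <- annotations$known[m[hit]] | TRUE
      ev$clnsig[hit] <- annotations$clnsig[m[hit]]
      ev$gwascat_id[hit] <- annotations$gwascat_id[m[hit]]
      ev$odds_ratio[hit] <- annotations$odds_ratio[m[hit]]
    }
  }

  site_rows <- which(calls$source != "VARIANT_RECORD")
  if (!emit_nocalls) {
    site_rows <- site_rows[calls$call_class[site_rows] != "NO_CALL"]
  }
  add <- evcf_records_template(length(site_rows))
  if (length(site_rows) > 0) {
    sr <- site_rows
    add$contig <- calls$contig[sr]
    add$pos <- calls$pos[sr]
    add$id <- calls$rsid[sr]
    add$ref <- calls$ref[sr]
    add$alt <- NA_character_
    add$filter <- ifelse(calls$call_class[sr] == "HOM_REF", "PASS", NA_character_)
    add$kind <- "BLOCK"
    add$end <- calls$pos[sr] + nchar(calls$ref[sr]) - 1L
    add$gt <- ifelse(calls$call_class[sr] == "HOM_REF", "0/0", "./.")
    add$gqx <- calls$gqx[sr]
    add$dp <- as.integer(calls$dp[sr])
    add$known <- TRUE
    add$conflict <- calls$conflict[sr]
    add$call_class <- calls$call_class[sr]
    add$source <- calls$source[sr]
    if (!is.null(annotations)) {
      add$known <- annotations$known[sr] | TRUE
      add$clnsig <- annotations$clnsig[sr]
      add$gwascat_id <- annotations$gwascat_id[sr]
      add$odds_ratio <- annotations$odds_ratio[sr]
    }
  }

  rec <- rbind(ev, add)
  contig_order <- unique(c(gvcf$contig, catalog$contig))
  rec <- rec[order(match(rec$contig, contig_order), rec$pos), ]
  rownames(rec) <- NULL
  class(rec) <- c("evcf_records", "gvcf_records", "data.frame")

  structure(list(
    records = rec,
    summary = call_summary(calls, n_variant_records_passthrough = nrow(ev)),
    calls = calls
  ), class = "evcf_build")
}

#' @export
print.evcf_build <- function(x, ...) {
  cat(sprintf("eVCF build: %d records (%d caller variants + %d catalog site records)\n",
              nrow(x$records), x$summary$n_variant_records_passthrough,
              nrow(x$records) - x$summary$n_variant_records_passthrough))
  print(x$summary)
  invisible(x)
}
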