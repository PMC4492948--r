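# Site catalogs: dbSNP-style membership, ClinVar-style significance, GWAS
# catalog associations, and the audit of positions where the reference genome
# itself carries the minor (possibly rare, pathogenic or risk) allele.

#' Load a GWAS-catalog TSV and map coordinates by rsID
#'
#' GWAS catalog releases are coordinate-annotated on the current assembly;
#' the join back onto the working assembly is keyed purely on rsID against a
#' site table (no chain-file liftover). Associations whose rsID is absent
#' from the mapping are dropped and counted.
#'
#' @param lines TSV lines (with header) or a data frame.
#' @param rsid_to_site `site_records` table supplying `contig`/`pos` per rsID.
#' @param cols Named vector mapping roles `rsid`, `trait`, `risk_allele`,
#'   `odds_ratio` to column names in the TSV.
#' @return List with `associations` (data frame: `rsid`, `trait`,
#'   `risk_allele`, `odds_ratio`, `contig`, `pos`) and `dropped` (count of
#'   unmapped associations). An unparsable odds-ratio field (e.g. `"NR"`)
#'   keeps the association with `odds_ratio = NA`.
#' @export
load_gwas_catalog <- function(lines, rsid_to_site,
                              cols = c(rsid = "rsid", trait = "trait",
                                       risk_allele = "risk_allele",
                                       odds_ratio = "odds_ratio")) {
  tab <- if (is.data.frame(lines)) {
    lines
  } else {
    utils::read.delim(text = lines, header = TRUE, sep = "\t",
                      colClasses = "character", check.names = FALSE)
  }
  missing_cols <- setdiff(unname(cols), names(tab))
  if (length(missing_cols) > 0) {
    stop("GWAS catalog lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  rsid <- as.character(tab[[cols[["rsid"]]]])
  risk <- toupper(trimws(as.character(tab[[cols[["risk_allele"]]]])))
  risk[!risk %in% c("A", "C", "G", "T")] <- NA_character_
  or <- suppressWarnings(as.numeric(tab[[cols[["odds_ratio"]]]]))
  or[!is.na(or) & or <= 0] <- NA_real_
  m <- match(rsid, rsid_to_site$rsid)
  mapped <- !is.na(m)
  assoc <- data.frame(
    rsid = rsid[mapped],
    trait = as.character(tab[[cols[["trait"]]]])[mapped],
    risk_allele = risk[mapped],
    odds_ratio = or[mapped],
    contig = rsid_to_site$contig[m[mapped]],
    pos = rsid_to_site$pos[m[mapped]],
    stringsAsFactors = FALSE
  )
  list(associations = assoc, dropped = sum(!mapped))
}

#' Classify the reference allele at catalog sites
#'
#' At a large number of known polymorphic positions the reference genome
#' carries the \emph{minor} allele, so a hom-ref genotype is itself
#' informative. Given per-ALT population frequencies, the reference allele
#' frequency is `1 - sum(alt frequencies)`; the site is minor-on-reference
#' when that frequency is strictly below 0.5, and is binned by the tightest
#' matching threshold: `LT1` (< 1%), `LT5` (< 5%), `LT50` (< 50%), else
#' `NOT_MINOR`. Ties at exactly 0.5 are `NOT_MINOR`.
#'
#' @param sites `site_records` table with `alt_freqs` present.
#' @param tol Tolerance on the frequency-sum sanity check.
#' @return Data frame with one row per site: `minor_on_ref`, `maf_bin`,
#'   `ref_allele_freq` (NA throughout where frequencies are missing).
#' @details Frequencies summing above `1 + tol` are an inconsistency error.
#' @export
classify_reference_allele <- function(sites, tol = 1e-6) {
  n <- nrow(sites)
  ref_freq <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    fq <- suppressWarnings(as.numeric(split_csv(sites$alt_freqs[i])))
    if (length(fq) == 0 || anyNA(fq)) next
    s <- sum(fq)
    if (s > 1 + tol) {
      stop(sprintf("inconsistent allele frequencies at %s:%d (sum %.4f > 1)",
                   sites$contig[i], sites$pos[i], s))
    }
    ref_freq[i] <- max(0, 1 - s)
  }
  minor <- ref_freq < 0.5
  bin <- rep(NA_character_, n)
  bin[!is.na(minor) & !minor] <- "NOT_MINOR"
  bin[!is.na(minor) & minor] <- "LT50"
  bin[!is.na(ref_freq) & ref_freq < 0.05] <- "LT5"
  bin[!is.na(ref_freq) & ref_freq < 0.01] <- "LT1"
  data.frame(minor_on_ref = minor, maf_bin = bin, ref_allele_freq = ref_freq,
             stringsAsFactors = FALSE)
}

#' Annotate catalog sites against dbSNP / ClinVar / GWAS catalogs
#'
#' Marks each site `known` when it matches the dbSNP-style membership catalog
#' by `(contig, pos, ref)` (rsID as fallback), attaches ClinVar significance
#' labels, and attaches every matching GWAS association (matched by position,
#' rsID fallback) as comma-joined aligned lists. A membership match at the
#' right position but with a different REF raises a catalog-conflict warning
#' and is not accepted.
#'
#' @param sites `site_records` to annotate.
#' @param dbsnp Optional `site_records` membership catalog.
#' @param clinvar Optional `site_records` with a `clnsig` column.
#' @param gwas Optional association data frame from [load_gwas_catalog()].
#' @return Data frame aligned to `sites`: `known`, `clnsig`, `gwascat_id`,
#'   `odds_ratio`, `risk_allele` (aligned comma-joined lists), `n_gwas`.
#'   Annotation is independent of the order the catalogs were loaded in.
#' @export
annotate_sites <- function(sites, dbsnp = NULL, clinvar = NULL, gwas = NULL) {
  n <- nrow(sites)
  known <- rep(FALSE, n)
  if (!is.null(dbsnp) && nrow(dbsnp) > 0) {
    key <- paste(sites$contig, sites$pos, sites$ref, sep = "\r")
    dkey <- paste(dbsnp$contig, dbsnp$pos, dbsnp$ref, sep = "\r")
    known <- key %in% dkey
    rs_hit <- !known & !is.na(sites$rsid) & sites$rsid %in% dbsnp$rsid
    known <- known | rs_hit
    # same position, different REF: catalog conflict
    pkey <- paste(sites$contig, sites$pos, sep = "\r")
    dpkey <- paste(dbsnp$contig, dbsnp$pos, sep = "\r")
    conf <- !known & pkey %in% dpkey
    if (any(conf)) {
      warning(sprintf("catalog conflict: %d site(s) match dbSNP position but not REF",
                      sum(conf)))
    }
  }
  clnsig <- rep(NA_character_, n)
  if (!is.null(clinvar) && nrow(clinvar) > 0) {
    m <- match(paste(sites$contig, sites$pos, sites$ref, sep = "\r"),
               paste(clinvar$contig, clinvar$pos, clinvar$ref, sep = "\r"))
    clnsig <- clinvar$clnsig[m]
  }
  gid <- rep(NA_character_, n); or <- rep(NA_character_, n)
  ra <- rep(NA_character_, n); n_gwas <- rep(0L, n)
  if (!is.null(gwas) && nrow(gwas) > 0) {
    skey <- paste(sites$contig, sites$pos, sep = "\r")
    gkey <- paste(gwas$contig, gwas$pos, sep = "\r")
    by_pos <- split(seq_len(nrow(gwas)), gkey)
    gwas_id <- paste0(gwas$rsid, ":", gsub("[,;\t ]+", "_", gwas$trait))
    for (i in seq_len(n)) {
      hits <- by_pos[[skey[i]]]
      if (is.null(hits) && !is.na(sites$rsid[i])) {
        hits <- which(gwas$rsid == sites$rsid[i])
        if (length(hits) == 0) hits <- NULL
      }
      if (is.null(hits)) next
      hits <- hits[order(gwas_id[hits])]  # loading-order independence
      n_gwas[i] <- length(hits)
      gid[i] <- paste(gwas_id[hits], collapse = ",")
      or[i] <- paste(ifelse(is.na(gwas$odds_ratio[hits]), ".",
                            fmt_num(gwas$odds_ratio[hits])), collapse = ",")
      ra[i] <- paste(ifelse(is.na(gwas$risk_allele[hits]), ".",
                            gwas$risk_allele[hits]), collapse = ",")
    }
  }
  data.frame(known = known, clnsig = clnsig, gwascat_id = gid,
             odds_ratio = or, risk_allele = ra, n_gwas = n_gwas,
             stringsAsFactors = FALSE)
}

#' Score risk-allele zygosity at a called site
#'
#' Given a resolved genotype and a GWAS association, reports whether the
#' reference genome itself carries the risk allele, how many copies of the
#' risk allele the called genotype holds, and whether the risk allele is
#' observable at all at this site (it must be the REF or one of the ALTs).
#' The canonical pattern this surfaces is a site where the reference carries
#' the risk allele and the sample is hom-ref: a standard variant-only VCF is
#' silent there, yet the sample carries two risk copies.
#'
#' @param call A genotype call row (from [resolve_genotypes()] or
#'   [array_to_calls()]): needs `call_class` and `alleles` (e.g. `"A/G"`).
#' @param site The matching `site_records` row (`ref`, `alt`).
#' @param risk_allele Single risk allele base from the association.
#' @return List with `risk_on_ref`, `risk_allele_dosage` (0/1/2, NA when not
#'   resolvable) and `resolvable`.
#' @export
classify_gwas_zygosity <- function(call, site, risk_allele) {
  if (is.na(risk_allele)) stop("association has no risk allele")
  cls <- call$call_class
  if (is.na(cls) || cls == "NO_CALL") {
    stop("classify_gwas_zygosity requires a called genotype (not NO_CALL)")
  }
  observable <- c(site$ref, split_csv(site$alt))
  resolvable <- risk_allele %in% observable
  alleles <- strsplit(call$alleles, "/", fixed = TRUE)[[1]]
  list(
    risk_on_ref = identical(risk_allele, site$ref),
    risk_allele_dosage = if (resolvable) sum(alleles == risk_allele) else NA_integer_,
    resolvable = resolvable
  )
}
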