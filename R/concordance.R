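# Callset comparison: WGS-derived genotype calls vs an array/panel callset,
# with array-allele strand normalization and the probe-interference filter
# (probes with another polymorphism 1-10 bp from the assayed base report
# unreliable genotypes and are excluded before computing rates).

#' Normalize array-reported alleles against the expected site alleles
#'
#' Array exports report alleles on the manifest strand, which does not always
#' match the reference strand. Alleles are matched to `{REF} U ALTs` directly,
#' and failing that via Watson-Crick complement. A/T and C/G sites, where the
#' direct and complemented readings are both consistent, are strand-ambiguous
#' and returned `UNRESOLVABLE` unless `trust_strand` is set. A both-missing
#' row is an array no-call.
#'
#' @param allele_a,allele_b The two reported alleles (NA for a no-call).
#' @param site Matching one-row `site_records` (needs `ref`, `alt`).
#' @param trust_strand Accept the direct reading on strand-ambiguous sites.
#' @return List: `status` (`"OK"`, `"NO_CALL"` or `"UNRESOLVABLE"`),
#'   `call_class`, `alleles` (normalized, reference strand), `reason`.
#' @export
align_array_alleles <- function(allele_a, allele_b, site, trust_strand = FALSE) {
  if (is.na(allele_a) && is.na(allele_b)) {
    return(list(status = "NO_CALL", call_class = "NO_CALL",
                alleles = NA_character_, reason = "array no-call"))
  }
  expected <- c(site$ref, split_csv(site$alt))
  direct <- c(allele_a, allele_b)
  comp <- complement_base(direct)
  direct_ok <- all(direct %in% expected)
  comp_ok <- all(comp %in% expected)
  use <- NULL
  if (direct_ok && comp_ok && !trust_strand) {
    return(list(status = "UNRESOLVABLE", call_class = NA_character_,
                alleles = NA_character_,
                reason = "strand-ambiguous site: direct and complemented readings both consistent"))
  }
  if (direct_ok) use <- direct else if (comp_ok) use <- comp
  if (is.null(use)) {
    return(list(status = "UNRESOLVABLE", call_class = NA_character_,
                alleles = NA_character_,
                reason = sprintf("alleles %s/%s match neither directly nor complemented",
                                 allele_a, allele_b)))
  }
  n_ref <- sum(use == site$ref)
  cls <- if (n_ref == 2) "HOM_REF"
    else if (n_ref == 1) "HET"
    else if (use[1] == use[2]) "HOM_ALT"
    else "HET_ALT"
  list(status = "OK", call_class = cls,
       alleles = format_alleles(use[1], use[2]), reason = NA_character_)
}

#' Convert an array report into a genotype callset
#'
#' Applies [align_array_alleles()] row by row against the matching catalog
#' sites. Strand-ambiguous or otherwise unresolvable rows are dropped from
#' the callset (counted in attribute `"n_unresolvable"`); array no-calls are
#' kept as `NO_CALL`.
#'
#' @param ag `array_genotypes` from [parse_array_report()].
#' @param sites `site_records` catalog (matched by marker id, then position).
#' @param trust_strand Passed to [align_array_alleles()].
#' @return Genotype-call data frame in the [resolve_genotypes()] layout.
#' @export
array_to_calls <- function(ag, sites, trust_strand = FALSE) {
  m <- match(ag$marker_id, sites$rsid)
  pm <- match(paste(ag$contig, ag$pos), paste(sites$contig, sites$pos))
  m[is.na(m)] <- pm[is.na(m)]
  keep <- !is.na(m)
  n_unresolvable <- 0L
  rows <- vector("list", sum(keep))
  ki <- which(keep)
  for (j in seq_along(ki)) {
    i <- ki[j]
    st <- sites[m[i], ]
    al <- align_array_alleles(ag$allele_a[i], ag$allele_b[i], st, trust_strand)
    if (al$status == "UNRESOLVABLE") {
      n_unresolvable <- n_unresolvable + 1L
      next
    }
    rows[[j]] <- data.frame(
      contig = st$contig, pos = st$pos, rsid = st$rsid, ref = st$ref,
      alt = st$alt, call_class = al$call_class, alleles = al$alleles,
      source = "ARRAY", gqx = NA_real_, dp = NA_real_, conflict = FALSE,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) out <- empty_calls()
  rownames(out) <- NULL
  attr(out, "n_unresolvable") <- n_unresolvable
  out
}

#' Filter array probes subject to interference from nearby polymorphisms
#'
#' A target is removed when some interfering variant lies at distance `d`
#' with `1 <= d <= window_bp` on the same contig, `d` being measured from the
#' target position to the nearest base of the variant's REF span. Distance 0
#' (the assayed base itself) is the queried polymorphism, not interference,
#' and is kept.
#'
#' @param targets Data frame of assayed sites (`contig`, `pos`).
#' @param interfering Data frame of interfering variants: `contig`, `pos`,
#'   and either `end` or `ref` (to derive the REF span; a point when absent).
#' @param window_bp Interference window in bp (default 10).
#' @return List of class `probe_filter_result`: `kept` and `removed` (row
#'   subsets of `targets`, disjoint and jointly exhaustive), and
#'   `removal_reason` (per removed target: nearest interfering variant and
#'   its distance).
#' @export
probe_interference_filter <- function(targets, interfering, window_bp = 10) {
  stopifnot(window_bp >= 1)
  if (is.null(interfering$end)) {
    if (!is.null(interfering$ref)) {
      interfering$end <- interfering$pos + nchar(interfering$ref) - 1L
    } else {
      interfering$end <- interfering$pos
    }
  }
  n <- nrow(targets)
  removed <- logical(n)
  nearest <- rep(NA_integer_, n)
  dist <- rep(NA_integer_, n)
  for (ct in unique(targets$contig)) {
    ti <- which(targets$contig == ct)
    vi <- which(interfering$contig == ct)
    if (length(vi) == 0) next
    qr <- IRanges::IRanges(pmax(1L, targets$pos[ti] - as.integer(window_bp)),
                           targets$pos[ti] + as.integer(window_bp))
    vr <- IRanges::IRanges(interfering$pos[vi], interfering$end[vi])
    ov <- IRanges::findOverlaps(qr, vr)
    if (length(ov) == 0) next
    q <- S4Vectors::queryHits(ov); s <- S4Vectors::subjectHits(ov)
    p <- targets$pos[ti][q]
    d <- pmax(0L, pmax(IRanges::start(vr)[s] - p, p - IRanges::end(vr)[s]))
    inside <- d >= 1 & d <= window_bp
    if (!any(inside)) next
    q <- q[inside]; s <- s[inside]; d <- d[inside]
    best <- tapply(seq_along(q), q, function(k) k[which.min(d[k])])
    bq <- as.integer(names(best)); bk <- as.integer(best)
    removed[ti[bq]] <- TRUE
    nearest[ti[bq]] <- vi[s[bk]]
    dist[ti[bq]] <- d[bk]
  }
  reason <- data.frame(
    contig = targets$contig[removed], pos = targets$pos[removed],
    interfering_contig = interfering$contig[nearest[removed]],
    interfering_pos = interfering$pos[nearest[removed]],
    distance_bp = dist[removed], stringsAsFactors = FALSE
  )
  structure(list(
    kept = targets[!removed, , drop = FALSE],
    removed = targets[removed, , drop = FALSE],
    removal_reason = reason
  ), class = "probe_filter_result")
}

call_key <- function(calls) paste(calls$contig, calls$pos, sep = "\r")

#' Compare two genotype callsets
#'
#' Cross-tabulates the call classes of a truth and a test callset over their
#' shared sites and computes truth-referenced rates over the mutually called
#' sites (neither side `NO_CALL`):
#' \itemize{
#'   \item sensitivity: truth-variant sites (HET/HOM_ALT/HET_ALT) called
#'     variant by the test set, over truth-variant sites;
#'   \item specificity: truth hom-ref sites called hom-ref, over truth
#'     hom-ref sites;
#'   \item concordance: exact class-and-allele matches over all mutually
#'     called shared sites (symmetric in its two arguments);
#'   \item concordance_variant_sites: the same restricted to truth-variant
#'     sites.
#' }
#' No-calls on either side are excluded from the rates but appear in the
#' cross-tabulation margins and in `no_call_rate`.
#'
#' @param truth,test Genotype-call data frames (layout of
#'   [resolve_genotypes()]), keyed by `(contig, pos)`.
#' @return Object of class `concordance_report`: `cross_tab` (5x5 truth x
#'   test counts over shared sites), `n_compared`, `n_truth_only`,
#'   `n_test_only`, `sensitivity`, `specificity`, `concordance`,
#'   `concordance_variant_sites`, `no_call_rate`.
#' @details It is an error for the two callsets to share no mutually called
#'   site.
#' @export
compare_callsets <- function(truth, test) {
  tk <- call_key(truth); sk <- call_key(test)
  shared <- intersect(tk, sk)
  i <- match(shared, tk); j <- match(shared, sk)
  a <- factor(truth$call_class[i], levels = CALL_CLASSES)
  b <- factor(test$call_class[j], levels = CALL_CLASSES)
  cross_tab <- table(truth = a, test = b)

  called <- a != "NO_CALL" & b != "NO_CALL"
  if (!any(called)) stop("no mutually called site shared by the two callsets")
  av <- as.character(a[called]); bv <- as.character(b[called])
  ta <- truth$alleles[i][called]; sa <- test$alleles[j][called]
  variant_classes <- c("HET", "HOM_ALT", "HET_ALT")

  truth_var <- av %in% variant_classes
  truth_hr <- av == "HOM_REF"
  sens <- if (any(truth_var)) mean(bv[truth_var] %in% variant_classes) else NA_real_
  spec <- if (any(truth_hr)) mean(bv[truth_hr] == "HOM_REF") else NA_real_
  exact <- av == bv & (is.na(ta) | is.na(sa) | ta == sa)
  conc <- mean(exact)
  conc_var <- if (any(truth_var)) mean(exact[truth_var]) else NA_real_

  structure(list(
    cross_tab = cross_tab,
    n_compared = sum(called),
    n_truth_only = sum(!tk %in% sk),
    n_test_only = sum(!sk %in% tk),
    sensitivity = sens,
    specificity = spec,
    concordance = conc,
    concordance_variant_sites = conc_var,
    no_call_rate = mean(!called),
    n_filtered_probes = NA_integer_
  ), class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, digits = 4, ...) {
  cat("Genotype concordance report\n")
  cat(sprintf("  shared sites compared (both called): %d\n", x$n_compared))
  cat(sprintf("  truth-only: %d   test-only: %d   no-call rate: %.4f\n",
              x$n_truth_only, x$n_test_only, x$no_call_rate))
  cat(sprintf("  sensitivity (variant detection):  %s\n",
              format(x$sensitivity, digits = digits)))
  cat(sprintf("  specificity (hom-ref detection):  %s\n",
              format(x$specificity, digits = digits)))
  cat(sprintf("  concordance (exact genotype):     %s\n",
              format(x$concordance, digits = digits)))
  cat(sprintf("  concordance at truth-variant sites: %s\n",
              format(x$concordance_variant_sites, digits = digits)))
  if (!is.na(x$n_filtered_probes)) {
    cat(sprintf("  probes removed by interference filter: %d\n", x$n_filtered_probes))
  }
  cat("\n  truth x test cross-tabulation:\n")
  print(x$cross_tab)
  invisible(x)
}
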