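# Per-base coverage QC: gap detection, region coverage fractions, GC/AT
# sequence-context classes, and binomial coverage thinning. A base is
# "covered" when read depth, mapping quality and basecall quality all meet
# their thresholds; a gap is a maximal run of uncovered bases longer than
# 10 bp.

#' QC thresholds
#'
#' @param min_depth Minimum read depth for a covered base (default 5).
#' @param min_mapq Minimum mapping/alignment quality (default 10).
#' @param min_baseq Minimum basecall quality (default 10).
#' @param min_gap_len Minimum reported gap length (default 11: gaps are runs
#'   strictly longer than 10 bp).
#' @param gc_high,gc_extreme GC-content window classes (defaults 0.75, 0.85).
#' @param gc_window GC window length in bp (default 100, non-overlapping).
#' @param at_run_min Minimum length of an alternating AT-dinucleotide run
#'   (default 30 bp).
#' @return Object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_depth = 5, min_mapq = 10, min_baseq = 10,
                          min_gap_len = 11, gc_high = 0.75, gc_extreme = 0.85,
                          gc_window = 100, at_run_min = 30) {
  stopifnot(min_gap_len >= 1, gc_high >= 0, gc_high <= gc_extreme, gc_extreme <= 1)
  structure(list(min_depth = min_depth, min_mapq = min_mapq,
                 min_baseq = min_baseq, min_gap_len = as.integer(min_gap_len),
                 gc_high = gc_high, gc_extreme = gc_extreme,
                 gc_window = as.integer(gc_window),
                 at_run_min = as.integer(at_run_min)),
            class = "qc_thresholds")
}

#' Per-base coverage profile
#'
#' @param contig Contig name.
#' @param start 1-based position of the first profiled base.
#' @param depth,mapq,baseq Aligned non-negative numeric arrays (equal length):
#'   read depth and whatever per-base summaries of mapping and basecall
#'   quality the upstream tool emits (consumed as given).
#' @return Object of class `coverage_profile`.
#' @export
coverage_profile <- function(contig, start, depth, mapq, baseq) {
  stopifnot(length(depth) == length(mapq), length(mapq) == length(baseq),
            all(depth >= 0), all(mapq >= 0), all(baseq >= 0))
  structure(list(contig = contig, start = as.integer(start),
                 depth = as.numeric(depth), mapq = as.numeric(mapq),
                 baseq = as.numeric(baseq)),
            class = "coverage_profile")
}

#' Read a per-base coverage profile TSV
#'
#' Expects columns `contig`, `pos`, `depth`, `mapq`, `baseq` with contiguous
#' positions per contig; returns one [coverage_profile()] per contig.
#'
#' @param path TSV path.
#' @return Named list of `coverage_profile` objects.
#' @export
read_coverage_tsv <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t")
  lapply(split(tab, tab$contig), function(s) {
    s <- s[order(s$pos), ]
    if (any(diff(s$pos) != 1)) {
      stop("coverage profile positions are not contiguous on contig ", s$contig[1])
    }
    coverage_profile(as.character(s$contig[1]), s$pos[1], s$depth, s$mapq, s$baseq)
  })
}

covered_mask <- function(profile, t) {
  profile$depth >= t$min_depth & profile$mapq >= t$min_mapq &
    profile$baseq >= t$min_baseq
}

#' Detect coverage gaps
#'
#' A base is covered when depth, mapping quality and basecall quality all
#' meet their thresholds. With `gap_logic = "any"` (default) a gap base is
#' any uncovered base (some criterion fails); with `"all"` a gap base must
#' fail all three criteria. Gaps are maximal runs of gap bases longer than
#' 10 bp (length `>= min_gap_len`), returned sorted and non-overlapping.
#'
#' @param profile A [coverage_profile()].
#' @param t [qc_thresholds()].
#' @param gap_logic `"any"` or `"all"` (which criteria must fail on a gap
#'   base).
#' @return Data frame of gap intervals: `contig`, `start`, `end` (1-based
#'   inclusive), `length`, `mean_depth`.
#' @export
detect_gaps <- function(profile, t = qc_thresholds(), gap_logic = c("any", "all")) {
  gap_logic <- match.arg(gap_logic)
  stopifnot(length(profile$depth) > 0)
  gap_base <- if (gap_logic == "any") {
    !covered_mask(profile, t)
  } else {
    profile$depth < t$min_depth & profile$mapq < t$min_mapq &
      profile$baseq < t$min_baseq
  }
  r <- rle(gap_base)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= t$min_gap_len
  out <- data.frame(
    contig = rep(profile$contig, sum(keep)),
    start = profile$start + starts[keep] - 1L,
    end = profile$start + ends[keep] - 1L,
    length = r$lengths[keep],
    mean_depth = vapply(which(keep), function(k) {
      mean(profile$depth[starts[k]:ends[k]])
    }, numeric(1)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Fraction of region bases covered
#'
#' @param profiles A [coverage_profile()] or list of them.
#' @param regions Data frame of 1-based inclusive intervals (`contig`,
#'   `start`, `end`), e.g. from [read_bed()]; must be non-empty and fully
#'   inside the profiles.
#' @param t [qc_thresholds()].
#' @return Fraction in `[0, 1]` of region bases meeting all three coverage
#'   criteria.
#' @export
coverage_fraction <- function(profiles, regions, t = qc_thresholds()) {
  if (inherits(profiles, "coverage_profile")) profiles <- list(profiles)
  if (is.null(regions) || nrow(regions) == 0) stop("empty region list")
  covered <- 0; total <- 0
  for (i in seq_len(nrow(regions))) {
    hit <- NULL
    for (p in profiles) {
      p_end <- p$start + length(p$depth) - 1L
      if (p$contig == regions$contig[i] && regions$start[i] >= p$start &&
          regions$end[i] <= p_end) { hit <- p; break }
    }
    if (is.null(hit)) {
      stop(sprintf("region %s:%d-%d lies outside every coverage profile",
                   regions$contig[i], regions$start[i], regions$end[i]))
    }
    off <- (regions$start[i]:regions$end[i]) - hit$start + 1L
    m <- covered_mask(hit, t)[off]
    covered <- covered + sum(m)
    total <- total + length(m)
  }
  covered / total
}

#' Read a BED file as 1-based inclusive intervals
#'
#' BED is 0-based half-open; on read, `start` gains 1 and `end` is kept, so
#' the returned intervals follow the package-wide 1-based inclusive
#' convention (matching VCF POS/END).
#'
#' @param path BED file path (first three columns used).
#' @return Data frame: `contig`, `start`, `end`.
#' @export
read_bed <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  data.frame(contig = as.character(tab[[1]]), start = as.integer(tab[[2]]) + 1L,
             end = as.integer(tab[[3]]), stringsAsFactors = FALSE)
}

#' Classify GC content in tiled windows
#'
#' Non-overlapping windows of `gc_window` bp tiled from the sequence start
#' (a trailing partial window is skipped) are classed by GC fraction:
#' `EXTREME_GC` at `>= gc_extreme`, else `HIGH_GC` at `>= gc_high`, else
#' `NORMAL`. `N` bases count in neither numerator nor denominator; a window
#' of only `N` is `NORMAL`.
#'
#' @param sequence DNA string (A/C/G/T/N).
#' @param t [qc_thresholds()].
#' @return Data frame: `start`, `end` (1-based), `gc_fraction`, `class`.
#' @export
classify_gc_windows <- function(sequence, t = qc_thresholds()) {
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  if (any(!chars %in% c("A", "C", "G", "T", "N"))) {
    stop("input error: sequence contains non-ACGTN characters")
  }
  w <- t$gc_window
  n_win <- length(chars) %/% w
  if (n_win == 0) {
    return(data.frame(start = integer(0), end = integer(0),
                      gc_fraction = numeric(0), class = character(0)))
  }
  is_gc <- chars %in% c("G", "C")
  is_n <- chars == "N"
  idx <- seq_len(n_win * w)
  win <- factor(rep(seq_len(n_win), each = w), levels = seq_len(n_win))
  gc <- tapply(is_gc[idx], win, sum)
  denom <- tapply(!is_n[idx], win, sum)
  frac <- ifelse(denom > 0, gc / denom, 0)
  cls <- ifelse(denom == 0, "NORMAL",
                ifelse(frac >= t$gc_extreme, "EXTREME_GC",
                       ifelse(frac >= t$gc_high, "HIGH_GC", "NORMAL")))
  data.frame(start = (seq_len(n_win) - 1L) * w + 1L,
             end = seq_len(n_win) * w,
             gc_fraction = as.numeric(frac), class = unname(cls),
             stringsAsFactors = FALSE)
}

#' Find alternating AT-dinucleotide runs
#'
#' Maximal runs of strictly alternating A/T (`ATAT...` or `TATA...`; a
#' homopolymer does not qualify) with length `>= at_run_min`.
#'
#' @param sequence DNA string.
#' @param t [qc_thresholds()].
#' @return Data frame of 1-based inclusive intervals: `start`, `end`,
#'   `length`.
#' @export
find_at_runs <- function(sequence, t = qc_thresholds()) {
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  n <- length(chars)
  if (n == 0) {
    return(data.frame(start = integer(0), end = integer(0), length = integer(0)))
  }
  is_at <- chars %in% c("A", "T")
  # a new run starts where the base is not A/T-alternating with its predecessor
  brk <- c(TRUE, !(is_at[-1] & is_at[-n] & chars[-1] != chars[-n]))
  grp <- cumsum(brk)
  starts <- which(brk)
  ends <- c(starts[-1] - 1L, n)
  len <- ends - starts + 1L
  keep <- is_at[starts] & len >= t$at_run_min
  data.frame(start = starts[keep], end = ends[keep], length = len[keep])
}

#' Thin a coverage profile to a lower mean depth
#'
#' Emulates sub-sampling a sequencing dataset to a lower average coverage:
#' each base's depth is replaced by a binomial draw with success probability
#' `target_mean / mean(depth)` (zero-depth bases stay zero); mapping and
#' basecall qualities are unchanged. Reproducible for a fixed seed.
#'
#' @param profile A [coverage_profile()].
#' @param target_mean Desired mean depth; must not exceed the current mean.
#' @param seed Integer seed.
#' @return A thinned `coverage_profile`.
#' @export
thin_coverage <- function(profile, target_mean, seed) {
  cur <- mean(profile$depth)
  if (target_mean > cur) {
    stop(sprintf("target mean depth %.2f exceeds current mean %.2f",
                 target_mean, cur))
  }
  p <- target_mean / cur
  depth <- with_seed(seed, stats::rbinom(length(profile$depth),
                                         size = as.integer(profile$depth),
                                         prob = p))
  coverage_profile(profile$contig, profile$start, depth, profile$mapq,
                   profile$baseq)
}
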