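# Independent brute-force oracles and fixture builders. These deliberately
# avoid the package's index/vectorized code paths: per-base and all-pairs
# scans only, so they can arbitrate the fast implementations.

gvcf_fixture_lines <- function(body) {
  c("##fileformat=VCFv4.1",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "S1", sep = "\t"),
    body)
}

# Linear per-site genotype resolution without any interval index: scan every
# record; check block coverage base by base.
oracle_resolve <- function(site, rec, policy = confidence_policy()) {
  span <- site$pos:(site$pos + nchar(site$ref) - 1L)
  vi <- which(rec$kind == "VARIANT" & rec$contig == site$contig &
                rec$pos == site$pos)
  if (length(vi) > 0) {
    r <- vi[1]
    if (!identical(rec$ref[r], site$ref)) {
      return(list(call_class = "NO_CALL", conflict = TRUE))
    }
    gt <- rec$gt[r]
    idx <- suppressWarnings(as.integer(strsplit(
      gsub("|", "/", if (is.na(gt)) "." else gt, fixed = TRUE),
      "/", fixed = TRUE)[[1]]))
    if (anyNA(idx)) return(list(call_class = "NO_CALL", conflict = FALSE))
    n_ref <- sum(idx == 0)
    cls <- if (n_ref == 2) "HOM_REF" else if (n_ref == 1) "HET"
      else if (idx[1] == idx[2]) "HOM_ALT" else "HET_ALT"
    return(list(call_class = cls, conflict = FALSE))
  }
  pass_dp <- ifelse(!is.na(rec$min_dp), rec$min_dp, rec$dp)
  ok <- rec$kind == "BLOCK" & rec$contig == site$contig &
    !is.na(rec$gqx) & rec$gqx >= policy$min_gqx &
    !is.na(pass_dp) & pass_dp >= policy$min_dp
  if (policy$require_pass) ok <- ok & !is.na(rec$filter) & rec$filter == "PASS"
  covered <- vapply(span, function(p) {
    any(ok & rec$pos <= p & rec$end >= p)
  }, logical(1))
  if (all(covered)) list(call_class = "HOM_REF", conflict = FALSE)
  else list(call_class = "NO_CALL", conflict = FALSE)
}

# Gap detection by explicit enumeration of every maximal uncovered run.
oracle_gaps <- function(profile, t = qc_thresholds()) {
  bad <- !(profile$depth >= t$min_depth & profile$mapq >= t$min_mapq &
             profile$baseq >= t$min_baseq)
  n <- length(bad)
  out <- NULL
  i <- 1
  while (i <= n) {
    if (bad[i]) {
      j <- i
      while (j < n && bad[j + 1]) j <- j + 1
      if (j - i + 1 >= t$min_gap_len) {
        out <- rbind(out, data.frame(start = profile$start + i - 1L,
                                     end = profile$start + j - 1L))
      }
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  out
}

# Direct per-window GC counting.
oracle_gc <- function(sequence, t = qc_thresholds()) {
  chars <- strsplit(sequence, "")[[1]]
  n_win <- length(chars) %/% t$gc_window
  vapply(seq_len(n_win), function(k) {
    w <- chars[((k - 1) * t$gc_window + 1):(k * t$gc_window)]
    w <- w[w != "N"]
    frac <- if (length(w) == 0) 0 else sum(w %in% c("G", "C")) / length(w)
    if (length(w) > 0 && frac >= t$gc_extreme) "EXTREME_GC"
    else if (length(w) > 0 && frac >= t$gc_high) "HIGH_GC"
    else "NORMAL"
  }, character(1))
}

# AT-run discovery by checking every candidate interval start.
oracle_at_runs <- function(sequence, t = qc_thresholds()) {
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  alt_ok <- function(i, j) {
    all(chars[i:j] %in% c("A", "T")) &&
      (j == i || all(chars[(i + 1):j] != chars[i:(j - 1)]))
  }
  out <- NULL
  i <- 1
  while (i <= n) {
    if (chars[i] %in% c("A", "T")) {
      j <- i
      while (j < n && chars[j + 1] %in% c("A", "T") && chars[j + 1] != chars[j]) {
        j <- j + 1
      }
      if (j - i + 1 >= t$at_run_min && alt_ok(i, j)) {
        out <- rbind(out, data.frame(start = i, end = j))
      }
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  out
}

# All-pairs probe-interference scan.
oracle_probe_filter <- function(targets, interfering, window_bp = 10) {
  if (is.null(interfering$end)) interfering$end <- interfering$pos
  removed <- vapply(seq_len(nrow(targets)), function(i) {
    any(vapply(seq_len(nrow(interfering)), function(j) {
      if (targets$contig[i] != interfering$contig[j]) return(FALSE)
      d <- max(0, max(interfering$pos[j] - targets$pos[i],
                      targets$pos[i] - interfering$end[j]))
      d >= 1 && d <= window_bp
    }, logical(1)))
  }, logical(1))
  removed
}

# data.frame comparison stripped of carrier attributes (header, features, ...)
plain_df <- function(x) {
  y <- as.data.frame(x)
  for (a in setdiff(names(attributes(y)), c("names", "row.names", "class"))) {
    attr(y, a) <- NULL
  }
  rownames(y) <- NULL
  y
}

# Random gvcf_records table for round-trip properties.
random_gvcf_records <- function(n, seed) {
  withr::with_seed(seed, {
    pos <- sort(sample.int(100000, n))
    kind <- sample(c("BLOCK", "VARIANT"), n, replace = TRUE)
    ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    alt <- ifelse(kind == "VARIANT",
                  sample(c("A", "C", "G", "T", "A,G", "C,T"), n, replace = TRUE),
                  NA_character_)
    end <- ifelse(kind == "BLOCK", pos + sample(0:200, n, replace = TRUE),
                  pos + nchar(sub(",.*", "", ref)) - 1L)
    # keep blocks from running into the next record
    end <- pmin(end, c(pos[-1] - 1L, max(pos) + 500L))
    end <- pmax(end, pos)
    rec <- data.frame(
      contig = "chr1", pos = pos,
      id = ifelse(stats::runif(n) < 0.3, paste0("rs", seq_len(n)), NA_character_),
      ref = ref, alt = alt,
      qual = ifelse(stats::runif(n) < 0.5, round(stats::runif(n, 1, 500), 2), NA_real_),
      filter = sample(c("PASS", "LowGQX", NA_character_), n, replace = TRUE),
      kind = kind, end = as.integer(end),
      gt = ifelse(kind == "BLOCK", "0/0",
                  sample(c("0/1", "1/1", "1/2", "./."), n, replace = TRUE)),
      gqx = ifelse(stats::runif(n) < 0.8, sample(0:99, n, replace = TRUE), NA_real_),
      dp = ifelse(stats::runif(n) < 0.8, sample(1:60, n, replace = TRUE), NA_integer_),
      min_dp = ifelse(kind == "BLOCK", sample(1:50, n, replace = TRUE), NA_integer_),
      stringsAsFactors = FALSE
    )
    class(rec) <- c("gvcf_records", "data.frame")
    rec
  })
}
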