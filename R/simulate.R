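# Deterministic synthetic data with known truth: a random reference sequence,
# catalog sites with population alt-allele frequencies, Hardy-Weinberg
# genotypes, an Isaac-style gVCF (variant records plus quality-banded
# non-variant blocks, with low-confidence intervals), and a genotyping-array
# report with injectable genotype errors and strand flips. Everything other
# modules need is generated locally; no downloads.

#' Simulation configuration
#'
#' @param genome_length Reference length in bp.
#' @param n_sites Number of catalog sites (`<= genome_length`).
#' @param gc_content Expected reference GC fraction (default 0.41, the
#'   human-genome average).
#' @param alt_freq_shape1,alt_freq_shape2 Beta parameters for per-site alt
#'   allele frequency; the default Beta(1, 1) draws frequencies uniformly, so
#'   the simulated catalog mixes common and rare alleles, including sites
#'   with the minor allele on the reference.
#' @param nocall_fraction Fraction of the genome placed in low-confidence
#'   blocks (blocks whose GQX fails the default policy).
#' @param array_error_rate Probability an array genotype is perturbed to a
#'   different class.
#' @param strand_flip_rate Probability an array row reports complemented
#'   alleles (manifest on the opposite strand).
#' @param mean_block_length Mean non-variant block length in bp (default 100,
#'   emulating the GQX quality banding that fragments real WGS gVCF blocks).
#' @param seed Integer seed; every generator consumes a stream derived from
#'   it, so a config is bit-reproducible.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(genome_length = 100000, n_sites = 500,
                       gc_content = 0.41, alt_freq_shape1 = 1,
                       alt_freq_shape2 = 1, nocall_fraction = 0,
                       array_error_rate = 0, strand_flip_rate = 0,
                       mean_block_length = 100, seed = 1) {
  stopifnot(n_sites <= genome_length,
            nocall_fraction >= 0, nocall_fraction <= 1,
            array_error_rate >= 0, array_error_rate <= 1,
            strand_flip_rate >= 0, strand_flip_rate <= 1)
  structure(list(genome_length = as.integer(genome_length),
                 n_sites = as.integer(n_sites), gc_content = gc_content,
                 alt_freq_shape1 = alt_freq_shape1,
                 alt_freq_shape2 = alt_freq_shape2,
                 nocall_fraction = nocall_fraction,
                 array_error_rate = array_error_rate,
                 strand_flip_rate = strand_flip_rate,
                 mean_block_length = as.integer(mean_block_length),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate a random reference sequence
#'
#' Bases are drawn i.i.d. with the requested expected GC fraction. Optional
#' embedded features plant sequence contexts at recorded positions: a GC-rich
#' window (`list(type = "gc", length = 100, gc = 0.9)`, aligned to the
#' 100 bp window grid so window classification recovers it exactly) or an
#' alternating AT-dinucleotide run (`list(type = "at", length = 30)`, with
#' G/C flanks so the run is maximal).
#'
#' @param length Sequence length (`>= 1`).
#' @param gc_content Expected GC fraction in `[0, 1]`.
#' @param features Optional list of feature specs (above).
#' @param seed Integer seed, or `NULL` to use the current RNG stream.
#' @return DNA string with attribute `"features"` (data frame `type`,
#'   `start`, `end`, `gc`).
#' @export
generate_reference <- function(length, gc_content = 0.41, features = NULL,
                               seed = NULL) {
  stopifnot(length >= 1)
  with_seed(seed, {
    probs <- c(A = (1 - gc_content) / 2, C = gc_content / 2,
               G = gc_content / 2, T = (1 - gc_content) / 2)
    chars <- sample(names(probs), length, replace = TRUE, prob = probs)
    placed <- data.frame(type = character(0), start = integer(0),
                         end = integer(0), gc = numeric(0),
                         stringsAsFactors = FALSE)
    for (ft in features %||% list()) {
      len <- as.integer(ft$length)
      if (len + 2 > length) stop("feature longer than the genome")
      start <- NA_integer_
      for (try in 1:1000) {
        cand <- if (identical(ft$type, "gc")) {
          # align to the 100 bp tiling grid used by window classification
          grid <- seq(1L, length - len + 1L, by = 100L)
          sample(grid, 1)
        } else {
          sample(2:(length - len), 1)
        }
        if (nrow(placed) == 0 ||
            all(cand > placed$end + 1 | cand + len - 1 < placed$start - 1)) {
          start <- cand
          break
        }
      }
      if (is.na(start)) stop("could not place feature without overlap")
      end <- start + len - 1L
      if (identical(ft$type, "gc")) {
        n_gc <- round((ft$gc %||% 0.9) * len)
        bases <- sample(c(rep(c("G", "C"), length.out = n_gc),
                          rep(c("A", "T"), length.out = len - n_gc)))
        chars[start:end] <- bases
        placed <- rbind(placed, data.frame(type = "gc", start = start,
                                           end = end, gc = n_gc / len))
      } else if (identical(ft$type, "at")) {
        chars[start:end] <- rep(c("A", "T"), length.out = len)
        if (start > 1) chars[start - 1] <- "C"
        if (end < length) chars[end + 1] <- "G"
        placed <- rbind(placed, data.frame(type = "at", start = start,
                                           end = end, gc = NA_real_))
      } else {
        stop("unknown feature type: ", ft$type)
      }
    }
    seqn <- paste(chars, collapse = "")
    attr(seqn, "features") <- placed
    seqn
  })
}

#' Simulate catalog sites on a reference
#'
#' Draws `n_sites` distinct positions, takes the reference base as REF, one
#' random other base as ALT, and a Beta-distributed alt allele frequency.
#'
#' @param reference DNA string.
#' @param config [sim_config()].
#' @param seed Integer seed, or `NULL` to use the current stream.
#' @return `site_records` data frame with sequential rsIDs.
#' @export
simulate_sites <- function(reference, config, seed = NULL) {
  with_seed(seed, {
    L <- nchar(reference)
    pos <- sort(sample.int(L, config$n_sites))
    ref <- substring(reference, pos, pos)
    bases <- c("A", "C", "G", "T")
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1),
                  USE.NAMES = FALSE)
    q <- stats::rbeta(config$n_sites, config$alt_freq_shape1,
                      config$alt_freq_shape2)
    q <- pmin(pmax(q, 1e-4), 1 - 1e-4)
    out <- data.frame(
      contig = "chr1", pos = pos, rsid = paste0("rs", seq_along(pos)),
      ref = ref, alt = alt, alt_freqs = fmt_num(q),
      clnsig = NA_character_, duplicate = FALSE, stringsAsFactors = FALSE
    )
    class(out) <- c("site_records", "data.frame")
    out
  })
}

#' Draw Hardy-Weinberg genotypes at simulated sites
#'
#' Per site with alt frequency `q`: hom-ref with probability `(1-q)^2`, het
#' with `2q(1-q)`, hom-alt with `q^2`.
#'
#' @param sites `site_records` with one alt frequency per site, each strictly
#'   inside `(0, 1)`.
#' @param seed Integer seed, or `NULL`.
#' @return Character vector of true call classes aligned to `sites`.
#' @export
simulate_genotypes <- function(sites, seed = NULL) {
  q <- suppressWarnings(as.numeric(sites$alt_freqs))
  if (anyNA(q) || any(q <= 0) || any(q >= 1)) {
    stop("alt allele frequencies must lie strictly inside (0, 1)")
  }
  with_seed(seed, {
    u <- stats::runif(length(q))
    p_hr <- (1 - q)^2
    p_het <- 2 * q * (1 - q)
    ifelse(u < p_hr, "HOM_REF", ifelse(u < p_hr + p_het, "HET", "HOM_ALT"))
  })
}

#' Simulate a full truth set
#'
#' Composes [generate_reference()], [simulate_sites()] and
#' [simulate_genotypes()] under the config's seed and places the
#' low-confidence (no-call) intervals: random stretches totalling
#' `nocall_fraction` of the genome, excluding the positions of variant
#' records (a variant record is the caller's own evidence and is never masked
#' away), so no-calls arise where a mask interval overlaps a hom-ref catalog
#' site.
#'
#' @param config [sim_config()].
#' @return Object of class `truth_set`: `reference`, `sites`, `genotypes`,
#'   `nocall_mask` (interval data frame), `config`.
#' @export
simulate_truth <- function(config) {
  with_seed(config$seed, {
    reference <- generate_reference(config$genome_length, config$gc_content)
    sites <- simulate_sites(reference, config)
    genotypes <- simulate_genotypes(sites)
    L <- config$genome_length
    target <- round(config$nocall_fraction * L)
    mask <- rep(FALSE, L)
    if (target >= L) {
      mask[] <- TRUE
    } else if (target > 0) {
      while (sum(mask) < target) {
        len <- max(1L, min(L, stats::rgeom(1, 1 / 100) + 1L))
        s <- sample.int(L - len + 1L, 1)
        mask[s:(s + len - 1L)] <- TRUE
      }
      # trim overshoot from the last interval's tail
      excess <- sum(mask) - target
      if (excess > 0) {
        on_idx <- which(mask)
        mask[on_idx[seq_len(excess)]] <- FALSE
      }
    }
    mask[sites$pos[genotypes != "HOM_REF"]] <- FALSE
    r <- rle(mask)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    nocall_mask <- data.frame(start = starts[r$values], end = ends[r$values])
    structure(list(reference = reference, sites = sites, genotypes = genotypes,
                   nocall_mask = nocall_mask, config = config),
              class = "truth_set")
  })
}

# split a [s, e] run into chunks around the configured mean block length
chunk_run <- function(s, e, mean_len) {
  out_s <- integer(0)
  while (s <= e) {
    len <- sample(seq(max(1L, round(mean_len / 2)), round(mean_len * 1.5)), 1)
    out_s <- c(out_s, s)
    s <- s + len
  }
  cbind(start = out_s, end = c(out_s[-1] - 1L, e))
}

#' Emit an Isaac-style gVCF from a truth set
#'
#' Het and hom-alt sites become variant records; every other position is
#' covered by non-variant blocks (GT `0/0`, `END`, `GQX`, `MIN_DP`). Blocks
#' inside the truth set's no-call mask draw GQX uniformly from `[0, 19]`
#' (failing the default policy floor of 20); all other blocks draw from
#' `[30, 99]` and are split into runs around `mean_block_length` bp,
#' emulating quality banding.
#'
#' @param truth [simulate_truth()] result.
#' @param seed Integer seed, or `NULL`.
#' @return `gvcf_records` data frame (valid under [parse_gvcf()] /
#'   [write_gvcf()]).
#' @export
emit_gvcf <- function(truth, seed = NULL) {
  cfg <- truth$config
  with_seed(seed %||% (cfg$seed + 101L), {
    L <- cfg$genome_length
    state <- integer(L)                       # 0 pass block, 1 fail block, 2 variant
    if (nrow(truth$nocall_mask) > 0) {
      for (k in seq_len(nrow(truth$nocall_mask))) {
        state[truth$nocall_mask$start[k]:truth$nocall_mask$end[k]] <- 1L
      }
    }
    var_idx <- which(truth$genotypes != "HOM_REF")
    state[truth$sites$pos[var_idx]] <- 2L

    r <- rle(state)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    blocks <- list()
    for (k in seq_along(r$values)) {
      if (r$values[k] == 2L) next
      ch <- chunk_run(starts[k], ends[k], cfg$mean_block_length)
      blocks[[length(blocks) + 1L]] <-
        cbind(ch, fail = rep(r$values[k], nrow(ch)))
    }
    blocks <- do.call(rbind, blocks)

    n_b <- if (is.null(blocks)) 0L else nrow(blocks)
    b_gqx <- numeric(n_b)
    if (n_b > 0) {
      fail <- blocks[, "fail"] == 1L
      b_gqx[!fail] <- sample(30:99, sum(!fail), replace = TRUE)
      b_gqx[fail] <- sample(0:19, sum(fail), replace = TRUE)
    }
    block_rec <- if (n_b > 0) data.frame(
      contig = "chr1", pos = as.integer(blocks[, "start"]),
      id = NA_character_,
      ref = substring(truth$reference, blocks[, "start"], blocks[, "start"]),
      alt = NA_character_, qual = NA_real_, filter = "PASS", kind = "BLOCK",
      end = as.integer(blocks[, "end"]), gt = "0/0", gqx = b_gqx,
      dp = 32L, min_dp = 30L, stringsAsFactors = FALSE
    ) else empty_gvcf_records()

    n_v <- length(var_idx)
    var_rec <- if (n_v > 0) data.frame(
      contig = "chr1", pos = truth$sites$pos[var_idx],
      id = truth$sites$rsid[var_idx], ref = truth$sites$ref[var_idx],
      alt = truth$sites$alt[var_idx],
      qual = round(stats::runif(n_v, 50, 500)), filter = "PASS",
      kind = "VARIANT", end = truth$sites$pos[var_idx],
      gt = ifelse(truth$genotypes[var_idx] == "HET", "0/1", "1/1"),
      gqx = sample(30:99, n_v, replace = TRUE), dp = 30L,
      min_dp = NA_integer_, stringsAsFactors = FALSE
    ) else empty_gvcf_records()

    rec <- rbind(block_rec, var_rec)
    rec <- rec[order(rec$pos), ]
    rownames(rec) <- NULL
    class(rec) <- c("gvcf_records", "data.frame")
    attr(rec, "header") <- gvcf_standard_header()
    rec
  })
}

#' Truth genotype calls in the standard call layout
#'
#' @param truth [simulate_truth()] result.
#' @return Genotype-call data frame comparable with [compare_callsets()].
#' @export
truth_calls <- function(truth) {
  s <- truth$sites
  cls <- truth$genotypes
  a1 <- ifelse(cls == "HOM_REF", s$ref, ifelse(cls == "HET", s$ref, s$alt))
  a2 <- ifelse(cls == "HOM_REF", s$ref, s$alt)
  data.frame(contig = s$contig, pos = s$pos, rsid = s$rsid, ref = s$ref,
             alt = s$alt, call_class = cls, alleles = format_alleles(a1, a2),
             source = "TRUTH", gqx = NA_real_, dp = NA_real_, conflict = FALSE,
             stringsAsFactors = FALSE)
}

#' Emit a genotyping-array report from a truth set
#'
#' Per site: with probability `array_error_rate` the reported genotype class
#' is perturbed to a different class (uniformly among the other two of
#' hom-ref/het/hom-alt); with probability `strand_flip_rate` the reported
#' alleles are complemented (manifest-strand flip). The class actually
#' reported (post-perturbation, pre-flip) is kept in attribute
#' `"reported_class"` so tests can compute exact expectations.
#'
#' @param truth [simulate_truth()] result.
#' @param seed Integer seed, or `NULL`.
#' @return `array_genotypes` data frame.
#' @export
emit_array_report <- function(truth, seed = NULL) {
  cfg <- truth$config
  with_seed(seed %||% (cfg$seed + 202L), {
    s <- truth$sites
    n <- nrow(s)
    cls <- truth$genotypes
    perturb <- stats::runif(n) < cfg$array_error_rate
    three <- c("HOM_REF", "HET", "HOM_ALT")
    cls[perturb] <- vapply(cls[perturb], function(cl) {
      sample(setdiff(three, cl), 1)
    }, character(1))
    a1 <- ifelse(cls == "HOM_REF", s$ref, ifelse(cls == "HET", s$ref, s$alt))
    a2 <- ifelse(cls == "HOM_REF", s$ref, s$alt)
    flip <- stats::runif(n) < cfg$strand_flip_rate
    a1[flip] <- complement_base(a1[flip])
    a2[flip] <- complement_base(a2[flip])
    out <- data.frame(marker_id = s$rsid, contig = s$contig, pos = s$pos,
                      allele_a = a1, allele_b = a2, unmatched = FALSE,
                      stringsAsFactors = FALSE)
    class(out) <- c("array_genotypes", "data.frame")
    attr(out, "reported_class") <- cls
    out
  })
}

#' Write a complete synthetic dataset to a directory
#'
#' Writes `reference.fa`, `sites.vcf`, `sample.gvcf`, `array.tsv` and
#' `truth.tsv` (true classes and the no-call mask) for a config, all derived
#' deterministically from its seed.
#'
#' @param config [sim_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the [simulate_truth()] object.
#' @export
simulate_dataset <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  truth <- simulate_truth(config)
  dna <- Biostrings::DNAStringSet(truth$reference)
  names(dna) <- "chr1"
  Biostrings::writeXStringSet(dna, file.path(dir, "reference.fa"))
  write_site_vcf(truth$sites, file.path(dir, "sites.vcf"))
  write_gvcf(emit_gvcf(truth), file.path(dir, "sample.gvcf"))
  write_array_report(emit_array_report(truth), file.path(dir, "array.tsv"))
  tt <- data.frame(contig = truth$sites$contig, pos = truth$sites$pos,
                   rsid = truth$sites$rsid, true_class = truth$genotypes)
  utils::write.table(tt, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (nrow(truth$nocall_mask) > 0) {
    utils::write.table(cbind(contig = "chr1", truth$nocall_mask),
                       file.path(dir, "nocall_mask.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(truth)
}
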