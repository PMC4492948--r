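#' Genotype call classes
#'
#' The five call classes used throughout the package, in the fixed order used
#' by cross-tabulations: homozygous reference, heterozygous (reference plus
#' one alternate), homozygous alternate, heterozygous for two alternates, and
#' no-call (evidence below the confidence policy).
#'
#' @format Character vector of length 5.
#' @export
CALL_CLASSES <- c("HOM_REF", "HET", "HOM_ALT", "HET_ALT", "NO_CALL")

# Watson-Crick complement for a vector of single-base allele strings.
# Missing values stay missing.
complement_base <- function(x) {
  map <- c(A = "T", C = "G", G = "C", T = "A")
  out <- unname(map[x])
  out[is.na(x)] <- NA_character_
  if (anyNA(out) && !all(is.na(x) == is.na(out))) {
    bad <- unique(x[!is.na(x) & is.na(out)])
    stop("cannot complement non-ACGT allele(s): ", paste(bad, collapse = ", "))
  }
  out
}

# Run code with a private RNG stream, restoring the caller's .Random.seed.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

# Normalized diploid genotype string "A/G" with alleles sorted, or NA.
format_alleles <- function(a1, a2) {
  out <- rep(NA_character_, length(a1))
  ok <- !is.na(a1) & !is.na(a2)
  lo <- pmin(a1[ok], a2[ok])
  hi <- pmax(a1[ok], a2[ok])
  out[ok] <- paste(lo, hi, sep = "/")
  out
}

# Classify a diploid genotype by its two allele index values (0 = ref).
classify_gt_indices <- function(i1, i2) {
  ifelse(is.na(i1) | is.na(i2), "NO_CALL",
    ifelse(i1 == 0 & i2 == 0, "HOM_REF",
      ifelse(i1 == 0 | i2 == 0, "HET",
        ifelse(i1 == i2, "HOM_ALT", "HET_ALT"))))
}

split_csv <- function(x) {
  if (is.na(x) || !nzchar(x)) character(0) else strsplit(x, ",", fixed = TRUE)[[1]]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
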