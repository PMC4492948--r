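---
title: "Genotyping non-variant sites from gVCF blocks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotyping non-variant sites from gVCF blocks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evcfkit)
```

## The model

A diploid genotype at a catalog site takes one of five classes: `HOM_REF`,
`HET`, `HOM_ALT`, `HET_ALT` (two different alternate alleles), `NO_CALL`.
A variant-only VCF observes only the middle three; `evcfkit`'s central
operation, `resolve_genotypes()`, recovers the other two from a gVCF:

1. **Variant route.** A variant record at the site's `(contig, pos)` supplies
   the genotype directly from its `GT` allele indices. The confidence policy
   is *not* applied here: variant records carry the caller's own `FILTER`,
   which is copied through unchanged. (Whether a clinical pipeline should
   instead demote filtered variant records to no-calls is a judgement call;
   this package passes them through and counts them as called, keeping the
   VCF side of the output bit-identical to the caller's.)
2. **Block route.** Otherwise the site is homozygous reference if and only if
   *every base* of its REF span `[pos, pos + nchar(ref) - 1]` is covered by
   non-variant block records that pass the policy. Full-span containment is
   deliberately conservative for indel-length REF alleles: a half-covered
   reference claim is never made. The reported `GQX`/depth are the minima
   over the covering blocks.
3. **No-call.** Anything else. Every site resolves to exactly one class, so
   the five class counts always sum to the catalog size (asserted on every
   run).

A catalog site whose REF disagrees with the REF of a co-located variant
record is resolved `NO_CALL` with a `conflict` flag rather than aborting:
one bad catalog line must not kill a clinical run.

## The confidence policy

`confidence_policy(min_gqx = 20, min_dp = 5, require_pass = TRUE)` gives
meaning to "high-confidence block". The gVCF convention never fixes the
thresholds, so these defaults are the package's choice: 20 is the
conventional Q20 floor for `GQX` (a genotype-quality floor field emitted by
gVCF-producing callers), and 5 matches the read-depth floor used throughout
the coverage QC. `MIN_DP` is used where present, `DP` otherwise. A block
with *missing* `GQX` fails any finite threshold — conservative, because an
unquantified hom-ref assertion is exactly what the format exists to avoid.
All three parameters are recorded in the eVCF header
(`##confidencePolicy=...`), so a file documents its own calling stringency.

Two monotonicity properties follow and are tested: raising `min_gqx` or
`min_dp` never converts a `NO_CALL` into a call and never touches
variant-route calls; and the set of sites genotyped from the full gVCF is
always a superset of the set genotyped from its variant-only view.

## The eVCF representation

The output records are ordinary VCF 4.x. Record layout for catalog sites is
a design choice (no published layout exists for this content):

- hom-ref: `ALT .`, `GT 0/0` — valid VCF, unambiguous, accepted by the
  annotation engines we cross-check against (`VariantAnnotation` in the test
  suite; `bcftools` parses the files as well);
- no-call: `GT ./.`, emitted by default (`emit_nocalls = TRUE`). Silently
  dropping no-calls would re-create the very ambiguity the format removes,
  so suppression is opt-in.
- provenance: one `##siteCatalog=<name=...,version=...>` line; writing
  catalog records with an empty name/version is an error.

INFO carries `known` (catalog membership), `gwascat_id`/`odds_ratio`
(comma-joined aligned lists — a site may have several associations),
`clnsig`, and `conflict`. Coordinates are 1-based inclusive everywhere
internally, matching VCF `POS`/`END`; BED input is converted on read.

## Catalogs and the reference-allele audit

dbSNP-style membership matches by `(contig, pos, ref)` with rsID fallback; a
position match with a different REF is a warning, never a silent accept.
GWAS-catalog rows are joined onto working-assembly coordinates purely by
rsID (no chain-file liftover); rows whose rsID is unknown are dropped and
counted, and an unparsable odds-ratio field (`"NR"`) keeps the association
with the odds ratio missing.

The reference-allele audit computes the reference allele frequency as
`1 - sum(alt frequencies)` and calls a site *minor-on-reference* when that
frequency is strictly below 0.5 (a tie at exactly 0.5 is `NOT_MINOR`). Bins
are the tightest containing threshold — `LT1` (< 1%), `LT5` (< 5%), `LT50`
(< 50%) — so they partition the catalog; the cumulative view (`LT1` ⊆
`LT5` ⊆ `LT50`) is asserted in tests. Which population's frequency field a
catalog provides varies, so the INFO key is configurable (`CAF`-style lists
with a leading reference frequency are detected by length).

## Concordance definitions

Published concordance figures rarely state their formulas, so the package
fixes truth-referenced definitions and prints them with the report:

- *sensitivity* = truth-variant sites called variant by the test set /
  truth-variant sites;
- *specificity* = truth-hom-ref sites called hom-ref / truth-hom-ref sites;
- *concordance* = exact class-and-allele matches / mutually called shared
  sites (symmetric in its arguments; the other two are intentionally not);
- sites where either side is `NO_CALL` are excluded from all three rates but
  kept in the cross-tabulation margins and in `no_call_rate`. Both
  `concordance` and `concordance_variant_sites` are reported, since either
  denominator is defensible.

Array alleles are matched to the expected `{REF} ∪ ALTs` directly, then via
Watson–Crick complement (array manifests are strand-agnostic). At A/T and
C/G sites both readings are consistent, so the genotype is
strand-unresolvable; the default is to exclude such sites from the rates
(`trust_strand = TRUE` accepts the direct reading). The probe-interference
filter removes targets with another polymorphism at distance 1–10 bp
(distance to the nearest base of an indel's REF span; distance 0 is the
assayed polymorphism itself, not interference).

## Coverage QC

A base is *covered* when read depth ≥ 5, mapping quality ≥ 10 and basecall
quality ≥ 10 (all configurable). The source material states the gap rule
both as "all three low" and as the complement of the coverage rule; the two
differ on bases failing only some criteria, so both are implemented:
`gap_logic = "any"` (default — a gap base is any uncovered base) and
`"all"`. Gaps are maximal runs *strictly longer than 10 bp*
(`min_gap_len = 11`); the boundary (run of 10 → no gap, 11 → gap) is pinned
by tests against a brute-force enumerator. Thresholds are applied as `>=`,
following the coverage-fraction convention. The per-base `mapq`/`baseq`
arrays are consumed as whatever summary the upstream tool emits (mean or
minimum over reads — a pass-through, documented rather than reinterpreted).

GC windows are non-overlapping 100 bp tiles from the contig start (stride
is not specified by any convention; tiling is the simplest reproducible
choice), classed `HIGH_GC` at ≥ 75% and `EXTREME_GC` at ≥ 85%, with `N`
bases excluded from numerator and denominator. AT runs are maximal strictly
alternating `ATAT…`/`TATA…` stretches ≥ 30 bp — a homopolymer does not
qualify. Coverage thinning replaces each base's depth with a binomial draw
at `p = target_mean / current_mean`: read-level resampling is out of scope,
and binomial thinning preserves exactly the mean-coverage semantics of
sub-sampled datasets (zeros stay zero; same seed, same output).

## What the synthetic data does and does not emulate

`sim_config()` defaults define the simulated study conditions:

- genome 100 kb, GC 0.41 (human average), catalog sites uniform over the
  genome with Beta(1, 1) alt-allele frequencies — a flat spectrum that mixes
  common and rare alleles so both hom-ref-informative (minor-on-reference)
  and variant sites occur;
- Hardy–Weinberg genotypes per site;
- an Isaac-style gVCF: het/hom-alt sites become variant records; everything
  else is tiled by blocks with `GQX` drawn uniformly from [30, 99] (passing)
  or [0, 19] (failing), bracketing the default floor of 20; passing runs are
  split into blocks of ~100 bp mean length, emulating the `GQX` quality
  banding that makes real WGS gVCFs large (a human-genome gVCF at ~1 GB
  implies a block per ~100–150 bp) — without banding a noise-free synthetic
  gVCF collapses into a handful of giant blocks and any file-size comparison
  would be meaningless;
- low-confidence intervals (geometric lengths, mean 100 bp) are placed
  uniformly until they cover `nocall_fraction` of the genome, then variant
  positions are excised from them: the caller's variant records are never
  masked away. Consequently only truth hom-ref sites can become no-calls,
  and the recovered no-call rate is defined *among those eligible sites*,
  where its expectation equals the nominal fraction; measured over all sites
  its expectation would be `nocall_fraction × P(hom-ref)` and would track
  nothing interpretable;
- the array report perturbs each genotype to a different class with
  probability `array_error_rate` (so `1 − concordance` estimates that rate
  directly) and complements alleles with probability `strand_flip_rate`.

Not emulated: reads and sequencing error (no FASTQ; depth enters as given),
indel catalog sites and multi-allelic sites (hand-written fixtures cover
those code paths), linkage structure, sex-chromosome ploidy (caller
genotypes are passed through without hemizygosity reinterpretation), and
multi-sample data (single-sample only, as the gVCF block model itself
implies). Passing tests therefore demonstrate the correctness of the
resolution, accounting and format logic under the stated generative model —
not caller accuracy on real reads.

## Numerical and degenerate-input choices

- Interval queries go through `IRanges`; a brute-force per-base linear scan
  lives in the test suite as the oracle, and the two are required to agree
  at 100% of sites on randomized genomes (20 genomes × 1,000 sites in the
  test suite, sized to keep the default run around a minute for this check).
- Frequencies summing to more than 1 (beyond 1e-6 tolerance) are an error;
  sums just under 1 clamp the reference frequency at 0.
- Overlapping block records are a structural error; a variant record
  co-located with a block draws a warning and the variant wins.
- Multiallelic catalog lines stay one site with the full ALT list; duplicate
  `(contig, pos, ref, id)` lines are kept and flagged rather than dropped.
- Array exports with exactly one missing allele are treated as full
  no-calls (they only arise from malformed exports).
- `parse_gvcf` accepts `MIN_DP`/`GQX` from INFO or FORMAT — callers differ
  on the placement, and nothing in the format pins it down.

## Known limitations

- Sensitivity/specificity are undefined (NA) when the truth set lacks
  variant or hom-ref calls among the mutually called sites.
- The hom-ref block route trusts the gVCF's own reference encoding; it does
  not re-check block REF bases against a FASTA.
- The probe-interference filter expects interfering variants as records with
  a REF span; symbolic/structural ALTs are out of scope everywhere.
- rsID-keyed GWAS remapping surfaces merged or multi-mapped rsIDs only as
  dropped rows; it does not attempt to resolve them.
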