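test_that("gVCF block and variant lines map to records field by field", {
  g <- parse_gvcf(gvcf_fixture_lines(c(
    "chr1\t100\t.\tA\t.\t.\tPASS\tEND=199\tGT:GQX:DP:MIN_DP\t0/0:50:32:30",
    "chr1\t1500\trs1\tA\tG\t120\tPASS\t.\tGT:GQX\t0/1:110"
  )))
  expect_equal(nrow(g), 2)
  blk <- g[1, ]
  expect_equal(blk$kind, "BLOCK")
  expect_equal(blk$contig, "chr1")
  expect_equal(blk$pos, 100L)
  expect_equal(blk$end, 199L)
  expect_equal(blk$gqx, 50)
  expect_equal(blk$min_dp, 30L)
  expect_equal(blk$filter, "PASS")
  expect_true(is.na(blk$alt))
  v <- g[2, ]
  expect_equal(v$kind, "VARIANT")
  expect_equal(v$pos, 1500L)
  expect_equal(v$end, 1500L)
  expect_equal(v$gt, "0/1")
  expect_equal(v$id, "rs1")
})

test_that("gVCF parser accepts MIN_DP/GQX from INFO as well as FORMAT", {
  g <- parse_gvcf(gvcf_fixture_lines(
    "chr1\t100\t.\tA\t.\t.\tPASS\tEND=150;MIN_DP=12;GQX=44\tGT\t0/0"
  ))
  expect_equal(g$min_dp, 12L)
  expect_equal(g$gqx, 44)
})

test_that("malformed, inverted-END and out-of-order gVCF lines raise located errors", {
  expect_error(
    parse_gvcf(gvcf_fixture_lines("chr1\t100\t.\tA")),
    "line 3")
  expect_error(
    parse_gvcf(gvcf_fixture_lines(
      "chr1\t100\t.\tA\t.\t.\tPASS\tEND=99\tGT\t0/0")),
    "END \\(99\\) < POS \\(100\\)")
  expect_error(
    parse_gvcf(gvcf_fixture_lines(c(
      "chr1\t500\t.\tA\tG\t10\tPASS\t.\tGT\t0/1",
      "chr1\t100\t.\tA\tG\t10\tPASS\t.\tGT\t0/1"))),
    "ordering error")
  expect_error(
    parse_gvcf(gvcf_fixture_lines(c(
      "chr2\t10\t.\tA\tG\t10\tPASS\t.\tGT\t0/1",
      "chr1\t20\t.\tA\tG\t10\tPASS\t.\tGT\t0/1",
      "chr2\t30\t.\tA\tG\t10\tPASS\t.\tGT\t0/1"))),
    "ordering error")
})

test_that("every well-formed gVCF line maps to exactly one record", {
  rec <- random_gvcf_records(200, seed = 11)
  lines <- write_gvcf(rec)
  n_header <- sum(startsWith(lines, "#"))
  expect_equal(length(lines), n_header + nrow(rec))
  expect_equal(nrow(parse_gvcf(lines)), nrow(rec))
})

test_that("gVCF write/parse round-trips field by field on randomized records", {
  for (seed in c(1, 7, 42)) {
    rec <- random_gvcf_records(150, seed = seed)
    back <- parse_gvcf(write_gvcf(rec))
    expect_equal(plain_df(back), plain_df(rec))
  }
})

test_that("sites-only VCF parsing handles CAF, multiallelics, skips and duplicates", {
  s <- parse_site_vcf(c(
    "##fileformat=VCFv4.1",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "chr1\t300\trs42\tA\tG\t.\t.\tCAF=0.8,0.2",
    "chr1\t400\trs43\tC\tG,T\t.\t.\t.",
    "chr1\t500\trs44\tT\t.\t.\t.\t.",
    "chr1\t600\trs45\tG\tA\t.\t.\tCAF=0.99,0.01",
    "chr1\t600\trs45\tG\tA\t.\t.\tCAF=0.99,0.01"
  ))
  expect_equal(nrow(s), 4)
  expect_equal(attr(s, "n_skipped"), 1L)
  expect_equal(s$rsid[1], "rs42")
  expect_equal(as.numeric(s$alt_freqs[1]), 0.2)
  expect_equal(s$alt[2], "G,T")
  expect_false(s$duplicate[1])
  expect_true(all(s$duplicate[3:4]))
  expect_error(parse_site_vcf(c(
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "chr1\t300\trs42\t.\tG\t.\t.\t.")), "missing REF")
})

test_that("eVCF serialization follows the hom-ref and no-call record rules", {
  cfg <- sim_config(genome_length = 5000, n_sites = 20, nocall_fraction = 0.2,
                    seed = 5)
  tr <- simulate_truth(cfg)
  b <- build_evcf(emit_gvcf(tr), tr$sites)
  meta <- evcf_header_meta("dbSNP-sim", "141-sim", policy = confidence_policy())
  lines <- write_evcf(b$records, meta)
  expect_true(any(grepl("^##siteCatalog=<name=dbSNP-sim,version=141-sim>", lines)))
  body <- lines[!startsWith(lines, "#")]
  f <- strsplit(body, "\t", fixed = TRUE)
  alt <- vapply(f, `[`, character(1), 5)
  gt <- sub(":.*", "", vapply(f, `[`, character(1), 10))
  info <- vapply(f, `[`, character(1), 8)
  homref <- b$records$call_class == "HOM_REF" & b$records$source == "BLOCK"
  expect_true(all(alt[homref] == "."))
  expect_true(all(gt[homref] == "0/0"))
  expect_true(all(grepl("known", info[homref])))
  nocall <- b$records$call_class == "NO_CALL"
  if (any(nocall)) expect_true(all(gt[nocall] == "./."))
  # reparse is clean and genotypes survive
  back <- parse_evcf(lines)
  expect_equal(nrow(back), nrow(b$records))
  expect_equal(back$gt, b$records$gt)
  expect_equal(back$known, b$records$known %in% TRUE)
})

test_that("write_evcf enforces provenance and key declarations", {
  cfg <- sim_config(genome_length = 2000, n_sites = 5, seed = 2)
  tr <- simulate_truth(cfg)
  b <- build_evcf(emit_gvcf(tr), tr$sites)
  expect_error(write_evcf(b$records, evcf_header_meta("dbSNP-sim", "")),
               "catalog_version")
  meta <- evcf_header_meta("dbSNP-sim", "141-sim")
  meta$extra_info_keys <- meta$extra_info_keys[
    setdiff(names(meta$extra_info_keys), "known")]
  expect_error(write_evcf(b$records, meta), "not declared")
  unsorted <- b$records[rev(seq_len(nrow(b$records))), ]
  expect_error(write_evcf(unsorted, evcf_header_meta("a", "b")),
               "ordering error")
})

test_that("array reports normalize no-calls and reject bad alleles", {
  sites <- parse_site_vcf(c(
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "chr1\t300\trs42\tA\tG\t.\t.\t."))
  tsv <- c("marker_id\tcontig\tpos\tallele_a\tallele_b",
           "rs42\tchr1\t300\tA\tG",
           "rs42\tchr1\t300\t-\t-",
           "rs99\tchr1\t999\tC\tC")
  ag <- parse_array_report(tsv, expected_sites = sites)
  expect_equal(ag$allele_a[1], "A")
  expect_equal(ag$allele_b[1], "G")
  expect_true(is.na(ag$allele_a[2]) && is.na(ag$allele_b[2]))
  expect_false(ag$unmatched[1])
  expect_true(ag$unmatched[3])
  expect_error(
    parse_array_report(c("marker_id\tcontig\tpos\tallele_a\tallele_b",
                         "rs1\tchr1\t5\tN\tA")),
    "non-ACGT")
})

test_that("annotation-table export follows the left-anchor dialect", {
  rec <- as.data.frame(random_gvcf_records(1, seed = 1))[0, ]
  mk <- function(pos, ref, alt, gt) {
    r <- rec[0, ]
    r[1, c("contig", "pos", "ref", "alt", "gt", "kind", "end")] <-
      list("chr1", pos, ref, alt, gt, "VARIANT", pos + nchar(ref) - 1L)
    r
  }
  het <- export_annotation_table(mk(100L, "A", "G", "0/1"))
  expect_equal(unlist(het[1, ], use.names = FALSE),
               c("chr1", "100", "100", "A", "G"))
  hr <- mk(300L, "A", NA_character_, "0/0")
  out <- export_annotation_table(hr)
  expect_equal(out$sample_observed, out$reference_observed)
  expect_equal(out$start, 300L)
  del <- export_annotation_table(mk(100L, "AG", "A", "0/1"))
  expect_equal(unlist(del[1, ], use.names = FALSE),
               c("chr1", "101", "101", "G", "-"))
  ins <- export_annotation_table(mk(100L, "A", "AG", "0/1"))
  expect_equal(unlist(ins[1, ], use.names = FALSE),
               c("chr1", "100", "100", "-", "G"))
  hetalt <- export_annotation_table(mk(100L, "A", "G,T", "1/2"))
  expect_equal(nrow(hetalt), 2)
  expect_setequal(hetalt$sample_observed, c("G", "T"))
  nc <- mk(100L, "A", "G", "./.")
  skipped <- export_annotation_table(nc, skip_nocalls = TRUE)
  expect_equal(nrow(skipped), 0)
  expect_equal(attr(skipped, "n_skipped"), 1L)
})

test_that("emitted files re-parse with zero errors across generator settings", {
  for (nf in c(0, 0.3)) {
    cfg <- sim_config(genome_length = 8000, n_sites = 40, nocall_fraction = nf,
                      seed = 9)
    tr <- simulate_truth(cfg)
    g <- emit_gvcf(tr)
    expect_silent(parse_gvcf(write_gvcf(g)))
    expect_silent(parse_site_vcf(write_site_vcf(tr$sites)))
    b <- build_evcf(g, tr$sites)
    expect_silent(parse_evcf(write_evcf(
      b$records, evcf_header_meta("dbSNP-sim", "141-sim"))))
    expect_silent(parse_array_report(write_array_report(emit_array_report(tr))))
  }
})

test_that("written eVCF is valid VCF under an independent parser", {
  cfg <- sim_config(genome_length = 10000, n_sites = 60, nocall_fraction = 0.1,
                    seed = 17)
  tr <- simulate_truth(cfg)
  b <- build_evcf(emit_gvcf(tr), tr$sites)
  path <- tempfile(fileext = ".vcf")
  write_evcf(b$records, evcf_header_meta("dbSNP-sim", "141-sim"), path)
  v <- suppressWarnings(VariantAnnotation::readVcf(path, genome = "sim"))
  expect_equal(nrow(v), nrow(b$records))
  gt <- VariantAnnotation::geno(v)$GT[, 1]
  expect_equal(unname(gt), b$records$gt)
  unlink(path)
})
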