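site_row <- function(contig, pos, ref, alt = "G", rsid = "rs1") {
  s <- data.frame(contig = contig, pos = as.integer(pos), rsid = rsid,
                  ref = ref, alt = alt, alt_freqs = NA_character_,
                  clnsig = NA_character_, duplicate = FALSE,
                  stringsAsFactors = FALSE)
  class(s) <- c("site_records", "data.frame")
  s
}

block_line <- function(pos, end, gqx = 50, min_dp = 30, filter = "PASS") {
  sprintf("chr1\t%d\t.\tA\t.\t.\t%s\tEND=%d\tGT:GQX:DP:MIN_DP\t0/0:%s:32:%d",
          pos, filter, end, gqx, min_dp)
}

test_that("index point queries return exactly the covering records", {
  g <- parse_gvcf(gvcf_fixture_lines(c(
    block_line(100, 199),
    "chr1\t1500\trs1\tA\tG\t120\tPASS\t.\tGT:GQX\t0/1:110"
  )))
  idx <- index_gvcf(g)
  expect_equal(query_gvcf_index(idx, "chr1", 150), 1L)
  expect_equal(query_gvcf_index(idx, "chr1", 1500), 2L)
  expect_equal(query_gvcf_index(idx, "chr1", 5000), integer(0))
  expect_equal(query_gvcf_index(idx, "chrX", 150), integer(0))
})

test_that("overlapping blocks are an error; a variant inside a block warns", {
  overlapping <- parse_gvcf(gvcf_fixture_lines(c(
    block_line(100, 199), block_line(150, 250))))
  expect_error(index_gvcf(overlapping), "overlap error")
  nested <- parse_gvcf(gvcf_fixture_lines(c(
    block_line(100, 199),
    "chr1\t150\t.\tA\tG\t99\tPASS\t.\tGT\t0/1")))
  expect_warning(index_gvcf(nested), "variant record")
  # abutting blocks are fine
  expect_silent(index_gvcf(parse_gvcf(gvcf_fixture_lines(c(
    block_line(100, 199), block_line(200, 299))))))
})

test_that("genotype resolution applies the confidence policy to blocks only", {
  g <- parse_gvcf(gvcf_fixture_lines(c(
    block_line(150, 250, gqx = 50, min_dp = 30),
    "chr1\t1500\trs9\tA\tG\t120\tLowGQX\t.\tGT:GQX:DP\t0/1:110:40"
  )))
  idx <- index_gvcf(g)
  hr <- resolve_genotype(site_row("chr1", 200, "A"), idx)
  expect_equal(hr$call_class, "HOM_REF")
  expect_equal(hr$source, "BLOCK")
  expect_equal(hr$alleles, "A/A")
  expect_equal(hr$gqx, 50)

  low <- parse_gvcf(gvcf_fixture_lines(block_line(150, 250, gqx = 10)))
  nc <- resolve_genotype(site_row("chr1", 200, "A"), index_gvcf(low))
  expect_equal(nc$call_class, "NO_CALL")
  expect_equal(nc$source, "NONE")
  expect_true(is.na(nc$alleles))

  het <- resolve_genotype(site_row("chr1", 1500, "A"), idx)
  expect_equal(het$call_class, "HET")       # non-PASS variant passed through
  expect_equal(het$alleles, "A/G")
  expect_equal(het$source, "VARIANT_RECORD")

  # missing GQX fails any finite threshold
  nogqx <- parse_gvcf(gvcf_fixture_lines(
    "chr1\t150\t.\tA\t.\t.\tPASS\tEND=250\tGT:DP:MIN_DP\t0/0:32:30"))
  expect_equal(resolve_genotype(site_row("chr1", 200, "A"),
                                index_gvcf(nogqx))$call_class, "NO_CALL")
})

test_that("hom-ref requires block coverage of the full REF span", {
  g <- index_gvcf(parse_gvcf(gvcf_fixture_lines(block_line(150, 249))))
  # per-base brute force on the 3 bp span 248..250: base 250 uncovered
  expect_equal(resolve_genotype(site_row("chr1", 248, "ATG"), g)$call_class,
               "NO_CALL")
  expect_equal(resolve_genotype(site_row("chr1", 247, "ATG"), g)$call_class,
               "HOM_REF")
  # span covered by two abutting passing blocks counts as covered
  two <- index_gvcf(parse_gvcf(gvcf_fixture_lines(c(
    block_line(150, 248, gqx = 44), block_line(249, 300, gqx = 51)))))
  r <- resolve_genotype(site_row("chr1", 248, "ATG"), two)
  expect_equal(r$call_class, "HOM_REF")
  expect_equal(r$gqx, 44)                   # minimum over covering blocks
})

test_that("genotype classes follow the GT allele indices", {
  g <- index_gvcf(parse_gvcf(gvcf_fixture_lines(c(
    "chr1\t10\t.\tA\tG\t99\tPASS\t.\tGT\t0/0",
    "chr1\t20\t.\tA\tG\t99\tPASS\t.\tGT\t0/1",
    "chr1\t30\t.\tA\tG\t99\tPASS\t.\tGT\t1/1",
    "chr1\t40\t.\tA\tG,T\t99\tPASS\t.\tGT\t1/2",
    "chr1\t50\t.\tA\tG\t99\tPASS\t.\tGT\t./."
  ))))
  sites <- do.call(rbind, lapply(c(10, 20, 30, 40, 50), function(p) {
    site_row("chr1", p, "A")
  }))
  class(sites) <- c("site_records", "data.frame")
  calls <- resolve_genotypes(sites, g)
  expect_equal(calls$call_class,
               c("HOM_REF", "HET", "HOM_ALT", "HET_ALT", "NO_CALL"))
  expect_equal(calls$alleles[4], "G/T")
  expect_equal(calls$source[5], "VARIANT_RECORD")
})

test_that("indexed resolution agrees with the linear per-site oracle", {
  for (seed in c(3, 14)) {
    cfg <- sim_config(genome_length = 30000, n_sites = 300,
                      nocall_fraction = 0.15, seed = seed)
    tr <- simulate_truth(cfg)
    g <- emit_gvcf(tr)
    calls <- resolve_genotypes(tr$sites, g)
    pol <- confidence_policy()
    expected <- vapply(seq_len(nrow(tr$sites)), function(i) {
      oracle_resolve(tr$sites[i, ], g, pol)$call_class
    }, character(1))
    expect_equal(calls$call_class, expected)
  }
})

test_that("raising policy thresholds never converts a no-call into a call", {
  cfg <- sim_config(genome_length = 20000, n_sites = 200,
                    nocall_fraction = 0.1, seed = 8)
  tr <- simulate_truth(cfg)
  g <- emit_gvcf(tr)
  loose <- resolve_genotypes(tr$sites, g, confidence_policy(min_gqx = 10, min_dp = 2))
  strict1 <- resolve_genotypes(tr$sites, g, confidence_policy(min_gqx = 60, min_dp = 2))
  strict2 <- resolve_genotypes(tr$sites, g, confidence_policy(min_gqx = 10, min_dp = 40))
  for (strict in list(strict1, strict2)) {
    was_nc <- loose$call_class == "NO_CALL"
    expect_true(all(strict$call_class[was_nc] == "NO_CALL"))
    # variant-record calls are policy-exempt
    vr <- loose$source == "VARIANT_RECORD"
    expect_equal(strict$call_class[vr], loose$call_class[vr])
    expect_lte(sum(strict$call_class == "HOM_REF"),
               sum(loose$call_class == "HOM_REF"))
  }
})

test_that("an empty catalog reproduces the gVCF's variant records exactly", {
  cfg <- sim_config(genome_length = 10000, n_sites = 50, seed = 4)
  tr <- simulate_truth(cfg)
  g <- emit_gvcf(tr)
  b <- build_evcf(g, tr$sites[0, ])
  vrec <- g[g$kind == "VARIANT", ]
  expect_equal(nrow(b$records), nrow(vrec))
  expect_equal(b$records$pos, vrec$pos)
  expect_equal(b$records$gt, vrec$gt)
  expect_equal(b$summary$n_sites, 0L)
})

test_that("catalog sites inside passing blocks each add one hom-ref record", {
  g <- parse_gvcf(gvcf_fixture_lines(block_line(1, 1000)))
  sites <- do.call(rbind, lapply(c(100, 300, 500), function(p) {
    site_row("chr1", p, "A", rsid = paste0("rs", p))
  }))
  class(sites) <- c("site_records", "data.frame")
  b <- build_evcf(g, sites)
  expect_equal(nrow(b$records), 3)
  expect_true(all(b$records$gt == "0/0"))
  expect_true(all(b$records$call_class == "HOM_REF"))
  expect_equal(b$summary$n_hom_ref, 3L)
})

test_that("a catalog REF conflicting with the caller yields a flagged no-call", {
  g <- parse_gvcf(gvcf_fixture_lines(
    "chr1\t100\t.\tA\tG\t99\tPASS\t.\tGT\t0/1"))
  b <- build_evcf(g, site_row("chr1", 100, "C", alt = "T"))
  expect_equal(b$calls$call_class, "NO_CALL")
  expect_true(b$calls$conflict)
  expect_equal(b$summary$n_conflicts, 1L)
  site_rec <- b$records[is.na(b$records$alt), ]
  expect_equal(site_rec$gt, "./.")
  expect_true(site_rec$conflict)
})

test_that("call summary conservation holds across random runs", {
  nocall_levels <- c(0, 0.1, 0.2, 0.3, 0.4)
  for (seed in 1:5) {
    cfg <- sim_config(genome_length = 15000, n_sites = 120,
                      nocall_fraction = nocall_levels[seed], seed = seed)
    tr <- simulate_truth(cfg)
    b <- build_evcf(emit_gvcf(tr), tr$sites)
    s <- b$summary
    expect_equal(s$n_sites,
                 s$n_hom_ref + s$n_het + s$n_hom_alt + s$n_het_alt + s$n_no_call)
    expect_equal(s$n_sites, nrow(tr$sites))
    # record count = variant passthrough + catalog sites not on variant records
    n_site_records <- sum(b$calls$source != "VARIANT_RECORD")
    expect_equal(nrow(b$records),
                 s$n_variant_records_passthrough + n_site_records)
    # and with no-call records suppressed
    b2 <- build_evcf(emit_gvcf(tr), tr$sites, emit_nocalls = FALSE)
    expect_equal(nrow(b2$records),
                 b2$summary$n_variant_records_passthrough +
                   sum(b2$calls$source == "BLOCK"))
  }
})

test_that("gVCF genotyping is a superset of the variant-only view", {
  for (nf in c(0, 0.2)) {
    cfg <- sim_config(genome_length = 20000, n_sites = 150,
                      nocall_fraction = nf, seed = 31)
    tr <- simulate_truth(cfg)
    g <- emit_gvcf(tr)
    full <- resolve_genotypes(tr$sites, g)
    vcf_view <- g[g$kind == "VARIANT", ]
    varonly <- resolve_genotypes(tr$sites, vcf_view)
    called_full <- full$pos[full$call_class != "NO_CALL"]
    called_var <- varonly$pos[varonly$call_class != "NO_CALL"]
    expect_true(all(called_var %in% called_full))
    if (nf == 0) {
      expect_equal(length(called_full), nrow(tr$sites))
      expect_setequal(called_var, tr$sites$pos[tr$genotypes != "HOM_REF"])
    }
  }
})
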