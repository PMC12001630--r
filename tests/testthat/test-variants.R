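# The 12-record fixture exercises every filter branch: each site-level
# annotation at its boundary, the lenient total-depth boundary, and the
# stringent AD / allele-ratio boundaries. Expected survivor sets are
# hand-enumerated.
branch_fixture <- function() {
  ad_std <- rbind(c(5, 5), c(5, 5), c(5, 5)) # DP_total 30, alt 15
  dplyr::bind_rows(
    make_variant(pos = 101, qd = 25, fs = 5, mqrs = 0, rprs = 0, sor = 2, ad = ad_std), # 1 pass
    make_variant(pos = 102, qd = 19.9, fs = 5, mqrs = 0, rprs = 0, sor = 2, ad = ad_std), # 2 QD fail
    make_variant(pos = 103, qd = 20.0, fs = 5, mqrs = 0, rprs = 0, sor = 2, ad = ad_std), # 3 QD boundary pass
    make_variant(pos = 104, qd = 25, fs = 20.1, mqrs = 0, rprs = 0, sor = 2, ad = ad_std), # 4 FS fail
    make_variant(pos = 105, qd = 25, fs = 5, mqrs = -12.6, rprs = 0, sor = 2, ad = ad_std), # 5 MQRS fail
    make_variant(pos = 106, qd = 25, fs = 5, mqrs = 0, rprs = -8.1, sor = 2, ad = ad_std), # 6 RPRS fail
    make_variant(pos = 107, qd = 25, fs = 5, mqrs = 0, rprs = 0, sor = 5.1, ad = ad_std), # 7 SOR fail
    make_variant(pos = 108, ad = ad_std), # 8 unannotated
    make_variant(pos = 109, qd = 25, ad = rbind(c(8, 1), c(0, 0), c(0, 0))), # 9 DP_total 9
    make_variant(pos = 110, qd = 25, ad = rbind(c(9, 1), c(0, 0), c(0, 0))), # 10 DP_total 10, AR 0.1 at DP 10
    make_variant(pos = 111, qd = 25, ad = rbind(c(10, 2), c(10, 0), c(10, 0))), # 11 AD 2
    make_variant(pos = 112, qd = 25, ad = rbind(c(10, 1), c(5, 0), c(5, 0))) # 12 AR 0.091 at DP 11
  )
}

test_that("site hard filter applies each threshold at its boundary", {
  v <- site_hard_filter(branch_fixture())
  expect_equal(which(v$pass), c(1, 3, 8, 9, 10, 11, 12))
  expect_equal(v$failed_filters[2], "QD")
  expect_equal(v$failed_filters[4], "FS")
  expect_equal(v$failed_filters[5], "MQRankSum")
  expect_equal(v$failed_filters[6], "ReadPosRankSum")
  expect_equal(v$failed_filters[7], "SOR")
  expect_true(v$unannotated[8])
  expect_false(any(v$unannotated[-8]))
})

test_that("lenient and stringent criteria match hand enumeration", {
  v <- branch_fixture()
  len <- filter_lenient(v)
  expect_equal(len$pos, c(101:108, 110:112))
  expect_equal(len$dp_total[len$pos == 110], 10)

  str_ <- filter_stringent(v)
  expect_equal(str_$pos, c(101:108, 111))
  expect_true(all(lengths(str_$kept_alts) == 1))

  # recalculated-depth boundary: 5 kept, 4 dropped
  at5 <- make_variant(ad = rbind(c(3, 2)))
  at4 <- make_variant(ad = rbind(c(2, 2)))
  expect_equal(nrow(filter_stringent(at5)), 1)
  expect_equal(nrow(filter_stringent(at4)), 0)

  # allele-ratio branch kept at AR 0.1 with DP 20
  ar_ok <- make_variant(ad = rbind(c(18, 2)))
  expect_equal(nrow(filter_stringent(ar_ok)), 1)

  # DP = 0 with nonzero AD: AR undefined, AD branch still applies
  weird <- make_variant(ad = rbind(c(0, 3)), dp = 0)
  expect_equal(nrow(filter_stringent(weird, dp_total_recalc_min = 3)), 1)

  # dp_sum recalc strategy switch
  expect_equal(nrow(filter_stringent(at5, recalc = "dp_sum")), 1)
})

test_that("multiallelic records are filtered per allele", {
  m <- cbind(ref = c(10L, 10L), alt1 = c(3L, 0L), alt2 = c(1L, 0L))
  v <- tibble::tibble(
    chrom = "1", pos = 500L, ref = "A", alt = list(c("T", "G")),
    qd = 30, fs = 1, mq_rank_sum = 0, read_pos_rank_sum = 0, sor = 1,
    ad = list(m), dp = list(as.integer(rowSums(m)))
  )
  out <- filter_stringent(v)
  expect_equal(out$kept_alts[[1]], 1L) # only the first alt is supported
})

test_that("the 12-record fixture survives a VCF round trip unchanged", {
  v <- branch_fixture()
  f <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(v, f)
  v2 <- read_vcf(f)
  expect_equal(v2$pos, v$pos)
  expect_equal(v2$qd, v$qd, tolerance = 1e-3)
  expect_true(all(is.na(v2$fs[8:12]) == is.na(v$fs[8:12])))
  expect_equal(filter_lenient(v2)$pos, filter_lenient(v)$pos)
  expect_equal(filter_stringent(v2)$pos, filter_stringent(v)$pos)
  expect_equal(which(site_hard_filter(v2)$pass), which(site_hard_filter(v)$pass))
})

test_that("stringent survivors are a subset of lenient survivors on random fixtures", {
  genes <- simulate_gene_models(n_genes = 20, seed = 1)
  for (s in 1:20) {
    v <- simulate_variant_records(n_variants = 40, genes = genes, seed = s)
    str_keys <- filter_stringent(v)$pos
    len_keys <- filter_lenient(v)$pos
    expect_true(all(str_keys %in% len_keys))
  }
})

test_that("intragenic classification uses inclusive 1-based intervals", {
  genes <- tibble::tibble(
    gene_id = c("gA", "gB", "gBnested"),
    chrom = c("1", "1", "1"),
    start = c(100L, 500L, 520L),
    end = c(200L, 600L, 560L),
    strand = c("+", "-", "+")
  )
  v <- dplyr::bind_rows(
    make_variant(pos = 100, ad = rbind(c(5, 5))), # gene start
    make_variant(pos = 201, ad = rbind(c(5, 5))), # end + 1
    make_variant(pos = 550, ad = rbind(c(5, 5))), # nested overlap
    make_variant(chrom = "2", pos = 150, ad = rbind(c(5, 5))) # wrong chrom
  )
  cls <- classify_intragenic(v, genes)
  expect_equal(cls$intragenic, c(TRUE, FALSE, TRUE, FALSE))
  expect_setequal(cls$gene_ids[[3]], c("gB", "gBnested"))
})

test_that("relative positions are strand-aware with 3' at r = 1", {
  expect_equal(relative_position(200, 100, 200, "+"), 1)
  expect_equal(relative_position(100, 100, 200, "-"), 1)
  expect_equal(relative_position(150, 100, 200, "+"), 0.5)
  expect_equal(relative_position(150, 100, 200, "-"), 0.5)
  expect_equal(relative_position(42, 42, 42, "+"), 0) # single-base gene
  expect_error(relative_position(99, 100, 200, "+"), class = "satseq_contract_error")
})

test_that("position histogram bins and conserves counts", {
  h <- position_histogram(rep(1, 7), n_bins = 10)
  expect_equal(h$count[10], 7L)
  expect_equal(sum(h$count), 7)
  expect_equal(sum(position_histogram(numeric(0), 5)$count), 0)
  expect_error(position_histogram(c(0.5, 1.2)), class = "satseq_contract_error")

  withr::with_seed(5, {
    u <- runif(10000)
    h <- position_histogram(u, n_bins = 10)
    se <- sqrt(10000 * 0.1 * 0.9)
    expect_true(all(abs(h$count - 1000) < 3 * se))
  })
})

test_that("strand reflection leaves the relative-position histogram invariant", {
  # non-overlapping genes so each variant reflects within a unique gene
  genes <- tibble::tibble(
    gene_id = sprintf("g%02d", 1:30),
    chrom = "1",
    start = as.integer((0:29) * 10000 + 1),
    end = as.integer((0:29) * 10000 + 5000),
    strand = rep(c("+", "-"), 15)
  )
  v <- simulate_variant_records(n_variants = 300, genes = genes, seed = 8)
  r1 <- relative_positions(v, genes)

  mirrored <- genes
  mirrored$strand <- ifelse(genes$strand == "+", "-", "+")
  v2 <- v
  # reflect each intragenic position within its (single) gene
  cls <- classify_intragenic(v, genes)
  for (i in which(cls$intragenic)) {
    g <- genes[match(cls$gene_ids[[i]][1], genes$gene_id), ]
    v2$pos[i] <- as.integer(g$start + g$end - v$pos[i])
  }
  r2 <- relative_positions(v2, mirrored)
  # same gene set, mirrored positions under mirrored strands: identical histogram
  h1 <- position_histogram(r1$rel_pos, 10)
  h2 <- position_histogram(r2$rel_pos, 10)
  expect_equal(h1$count, h2$count)
})

test_that("known-site overlap counts and fractions", {
  genes <- simulate_gene_models(n_genes = 5, seed = 2)
  v <- simulate_variant_records(n_variants = 6, genes = genes, indel_fraction = 0, seed = 3)
  known_all <- tibble::tibble(
    chrom = v$chrom, pos = v$pos, ref = v$ref,
    alt = vapply(v$alt, `[`, character(1), 1)
  )
  ov <- known_site_overlap(v, known_all)
  expect_equal(ov$summary$fraction_known, 1)

  disjoint <- dplyr::mutate(known_all, pos = pos + 1L)
  expect_equal(known_site_overlap(v, disjoint)$summary$fraction_known, 0)

  four <- dplyr::bind_rows(known_all[1:4, ], dplyr::mutate(known_all[5:6, ], alt = "N"))
  ov4 <- known_site_overlap(v, four)
  expect_equal(ov4$summary$n_known, 4)
  expect_equal(ov4$summary$n_known + ov4$summary$n_novel, nrow(v))
  expect_equal(ov4$summary$fraction_known, 4 / 6)
  # position-only matching ignores the mismatched alleles
  expect_equal(known_site_overlap(v, four, match = "position")$summary$n_known, 6)
})

test_that("SNP/INDEL classification follows allele lengths", {
  v <- dplyr::bind_rows(
    make_variant(ref = "A", alt = "T", ad = rbind(c(5, 5))),
    make_variant(ref = "AT", alt = "A", ad = rbind(c(5, 5))),
    make_variant(ref = "A", alt = "ATT", ad = rbind(c(5, 5)))
  )
  expect_equal(variant_type(v)$type, c("SNP", "INDEL", "INDEL"))
})
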