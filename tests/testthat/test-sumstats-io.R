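test_that("marker tokens parse into variant keys with the right build", {
  vk <- parse_marker_id("13_25200000_A_G_b37")
  expect_s3_class(vk, "variant_key")
  expect_equal(vk$chrom, "13")
  expect_equal(vk$pos, 25200000L)
  expect_equal(vk$ref, "A")
  expect_equal(vk$alt, "G")
  expect_equal(vk$build, "hg19")
  expect_equal(parse_marker_id("1_500_C_T_b38")$build, "hg38")
  expect_equal(parse_marker_id("chrX_100_AT_A_b37")$chrom, "X")
  expect_s3_class(parse_marker_id("rs7512462"), "unresolved_rsid")
  expect_error(parse_marker_id("13_25200000"), class = "sscoloc_parse_error")
  expect_error(parse_marker_id("13_100_A_A_b37"), class = "sscoloc_parse_error")
})

test_that("marker-column files parse, clamp p = 0 and drop bad rows with accounting", {
  path <- write_tsv(data.frame(
    markerid = c("13_25200000_A_G_b37", "13_25201000_C_T_b37",
                 "13_25202000_G_A_b37", "13_25203000_T_C_b37", "not_a_marker"),
    pval = c(0.5, 1.5, 0, 1e-8, 0.2)))
  suppressMessages(
    ds <- parse_summary_stats(path, column_map = list(marker = "markerid", p = "pval")))
  expect_s3_class(ds, "sumstat_dataset")
  expect_equal(attr(ds, "build"), "hg19")
  expect_equal(nrow(ds), 3L)                      # p=1.5 and bad marker dropped
  expect_equal(ds$p[ds$pos == 25202000], 1e-300)  # p=0 clamped
  # every dropped row is accounted for
  expect_equal(attr(ds, "n_input"), nrow(ds) + attr(ds, "n_dropped"))
})

test_that("duplicate variants keep the smallest p-value", {
  path <- write_tsv(data.frame(
    CHROM = "13", POS = c(100, 100, 200), REF = "A", ALT = "G",
    P = c(0.5, 0.01, 0.3)))
  suppressMessages(ds <- parse_summary_stats(path))
  expect_equal(nrow(ds), 2L)
  expect_equal(ds$p[ds$pos == 100], 0.01)
  expect_equal(attr(ds, "n_duplicates"), 1L)
})

test_that("missing mapped column and zero valid rows raise distinct errors", {
  path <- write_tsv(data.frame(CHROM = "13", POS = 1, REF = "A", ALT = "G", P = 0.5))
  expect_error(parse_summary_stats(path, column_map = list(p = "PVALUE")),
               class = "sscoloc_config_error")
  bad <- write_tsv(data.frame(CHROM = "13", POS = 1, REF = "A", ALT = "G", P = 2))
  expect_error(suppressMessages(parse_summary_stats(bad)),
               class = "sscoloc_input_error")
})

test_that("rsID markers resolve through the lookup table", {
  lk <- write_tsv(data.frame(rsid = "rs42", chrom = "13", pos = 777,
                             ref = "A", alt = "C"))
  path <- write_tsv(data.frame(marker = c("rs42", "rs99"), P = c(0.1, 0.2)))
  suppressMessages(
    ds <- parse_summary_stats(path, column_map = list(marker = "marker"),
                              rsid_lookup = read_rsid_lookup(lk)))
  expect_equal(nrow(ds), 1L)  # rs99 unresolved, dropped
  expect_equal(ds$pos, 777L)
  expect_equal(ds$ref, "A")
})

test_that("datasets round-trip through write and re-parse", {
  ds <- make_ds(pos = c(100, 200, 300), p = c(0.5, 1e-12, 0.999),
                ref = c("A", "C", "G"), alt = c("G", "T", "A"))
  path <- tempfile(fileext = ".tsv")
  write_summary_stats(ds, path)
  ds2 <- parse_summary_stats(path)
  expect_equal(ds2$pos, ds$pos)
  expect_equal(ds2$ref, ds$ref)
  expect_equal(ds2$p, ds$p, tolerance = 1e-15)
})

test_that("region validation enforces ordering and the 2 Mbp cap inclusively", {
  r <- validate_region(13, 25200000, 25350000)
  expect_equal(r$span, 150001L)
  expect_silent(validate_region("1", 1, 2000000))          # exactly 2 Mbp
  expect_error(validate_region("1", 1, 2000001), class = "sscoloc_region_error")
  expect_error(validate_region("1", 10, 5), class = "sscoloc_region_error")
  expect_error(validate_region("banana", 1, 10), class = "sscoloc_region_error")
})

test_that("harmonization intersects all three sources and matches swapped alleles", {
  primary <- make_ds(pos = c(1, 2, 3), p = c(0.1, 0.2, 0.3))
  secondary <- make_ds(pos = c(2, 3, 4), p = c(0.5, 0.6, 0.7))
  # LD panel holds positions 1-4; position 2 listed with swapped alleles
  ld_snps <- data.frame(chrom = "13", pos = 1:4,
                        ref = c("A", "G", "A", "A"),
                        alt = c("G", "A", "G", "G"), stringsAsFactors = FALSE)
  ld <- ld_matrix(ld_snps, diag(4), signed = TRUE, build = "hg19")
  h <- harmonize_datasets(primary, secondary, ld)
  expect_equal(h$variants$pos, c(2L, 3L))
  expect_equal(h$secondary_idx, c(1L, 2L))
  expect_equal(h$ld_idx, c(2L, 3L))

  # swapped secondary alleles still match
  sec_sw <- make_ds(pos = c(2, 3), p = c(0.5, 0.6), ref = "G", alt = "A")
  h2 <- harmonize_datasets(primary, sec_sw, ld)
  expect_equal(h2$variants$pos, c(2L, 3L))

  disjoint <- make_ds(pos = c(50, 60), p = c(0.5, 0.6))
  expect_error(harmonize_datasets(primary, disjoint, ld),
               class = "sscoloc_no_overlap_error")
})

test_that("harmonization is insensitive to input row order", {
  set.seed(3)
  primary <- make_ds(pos = 1:20, p = runif(20))
  secondary <- make_ds(pos = 5:25, p = runif(21))
  ld <- make_ld(make_ds(pos = 1:25, p = runif(25)))
  h1 <- harmonize_datasets(primary, secondary, ld)
  perm <- sample(nrow(secondary))
  sec_perm <- secondary[perm, , drop = FALSE]
  attr(sec_perm, "build") <- "hg19"
  h2 <- harmonize_datasets(primary, sec_perm, ld)
  expect_setequal(h1$variants$pos, h2$variants$pos)
  expect_equal(secondary$p[h1$secondary_idx], sec_perm$p[h2$secondary_idx])
})
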