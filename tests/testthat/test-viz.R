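test_that("LD colour bins follow the LocusZoom partition with a closed top bin", {
  expect_equal(as.character(bin_ld_colors(0.85)), "ge0.8")
  expect_equal(as.character(bin_ld_colors(0.8)), "ge0.8")
  expect_equal(as.character(bin_ld_colors(0.7999)), "0.6to0.8")
  expect_equal(as.character(bin_ld_colors(1)), "ge0.8")
  expect_equal(as.character(bin_ld_colors(0)), "lt0.2")
  expect_equal(as.character(bin_ld_colors(NA)), "missing")
  expect_equal(as.character(bin_ld_colors(0.99, is_lead = TRUE)), "lead")
  expect_error(bin_ld_colors(1.2), class = "sscoloc_domain_error")
  expect_error(bin_ld_colors(-0.1), class = "sscoloc_domain_error")
})

test_that("every r-squared value maps to exactly one bin", {
  r2 <- seq(0, 1, by = 0.0001)
  bins <- bin_ld_colors(r2)
  expect_false(anyNA(bins))
  expect_true(all(table(bins)[c("lead", "missing")] == 0))
  # boundaries land in the upper bin (half-open [lo, hi))
  expect_equal(as.character(bin_ld_colors(c(0.2, 0.4, 0.6))),
               c("0.2to0.4", "0.4to0.6", "0.6to0.8"))
})

test_that("window width follows (region size / 1e6) x factor", {
  reg <- validate_region("13", 25200000, 25350000)
  tr <- window_min_trace(c(25200000, 25200023), c(0.5, 0.2), reg)
  # 150-kbp region -> 22.5-bp windows; the two SNPs land in windows 0 and 1
  expect_equal(tr$window_index, c(0L, 1L))
  expect_equal(diff(tr$window_start), 22.5)

  reg1m <- validate_region("1", 1, 1000001)
  tr1 <- window_min_trace(c(1, 151), c(0.5, 0.2), reg1m)
  expect_equal(diff(tr1$window_start), 150)

  # minimum p within a shared window
  tr2 <- window_min_trace(c(25200001, 25200005, 25200010),
                          c(0.5, 0.01, 0.2), reg)
  expect_equal(nrow(tr2), 1L)
  expect_equal(tr2$min_p, 0.01)

  expect_error(window_min_trace(25200000, 0.5, validate_region("13", 5, 5)),
               class = "sscoloc_region_error")
})

test_that("windows tile the region without overlap and cover all positions", {
  set.seed(31)
  reg <- validate_region("13", 25200000, 25350000)
  pos <- sample(reg$start:reg$end, 400)
  p <- stats::runif(400)
  tr <- window_min_trace(pos, p, reg)
  w <- (reg$end - reg$start) / 1e6 * 150
  idx <- floor((pos - reg$start) * 1e6 / ((reg$end - reg$start) * 150))
  # each position belongs to exactly one window, and that window is reported
  expect_true(all(idx %in% tr$window_index))
  expect_false(any(duplicated(tr$window_index)))
  # reported minima are true minima per window
  for (k in seq_len(nrow(tr))) {
    expect_equal(tr$min_p[k], min(p[idx == tr$window_index[k]]))
  }
  # window starts are consistent with the exact-width grid
  expect_equal(tr$window_start, reg$start + tr$window_index * w, tolerance = 1e-9)
})

write_toy_gtf <- function(lines) {
  f <- tempfile(fileext = ".gtf")
  writeLines(lines, f)
  f
}

gtf_line <- function(type, start, end, gene, tx = NULL) {
  attrs <- sprintf('gene_id "%s"; gene_name "%s";', gene, gene)
  if (!is.null(tx)) {
    attrs <- sprintf('gene_id "%s"; transcript_id "%s"; gene_name "%s";',
                     gene, tx, gene)
  }
  sprintf("1\ttoy\t%s\t%d\t%d\t.\t+\t.\t%s", type, start, end, attrs)
}

test_that("transcript isoforms collapse into single gene models", {
  f <- write_toy_gtf(c(
    gtf_line("gene", 100, 500, "GA"),
    gtf_line("exon", 100, 200, "GA", "GA.1"),
    gtf_line("exon", 150, 300, "GA", "GA.2"),   # overlapping -> merged
    gtf_line("exon", 400, 500, "GA", "GA.2"),   # disjoint -> retained
    gtf_line("gene", 9000, 9500, "GB"),         # fully outside the region
    gtf_line("exon", 9000, 9500, "GB", "GB.1")))
  reg <- validate_region("1", 50, 1000)
  models <- collapse_gene_models(f, reg)
  expect_length(models, 1L)
  expect_equal(models[[1]]$gene_id, "GA")
  expect_equal(models[[1]]$exons$start, c(100, 400))
  expect_equal(models[[1]]$exons$end, c(300, 500))
  # collapsed intervals are disjoint and no longer than the transcript sum
  ex <- models[[1]]$exons
  expect_true(all(ex$start[-1] > ex$end[-nrow(ex)]))
  expect_lte(sum(ex$end - ex$start + 1), (200 - 100 + 1) + (300 - 150 + 1) + (500 - 400 + 1))
})

test_that("malformed GTF lines are rejected with their line number", {
  f <- write_toy_gtf(c(gtf_line("gene", 1, 10, "G"), "broken line"))
  expect_error(collapse_gene_models(f, validate_region("1", 1, 100)),
               regexp = "line 2", class = "sscoloc_parse_error")
})

test_that("the plot payload is complete and round-trips through JSON", {
  cfg <- scenario_config("C", seed = 8)
  sim <- simulate_summary_stats(cfg, with_genotypes = FALSE)
  lead <- select_lead_snp(sim$primary, sim$ld$snps)
  ssr <- default_ss_region(lead, sim$region)
  lead_idx <- which(sim$primary$pos == lead$pos)
  r2 <- sim$ld$r[, lead_idx]^2
  bins <- bin_ld_colors(r2, is_lead = seq_len(nrow(sim$primary)) == lead_idx)
  traces <- lapply(sim$collection$entries, function(e)
    window_min_trace(e$pos, e$p, sim$region))
  mat <- compute_coloc_matrix(sim$primary, sim$collection, sim$ld, ssr)
  payload <- build_plot_payload(sim$primary, traces, bins, list(), mat,
                                ss_region = ssr, region = sim$region)
  # every GWAS point carries exactly one LD bin
  expect_equal(length(payload$gwas$ld_bin), nrow(sim$primary))
  expect_false(anyNA(payload$gwas$ld_bin))
  expect_equal(sum(payload$gwas$ld_bin == "lead"), 1L)
  # payload's gray-shading interval equals the computed SS region
  expect_equal(payload$ss_region$start, ssr$start)
  expect_equal(payload$ss_region$end, ssr$end)

  f <- tempfile(fileext = ".json")
  write_plot_payload(payload, f)
  back <- read_plot_payload(f)
  expect_equal(back$region$start, sim$region$start)
  expect_equal(back$gwas$neglog10_p, payload$gwas$neglog10_p, tolerance = 1e-12)
  expect_equal(back$heatmap$values, unname(mat$values), tolerance = 1e-12)
})
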