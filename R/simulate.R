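# Synthetic colocalization loci: LD, summary statistics and genotypes under
# named scenarios. The generator is the single source of truth for the
# statistical calibration checks (type-I error, power) of the Simple Sum
# test.
#
# Scenarios:
#   A  null           no signal in either dataset
#   B  eQTL-only      secondary signal at a causal SNP, GWAS null
#   C  colocalized    one shared causal SNP drives both mean vectors
#   D  independent    distinct causal SNPs for GWAS and eQTL
#
# Mean z-score vectors follow the single-causal-variant pattern under LD,
# mu = effect * R[, causal], i.e. the causal SNP carries the full effect and
# correlated SNPs inherit it proportionally to r.

#' Scenario configuration for the synthetic-locus generator
#'
#' @param scenario One of "A" (null), "B" (eQTL-only), "C" (colocalized),
#'   "D" (independent signals).
#' @param n_snps Number of SNPs (>= 2; default 50).
#' @param n_samples Reference-panel samples for genotype realization
#'   (default 1000).
#' @param rho AR(1) LD parameter in [0, 1) (default 0.8), or within-block
#'   correlation for `ld_model = "block"`.
#' @param effect_size Causal-SNP mean z-score (default 6, a strong
#'   molecular-QTL association).
#' @param maf Minor-allele frequency used for all SNPs (default 0.3).
#' @param seed Explicit RNG seed (required).
#' @param ld_model "ar1" (r_jk = rho^|j-k|) or "block" (block-diagonal).
#' @param block_size Block width for the block LD model.
#' @param chrom,start,spacing Genomic placement of the SNP ladder (defaults:
#'   chr13 from 25,200,000 every 3 kbp, a 150-kbp locus at 50 SNPs).
#' @param build Build tag.
#' @param genes,datasets Labels for the secondary collection entries; every
#'   gene x dataset pair receives one entry.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(scenario = c("A", "B", "C", "D"), n_snps = 50L,
                            n_samples = 1000L, rho = 0.8, effect_size = 6,
                            maf = 0.3, seed, ld_model = c("ar1", "block"),
                            block_size = 10L, chrom = "13", start = 25200000L,
                            spacing = 3000L, build = "hg19",
                            genes = "GENE1", datasets = "TISSUE1") {
  scenario <- match.arg(scenario)
  ld_model <- match.arg(ld_model)
  if (missing(seed) || !is_count(seed)) {
    ss_stop("an explicit integer seed is required", "sscoloc_config_error")
  }
  if (!is_count(n_snps) || n_snps < 2) {
    ss_stop("n_snps must be an integer >= 2", "sscoloc_config_error")
  }
  if (rho < 0 || rho >= 1) {
    ss_stop("rho must lie in [0, 1)", "sscoloc_config_error")
  }
  if (maf <= 0 || maf >= 0.5) {
    ss_stop("maf must lie in (0, 0.5)", "sscoloc_config_error")
  }
  structure(list(scenario = scenario, n_snps = as.integer(n_snps),
                 n_samples = as.integer(n_samples), rho = rho,
                 effect_size = effect_size, maf = maf, seed = as.integer(seed),
                 ld_model = ld_model, block_size = as.integer(block_size),
                 chrom = normalize_chrom(chrom), start = as.integer(start),
                 spacing = as.integer(spacing), build = build,
                 genes = genes, datasets = datasets),
            class = "scenario_config")
}

ld_correlation <- function(config) {
  n <- config$n_snps
  if (config$ld_model == "ar1") {
    r <- config$rho^abs(outer(seq_len(n), seq_len(n), "-"))
  } else {
    blk <- (seq_len(n) - 1L) %/% config$block_size
    r <- ifelse(outer(blk, blk, "=="), config$rho, 0)
    diag(r) <- 1
  }
  r
}

make_variants <- function(config) {
  n <- config$n_snps
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), "")
  data.frame(chrom = config$chrom,
             pos = config$start + (seq_len(n) - 1L) * config$spacing,
             ref = ref, alt = unname(alt), stringsAsFactors = FALSE)
}

#' Simulate an LD matrix under the configured model
#'
#' @param config A `scenario_config`.
#' @return An `ld_matrix` (signed, positive semi-definite).
#' @export
simulate_ld_matrix <- function(config) {
  set.seed(config$seed)
  r <- ld_correlation(config)
  lam <- eigen(r, symmetric = TRUE, only.values = TRUE)$values
  if (min(lam) < -1e-10) {
    ss_stop("simulated LD matrix is not positive semi-definite", "sscoloc_internal_error")
  }
  ld_matrix(make_variants(config), r, signed = TRUE, build = config$build)
}

#' Simulate a full synthetic locus
#'
#' Draws z-scores as N(mu, R) per dataset with the scenario-specific mean
#' vectors, converts them to two-sided normal-tail p-values, and (optionally)
#' realizes a genotype reference panel consistent with R by thresholding
#' latent Gaussian haplotypes at the Hardy-Weinberg quantile of the
#' configured MAF (Gaussian copula). The same seed always yields
#' bit-identical output.
#'
#' @param config A `scenario_config`.
#' @param with_genotypes Set `FALSE` to skip the genotype panel (faster;
#'   used by replicated calibration runs).
#' @return A `locus_sim` list: `config`, `region`, `primary`
#'   (`sumstat_dataset`), `collection` (`secondary_collection`), `ld`
#'   (`ld_matrix`), `genotypes` (`genotype_block` or NULL) and `causal`
#'   (causal indices used).
#' @export
simulate_summary_stats <- function(config, with_genotypes = TRUE) {
  set.seed(config$seed)
  n <- config$n_snps
  R <- ld_correlation(config)
  variants <- make_variants(config)
  L <- t(chol(R + diag(1e-10, n)))

  causal_e <- sample.int(n, 1L)
  causal_g <- switch(config$scenario,
                     A = NA_integer_, B = NA_integer_, C = causal_e,
                     D = sample(setdiff(seq_len(n), causal_e), 1L))
  eff <- config$effect_size
  mu_e <- switch(config$scenario, A = rep(0, n), B = eff * R[, causal_e],
                 C = eff * R[, causal_e], D = eff * R[, causal_e])
  mu_g <- if (is.na(causal_g)) rep(0, n) else eff * R[, causal_g]

  draw <- function(mu) {
    z <- mu + as.numeric(L %*% stats::rnorm(n))
    p <- 2 * stats::pnorm(-abs(z))
    p[p == 0] <- 1e-300
    p
  }
  primary <- structure(
    data.frame(variants, p = draw(mu_g), stringsAsFactors = FALSE),
    class = c("sumstat_dataset", "data.frame"),
    label = "GWAS", build = config$build,
    n_input = n, n_dropped = 0L, n_duplicates = 0L)

  entries <- list()
  for (g in config$genes) {
    for (d in config$datasets) {
      k <- paste(g, d, sep = "|")
      entries[[k]] <- structure(
        data.frame(variants, p = draw(mu_e), stringsAsFactors = FALSE),
        class = c("sumstat_dataset", "data.frame"),
        label = k, build = config$build,
        n_input = n, n_dropped = 0L, n_duplicates = 0L)
    }
  }

  genotypes <- NULL
  if (with_genotypes) {
    thr <- stats::qnorm(config$maf)
    hap <- function() {
      lat <- L %*% matrix(stats::rnorm(n * config$n_samples), n)
      lat < thr
    }
    dos <- hap() + hap()  # two haplotypes per sample
    genotypes <- structure(list(samples = config$n_samples, snps = variants,
                                dosages = unname(dos * 1.0)),
                           class = "genotype_block", build = config$build)
  }
  region <- validate_region(config$chrom, config$start,
                            config$start + (n - 1L) * config$spacing)
  structure(list(config = config, region = region, primary = primary,
                 collection = secondary_collection(entries, build = config$build),
                 ld = ld_matrix(variants, R, signed = TRUE, build = config$build),
                 genotypes = genotypes,
                 causal = list(gwas = causal_g, eqtl = causal_e)),
            class = "locus_sim")
}

#' Write a simulated locus as the standard file formats
#'
#' Emits exactly what the I/O modules consume: primary TSV, long-format
#' secondary TSV, a PLINK-style square `.ld` matrix (r-squared), a VCF of
#' the genotype panel, and a toy GTF with two genes (two transcripts each)
#' spanning the locus. All files are mutually consistent.
#'
#' @param bundle A `locus_sim` from [simulate_summary_stats()] (with
#'   genotypes when a VCF is wanted).
#' @param dir Output directory (created if needed).
#' @return Named list of file paths.
#' @export
write_fixture_files <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(primary = file.path(dir, "primary.tsv"),
                secondary = file.path(dir, "secondary.tsv"),
                ld = file.path(dir, "panel.ld"),
                vcf = file.path(dir, "panel.vcf"),
                gtf = file.path(dir, "genes.gtf"))
  write_summary_stats(bundle$primary, paths$primary)

  long <- do.call(rbind, lapply(names(bundle$collection$entries), function(k) {
    parts <- strsplit(k, "|", fixed = TRUE)[[1]]
    e <- bundle$collection$entries[[k]]
    data.frame(gene = parts[1], dataset = parts[2],
               CHROM = e$chrom, POS = e$pos, REF = e$ref, ALT = e$alt,
               P = e$p, stringsAsFactors = FALSE)
  }))
  utils::write.table(format(long, digits = 17, trim = TRUE, scientific = FALSE),
                     paths$secondary, sep = "\t", quote = FALSE, row.names = FALSE)

  write_plink_ld(bundle$ld, paths$ld, what = "r2")
  write_fixture_vcf(bundle, paths$vcf)
  write_fixture_gtf(bundle, paths$gtf)
  paths
}

write_fixture_vcf <- function(bundle, path) {
  gb <- bundle$genotypes
  if (is.null(gb)) {
    ss_stop("bundle has no genotypes; rerun simulate_summary_stats(with_genotypes = TRUE)",
            "sscoloc_config_error")
  }
  snps <- gb$snps
  gt <- matrix(c("0/0", "0/1", "1/1")[gb$dosages + 1L], nrow = nrow(snps))
  gt[is.na(gb$dosages)] <- "./."
  header <- c("##fileformat=VCFv4.2",
              sprintf("##contig=<ID=%s>", unique(snps$chrom)),
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT",
                      sprintf("S%04d", seq_len(gb$samples))), collapse = "\t"))
  body <- vapply(seq_len(nrow(snps)), function(i) {
    paste(c(snps$chrom[i], snps$pos[i],
            variant_id(snps$chrom[i], snps$pos[i], snps$ref[i], snps$alt[i]),
            snps$ref[i], snps$alt[i], ".", "PASS", ".", "GT", gt[i, ]),
          collapse = "\t")
  }, "")
  writeLines(c(header, body), path)
  invisible(path)
}

write_fixture_gtf <- function(bundle, path) {
  reg <- bundle$region
  mid <- (reg$start + reg$end) %/% 2L
  gene <- function(id, name, g_start, g_end, strand) {
    # two transcripts with overlapping exon sets; collapses to 3 exons
    len <- g_end - g_start
    e <- list(t1 = rbind(c(g_start, g_start + len %/% 5),
                         c(g_start + 2 * len %/% 5, g_start + 3 * len %/% 5)),
              t2 = rbind(c(g_start + len %/% 10, g_start + len %/% 4),
                         c(g_start + 4 * len %/% 5, g_end)))
    lines <- sprintf(
      '%s\ttoy\tgene\t%d\t%d\t.\t%s\t.\tgene_id "%s"; gene_name "%s";',
      reg$chrom, g_start, g_end, strand, id, name)
    for (tx in names(e)) {
      tid <- paste0(id, ".", tx)
      lines <- c(lines, sprintf(
        '%s\ttoy\ttranscript\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s"; gene_name "%s";',
        reg$chrom, min(e[[tx]]), max(e[[tx]]), strand, id, tid, name))
      for (i in seq_len(nrow(e[[tx]]))) {
        lines <- c(lines, sprintf(
          '%s\ttoy\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s"; gene_name "%s";',
          reg$chrom, e[[tx]][i, 1], e[[tx]][i, 2], strand, id, tid, name))
      }
    }
    lines
  }
  writeLines(c(gene("TOY0001", "GENE1", reg$start, mid, "+"),
               gene("TOY0002", "GENE2", mid + 1000L, reg$end, "-")),
             path)
  invisible(path)
}

#' Empirical Simple Sum rejection rate under a scenario
#'
#' Replicates the full pipeline (simulate locus, harmonize, two-stage test)
#' and reports the fraction of OK results with SS p at or below `level`,
#' the quantity used for type-I error (scenario B) and power (scenario C)
#' assessment.
#'
#' @param scenario Scenario letter (see [scenario_config()]).
#' @param n_reps Number of replicate loci.
#' @param seed Base seed; replicate i uses `seed + i`.
#' @param level Rejection level on the SS p-value (default 0.05).
#' @param alpha,m Stage-1 gate parameters.
#' @param ... Passed to [scenario_config()].
#' @return List with `rate` (rejections / OK), `n_ok`, `n_reject` and the
#'   table of statuses.
#' @export
simulate_rejection_rate <- function(scenario, n_reps, seed, level = 0.05,
                                    alpha = 0.05, m = 1L, ...) {
  statuses <- character(n_reps)
  reject <- logical(n_reps)
  for (i in seq_len(n_reps)) {
    cfg <- scenario_config(scenario = scenario, seed = seed + i, ...)
    sim <- simulate_summary_stats(cfg, with_genotypes = FALSE)
    res <- run_simple_sum(sim$primary, sim$collection$entries[[1]], sim$ld,
                          sim$region, alpha = alpha, m = m)
    statuses[i] <- res$status
    reject[i] <- res$status == "OK" && res$ss_p <= level
  }
  n_ok <- sum(statuses == "OK")
  list(rate = if (n_ok > 0) sum(reject) / n_ok else NA_real_,
       n_ok = n_ok, n_reject = sum(reject), statuses = table(statuses))
}
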