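#' Construct an LD matrix object
#'
#' @param snps Data frame of variant keys (`chrom`, `pos`, `ref`, `alt`)
#'   ordered as the matrix rows.
#' @param r Square symmetric matrix of pairwise correlations.
#' @param signed `TRUE` when entries are signed correlations r; `FALSE` when
#'   they are nonnegative square roots of r-squared.
#' @param build Optional genome-build tag carried as metadata.
#' @return An object of class `ld_matrix`.
#' @export
ld_matrix <- function(snps, r, signed = TRUE, build = NA_character_) {
  r <- as.matrix(r)
  if (nrow(r) != ncol(r)) {
    ss_stop("LD matrix must be square", "sscoloc_format_error")
  }
  if (nrow(r) != nrow(snps)) {
    ss_stop(sprintf("LD matrix dimension (%d) does not match SNP list (%d)",
                    nrow(r), nrow(snps)), "sscoloc_alignment_error")
  }
  if (max(abs(r - t(r))) > 1e-6) {
    ss_stop("LD matrix is not symmetric", "sscoloc_format_error")
  }
  r <- (r + t(r)) / 2
  if (max(abs(r)) > 1 + 1e-8) {
    ss_stop("LD matrix entries must lie in [-1, 1]", "sscoloc_format_error")
  }
  r[r > 1] <- 1; r[r < -1] <- -1
  diag(r) <- 1
  dimnames(r) <- NULL
  structure(list(snps = as.data.frame(snps), r = r, signed = isTRUE(signed)),
            class = "ld_matrix", build = build)
}

#' Read a PLINK-style square LD matrix file
#'
#' Reads the whitespace-delimited, headerless square matrix written by
#' PLINK's `--r2 square` (or `--r square`). If every entry is in [0,1] with a
#' unit diagonal the file is interpreted as r-squared and the square roots
#' are stored (`signed = FALSE`, with a logged warning that signs are
#' unrecoverable); any negative entry switches interpretation to signed r.
#'
#' @param path Path to the `.ld` file.
#' @param snps Data frame of the variant keys the rows/columns correspond
#'   to, in file order.
#' @param build Optional build tag.
#' @return An `ld_matrix`.
#' @export
read_plink_ld <- function(path, snps, build = NA_character_) {
  if (!file.exists(path)) {
    ss_stop(sprintf("LD file not found: %s", path), "sscoloc_config_error")
  }
  rows <- readLines(path)
  rows <- rows[nzchar(trimws(rows))]
  cells <- strsplit(trimws(rows), "[ \t]+")
  ncols <- lengths(cells)
  if (length(unique(ncols)) != 1L || length(rows) != ncols[1]) {
    ss_stop(sprintf("LD file is not a square matrix (%d rows, %s columns)",
                    length(rows), paste(unique(ncols), collapse = "/")),
            "sscoloc_format_error")
  }
  m <- matrix(suppressWarnings(as.numeric(unlist(cells))),
              nrow = length(rows), byrow = TRUE)
  if (anyNA(m)) {
    ss_stop("LD file contains non-numeric entries", "sscoloc_format_error")
  }
  if (any(m < 0)) {
    return(ld_matrix(snps, m, signed = TRUE, build = build))
  }
  if (max(m) > 1 + 1e-8) {
    ss_stop("LD entries exceed 1; neither r nor r-squared", "sscoloc_format_error")
  }
  ss_log("LD file has no negative entries; interpreting as r-squared and storing sqrt(r2); signs are unrecoverable")
  ld_matrix(snps, sqrt(pmin(m, 1)), signed = FALSE, build = build)
}

#' Write an LD matrix in the PLINK square dialect
#'
#' @param ld An `ld_matrix` (or a bare matrix).
#' @param path Output path.
#' @param what `"r2"` (default, mirrors `--r2 square`) or `"r"`.
#' @return `path`, invisibly.
#' @export
write_plink_ld <- function(ld, path, what = c("r2", "r")) {
  what <- match.arg(what)
  m <- if (inherits(ld, "ld_matrix")) ld$r else as.matrix(ld)
  if (what == "r2") m <- m * m
  lines <- apply(m, 1L, function(row) paste(format(row, digits = 17, trim = TRUE,
                                                   scientific = FALSE),
                                            collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read genotype dosages from a VCF
#'
#' Extracts per-sample ALT-allele dosages (0/1/2, NA for missing genotypes)
#' from a VCF file, as input for [compute_ld_from_genotypes()]. Any VCF can
#' serve as the LD reference panel.
#'
#' @param path Path to a VCF (optionally bgzipped).
#' @param region Optional `region` to restrict to.
#' @param build Build tag carried as metadata.
#' @return A `genotype_block`: list with `samples`, `snps` (variant key data
#'   frame) and `dosages` (SNP x sample matrix).
#' @export
read_vcf_genotypes <- function(path, region = NULL, build = NA_character_) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  snps <- data.frame(chrom = normalize_chrom(fix$CHROM),
                     pos = as.integer(fix$POS),
                     ref = fix$REF, alt = fix$ALT,
                     stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dos <- matrix(NA_real_, nrow = nrow(snps), ncol = ncol(gt))
  if (ncol(gt) > 0) {
    clean <- gsub("\\|", "/", gt)
    dos[] <- vapply(seq_len(ncol(gt)), function(j) {
      g <- clean[, j]
      out <- rep(NA_real_, length(g))
      out[g %in% c("0/0")] <- 0
      out[g %in% c("0/1", "1/0")] <- 1
      out[g %in% c("1/1")] <- 2
      out
    }, numeric(nrow(snps)))
  }
  if (!is.null(region)) {
    keep <- snps$chrom == region$chrom & snps$pos >= region$start & snps$pos <= region$end
    snps <- snps[keep, , drop = FALSE]
    dos <- dos[keep, , drop = FALSE]
  }
  rownames(snps) <- NULL
  structure(list(samples = ncol(dos), snps = snps, dosages = unname(dos)),
            class = "genotype_block", build = build)
}

#' Compute an LD matrix from genotype dosages
#'
#' Pairwise Pearson correlation of allele-dosage vectors over
#' pairwise-complete samples, matching the PLINK `--r square` definition (so
#' squaring reproduces `--r2 square`). Monomorphic SNPs are excluded with a
#' warning before matrix construction.
#'
#' @param block A `genotype_block`.
#' @param snps Optional variant-key data frame restricting (and ordering)
#'   the SNPs used.
#' @return An `ld_matrix` with `signed = TRUE`.
#' @export
compute_ld_from_genotypes <- function(block, snps = NULL) {
  if (block$samples < 2) {
    ss_stop("at least 2 samples are required to compute LD", "sscoloc_input_error")
  }
  dos <- block$dosages
  keys <- block$snps
  if (!is.null(snps)) {
    want <- variant_id(snps$chrom, snps$pos, snps$ref, snps$alt)
    have <- variant_id(keys$chrom, keys$pos, keys$ref, keys$alt)
    idx <- match(want, have)
    if (anyNA(idx)) {
      ss_stop(sprintf("%d requested SNP(s) absent from genotype block", sum(is.na(idx))),
              "sscoloc_alignment_error")
    }
    dos <- dos[idx, , drop = FALSE]
    keys <- keys[idx, , drop = FALSE]
  }
  v <- apply(dos, 1L, stats::var, na.rm = TRUE)
  mono <- is.na(v) | v < .Machine$double.eps
  if (any(mono)) {
    ss_log(sprintf("excluding %d monomorphic SNP(s) from LD computation", sum(mono)))
    dos <- dos[!mono, , drop = FALSE]
    keys <- keys[!mono, , drop = FALSE]
  }
  if (nrow(dos) == 0L) {
    ss_stop("no polymorphic SNPs left for LD computation", "sscoloc_input_error")
  }
  r <- suppressWarnings(stats::cor(t(dos), use = "pairwise.complete.obs"))
  if (anyNA(r)) {
    ss_stop("LD undefined for some SNP pair (fewer than 2 complete sample pairs)",
            "sscoloc_degenerate_error")
  }
  rownames(keys) <- NULL
  ld_matrix(keys, r, signed = TRUE, build = attr(block, "build"))
}

#' Select the lead SNP
#'
#' Returns the user's choice when it is present in both the dataset and the
#' LD panel; otherwise iterates over dataset variants in ascending p-value
#' order (ties broken by smaller genomic position) until one present in the
#' LD panel is found.
#'
#' @param dataset A `sumstat_dataset`.
#' @param ld_snps Variant keys available in the LD panel: a data frame or a
#'   character vector of `chrom_pos_ref_alt` ids.
#' @param user_choice Optional `variant_key` (or marker string) override.
#' @return The selected variant as a one-row data frame.
#' @export
select_lead_snp <- function(dataset, ld_snps, user_choice = NULL) {
  if (nrow(dataset) == 0L) {
    ss_stop("empty dataset; cannot select a lead SNP", "sscoloc_input_error")
  }
  ld_ids <- if (is.character(ld_snps)) ld_snps else
    c(variant_id(ld_snps$chrom, ld_snps$pos, ld_snps$ref, ld_snps$alt),
      variant_id_swapped(ld_snps$chrom, ld_snps$pos, ld_snps$ref, ld_snps$alt))
  ids <- variant_id(dataset$chrom, dataset$pos, dataset$ref, dataset$alt)
  if (!is.null(user_choice)) {
    if (is.character(user_choice)) user_choice <- parse_marker_id(user_choice)
    uid <- variant_id(user_choice$chrom, user_choice$pos, user_choice$ref, user_choice$alt)
    hit <- match(uid, ids)
    if (!is.na(hit) && uid %in% ld_ids) {
      return(dataset[hit, , drop = FALSE])
    }
    ss_log(sprintf("requested lead SNP %s not found in dataset and LD panel; falling back to smallest p-value", uid))
  }
  ord <- order(dataset$p, dataset$pos)
  for (i in ord) {
    if (ids[i] %in% ld_ids) {
      return(dataset[i, , drop = FALSE])
    }
  }
  ss_stop("no dataset variant is present in the LD panel", "sscoloc_no_lead_error")
}

#' Default Simple Sum region around the lead SNP
#'
#' The Simple Sum test region defaults to 0.1 Mbp on each side of the lead
#' SNP, intersected with the viewing region; a user-supplied override
#' replaces the default.
#'
#' @param lead Lead variant (one-row data frame or `variant_key`).
#' @param view The viewing `region` (must contain the lead SNP).
#' @param override Optional `region` to use instead of the default.
#' @return A `region`.
#' @export
default_ss_region <- function(lead, view, override = NULL) {
  if (!is.null(override)) {
    if (!inherits(override, "region")) {
      ss_stop("override must be a validated region", "sscoloc_region_error")
    }
    return(override)
  }
  pos <- lead$pos[1]
  if (pos < view$start || pos > view$end) {
    ss_stop("lead SNP lies outside the viewing region", "sscoloc_region_error")
  }
  validate_region(view$chrom, max(view$start, pos - 1e5), min(view$end, pos + 1e5))
}

#' @export
print.ld_matrix <- function(x, ...) {
  cat(sprintf("<ld_matrix> %d SNPs, %s entries\n", nrow(x$r),
              if (x$signed) "signed r" else "unsigned sqrt(r2)"))
  invisible(x)
}
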