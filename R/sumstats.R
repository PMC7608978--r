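#' Read and validate a summary-statistics file
#'
#' Reads a header-bearing, tab- or whitespace-separated table of per-SNP
#' association results into a validated `sumstat_dataset`. Variants are
#' identified either by explicit chromosome/position/allele columns or by a
#' single marker column in `chrom_pos_ref_alt_b37/b38` (or rsID) form.
#'
#' Rows with unparseable or out-of-range p-values are dropped and counted;
#' p = 0 is clamped to 1e-300 so that -log10 evidence stays finite. Duplicate
#' variants keep the smallest p-value. Optional effect columns (beta, se, maf,
#' n) are carried through but unused by the Simple Sum test.
#'
#' @param path Path to the file.
#' @param column_map Named list mapping roles to column names. Recognized
#'   roles: `chrom`, `pos`, `ref`, `alt`, `p`, `marker`, `beta`, `se`, `maf`,
#'   `n`, `gene`, `dataset`. Defaults: `CHROM`, `POS`, `REF`, `ALT`, `P`.
#'   Supplying `marker` switches to marker-token parsing.
#' @param build Genome build tag ("hg19" or "hg38"); metadata only. When a
#'   marker column carries `b37`/`b38` suffixes the build is taken from the
#'   tokens themselves.
#' @param rsid_lookup Optional lookup table from [read_rsid_lookup()] used to
#'   resolve rsID marker tokens; unresolved rsIDs are dropped and counted.
#' @param label Dataset label; defaults to the file name.
#' @return A data frame of class `sumstat_dataset` with columns `chrom`,
#'   `pos`, `ref`, `alt`, `p` (plus any carried optional columns), and
#'   attributes `label`, `build`, `n_input`, `n_dropped`, `n_duplicates`.
#' @export
parse_summary_stats <- function(path, column_map = list(), build = "hg19",
                                rsid_lookup = NULL, label = NULL) {
  if (!file.exists(path)) {
    ss_stop(sprintf("summary-statistics file not found: %s", path),
            "sscoloc_config_error")
  }
  cm <- default_column_map(column_map)
  tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                           check.names = FALSE, comment.char = "")
  build_sumstat_dataset(tab, cm, build, rsid_lookup,
                        label = if (is.null(label)) basename(path) else label)
}

default_column_map <- function(column_map) {
  cm <- list(chrom = "CHROM", pos = "POS", ref = "REF", alt = "ALT", p = "P",
             marker = NULL, beta = NULL, se = NULL, maf = NULL, n = NULL,
             gene = "gene", dataset = "dataset")
  unknown <- setdiff(names(column_map), names(cm))
  if (length(unknown)) {
    ss_stop(sprintf("unknown column roles: %s", paste(unknown, collapse = ", ")),
            "sscoloc_config_error")
  }
  cm[names(column_map)] <- column_map
  cm
}

# core table -> dataset conversion shared by primary and secondary readers
build_sumstat_dataset <- function(tab, cm, build, rsid_lookup, label) {
  need <- function(role) {
    col <- cm[[role]]
    if (is.null(col) || !col %in% names(tab)) {
      ss_stop(sprintf("mapped column for role '%s' (%s) not found in input",
                      role, if (is.null(col)) "<unset>" else col),
              "sscoloc_config_error")
    }
    tab[[col]]
  }
  n_input <- nrow(tab)
  if (!is.null(cm$marker) || !all(c(cm$chrom, cm$pos) %in% names(tab))) {
    if (is.null(cm$marker) || !cm$marker %in% names(tab)) {
      ss_stop("no chrom/pos columns and no marker column mapped",
              "sscoloc_config_error")
    }
    parsed <- parse_marker_column(tab[[cm$marker]], rsid_lookup)
    df <- parsed$df
    keep_marker <- parsed$keep
    if (any(!is.na(df$build))) {
      builds <- unique(df$build[!is.na(df$build)])
      if (length(builds) > 1L) {
        ss_stop("mixed genome builds in marker column", "sscoloc_input_error")
      }
      build <- builds
    }
    df$build <- NULL
  } else {
    df <- data.frame(chrom = normalize_chrom(need("chrom")),
                     pos = suppressWarnings(as.integer(need("pos"))),
                     ref = toupper(as.character(need("ref"))),
                     alt = toupper(as.character(need("alt"))),
                     stringsAsFactors = FALSE)
    keep_marker <- !is.na(df$pos) & df$pos >= 1 & df$chrom %in% VALID_CHROMS &
      grepl("^[ACGT]+$", df$ref) & grepl("^[ACGT]+$", df$alt) & df$ref != df$alt
  }
  p <- suppressWarnings(as.numeric(need("p")))
  keep_p <- !is.na(p) & p >= 0 & p <= 1
  p[!is.na(p) & p == 0] <- 1e-300
  keep <- keep_marker & keep_p

  df$p <- p
  for (role in c("beta", "se", "maf", "n")) {
    col <- cm[[role]]
    if (!is.null(col) && col %in% names(tab)) {
      df[[role]] <- suppressWarnings(as.numeric(tab[[col]]))
    }
  }
  df <- df[keep, , drop = FALSE]
  n_dropped <- n_input - nrow(df)
  if (n_dropped > 0) {
    ss_log(sprintf("%s: dropped %d of %d rows (unparseable marker or p-value out of (0,1])",
                   label, n_dropped, n_input))
  }
  if (nrow(df) == 0L) {
    ss_stop(sprintf("%s: no valid rows after filtering", label),
            "sscoloc_input_error")
  }
  dedup <- dedup_min_p(df)
  if (dedup$n_duplicates > 0) {
    ss_log(sprintf("%s: %d duplicate variant record(s); kept smallest p-value",
                   label, dedup$n_duplicates))
  }
  df <- dedup$df
  rownames(df) <- NULL
  structure(df,
            class = c("sumstat_dataset", "data.frame"),
            label = label, build = build,
            n_input = n_input, n_dropped = n_dropped,
            n_duplicates = dedup$n_duplicates)
}

parse_marker_column <- function(tokens, rsid_lookup) {
  tokens <- as.character(tokens)
  n <- length(tokens)
  chrom <- character(n); pos <- rep(NA_integer_, n)
  ref <- character(n); alt <- character(n); bld <- rep(NA_character_, n)
  keep <- logical(n)
  for (i in seq_len(n)) {
    vk <- tryCatch(parse_marker_id(tokens[i]), sscoloc_parse_error = function(e) NULL)
    if (is.null(vk)) next
    if (inherits(vk, "unresolved_rsid")) {
      if (!is.null(rsid_lookup)) {
        hit <- match(vk$rsid, rsid_lookup$rsid)
        if (!is.na(hit)) {
          chrom[i] <- rsid_lookup$chrom[hit]; pos[i] <- rsid_lookup$pos[hit]
          ref[i] <- rsid_lookup$ref[hit]; alt[i] <- rsid_lookup$alt[hit]
          keep[i] <- TRUE
        }
      }
      next
    }
    chrom[i] <- vk$chrom; pos[i] <- vk$pos; ref[i] <- vk$ref; alt[i] <- vk$alt
    bld[i] <- vk$build
    keep[i] <- TRUE
  }
  list(df = data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                       build = bld, stringsAsFactors = FALSE),
       keep = keep)
}

# keep the smallest p per variant key, preserving first-occurrence order
dedup_min_p <- function(df) {
  ids <- variant_id(df$chrom, df$pos, df$ref, df$alt)
  if (!anyDuplicated(ids)) {
    return(list(df = df, n_duplicates = 0L))
  }
  ord <- order(match(ids, unique(ids)), df$p)
  df2 <- df[ord, , drop = FALSE]
  ids2 <- ids[ord]
  first <- !duplicated(ids2)
  list(df = df2[first, , drop = FALSE], n_duplicates = sum(!first))
}

#' Read an rsID lookup table
#'
#' A 5-column TSV (header `rsid chrom pos ref alt`) used to resolve rsID
#' marker tokens to genomic coordinates in place of a dbSNP service.
#'
#' @param path Path to the TSV.
#' @return A data frame with columns rsid/chrom/pos/ref/alt.
#' @export
read_rsid_lookup <- function(path) {
  tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  needed <- c("rsid", "chrom", "pos", "ref", "alt")
  if (!all(needed %in% names(tab))) {
    ss_stop("rsID lookup must have columns: rsid chrom pos ref alt",
            "sscoloc_config_error")
  }
  tab$chrom <- normalize_chrom(tab$chrom)
  tab$pos <- as.integer(tab$pos)
  tab
}

#' Write a summary-statistics dataset as TSV
#'
#' @param dataset A `sumstat_dataset`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(dataset, path) {
  out <- as.data.frame(dataset)
  names(out)[match(c("chrom", "pos", "ref", "alt", "p"), names(out))] <-
    c("CHROM", "POS", "REF", "ALT", "P")
  utils::write.table(format(out, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# restrict a dataset to a region (1-based inclusive), keeping metadata
subset_region <- function(dataset, region) {
  keep <- dataset$chrom == region$chrom &
    dataset$pos >= region$start & dataset$pos <= region$end
  out <- dataset[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "label") <- attr(dataset, "label")
  attr(out, "build") <- attr(dataset, "build")
  out
}

#' Align a primary dataset, a secondary dataset and an LD matrix
#'
#' Computes the ordered intersection of variants present in all three
#' sources. A secondary or LD variant whose ref/alt alleles are swapped
#' relative to the primary still matches (p-values are allele-order
#' invariant); strand flips are not attempted.
#'
#' @param primary,secondary `sumstat_dataset` objects on the same build.
#' @param ld An `ld_matrix`.
#' @return A list with `variants` (the matched primary rows, in primary
#'   order), index vectors `primary_idx`, `secondary_idx`, `ld_idx`, and
#'   `n_excluded` counts per source.
#' @export
harmonize_datasets <- function(primary, secondary, ld) {
  b1 <- attr(primary, "build"); b2 <- attr(secondary, "build")
  b3 <- attr(ld, "build")
  builds <- unique(c(b1, b2, b3))
  builds <- builds[!is.na(builds) & nzchar(builds)]
  if (length(builds) > 1L) {
    ss_stop(sprintf("datasets are on different builds: %s",
                    paste(builds, collapse = ", ")), "sscoloc_config_error")
  }
  pid <- variant_id(primary$chrom, primary$pos, primary$ref, primary$alt)
  sec_direct <- variant_id(secondary$chrom, secondary$pos, secondary$ref, secondary$alt)
  sec_swap <- variant_id_swapped(secondary$chrom, secondary$pos, secondary$ref, secondary$alt)
  lsn <- ld$snps
  ld_direct <- variant_id(lsn$chrom, lsn$pos, lsn$ref, lsn$alt)
  ld_swap <- variant_id_swapped(lsn$chrom, lsn$pos, lsn$ref, lsn$alt)

  si <- match(pid, sec_direct)
  si[is.na(si)] <- match(pid, sec_swap)[is.na(si)]
  li <- match(pid, ld_direct)
  li[is.na(li)] <- match(pid, ld_swap)[is.na(li)]

  keep <- !is.na(si) & !is.na(li)
  if (!any(keep)) {
    ss_stop("no variants shared by primary, secondary and LD sources",
            "sscoloc_no_overlap_error")
  }
  list(variants = primary[keep, , drop = FALSE],
       primary_idx = which(keep),
       secondary_idx = si[keep],
       ld_idx = li[keep],
       n_excluded = c(primary = sum(!keep),
                      secondary = nrow(secondary) - sum(keep),
                      ld = nrow(lsn) - sum(keep)))
}

#' @export
print.sumstat_dataset <- function(x, ...) {
  cat(sprintf("<sumstat_dataset> %s: %d variants (%s), min p = %.3g\n",
              attr(x, "label"), nrow(x), attr(x, "build"), min(x$p)))
  NextMethod()
}
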