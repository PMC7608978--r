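#' Read a long-format secondary summary-statistics collection
#'
#' Reads a TSV holding secondary associations for several genes and
#' datasets (tissues), keyed by a `gene` and a `dataset` column, and groups
#' it into one `sumstat_dataset` per (gene, dataset) pair. Duplicated
#' (gene, dataset, variant) rows keep the smallest p-value; empty groups are
#' dropped.
#'
#' @param path Path to the long-format TSV.
#' @param column_map As in [parse_summary_stats()]; the `gene` and `dataset`
#'   roles default to columns named `gene` and `dataset`.
#' @param build Build tag (metadata).
#' @param rsid_lookup Optional rsID lookup table.
#' @return A `secondary_collection`: list with `entries` (named
#'   `gene|dataset` -> `sumstat_dataset`), `genes` and `datasets` in order
#'   of first appearance.
#' @export
parse_secondary_collection <- function(path, column_map = list(), build = "hg19",
                                       rsid_lookup = NULL) {
  if (!file.exists(path)) {
    ss_stop(sprintf("secondary collection file not found: %s", path),
            "sscoloc_config_error")
  }
  cm <- default_column_map(column_map)
  tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                           check.names = FALSE, comment.char = "")
  for (role in c("gene", "dataset")) {
    if (!cm[[role]] %in% names(tab)) {
      ss_stop(sprintf("secondary collection lacks the '%s' column (%s)",
                      role, cm[[role]]), "sscoloc_config_error")
    }
  }
  gene <- as.character(tab[[cm$gene]])
  dset <- as.character(tab[[cm$dataset]])
  key <- paste(gene, dset, sep = "|")
  entries <- list()
  for (k in unique(key)) {
    rows <- tab[key == k, , drop = FALSE]
    entry <- tryCatch(
      build_sumstat_dataset(rows, cm, build, rsid_lookup, label = k),
      sscoloc_input_error = function(e) NULL)
    if (!is.null(entry)) entries[[k]] <- entry
  }
  if (length(entries) == 0L) {
    ss_stop("secondary collection has no valid entries", "sscoloc_input_error")
  }
  keys <- do.call(rbind, strsplit(names(entries), "|", fixed = TRUE))
  structure(list(entries = entries,
                 genes = unique(keys[, 1]),
                 datasets = unique(keys[, 2])),
            class = "secondary_collection", build = build)
}

# assemble a collection from in-memory datasets (used by the simulator)
secondary_collection <- function(entries, build = "hg19") {
  keys <- do.call(rbind, strsplit(names(entries), "|", fixed = TRUE))
  structure(list(entries = entries,
                 genes = unique(keys[, 1]),
                 datasets = unique(keys[, 2])),
            class = "secondary_collection", build = build)
}

#' Simple Sum colocalization across all genes and secondary datasets
#'
#' Runs [run_simple_sum()] for every (gene, dataset) cell of the collection
#' with Bonferroni denominator m = number of entries, and assembles the
#' sentinel-coded heatmap matrix. Gene/dataset pairs with no entry are
#' rendered as sentinel -1 so the grid is always rectangular. Rows follow
#' genomic gene order; columns follow submission order.
#'
#' @param primary GWAS `sumstat_dataset`.
#' @param collection A `secondary_collection`.
#' @param ld An `ld_matrix`.
#' @param ss_region The Simple Sum `region`.
#' @param alpha Stage-1 nominal level (default 0.05).
#' @param min_snps Minimum harmonized SNPs for stage 2.
#' @return A `coloc_matrix`: list with `genes`, `datasets`, `values`
#'   (-log10 SS p or sentinel), `status`, `stage1_p`, `n_snps`, `alpha`,
#'   `m`, and the per-cell `results`.
#' @export
compute_coloc_matrix <- function(primary, collection, ld, ss_region,
                                 alpha = 0.05, min_snps = 5L) {
  entries <- collection$entries
  m <- length(entries)
  # genomic gene order: smallest variant position among the gene's entries
  keyparts <- strsplit(names(entries), "|", fixed = TRUE)
  entry_gene <- vapply(keyparts, `[`, "", 1L)
  gene_pos <- vapply(collection$genes, function(g) {
    min(vapply(entries[entry_gene == g], function(e) min(e$pos), numeric(1)))
  }, numeric(1))
  genes <- collection$genes[order(gene_pos, collection$genes)]
  datasets <- collection$datasets

  dims <- list(genes, datasets)
  values <- matrix(as.numeric(SENTINEL_NO_DATA), length(genes), length(datasets),
                   dimnames = dims)
  status <- matrix("NO_DATA", length(genes), length(datasets), dimnames = dims)
  stage1 <- matrix(NA_real_, length(genes), length(datasets), dimnames = dims)
  nsnp <- matrix(0L, length(genes), length(datasets), dimnames = dims)
  results <- vector("list", m)
  names(results) <- names(entries)

  for (k in sort(names(entries))) {
    gk <- keyparts[[match(k, names(entries))]]
    res <- run_simple_sum(primary, entries[[k]], ld, ss_region,
                          alpha = alpha, m = m, min_snps = min_snps, label = k)
    results[[k]] <- res
    values[gk[1], gk[2]] <- if (res$status == "OK") res$neglog10_ss_p else as.numeric(res$sentinel)
    status[gk[1], gk[2]] <- res$status
    stage1[gk[1], gk[2]] <- res$stage1_p
    nsnp[gk[1], gk[2]] <- res$n_snps
  }
  structure(list(genes = genes, datasets = datasets, values = values,
                 status = status, stage1_p = stage1, n_snps = nsnp,
                 alpha = alpha, m = m, results = results),
            class = "coloc_matrix")
}

#' Export the heatmap matrix as TSV (+ JSON companion)
#'
#' Writes the genes x datasets grid with genes as rows; OK cells hold
#' -log10(SS p) and sentinel cells their code verbatim. A companion JSON
#' carries per-cell statuses and human-readable sentinel reasons.
#'
#' @param matrix A `coloc_matrix`.
#' @param path Output TSV path.
#' @param json_path Companion JSON path (default: `path` with a .json
#'   extension).
#' @return `path`, invisibly.
#' @export
export_heatmap_table <- function(matrix, path, json_path = NULL) {
  if (is.null(json_path)) {
    json_path <- paste0(tools::file_path_sans_ext(path), ".json")
  }
  out <- data.frame(gene = matrix$genes, matrix$values, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(format(out, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  reasons <- matrix$status
  reasons[] <- vapply(seq_along(matrix$status), function(i) {
    st <- matrix$status[i]
    if (st == "OK") "OK" else sentinel_reason(
      c(NO_DATA = -1L, NOT_SIGNIFICANT = -2L, FAILED = -3L)[[st]])
  }, "")
  payload <- list(genes = matrix$genes, datasets = matrix$datasets,
                  values = matrix$values, status = matrix$status,
                  reasons = reasons, alpha = matrix$alpha, m = matrix$m)
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' Read back an exported heatmap TSV
#'
#' @param path Path written by [export_heatmap_table()].
#' @return Numeric matrix (genes x datasets).
#' @export
read_heatmap_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                           stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- tab$gene
  m
}

#' Write the per-cell Simple Sum result table as TSV
#'
#' One row per (gene, dataset): status, sentinel or -log10 SS p value,
#' stage-1 p and harmonized SNP count.
#'
#' @param matrix A `coloc_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ss_results <- function(matrix, path) {
  df <- as.data.frame(matrix)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
as.data.frame.coloc_matrix <- function(x, ...) {
  rows <- expand.grid(gene = x$genes, dataset = x$datasets,
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  rows <- rows[order(match(rows$gene, x$genes), match(rows$dataset, x$datasets)), ]
  data.frame(rows,
             status = x$status[cbind(rows$gene, rows$dataset)],
             value = x$values[cbind(rows$gene, rows$dataset)],
             stage1_p = x$stage1_p[cbind(rows$gene, rows$dataset)],
             n_snps = x$n_snps[cbind(rows$gene, rows$dataset)],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @export
print.coloc_matrix <- function(x, ...) {
  cat(sprintf("<coloc_matrix> %d gene(s) x %d dataset(s), alpha = %g, m = %d\n",
              length(x$genes), length(x$datasets), x$alpha, x$m))
  print(round(x$values, 3))
  invisible(x)
}

#' @export
summary.coloc_matrix <- function(object, ...) {
  df <- as.data.frame(object)
  ok <- df$status == "OK"
  cat(sprintf("Simple Sum colocalization matrix: %d cells (%d OK, %d no-data, %d not-significant, %d failed)\n",
              nrow(df), sum(ok), sum(df$status == "NO_DATA"),
              sum(df$status == "NOT_SIGNIFICANT"), sum(df$status == "FAILED")))
  if (any(ok)) {
    top <- df[ok, ][which.max(df$value[ok]), ]
    cat(sprintf("Top cell: %s / %s with -log10(SS p) = %.3f\n",
                top$gene, top$dataset, top$value))
  }
  invisible(df)
}

#' @export
plot.coloc_matrix <- function(x, ...) {
  v <- x$values
  v[v < 0] <- NA  # sentinel cells rendered as missing (gray)
  op <- graphics::par(mar = c(6, 6, 2, 1)); on.exit(graphics::par(op))
  graphics::image(seq_along(x$datasets), seq_along(x$genes), t(v),
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  axes = FALSE, xlab = "", ylab = "", ...)
  graphics::axis(1, seq_along(x$datasets), x$datasets, las = 2, cex.axis = 0.8)
  graphics::axis(2, seq_along(x$genes), x$genes, las = 2, cex.axis = 0.8)
  graphics::box()
  invisible(x)
}
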