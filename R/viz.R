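# Plot-ready regional summaries: LD colour bins, windowed minimum-p traces,
# collapsed gene models, and the combined JSON payload.

LD_BIN_LEVELS <- c("lead", "ge0.8", "0.6to0.8", "0.4to0.6", "0.2to0.4",
                   "lt0.2", "missing")

#' LocusZoom-style LD colour bins
#'
#' Assigns each SNP's r-squared with the lead SNP to one of the standard
#' colour bins. Bins are half-open `[lo, hi)` with the top bin closed at 1
#' (r2 >= 0.8), so that every r-squared maps to exactly one category;
#' missing LD maps to `missing` and the lead SNP itself to `lead`.
#'
#' @param r2 Vector of r-squared values in [0, 1]; NA for missing.
#' @param is_lead Logical vector (or scalar) flagging the lead SNP.
#' @return Factor with levels lead, ge0.8, 0.6to0.8, 0.4to0.6, 0.2to0.4,
#'   lt0.2, missing.
#' @examples
#' bin_ld_colors(c(0.85, 0.8, 0.7999, NA))
#' @export
bin_ld_colors <- function(r2, is_lead = FALSE) {
  r2 <- as.numeric(r2)
  if (any(!is.na(r2) & (r2 < 0 | r2 > 1))) {
    ss_stop("r-squared values must lie in [0, 1]", "sscoloc_domain_error")
  }
  is_lead <- rep_len(is_lead, length(r2))
  out <- character(length(r2))
  out[is.na(r2)] <- "missing"
  idx <- !is.na(r2)
  out[idx] <- as.character(cut(r2[idx], breaks = c(0, 0.2, 0.4, 0.6, 0.8, 1 + 1e-9),
                               labels = c("lt0.2", "0.2to0.4", "0.4to0.6",
                                          "0.6to0.8", "ge0.8"),
                               right = FALSE, include.lowest = TRUE))
  out[is_lead] <- "lead"
  factor(out, levels = LD_BIN_LEVELS)
}

#' Windowed minimum-p trace for a secondary dataset
#'
#' Summarizes a secondary dataset as the lowest p-value per window, the
#' line traces drawn over the regional plot. The window width is
#' `(region size / 1,000,000) * factor` base pairs, where region size is
#' `end - start` (the 150-kbp example region gives 22.5-bp windows at the
#' default factor of 150). Windows tile the region left-closed from the
#' region start; the (possibly fractional) width is kept exact for boundary
#' assignment so windows do not drift. Empty windows are omitted.
#'
#' @param positions Base positions (within the region).
#' @param pvalues p-values aligned to `positions`, in (0, 1].
#' @param region A `region`.
#' @param factor Window-size factor (default 150).
#' @return Data frame with `window_start`, `window_index` and `min_p`, one
#'   row per non-empty window, ordered by position.
#' @export
window_min_trace <- function(positions, pvalues, region, factor = 150) {
  size <- region$end - region$start
  if (size <= 0) {
    ss_stop("region has zero extent; cannot define windows", "sscoloc_region_error")
  }
  if (length(positions) != length(pvalues)) {
    ss_stop("positions and pvalues must be aligned", "sscoloc_input_error")
  }
  if (any(positions < region$start | positions > region$end)) {
    ss_stop("positions outside the region", "sscoloc_domain_error")
  }
  if (length(positions) == 0L) {
    return(data.frame(window_start = numeric(0), window_index = integer(0),
                      min_p = numeric(0)))
  }
  w <- size / 1e6 * factor
  # exact-rational assignment: floor((pos - start) * 1e6 / (size * factor))
  idx <- floor((positions - region$start) * 1e6 / (size * factor))
  minp <- tapply(pvalues, idx, min)
  uidx <- as.numeric(names(minp))
  ord <- order(uidx)
  data.frame(window_start = region$start + uidx[ord] * w,
             window_index = as.integer(uidx[ord]),
             min_p = as.numeric(minp)[ord], row.names = NULL)
}

#' Collapse transcript isoforms into single gene models
#'
#' Reads gene annotation from a GTF and, for every gene overlapping the
#' region, takes the union of all transcript exon intervals, merging
#' overlapping or adjacent exons into a single-gene model (the collapsed
#' gene track drawn under regional plots).
#'
#' @param gtf_path Path to a GTF with gene/transcript/exon features and
#'   GENCODE-style attributes.
#' @param region A `region`.
#' @return List of gene models, each a list with `gene_id`, `name`,
#'   `strand` and an `exons` data frame of disjoint sorted intervals;
#'   ordered by gene start. Genes with no overlap of the region are
#'   excluded.
#' @export
collapse_gene_models <- function(gtf_path, region) {
  if (!file.exists(gtf_path)) {
    ss_stop(sprintf("GTF file not found: %s", gtf_path), "sscoloc_config_error")
  }
  lines <- readLines(gtf_path)
  body <- which(!grepl("^#", lines) & nzchar(lines))
  nfield <- vapply(strsplit(lines[body], "\t", fixed = TRUE), length, 0L)
  if (any(nfield < 9L)) {
    bad <- body[which(nfield < 9L)[1]]
    ss_stop(sprintf("malformed GTF line %d: fewer than 9 tab-separated fields", bad),
            "sscoloc_parse_error")
  }
  g <- rtracklayer::import(gtf_path, format = "gtf")
  ex <- g[!is.na(g$type) & g$type == "exon"]
  if (length(ex) == 0L) return(list())
  target <- GenomicRanges::GRanges(region$chrom,
                                   IRanges::IRanges(region$start, region$end))
  chr <- normalize_chrom(as.character(GenomicRanges::seqnames(ex)))
  gene_ids <- as.character(ex$gene_id)
  models <- list()
  for (gid in unique(gene_ids)) {
    sel <- gene_ids == gid & chr == region$chrom
    if (!any(sel)) next
    exi <- IRanges::IRanges(GenomicRanges::start(ex)[sel], GenomicRanges::end(ex)[sel])
    collapsed <- IRanges::reduce(exi)
    gene_range <- range(c(IRanges::start(collapsed), IRanges::end(collapsed)))
    if (gene_range[2] < region$start || gene_range[1] > region$end) next
    name <- ex$gene_name[sel][1]
    models[[gid]] <- list(
      gene_id = gid,
      name = if (is.null(name) || is.na(name)) gid else as.character(name),
      strand = as.character(GenomicRanges::strand(ex)[sel][1]),
      exons = data.frame(start = IRanges::start(collapsed),
                         end = IRanges::end(collapsed)))
  }
  if (length(models) == 0L) return(list())
  starts <- vapply(models, function(m) min(m$exons$start), numeric(1))
  unname(models[order(starts)])
}

#' Assemble the plot-ready JSON payload
#'
#' Bundles everything the regional colocalization figure needs: the GWAS
#' scatter (-log10 p with one LD bin per point), the windowed minimum-p
#' trace per secondary dataset, collapsed gene models, the heatmap block
#' and the Simple Sum region bounds (the gray-shaded interval).
#'
#' @param primary GWAS `sumstat_dataset`.
#' @param traces Named list of [window_min_trace()] outputs, one per
#'   secondary dataset.
#' @param ld_bins Factor from [bin_ld_colors()], aligned to `primary`.
#' @param gene_models Output of [collapse_gene_models()].
#' @param matrix A `coloc_matrix` (or NULL).
#' @param ss_region The Simple Sum `region`.
#' @param region The viewing `region`.
#' @return A list ready for [write_plot_payload()].
#' @export
build_plot_payload <- function(primary, traces, ld_bins, gene_models,
                               matrix = NULL, ss_region, region) {
  stopifnot(length(ld_bins) == nrow(primary))
  payload <- list(
    region = list(chrom = region$chrom, start = region$start, end = region$end),
    ss_region = list(chrom = ss_region$chrom, start = ss_region$start,
                     end = ss_region$end),
    gwas = data.frame(pos = primary$pos,
                      neglog10_p = -log10(primary$p),
                      ld_bin = as.character(ld_bins),
                      stringsAsFactors = FALSE),
    traces = traces,
    genes = gene_models)
  if (!is.null(matrix)) {
    payload$heatmap <- list(genes = matrix$genes, datasets = matrix$datasets,
                            values = matrix$values)
  }
  payload
}

#' Serialize / deserialize the plot payload
#'
#' @param payload List from [build_plot_payload()].
#' @param path JSON path.
#' @return `path` (write) or the payload list (read).
#' @export
write_plot_payload <- function(payload, path) {
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_plot_payload
#' @export
read_plot_payload <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
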