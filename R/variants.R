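#' Parse a marker identifier
#'
#' Marker tokens follow the `chrom_pos_ref_alt_b37` / `..._b38` convention
#' (build suffix `b37` maps to hg19, `b38` to hg38). rsID tokens (`rs123`)
#' cannot be positioned without an external lookup and are returned as
#' unresolved markers; see [read_rsid_lookup()].
#'
#' @param token A single marker string.
#' @return For positional tokens, a `variant_key`: a list with `chrom`, `pos`,
#'   `ref`, `alt` and `build`. For rsID tokens, an `unresolved_rsid` list
#'   holding the token.
#' @examples
#' parse_marker_id("13_25200000_A_G_b37")
#' parse_marker_id("rs7512462")
#' @export
parse_marker_id <- function(token) {
  if (!is.character(token) || length(token) != 1L || !nzchar(token)) {
    ss_stop("marker token must be a single non-empty string", "sscoloc_parse_error")
  }
  if (grepl("^rs[0-9]+$", token)) {
    return(structure(list(rsid = token), class = "unresolved_rsid"))
  }
  m <- regmatches(token, regexec(
    "^(chr)?([0-9]{1,2}|X)_([0-9]+)_([ACGT]+)_([ACGT]+)_b(37|38)$",
    token, ignore.case = FALSE))[[1]]
  if (length(m) == 0L) {
    ss_stop(sprintf("cannot parse marker token '%s' (expected chrom_pos_ref_alt_b37/b38 or rsID)",
                    token), "sscoloc_parse_error")
  }
  chrom <- m[3]
  if (!chrom %in% VALID_CHROMS) {
    ss_stop(sprintf("unrecognized chromosome '%s' in marker '%s'", chrom, token),
            "sscoloc_parse_error")
  }
  ref <- m[5]; alt <- m[6]
  if (identical(ref, alt)) {
    ss_stop(sprintf("ref and alt alleles identical in marker '%s'", token),
            "sscoloc_parse_error")
  }
  structure(list(
    chrom = chrom,
    pos = as.integer(m[4]),
    ref = ref,
    alt = alt,
    build = if (m[7] == "37") "hg19" else "hg38"
  ), class = "variant_key")
}

#' Validate a genomic region
#'
#' Regions are 1-based and inclusive on both ends. The viewable/testable
#' region is capped at 2 Mbp.
#'
#' @param chrom Chromosome label ("1"-"22", "X"; a "chr" prefix is stripped).
#' @param start,end 1-based inclusive coordinates.
#' @return A `region` list with `chrom`, `start`, `end` and `span`
#'   (`end - start + 1`).
#' @examples
#' validate_region("13", 25200000, 25350000)
#' @export
validate_region <- function(chrom, start, end) {
  chrom <- normalize_chrom(chrom)
  if (!chrom %in% VALID_CHROMS) {
    ss_stop(sprintf("unrecognized chromosome '%s'", chrom), "sscoloc_region_error")
  }
  if (!is_count(start) || !is_count(end) || start < 1) {
    ss_stop("start and end must be positive integers", "sscoloc_region_error")
  }
  if (start > end) {
    ss_stop(sprintf("region start (%d) exceeds end (%d)", start, end),
            "sscoloc_region_error")
  }
  span <- end - start + 1
  if (span > 2e6) {
    ss_stop(sprintf("region span %s bp exceeds the 2 Mbp cap", format(span, big.mark = ",")),
            "sscoloc_region_error")
  }
  structure(list(chrom = chrom, start = as.integer(start), end = as.integer(end),
                 span = as.integer(span)),
            class = "region")
}

# parse "chr13:25,200,000-25,350,000"-style strings (commas optional)
parse_region_string <- function(x) {
  x <- gsub(",", "", x)
  m <- regmatches(x, regexec("^(chr)?([0-9XY]+):([0-9]+)-([0-9]+)$", x))[[1]]
  if (length(m) == 0L) {
    ss_stop(sprintf("cannot parse region '%s' (expected chrom:start-end)", x),
            "sscoloc_region_error")
  }
  validate_region(m[3], as.numeric(m[4]), as.numeric(m[5]))
}

#' @export
print.region <- function(x, ...) {
  cat(sprintf("chr%s:%s-%s (%s bp)\n", x$chrom,
              format(x$start, big.mark = ","), format(x$end, big.mark = ","),
              format(x$span, big.mark = ",")))
  invisible(x)
}

#' @export
print.variant_key <- function(x, ...) {
  cat(sprintf("%s_%s_%s_%s (%s)\n", x$chrom, x$pos, x$ref, x$alt, x$build))
  invisible(x)
}
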