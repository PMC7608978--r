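# in-code fixtures shared across test files

variant_id <- sscoloc:::variant_id

# build a sumstat_dataset without touching the file readers
make_ds <- function(pos, p, chrom = "13", ref = "A", alt = "G",
                    build = "hg19", label = "test") {
  n <- length(pos)
  structure(
    data.frame(chrom = rep_len(chrom, n), pos = as.integer(pos),
               ref = rep_len(ref, n), alt = rep_len(alt, n), p = p,
               stringsAsFactors = FALSE),
    class = c("sumstat_dataset", "data.frame"),
    label = label, build = build, n_input = n, n_dropped = 0L,
    n_duplicates = 0L)
}

make_ld <- function(ds, r = NULL) {
  n <- nrow(ds)
  if (is.null(r)) r <- diag(n)
  ld_matrix(ds[, c("chrom", "pos", "ref", "alt")], r, signed = TRUE,
            build = attr(ds, "build"))
}

write_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# textbook two-pass Pearson correlation, complete pairs only
pearson_oracle <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}
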