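# internal helpers shared across modules

VALID_CHROMS <- c(as.character(1:22), "X")

ss_stop <- function(msg, class) {
  stop(structure(
    class = c(class, "sscoloc_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

ss_log <- function(...) message("[sscoloc] ", ...)

# canonical join key for a variant; alleles in file order
variant_id <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = "_")
}

# allele-swapped key (ref/alt exchanged); p-values are allele-order invariant
variant_id_swapped <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, alt, ref, sep = "_")
}

normalize_chrom <- function(chrom) {
  sub("^chr", "", as.character(chrom), ignore.case = TRUE)
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x == round(x)
}
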