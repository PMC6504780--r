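# Byte-stable TSV formatting: numeric columns rendered with "." decimal and
# 6 significant digits in scientific notation where needed.
format_tsv_numbers <- function(df) {
  for (nm in names(df)) {
    if (is.double(df[[nm]])) {
      df[[nm]] <- vapply(df[[nm]], function(x) {
        if (is.na(x)) "NA" else format(signif(x, 6), scientific = abs(x) < 1e-3 && x != 0)
      }, character(1))
    }
  }
  df
}

write_stage_tsv <- function(df, path) {
  utils::write.table(format_tsv_numbers(df), path, quote = FALSE, sep = "\t",
                     row.names = FALSE)
  invisible(path)
}

# Derive a reproducible 31-bit child seed from a base seed and a stream label.
child_seed <- function(seed, stream) {
  (as.integer(seed) * 1009L + stream * 9973L) %% 2147483629L
}
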