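# Shared residue alphabet: the 20 standard amino acids, plus 'X' for
# ambiguous/unknown residues ('X' scores 0 against everything and never
# counts as identical).
AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
AAX <- c(AA20, "X")

# fast char -> 0-based index lookup (position in AAX), NA for anything else
.aa_lookup <- local({
  v <- rep(NA_integer_, 127L)
  for (i in seq_along(AAX)) v[utf8ToInt(AAX[i])] <- i - 1L
  v
})

# Encode an amino-acid string as 0-based indices into AAX; NA marks unknown
# characters (callers decide whether that is an error).
encode_seq <- function(s) {
  .aa_lookup[utf8ToInt(s)]
}

input_error <- function(fmt, ...) {
  stop(structure(
    class = c("hgscreen_input_error", "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}
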