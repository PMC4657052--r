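# Shared constants and small internal helpers.

# The 20 canonical amino acids, alphabetical one-letter order.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Flanking offsets used throughout the sequence-environment analysis.
ENV_OFFSETS <- c(-10:-1, 1:10)

# run `code` under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_metox <- function(...) stop(..., call. = FALSE)

# split an amino-acid string into a character vector of residues
seq_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]

# named lookup id -> sequence from a protein set data.frame
seq_lookup <- function(proteins) {
  stats::setNames(proteins$seq, proteins$id)
}
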