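# IUPAC nucleotide codes as 4-bit sets over {A=1, C=2, G=4, T=8}.
# Shared by the conservation, design and in-silico PCR machinery.

IUPAC_BITS <- c(
  A = 1L, C = 2L, G = 4L, T = 8L,
  R = 5L, Y = 10L, S = 6L, W = 9L, K = 12L, M = 3L,
  B = 14L, D = 13L, H = 11L, V = 7L, N = 15L
)

# bitmask -> IUPAC letter (index = mask value 1..15)
BITS_IUPAC <- character(15L)
BITS_IUPAC[IUPAC_BITS] <- names(IUPAC_BITS)

IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", D = "H", H = "D", V = "B", N = "N"
)

#' Reverse complement of a DNA string (IUPAC-aware)
#'
#' @param seq character vector of DNA strings (uppercase IUPAC codes).
#' @return character vector of reverse complements.
#' @export
#' @examples
#' revcomp("ACGTR")  # "YACGT"
revcomp <- function(seq) {
  vapply(seq, function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    cc <- IUPAC_COMPLEMENT[ch]
    if (anyNA(cc)) gp_format_error("non-IUPAC character in sequence")
    paste(rev(cc), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# validate an unaligned IUPAC DNA string (no gaps)
is_valid_dna <- function(seq) {
  nzchar(seq) & !grepl(sprintf("[^%s]", paste(names(IUPAC_BITS), collapse = "")), seq)
}

# expand a degenerate oligo into its plain A/C/G/T realizations, capped at
# `cap` expansions (deterministic truncation)
iupac_expansions <- function(seq, cap = 64L) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  sets <- lapply(ch, function(c) {
    b <- IUPAC_BITS[[c]]
    c("A", "C", "G", "T")[bitwAnd(c(1L, 2L, 4L, 8L), b) > 0L]
  })
  out <- ""
  for (s in sets) {
    out <- as.vector(t(outer(out, s, paste0)))
    if (length(out) > cap) out <- out[seq_len(cap)]
  }
  out
}

n_degenerate <- function(seq) {
  vapply(strsplit(seq, "", fixed = TRUE),
         function(ch) sum(!ch %in% c("A", "C", "G", "T")), integer(1))
}
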