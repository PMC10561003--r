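# Builds the plain-text fixtures under inst/extdata/. Deterministic; rerun
# only if the fixture design changes.
#
# The two *synthetic* 16S templates are constructed stand-ins for the
# full-length B. subtilis / A. baumannii 16S rRNA genes: a random 1550 bp
# backbone carrying the published genus-specific primer footprints at the
# reported product spacings (626 bp for the Bacillus pair, 536 bp for the
# Acinetobacter pair). They are NOT biological sequences.

library(genusprimer)

primers <- data.frame(
  genus = c("Bacillus", "Acinetobacter"),
  fwd_name = c("F", "F2"), rev_name = c("R", "R2"),
  fwd = c("GTCTGTAACTGACGCTGAGGC", "ATGTGAAATCCCCGAGCTT"),
  rev = c("GCGATTACTAGCGATTCCA", "AGTTTGTCACTGGCAGTATCCT"),
  product_bp = c(626L, 536L),
  stringsAsFactors = FALSE)

make_template <- function(fwd, rev, product_bp, fwd_start, total_len, seed) {
  set.seed(seed)
  repeat {
    bb <- sample(c("A", "C", "G", "T"), total_len, replace = TRUE)
    s <- paste(bb, collapse = "")
    f_at <- fwd_start
    r_end <- fwd_start + product_bp            # 0-based half-open product
    stopifnot(r_end + 1 <= total_len)
    substr(s, f_at + 1, f_at + nchar(fwd)) <- fwd
    rc <- revcomp(rev)
    substr(s, r_end - nchar(rev) + 1, r_end) <- rc
    # accept only if the pair gives exactly this one product
    amp <- simulate_pcr(fwd, rev, data.frame(id = "t", seq = s),
                        max_mm = 2, three_prime_exact = 3,
                        min_len = 50, max_len = 3000)
    if (nrow(amp) == 1L && amp$length == product_bp) return(s)
  }
}

dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)

b <- make_template(primers$fwd[1], primers$rev[1], 626L, 300L, 1550L, 20260921)
a <- make_template(primers$fwd[2], primers$rev[2], 536L, 350L, 1550L, 20260922)

write_fasta(data.frame(
  id = "synthetic_Bsubtilis_16S", genus = "Bacillus",
  species = "Bacillus subtilis (synthetic stand-in)", seq = b),
  "inst/extdata/synthetic_bacillus_16S_template.fasta")
write_fasta(data.frame(
  id = "synthetic_Abaumannii_16S", genus = "Acinetobacter",
  species = "Acinetobacter baumannii (synthetic stand-in)", seq = a),
  "inst/extdata/synthetic_acinetobacter_16S_template.fasta")
write.table(primers, "inst/extdata/published_primer_pairs.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

# small labeled panel for examples / CLI smoke runs: 10 in-group + 10
# out-group sequences from the simulator
cfg <- sim_config(seed = 7L, n_genera = 2L, n_species_per_genus = 5L,
                  n_seqs_per_species = 2L)
panel <- simulate_genus_panel(cfg)
write_fasta(panel$ingroup, "inst/extdata/example_ingroup.fasta")
write_fasta(panel$outgroup, "inst/extdata/example_outgroup.fasta")

cat("fixtures written\n")
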