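# Unified nearest-neighbor thermodynamic parameters for DNA/DNA duplexes
# (SantaLucia 1998, 1 M NaCl reference state). dH in kcal/mol, dS in
# cal/(mol*K), for the ten unique dinucleotide stacks read 5'->3' on the
# top strand; the remaining six stacks are obtained by reverse-complement
# symmetry. Initiation terms depend on the terminal base pair.
# Frozen here; do not edit without revalidating tm_nn() against the
# table-summation oracle in the test suite.

NN_DH <- c(
  AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4,
  CT = -7.8, GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0
)

NN_DS <- c(
  AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, GT = -22.4,
  CT = -21.0, GA = -22.2, CG = -27.2, GC = -24.4, GG = -19.9
)

NN_INIT_DH <- c(GC = 0.1, AT = 2.3)   # per terminal G:C / A:T pair
NN_INIT_DS <- c(GC = -2.8, AT = 4.1)

GAS_CONSTANT_CAL <- 1.987  # cal/(mol*K)

# map all 16 dinucleotides onto the 10 tabulated stacks
nn_key <- function(dinuc) {
  if (dinuc %in% names(NN_DH)) return(dinuc)
  rc <- chartr("ACGT", "TGCA", dinuc)
  paste0(substr(rc, 2, 2), substr(rc, 1, 1))
}
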