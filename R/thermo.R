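#' GC fraction of an oligo
#'
#' @param seq a DNA string over A/C/G/T.
#' @return the exact fraction of G+C bases.
#' @export
#' @examples
#' gc_fraction("GTCTGTAACTGACGCTGAGGC")  # 12/21
gc_fraction <- function(seq) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  if (!all(ch %in% c("A", "C", "G", "T")))
    gp_stop("gc_fraction requires a plain A/C/G/T oligo (score degenerate oligos per expansion)",
            "gp_unsupported_alphabet")
  sum(ch %in% c("G", "C")) / length(ch)
}

#' Nearest-neighbor melting temperature
#'
#' Unified nearest-neighbor model:
#' `Tm = dH * 1000 / (dS_salt + R * ln(C_T / 4)) - 273.15`,
#' where `dH` (kcal/mol) and `dS` (cal/mol/K) are summed over the
#' dinucleotide stacks plus the two terminal initiation terms, and the
#' monovalent-salt entropy correction is
#' `dS_salt = dS + 0.368 * (N - 1) * ln([Na+])`. The `C_T/4` factor assumes
#' the two strands are different and equimolar (the duplex of a primer and
#' its template). The parameter table is frozen in the package constants.
#'
#' @param seq a DNA string over A/C/G/T, length 8 to 40.
#' @param na_molar monovalent cation concentration in mol/L (default 0.05,
#'   i.e. 50 mM Na+; no divalent correction is applied).
#' @param oligo_molar total oligo strand concentration C_T in mol/L
#'   (default 5e-7, i.e. 500 nM).
#' @return melting temperature in degrees Celsius.
#' @export
tm_nn <- function(seq, na_molar = 0.05, oligo_molar = 5e-7) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(ch)
  if (n < 8L || n > 40L)
    gp_stop(paste0("tm_nn supports oligo lengths 8-40, got ", n),
            "gp_unsupported_length")
  if (!all(ch %in% c("A", "C", "G", "T")))
    gp_stop("tm_nn requires a plain A/C/G/T oligo", "gp_unsupported_alphabet")
  if (na_molar <= 0 || oligo_molar <= 0)
    gp_config_error("concentrations must be positive")
  dinucs <- paste0(ch[-n], ch[-1])
  keys <- vapply(dinucs, nn_key, character(1))
  dh <- sum(NN_DH[keys])
  ds <- sum(NN_DS[keys])
  term <- function(b) if (b %in% c("G", "C")) "GC" else "AT"
  dh <- dh + NN_INIT_DH[[term(ch[1])]] + NN_INIT_DH[[term(ch[n])]]
  ds <- ds + NN_INIT_DS[[term(ch[1])]] + NN_INIT_DS[[term(ch[n])]]
  ds_salt <- ds + 0.368 * (n - 1) * log(na_molar)
  dh * 1000 / (ds_salt + GAS_CONSTANT_CAL * log(oligo_molar / 4)) - 273.15
}

# worst-case (minimum) Tm over the expansions of a possibly degenerate oligo
tm_worst_case <- function(seq, na_molar = 0.05, oligo_molar = 5e-7,
                          cap = 64L) {
  min(vapply(iupac_expansions(seq, cap), tm_nn, numeric(1),
             na_molar = na_molar, oligo_molar = oligo_molar))
}

#' Recommended annealing temperature for a primer pair
#'
#' The conventional rule of thumb: 5 degrees below the lower of the two
#' primer melting temperatures, rounded to the nearest integer.
#'
#' @param tm_fwd,tm_rev melting temperatures of the two primers in Celsius
#'   (e.g. from [tm_nn()]).
#' @return recommended annealing temperature in Celsius (integer-valued).
#' @export
#' @examples
#' recommend_annealing(60.0, 62.3)  # 55
recommend_annealing <- function(tm_fwd, tm_rev) {
  round(min(tm_fwd, tm_rev) - 5.0)
}

#' Longest homopolymer run
#'
#' @param seq a DNA string.
#' @return length of the longest run of one repeated base.
#' @export
max_homopolymer <- function(seq) {
  r <- rle(strsplit(seq, "", fixed = TRUE)[[1]])
  max(r$lengths)
}

#' Primer-dimer and hairpin screen
#'
#' The dimer score is the longest run of contiguous Watson-Crick base pairs
#' formed between `seq_a` (5'->3') and `seq_b` read 3'->5', maximized over
#' all relative offsets — i.e. the longest perfect duplex stretch the two
#' oligos can form in antiparallel orientation. The hairpin flag reports
#' whether `seq_a` can fold back on itself with a stem of at least
#' `min_stem` base pairs enclosing a loop of at least `min_loop` bases.
#'
#' @param seq_a,seq_b plain A/C/G/T oligos; `seq_b` defaults to `seq_a`
#'   (self-dimer).
#' @param min_stem,min_loop hairpin geometry thresholds.
#' @return a list with `self_dimer_score` (seq_a vs itself),
#'   `cross_dimer_score` (seq_a vs seq_b) and `hairpin_flag` (for seq_a).
#' @export
dimer_and_hairpin <- function(seq_a, seq_b = seq_a, min_stem = 4L,
                              min_loop = 3L) {
  list(self_dimer_score = dimer_score(seq_a, seq_a),
       cross_dimer_score = dimer_score(seq_a, seq_b),
       hairpin_flag = has_hairpin(seq_a, min_stem, min_loop))
}

# longest contiguous WC-complementary run between a (5'->3') and rev(b)
dimer_score <- function(seq_a, seq_b) {
  a <- strsplit(seq_a, "", fixed = TRUE)[[1]]
  b <- rev(strsplit(seq_b, "", fixed = TRUE)[[1]])
  wc <- c(A = "T", C = "G", G = "C", T = "A")
  na <- length(a); nb <- length(b)
  best <- 0L
  for (off in (-(nb - 1L)):(na - 1L)) {
    run <- 0L
    for (i in seq_len(nb)) {
      j <- i + off
      if (j < 1L || j > na) { run <- 0L; next }
      if (a[j] == wc[[b[i]]]) {
        run <- run + 1L
        if (run > best) best <- run
      } else run <- 0L
    }
  }
  best
}

has_hairpin <- function(seq, min_stem = 4L, min_loop = 3L) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  wc <- c(A = "T", C = "G", G = "C", T = "A")
  n <- length(ch)
  # stem: ch[a..a+s) pairs with reverse complement of ch[b..b+s),
  # loop = b - (a + s)
  for (s in min_stem:max(min_stem, floor((n - min_loop) / 2))) {
    if (2L * s + min_loop > n) break
    for (a in 1L:(n - 2L * s - min_loop + 1L)) {
      for (b in (a + s + min_loop):(n - s + 1L)) {
        ok <- TRUE
        for (i in 0L:(s - 1L)) {
          if (ch[a + i] != wc[[ch[b + s - 1L - i]]]) { ok <- FALSE; break }
        }
        if (ok) return(TRUE)
      }
    }
  }
  FALSE
}

#' Physical report for one oligo
#'
#' Bundles length, GC fraction, nearest-neighbor Tm, longest homopolymer,
#' self-dimer score and hairpin flag. Degenerate oligos are scored by the
#' worst case (minimum Tm, extreme GC) over their expansions, capped at 64
#' expansions.
#'
#' @param seq an IUPAC DNA string.
#' @param na_molar,oligo_molar conditions passed to [tm_nn()].
#' @return a one-row `data.frame` with columns `seq`, `length`, `gc_frac`
#'   (worst-case minimum over expansions for degenerate oligos), `gc_max`,
#'   `tm_celsius` (worst case), `max_homopolymer`, `self_dimer_score`,
#'   `hairpin_flag`, `n_degenerate`.
#' @export
oligo_report <- function(seq, na_molar = 0.05, oligo_molar = 5e-7) {
  exps <- iupac_expansions(seq)
  gcs <- vapply(exps, gc_fraction, numeric(1))
  tms <- vapply(exps, tm_nn, numeric(1), na_molar = na_molar,
                oligo_molar = oligo_molar)
  homos <- vapply(exps, max_homopolymer, numeric(1))
  dh <- dimer_and_hairpin(exps[[1]])
  data.frame(seq = seq, length = nchar(seq), gc_frac = min(gcs),
             gc_max = max(gcs), tm_celsius = min(tms),
             max_homopolymer = max(homos),
             self_dimer_score = dh$self_dimer_score,
             hairpin_flag = dh$hairpin_flag,
             n_degenerate = n_degenerate(seq),
             stringsAsFactors = FALSE)
}
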