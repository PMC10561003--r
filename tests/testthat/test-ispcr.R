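test_that("amplicon coordinates span both primer footprints", {
  set.seed(61)
  template <- rand_dna(600)
  fwd <- substr(template, 11, 31)            # [10, 31) 0-based
  rev <- revcomp(substr(template, 481, 500)) # [480, 500)
  amp <- simulate_pcr(fwd, rev, data.frame(id = "t1", seq = template),
                      max_mm = 0, three_prime_exact = 3)
  expect_equal(nrow(amp), 1L)
  expect_equal(amp$start, 10L)
  expect_equal(amp$end, 500L)
  expect_equal(amp$length, 490L)
  expect_equal(amp$seq, substr(template, 11, 500))

  # convergence required: remove the reverse site
  no_rev <- simulate_pcr(fwd, "GGGGGGGGGGGGGGGGGGGG",
                         data.frame(id = "t1", seq = template))
  expect_equal(nrow(no_rev), 0L)
})

test_that("multiple upstream sites give one amplicon each", {
  set.seed(67)
  f <- rand_dna(20)
  r_site <- rand_dna(20)
  template <- paste0(rand_dna(30), f, rand_dna(100), f, rand_dna(150),
                     revcomp(r_site), rand_dna(30))
  amp <- simulate_pcr(f, r_site, data.frame(id = "t1", seq = template),
                      max_mm = 0, min_len = 50, max_len = 1000)
  expect_equal(nrow(amp), 2L)
  want <- oracle_amplicons(f, r_site, template, 0, 3, 50, 1000)
  expect_equal(amp[, c("start", "end", "length")], want,
               ignore_attr = TRUE)
})

test_that("in-silico PCR matches the brute-force oracle on random cases", {
  set.seed(71)
  for (i in 1:30) {
    tlen <- sample(300:2000, 1)
    template <- rand_dna(tlen)
    # plant a convergent pair with a few mutations
    flen <- sample(16:22, 1); rlen <- sample(16:22, 1)
    fs <- sample(1:(tlen %/% 3), 1)
    re <- sample((2 * tlen %/% 3):(tlen - 1), 1)
    fwd <- substr(template, fs, fs + flen - 1)
    rev <- revcomp(substr(template, re - rlen + 1, re))
    mutate1 <- function(s) {
      ch <- strsplit(s, "")[[1]]
      j <- sample(length(ch) - 4, 1)  # keep the 3' clamp intact
      ch[j] <- sample(setdiff(c("A", "C", "G", "T"), ch[j]), 1)
      paste(ch, collapse = "")
    }
    if (i %% 2 == 0) { fwd <- mutate1(fwd); rev <- mutate1(rev) }
    max_mm <- sample(1:2, 1)
    got <- simulate_pcr(fwd, rev, data.frame(id = "t", seq = template),
                        max_mm = max_mm, three_prime_exact = 3,
                        min_len = 50, max_len = tlen)
    want <- oracle_amplicons(fwd, rev, template, max_mm, 3, 50, tlen)
    expect_equal(got[, c("start", "end", "length")], want,
                 ignore_attr = TRUE)
  }
})

test_that("reverse-complementing the template preserves amplicon lengths", {
  set.seed(73)
  for (i in 1:10) {
    template <- rand_dna(800)
    fwd <- substr(template, 101, 120)
    rev <- revcomp(substr(template, 601, 620))
    a <- simulate_pcr(fwd, rev, data.frame(id = "t", seq = template))
    b <- simulate_pcr(fwd, rev, data.frame(id = "t", seq = revcomp(template)))
    expect_equal(sort(a$length), sort(b$length))
    expect_setequal(800 - a$end, b$start)
  }
})

test_that("amplicon ends are compatible with the primers that made them", {
  set.seed(79)
  cfg <- sim_config(seed = 403, n_genera = 2, n_species_per_genus = 4,
                    n_seqs_per_species = 1)
  panel <- simulate_genus_panel(cfg)
  up <- universal_primers(panel)
  amps <- simulate_pcr(up$fwd, up$rev, panel$templates, max_mm = 2)
  expect_gt(nrow(amps), 0L)
  for (i in seq_len(nrow(amps))) {
    head_region <- substr(amps$seq[i], 1, nchar(up$fwd))
    tail_region <- substr(amps$seq[i], nchar(amps$seq[i]) - nchar(up$rev) + 1,
                          nchar(amps$seq[i]))
    ok_head <- nrow(binds(up$fwd, head_region, 2, 0, all = TRUE)) > 0 ||
      nrow(binds(up$rev, head_region, 2, 0, all = TRUE)) > 0
    ok_tail <- nrow(binds(up$rev, tail_region, 2, 0, all = TRUE)) > 0 ||
      nrow(binds(up$fwd, tail_region, 2, 0, all = TRUE)) > 0
    expect_true(ok_head && ok_tail)
  }
})

test_that("virtual gel collapses bands and annotates the ladder", {
  amps <- data.frame(
    template_id = c("t1", "t1", "t1", "t2"),
    start = c(0L, 0L, 5L, 0L), end = c(626L, 626L, 400L, 536L),
    length = c(626L, 626L, 395L, 536L),
    seq = "", fwd_strand = "+", fwd_start = 0L, fwd_mm = 0L,
    rev_strand = "-", rev_start = 0L, rev_mm = 0L,
    stringsAsFactors = FALSE)
  gel <- virtual_gel(amps, ladder = seq(100, 2000, by = 100),
                     template_ids = c("t1", "t2", "t3"))
  t1 <- gel[gel$template_id == "t1", ]
  expect_equal(t1$band_bp, c(395L, 626L))
  expect_equal(t1$multiplicity, c(1L, 2L))
  expect_equal(t1$nearest_ladder_bp, c(400, 600))
  expect_true(is.na(gel$band_bp[gel$template_id == "t3"]))
})
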