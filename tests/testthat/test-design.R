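test_that("binding-site search matches the exhaustive oracle", {
  set.seed(31)
  for (i in 1:50) {
    tlen <- sample(60:400, 1)
    template <- rand_dna(tlen)
    plen <- sample(12:24, 1)
    # half the cases: primer planted (possibly mutated) in the template
    if (i %% 2 == 0) {
      at <- sample(tlen - plen, 1)
      primer <- substr(template, at + 1, at + plen)
      ch <- strsplit(primer, "")[[1]]
      nmut <- sample(0:3, 1)
      if (nmut > 0) {
        idx <- sample(plen, nmut)
        for (j in idx) ch[j] <- sample(setdiff(c("A", "C", "G", "T"),
                                               ch[j]), 1)
      }
      primer <- paste(ch, collapse = "")
      if (i %% 4 == 0) primer <- revcomp(primer)
    } else {
      primer <- rand_dna(plen)
    }
    max_mm <- sample(0:3, 1); tpe <- sample(0:4, 1)
    got <- binds(primer, template, max_mm, tpe, all = TRUE)
    want <- oracle_sites(primer, template, max_mm, tpe)
    expect_equal(got[, c("strand", "start", "mismatches")], want,
                 ignore_attr = TRUE)
  }
})

test_that("the 3' clamp vetoes sites regardless of total mismatches", {
  template <- rand_dna(200)
  primer <- substr(template, 51, 70)
  # mismatch the 3'-terminal base only
  ch <- strsplit(primer, "")[[1]]
  ch[20] <- setdiff(c("A", "C", "G", "T"), ch[20])[1]
  mism <- paste(ch, collapse = "")
  expect_equal(nrow(binds(mism, template, max_mm = 2,
                          three_prime_exact = 3)), 0L)
  expect_gt(nrow(binds(mism, template, max_mm = 2,
                       three_prime_exact = 0)), 0L)
})

test_that("binds is strand-symmetric under template reverse complement", {
  set.seed(37)
  for (i in 1:20) {
    template <- rand_dna(300)
    primer <- substr(template, 101, 120)
    a <- binds(primer, template, 2, 3, all = TRUE)
    b <- binds(primer, revcomp(template), 2, 3, all = TRUE)
    expect_equal(nrow(a), nrow(b))
    # mirrored coordinates: start' = len - (start + L)
    expect_setequal(300 - (a$start + nchar(primer)), b$start)
    expect_setequal(a$strand,
                    chartr("+-", "-+", b$strand))
  }
})

test_that("candidate enumeration is exhaustive, filtered and ordered", {
  # an unambiguous 21-column window emits exactly forward + reverse when
  # physical filters are disabled
  win <- data.frame(window_id = "w01", start = 100L, end = 121L,
                    mean_cons = 1, consensus = "GTCTGTAACTGACGCTGAGGC",
                    stringsAsFactors = FALSE)
  loose <- design_params(Lmin = 21L, Lmax = 21L, gc_min = 0, gc_max = 1,
                         tm_min = -100, tm_max = 200,
                         max_homopolymer = 25L, gc_clamp = FALSE)
  cands <- enumerate_candidates(win, loose)
  expect_equal(nrow(cands), 2L)
  expect_equal(cands$orientation, c("forward", "reverse"))
  expect_equal(cands$seq[1], win$consensus)
  expect_equal(cands$seq[2], revcomp(win$consensus))
  expect_equal(cands$aln_start, c(100L, 100L))

  # window shorter than Lmin yields nothing
  short <- data.frame(window_id = "w01", start = 0L, end = 10L,
                      mean_cons = 1, consensus = "ACGTACGTAC",
                      stringsAsFactors = FALSE)
  expect_equal(nrow(enumerate_candidates(short, design_params())), 0L)

  # substring counting: 24-column window, lengths 18-20, no filters
  win24 <- data.frame(window_id = "w01", start = 0L, end = 24L,
                      mean_cons = 1, consensus = rand_dna(24),
                      stringsAsFactors = FALSE)
  loose2 <- design_params(Lmin = 18L, Lmax = 20L, gc_min = 0, gc_max = 1,
                          tm_min = -100, tm_max = 200,
                          max_homopolymer = 25L, gc_clamp = FALSE)
  expect_equal(nrow(enumerate_candidates(win24, loose2)), (7 + 6 + 5) * 2)
})

test_that("specificity reports exact binding fractions", {
  set.seed(43)
  shared <- rand_dna(25)
  ingroup <- data.frame(
    id = paste0("in", 1:10),
    seq = replicate(10, paste0(rand_dna(80), shared, rand_dna(80))),
    stringsAsFactors = FALSE)
  outgroup <- data.frame(id = paste0("out", 1:10),
                         seq = replicate(10, rand_dna(185)),
                         stringsAsFactors = FALSE)
  cand <- data.frame(cand_id = "c1", seq = substr(shared, 1, 20),
                     window_id = "w01", aln_start = 0L, aln_end = 20L,
                     orientation = "forward", length = 20L,
                     ingroup_cov = NA_real_, outgroup_hit = NA_real_,
                     stringsAsFactors = FALSE)
  sc <- specificity(cand, ingroup, outgroup)
  expect_equal(sc$ingroup_cov, 1.0)
  expect_equal(sc$outgroup_hit, 0.0)

  # 8 of 10 in-group carry the site
  ingroup$seq[1:2] <- replicate(2, rand_dna(185))
  sc2 <- specificity(cand, ingroup, outgroup)
  expect_equal(sc2$ingroup_cov, 0.8)

  expect_warning(specificity(cand, ingroup, NULL), "out-group")
})

test_that("with out-group equal to in-group, hit equals coverage", {
  set.seed(47)
  shared <- rand_dna(30)
  grp <- data.frame(
    id = paste0("t", 1:6),
    seq = replicate(6, paste0(rand_dna(50), shared, rand_dna(50))),
    stringsAsFactors = FALSE)
  cand <- data.frame(cand_id = "c1", seq = substr(shared, 3, 24),
                     window_id = "w01", aln_start = 0L, aln_end = 22L,
                     orientation = "forward", length = 22L,
                     ingroup_cov = NA_real_, outgroup_hit = NA_real_,
                     stringsAsFactors = FALSE)
  sc <- specificity(cand, grp, grp)
  expect_equal(sc$outgroup_hit, sc$ingroup_cov)
})

test_that("pairing respects product bounds and coverage accounting", {
  set.seed(53)
  w1 <- rand_dna(24); w2 <- rand_dna(24)
  mid <- rand_dna(460)
  templates <- data.frame(
    id = paste0("t", 1:5),
    seq = vapply(1:5, function(i)
      paste0(rand_dna(20), w1, mid, w2, rand_dna(20)), character(1)),
    stringsAsFactors = FALSE)
  cands <- data.frame(
    cand_id = c("f1", "r1"),
    seq = c(substr(w1, 1, 20), revcomp(substr(w2, 5, 24))),
    window_id = c("wA", "wB"),
    aln_start = c(20L, 528L), aln_end = c(40L, 548L),
    orientation = c("forward", "reverse"), length = c(20L, 20L),
    tm_celsius = c(60, 60), ingroup_cov = c(1, 1),
    outgroup_hit = c(0, 0), stringsAsFactors = FALSE)
  params <- design_params(prod_min = 400L, prod_max = 700L)
  pairs <- pair_and_rank(cands, templates, NULL, params)
  expect_equal(nrow(pairs), 1L)
  expect_equal(pairs$pair_ingroup_cov, 1.0)
  # product spans fwd footprint start [20] to rev footprint end [508+20)
  expect_equal(pairs$product_min, 508L)
  # same geometry with tight bounds yields nothing
  expect_warning(
    none <- pair_and_rank(cands, templates, NULL,
                          design_params(prod_min = 100L, prod_max = 300L)),
    "no primer pair")
  expect_equal(nrow(none), 0L)
  expect_true(!is.null(attr(none, "diagnostics")))
})

test_that("pair coverage never exceeds either member's coverage", {
  set.seed(59)
  for (i in 1:5) {
    cfg <- sim_config(seed = 100 + i, n_genera = 2,
                      n_species_per_genus = 4, n_seqs_per_species = 1,
                      universal_windows = list())
    panel <- simulate_genus_panel(cfg)
    pairs <- suppressWarnings(
      design_pairs(panel$aln, panel$ingroup, panel$outgroup))
    if (nrow(pairs) == 0) next
    cands <- attr(pairs, "candidates")
    cov <- setNames(cands$ingroup_cov, cands$cand_id)
    expect_true(all(pairs$pair_ingroup_cov <=
                      pmin(cov[pairs$fwd_id], cov[pairs$rev_id]) + 1e-12))
  }
})
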