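mk_refs <- function(n = 4, len = 400, seed = 1) {
  set.seed(seed)
  data.frame(id = paste0("ref", seq_len(n)),
             genus = paste0("Genus", LETTERS[seq_len(n)]),
             species = paste0("Genus", LETTERS[seq_len(n)], " sp1"),
             seq = replicate(n, rand_dna(len)),
             stringsAsFactors = FALSE)
}

test_that("a read equal to a reference substring is a perfect hit", {
  refs <- mk_refs()
  read <- data.frame(id = "r1", seq = substr(refs$seq[2], 101, 300),
                     stringsAsFactors = FALSE)
  asg <- assign_reads(read, refs)
  expect_equal(asg$identity, 1.0)
  expect_equal(asg$genus, "GenusB")
  expect_equal(asg$species, "GenusB sp1")
  expect_equal(asg$status, "assigned")
  # same read reverse-complemented scores identically
  asg_rc <- assign_reads(data.frame(id = "r1", seq = revcomp(read$seq)),
                         refs)
  expect_equal(asg_rc$identity, 1.0)
  expect_equal(asg_rc$genus, "GenusB")
})

test_that("random reads stay unassigned at a 0.90 identity threshold", {
  set.seed(83)
  refs <- mk_refs()
  reads <- data.frame(id = paste0("r", 1:20),
                      seq = replicate(20, rand_dna(150)),
                      stringsAsFactors = FALSE)
  asg <- assign_reads(reads, refs)
  expect_true(all(asg$status == "unassigned"))
  expect_true(all(asg$genus == ""))
  expect_error(assign_reads(reads, refs[0, ]), class = "gp_config_error")
})

test_that("identity agrees with a full-alignment oracle on noisy reads", {
  set.seed(89)
  refs <- mk_refs(n = 3, len = 500, seed = 89)
  for (i in 1:100) {
    ref_i <- sample(3, 1)
    at <- sample(300, 1)
    rlen <- sample(80:150, 1)
    read <- substr(refs$seq[ref_i], at, at + rlen - 1)
    ch <- strsplit(read, "")[[1]]
    # up to 10% errors, substitution-biased with a few indels
    nerr <- rpois(1, 0.05 * length(ch))
    for (j in sample(length(ch), min(nerr, length(ch)))) {
      ch[j] <- sample(setdiff(c("A", "C", "G", "T"), ch[j]), 1)
    }
    if (runif(1) < 0.3) ch <- ch[-sample(length(ch), 1)]      # deletion
    if (runif(1) < 0.3) {                                     # insertion
      at2 <- sample(length(ch), 1)
      ch <- append(ch, sample(c("A", "C", "G", "T"), 1), after = at2)
    }
    read <- paste(ch, collapse = "")
    asg <- assign_reads(data.frame(id = "r", seq = read), refs,
                        genus_thr = 0)
    want <- max(vapply(refs$seq, function(rs)
      max(oracle_semiglobal_identity(read, rs),
          oracle_semiglobal_identity(revcomp(read), rs)), numeric(1)))
    expect_equal(asg$identity, want, tolerance = 1e-9)
  }
})

test_that("effective rate counts target-genus reads over all reads", {
  asg <- data.frame(
    read_id = paste0("r", 1:10),
    ref_id = NA_character_,
    genus = c(rep("Bacillus", 8), "Other", ""),
    species = c(rep("Bacillus velezensis", 5), rep("", 5)),
    identity = 0.99,
    status = c(rep("assigned", 9), "unassigned"),
    stringsAsFactors = FALSE)
  r <- effective_rate(asg, "Bacillus")
  expect_equal(r$effective_rate, 0.8)
  expect_equal(r$n_assigned_target, 8L)
  # denominator switch
  r2 <- effective_rate(asg, "Bacillus", denominator = "assigned")
  expect_equal(r2$effective_rate, 8 / 9)
  # zero hits
  r0 <- effective_rate(asg, "Absent")
  expect_equal(r0$effective_rate, 0)
  expect_error(effective_rate(asg[0, ], "Bacillus"),
               class = "gp_undefined_rate")
})

test_that("genus abundance fractions over assigned reads sum to one", {
  set.seed(97)
  cfg <- sim_config(seed = 550, n_genera = 3, n_species_per_genus = 3,
                    n_seqs_per_species = 1,
                    composition = c(GenusA = 0.5, GenusB = 0.3,
                                    GenusC = 0.2))
  panel <- simulate_genus_panel(cfg)
  up <- universal_primers(panel)
  rs <- simulate_reads(panel$templates, up$fwd, up$rev, cfg, n_reads = 200)
  refs <- panel$templates[!duplicated(panel$templates$species), ]
  asg <- assign_reads(rs$reads, refs)
  r <- effective_rate(asg, "GenusA")
  expect_equal(sum(unlist(r$abundance$genus)), 1, tolerance = 1e-9)
  expect_lte(sum(unlist(r$abundance$species)), 1 + 1e-9)
  # invariance to read order
  perm <- sample(nrow(asg))
  expect_equal(effective_rate(asg[perm, ], "GenusA")$effective_rate,
               r$effective_rate)
})

test_that("raising the genus threshold never raises the rate", {
  set.seed(101)
  cfg <- sim_config(seed = 660, n_genera = 2, n_species_per_genus = 3,
                    n_seqs_per_species = 1, read_error = 0.08)
  panel <- simulate_genus_panel(cfg)
  up <- universal_primers(panel)
  rs <- simulate_reads(panel$templates, up$fwd, up$rev, cfg, n_reads = 150)
  refs <- panel$templates[!duplicated(panel$templates$species), ]
  rates <- vapply(c(0.80, 0.90, 0.95, 0.99), function(thr) {
    asg <- assign_reads(rs$reads, refs, genus_thr = thr)
    effective_rate(asg, "GenusA")$effective_rate
  }, numeric(1))
  expect_true(all(diff(rates) <= 1e-12))
})
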