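test_that("FASTA taxonomy headers parse under each convention", {
  f <- write_tmp(c(
    ">s1 tax=g:Bacillus,s:Bacillus velezensis", "ACGTACGT",
    ">s2", "acguacgu",
    ">s3 Bacteria;Firmicutes;Bacilli;Bacillaceae;Bacillus;Bacillus subtilis",
    "ACGTNRYA"))
  recs <- read_fasta(f, header_convention = "tax")
  expect_equal(recs$id, c("s1", "s2", "s3"))
  expect_equal(recs$genus[1], "Bacillus")
  expect_equal(recs$species[1], "Bacillus velezensis")
  expect_equal(recs$genus[2], "")
  expect_equal(recs$species[2], "")
  # lowercase uppercased, U mapped to T
  expect_equal(recs$seq[2], "ACGTACGT")
  # IUPAC codes allowed
  expect_equal(recs$seq[3], "ACGTNRYA")

  none <- read_fasta(f, header_convention = "none")
  expect_true(all(none$genus == ""))

  lin <- read_fasta(f, header_convention = "lineage")
  expect_equal(lin$genus[3], "Bacillus")
  expect_equal(lin$species[3], "Bacillus subtilis")
})

test_that("FASTA round-trip is identity on id, labels and sequence", {
  recs <- data.frame(
    id = c("a", "b", "c"),
    genus = c("Bacillus", "", "Acinetobacter"),
    species = c("Bacillus subtilis", "", ""),
    seq = c(rand_dna(150), rand_dna(71), rand_dna(70)),
    stringsAsFactors = FALSE)
  f <- tempfile(fileext = ".fasta")
  write_fasta(recs, f)
  back <- read_fasta(f)
  expect_equal(back, recs)
})

test_that("malformed and empty FASTA raise classed errors", {
  expect_error(read_fasta(write_tmp(c("ACGT", ">s1", "ACGT"))),
               class = "gp_format_error")
  expect_error(read_fasta(write_tmp(character(0))),
               class = "gp_empty_input")
  # gap characters rejected in unaligned input
  expect_error(read_fasta(write_tmp(c(">s1", "AC-GT"))),
               class = "gp_format_error")
  # duplicate ids rejected
  expect_error(read_fasta(write_tmp(c(">s1", "ACGT", ">s1", "ACGT"))),
               class = "gp_format_error")
})

test_that("aligned FASTA parses with equal-length gapped rows", {
  f <- write_tmp(c(">r1", "AC-GT", ">r2", "ACAGT"))
  aln <- read_alignment(f, "fasta")
  expect_s3_class(aln, "gp_alignment")
  expect_equal(aln$n_cols, 5L)
  expect_equal(aln$seq, c("AC-GT", "ACAGT"))
  expect_error(read_alignment(write_tmp(c(">r1", "ACGTA", ">r2", "ACGTAA")),
                              "fasta"),
               class = "gp_format_error")
})

test_that("interleaved Clustal blocks concatenate per row id", {
  block1 <- strrep("ACGT", 15)  # 60 columns
  block2 <- strrep("TGCA", 15)
  pad <- function(nm, s) sprintf("%-16s%s", nm, s)
  f <- write_tmp(c("CLUSTAL W (1.83) multiple sequence alignment", "",
                   pad("seq1", block1), pad("seq2", block1), "",
                   pad("seq1", block2), pad("seq2", block2), ""))
  aln <- read_alignment(f, "clustal")
  expect_equal(aln$n_cols, 120L)
  expect_equal(aln$id, c("seq1", "seq2"))
  expect_equal(aln$seq[1], paste0(block1, block2))
})

test_that("read files are sniffed as FASTA or FASTQ", {
  fq <- write_tmp(c("@r1", "ACGTACGTAA", "+", "IIIIIIIIII",
                    "@r2", "TTGGCCAATT", "+", "FFFFFFFFFF"))
  reads <- read_reads(fq)
  expect_equal(nrow(reads), 2L)
  expect_equal(reads$qual, c("IIIIIIIIII", "FFFFFFFFFF"))

  fa <- write_tmp(c(">r1", "ACGTACGTAA", ">r2", "TTGGCCAATT"))
  reads_fa <- read_reads(fa)
  expect_equal(reads_fa$seq, reads$seq)
  expect_true(all(is.na(reads_fa$qual)))

  expect_error(read_reads(write_tmp(c("r1", "ACGT"))),
               class = "gp_format_error")
  expect_error(read_reads(write_tmp(character(0))),
               class = "gp_empty_input")
})

test_that("write_table emits a deterministic header TSV", {
  df <- data.frame(x = c("a", "b"), n = c(1L, 2L))
  f <- tempfile(fileext = ".tsv")
  write_table(df, f)
  lines <- readLines(f)
  expect_equal(lines[1], "x\tn")
  expect_equal(lines[2], "a\t1")
})

test_that("alignment rows stay equal length across random parse paths", {
  set.seed(41)
  for (i in 1:20) {
    n_rows <- sample(2:6, 1)
    n_cols <- sample(10:40, 1)
    rows <- vapply(seq_len(n_rows), function(j) {
      s <- strsplit(rand_dna(n_cols), "")[[1]]
      s[runif(n_cols) < 0.15] <- "-"
      paste(s, collapse = "")
    }, character(1))
    # keep at least one non-gap character per row
    rows <- vapply(rows, function(r)
      if (gsub("-", "", r) == "") sub("-", "A", r) else r, character(1))
    f <- write_tmp(as.vector(rbind(paste0(">r", seq_len(n_rows)), rows)))
    aln <- read_alignment(f, "fasta")
    expect_equal(rep(aln$n_cols, n_rows), nchar(aln$seq))
  }
})
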