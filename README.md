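# genusprimer

Design and validate **genus-specific 16S rRNA PCR primer pairs**, and
quantify how well they detect a target genus in amplicon sequencing data.

Culture-based counting and whole-community metabarcoding are both poor fits
when a workflow needs to ask a narrow question such as *"which Bacillus (or
Acinetobacter) species are in this fermentation starter, and how much of the
signal do they carry?"*. A practical alternative is genus-specific PCR: find
regions of the 16S rRNA gene that are conserved within the target genus but
divergent outside it, design a primer pair there, amplify, sequence the
amplicons, and measure what fraction of the reads actually belongs to the
genus. `genusprimer` implements that whole dry-lab loop:

* **Conservation analysis** — per-column profiles over an in-group
  alignment. The conservation score of a column is the modal-base fraction
  `c_j = max_b n_jb / Σ_b n_jb` over unambiguous bases (an entropy score
  `1 − H_j/2` is available as an alternative); maximal runs with
  `c_j ≥ τ` (default 0.90) and gap fraction `≤ γ` (default 0.10) of primer
  length or more become candidate windows with IUPAC consensus.
* **Primer design** — exhaustive enumeration of window-consensus substrings
  (18–25 nt) under standard physical filters (GC 0.40–0.60, Tm 55–65 °C,
  homopolymers ≤ 4, ≤ 2 degenerate positions, 3′ G/C clamp), then genus
  specificity scored per primer and per pair as *in-group coverage* vs
  *out-group hit rate* under a PCR-relevant binding model: at most
  `max_mm = 2` IUPAC-incompatible positions and a perfectly matched
  3′-terminal triplet. Pairs are ranked by (out-group hit ↑, in-group
  coverage ↓, |ΔTm| ↑, distance from the target product size ↑).
* **Oligo thermodynamics** — unified nearest-neighbor melting temperature
  `Tm = ΔH·1000 / (ΔS + 0.368·(N−1)·ln[Na⁺] + R·ln(C_T/4)) − 273.15`
  with the frozen stack/initiation parameter table in
  `R/thermo-constants.R`, plus GC, homopolymer, primer-dimer and hairpin
  screens, and an annealing recommendation (min Tm − 5 °C).
* **In-silico PCR** — exhaustive convergent-site search on both strands;
  every (plus-strand site, downstream minus-strand site) combination within
  the product-size bounds becomes a predicted amplicon whose length
  includes both primer footprints (what a gel would show), plus a
  "virtual gel" band report.
* **Read classification and the effective amplification rate** — amplicon
  reads are assigned to genus/species by best-hit identity against a
  labeled reference panel (k-mer prefilter, banded semi-global alignment,
  identity thresholds 0.90 / 0.97), and the *effective amplification rate*
  of a target genus is the fraction of reads assigned to it — the
  statistic used to judge a genus-specific assay on real sequencing runs.
* **A seeded simulator** of 16S-like sequence families — shared ~1.5 kb
  backbone, universally conserved windows, genus-private conserved
  signature windows embedded in hypervariable regions, species-level point
  variation, and error-bearing mock-community reads with full ground
  truth — so the entire pipeline is testable end to end without downloads.

All coordinates in all outputs are 0-based, half-open, on the plus strand
of the named template.

## Worked example

Predict the products of the published *Bacillus*-specific pair
(F `GTCTGTAACTGACGCTGAGGC` / R `GCGATTACTAGCGATTCCA`) on the packaged
template (a synthetic stand-in for a full-length *B. subtilis* 16S gene —
see `inst/extdata/`):

```r
library(genusprimer)
primers  <- read.delim(system.file("extdata", "published_primer_pairs.tsv",
                                   package = "genusprimer"))
template <- read_fasta(system.file("extdata",
                                   "synthetic_bacillus_16S_template.fasta",
                                   package = "genusprimer"))
simulate_pcr(primers$fwd[1], primers$rev[1], template)[, 1:4]
#>               template_id start end length
#> 1 synthetic_Bsubtilis_16S   300 926    626

tm_nn(primers$fwd[1])                          # 58.26 °C
tm_nn(primers$rev[1])                          # 52.54 °C
recommend_annealing(58.26, 52.54)              # 48 °C
```

One product of 626 bp and no off-target product on the *Acinetobacter*
template — the in-silico analogue of a single clean gel band. Designing
fresh genus-specific pairs on the packaged example panel (10 in-group +
10 out-group simulated 16S-like genes):

```r
aln   <- read_alignment(system.file("extdata", "example_ingroup.fasta",
                                    package = "genusprimer"), "fasta")
outg  <- read_fasta(system.file("extdata", "example_outgroup.fasta",
                                package = "genusprimer"))
pairs <- design_pairs(aln, outgroup = outg)
head(pairs[, c("rank", "fwd_seq", "rev_seq", "product_min",
               "pair_ingroup_cov", "pair_outgroup_hit", "genus_specific")], 3)
#>   rank                  fwd_seq                   rev_seq product_min
#> 1    1    AAATGCGCGATCGGAATCGCG ACGGGAAGTCAGGCTACGAACCTAG         521
#> 2    2 GCCTGTTGACGTCAGGCAACCTTG CGCGGCGAAAGGATGGTACAACAAG         772
#> 3    3     AGAAATGCGCGATCGGAATC       ACACGGGAAGTCAGGCTAC         525
#>   pair_ingroup_cov pair_outgroup_hit genus_specific
#> 1                1                 0           TRUE
#> 2                1                 0           TRUE
#> 3                1                 0           TRUE
```

The top pair binds every in-group sequence, no out-group sequence, and is
flagged `genus_specific` (coverage ≥ 0.90, out-group hit ≤ 0.05).

The same steps are scriptable through the thin CLI in `exec/`:

```sh
exec/genusprimer design --ingroup in.fasta --outgroup out.fasta --out pairs.tsv
exec/genusprimer pcr --fwd GTCTGTAACTGACGCTGAGGC --rev GCGATTACTAGCGATTCCA \
    --templates db.fasta --out amplicons.fasta --report bands.tsv
exec/genusprimer run-all --seed 1 --out-dir gp-out     # simulate → rate
```

Exit codes: 0 ok, 2 config error, 3 format error, 4 empty result.

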