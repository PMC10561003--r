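---
title: "Genus-specific 16S primer design: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genus-specific 16S primer design: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(genusprimer)
```

`genusprimer` turns the informal recipe behind genus-specific 16S assays —
"align the in-group, find the conserved regions, put primers there, check
they hit nothing else, sequence the products and count" — into explicit,
testable operations. This vignette records the models, the defaults and
the reasoning behind the choices that were genuinely open.

## The conservation model

Given an in-group multiple sequence alignment, each column *j* gets

* base counts `n_jb` over unambiguous A/C/G/T characters,
* a gap fraction over all rows, and
* a conservation score `c_j = max_b n_jb / Σ_b n_jb` — the modal-base
  fraction.

The modal-base fraction was chosen over an entropy score because it has a
direct operational meaning for primer design: it is the fraction of
in-group sequences a consensus base will match at that column. An entropy
alternative (`1 − H_j/2`, H in bits) is exposed via
`conserved_windows(..., score = "entropy")` for users who want rare
variants weighted more smoothly; the default pipeline does not use it.

IUPAC ambiguity codes in input rows contribute to neither the base counts
nor the gap count. Ambiguity in a deposited sequence is ignorance about
the base, not evidence for any of them; counting codes fractionally would
let a handful of sloppy submissions dilute (or inflate) conservation.
A column containing only ambiguity codes scores 0. A consequence worth
knowing: the denominator of `c_j` is the unambiguous-character count, so
a column that is `A` in 4 rows and `N` in 6 rows still scores 1.0.

Conserved windows are maximal runs with `c_j ≥ τ` and gap fraction
`≤ γ`, at least `min_len` columns long. Defaults: `τ = 0.90`,
`γ = 0.10`, `min_len = 18` — a primer must fit inside a window, and 0.90
mirrors the conventional genus-level identity neighborhood of 16S data.
The window consensus emits, per column, the IUPAC code covering exactly
the bases with frequency `≥ min_freq` (default 0.70) among unambiguous
characters; when no base reaches the threshold the code covers all
observed bases. Consensus never emits gaps, and an all-gap column inside
a requested window is an error rather than a silent placeholder.

## Oligo thermodynamics

Melting temperatures use the unified nearest-neighbor model:

\[ T_m = \frac{\Delta H \cdot 1000}
             {\Delta S + 0.368\,(N-1)\ln[\mathrm{Na}^+] + R \ln(C_T/4)}
        - 273.15 \]

with ΔH (kcal/mol) and ΔS (cal/mol·K) summed over dinucleotide stacks
plus two terminal initiation terms. The parameter table is frozen in
`R/thermo-constants.R`; the test suite holds `tm_nn()` to an
independently coded table summation to < 0.01 °C, so the table cannot
drift silently. Default conditions are 50 mM monovalent Na⁺ and 500 nM
total oligo (`C_T/4` assumes the primer–template duplex of two different,
equimolar strands); there is no divalent-cation correction — both are
stated limitations, overridable per call. Degenerate oligos are scored by
the worst case (minimum Tm, extreme GC, longest homopolymer) over their
expansions, capped at 64 expansions: conservative and bounded.

The annealing recommendation is the standard bench rule
`min(Tm_fwd, Tm_rev) − 5 °C`, rounded. It is a starting point for a
gradient, not a substitute for one; empirically chosen annealing
temperatures on real instruments routinely sit a few degrees away from
any NN-model recommendation.

## The binding model and "genus specificity"

Published descriptions of genus-specific design are usually qualitative
("high homology inside the genus, little outside"). The toolkit
operationalizes homology as PCR-relevant binding: a primer binds a
template site when at most `max_mm = 2` positions are IUPAC-incompatible
**and** the `three_prime_exact = 3` terminal bases of the primer match
perfectly, because extension initiates at the 3′ end and terminal
mismatches are what actually kill amplification. Both strands are scanned
at every offset; for degenerate primers, compatibility means non-empty
intersection of the IUPAC sets.

Specificity is then measured, not asserted: `ingroup_cov` is the fraction
of in-group templates with at least one qualifying site, `outgroup_hit`
the same fraction over the out-group, and for pairs both are recomputed
at the pair level — a template counts only when both primers bind
convergently with an in-bounds product. A pair is flagged
`genus_specific` when pair coverage ≥ 0.90 and pair out-group hit
≤ 0.05, a quantitative rendering of the qualitative claim. Whether an
out-group was used at all is always the caller's decision; an empty
out-group yields hit 0 with a loud warning rather than an error.

Candidates are enumerated from window consensus rather than per sequence.
This keeps the search space bounded and deterministic; per-sequence
binding is still what the coverage numbers measure, so a consensus
candidate that fails to bind divergent in-group members is penalized
where it matters.

Ranking is lexicographic: out-group hit ascending, in-group coverage
descending, |ΔTm| ascending, |mean product − 600 bp| ascending, then
primer sequences. Product bounds default to [300, 1000] bp with a 600 bp
target — the size range in which genus-diagnostic 16S products are
usually run on gels and sequenced. There is no randomness anywhere in
design; identical inputs give identical rankings.

## In-silico PCR

`simulate_pcr()` reports every convergent site combination within the
size bounds, with either primer allowed to play either role on either
strand. Amplicon coordinates include both primer footprints, so reported
lengths are gel lengths. "Specific" in reports means exactly one product
per in-group template and none on the out-group. Circular templates are
not supported (16S amplicons do not need them). The implementation is
held to an exhaustive double-loop oracle over all offsets and strands in
the test suite.

## Read classification and the effective amplification rate

Reads are assigned by best-hit identity against a labeled reference
panel: a k-mer prefilter (k = 12, top 10 references sharing at least one
k-mer, both orientations) followed by a banded semi-global alignment —
the read end-to-end, the reference window free at both ends, unit edit
costs, band half-width 48 around the modal shared-k-mer diagonal.
Identity is `1 − distance / read length`. Thresholds follow 16S
convention: genus at 0.90, species at 0.97. Ties go to the earlier
reference in panel order, deterministically. The banded implementation is
checked against a full unbanded alignment oracle on noisy reads.

The effective amplification rate of a target genus is the fraction of
reads assigned to that genus. The denominator is ALL input reads by
default — the conservative reading, under which unclassifiable reads
count against the assay — with `denominator = "assigned"` as the
alternative for comparison with pipelines that discard unassigned reads
first. Published values of such rates rarely state their denominator;
when comparing, check this switch first.

## What the simulator emulates — and what it does not

`sim_config()` / `simulate_genus_panel()` generate 16S-like families: a
random ~1.5 kb backbone shared by all genera; *universal windows*
(default two 30 bp windows) kept identical everywhere, standing in for
the universally conserved regions that universal primers exploit;
per-genus *signature windows* (default two per genus) carrying fresh
GC-balanced random sequence, private to the genus and kept exact within
it; hypervariable flanks (default 40 bp at substitution rate 0.40)
around every signature window, because real genus-diagnostic signatures
are conserved islands inside hypervariable regions and in-group
conservation should fall off sharply at their boundaries; genus-level
divergence (default 0.02 per site) and species-level variation (default
0.05 per site) elsewhere. Signatures are drawn GC-balanced so that a
planted window is primer-compatible by construction — the generator's
purpose is to plant recoverable truth, not to model signature base
composition. Reads are drawn from in-silico amplicons in planted genus
proportions with per-base substitution errors (default 0.01), matching
typical post-filtering amplicon error rates.

The mutation model is substitution-only. This is a deliberate trade: with
no indels the true alignment is the trivial columnwise one, so
conservation ground truth is exact and free. The cost is realism —
real 16S families contain indels, chimeras, variable gene copies and
composition biases the simulator does not model. Passing the simulation
studies therefore demonstrates that the algorithms recover planted
structure under controlled noise, not that any particular wet-lab assay
will achieve a given rate. An indel-aware mode is the natural extension
point; the classifier already tolerates indels (banded alignment), so
only the generator and the alignment bookkeeping would change.

## Validation studies and the problem sizes used

Three simulation studies back the package's claims; their sizes were
chosen to exercise the statistics at meaningful resolution while keeping
a full check runnable on a laptop:

* **Mock-community recovery** — 20 seeds × 1000 reads, 80% target genus,
  1% read error, panels of 2 genera × 5 species; the recovered effective
  rate is required to sit within 3 binomial standard deviations of 0.80
  in at least 19 of 20 seeds.
* **Planted-signature recovery** — 100 seeds of two-genus panels
  (10 species per genus, one sequence per species) in which everything
  outside two planted 36 bp signature windows per genus is hypervariable
  (substitution rate 0.40), so the planted windows are the only conserved
  windows — the regime the recovery property is about. The top-ranked
  pair must lie inside the planted windows with pair coverage ≥ 0.90 and
  zero out-group hits in ≥ 95 seeds. The residual failures are panels
  whose random signature content yields no filter-passing candidate in
  one window, plus occasional one-column chance-conservation extensions
  of a window boundary.
* **Oracle equivalence** — exhaustive brute-force re-implementations of
  site search, product enumeration and window extraction, plus the
  independent Tm summation, on hundreds of randomized cases.

`scripts/acceptance.R` reruns compact versions of these from scratch
(20 mock seeds, 50 recovery seeds) together with the packaged worked
example, and writes the numbers as JSON.

## Numerical and degenerate-input conventions

* Coordinates: 0-based, half-open, plus strand, everywhere.
* Site ties in `binds()` resolve to fewest mismatches, then plus strand,
  then leftmost start. A minus-strand site's `start` is the leftmost
  plus-strand coordinate of the footprint, keeping
  `0 ≤ start ≤ len − L` uniform across strands (the primer's 5′-most
  base is then the rightmost footprint base on that strand).
* Empty inputs are classed errors (`gp_empty_input`), malformed files are
  `gp_format_error`, bad parameters are `gp_config_error`; the CLI maps
  these to exit codes 3/3/2, and "ran fine but found nothing" to 4,
  so scripts can tell failure from absence.
* `U` is normalized to `T` and lowercase to uppercase on read; gap
  characters are rejected in unaligned input. Unaligned matchers never
  see gaps.
* The dumped YAML config reloads to an equal object, and unknown keys are
  rejected by name — a typo in a config dies loudly instead of silently
  running defaults.
* Manifests contain artifact names, MD5 checksums, counts, parameters and
  the seed — no timestamps, no absolute paths — so a rerun with the same
  config and seed is byte-identical.

## Known limitations

* The Tm model has no divalent (Mg²⁺/dNTP) correction; recommendations at
  bench buffer compositions will differ by a few degrees.
* Thermodynamic filtering of binding sites is mismatch-count-based, not
  ΔG-based; a stability-weighted site model is a possible refinement.
* The classifier's identity denominator is read length, which slightly
  penalizes long insertions in reads relative to an alignment-length
  denominator.
* The simulator's substitution-only model and flat per-site rates are a
  testability device, not a phylogenetic model; do not use it to
  benchmark taxonomic classifiers against real-data error structure.
* Reproducing published effective-amplification-rate values for a real
  assay requires that assay's reads and reference panel; the package
  computes the statistic but cannot conjure the data.
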