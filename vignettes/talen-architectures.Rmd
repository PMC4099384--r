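---
title: "Geometry and analysis of paired TALE-FokI nuclease architectures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometry and analysis of paired TALE-FokI nuclease architectures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(talenarch)
```

## The model

A TALE nuclease monomer is a TALE DNA-binding array fused to the FokI
catalytic domain. The array reads one base per repeat through its
repeat-variable di-residues under the canonical code (NI:A, HD:C, NN:G,
NG:T), and requires a thymine — the T0 — immediately 5' of the recognised
sequence on the bound strand. Because FokI only cuts as a dimer, nucleases
work as pairs, and the fusion topology of each monomer fixes where its
FokI domain can reach:

* `TALE_FOKI` ("tail" fusion, FokI at the TALE C-terminus) reaches the
  spacer close to its own binding site;
* `FOKI_TALE` ("head" fusion, FokI at the TALE N-terminus) reaches further
  into the spacer.

Three pair geometries follow. The classical **TtT** pair puts two tail
fusions on opposite strands with T0s distal to the spacer; the **HtH**
pair puts two head fusions on opposite strands with T0s adjacent to the
spacer; the asymmetric **TtH** pair puts one tail and one head fusion in
tandem *on the same strand*. Only TtH needs thymines on a single strand,
which is what lets it reach loci such as (CAG)n, (CTG)n, (GAA)n and
(CCTG)n expansions whose forward strand is thymine-free.

### The additive cleavage-offset model

We model each scaffold as cutting at a fixed distance from the
spacer-proximal edge of its binding site: 7.5 bp for `TALE_FOKI` and
12.5 bp for `FOKI_TALE`. The dimer's optimal spacer is then simply the sum
of the two offsets:

```{r}
sapply(c("TtT", "TtH", "HtH"), function(a)
  predicted_optimal_spacer(architecture(a)))
```

These two offsets are the unique half-integer pair that reproduces all
three measured optima (15, 20 and 25 bp) simultaneously, and they place
the asymmetric optimum exactly half-way between the symmetric ones. The
model also predicts *where* in the spacer the cut falls: symmetric pairs
cut mid-spacer, while the TtH pair cuts `(7.5 - 12.5)/2 = -2.5` bp left of
the middle, i.e. shifted toward the tail (TALE::FokI) site —
`predicted_cut_center(architecture("TtH"), 20)` gives a relative offset of
-3.0 under the centre convention below. One caveat: the measured
cut-distance ranges (7–8 bp and 12–13 bp) are sometimes quoted with the
scaffold names in the opposite pairing; we follow the additive
arithmetic, which is the only assignment consistent with all three
optima, and treat the reversed pairing as a label swap.

### Spacer-centre convention

Spacer bases are numbered 1..s along the bound strand and the centre is
base `(s+1)/2`: base 8 for s = 15 and base 13 for s = 25 (half-integer for
even s). This base is spacer-relative coordinate 0 for all deletion-centre
statistics. The convention makes the expected centre of a symmetric
architecture's deletions -0.5 rather than 0 for odd spacers — the
"shift close to -1" seen in symmetric data is an artefact of the
convention, while the TtH shift of -3 is real geometry.

## Target scanning

`find_sites()` reports every position with a bound-strand T0 followed by
`L_rec` unambiguous bases; `find_paired_targets()` pairs sites under a
geometry's strand/T0 layout and its spacer windows. Two window presets
ship:

| preset | TtT | HtH | TtH |
|---|---|---|---|
| `results` (activity windows) | 10–27 | 22–27 | 18–22, 27–33 |
| `chr1-scan` (design windows) | 10–16, 20–25 | 22–27 | 17–23, 26–33 |

The two published TtH window sets do not agree with each other; both are
kept as presets, neither privileged. The
`chr1-scan` preset has no separate HtH entry, so HtH keeps its activity
window there. Note the published off-site argument counts 25, 8 and 16
admissible spacers for TtT, HtH and TtH; the printed windows enumerate 18,
6 and 12. The counts evidently come from activity thresholds read off
filter images rather than the printed ranges; `offtarget_ratio()` takes
counts as arguments and does not attempt to re-derive them.

Design choices that were genuinely open:

* **Targetable** is defined at base resolution by footprint membership,
  not cut-site position, because target-devoid regions are a footprint
  notion.
* Overlapping and nested targets are all reported — coverage and
  off-target counting need the complete set. Palindromic self-pairs are
  counted by default (`distinct_monomers = TRUE` excludes them).
* Coordinates are 0-based half-open on the forward strand (BED
  convention); reverse-strand sites carry a strand flag. Half-integer cut
  positions denote between-base boundaries.
* Lowercase (soft-masked) bases are treated as ordinary bases unless
  `respect_mask = TRUE`; ambiguous bases never satisfy T0 and never match
  a recognised base.
* `coverage_scan()` streams long sequences in windows whose overlap is at
  least the maximal footprint and de-duplicates targets found twice, so
  the windowed result provably equals the whole-sequence scan.

We deliberately do not attempt to reproduce published chromosome-1
targetability figures (99.8% covered, 2945 devoid regions): they depend on
an unstated genome build and masking. The scanner is instead validated
against an interval-union oracle on random sequence, and the qualitative
claim — repeat expansions with single-strand thymines are TtT-devoid but
TtH-covered — is asserted directly on (CAG)50.

## Off-target enumeration

Off-site targets of a designed pair combine monomer matches in all three
combinations (L+R, L+L, R+R). Each combination is laid out in the geometry
its scaffold kinds force — FokI dimerisation constrains layout, not
identity: two tails can only meet Tail-to-Tail, two heads Head-to-Head, a
mixed pair Tail-to-Head. Matching is pure Hamming distance over the
recognised bases with a hard T0 requirement (a non-T at T0 disqualifies
rather than counting as a mismatch, reflecting the T0's role as binding
anchor); no position-dependent weighting is applied because none is
established for these scaffolds.

## Indel analysis

Reads are aligned globally (Needleman–Wunsch with affine gaps: match +2,
mismatch -4, gap open -10, gap extend -1; a gap of length L costs
10 + L). Distinct read sequences are aligned once and results fanned back
out, since amplicon sets are dominated by recurrent alleles.

Numerical conventions:

* **Left-normalisation.** Indel placements inside repeated context are
  ambiguous; all calls are slid to their leftmost equivalent placement so
  identical molecules get identical coordinates regardless of aligner
  tie-breaking.
* **Equivalence-class centres.** A left-normalised interval sits at the
  left edge of its micro-homology ambiguity range, which would bias
  deletion-centre means left by about a third of a base on random
  sequence. The reported centre is therefore the midpoint over the
  equivalence class (average of the leftmost and rightmost equivalent
  placements), which is unbiased for the true break position.
* **Analysis window.** Indels are called only within the target footprint
  ± 30 bp (configurable); indels wholly outside are treated as
  sequencing artefacts. Substitutions alone never make a read an event.
* **Event accounting.** Total events = reads - WT. A MIXED read (at least
  one insertion and one deletion) counts once in the total and once in
  each of the insertion and deletion tallies — the only convention under
  which insertions + deletions may exceed totals, as the published
  per-locus tables show. One published row (HtH RAG1) is internally
  inconsistent under any convention and is excluded from validation.
* **Percent formatting.** `format_percent()` mirrors the tables' mixed
  precision (one decimal at ≥ 1%, two significant digits below); all
  comparisons elsewhere use full precision.
* **Degenerate inputs.** Zero reads make the percentage undefined (error);
  fewer than two deletion centres make the variance undefined (error);
  `compare_centers()` refuses two zero-variance groups. Reads shorter than
  half the amplicon are discarded and counted.

Deletion-size profiles (`deletion_size_distribution()`) use per-locus
relative frequencies with a 20-event inclusion threshold and report the
across-locus mean ± sd per size bin. `center_stats()` returns the sample
mean and variance of centres plus the matching unit-area Gaussian summary
curve; `compare_centers()` is a two-sided pooled-variance Student t-test
by default (Welch optional). Published p-values from the wet-lab data
(0.00155, 0.3852) are outcomes of those experiments, not reproducible
quantities; the test implementation is instead verified against a
closed-form pooled-variance oracle.

## The synthetic-data generator

`make_genome()` draws sequence under a base-composition model and plants
tandem-repeat features verbatim. `simulate_reads()` draws, per read: an
event with probability `event_rate`; insertion vs deletion with
probability `p_ins` (default 0.3, near the insertion fraction of the
published TtH rows); geometric deletion lengths with mean 8 bp (most
deletions under 20 bp, consistent with published size profiles);
normal deletion centres around the locus's predicted cut offset with sd
3 bp. Deletions are laid out symmetric about the sampled centre and
clipped to integer endpoints by a seeded unbiased floor/ceil split, so the
analyser's midpoint definition recovers the sampled centre without bias;
deletions that would leave the amplicon are resampled and counted. The
truth table records both the planted placement and its left-normalised
equivalent, so pipeline output can be compared exactly.

What the generator does **not** emulate: platform-specific error profiles
(e.g. pyrosequencing homopolymer errors), PCR chimeras, coverage bias,
micro-homology-directed repair preferences, and multi-event reads beyond
one indel per read. Passing recovery tests therefore demonstrates that the
analysis is a correct inverse of this idealised model, not that it is
robust to every artefact of real amplicon data.

## Validation problem sizes

The shipped checks run the scanner against exhaustive enumeration on 200
random sequences up to 500 bp for all three geometries and against an
interval-union oracle on 100 random 10-kb sequences; the aligner against
an independent quadratic Gotoh implementation on 100 simulated mutant
reads; and parameter recovery on 5000 simulated reads at event rate 0.087
with centre mean -3.0 (the TtH prediction), requiring the recovered rate
inside the 99% binomial interval and the centre mean within three
standard errors. These sizes give stable verdicts at interactive runtimes;
all stochastic checks run under fixed seeds.

## Limitations

* The cleavage-offset model is geometric, not thermodynamic: it predicts
  optimal spacers and cut positions, not activity levels, and says nothing
  about RVD-composition effects on binding.
* Off-target enumeration is exact Hamming matching; it will not rank hits
  by cleavage likelihood.
* The scanner treats every T0-anchored sequence as bindable; real arrays
  have composition constraints (e.g. long G-runs) it ignores.
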