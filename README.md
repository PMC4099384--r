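# talenarch

Design and analysis of paired TALE–FokI nuclease architectures.

TALE nucleases cut DNA as FokI dimers guided by two TALE binding sites.
The classical pair (**TtT**, Tail-to-Tail) and its inverted-fusion
counterpart (**HtH**, Head-to-Head) bind opposite strands, so each needs a
T0 thymine on both strands of the locus. The asymmetric **TtH**
(Tail-to-Head) pair — one TALE::FokI and one FokI::TALE monomer bound in
tandem on the *same* strand — needs thymines on one strand only, which
opens up loci such as (CAG)n/(CTG)n/(GAA)n/(CCTG)n repeat expansions that
are invisible to the classical geometry. This package is for people
designing such nucleases and quantifying what they do: it provides

* the **additive cleavage-offset model**: each scaffold cuts at a fixed
  distance from the spacer-proximal edge of its site (7.5 bp for
  TALE::FokI, 12.5 bp for FokI::TALE), so the optimal spacer of a pair is
  the sum of its two offsets — 15 bp (TtT), 20 bp (TtH), 25 bp (HtH) — and
  the TtH cut centre is shifted ~2–3 bp toward the TALE::FokI site;
* **RVD array design** under the canonical code (NI:A, HD:C, NN:G, NG:T);
* **paired-target scanning** of arbitrary FASTA sequence with
  per-architecture spacer windows, coverage reports and maximal
  target-devoid regions (BED/JSON output);
* **off-target enumeration** for a designed pair under Hamming mismatch
  tolerance, over all monomer combinations (L+R, L+L, R+R) in the
  geometry their scaffold kinds force;
* **amplicon indel analysis**: global affine-gap alignment,
  WT/INS/DEL/MIXED read classification, event accounting in the
  deep-sequencing table convention, deletion-size distributions,
  spacer-centred deletion-centre statistics with Gaussian summaries, and
  pooled-variance location tests;
* a seeded **synthetic-data generator** (genomes with planted repeat
  expansions; reads under a parametric NHEJ indel model with a truth
  table) for end-to-end validation.

## Worked example

```r
library(talenarch)

## RVD array for an 18-bp target
rvd_for_sequence("ATATAAACCTAACCCTCT")
#>  [1] "NI" "NG" "NI" "NG" "NI" "NI" "NI" "HD" "HD" "NG" "NI" "NI" "HD" "HD" "HD"
#> [16] "NG" "HD" "NG"

## the asymmetric architecture and its predicted optimum
architecture("TtH")
#> <TtH architecture: left TALE_FOKI (7.5) / right FOKI_TALE (12.5)>
#> <spacer windows: 18-22, 27-33 bp>
#>   predicted optimal spacer: 20 bp

## targetability of a genome carrying a (CAG)50 expansion
g <- make_genome(20000, seed = 42,
                 features = list(list(motif = "CAG", copies = 50, pos = 10000)))
coverage_scan(g, lapply(c("TtT", "TtH"), architecture))
#> <coverage report: 20000 / 20000 bp covered (100.0000%), 0 devoid region(s)>
#>  arch n_targets covered_bp
#>   TtT     22295      19899
#>   TtH     29846      20000

## the expansion itself is TtT-devoid but TtH-targetable
nrow(find_paired_targets(substring(g, 10001, 10150), architecture("TtT")))
#> [1] 0
nrow(find_paired_targets(substring(g, 10001, 10150), architecture("TtH")))
#> [1] 124

## simulate an amplicon experiment at a TtH locus and analyse it
loc <- simulate_locus(architecture("TtH"), seed = 1)
sim <- simulate_reads(loc, indel_model(event_rate = 0.087), n = 2000, seed = 2)
cls <- classify_reads(align_reads(sim$reads, loc$ref), loc)
summarize_classifications(cls)
#> <mutagenesis: 8.5% events (170/2000 reads; 57 ins, 113 del, 1830 wt)>
center_stats(attr(cls, "deletions")$center)
#> <deletion centres: n=113, mean=-3.035, var=9.191>
```

The recovered event rate (8.5% vs the simulated 8.7%) and deletion-centre
mean (-3.0, the TtH model's predicted offset from the spacer centre) show
the analysis inverting the generative model: deletions cluster 3 bp left
of the spacer centre, toward the TALE::FokI binding site, exactly as the
asymmetric geometry predicts.

A thin shell wrapper over the same functions is installed at
`system.file("scripts", "talenarch", package = "talenarch")` with
subcommands `design`, `scan`, `offtarget`, `indels` and `simulate`; every
run writes a manifest JSON echoing its resolved configuration.

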