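---
title: "Methods: calling and comparing transcript processing sites from dRNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calling and comparing transcript processing sites from dRNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tpsmap)
```

## The signal model

dRNA-seq discriminates RNA 5′ ends by their phosphorylation state. TEX
degrades 5′-monophosphorylated molecules, so a processed 5′ end produces
a pile-up of read starts in the untreated (TEX−) library that largely
disappears after treatment (TEX+), while a primary (5′-PPP) end shows the
opposite pattern. `tpsmap` tests each strand-specific genomic position
for the depletion signature TEX− > TEX+ and calls the significant ones
transcript processing sites (TPS).

The null model treats read-start counts at one position in the two
libraries as independent Poisson draws with locally estimated rates. The
observed difference d = n₋ − n₊ is then Skellam-distributed and the
p-value is the upper tail P(D ≥ d). Modelling the *difference* rather
than a ratio keeps the test well-defined when the TEX+ count is zero,
which is the expected signature at a strong TPS.

### Local background

`local_background()` estimates each library's rate λ as the mean count
over a `background_window` (default 1000 nt, i.e. 500 nt per side)
centered on the focal position, with three guards:

* the focal position is excluded, so a genuine site never contributes to
  its own null;
* window counts above the `winsor_quantile` (default 0.975) empirical
  quantile are capped before averaging, so a handful of neighbouring
  sites cannot inflate λ — in a mostly-zero window even a 1000-count
  spike is capped to the 97.5% quantile;
* λ is floored at `lambda_floor` (default 0.01) so the Skellam test is
  never run with a degenerate zero rate.

The window is truncated at replicon edges (mean over the available
positions). Because each library's λ comes from its own window, library
depth differences are absorbed locally and no explicit size
normalization enters the test; the null stays self-calibrating.

### Test parameters

* `alpha = 1e-9` — a deliberately stringent raw per-position cutoff.
  With ~10⁶–10⁷ testable positions in a prokaryotic genome, a raw
  10⁻⁹ threshold keeps the expected number of false positives well below
  one without a multiplicity correction; an optional Benjamini–Hochberg
  mode (`fdr = TRUE`) exists but is off by default.
* `min_reads = 10` — a position is only evaluated when the favored
  library (TEX− for TPS mode) has at least 10 raw read starts. The
  threshold intentionally applies to the library whose enrichment is
  claimed, not to the pooled pair.
* `cluster_gap = 5` — significant positions within 5 nt are merged into
  one site. "Grouping within 5 nt" is read as *merge if gap ≤ 5*; the
  alternative minimum-separation reading would split chains that this
  implementation merges, which matters only for unusually broad signals.
  The representative is the member with the highest favored count, ties
  resolved toward the 5′-most member relative to the strand, and the
  site p-value is the minimum over members.
* `mode = "TSS"` swaps the library roles, turning the same machinery
  into a conventional enrichment (TSS) caller; the duality is tested.

### Numerical notes

The Skellam survival function is computed by marginalizing over the
TEX+ count with the exact Poisson CDF (`ppois`) in log space; the
mixture is truncated where the remaining Poisson mass is below 10⁻¹⁸.
When d lies below the distribution mean the complementary tail is
computed instead, so values near 1 are exact and d below the reachable
support returns exactly 1. Results are floored at the smallest positive
double, and the BED export caps scores at −log₁₀p = 300. The test suite
checks agreement with an independent joint-enumeration oracle to a
relative error of 10⁻¹⁰ over λ ∈ [0.01, 20], d ∈ [−60, 60], and
stability up to λ = 10⁴, |d| = 10⁵.

## Normalized position and categories

A site at genomic coordinate x in a CDS gets

D = 100 · σ · (x − x_CDSstart) / |x_CDSstart − x_CDSend|,

with σ = +1 for forward and −1 for reverse genes: D = 0 at the first
base of the start codon, D = 100 at the last CDS base, and out-of-bound
sites map to D < 0 (5′) or D > 100 (3′). Two design choices deserve
comment. First, the signed form is used rather than an absolute value:
it is the only reading under which upstream sites can produce negative
D. Second, the denominator is |x_CDSstart − x_CDSend| = length − 1
exactly, so D = 100 falls *on* the last base rather than one past it.
Categories partition the axis with the internal class strict
(25 < D < 75) and the proximal classes owning the boundaries; the
partition is tested at the boundary values and under full
reverse-complementation of the genome.

## Assignment policy

A call is sense-assigned to every same-strand gene whose interval,
extended by 150 nt upstream and 150 nt downstream (strand aware),
contains it; antisense assignment (aTPS) uses the unextended interval.
The 150-nt default reflects the largely leaderless transcription of the
halophile genomes this tool targets (~70% of transcripts start at or
within a few nt of the start codon), so generous UTR allowances are
unnecessary; both extensions are configurable. Overlapping genes are
real, so multi-assignment is allowed and downstream per-gene counts use
distinct loci. Assignment is monotone in the extensions (enlarging them
never removes an assignment), which the suite tests.

## Comparative layers

Conservation uses a one-to-one ortholog table and reports *all*
cross-combinations of sense sites in a gene pair with |D_A − D_B| below
the threshold (default 3, strict inequality; configurable). Reporting
combinations rather than genes is deliberate — a single gene pair can
harbour several conserved processing events — and the distinct-site
count is attached as an attribute. Species-specific internal sites use
the strict internal window on one side and its absence on the other.
Antisense conservation is presence-only (both partners carry ≥ 1 aTPS,
no positional requirement): antisense transcription is poorly conserved
at nucleotide resolution, so co-presence is the meaningful signal.
Sense/antisense coincidences pair opposite-strand sites within 5 nt.

## Quantitative layers

Two library-normalization conventions are provided: `per_million`
(signal integral scaled to 10⁶) and `match_max` (shallower libraries
rescaled to the deepest). Differential processing compares the
read-start signal in a ±2-nt window around each site between two
conditions against the mean signal of the whole CDS, as
pseudocount-stabilized log2 fold-changes; a site is *discordant* when
the two layers move in opposite directions and both exceed an effect
floor (default 1 log2 unit). The rule is deliberately minimal — a sign
test with an effect floor — because the underlying comparison is
qualitative in nature; the defaults are conservative and every knob is
exposed.

Ribo-seq overlap needs a peak definition, and none is standard at this
granularity, so a transparent one is used: a summit is a strict local
maximum over a ±100-nt window with depth ≥ 5 and a z-score ≥ 2 against
the surrounding window (SD floored at 1, focal position excluded,
equal-height ties resolved leftmost). A site overlaps a peak when a
summit lies within ±10 nt — codon-scale adjacency — and the per-site
nearest-summit distance is reported so the sensitivity of any headline
percentage to this choice can be explored directly.

## The synthetic generator

The generators exist so that every stage can be validated against
planted truth without any external download. The model is chosen to
match the caller's null assumptions: independent Poisson background
(λ_bg per position per library) plus independent Poisson site
contributions. A TPS of strength μ adds mean μ to TEX− and
μ·`tex_plus_leak` to TEX+; a TSS adds μ·`tss_enrichment` to TEX+ and
μ·`tss_minus_fraction` to TEX−. Defaults: leak 0.02 (TEX digestion is
efficient but not complete; no measured efficiency exists, so this is a
convention, and it is configurable), enrichment 3, minus-fraction 1.
Default per-gene TPS multiplicity (40% none, 35% one, 15% two, 10%
three) mirrors the empirical shape of processing-site maps in halophilic
archaea, where single-TPS genes dominate among genes with any site;
strengths default to lognormal around 30 extra read starts, comfortably
detectable over λ_bg = 1 yet not trivially so.

Planted same-kind, same-strand sites keep a minimum spacing of 6 nt
(clustering gap + 1), enforced by rejection, so that matching calls to
truth is unambiguous; real genomes violate this, which is a documented
simplification. In the two-species generator, conserved pairs place the
partner site at D_B = D_A + U(−jitter, +jitter), while *non-conserved*
pairs re-draw D_B until it lies at least threshold + 1 D-units away from
D_A. That margin (plus sub-0.2-unit rounding slack from converting D to
integer coordinates) keeps chance co-placements out of the conservation
window, making "the recovered set equals the planted set" a well-posed
expectation; jitter ≥ threshold is refused outright for the same reason.
Ribo-seq coverage is a flat in-CDS baseline plus triangular peaks of
exact summit height `base + peak_height` at a chosen fraction of planted
TPS.

What the generator does **not** emulate: overdispersion beyond Poisson
(real libraries are closer to negative binomial), position-correlated
coverage along transcripts, sequencing error, multi-mapping ambiguity,
true UTR structure, and sub-spacing site clusters. Passing recovery
tests therefore demonstrates correctness of the statistical machinery
under its own assumptions, not robustness to every artefact of real
libraries — the stringent `alpha` and the winsorized background are the
main defences carried over to real data.

## Validation problem sizes

The packaged validation runs at sizes chosen to exercise the method
meaningfully while staying quick on a laptop: the Skellam oracle grid at
λ ∈ {0.01, 0.1, 1, 5, 20} × d ∈ [−60, 60]; a 10⁶-position null
simulation at λ_bg = 2 (expected false candidates ≈ 10⁻³ at the 10⁻⁹
cutoff, so the observed count should be 0); 100 planted sites of μ = 30
over λ_bg = 1 on a 100-kb replicon (recall and precision ≥ 0.95 at ±2
nt); and a 100-pair two-species study at conserved fraction 0.5 with
jitter 1. All are seeded and deterministic.

## Known limitations

* The caller is a fully specified substitute for segmentation-based TSS
  tools; it reproduces their parameter semantics (cutoff, minimum reads,
  grouping) but not any particular tool's internal model, so numeric
  agreement with such tools is not expected site-by-site.
* Replicates are combined by pooling; no dispersion across replicates is
  modelled.
* When replicon lengths are unknown (bare bedGraph input), edge windows
  treat positions beyond the last observed coordinate as zero-count,
  which slightly deflates λ near the right edge; supply `seqlengths`
  where available.
* The discordance flag is a screening rule, not an inferential test; it
  carries no error rate.
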