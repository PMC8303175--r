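# tpsmap

Genome-wide mapping of transcript processing sites (TPS) from differential
RNA-seq (dRNA-seq).

## The problem

dRNA-seq sequences each RNA sample twice: once after treatment with
Terminator 5′-phosphate-dependent exonuclease (TEX), which degrades
5′-monophosphorylated RNA, and once untreated. Primary transcripts
(5′-PPP) survive TEX and are *enriched* in the TEX+ library — the classic
way to map transcription start sites (TSS). Running the same contrast in
reverse finds the opposite signature: positions where read 5′ ends are
abundant in the TEX− library but *depleted* by TEX treatment are the 5′
ends of processed transcripts — transcript processing sites (TPS), the
RNA-side footprint of ribonuclease activity. `tpsmap` implements this
inverted contrast as a reusable, testable pipeline for anyone reanalyzing
paired TEX+/TEX− libraries (its motivating use case is the halophilic
archaea *Halobacterium salinarum* and *Haloferax volcanii*).

## The statistic

For each genomic position *i* on each strand, let *n*₋ and *n*₊ be the
read 5′-end counts in the (pooled) TEX− and TEX+ libraries. Local
background rates λ₋ and λ₊ are estimated as winsorized means over a
1000-nt window around *i* (the focal position excluded, so a genuine site
does not inflate its own null). Under the null the counts are independent
Poissons, so the difference *d* = *n*₋ − *n*₊ follows a Skellam
distribution, and the site p-value is the upper tail

> p = P(D ≥ d),  D = N₋ − N₊,  N₋ ~ Pois(λ₋), N₊ ~ Pois(λ₊).

A position is a candidate when *n*₋ ≥ 10 and p < 10⁻⁹ (both configurable);
candidates within 5 nt are clustered into one TPS. Swapping the library
roles (`mode = "TSS"`) calls enrichment sites instead.

Downstream layers:

* **Normalized position.** Each TPS in a CDS gets
  *D* = 100·σ·(x − x_CDSstart)/|x_CDSstart − x_CDSend| (σ = ±1 by strand):
  0 at the start codon, 100 at the last CDS base, out-of-bounds values
  allowed. Categories: upstream (D < 0), start-proximal (0 ≤ D ≤ 25),
  internal (25 < D < 75, strict), stop-proximal (75 ≤ D ≤ 100),
  downstream (D > 100).
* **Conservation.** In a one-to-one ortholog table, site pairs with
  |D_A − D_B| < 3 are positionally conserved; species-specific internal
  sites and antisense co-presence are reported alongside.
* **Antisense.** TPS falling inside an opposite-strand CDS are aTPS;
  sense/antisense coincidences within 5 nt are candidate double-stranded
  cleavage signatures.
* **Quantitative layers.** Library normalization (integral-to-one "per
  million" or rescale-to-deepest), site-vs-gene log2 fold-changes with a
  discordance flag, and overlap of sites with Ribo-seq coverage peaks.

A seeded synthetic generator (`sim_design()`, `generate_annotation()`,
`plant_truth()`, `simulate_library()`, `simulate_ortholog_study()`,
`simulate_riboseq()`) produces annotations, planted TSS/TPS truth and
dRNA-seq/Ribo-seq tracks with exactly the statistical structure the
caller assumes, so every stage is validated against known ground truth.

## Worked example

```r
library(tpsmap)
design <- sim_design(n_genes = 10, replicon_length = 30000, lambda_bg = 1, seed = 42)
genes  <- generate_annotation(design)
truth  <- plant_truth(genes, tps_per_gene = 1, tss_per_gene = 0, strength = 40, seed = 42)
tex_minus <- simulate_library(truth, design, "TEX_MINUS", seed = 42)
tex_plus  <- simulate_library(truth, design, "TEX_PLUS",  seed = 42)
calls <- call_sites(tex_minus, tex_plus)
print(calls)
#> TPS calls: 10 site(s) on 1 replicon(s)
#>              tps_id replicon strand position      p_value n_minus n_plus ...
#>   TPS_chrSim_+_5301   chrSim      +     5301 2.228099e-34      33      3
#>   TPS_chrSim_-_5537   chrSim      -     5537 4.915554e-55      44      0
#>   TPS_chrSim_+_9800   chrSim      +     9800 1.193796e-56      47      3
#>   ...
```

All 10 planted sites are recovered at their exact planted coordinates:
at each site the TEX− library keeps ~40 extra read starts (`n_minus`)
over a background of λ ≈ 1 (`lambda_minus`), while TEX treatment removes
them (`n_plus` ≈ 1–3), giving Skellam p-values far below the 10⁻⁹ cutoff.
Annotation then places each site on its host gene:

```r
head(assign_tps(calls, genes)[, c("tps_id", "locus_tag", "orientation", "D", "category")])
#>               tps_id locus_tag orientation         D       category
#> 1  TPS_chrSim_+_5301 SIMG_0001       sense 91.481747  STOP_PROXIMAL
#> 2  TPS_chrSim_+_5301 SIMG_0002   antisense 22.845130 START_PROXIMAL
#> 3  TPS_chrSim_-_5537 SIMG_0002       sense  6.306938 START_PROXIMAL
#> 4  TPS_chrSim_+_9800 SIMG_0003       sense 28.601546       INTERNAL
```

The first site sits near its gene's stop codon (D ≈ 91) and also lies
antisense to an overlapping gene on the other strand — an aTPS for that
locus. `summarize_annotations()` adds the per-gene multiplicity table, a
3-unit D histogram and the densest site window; `run_pipeline()` (or
`inst/scripts/run_pipeline.R` from a shell) chains every stage from a
YAML config into a TSV/BED output bundle with a checksum manifest.

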