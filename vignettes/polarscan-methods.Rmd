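---
title: "Allele polarization and haplotype-based selection scans with polarscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Allele polarization and haplotype-based selection scans with polarscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polarscan)
```

## The problem

Haplotype-based selection statistics compare the length of haplotype
homozygosity around the two alleles of a core site. Extended haplotype
homozygosity (EHH) at distance $x$ from a core is the probability that two
randomly drawn chromosomes carrying a given core allele are identical at
every site between the core and $x$; the integrated haplotype homozygosity
iHH is the area under the EHH decay curve over genetic distance, and the
integrated haplotype score is

$$\mathrm{iHS}_{\text{raw}} = \ln \frac{\mathrm{iHH}_{\text{derived}}}
{\mathrm{iHH}_{\text{ancestral}}},$$

standardized to mean 0 and variance 1 within derived-allele-frequency bins.
The sign of iHS is only interpretable if "derived" and "ancestral" mean what
they say. Phased VCFs, however, code alleles as REF/ALT — an essentially
arbitrary orientation relative to the ancestral state. polarscan recodes
phased haplotypes so that 0 = ancestral and 1 = derived, using a
per-chromosome ancestral-allele FASTA inferred from multi-primate alignments
(Ensembl convention), builds the matching genetic map, and emits the
`.hap`/`.map` pair that selscan and HaploSweep consume. Under the sign
convention those tools use — which polarscan's built-in engine follows —
extreme *positive* standardized iHS marks long haplotypes around the derived
allele (a classic sweep) and extreme *negative* scores mark long haplotypes
around the ancestral allele (selection on standing variation).

## Polarization rules

For each biallelic SNV the ancestral base at the same coordinate is looked
up in the FASTA, where case encodes confidence: `ACGT` are high-confidence
calls, `acgt` low-confidence, and `.`, `-`, `N` mean no usable call.

* ancestral base equals REF: the column is copied (0 stays ancestral);
* equals ALT: the column is bit-flipped and the site flagged `flipped`;
* unknown: dropped with reason `no_ancestral_call`;
* low-confidence: dropped with reason `low_confidence` by default. Only
  high-confidence calls polarize reliably, so the curated output trades
  sites for accuracy; `keep_low_confidence = TRUE` matches
  case-insensitively instead, for sensitivity analyses;
* equal to neither allele: dropped with reason `mismatch`. Force-coding such
  sites would fabricate a polarity the reference cannot support.

Every removed site lands in a drop log (vid, position, alleles, ancestral
base, reason) with per-reason counts and the overall loss fraction, so the
cost of curation is always visible. Comparison is strand-naive — the
Ensembl ancestral FASTA is given on the reference forward strand — and no
reverse-complement rescue is attempted, because a strand flip is
indistinguishable from a genuine mismatch at A/T and C/G sites.

Polarization is involutive by construction: swapping REF/ALT labels while
bit-flipping the genotypes (the same data in the opposite file orientation)
yields the identical polarized matrix, drop log, and byte-identical `.hap`
output. The test suite asserts this directly.

## Genetic map interpolation

Genetic positions are linearly interpolated from a PLINK-format reference
map (chromosome, ID, cM, bp). Anchors are sorted by bp; duplicate-bp anchors
keep the first occurrence (with a warning) so behavior over arbitrary public
maps is deterministic; a map whose cM decrease after sorting is rejected as
corrupt. A query at an anchor returns that anchor's cM exactly; between
anchors the flanking pair defines the usual linear form. Queries outside the
anchor range — telomeric sites a generic map does not reach — are
extrapolated with the slope of the nearest terminal interval and floored at
0 cM. Dropping unanchored sites instead would silently shrink the dataset,
and downstream tools require a finite, non-decreasing cM for every site;
the floor exists because a negative genetic position is meaningless.

## The interchange formats

`write_hap()` emits one space-separated line of 0/1 tokens per haplotype
(2N lines), no header; `write_map()` emits one `chrom vid cM bp` line per
site with cM at six decimal places (common PLINK map precision, and stable
for golden-file tests). Both accept a `.gz` suffix. The orientation of the
`.hap` matrix is a documented flag (`transposed = TRUE` writes one line per
site) because both downstream tools accept haplotype-matrix input and
conventions vary in the wild; the dimensions in use are reported in a
message. `read_hap_map()` inverts the writers and hard-errors on ragged
rows, non-binary tokens, or a `.hap`/`.map` dimension mismatch.

## The EHH/iHS engine

The engine exists so the whole pipeline is verifiable end to end without
external binaries, and for small-scale scans. EHH is computed by extending
identical-haplotype groups one site at a time outward from the core: if the
$n_c$ carrier haplotypes currently split into groups of sizes $n_g$,

$$\mathrm{EHH} = \frac{\sum_g \binom{n_g}{2}}{\binom{n_c}{2}},$$

which is exactly the all-pairs shared-prefix probability; the test suite
checks the grouping implementation against a brute-force all-pairs oracle
on randomized instances. The walk stops at the chromosome end or when EHH
falls below the truncation cutoff (default 0.05, the common selscan
default); the first below-cutoff point is retained so the final trapezoid
is part of the integral. iHH is the trapezoid-rule integral of EHH against
cM — genetic, not physical, distance: the genetic map is built precisely so
that integration happens on the recombination scale. Singleton allele
classes make EHH undefined and raise an explicit error rather than a silent
zero.

The raw score is computed as $\log(\mathrm{iHH}_1) - \log(\mathrm{iHH}_0)$
rather than $\log(\mathrm{iHH}_1/\mathrm{iHH}_0)$ so that relabeling
ancestral and derived alleles negates it bit-exactly, an invariant the
tests assert with `expect_identical()`.

### Standardization and its small-sample regime

Scores are standardized within equal-width derived-allele-frequency bins
over $[0,1]$ (default 20 bins; selscan's norm uses 100, which suits
chromosome-scale site counts). A bin holding fewer than two finite scores
cannot be standardized; such scores are left raw and flagged rather than
dropped. Because each bin uses its own sample mean and standard deviation,
a bin with $n$ scores can never produce $|z| > (n-1)/\sqrt{n}$: with
8 scores per bin the attainable maximum is about 2.5, which both truncates
the neutral tail and caps detectable outliers. The desk-scale study
conditions therefore use 500 sites per cohort (the simulator default),
giving roughly 20–25 scores per occupied bin — enough for the
$|\mathrm{iHS}| > 2$ tail to approach its nominal ≈5% and for planted
sweeps to clear the threshold. Sites with minor allele frequency at or
below `maf_min` (default 0.05, selscan's default) are not scored.

## What the simulator emulates — and what it does not

`simulate_cohort()` generates the full input set (phased VCF, ancestral
FASTA, PLINK map, gene file) plus a truth table, deterministically per
seed; seeds are recorded in the emitted VCF and FASTA headers. The
haplotype background is exchangeable-random: each site draws an independent
derived-allele frequency from $U(0.05, 0.95)$ and haplotypes are
independent Bernoulli draws. A planted sweep places a fraction of
haplotypes (default 0.6) on one shared haplotype across a segment of given
genetic length (default 1 cM) around a focal site — the long-homozygosity
signature the statistics detect. Confidence classes (low-confidence,
unknown, mismatching ancestral bases; defaults 5%, 5%, 2%) and missing IDs
(10%) are planted with exact counts so every drop is predictable from the
truth table.

Default conditions: 50 diploid samples (100 haplotypes), 500 SNVs on a
5 Mb chromosome, a 20-anchor map averaging 1 cM/Mb (the human genome-wide
average) with locally jittered rates.

The background deliberately carries **no linkage disequilibrium**: between
sites, alleles are independent, so EHH decays geometrically rather than
with the long-range correlation of coalescent genealogies, and the neutral
iHS distribution is only approximately normal. Passing tests on this
fixture therefore demonstrate the correctness of the bookkeeping, the
estimator arithmetic, the sign conventions, and the sweep/no-sweep
contrast — not calibration against human demography, recombination
hotspots, or background selection. A coalescent simulator can be swapped
in for that purpose; none of the package's guarantees depend on one.

## Numerical and degenerate-input choices

* Coordinates are 1-based throughout, matching VCF; BED-style gene
  intervals are the single 0-based half-open exception, stated in the
  plotting documentation.
* Missing or unphased genotypes are hard errors naming site and sample:
  silently dropping them would desynchronize the haplotype matrix from the
  site table, and haplotype statistics are undefined on partial data.
* An empty retained-site set refuses to write a `.hap` file rather than
  emitting an empty one.
* Anchor-identity interpolation is exact (the anchor's cM is returned, not
  recomputed), so map round trips are byte-stable.
* Outlier classification at a threshold $t$ uses strict inequalities
  ($\mathrm{iHS} < -t$, $\mathrm{iHS} > t$); scores exactly at the
  threshold are non-extreme.
* The polarized-versus-unpolarized comparison uses a continuity-corrected
  chi-square two-proportion test (`prop.test`), the textbook choice for a
  2×2 dataset-by-extremeness table.

## Plots

`manhattan_plot()` draws standardized iHS against position (Mb) with dashed
horizontal lines at ±threshold; points above +threshold red, below
−threshold green, neutral gray (all overrideable); chosen variants are
labeled with their identifiers, and a BED-like gene annotation produces a
text file of genes harboring outlier scores. `ehh_plot()` draws the
two-allele EHH decay against signed distance from the core — physical (Mb)
on the x-axis by default, with a genetic-distance (cM) option — derived
series red, ancestral blue, with a legend. Both return the ggplot object,
so tests verify the data layer (point coordinates, line positions, colors,
labels) rather than pixels, and both save any subset of pdf/eps/svg/png.

## Known limitations

* Only biallelic SNVs are polarized; multiallelic records and indels are
  skipped at ingestion (counted, never silent).
* No gap-scale penalty for large physical gaps between consecutive sites
  (a selscan refinement); the engine targets selscan-style normalization
  only, and HaploSweep's normalization scheme is handled at the parsing
  layer, not re-implemented.
* The engine is written for clarity and verification, not performance
  parity with selscan; chromosome-scale scans should still go through
  selscan/HaploSweep using the files this package writes.
* Strongly negative iHS near a genuinely swept derived allele can reflect
  hitchhiking ancestral haplotypes rather than selection on the ancestral
  allele itself; corroborate signals with additional evidence.
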