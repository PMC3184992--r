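---
title: "Methods: twin-cohort methylation models in twinmeth"
author: "twinmeth authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: twin-cohort methylation models in twinmeth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinmeth)
```

# Scope

`twinmeth` analyses CpG-unit DNA methylation in cohorts of monozygotic
(MZ) and dizygotic (DZ) twins, with imprinting control regions (ICRs)
as the motivating use case. Because no individual-level twin
methylation data of this design are publicly deposited, the package
pairs every analysis operation with a synthetic-data generator whose
defaults encode the study conditions the analyses assume: 128 MZ and
128 DZ pairs (512 individuals), five regions totalling 54 CpG units,
imprinted observed levels near 50%, and a maternal-allele SNP effect in
the H19-ICR. All statistics also run unchanged on real tables read from
TSV.

# The cohort simulator

## Variance model

Each CpG unit's methylation, per parental allele, is

    value = baseline + A + C + E + beta * [origin-matched effect allele]

with the classical ACE decomposition: the additive-genetic component A
is identical within MZ pairs and has correlation 1/2 within DZ pairs
(implemented by averaging two simulated parental values and adding
Mendelian segregation noise, which gives the DZ correlation of exactly
1/2 in expectation); C is shared by both members of any pair; E is
individual noise. Components are drawn once per individual and unit and
added to both alleles, so the observed value (the allele mean) has
variance `sigmaA2 + sigmaC2 + sigmaE2` and intra-pair correlations
`(sigmaA2 + sigmaC2) / total` (MZ) and `(sigmaA2/2 + sigmaC2) / total`
(DZ). Units of one region share a fraction `rhoW` of every component,
giving within-region correlation `rhoW`.

Components are Gaussian and allele values are clipped to [0, 1]. A
clipped-Gaussian scale (rather than a Beta or logit model) was chosen
so that the ACE expectations remain exact, checkable arithmetic; the
cost is boundary distortion, discussed under *Limitations*.

## Default study conditions

`defaultRegionModels()` fixes five regions. The four imprinted regions
use allele baselines 0.05/0.95 (paternally methylated H19-ICR and
IGF2-DMR; maternally methylated KvDMR and NESPAS-ICR), so observed
levels sit near 0.5. The RUNX1-like promoter is lowly methylated on
both alleles, with per-unit baselines spanning 0 to 0.18. Total
variance per region is calibrated from the reported inter-individual
interquartile ranges (0.12, 0.12, 0.05, 0.05, 0.06 for H19-ICR,
IGF2-DMR, NESPAS-ICR, KvDMR, RUNX1) via the Gaussian identity
`sigma = IQR / 1.349`. The A:C:E split (0.3-0.5 : 0.15-0.2 : rest) and
the within-region correlations (0.3-0.75, strongest in KvDMR and
NESPAS-ICR) are simulation choices: they produce the qualitative
orderings the analyses test (MZ discordance below DZ below non-related;
strong within-region correlation blocks), and the H19-ICR receives the
largest genetic share because that is the region where genetic
proximity is expected to matter most. Unit counts (9, 5, 10, 11, 19)
total 54.

`defaultSnpModels()` defines rs10732516 (A/G, frequency 0.5 under
Hardy-Weinberg; no carrier counts per group are reported, so 0.5 is a
neutral choice) with a maternal-allele-only effect `beta = 0.15` on the
early H19-ICR units u02-u04, and rs2839701 (G/C) in complete linkage
(maternal/paternal rs10732516 A always carries rs2839701 G). Parental
origin is emitted as simulation ground truth; for real data the origin
is an input column, never inferred, since how origin was resolved in
heterozygotes is not specified by the motivating study.

## Aberrations and missingness

`injectAberrations()` plants loss/gain-of-methylation (LOM/GOM) events
of known magnitude at local (one unit), regional (contiguous units) or
trans (two regions) scope, hitting one twin (discordant) or both
(concordant). The observed level moves by the full magnitude: a loss is
drawn from the methylated allele first, because that is where the
methylation to lose resides; a gain fills the unmethylated allele
first. Sampled targets are restricted to units whose cohort median can
express the shift (a 0.2 loss is not placed on a 2%-methylated unit),
which is also the biologically meaningful choice. The ground-truth
event log is stored in the object metadata so that caller recovery is
measurable. `applyMissingness()` masks entries independently at a fixed
rate across all assays, which is what the 75% coverage filter is
exercised against.

# The in-silico MassCleave model

The T-cleavage chemistry is modelled end to end: bisulfite conversion
(non-CpG C to T; CpG C retained only when methylated), transcription of
the reverse strand from the T7-tagged reverse primer, and RNase A
cleavage 3' of every rU. Because dCTP replaces rCTP, C is
non-cleavable; cleavage sites therefore correspond to plus-strand
adenines and are independent of methylation state. A methylated CpG
places G instead of A in the transcript, shifting the fragment mass by
16.00 Da (average residue masses G 345.21 minus A 329.21). Fragment
masses are sums of average residue masses (A 329.21, G 345.21, U
306.17, deoxy-C 289.18) plus a terminal adjustment of +18.02 Da; the
terminal convention is configurable through `massCleaveMasses()`
because absolute masses depend on the terminal chemistry assumed while
mass *differences* — all the quantitative structure used downstream —
do not. Only T-cleavage is implemented; the rUTP/dCTP chemistry the
model follows performs no C-cleavage.

CpG sites sharing a fragment form one CpG unit (`buildUnitMap()`).
Units whose mass series approaches another fragment's series within
±0.5 Da are flagged as collisions and return missing from
`estimateMethylation()` — flagging, never intensity apportioning,
mirrors how a confounded unit is excluded in practice. Units on
SNP-overlapping fragments are likewise marked for exclusion. The
methylation ratio of a k-CpG unit with series intensities `I_0..I_k`
is `sum(c * I_c) / (k * sum(I_c))`. `callSnpAlleles()` detects each
allele through its allele-specific (diagnostic) fragment series above a
relative intensity floor (default 5% of the strongest peak) and reads
per-allele methylation from each allele's own series, which is what
makes simultaneous genotyping and allele-specific methylation possible
from one spectrum.

`exampleH19Design()` is a synthetic amplicon (it reproduces the assay's
logic, not the genomic sequence): the reference [G] allele leaves a
4-CpG fragment whose series spans 64 Da, and the [A] allele introduces
a novel cleavage site splitting off a single-CpG diagnostic fragment.
Coordinates are 0-based half-open internally; reports are 1-based.

# Cohort statistics

* **Coverage filter.** Units observed in fewer than 75% of individuals
  are dropped (`filterUnits()`), plus explicit exclusions such as a
  SNP-confounded unit. The filter is idempotent.
* **Summaries.** Medians and IQRs use linear-interpolation (type 7)
  quantiles — the most common convention, fixed so tests are exact.
  Region-level IQR is the unweighted mean of unit IQRs.
* **Correlation.** `spearmanMatrix()` uses pairwise-complete
  observations (maximising n per cell, consistent with the per-unit
  filter) and average ranks for ties; cells with fewer than 3 shared
  observations are missing. `correlationThreshold()` inverts the t
  approximation; at alpha = 1e-4 it gives ~0.17 at n = 512 and ~0.23
  at n = 286. A printed threshold of 0.23 therefore corresponds to an
  effective n near 286 rather than the full 512; the package reports
  the threshold for the actual per-cell n and does not force
  agreement.
* **Discordance.** Region-level intra-pair discordance is the mean
  absolute difference over units observed in both members, rescaled by
  the region's unit count — a missing-robust equivalent of the
  sum-over-units; a raw-sum mode is retained. Non-related (NR)
  pseudo-pairs are a random perfect matching with no same-family pair,
  found by rejection sampling.
* **Kruskal-Wallis / Dunn.** The tie-corrected H uses the chi-square
  approximation (delegated to `stats::kruskal.test`); Dunn z tests on
  rank means use the tie-corrected variance and Bonferroni adjustment
  over all pairwise comparisons — the common reading of "Dunn's
  multiple comparison test" when no adjustment is named. The degenerate
  all-identical input returns H = 0, p = 1.
* **LOM/GOM calling.** A call requires a *strict* deviation beyond the
  cutoff from the unit's reference median; "10% difference" is
  interpreted as 0.10 absolute on the 0-1 methylation-fraction scale,
  which keeps calls scale-free. The reference median is computed over
  the whole cohort by default, with a per-zygosity option, since either
  reading is defensible. Pair concordance is tabulated per pair and
  unit by default; an individual-level observation mode (each co-twin
  contributes an observation classified by its pair's status) is
  provided because the observation unit behind published tallies is
  not always derivable from totals.
* **Percentages** are rounded half away from zero to one decimal
  (base R's `round()` is round-half-even, which disagrees with
  reported tables).
* **3x2 chi-square.** Pearson statistic over the
  (concordant/discordant/none) x (MZ/DZ) table with df fixed at 2 even
  when a class is empty in both groups; zero-margin cells contribute
  nothing. This follows the published table-note convention rather
  than reducing df.

# Motif enrichment

PWMs are normalised with a pseudocount of 0.01 times the column total
(avoiding infinite log-odds on zero counts) and scored as log2-odds
against a uniform background. "At least 80% sequence match" is
implemented as the fractional score `(score - min) / (max - min) >=
0.8`; a consensus-base-identity mode is provided as an alternative
because the phrase is ambiguous. Both strands are scanned; ambiguous
bases score as background (log-odds 0); a completely flat matrix
cannot discriminate and scores every window as a full match.
`mutatePWM()` exchanges the weights of two bases at one position, so
the inverse substitution restores the matrix exactly.

Meta-profiles anchor at the motif midpoint, reverse minus-strand
windows so position 6 is orientation-consistent, and treat positions
outside the track as 0. Profile comparisons are within one track only,
where sequencing-depth normalisation cancels.

The planted-signal construction (`plantedMotifGenome()`) places
consensus motifs under full-height triangular peaks and
position-6-variant motifs under half-height peaks, spaced so windows do
not overlap. The bundled `exampleCtcfPWM()` makes the sharp position-6
column carry enough score weight that a single C-to-T change drops a
site below a 0.85 fractional match; the demonstration therefore scans
at `minMatch = 0.85`. With the default 12-column matrix and a ~106-kb
genome, the consensus-to-variant central-window ratio recovers the
planted factor of 2.

# Problem sizes and numerical checks

The test suite runs the generator at 128+128 pairs for power and
recovery checks (the full study-scale cohort), 5,000+5,000 pairs for
ACE correlation checks, 1,000 random amplicons (up to 200 bp) against a
brute-force cleavage oracle, 400-500 replicate spectra for estimator
bias, 1,000 replicates for chi-square test size, and 500 replicate
cohorts for Kruskal-Wallis size; these sizes give Monte-Carlo error
comfortably inside each asserted tolerance. Determinism is enforced by
routing every random draw through an explicit seed; a fixed seed
reproduces tables byte-identically.

# Limitations

* The clipped-Gaussian allele scale distorts moments at the [0, 1]
  boundary: at imprinted baselines (0.05/0.95) the per-allele noise is
  asymmetrically truncated, which compresses observed tails, biases
  recovered allele-level effects slightly downward (a maternal shift of
  0.15 is recovered as ~0.13-0.14 at the H19 baseline), and perturbs
  group-variance comparisons near the boundary. Tests of closed-form
  variance arithmetic therefore use interior baselines.
* Whole-blood cell composition, age and sex effects, and X-inactivation
  are deliberately not modelled; passing tests say nothing about those
  axes of real data.
* Absolute fragment masses depend on the assumed terminal chemistry;
  only mass differences (the 16-Da methylation series and
  SNP-diagnostic spacings) are treated as meaningful.
* The motif analysis demonstrates its logic on a synthetic genome and
  track; genome-wide site counts on a real assembly are
  assembly-dependent and out of scope.
* Pooling both members of a twin pair in genotype-stratified tests
  inflates the effective n; the package defaults to one member per MZ
  pair and its own size checks use one member per pair, with a
  full-cohort mode retained for comparability.
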