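---
title: "Methods: ROH calling, genomic inbreeding and diversity scans in rohatlas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ROH calling, genomic inbreeding and diversity scans in rohatlas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rohatlas)
```

# Scope and model

`rohatlas` characterizes the genomic footprint of inbreeding and selection
in diploid biallelic SNP panels, built around the study system of domestic
and wild turbot (*Scophthalmus maximus*): a 22-chromosome, 567-Mb genome
genotyped with reduced-representation panels of roughly 18,000–26,000
SNPs (1 SNP per 22–31 kb). The pipeline starts at genotypes: read
trimming, alignment and genotype calling are upstream and out of scope.
Coordinates are 1-based inclusive everywhere; exported BED files convert
to 0-based half-open.

Four statistics are central:

* **ROH** — runs of homozygosity, contiguous stretches where one
  individual's two chromosome copies carry the same alleles, called with
  the observational sliding-window semantics of PLINK 1.9.
* **F_ROH** — the genomic inbreeding coefficient: the summed length of an
  individual's ROH above a length cut-off divided by the genome length
  (567 Mb by default).
* **θ (kinship)** — for a parent pair, the probability that two alleles
  sampled one from each parent are identical by descent; it equals the
  expected inbreeding coefficient of their offspring, which is what makes
  the family-based calibration below possible.
* **Hp / ZHp** — pooled heterozygosity of a 37-SNP window,
  `Hp = 2*S_maj*S_min / (S_maj + S_min)^2`, where `S_maj` and `S_min` sum
  the per-SNP major and minor allele counts over the window, and its
  genome-wide Z-standardization. Windows with strongly negative ZHp mark
  candidate selective sweeps (low diversity); strongly positive ZHp marks
  balancing-selection-like regions.

# ROH calling semantics

`call_roh()` fixes the following five-step definition, enforced in the
test suite by an independent brute-force implementation that enumerates
every window and run explicitly:

1. a window of `window_snp` consecutive SNPs slides one SNP at a time,
   never across a chromosome boundary; the window is *homozygous* when it
   has at most `window_het` heterozygous and `window_missing` missing
   calls;
2. each SNP's hit fraction is the share of homozygous windows among the
   windows containing it (only windows fully inside the chromosome count,
   so SNPs near chromosome ends have fewer); the SNP is eligible when the
   fraction reaches `hit_threshold`;
3. maximal runs of consecutive eligible SNPs become candidates, split
   where adjacent SNPs are more than `max_gap_kb` apart;
4. candidate ends are trimmed to the outermost homozygous (non-het,
   non-missing) call;
5. segments survive if they have at least `min_snp` SNPs, span at least
   `min_kb` kb, and average at most `density_kb` kb per SNP.

The published description of this caller does not restate PLINK's inner
rules (end trimming, density accounting), so the definition above is this
package's normative one; divergence from any particular PLINK build is
possible and accepted. Defaults follow the published constant settings:
`min_kb = 200`, `max_gap_kb = 1000`, `window_missing = 5`,
`hit_threshold = 0.05`, `density_kb = 50` (the PLINK default, since the
published wording conflates density with the SNP grid). The calibration
grid varies `window_snp` from 24 to 40 with `min_snp` tied to it, and
`window_het` over 0/1 — allowing one heterozygote absorbs genotyping
errors that would otherwise break long ROH into medium ones.

`f_roh()` uses a strict inequality (segments *longer than* the cut-off)
and explores cut-offs of 1, 2, 4, 8 and 10 Mb; 1 Mb is what the
calibration selects. `roh_size_classes()` bins segments at
(<1, 1–2, 2–4, 4–8, 8–12, 12–16, 16–24, >24) Mb.

# Kinship estimation and classes

`estimate_ibd()` implements Purcell-style method-of-moments inversion of
identity-by-state counts into IBD-state proportions Z0/Z1/Z2, using
allele frequencies estimated from the full input sample, bounding
negative raw estimates at zero and renormalizing; `PI_HAT = Z1/2 + Z2`
and `θ = PI_HAT/2`. The source study describes the tool it invoked as a
hidden Markov model, but that tool's pairwise estimator is in fact
method-of-moments, which is what we implement — simpler and faithful to
what was actually run. PLINK's small-sample bias corrections are omitted;
at the panel sizes involved (thousands of markers) the class assignment
is unaffected.

`classify_kinship()` uses the published boundaries — unrelated below
0.0076, second cousin to 0.038, first cousin to 0.0937, half-sibling to
0.1872, full-sibling above — with exact boundary values assigned to the
higher-relatedness class (the published intervals are open and do not
specify ties). Note that the unrelated/second-cousin boundary is narrow
relative to estimation noise, so some truly unrelated pairs classify as
second cousins; the source study observed the same ambiguity in its
non-inbred families.

# Family-based calibration

`calibrate()` computes every offspring's F_ROH under each calling
condition and cut-off and regresses it by ordinary least squares on the
parental kinship of its family, one observation per offspring (the
larger-n reading of an ambiguous published setup; a per-family-mean
regression can be emulated by averaging before the call).
`cv_across_panels()` compares conditions across marker panels by the
percent coefficient of variation (sample standard deviation over mean) of
intercept and slope.

`select_best()` ranks conditions (heterozygote allowance × window ×
cut-off) by mean R² across panels, breaking ties by the lower slope CV
then intercept CV, and then picks the panel with the highest R² within
the winning condition. A literal highest-single-R² rule would pick a
relaxed-QC panel cell whose R² is marginally higher but whose
cross-panel behavior is erratic; ranking conditions first reflects the
logic of choosing a *condition* that is stable across QC stringencies.
Panel ties are broken toward the smaller absolute intercept — the
intercept is the baseline F_ROH of nominally unrelated parents, so a
larger value indicates spurious ROH from genotyping artifacts — and then
toward the slope closest to 1. On the bundled published calibration
table this returns the 21,615-SNP panel with one heterozygote allowed
and the 1 Mb cut-off, the condition the source study adopted. One cell
of that table (4 Mb cut-off, 1 het, 18,198-SNP panel, intercept 0.08) is
carried as printed but flagged as a probable typo for 0.008; no silent
correction is applied.

# ROH islands

`roh_islands()` tiles the genome into 50-kb windows, counts the
individuals with at least 1 bp of ROH overlap in each, and tests the
count against an upper-tail binomial null. The null success probability
is not stated in the source study; we define `p0` as the genome-wide mean
per-individual ROH coverage fraction, documented and overridable. The
published Bonferroni denominator of "640 windows" cannot equal the
11,340 50-kb tiles of a 567-Mb genome; we correct over the windows that
carry at least one ROH (which lands in the same few-hundred range on
simulated data) and expose `bonferroni_n` as an override. The default
`alpha = 0.0128` reproduces the published per-window threshold of
2e-5 at a 640-window correction. Adjacent significant windows merge into
islands.

# Diversity scan choices

Major/minor allele counts use observed alleles among non-missing calls
(missing-data handling inside windows is unstated in the source; counting
observed alleles is the natural pooled estimator). Exact 0.5 frequency
ties are broken toward the alternate allele, which cannot change Hp. The
ZHp standardization uses the population (n) standard deviation across all
windows; at realistic window counts (about 20,000) the n vs n−1 choice
changes ZHp by under 1e-4. Windows never span chromosome boundaries, so a
chromosome with `n_c >= 37` markers contributes `n_c - 36` windows;
chromosomes below the window size are skipped with a warning. Suggestive
and strict classifications use |ZHp| thresholds of 2.5 and 3.0. Region
merging joins overlapping or bookended same-class windows — the source
study's grouping of windows into "genomic regions" is not described, so
this rule is declared rather than inferred, and the strict tier is always
nested inside the suggestive tier.

# The simulator

`build_design()` provides the synthetic study system, with exact ground
truth for every quantity the pipeline estimates:

* **Genome and map** — 22 equal-length chromosomes totaling 567 Mb
  (overridable), markers placed uniformly per chromosome in proportion to
  length.
* **Founders** — haplotypes drawn site-wise independently at frequencies
  from a configurable spectrum: Beta(0.8, 0.8) for the rare-allele-
  depleted broodstock, Beta(0.3, 1.2) for the rare-allele-enriched wild
  sample, qualitatively matching the published rare-allele fractions
  (about 30% vs 53% of loci with MAF < 0.05). Exact spectra are free
  parameters.
* **Meiosis** — crossover counts per chromosome are Poisson with mean
  given by the 0.6 Mb/cM turbot map ratio (Haldane, no interference — the
  simplest defensible model given that only the ratio is reported);
  crossover positions are uniform. Every haplotype carries founder-genome
  labels as exact base-pair segments, so realized kinship and realized
  offspring autozygosity are computed from ancestry, not estimated.
* **Families** — parent pairs realizing the five kinship classes are
  built from minimal founder pedigrees (full sibs share both parents,
  half sibs one; first cousins descend from one shared grandparental
  couple, second cousins from one shared great-grandparental couple,
  i.e. a three-generation founder pedigree). The default design founds
  26 families (6 unrelated, 5 of each other class — the real families'
  composition is unpublished, so this spread is a documented choice) with
  40 offspring each.
* **Noise** — a mis-called genotype becomes one of the other two codes
  with equal probability (error rate 0.005 by default); genotypes go
  missing independently (0.03 by default). Noise is applied after truth
  capture. These rates emulate well-filtered reduced-representation
  panels.
* **Injected regions** — `inject_region()` copies one template haplotype
  across an interval with probability equal to the sweep intensity
  (toward fixation; a hard sweep at intensity 1 leaves it monomorphic) or
  redraws alleles at frequency 0.5 (balancing-like). Intervals must cover
  at least 37 markers, the width of the scanning window. Sweeps are
  injected, not evolved, and founders have no coalescent structure.

What the generator does *not* emulate — linkage disequilibrium among
founders, spatially autocorrelated allele frequencies, ascertainment
against sample-monomorphic sites, and RAD-typical heterogeneous
missingness — matters for one result: clusters of near-fixed sites arise
by chance under independent frequency draws, producing identity-by-state
ROH in nominally unrelated wild individuals that co-occur across
individuals. The site filters (`filter_sites()`: call rate above 0.56,
observed-monomorphic removal, one marker per locus tag) remove most but
not all of this, so the ROH-island scan occasionally flags such shared
low-diversity clusters in a no-sweep wild simulation (about 7–8% of
replicates). These are genuine diversity heterogeneities of the simulated
data rather than test artifacts; passing the wild-null check at a strict
family-wise level would require either haplotype-structured founders or
heavier missingness than the frozen defaults. Interpret island calls on
real data accordingly: the binomial null assumes a homogeneous genome.

# Problem sizes and numerical choices

The test suite exercises the full study scale where it matters: the
calibration recovery check simulates 26 families × 40 offspring at
21,615 SNPs and regresses offspring F_ROH (37-SNP window, 1 heterozygote,
1 Mb cut-off) on realized parental kinship, expecting a slope near 1 and
R² near 0.8. Property checks run at reduced sizes chosen for speed
without changing behavior: oracle equivalence on 1,000 random instances
of up to 250 SNPs × 5 individuals, kinship-class recovery on 75 families
at 6,000 markers, the wild island null on 200 replicates at full panel
size, and sweep recovery on 50 replicates. Degenerate inputs error
loudly: an all-identical-Hp scan ("degenerate scan"), fewer than 100
joint markers for a pair ("insufficient markers"), fewer than 3 distinct
kinship values for a regression ("degenerate regression"), an emptied
marker panel ("empty panel"). Missing genotypes are never imputed.

# Known limitations

* The ROH caller is this package's normative reading of the PLINK 1.9
  observational method; specific PLINK builds may differ at segment
  edges.
* The binomial island test has no family-wise error guarantee when
  per-window homozygosity probabilities vary along the genome (see
  above).
* The three published QC tiers (25,511 / 21,615 / 18,198 SNPs) arise from
  upstream genotyping QC that is not re-derivable here; they are treated
  as three input panels.
* Functional enrichment of candidate regions (gene retrieval, annotation
  clustering) requires external services and is out of scope; the atlas
  export provides region coordinates for manual lookup.
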