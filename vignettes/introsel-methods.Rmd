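---
title: "Methods and design notes for introsel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for introsel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`introsel` implements a complete population-genomics workflow for
SNP-array panels from conserved livestock breeds: quality control,
diversity and inbreeding, population structure and conservation
management, selection scans, introgression detection and mixed-model
association, together with a forward simulator that generates all of it
with known truth. This vignette records the models, the parameter
choices, and the design decisions taken where published practice leaves
the details open. It states no empirical result that the test-suite or
`scripts/acceptance.R` does not itself recompute.

## Genotype substrate and QC

A `genotypes` object is a diploid dosage matrix (counts of `allele1`,
`NA` for missing) with a SNP map (`chrom`, 1-based `bp`, optional `cm`,
alleles, optional ancestral-allele annotation) and per-individual
metadata (`id`, `population`, `sex`). PLINK binary (`bed/bim/fam`,
SNP-major, magic `6c 1b 01`) and text (`ped/map`) filesets are read and
written losslessly; the heterozygous-missing code `01` maps to `NA`.

QC applies four filters **sequentially**, in this order: (1) duplicate
individuals by pairwise IBS above 0.99, (2) minor allele frequency
below 0.01, (3) call rate below 90% — SNPs first, then individuals —
and (4) non-autosomal or unmapped SNPs. PLINK applies some of these
jointly; fixing a sequential order makes the removal counts in the QC
report well defined. Two deliberate determinism choices: duplicate
clusters keep the lexicographically smallest id (a random choice would
be irreproducible), and call-rate filtering is SNP-first (marginally
more conservative for individuals; the alternative order is not
exposed). Segment lengths and positions are 1-based inclusive
throughout, so a segment's length in bp is `end − start + 1`.

LD pruning follows `--indep-pairwise 50 10 0.5` semantics: windows of 50
SNPs advancing by 10, removing the **later** SNP of any pair with
r² > 0.5. r² is always the squared Pearson correlation of dosages
(composite genotypic LD, no phasing), computed pairwise-complete over
missing calls.

## Diversity, Ne and inbreeding

Expected heterozygosity uses the unbiased small-sample estimator
`2p(1−p)·2n/(2n−1)` per SNP (n = non-missing diploids), averaged over
SNPs; observed heterozygosity is the mean heterozygote fraction.
Monomorphic SNPs contribute zero rather than being dropped.

LD decay pairs every intra-chromosome SNP pair up to a distance cap.
Genetic distances come from the cM map when present, otherwise from a
1 cM/Mb fallback (recorded in the output's `map_source` attribute). The
LD extent is the linearly interpolated first downward crossing of the
binned mean-r² curve through a target (default r² = 0.3). Sved's
equilibrium relation `Ne_t = (1/4c)(1/r̄² − 1)` at `t = 1/2c` converts
binned LD into an Ne trajectory; the default 20 equal-width bins span
c ∈ [0.005, 0.25] Morgans, and the "recent Ne" summary averages bins
with t ≤ 5 generations. An optional `1/n` sampling correction on r̄² is
exposed but off by default, since the plain relation is what the
workflow's convention calls for; with it off, Ne at small sample sizes
is biased downward (the constant-size Wright–Fisher check in the
acceptance battery recovers N = 100 to well within a factor of two, from
below, for exactly this reason).

The SNP-based inbreeding coefficient is method-of-moments,
`F = (O_hom − E_hom)/(L − E_hom)`, on an LD-pruned set, with expected
homozygosity computed from the **individual's own population's** allele
frequencies — F is meant to measure inbreeding within a breed, not
differentiation between breeds.

## Runs of homozygosity

`call_roh()` emulates PLINK `--homozyg`: a 50-SNP window slides one SNP
at a time; a window passes with at most 1 heterozygous and 5 missing
calls; a SNP's hit fraction is the share of passing windows among those
covering it, thresholded at PLINK's default 0.05; candidate runs are
split at inter-SNP gaps above 1 Mb, trimmed at both ends to the
outermost homozygous non-missing call, and accepted if they satisfy the
minimum SNP count, the 1 Mb minimum length, and the 1 SNP/100 kb density
bound. The minimum SNP count defaults to the Lencz false-positive bound
`l = ⌈ln(α/(n_s·n_i))/ln(1 − het)⌉` with α = 0.05 and `het` the panel's
mean observed heterozygosity (the published sources do not say which
heterozygosity enters the formula; the panel mean is the natural choice
and `min_snps` is directly injectable when a fixed value is wanted).

One derivable edge effect is worth knowing: a homozygous run bounded by
heterozygous sites loses exactly one terminal SNP at each interior end,
because the terminal SNP is covered by only two passing windows
(2/50 < 0.05) while its inward neighbour collects three (3/50 ≥ 0.05).
PLINK behaves the same way. The planted-run recovery tests assert the
called bounds at this offset rather than pretending the caller can see
the planted span exactly. For the same reason `plant_roh()` delimits
each planted interval with **two** adjacent heterozygous sentinel SNPs:
one sentinel leaves the run boundary identifiable only up to chance
homozygous flanks; two make candidate runs terminate deterministically.

`F_ROH` divides summed ROH length by the autosomal genome length
(default 2.45 Gb, the pig autosome scale) and decomposes it into
<5 Mb / 5–10 Mb / >10 Mb classes, the conventional proxies for
ancestral, intermediate and recent inbreeding. The ROH-incidence scan
counts covering individuals per SNP and declares the empirical top 1%
significant; the top tail is the `⌈q·n⌉`-th largest order statistic with
ties included, so a constant score vector returns everything — a
documented degenerate case, not an error.

## Structure, ancestry and conservation tiers

IBS distance is `1 − mean(1 − |x_i − x_j|/2)` over shared non-missing
SNPs. FST is Weir–Cockerham θ with explicit variance components;
per-SNP values may be negative and are retained (ratio-of-sums
aggregation, the standard practice). Neighbor joining is delegated to
`ape::nj()` — a mature Saitou–Nei implementation — behind the
`nj_tree()` surface; the test-suite checks recovery of random additive
trees through it. The GRM is VanRaden/GCTA-style with per-SNP
centering and `2p(1−p)` scaling; monomorphic SNPs are excluded and
missing dosages mean-imputed inside the kernel (zero contribution).
PCA is the eigendecomposition of this GRM; the same kernel is the LMM
kinship, so `grm()` and `pca_grm()` cannot drift apart.

Supervised ancestry fixes per-lineage reference allele frequencies
(clamped to [0.001, 0.999]) and runs an EM iteration on each
individual's ancestry simplex — the supervised analogue of an ADMIXTURE
run with frozen allele frequencies. Unsupervised ADMIXTURE is out of
scope; the conservation workflow only needs a per-individual proportion
of the native lineage. A caveat that shaped the simulator's defaults
(below): the estimator is only as unbiased as the native reference is
close to the recipient's own pre-admixture background — private drift of
the reference panel (of order `t/2N + 1/2n`) is misattributed to the
donor side.

Conservation tiers cut the native-lineage proportion at the mean,
mean − 1 SD and mean − 2 SD: `nucleus` (≥ mean), `candidate1`,
`candidate2`, and `discard` (< mean − 2 SD). The mean and SD can be
supplied externally (e.g. from a larger published cohort), in which case
the cutpoints drop out exactly. Individuals whose F or F_ROH exceed its
own mean + 2 SD are flagged as inbreeding outliers. Family assignment
cuts the individual NJ tree's internal edges longest-first, keeping
every resulting monophyletic group at or above a minimum number of
boars, with an optional cap on the family count; the published analyses
delimit families visually, so a deterministic rule with an override was
chosen instead of attempting to reproduce any particular count.

## Selection scans

EHH is the probability that two random carriers of a core allele are
identical from the core out to a position,
`Σ_h C(n_h,2)/C(n,2)`, computed outward until it falls below 0.05. iHH
integrates EHH against genetic distance by trapezoid on both sides,
including the first sub-threshold point; extension is capped at 400 SNPs
per side (EHH is essentially always below threshold long before that at
array densities). uniHS = `ln(iHH_ancestral/iHH_derived)` is
standardized to mean 0, SD 1 within 50 derived-allele-frequency bins,
merging bins under 20 SNPs with their nearest populated neighbour —
selscan's `norm` conventions. SNPs without an ancestral-allele
annotation keep `allele2` as the reference orientation and are flagged
`polarized = FALSE`: their sign is untrusted, and like all SNPs they
enter the candidate ranking through |iHS| only.

EigenGWAS regresses a principal-component score on each SNP's dosage,
applies genomic control (λ = median χ²/0.4549 — part of the cited
method, switchable off) and a Bonferroni threshold 0.05/m. Two
properties matter for calibration and are easy to misread as bugs:
with the PC estimated from the same genotypes, the null median χ² is
inflated by roughly the top GRM eigenvalue, `(1 + √(n/m))²`, even for
unrelated individuals in exact HWE, and the Wald χ² adds a small-sample
t-distribution factor. λ therefore approaches 1 only when m ≫ n and
individuals are unrelated; the calibration check uses an iid HWE panel
of 50 individuals × 120,000 SNPs, where λ sits near 1.06. On samples
full of close relatives (e.g. a whole Wright–Fisher herd) λ is large
because the structure is real.

Candidate loci are SNPs flagged by at least two of the three scans
(ROH incidence, iHS, EigenGWAS), reported with ±50 kb flanks merged
into regions — the functional-annotation step downstream of these
windows (gene lookup, GO/KEGG) is outside the package's scope.

## Introgression

Site patterns are per-population derived-allele sample frequencies on
the quartet (((P1, P2), P3), O), polarized so the outgroup-major allele
is ancestral. Patterson's D is `Σ(ABBA − BABA)/Σ(ABBA + BABA)` with
`ABBA = (1−p1)p2p3(1−pO)`, `BABA = p1(1−p2)p3(1−pO)`; the jackknife
point estimate is exactly the ratio of sums (the jackknife affects only
the SE), with contiguous 5 Mb blocks by default (the block size is a
flag; published work rarely prints it). A normal p-value accompanies
the jackknife Z — the conventional significance route for D, preferred
here over a t-test. f3(A; B, C) subtracts the finite-sample correction
`p̂_A(1−p̂_A)/(n_A − 1)` (allele count n_A), which makes it unbiased when
A is simply another sample of B's source population — the test-suite
asserts exactly that property, and Z < −2 flags significant admixture.

Windowed f_dM uses 10-SNP windows stepping by 2 SNPs, never spanning
chromosomes, with Malinsky's dynamic-donor denominator; per-site
|numerator| ≤ denominator, so every defined window lies in [−1, 1].
Windows are Z-transformed against the empirical mean and SD of the scan
and tested one-sided (upper tail: introgression into P2 is the
alternative of interest); the printed f_dM threshold is therefore
dataset-specific by construction and recomputed per scan rather than
hard-coded. dxy and π are **per-variant** averages — the only choice on
array data, stated prominently because their absolute values are not
comparable to sequence-based estimates. π carries the 2n/(2n−1)
correction. The π-boost summary `(π_target − π_ref)/π_ref` is emitted
both over positive-f_dM windows and over significant windows, since the
published description is ambiguous about which set enters the average.
A constant f_dM scan yields zero significant windows with a warning
(a degenerate scan is an answer, not an error).

## Mixed-model association

`lmm_assoc()` fits `y = Wα + xβ + u + ε` with `u ~ N(0, Vg·K)` per SNP:
K is eigendecomposed once, δ = Ve/Vg is profiled by REML on a log₁₀ grid
of 41 points spanning 10⁻⁴–10⁴ with golden-section refinement in the
winning bracket, and β gets a Wald χ²₁ test. REML (not ML) matches the
cited software's default. With K = I the fit collapses to ordinary
least squares exactly (β and SE agree to 1e-8; the p-value is the Wald
normal version of OLS's t-test). Missing dosages at the tested SNP are
mean-imputed for the association stage only. Raw p-values are reported
without multiple-testing correction, matching how small candidate-gene
panels are conventionally presented; users scanning many SNPs should
correct downstream.

## The simulator: what it emulates, and what it does not

`simulate_panel()` runs a forward Wright–Fisher diploid simulation on
(((P1, P2), P3), O): founders draw alleles independently with
frequencies Uniform(0.05, 0.95); populations split at configurable
generations; recombination is Poisson on the cM map (uniform 1 cM/Mb by
default) with independent assortment between chromosomes; at the pulse
generation each parent of a recipient newborn is drawn from the donor
with probability α. Local ancestry is tracked exactly through every
meiosis, so truth tracts are bookkeeping, not inference — the reason a
forward simulator was chosen over a coalescent one.

Defaults are the package's stated study conditions: 2,000 SNPs on two
100 Mb chromosomes; recipient P2 of 200 diploids (the scale of a
conserved herd); donor split 60 generations and outgroup 100 generations
back; a native reference panel P1 of 400 diploids splitting from P2 only
6 generations before a pulse at generation 4; samples of 30/150/60/60
(O/P1/P2/P3). Two of these need justification. First, the generation
counts are deliberately compressed relative to real pig history — what
is preserved is the ordering and contrast (deep donor split ≫ recent
native divergence > pulse), which is what the frequency- and
haplotype-based statistics respond to; absolute divergence levels are
therefore lower than between real Chinese and European pigs. Second, P1
is parameterized as a large, very recently diverged native reference
rather than a deeply diverged wild population: supervised ancestry
misattributes the reference panel's private drift (≈ t/2N + 1/2n) to
the donor, so an accurate pulse-fraction recovery — which the test
battery asserts within ±0.05 — is only a fair expectation when the
native reference is a close proxy, exactly as the published workflow's
native cluster (built from many closely related Chinese breeds,
including the target's own samples) is. Ancestral (pre-split) pool
sizes are independently configurable because shared-branch drift is
common-mode for the ancestry estimator; defaults keep them at 150–200.

What the generator does **not** emulate: new mutations (all
polymorphism is standing founder variation, fine for frequency-based
statistics, a stated limitation for site-pattern realism), selection
during the simulated epochs, sex chromosomes, genotyping error and
missingness patterns of real chips, and ascertainment bias of array
content. Passing tests therefore demonstrate correctness of the
estimators under a clean neutral-admixture model, not robustness to
array artefacts.

`simulate_hwe_panel()` draws iid HWE genotypes — the exact "unrelated
panmictic" null used for the ROH false-positive guard and the genomic
control calibration. `plant_roh()` regenerates a panel at HWE with
frequencies Uniform(0.2, 0.8) (heterozygosity ≳ 0.32, so spurious long
runs are vanishingly rare) and forces planned intervals homozygous,
with the two-sentinel delimiting described above.
`simulate_phenotype()` adds `Σxβ + g + e` with `g ~ N(0, σ²_g·GRM)` and
the environmental variance set so the realized genetic share equals the
requested h².

## Problem sizes and determinism

All randomness flows from explicit seeds; the pipeline derives
per-stage streams from one root seed and reruns byte-identically. The
test-suite and the acceptance script use desk-scale sizes chosen to
exercise every code path in minutes: default simulations of 2,000 SNPs
and a few hundred diploids; 20 planted ROH configurations plus a
200 × 3,000 HWE false-positive guard at mean heterozygosity ≈ 0.365;
50 random 8-taxon trees for NJ; 20 pulse-free simulations for the D
null; 500 polygenic null phenotypes for the mixed model's type-I error;
six simulation replicates per pulse fraction α ∈ {0.1, 0.25, 0.5} for
ancestry recovery (single-run recovery error is dominated by genuine
ancestry drift, of SD ≈ `√(α(1−α)·t/2N)`, not estimator error, hence
the replicate averaging).

## Known limitations

* dxy/π are per-variant, not per-bp; compare only within a panel.
* Ne from the Sved relation without the `1/n` correction is biased
  downward at modest sample sizes (the correction is exposed as an
  option).
* iHS needs phased input; the package does not phase (the simulator
  emits phase, and imputation/phasing of real panels is upstream).
* The ROH caller inherits PLINK's hit-fraction boundary effect
  (one-SNP shaving at run edges) by design.
* The supervised ancestry estimator is biased when the native reference
  is strongly diverged from the target's background; interpret
  proportions against reference-panel quality.
* qpAdm/f4-ratio estimation, TreeMix graphs, unsupervised ADMIXTURE,
  VCF input and gene annotation are out of scope.
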