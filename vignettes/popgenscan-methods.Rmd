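---
title: "Models and methods behind popgenscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind popgenscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popgenscan)
```

popgenscan implements the inference chain used to characterise rare,
habitat-fragmented butterfly populations from whole-genome resequencing
data: how much diversity they hold, how structured they are, whether a
mimicry allele arrived by introgression, and how much deleterious load
they carry. This vignette explains each model, the tunable parameters and
their defaults, what the built-in coalescent simulator does and does not
emulate, and the numerical choices made where the design was open.

## Data model and filtering

Genotypes are stored as alternate-allele dosages (0/1/2, `NA` for
missing) in a sites × samples matrix with 1-based VCF-native coordinates.
Only biallelic SNPs are retained on input; indels, multi-allelic and
symbolic records are dropped with a count. Phased and unphased genotype
separators are treated identically and half-calls (`./1`) become missing
— the conservative, unambiguous reading.

Filtering follows the order of a standard GATK-style pipeline:
genotype-level quality masking first (calls with GQ below `min_gq`, a
Phred-scaled score, become missing; the conventional threshold is 10),
then site-level filters on missingness and minor allele frequency
(`min_maf`, typically 0.05 for structure analyses). Different analyses
legitimately use different filter combinations, so filters are
per-command configuration rather than a single global set.

Windows tile each chromosome from position 1 in 1-based inclusive
coordinates, `[k·L+1, (k+1)·L]`; a sliding mode starts windows at
`1, step+1, 2·step+1, ...`. Empty windows are emitted, because
length-normalised π needs them.

## Windowed statistics

**π.** Each site contributes its unbiased per-site heterozygosity
2k(n−k)/(n(n−1)), with n the called allele copies and k the
alternate-allele count in the focal population. The default denominator
is the window length in bp — monomorphic and uncalled positions count as
zero difference — which is the convention of the standard per-window VCF
tools and makes values comparable to published per-site π. Sites with
fewer than 4 called copies are skipped for all frequency-based
statistics: below that, the frequency estimate is too noisy to be worth a
site (the threshold is configurable).

**Tajima's D.** The classical statistic with its published constants
(a₁, a₂, b₁, b₂, c₁, c₂, e₁, e₂). Because those constants assume one
constant sample size, only sites where every genotype in the focal
population is called are used, with n = 2 × samples; the alternative —
per-site n with modal-n constants — was rejected as ambiguous. D is
undefined (reported `NA`) when S = 0. Note that even at neutral
equilibrium the expectation of D is not exactly zero but slightly
negative; calibration tests therefore use a 3-standard-error band around
zero at moderate replication rather than asserting an exact null.

**F_ST.** The two-population Weir–Cockerham variance-components
estimator, computed per site from sample sizes, allele frequencies and
observed heterozygote proportions, and combined across a window as the
weighted ratio Σa / Σ(a+b+c). Negative per-window values are reported
as-is in scan tables; clamping to zero happens only where the
isolation-by-distance analysis requires it. Sites need at least two
called diploids in each population.

**d_xy.** Absolute divergence Σ [p_A(1−p_B) + p_B(1−p_A)] / L, insensitive
to within-population diversity, with the same window-length denominator
as π.

## Introgression statistics

Four-taxon tests use taxa ordered (P1, P2, P3, O) and frequency-weighted
site patterns: ABBA = (1−p1)·p2·p3·(1−p4), BABA = p1·(1−p2)·p3·(1−p4).
The outgroup's sample frequency p4 is used directly rather than forcing
it to 0/1, so outgroup-polymorphic sites contribute with weight (1−p4) —
the frequency-weighted formulation of the standard genomics toolkits.
Patterson's D is the normalised difference of the summed patterns.

**Jackknife.** Genome-wide uncertainty comes from a delete-one block
jackknife over contiguous, equal-count blocks; the default 20 blocks
means each pseudo-replicate keeps 95% of the data. The point estimate is
the ratio-of-sums on the full data (the standard choice; the
mean-of-window-D alternative is not used), and
sd = √[((m−1)/m) Σ (θ₍₋ⱼ₎ − θ̄)²]. For a linear statistic this reduces
exactly to the classical standard error of a mean of block means, which
the tests verify.

**f_d.** The window-scale admixture-fraction estimator divides the
ABBA−BABA numerator by its value under complete sharing, where both P2
and P3 are replaced per site by the donor proxy — whichever of the two
has the larger derived frequency at that site. Negative values are
clamped to 0 (they carry no admixture interpretation) and a zero
denominator yields `NA`. f_d is reported per window only, never
aggregated genome-wide. Two properties matter for interpretation: it is
monotone in the true admixture fraction (verified on simulations across
f = 0, 0.25, 0.5, 1), and it is mildly conservative — with a recent 50%
pulse and well-diverged donor, window means settle around 0.44–0.48
rather than 0.50, because taking the per-site maximum of two noisy
frequencies inflates the denominator. Simulation tests therefore check
recovery to 0.1 absolute, not to pure sampling error.

**Peaks.** The scan literature rarely states a peak-calling rule, so the
package makes its choice explicit: windows with a robust z-score
(median/MAD) at or above 4 are flagged, and flagged windows within
`merge_gap` of each other merge into intervals reported with their
maximum-statistic window. When the MAD is zero (e.g. a majority of
clamped-zero f_d windows) the caller falls back to mean/SD z-scores with
a warning.

**Dating.** For an introgressed haplotype, the ratio of focal to
genome-wide divergence from the donor approximates the fraction of the
total divergence time since the haplotypes last shared an ancestor;
multiplied by a supplied total divergence time it gives an absolute date.
This deliberately ignores selection, recombination and rate variation in
the focal region, as any such ratio estimate must.

## Mutation load

Sites are polarized by outgroup majority: the ancestral allele is
assigned only when every outgroup sample is called and a strict majority
of outgroup allele copies agree; ties stay unassigned. Effect labels use
the snpEff vocabulary verbatim — synonymous_variant, intron_variant and
NONE are neutral; missense_variant, start_lost and stop_gained are
deleterious; everything else is excluded (stop_lost, for example, is in
neither set).

The unfolded SFS is tallied only over sites with exactly the target
number of called allele copies — no hypergeometric projection — matching
strict-call filtering and keeping counts interpretable. "Fixed in a
population" defaults to derived frequency 1 among called copies (the
standard substitution definition, consistent with contrasting "fixed"
against "polymorphic"); the literal per-individual-presence reading
(every individual carries ≥ 1 derived copy) is available behind
`per_individual = TRUE`. χ² tests are plain Pearson with
margin-derived expectations and no multiple-testing correction, which is
left to the caller.

## Demography and geography

N_e = π/(4μ) is the neutral-equilibrium point estimate; the confidence
interval maps the mutation-rate bounds inversely (high μ → low N_e). The
estimate inherits the equilibrium and neutrality assumptions of the
estimator and should be read accordingly.

Distances are haversine great circles on a sphere of radius 6371.0088 km
(the IUGG mean radius). The ellipsoidal geodesic used by some published
pipelines differs by under 0.5%, which is irrelevant to slope
comparisons; ellipsoid support would be a drop-in extension. Population
locations are geographic midpoints — unit-3-vector averages — of member
coordinates; for populations sampled at a single locality this is that
locality. Isolation by distance regresses F_ST/(1−F_ST) on distance by
ordinary least squares, with negative F_ST set to 0 first and F_ST = 1
pairs excluded (infinite linearised value). No Mantel test is attached;
the slope and r² are descriptive.

## Haplotype networks

Alignment columns containing a gap or N in any sequence are removed
first (complete deletion — pairwise deletion can make distances
non-metric), then identical sequences collapse into haplotypes numbered
by first occurrence. The network is the union of all minimum spanning
trees: edges are processed by increasing mutation count, and every edge
joining components still separate under strictly smaller distances is
kept before merging. This is the ε = 0 backbone of a median-joining
network; median (Steiner) vertices are not inferred, which on
low-divergence mitochondrial data leaves the topology class unchanged.
Alignment-based π divides mean pairwise differences by the retained
column count.

## The coalescent simulator

The simulator exists to validate the whole chain against known truth. It
is a structured Kingman coalescent run backward in time, in generations:
within a population of diploid size N each lineage pair coalesces at
rate 1/(2N); lineages migrate at per-generation backward rates; at a
split the derived population's lineages join the ancestral population;
at an admixture pulse each recipient lineage jumps to the source with
probability f; sizes are piecewise constant. Mutations follow the
infinite-sites model: Poisson on total branch length, placed
proportionally to branch length, carriers being the tips below the
branch. Haplotypes pair consecutively into diploids within populations
(random mating, no inbreeding parameter).

Deliberate simplifications, and what they mean for the tests:

- **One genealogy per window, no recombination.** The analyses treat
  windows as loci, so this is the matching idealisation — but it makes
  sites within a window fully linked. A direct consequence: the naive
  multinomial χ² goodness-of-fit of the pooled simulated SFS against the
  neutral (1/i)/a_{n−1} expectation is invalid (the statistic is
  inflated several-fold by within-window correlation even when the
  proportions are unbiased). Calibration tests therefore apply the χ² to
  one site per window — independent genealogies give a valid multinomial
  — alongside a total-variation bound on the pooled spectrum, and the
  i.i.d.-site version of the check is exercised through the
  frequency-class sampler below.
- **Deleterious sites are emulated by spectrum distortion**, not forward
  simulation with selection coefficients: `sample_sfs_sites` draws
  derived counts from arbitrary class weights (neutral ∝ 1/i), which
  suffices to test the load pipeline's bookkeeping and recovery, not to
  model selection dynamics.
- **No sequencing error, no missing-data process.** Passing calibration
  shows the estimators are correct on clean input; robustness to
  real-data artefacts is the province of the filters, exercised
  separately.

Time is generations throughout; any years conversion (e.g. four
generations per year) is presentation-layer.

## Validation strategy and problem sizes

Every statistic is checked against an independent brute-force oracle on
toy data (allele-pair enumeration for π, literal pattern counting for
ABBA/BABA, component-by-component evaluation for Weir–Cockerham,
first-principles constants for Tajima's D) to 1e−10, and the chain is
calibrated against coalescent theory: E[π] = θ and mean Tajima's D within
3 SE of 0 on 1000 constant-size windows (n = 12, θL = 10); E[T₂] = 2N
and Watterson's E[S] on replicate genealogies; D consistent with zero
(20-block jackknife, ≥ 2×10⁴ quartet sites) without gene flow; strict
f_d ordering across pulse fractions and correct localization of a pulse
confined to windows 91–100 of 200; a 10× bottleneck at 0.2N generations
producing positive Tajima's D and intermediate-frequency SFS excess.
These sizes keep the default suite in tens of seconds while leaving the
stochastic bands well separated.

## Configuration and reproducibility

The pipeline wrapper takes a declarative YAML config (unknown keys are
rejected) with flag-style overrides in code; every run writes a manifest
echoing the config, seed and package version. Missing values are "NA" in
all TSV outputs, never silent zeros. A single integer seed fixes all
randomness; identical seeds give byte-identical outputs, which the tests
enforce.

## Known limitations

Windowed statistics assume SNP-only input; haplotype-based selection
statistics, LD, and within-window recombination are out of scope. The
divergence-ratio date is a point approximation with no uncertainty
propagation. The jackknife assumes blocks are exchangeable at the chosen
granularity. The median-joining network's inferred median vertices are
not reproduced, only the ε = 0 backbone. The IBD midpoint rule collapses
each population to a single point, which understates within-population
geographic spread.
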