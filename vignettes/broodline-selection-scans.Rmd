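---
title: "Detecting selection across generations of isolated broodlines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting selection across generations of isolated broodlines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(broodscan)
```

## The problem

Hatchery salmonids that spawn on a fixed age schedule split into
reproductively isolated *broodlines*: the fish returning in year $y$ are the
descendants of those that returned in $y-3$, not of the intervening years.
A reintroduction program seeded from an external source stock therefore
carries several parallel lineages through the new habitat, each an
independent replicate of the same colonisation experiment. Genotyping each
year class gives, per broodline, a short time series of allele frequencies
at thousands of SNPs; the analytical task is to separate loci whose
frequencies moved because of directional selection from the large majority
that moved only by genetic drift at small effective size.

`broodscan` implements that analysis end to end: a QC cascade for
RAD-seq-style SNP panels, ordination to verify the broodline structure, two
complementary outlier scans run per broodline, a cross-method /
cross-broodline consensus, nearest-gene annotation of candidates, and a
Wright–Fisher simulator that generates studies of exactly this shape with
known truth, so every stage can be validated against planted selection.

## Data model

Genotypes live in a `genotype_dataset`: unordered diploid allele calls
(two integer matrices, `NA` = missing), unique sample and locus ids, and a
metadata table (`brood_year`, `broodline`, `generation`) carried in a
sidecar TSV because neither GenePop nor VCF stores it. Allele codes are
1-based; code 1 is the *tracked allele* (the VCF REF allele, or the lowest
code in a GenePop file), and every frequency the package reports is the
tracked-allele frequency. This convention is arbitrary — the paperwork of
which allele is "reference" carries no information — but it is applied
consistently and recorded in output headers, and both scans are invariant
to flipping it (the temporal statistic uses two-sided deviations; FST is
symmetric in the alleles).

Readers and writers cover GenePop (4/6-digit codes auto-detected), VCF with
GT genotypes (via `vcfR`), SAM alignments of locus tag sequences (mapQ
filter, multi-mapping retained on purpose), and GFF3 gene annotations (via
`ape::read.gff`). Round-trips preserve the call matrix exactly, including
the missingness pattern.

## The simulator and its defaults

`sim_config()` defaults describe the study the package is built around:

* 3 broodlines (A/B/C founded 2000/2001/2002), 3-year generation interval,
  4 generations each, broodline A missing its 2003 year class;
* per-year sample sizes `A: 24/–/63/80, B: 50/65/7/90, C: 55/70/85/75`
  (664 fish in total) — synthetic values chosen once to match the design
  constraints of the motivating reintroduction program (a 664-fish total,
  one 7-fish year class in line B, per-year counts between ~7 and ~100)
  and not revisited;
* 5,392 biallelic loci with founder frequencies `Uniform(0.05, 0.95)`
  (SNP panels are pre-ascertained, so no mutation model and no loci below
  the discovery MAF);
* drift as binomial resampling of `2*Ne` gametes with `Ne = 100` per
  generation, the order of a hatchery broodstock;
* `founder_divergence = 3` drift generations separating each broodline's
  founder pool from a common source pool, which reproduces the observed
  three-cluster ordination;
* 50 loci under shared additive selection with `s = 0.5` on the tracked
  allele (deterministic update `p' = p(1+s)/(1+ps)` before the binomial
  draw). Over three generations this moves a mid-frequency allele by
  ~0.2–0.3, the regime the scans are meant to detect;
* per-sample and per-locus missing-call rates drawn from `Beta(2, 38)`
  (mean 5% each, jointly ~10%), emulating unevenly sequenced libraries.

What the simulator deliberately does *not* emulate: linkage (loci are
exchangeable and independent, so clustering of hits along chromosomes
cannot be studied), age-structured gene flow by early-maturing males
(a migration parameter exists but defaults to 0), genotyping error and
null alleles (the HWE stage is therefore tested on clean data plus crafted
violations, not on a mechanistic error model), and read-level artefacts.
Passing tests consequently show that the *statistics* behave as intended
under drift and selection of the stated magnitude — not that real RAD data
are free of the artefacts QC exists to catch.

A calibration identity anchors the null process: the two-point temporal
FST (Nei–Tajima standardised variance, `temporal_fst()`) between
generation 0 and generation $t$ has expectation
$1 - (1 - \tfrac{1}{2N_e})^t$ under pure drift, and the simulator
reproduces it within a few percent over thousands of loci. Note that this
two-point quantity is *not* the same as the Weir–Cockerham estimate across
all four year classes, whose expectation under the same process is roughly
a quarter as large (the covariance structure of a drifting random walk,
not an error); the package keeps the two diagnostics separate.

## QC cascade

`run_qc()` applies four stages in a fixed, order-sensitive sequence:
(1) drop non-biallelic loci and loci with pooled minor allele frequency
below 5%; (2) drop samples with under 75% of calls at the remaining loci;
(3) drop loci with under 80% of calls in the remaining samples; (4) test
Hardy–Weinberg equilibrium pooling all remaining samples and remove loci
rejected by a Benjamini–Yekutieli step-up at α = 0.01. Removal is strictly
"less than" at every boundary, so an entity sitting exactly on a threshold
survives. The report telescopes (input = removed + surviving at each
stage) and records the effective BY threshold — the largest raw p-value
removed — for comparison across datasets; the package computes this from
the data rather than fixing a number, because it depends on the locus
count entering stage 4.

The HWE test is the two-sided *exact* conditional test (summing the
probabilities of all heterozygote configurations no more probable than the
one observed). At the small minor-allele counts RAD panels produce, the
chi-square approximation misbehaves, and the exact test costs nothing at
these sizes; it is verified against full enumeration for every genotype
triple up to n = 10. Pooling all broodlines into one HWE population mildly
mis-specifies the test (a Wahlund effect), but at the founder divergences
simulated here the implied inbreeding coefficient is below 0.01 and the
BY correction keeps the stage conservative — on HWE-conforming data it
removes well under 0.5% of loci.

## Ordination

Between-sample distances are squared Smouse–Peakall codominant genotypic
distances: per locus, half the squared Euclidean distance between
allele-count vectors (AA–AA 0, AA–AB 1, AB–AB 0, AB–CD 2, AA–BC 3,
AA–BB 4), summed over loci called in both samples. Missing data use
pairwise deletion with rescaling by `total loci / shared loci`; imputing
group means instead would leak broodline information into the distances,
which is exactly what the ordination is supposed to discover. Principal
coordinates follow by Gower double-centering (through `stats::cmdscale`);
axis signs are pinned by forcing each axis's largest-magnitude coordinate
positive, so plots are reproducible under sample reordering. Negative
eigenvalues (the metric is not exactly Euclidean under missingness
rescaling) are reported but contribute no coordinates.

One design note on the negative control used in validation: with
`founder_divergence = 0` the three *founding* year classes are exchangeable
and show no clusters, and that is where the control is evaluated. Later
generations separate by broodline even without founder divergence, because
each line accumulates its own drift — a real signal, not an artefact, but
not the one the control is meant to isolate.

## Temporal scan: regression slopes against Q–Q linearity

Per broodline, `run_temporal_scan()` regresses each locus's allele
frequency on generation index (missing year classes keep their true
spacing — slopes are per-generation rates), then asks whether any slopes
are too extreme for a normal slope distribution. The ordered slopes are
paired with normal quantiles at Blom positions $(i - 3/8)/(m + 1/4)$, a
reference line is fitted through the first/third-quartile points — the
robust convention, chosen so the suspect tails get no leverage — and each
locus's deviation $d_i = |b_i - e_i|$ from the line is referred to a
chi-square(1) through $X_i = d_i^2 / \bar d$. A locus is an outlier when
$p < 0.01$, equivalently when $d_i \ge \sqrt{q_{0.99}\,\bar d}$; the scan
reports that realized cutoff as a multiple of $\bar d$, which is the
dataset-dependent quantity users can compare across studies.

Two choices here deserve their reasoning spelled out:

* **The statistic is not scale-invariant, and the scan works in percentage
  points.** $X = d^2/\bar d$ changes with the units of the slopes. On raw
  proportion slopes, $\bar d$ in any realistic panel is ~10⁻³, putting the
  α = 0.01 cutoff at 60–100× the average deviation — beyond any achievable
  slope, so nothing could ever be flagged. On the percent scale the cutoff
  lands at a single-digit multiple of $\bar d$ and the scan has both its
  nominal size (~1% flags under pure drift) and real power, which is also
  the regime in which published uses of this construction report realized
  cutoffs of a few $\bar d$. Frequencies are therefore multiplied by 100
  inside the scan; the outlier set is what the cutoff multiple implies.
* **Signed slopes, untransformed frequencies.** Slope distributions under
  drift are symmetric about zero, and the Q–Q fit uses the signed values;
  no variance-stabilising transform is applied, because the method's
  reference is the empirical quartile line, not a parametric variance
  model. Loci observable in fewer than two generations are excluded from
  the Q–Q fit and reported as unscannable rather than non-significant.

Validation: equivariance (affine maps of the slopes leave the flagged set
unchanged), type-I control at roughly the nominal 1% under the simulator's
drift null, and ≥ 60% of planted `s = 0.5` loci detected in at least one
of the three broodline scans (the lines share the selective pressure, so
detection is read across replicates; single-scan power is ~50%).

## FST–heterozygosity scan with a temporal-drift null

`run_fst_scan()` treats each year class of one broodline as a population
(year classes below 8 fish are excluded — the scan mirrors the exclusion
of a 7-fish year class in the motivating study), estimates per-locus
Weir–Cockerham θ and expected heterozygosity, and compares each locus
against an He-conditioned envelope of simulated neutral loci. The null is
deliberately *not* an island-model coalescent, although the classic tools
this stage replaces use one: the "populations" are successive generations
of a single line, so the honest neutral model is multi-generation drift at
a calibrated effective size, sampled at the observed group sizes. The
mutation model is omitted entirely — over four generations at SNP scale
its contribution is nil. A subsample-size setting found in the classic
implementations has no reproducible role in this design and is omitted.

The neutral mean FST is estimated iteratively (mean, drop loci outside a
provisional envelope, re-estimate — so strong outliers do not inflate the
null), the effective size is calibrated by bisection until simulated
neutral loci match that mean, and the final envelope bins ≥ 50,000
simulated loci into ≥ 20 equal-count He bins with per-bin quantiles at
`(1±ci)/2`, interpolated between bin centres. Per locus, the empirical
p-value is the add-one-smoothed fraction of bin-matched simulated loci
with FST at least as large; Benjamini–Hochberg at FDR 0.1 designates
directional outliers, and loci under the lower envelope are reported
separately as balancing-selection candidates but never feed the
directional consensus. Held-out neutral loci fall inside the 95% envelope
at 95 ± 1%, and null empirical p-values are uniform to a
Kolmogorov–Smirnov distance < 0.05.

## Consensus and annotation

`build_consensus()` crosses methods (temporal, FST, optionally an external
Bayesian outlier table) with broodlines into a locus × test matrix,
distinguishing *not tested* from *not significant* — broodline A's missing
year class must not silently deflate its consensus. Tiers: candidate
(≥ 1 test), highly significant (≥ 2 tests overall), and within-broodline
consensus (≥ 2 of 3 methods). `venn_counts()` partitions the candidate set
along either axis. `nearest_genes()` reports up to three genes within
100,000 bases of each retained mapped position (boundary inclusive;
distance 0 inside a span; multi-mapped loci annotated at every position),
with ties broken by gene start then id for deterministic output. The
window is measured from the mapped tag start rather than the SNP's offset
within the tag; the discrepancy (≤ 80 bases) is immaterial at window
scale.

## Numerical and degenerate-input choices

* Exact HWE probabilities are computed in log space and the tail uses a
  `1 + 1e-7` relative tolerance when comparing configuration
  probabilities, so ties at equal probability are included.
* `by_fdr_filter()` / BH use `stats::p.adjust`; both are verified against
  naive sort-and-scan step-up oracles.
* Degenerate scans fail loudly: fewer than 20 slopes, zero interquartile
  spread, zero mean deviation, fewer than 100 scannable loci for envelope
  calibration, and QC stages that empty the dataset all raise errors
  naming the stage.
* Fractional effective sizes during calibration round the gamete count,
  and fixation is absorbing in all trajectories.
* All stochastic stages take explicit seeds; a pipeline run with the same
  configuration and seed reproduces every stage output byte-for-byte.

## Problem sizes used in validation

The shipped tests exercise the estimator oracles on hundreds of small
random fixtures; drift-null calibration on 20 simulated studies of 5,000
loci × 600 fish; power and consensus enrichment on one study with 50
planted loci at `s = 0.5`; ordination recovery on the full 664 × 5,392
default design; and envelope coverage with 50,000 simulated neutral loci
against 5,000 held-out loci. These sizes were chosen to give each check
comfortable statistical resolution (binomial standard errors well inside
the asserted tolerances) while keeping a full validation run in the
single-digit minutes.

## Limitations

The FST scan's empirical p-values are floored at `1/(bin size + 1)`
(~4 × 10⁻⁴ at the 50,000-sim, 20-bin default), so Benjamini–Hochberg at
FDR 0.1 can designate directional outliers only when a good number of loci
sit at that floor simultaneously; at the moderate effect sizes the
simulator plants, the scan's information is carried mainly by its
empirical p-values and envelope flags (which the tests check for
enrichment and coverage) rather than by large flag counts, and consensus
tiers at these effect sizes are driven mostly by the temporal scan
replicated across broodlines.
The percent-scale convention in the temporal scan is a modelling decision
forced by a scale-dependent statistic, not a derived property; users
comparing against other implementations should compare realized cutoff
multiples, not raw statistics. The FST envelope conditions on He but not
on group-size imbalance per locus (missingness shifts per-locus sample
sizes slightly; the envelope uses the group totals). The consensus tiers
treat tests as exchangeable evidence and ignore their dependence — the
two internal scans share the same frequency data, so "2 of 3 methods" is
weaker than two independent confirmations. And the simulator's
exchangeable-locus design cannot address questions about genomic
clustering of selected regions.
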