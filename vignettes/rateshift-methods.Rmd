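---
title: "Methods: genome-wide substitution-rate dynamics on a time tree"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genome-wide substitution-rate dynamics on a time tree}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`rateshift` analyses per-gene nucleotide substitution rates across a clade of
species whose phylogeny and divergence times are known. Its questions are the
classic ones of comparative molecular evolution: which genes evolve
significantly faster in one focal species than in its relatives; whether a
gene's rate has increased steadily since the common ancestor; whether rate
differences among lineages look like adaptive attraction to shifted optima
(Ornstein-Uhlenbeck) or like neutral drift (Brownian motion); whether fast
genes carry codon-level signatures of positive selection; and whether rates
covary with resting metabolic rate once body mass, temperature and shared
ancestry are controlled. Every stage can be run on synthetic data with
planted, labelled effects, so recovery, false-discovery and calibration
properties are measurable rather than assumed.

The default study conditions mirror a small teleost clade: 12 species on an
ultrametric time tree of root age 225.84 My containing a three-species focal
clade, around 500 single-copy orthologous genes, and per-species resting
metabolic rates compiled from heterogeneous literature sources.

# The rate model

## Two-stage estimation

For each gene we first estimate branch lengths \(\hat b_e\)
(substitutions/site) on the fixed topology by maximum likelihood under
JC or HKY, using Felsenstein pruning implemented in C++. Base frequencies are
the observed frequencies; the transition/transversion ratio \(\kappa\) is
estimated per gene.

Second, a Bayesian log-Brownian rate process is fitted on the time tree. The
log instantaneous rate \(x_v = \ln r_v\) at each node evolves as Brownian
motion, \(x_c \sim \mathrm{N}(x_p,\ \sigma^2_{\ln r}\, t_e)\), and the
estimated substitution count on each branch is treated as a Poisson
observation,
\[
\mathrm{round}(\hat b_e L) \sim \mathrm{Poisson}\!\left(L\, t_e\,
\tfrac{r_p + r_c}{2}\right),
\]
with the trapezoidal (endpoint-mean) integral of the rate along the branch.
Priors are weakly informative: \(x_{\mathrm{root}} \sim \mathrm{N}(\ln \bar
r, 10^2)\) around a tree-wide moment guess, and a half-Cauchy(1) prior on
\(\sigma^2_{\ln r}\). Two independent Metropolis-within-Gibbs chains of
20,000 iterations (25% burn-in, thinning 5) are run per gene; posterior
medians are reported.

This two-stage construction targets the same estimand as joint
sequence-level relaxed-clock samplers but runs orders of magnitude faster;
the recovery suite quantifies the approximation (rank correlation of true
versus estimated per-species rates above 0.9 at 10 kb, 90% credible-interval
coverage for \(\sigma^2_{\ln r}\) inside the nominal band).

## Units

Per-species rates are root-to-tip path sums of branch expected substitutions
\(d_e = t_e (r_p + r_c)/2\). Because every root-to-tip path spans exactly
one root age, these are *substitutions per site per root age* — the unit in
which species are compared (typical per-species means around 0.1–0.3 on the
default simulations). Instant node rates (substitutions/site/My) are also
exported; doubling the assumed root age halves every instant rate but leaves
path sums unchanged.

## Convergence policy

Convergence follows the two-chain rule — relative parameter discrepancy
below 0.1 and effective sample size above 300 — applied to the scalar trace
summaries (the tree-mean log rate and \(\log \sigma^2_{\ln r}\)), which is
how trace-comparison tools operate in practice. Applying a max-discrepancy
rule across all ~23 node-level rates would reject almost every finite chain
by multiplicity alone. Genes failing the rule are flagged and reported, not
silently dropped.

# Fast-gene calling

A gene is fast-evolving in the focal species when its rate there exceeds its
rates in the other species by an exact two-tailed Wilcoxon signed-rank test
on the 11 paired differences, with Benjamini-Hochberg control across genes
within the species and a direction gate (median difference positive). The
exact null distribution is enumerated by dynamic programming over doubled
ranks, which handles ties exactly.

Two structural properties of this design deserve emphasis, because they are
measurable on synthetic data and bound what the caller can do at 12 taxa:

* The signed-rank statistic saturates at its floor, \(p = 2/2^{11} \approx
  0.001\), whenever the focal species simply tops the gene's rate table —
  regardless of the margin. Under a neutral model the focal species is the
  maximum for roughly 1/12 of genes (more if its phylogenetic position makes
  it weakly correlated with the rest), and step-up FDR control across
  hundreds of genes then admits most of these as calls. Planted-effect false
  discovery proportions are therefore far above the nominal level at this
  taxon count; the same arithmetic explains why nearly half of all genes can
  be called fast in a fast lineage. This is a property of the test design,
  not of the implementation, and the acceptance suite reports it honestly.
* Sensitivity to a 3x focal-clade elevation is limited by the cross-species
  rate spread. The default diffusion
  \(\sigma_{\ln r} = 0.05\,/\sqrt{\mathrm{My}}\) gives instantaneous tip
  rates an e-fold scale of about 0.75 (roughly a tenfold extreme range);
  root-to-tip path averaging compresses that to a few-fold spread in the
  per-species rates, under which single background species still overtake
  the elevated focal species in a minority of genes.

# Ancestral trends

For each gene the posterior-median instantaneous rates at the nodes along
the root-to-focal-tip path are extracted; a gene shows a *constant trend*
when every consecutive step strictly increases (strictness is configurable).
The fold change tip/root is reported. Under a neutral model with symmetric
increments the chance level for a strict monotone path of \(m\) steps is
\(2^{-m}\), which the null suite verifies. Group-level contrasts (per-species
counts, ANOVA, Tukey HSD, ANCOVA with the number of path nodes as covariate)
use the standard `stats` machinery.

# Adaptive versus neutral rate evolution

Per gene, the log10 per-species rates are fitted with three Gaussian
process models on the tree: BM (2 parameters), single-optimum OU (OU1;
\(\alpha, \sigma^2, \theta\)), and multi-regime OU (OUM) with optima painted
on branches. The default painting contrasts the focal clade (crown plus
stem) with all other branches. The OU covariance uses the fixed-root form
\[
V_{ij} = \frac{\sigma^2}{2\alpha} e^{-\alpha d_{ij}}
\left(1 - e^{-2\alpha s_{ij}}\right),
\]
with \(d\) the patristic time distance and \(s\) the shared root-to-MRCA
time, and lineage expectations are the \(\alpha\)-weighted averages of the
optima along each root-to-tip branch history, the root sitting at its
regime's optimum. For fixed \(\alpha\) the optima and \(\sigma^2\) profile
out by generalized least squares, so each model needs only a 1-D search over
\(\alpha\) (log-spaced multi-start grid, \(10^{-4}/T\) to \(50/T\), then
local refinement). OUM support requires beating both BM (\(\chi^2_k\)) and
OU1 (\(\chi^2_{k-1}\)) with BH-adjusted \(p < 0.05\). The \(\chi^2\)
reference is anti-conservative for \(\alpha\)-on-boundary comparisons, which
the pipeline never tests alone; power at 12 taxa is modest by construction
and the synthetic suites document it (around 60–70% detection at a
three-stationary-SD optimum separation, under 7% under BM).

# Branch-site positive selection

The codon model is GY94-style with F3x4 frequencies and the universal code;
site classes follow model A (purifying, neutral, and the two positive
classes on foreground branches), with class proportions parameterized as
\(p_0, p_1, p_{2a} = (1 - p_0 - p_1)p_0/(p_0+p_1), p_{2b} = (1 - p_0 -
p_1)p_1/(p_0+p_1)\). Rate matrices for all classes share a *neutral
reference scale* — each \(Q(\omega)\) is normalized by the mean rate of the
\(\omega = 1\) matrix — so branch lengths are expected substitutions per
codon for a neutral site and positively selected classes genuinely evolve
faster. (Normalizing each class to its own unit rate would equalize total
substitution rates across classes and remove most of the test's power.)

Fitting uses a profile structure: for each outer parameter vector (a global
branch-length scale, \(\kappa\), \(\omega_0\), \(\omega_2\)) the class-wise
site log-likelihoods are computed once by pruning and the class proportions
are profiled out by a fast inner optimization with multiple starts. Relative
branch lengths come from nucleotide-level ML on the fixed topology; the
global scale is optimized under the alternative model and held for the null,
which re-optimizes its remaining free parameters. Full per-branch
codon-model branch-length optimization was deliberately traded away: it adds
~21 parameters per gene for negligible change in the likelihood-ratio
statistic at these divergences, at roughly tenfold cost. A coarse
\(\omega_2\) grid seeds the alternative fit, and the alternative is
restarted from the null solution whenever nesting is violated, so the LRT is
never negative beyond round-off.

Significance follows the unhalved \(\chi^2_1\) convention (conservative for
the boundary mixture), with two post-hoc filters: at least one site with
naive-empirical-Bayes positive-class posterior above 0.5, and — when more
than five such sites exist — a median inter-site gap above 10 codons to
guard against alignment-error clusters. NEB at the MLEs is used instead of
the BEB prior-grid integration; the 0.5 threshold operates identically and
the known difference is documented. No FDR correction is applied across
genes for this test, since most LRT p-values sit at or near 1 and step-up
correction would discard true positives.

# Substitution-saturation screen

Candidates are genes with any branch longer than 1 substitution/site or
total tree length above 2. For candidates, the saturation index is the mean
per-site Shannon entropy (base 2, gaps excluded per site) divided by the
*expected* plug-in entropy of the same number of sequences drawn from the
alignment-wide base frequencies — the exact finite-sample expectation, so
fully random data score close to 1. The critical value Iss.c is estimated by
simulation: alignments across a divergence gradient, neighbor-joining
reconstruction, and a logistic fit of recovery probability against Iss on
the decaying limb; Iss.c is where fitted recovery crosses 0.95 (the
threshold is configurable, since the original method's exact cut-off is not
restated in the sources this design follows). A one-sample t-test of the
per-site entropy ratios against Iss.c gives retain / marginal / flag
decisions. On the default synthetic conditions no gene reaches saturation,
so the screen retains everything — the expected behaviour for
genome-scale coding alignments at these divergences.

# Metabolic rate

Raw resting metabolic rates arrive as \(\mu\)W, ml O2/h, or ml CO2/h at
various body temperatures. Normalization: CO2 volumes divide by the
respiratory quotient (0.8); oxygen consumption converts to power with the
oxyjoule coefficient \(16 + 5.164\,\mathrm{RQ}\) J/ml O2; everything is
referred to 25 degC through \(Q_{10} = 1.65\). The allometric exponent of
\(\mathrm{RMR} = a M^b\) is estimated by phylogenetic GLS under Brownian
covariance, and the adjusted RMR (\(\mathrm{RMR}/M^{\hat b}\)) is by
construction free of any residual mass slope.

Gene-specific correlations between log rate and log adjusted RMR use a
bivariate Brownian model with unknown 2x2 diffusion covariance. Under the
reference prior the posterior of the covariance is inverse-Wishart, and the
sign probability of the diffusion correlation has a closed Student-t form
(the regression coefficient is marginally \(t_{n-2}\)); `pp` is that tail
mass and classification requires `pp > 0.95`. At 12 species this threshold
admits about 10% of null genes by calibration — the two-sided 0.10 level —
which the suites verify; power against planted correlations is limited at
this taxon count because a single shared trait realization is available.

# The synthetic-data generator

The generator is first-class, tested code. The focal clade and the backbone
of remaining species split at the root — the geometry of the emulated
system, whose focal lineage belongs to one side of a deep basal divergence —
with the focal crown at 0.6 of the root age and the backbone crown just
below the root; both sides are pure-birth subtrees rescaled to those depths,
which guarantees monophyly and makes the clade's depth (and hence the
operating characteristics of every clade-contrast analysis) independent of
the seed. Per-gene log rates follow the same Brownian law the estimator
assumes, with planted classes:

* *fast* genes: all focal-clade node rates multiplied by 3 (10% of genes);
* *trend* genes: positive drift along the root-to-focal path totalling a
  2.22-fold increase over the root age, with reduced diffusion (5%);
* *selected* genes: a 10% positive-site class at \(\omega_2 = 4\) on the
  focal branches, purifying (\(\omega_0 = 0.2\)) background (5%);
* *trait-correlated* genes: rate increments share correlation -0.7 with the
  RMR noise increments (10%).

The baseline rate \(8\times 10^{-4}\)/site/My puts typical path totals near
0.2 per root age, the scale reported for comparable fish datasets; the
per-gene cross-species spread of path rates is a few-fold (instantaneous
rates spread about tenfold — empirical datasets show even wider per-species
ranges, reflecting lineage effects beyond a homogeneous diffusion). Body
masses span roughly
0.5–6000 g, temperatures 3–28 degC, and raw RMR values rotate through the
three literature units. Sequences evolve site-independently (HKY for
nucleotides, GY94 for codons, no indels, no among-site rate variation beyond
the site classes); alignment error, GC evolution and saturation artefacts
are deliberately absent, so passing recovery tests demonstrate correctness
of the estimators under their own assumptions, not robustness to real-data
pathologies. All draws descend from one master seed with per-gene seeds, so
outputs are byte-identical across reruns and independent of execution order.

# Problem sizes and numerical choices

The shipped test-suite and acceptance-script problem sizes are desk-scale
choices that keep each property measurable: 50–100 genes for rate recovery
(10 kb Poisson exposure), 500 genes for the caller suites, 150–200 genes for
the OU suites, 25–50 replicates at 300 codons for the branch-site size and
power checks (simulated at the focal species' own rate scale, path totals
near 0.29 per root age, since selection is tested on the fast genes),
120–150 replicates for saturation recovery curves.
Optimizer bounds and tolerances: branch lengths in \([10^{-8}, 10]\)
subs/site on the log scale; \(\alpha \in [10^{-4}/T, 50/T]\); inner
proportion profiles from three fixed starts; matrix exponentials through
symmetric eigendecompositions of the \(\pi^{1/2}\)-similarity transform,
clamped to \([0,1]\); pruning partials rescaled on underflow. Degenerate
inputs (constant traits, all-gap columns, all-zero differences, singular
covariances) return defined results or named errors rather than NaN.

# Known limitations

* The signed-rank fast-gene design cannot control planted-effect FDR at 12
  taxa (see above); its calls are best read as a liberal screen, as the very
  large fast-gene fractions in comparable studies suggest.
* OU model selection at 12 tips has limited power and the \(\chi^2\)
  reference is approximate near boundaries.
* NEB site posteriors are slightly anti-conservative relative to BEB when
  parameter uncertainty is large.
* The trait correlation uses the two-stage fitted rates rather than a joint
  sequence-level model; attenuation from estimation noise is quantified by
  the calibration suite, not removed.
* Iss.c is re-simulated rather than taken from published lookup tables, so
  absolute values differ from table-based tools while the retain/flag
  decisions agree in the unsaturated regime.

# Running the pieces

```r
library(rateshift)
cfg <- sim_config(seed = 1, n_genes = 50)
study <- simulate_study(cfg)
est <- estimate_rate_matrix(study, L = 10000)
fast <- call_fast_genes(est$R, focal = "F1")
head(fast[fast$fast, ])
```

The full eight-stage pipeline, with per-stage TSV outputs and a manifest, is
`run_pipeline(cfg, out_dir)`; `scripts/acceptance.R` reruns the headline
recovery and calibration numbers from scratch for a given seed.
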