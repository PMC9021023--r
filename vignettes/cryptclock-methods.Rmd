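---
title: "Methods: somatic mutation burden, signatures and lifespan scaling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: somatic mutation burden, signatures and lifespan scaling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cryptclock)
```

# The scientific problem

A colorectal crypt is clonally derived from a single stem cell, so
whole-genome sequencing of one microdissected crypt reads out the somatic
mutations of one cell lineage. Dividing a crypt's mutation burden by the
age of the animal gives a somatic mutation rate per year, and comparing
such rates across species tests whether somatic mutagenesis scales with
lifespan (a prediction of the somatic mutation theory of ageing) or with
body mass (a candidate resolution of Peto's paradox). `cryptclock`
implements the full computational path from per-crypt candidate variant
tables to the cross-species scaling regressions, together with a
synthetic-data generator that reproduces the statistical structure each
stage relies on, with complete ground truth for scoring.

This vignette documents the models, their assumptions, the tunable
parameters, and the numerical and design decisions, in the order the
pipeline runs.

# Synthetic cohorts

`simulate_cohort()` draws a cohort under an explicit generative model:

* Species lifespans are log-uniform on 3–85 years and adult masses
  log-uniform on 20 g – 800 kg, spanning roughly the ranges seen in
  mammalian cohorts of this kind (mouse to human, and beyond in mass). A
  configuration switch (`mass_lifespan_cor`) induces a correlation between
  log-mass and log-lifespan to exercise the confounder analyses; the
  default is independence.
* Every species carries a true end-of-lifespan burden `k` (default 3000
  substitutions per genome, with `elb_sdlog = 0` by default so all species
  share `k` exactly; a lognormal species-level deviation is available by
  configuration). The per-crypt true mutation count is Poisson with mean
  `(k / L) * age`, with ages uniform on `(0.1 L, L)`.
* Reads: per-sample depths are negative binomial with mean 30
  (`depth_dispersion` is the NB size, default 30 — mild overdispersion
  around a typical 30× design). True variants are private to their crypt
  and binomially sampled at their VAF cluster; artifact sites are an
  *individual-level* process: each site has a low VAF (uniform on
  0.05–0.30 by default) and binomial read support in *every* sample of the
  individual. This is exactly the alternative hypothesis the beta-binomial
  filter discriminates against, which is why artifacts are simulated this
  way. A site is emitted as a candidate variant when its focal-sample alt
  count reaches the 4-read calling threshold.
* Signature activity per species is Dirichlet(1.2, 1.2, 0.8) over the
  three bundled processes. The low concentration is deliberate: real
  cohorts show strong inter-species contrast (some species dominated by
  oxidative damage, others by deamination), and that contrast is what
  makes joint signature extraction well-posed (see below).
* Mortality records are Gompertz (via `flexsurv`), left-truncated at the
  age of maturity, mirroring zoo mortality records with juvenile deaths
  removed.
* Coverage/BAF tracks: per-bin read counts are negative binomial with the
  sample mean scaled by `total CN / 2` (mixed with diploid normal cells at
  the given purity); heterozygous-SNP alt counts are beta-binomial around
  the allele fraction implied by (major, minor, purity).

What the generator does **not** emulate: read-level errors (no FASTQ/BAM),
alignment artifacts beyond the per-variant annotation fields, indel
sequence realism (indels carry class labels only), and germline variation.
Tests passing on these cohorts therefore demonstrate the correctness of
the *statistical machinery* under its stated model, not robustness to
every failure mode of real sequencing data.

All randomness flows from one master seed through named substreams
(`substream_seed()`), so any crypt's variant table can be regenerated
independently of the rest of the run.

# Variant filtering

`apply_filter_stack()` applies the post-calling filters in a fixed,
recorded order: caller quality flags → alignment quality → position masks
→ sequencing coverage → strand bias → indel proximity → spatial clustering
→ beta-binomial → minimum VAF → maximum indel VAF. Each filter is a pure
partition (pass ∪ fail = input), and only the minimum-VAF filter depends
on another filter's output (the beta-binomial survivors define its
threshold).

The beta-binomial filter is the scientific core. For each candidate site,
the pooled success fraction is fixed at its maximum-likelihood value
μ = Σalt/Σdepth across the individual's samples, and the overdispersion ρ
is maximized over a 50-point log-spaced grid on [10⁻⁶, 10⁻⁰·⁰⁵] of the
beta-binomial log-likelihood with α = μ(1−ρ)/ρ, β = (1−μ)(1−ρ)/ρ. A
genuine somatic variant is present at high VAF in one crypt and absent in
its siblings — a maximally overdispersed pattern — while artifacts recur
at similar low VAFs everywhere and look binomial. Variants with ρ > 0.3
are therefore **kept**; ρ ≤ 0.3 is discarded. The grid density is
configurable; μ is not profiled jointly with ρ.

Numerical/boundary conventions, chosen where the rule leaves room: spatial
clustering treats "within 1 kb" as distance ≤ 1000 bp inclusive and
clusters transitively; the coverage caps use the type-7 (linear
interpolation) 99th percentile of the sample-wide depth distribution, with
sites strictly above it removed; variant coordinates are 1-based (VCF
convention) while BED-style region inputs are 0-based half-open and
converted at the boundary. The two-section concordance statistic uses the
union of both call sets as its denominator.

# Clonality

The VAF distribution of each crypt is modelled as a K-component mixture of
binomials truncated at the 4-read calling minimum and renormalized
(`truncated_binomial_logpmf()`), with per-variant depths entering the
truncation normalizer individually. The EM algorithm uses exact truncated
responsibilities in the E-step; because the truncated likelihood has no
closed-form mean update, the M-step maximizes each cluster mean by bounded
1-D search (tolerance 10⁻⁸ on the probability). Initialization is by
quantile-spread means plus random restarts; convergence is declared at a
log-likelihood increase below 10⁻⁶. Identical (alt, depth) pairs share
responsibilities, so the EM runs on unique pairs with multiplicities — an
exact reformulation that makes model selection fast at 30× depth.

BIC (−2·loglik + (2K−1)·log n, counting K means and K−1 free weights)
selects K over 1–5, ties to the smaller K. Fitted mixing weights estimate
the composition of the *callable* (truncated) population; they are not
corrected for each cluster's detection probability, so a subclonal
cluster's weight refers to the variants that survived the 4-read minimum.

Sample verdicts follow three rules — fewer than 50 variants; burden above
3× the median of same-individual samples (computed over siblings with ≥ 50
variants); and fewer than 70% of variants hard-assigned (argmax
responsibility) to clusters with mean VAF ≥ 0.3. The low-VAF rule is
waived when *every* sample of the individual has a primary cluster (the
cluster with the largest mixing proportion) below 0.3 — those individuals
plausibly carry a high fraction of non-epithelial cells, and their crypts
may still each be dominated by one clone. A configuration allow-list can
rescue named samples, mirroring manual curation, instead of hard-coding
sample names.

# Burden, rate and end-of-lifespan burden

The analysable genome is the callable span minus the merged union of the
exclusion region sets (IRanges interval algebra; exact integer bp). The
adjusted burden multiplies the mutation density by the species' total
genome size; the rate per year divides by age, and the end-of-lifespan
burden multiplies by the lifespan estimate. The mitochondrial path applies
VAF > 0.01, depth ≥ 500×, D-loop exclusion and a 4× cohort-mean burden
rule, then reports the per-copy burden as the sum of variant VAFs
(heteroplasmy-weighted) scaled from analysable to full mtDNA length; a raw
variant count is available via `weighted = FALSE`, since the weighting
convention is a design choice rather than a published formula.

# Mutational signatures

Spectra are 96-channel counts in COSMIC channel order. Opportunities are
the trinucleotide frequencies of the analysable genome, collapsed onto the
pyrimidine strand (32 classes); signatures are stored genome-independent
and adjusted per spectrum by multiplying channel probabilities with
opportunity ratios and renormalizing, so conversions between
representations are exact and invertible.

`fit_exposures()` maximizes the multinomial likelihood of a spectrum under
an exposure-weighted signature mixture by EM multiplicative updates —
deterministic from uniform initialization, convergence at Δloglik < 10⁻⁸.
`extract_signatures()` generalizes this to joint fitting and extraction:
alternating multiplicative (KL/NMF) updates on exposures and on the de
novo signature rows, with fixed signatures frozen and per-row
opportunities applied, multiple seeded restarts keeping the best
likelihood. This maximum-likelihood scheme deliberately replaces the
Bayesian MCMC machinery used by signature packages such as sigfit;
goodness of fit is reported as the cosine similarity between observed and
reconstructed spectra.

One genuine limitation surfaced during development and is worth stating
plainly: with a nearly flat (clock-like) component in the basis, the ML
NMF likelihood has a quasi-ridge — mass can shift between the flat
signature and the others with almost no likelihood cost, so exposure
estimates are only well-constrained when the cohort's rows differ strongly
in their signature mix. This is why the generator defaults to contrasted
(low-concentration Dirichlet) exposures; with near-identical mixes across
species, recovered profiles remain accurate (cosine ≥ 0.95) but exposure
splits between flat-like components can drift by ~0.1–0.2. A Bayesian
prior would regularize this; the ML analogue reports it honestly instead.

Candidate-signature detection compares, per sample, the base model
(e.g. SBS1 + SBS5 + SBS18 + SBS34) against base + candidate (e.g. SBS88):
the statistic 2Δloglik is referred to χ²(1), which is conservative because
the exposure is boundary-constrained at zero, and Benjamini–Hochberg
correction is applied across samples (q < 0.05; the APOBEC rule requires
both the SBS2 and the SBS13 test to pass). Cohort depletion uses the
two-sided Fisher exact test on positive/negative counts.

The bundled signature catalogue (`reference_signatures()`,
`inst/extdata/signatures_synthetic.tsv`) is a **synthetic stand-in**: the
profiles mimic the qualitative channel structure of well-known COSMIC
signatures (deamination at NCG, APOBEC at TCN, flat clock-like, oxidative
C>A, and a distinctive colibactin-like T>N pattern) but are constructed,
not downloaded, and every test that uses them scores recovery of planted
truth rather than agreement with the real catalogue.

# Copy number

Per 100-kb bin, the caller scores all 15 ordered allele-specific states
(major ≥ minor, each 0–4) by a joint likelihood: negative binomial for the
bin's read count around `baseline × (purity·total + (1−purity)·2)/2`, and
a symmetric two-component beta-binomial for het-SNP alt counts around the
expected allele fraction and its complement — an exact, phasing-free
treatment of BAF folding. Dispersions default to method-of-moments
estimates from the genome-wide (diploid-dominated) data, refreshed per
sample. Bins below 10 reads in sample or normal are masked.

A penalty `λ·(|major−1| + |minor−1|)` (default λ = 2) biases calls toward
the diploid state; the value is a calibration of this implementation — set
so a one-allele event needs about two log-units of evidence per bin —
validated by the synthetic acceptance studies (zero false event segments
on diploid tracks; Jaccard ≥ 0.8 on injected ≥ 10-bin events at purity
0.85) rather than taken from a published table. Segmentation requires runs
of ≥ 5 identical states, merges same-state segments separated by < 5 bins,
and the cohort filter keeps only non-diploid segments that span ≥ 10 bins
(1 Mb) and are private to a single sample.

# Comparative regressions

Lifespan is the age by which 80% of adults have died: the type-7
(linear-interpolation) empirical quantile of adult ages at death, with a
percentile bootstrap over animals for the confidence interval — a
distribution-free substitute for a parametric survival fit. Multi-cohort
estimates (e.g. national census cohorts) are pooled by arithmetic mean.

The scaling model is a Gaussian linear mixed-effects regression of
per-crypt rates on species-level predictors with random *slopes* at the
individual and species levels and species-specific residual variances
(heteroscedasticity is essential: dividing burdens by age makes rate
variance scale with 1/age², which differs across species). The fit is by
direct maximum likelihood: the fixed effects are profiled out by
generalized least squares, and the log-variances are optimized
numerically (quasi-Newton with jittered restarts, variance floor 10⁻¹²).
Because the predictors are species-level constants and the design is
balanced, each species block's covariance has a closed-form eigenstructure
(grand mean / individual contrasts / within-individual contrasts), which
the implementation exploits; unbalanced or varying-predictor designs fall
back to a dense Cholesky path, and the two paths agree to optimizer
tolerance. The suite cross-checks the likelihood and estimates against
`nlme::lme` with `varIdent` weights on the same specification.

The zero-intercept inverse-lifespan model estimates `k`, the cross-species
mean end-of-lifespan burden; its Wald confidence interval comes from the
profiled GLS covariance. FVE = ESS/(ESS+RSS) is computed over *species
means* — observed means average per-individual means so crypt-rich
individuals do not dominate; predictions use fixed effects only — and the
same observed-mean centring is used for zero-intercept models. Nested
models are compared by likelihood-ratio tests with df equal to the
parameter-count difference. Allometric regressions are OLS on log10
scales; partial correlations regress the residuals of the two pairwise
allometric fits on each other. Bootstrap resamples species or individuals
with replacement (resampled units are relabelled, so a species drawn twice
contributes two independent blocks). PGLS uses Brownian-motion covariance
from the tree (`ape::vcv`) with ML-profiled scale; on a star phylogeny it
reduces exactly to OLS.

# Problem sizes used by the test suite

The suite's simulation studies use the cohort design the recovery claims
are stated for — 16 species × 3 individuals × 3 crypts — for the
k-recovery (100 cohorts) and explanatory-power ordering (100 cohorts)
studies; the nested-LRT size calibration uses 500 replicates of a leaner
8 × 3 × 2 design, which keeps the study's run time proportionate while
leaving the test's nominal-size window unchanged. Mixture-EM selection
and recovery use 100 replicates of 200-variant crypts at 30× depth;
copy-number studies use 300-bin tracks (50 diploid replicates, 10
event-injection replicates). These sizes are the package's declared study
conditions: the thresholds the studies assert against were fixed by the
analysis design, not adjusted to the observed outcomes.

# Known limitations

* Read-level filters (clipping, fragment quality, secondary alignments)
  are consumed as precomputed per-variant annotations; computing them from
  BAM files, and the inverted-repeat (hairpin) filter that requires raw
  reads, are out of scope.
* The mixture model estimates post-truncation cluster weights and does not
  estimate purity beyond cluster means.
* ML signature extraction inherits the NMF ridge discussed above; exposure
  estimates for near-flat components should be read with that caveat.
* The copy-number caller assumes a given purity (no purity estimation),
  reports no subclonal fractions, and does not refine breakpoints below
  bin resolution.
* PGLS is available only for species-mean rates with a simple
  Brownian-motion covariance; the heteroscedastic mixed-effects structure
  cannot be carried into it.
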