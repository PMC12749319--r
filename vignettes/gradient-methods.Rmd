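---
title: "Cortical gradient analysis in Lewy body disease: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cortical gradient analysis in Lewy body disease: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lbdgrad)
```

## The analysis in one paragraph

`lbdgrad` compares macroscale cortical organisation between healthy controls
(HC), cognitively normal Parkinson's disease (PD-NC), and Lewy body dementia
(LBD) from parcellated connectomes. Each subject's 200×200 connectivity
matrix is turned into a set of *cortical gradients* — eigenmaps of a
diffusion operator built on inter-regional connectivity similarity — and
groups are compared in two complementary ways: on the *spread* of the
principal gradient's score distribution (expansion vs contraction of the
cortical hierarchy) and *region by region* (reorganisation of a region's
place in the hierarchy). A composite deviation score summarises how far a
subject's whole gradient map sits from the control norm, and its rank
correlation with clinical scores links organisation to severity. Finally,
regional group-difference maps are contextualised against annotation maps
(cell-marker expression, cytoarchitectural axes, laminar thicknesses) and
region×gene expression tables, with spatially constrained spin permutations
providing the null model throughout.

## The gradient model

For a connectivity matrix with rows $x_i$ (a region's connectivity
profile), similarity is the normalised angle

$$A(i,j) = 1 - \frac{\arccos(\mathrm{cossim}(x_i, x_j))}{\pi},$$

computed after keeping only the strongest weights per row (sparsity 0.9 by
default: the top 10% of each row survives; 0.8 and 0.5 are replication
settings). Rows are sparsified before the kernel; the kernel restores
symmetry, so no re-symmetrisation is applied in between. Cosines within
$10^{-12}$ of $\pm 1$ are snapped to $\pm 1$ so that identical, orthogonal
and antiparallel profiles give exactly 1, 0.5 and 0 — `acos` has unbounded
derivative at the endpoints and would otherwise amplify representation
error by eight orders of magnitude.

Diffusion map embedding with anisotropy $\alpha = 0.5$ forms
$W = A / (d_i^\alpha d_j^\alpha)$ from the row sums $d$ of $A$, then the
Markov operator $P = W / d'$, and eigendecomposes it through the symmetric
conjugate $S = D'^{-1/2} W D'^{-1/2}$ (numerically stable; right
eigenvectors of $P$ are recovered as $D'^{-1/2} v$). The constant
eigenvector at $\lambda = 1$ is discarded; component $k$ is the $k$-th
remaining eigenvector, unit-normalised and scaled by
$\lambda_k/(1-\lambda_k)$ (the automatic diffusion-time convention).
A second unit eigenvalue means the sparsified graph is disconnected and the
embedding refuses to proceed, advising a lower sparsity. Eigenvector sign
is fixed by making each component's largest-magnitude entry positive.
Structural and functional matrices can be fused by horizontal concatenation
after rescaling each block to unit Frobenius norm, so neither modality
dominates the cosine geometry; block weighting beyond norm equalisation is
deliberately not attempted.

## Alignment convention

Individual gradients live in subject-specific eigenbases and must be
aligned to a group template (built by running the pipeline on the
element-wise mean of the control matrices) before any cross-subject
comparison. The package's `procrustes_align()` is the standard single-pass
orthogonal Procrustes rotation — no scaling, no centring — and recovers an
arbitrarily rotated template exactly.

How that rotation is *composed* with the diffusion-time scaling matters
more than is usually appreciated. Rotating the scaled scores directly (the
common toolchain convention) mixes components of unequal variance: whenever
a subject's regional organisation differs from the template's, the rotation
leaks variance from the dominant gradient into weaker ones, which shows up
as an apparent *contraction* of the subject's principal gradient. In
simulation this turns a pure reorganisation effect — which leaves the
connectome's spectrum exactly invariant, because permuting regions
conjugates the affinity matrix — into a 20–47% false-rejection rate for the
spread comparison. `cohort_gradients()` therefore rotates the orthonormal
eigenvector basis and re-applies the subject's own
$\lambda_k/(1-\lambda_k)$ scaling afterwards: a subject's spectral scale is
a property of its own connectome (its inter-regional differentiation) and
is not altered by the change of basis. Under this convention the spread
statistic is exactly invariant to regional permutation, expansion and
contraction remain fully visible (they act through $\lambda_1$), and the
spread test is calibrated (type-I 0.05 in 100-replicate simulation).

## Group comparisons

Per subject, the spread of the aligned principal gradient is summarised
three ways — SD (primary), range, and mean absolute deviation from the
median — because the source analyses do not pin down a single statistic;
all three scale homogeneously and order expansion > none > contraction.
Groups are compared with a tie-corrected Kruskal–Wallis test and Dunn
pairwise z tests (FDR across pairs). Regional comparisons are per-region
OLS of the aligned score on a group indicator plus age and a binary sex
indicator, giving an unthresholded t-map with two-sided p and
Benjamini–Hochberg q across the 200 parcels; the parcel-level OLS+FDR
replaces vertex-wise random-field FWE, whose assumptions do not apply at
200 parcels. Subjects with missing covariates are dropped listwise with a
warning; a rank-deficient design (e.g. a single-sex subgroup) is an
explicit error rather than a silent near-singular fit.

The composite deviation score is
$G_s = \sum_r |x_r - \mu_r| / \sigma_r$, with $\mu_r, \sigma_r$ the mean
and sample SD (denominator $n-1$) of the aligned scores across *controls
only*. $G_s$ is zero exactly at the control mean and equals the region
count when a subject sits one control SD away everywhere. Severity
correlations are Spearman; the covariate-adjusted variant rank-transforms
both variables and all non-binary covariates, residualises by least
squares, and applies a Pearson t test to the residual correlation with
$n - 2 - k$ degrees of freedom (ranking the covariates too is what makes a
covariate that drives both variables cancel exactly; residualising ranks on
a *raw* covariate leaves rank-nonlinearity in both residuals and a spurious
partial correlation).

## Spin permutation nulls

All annotation and transcriptomic inference uses spatially constrained
permutations: a uniform random rotation applied to the left hemisphere's
parcel centroids and its x-mirrored counterpart to the right, each
hemisphere living on its own registration sphere, with each parcel
reassigned the value of the nearest rotated centroid (duplicates allowed).
The disease t-map is spun; annotation maps are held fixed, so the null
preserves the annotation's empirical structure. Two-sided
$p_{spin} = (1 + \#\{|\rho_{null}| \ge |\rho_{obs}|\})/(n+1)$, FDR-adjusted
across the declared annotation family (24 comparisons per t-map in the
packaged configuration: 16 cellular marker maps and 8 microarchitectural
maps) to give $q_{spin}$. Shrinking a family changes q, never p.

Two geometric details are load-bearing. First, each hemisphere must be a
*full* sphere (the spherical-registration convention): restricting parcels
to half-spheres makes rotations fold at the boundary and produces wildly
non-uniform source usage. Second, mirrored rotations preserve
exchangeability only for maps with homotopic (mirror-symmetric) structure —
which real annotation maps largely have. The synthetic map generator is
therefore homotopic by default; with non-homotopic maps the spun ensemble
under-disperses and the test inflates (18–27% at nominal 5% in our
measurements). An occasional random rotation is small enough to collapse to
the identity assignment; that is expected and simply contributes one
conservative null draw. On very smooth maps (length scale above ~1 radian,
a handful of effective degrees of freedom) the test remains mildly liberal;
this is a known boundary regime of spin inference, not specific to this
implementation. Calibration at the default conditions (smoothness 0.6, 200
parcels, 1000 spins) is 0.04–0.07 at nominal 0.05.

## Transcriptomic PLS

Partial least squares regresses the t-map ($Y$, z-scored) on the
region×gene expression table ($X$, columns z-scored with population SD,
zero-variance genes dropped with a warning), by NIPALS with deflation
(tolerance $10^{-12}$, 500 iterations cap — for a univariate response each
component converges in one step, with the first weight vector proportional
to $X'y$, which also makes the spin refits exact and fast). Three
components are fitted by default; PLS1 variance explained is tested against
refits with the spun response, and each gene's PLS1 weight against its own
spin-null weight distribution (two-sided), BH-adjusted across genes.

One arithmetic consequence deserves emphasis: with $n$ spins the smallest
attainable p is $1/(n+1)$, so with $m$ genes a q below a threshold $t$
requires at least $m/((n+1)\,t)$ genes at the permutation floor — at
$m = 1000$, $n = 1000$, $t = 0.05$ that is 20 genes. An isolated associated
gene can therefore *never* be declared significant; discoveries require
co-expressed modules, exactly as in real transcriptomes. The validation
suite plants a strong gene inside a tight module for this reason. A second
subtlety: conditional on one fixed expression realisation the spin test for
PLS1 variance carries a small instance-specific bias (rejection 0.08–0.09);
marginally across instances it is calibrated (0.050 over 300 fresh-instance
replicates), and with spatially white genes it is calibrated conditionally
too (0.055).

Term-list comparisons are a one-sided hypergeometric over-enrichment test
and Spearman similarity of shared term ranks; enrichment computation itself
(ontology querying) is upstream of this package.

## The synthetic cohort generator

Real participant-level imaging for this disease spectrum is
restricted-access, so every stage is validated on synthetic cohorts whose
defaults *are* the study conditions: 23 HC, 46 PD-NC, 62 LBD; group ages
66.8 (8.6), 62.3 (7.2), 70.1 (6.7) years; male fractions 0.48, 0.48, 0.81;
200 parcels.

Connectomes are generated from a latent one-dimensional gradient: region
coordinates drawn uniformly on (−1.5, 1.5) and centred, with expected edge
weight $\exp(-|\ell_i-\ell_j|)$ (exponential kernel, unit length scale —
this produces a dominant first eigen-gradient aligned with the latent
axis). Structural edges are overdispersed negative-binomial streamline
counts (mean 150 at zero latent distance, size 8, so variance exceeds the
mean as for real streamline counts); functional edges map the kernel into
\[−1, 1\] through the Fisher-z domain with additive noise there. Disease
regimes act on the latent coordinates: expansion scales by γ = 1.3,
contraction by γ = 0.8, reorganisation permutes 30% of coordinates at
unchanged scale. γ values are simulator conventions, not estimates of the
source data's effect sizes, which the source does not quantify. The
reorganisation permutation is drawn once per group — a disease trait shared
by that group's subjects; per-subject permutations would cancel in the
group mean and no regional effect could exist. Each subject additionally
receives latent jitter (SD 0.12) and multiplicative log-normal edge noise
(scale 0.1); without jitter, subjects are clones up to counting noise and
between-subject spread variance is unrealistically tiny. Synthetic
cognitive scores are rank-coupled to each subject's planted deviation via a
Gaussian copula (Pearson $2\sin(\pi\rho_S/6)$ on normal scores targets the
Spearman coefficient directly); note that within a single group the planted
deviation is nearly constant, so within-group severity analyses should
couple to the realised per-subject deviation ($G_s$) instead.

Parcels are Fibonacci lattices on per-hemisphere unit spheres (right
mirrors left in x), rotated by a seeded random rotation. Annotation maps
are white noise smoothed by a within-hemisphere geodesic exponential kernel
and z-scored; homotopic by default (see above). Expression tables are
per-gene smooth maps (length scale 0.1, chosen so unplanted genes are
essentially independent of any target: median |ρ| ≈ 0.07 at 200 parcels)
squashed to \[0, 1\] by a sigmoid, emulating scaled outlier-robust
normalisation; planted genes mix a target map at a stated effect size with
the gene's own noise map, so effect 1 is a monotone transform of the
target.

What the generator does *not* emulate: tractography biases and distance
effects, motion artefacts, donor structure of expression atlases,
subcortical connectivity, and any spatial embedding of the connectome's
latent axis on the cortical sheet (the latent gradient is independent of
parcel geometry). Passing tests therefore show the pipeline recovers planted
effects under its own statistical assumptions — not that those assumptions
hold in any particular acquisition.

## Numerical and validation choices

- Symmetry tolerance $10^{-8}$ on input matrices (averaged with the
  transpose below it, error above); NaN always rejected; TSV round-trips
  use 17 significant digits and are bit-exact for doubles.
- Sparsification drops the smallest $\lfloor s \cdot n\rfloor$ entries per
  row; ties at the cut drop the smaller column index first (any
  deterministic rule would do; this one is documented and stable).
- Validation problem sizes: cohort-level Monte Carlo runs use 100-parcel
  connectomes and 100 replicates (the spread-ordering and dissociation
  properties were additionally spot-checked at 200 parcels); spin and PLS
  calibration use the full 200-parcel sphere with 1000 spins. At much
  smaller parcellations (≤ 60 regions) the top two template eigenvalues
  approach degeneracy and the latent axis can land on G2 — gradient
  analyses at such sizes are not recommended.
- Severity-coupling recovery is judged against the sampling-theory band for
  a Spearman estimate at n = 62 (95% band ±0.20 around 0.5, from a 20,000
  draw Monte Carlo of the copula construction).
- All randomised stages take explicit integer seeds (default 0) and are
  byte-reproducible; spin ensembles and cohorts regenerate identically from
  their seed.

## Known limitations

Spin tests are approximate for maps that are extremely smooth or strongly
non-homotopic, and mildly instance-biased conditional on a fixed expression
table. The Dunn post-hoc uses a normal approximation (fine at these group
sizes). The embedding assumes a connected sparsified graph; very high
sparsity on weak connectomes will disconnect it, and the error says so. The
partial Spearman is the residualised-rank construction, one of several
partial-rank conventions in use. Fused gradients equalise block norms but
no further weighting; whether that matches any particular upstream
toolchain's fusion should be checked before mixing results.
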