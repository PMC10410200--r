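---
title: "Molecular-enriched functional connectivity: model, inference and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Molecular-enriched functional connectivity: model, inference and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reactfc)
```

## The model

Neuromodulatory systems (noradrenaline, dopamine, serotonin, acetylcholine)
and the GABA-A receptor system innervate the cortex with characteristic
spatial density profiles that can be imaged with PET/SPECT. `reactfc`
estimates, for each BOLD run, how strongly each voxel's signal couples to
the *dominant fluctuation* of each molecular system, by dual regression
(REACT):

**Stage 1 (spatial).** Let $D$ be the $T \times V$ within-mask BOLD data
with every volume demeaned across voxels, and $M$ the $V \times K$ matrix
of conditioned molecular templates with every column demeaned across the
mask. The per-system time series are the OLS solution at every time point,

$$S = D\,M\,(M^\top M)^{-1} \in \mathbb{R}^{T \times K}.$$

**Stage 2 (temporal).** The columns of $S$ are demeaned and scaled to unit
standard deviation (population convention, $1/T$ denominator, so results
are bit-reproducible); each voxel's series is demeaned; the voxelwise
multiple-regression betas

$$\beta_v = (\tilde S^\top \tilde S)^{-1} \tilde S^\top d_v \in \mathbb{R}^K$$

are the molecular-enriched FC maps, in BOLD-signal units per unit-SD
fluctuation. Demeaning axes differ deliberately between the stages:
spatial in stage 1 (the design is a spatial pattern), temporal in stage 2
(the design is a time course). Both choices are covered by invariance
tests (adding a spatial constant to a volume, or a temporal constant to a
voxel, changes nothing).

### Template conditioning

Raw density templates are conditioned in two steps, in this order:

1. *Reference-region fill.* Voxels of the tracer's kinetic reference
   region carry no valid density signal and are replaced by the minimum
   density over grey matter, so they contribute minimally without being
   excluded.
2. *Min-max rescaling* over the grey-matter mask onto $[0, 1]$. This is an
   affine, shape-preserving map (not histogram equalisation): rank order
   and distributional shape are untouched, and VIFs are provably invariant
   to it.

The analysis mask is the set of grey-matter voxels where **every**
conditioned template is strictly positive — voxels with density
information from all systems. Collinearity is screened with pairwise
Pearson correlations and variance inflation factors,
$\mathrm{VIF}_k = 1/(1 - R^2_k)$, from regressing template $k$ on the
others (with intercept) over mask voxels; VIF $> 5$ flags strong
collinearity, and an exactly collinear template reports an infinite VIF
with a flag rather than an error, so screening can always complete. The
screen defaults to conditioned templates; because the conditioning is
affine, raw templates give identical VIFs.

### Signal conditioning

The pipeline accepts already-registered volumes and provides the minimal
remaining steps: mean-WM/CSF nuisance regression (per voxel, intercept
included; a constant nuisance series is dropped with a warning),
discrete-cosine high-pass filtering (all DCT terms with frequency below
0.005 Hz, plus intercept — the basis is orthogonal, so retained
frequencies are untouched), and separable Gaussian smoothing (FWHM 6 mm by
default, sigma converted per axis from the affine; boundary-renormalised
so constants are preserved). Nuisance regression and the high-pass run
sequentially, in that order; running them as one combined model would
differ only through the (tiny) correlation between drift terms and
nuisance means, which is irrelevant at the group level. Smoothing is off
by default in the pipeline (`smooth: false`) because empirical inputs are
normally smoothed upstream; the synthetic path enables it where spatial
autocorrelation matters (see *Validation* below). Motion correction,
brain extraction, ICA denoising and registration are out of scope.

## Group inference

Per system, the per-run beta maps enter a voxelwise $2 \times 4$
within-subject ANOVA (condition: audio/rest; state:
awake/light/deep/recovery), using the classical decomposition in which
each effect is tested against its own interaction with subjects:
$F_\mathrm{cond} = MS_C / MS_{C\times s}$ with df $(1, N-1)$, and state
and interaction with df $(3, 3(N-1))$ — $(1,16)$ and $(3,48)$ at
$N = 17$. Degrees of freedom are *not* sphericity-corrected; validity
comes from permutation, not from the F reference distribution.

Cluster-extent FWE correction: maps are thresholded at the critical F for
a cluster-forming $p = 0.001$, components are formed under
26-connectivity (a design choice; 6 and 18 are available), and each
observed cluster's FWE p is its size's rank in the permutation null of the
*maximum* cluster size, with the add-one estimator
$p = (1 + \#\{\mathrm{null max} \ge s\}) / (n_\mathrm{perm} + 1)$, so p is
never zero and never below $1/(n_\mathrm{perm}+1)$. Subjects are
exchangeability blocks; the relabelling rule is effect-specific:

* **condition** — swap the two condition labels within a random subset of
  subjects (sign-flip group of size $2^N$; enumerated exhaustively and the
  p-value made exact whenever $2^N \le n_\mathrm{perm}$);
* **state** — a random permutation of the four state labels within each
  subject, applied identically in both conditions (a config switch allows
  independent per-condition permutations);
* **interaction** — permutation of within-subject residual cells after
  removing both main-effect profiles (the interaction F is invariant to
  that residualisation, which the tests verify to machine precision).

Across the $K = 5$ systems, cluster p-values are Bonferroni-adjusted:
survival means FWE $p < \alpha / K = 0.01$.

Post-hoc decomposition extracts mean enriched FC over surviving-cluster
voxels per run, then runs paired t contrasts with Sidak adjustment
($p_\mathrm{adj} = 1 - (1-p)^m$; $m = 6$ state pairs, $m = 1$ for the
condition pair), with confidence intervals at the Sidak-adjusted level
$1 - (1-\alpha)^{1/m}$ — the adjusted-level convention was chosen (and is
switchable) because it is the one that pairs coherently with adjusted
p-values. Marginal contrasts average cells within subject before
differencing. A significant interaction is decomposed into simple main
effects: all six state pairs within each condition separately. Atlas
contextualisation thresholds a mean network map (at 3 by convention) and
reports per-region overlap fractions; it feeds no inference.

## The synthetic-study generator

Every stage is testable without any download: `simulateTemplates` builds
smooth Gaussian random fields mixed by the Cholesky factor of a target
correlation matrix (default: 0.2 background, one 0.5 pair — the
low-to-moderate collinearity regime typical of empirical transporter and
receptor maps), then min-max rescales them; `simulateMasks` partitions the
grid radially into WM / GM / CSF compartments with a reference region
inside GM; `simulateStudy` builds one run per design cell as

$$y_v(t) = \sum_k L_k(v)\, s_k(t) + \varepsilon_v(t),$$

with loadings $L_k(v)$ proportional to the conditioned template values
(so stage-2 enrichment *is* the generative truth: with zero noise the
betas equal the loadings exactly, which the tests assert to $10^{-6}$),
per-run unit-SD system time series, and white Gaussian noise with an
optional AR(1) switch. Planted effects add
$\mathrm{amplitude} \times \mathrm{profile}[c,s] \times \mathrm{template}_k(v)$
to the target system's loading inside a compact cluster; an interaction
profile is doubly centred (zero row/column margins), and the
qualitative finding pattern — state differences under audio, none at
rest — is the sum of such an interaction and a state profile
(`audioOnlyEffectPair`). With all amplitudes zero the study is an exact
null for all three effects. Defaults mirror the study design the package
emulates: 17 subjects, 2 conditions $\times$ 4 states, 155 (audio) / 256
(rest) volumes at TR 2 s, $K = 5$ systems, a 20^3 grid at 3 mm.

What the generator does **not** emulate: haemodynamic convolution,
physiological noise structure, motion, scanner drift beyond what the
high-pass removes, and inter-subject variability in loadings. Passing
tests therefore demonstrate correctness of the estimator and the
inference machinery under the stated model, not robustness to every
property of real BOLD data.

### Stage-1 cross-talk of planted effects

One genuine estimation phenomenon surfaced by the generator deserves
note. A planted loading perturbation confined to a cluster changes the
*estimated* stage-1 series (its scale and mixing) for the affected cells,
because the spatial regression sees the cluster's excess covariance with
the target template. After stage-2's unit-SD normalisation this leaks a
small, cell-dependent multiplicative factor into the beta map at **every**
voxel, proportional to amplitude times the cluster-to-mask size ratio.
With a strong planted effect on a small mask the leak itself can cross
the cluster-forming threshold and merge clusters mask-wide. The planted
recovery validation therefore runs on a 24^3 grid, where the 27-voxel
cluster is a small enough fraction of the ~5,500-voxel analysis mask that
the leak stays below threshold while the planted cluster remains
overwhelming. The same trade-off exists in empirical REACT analyses:
focal, very strong coupling changes are partially redistributed by the
global stage-1 fit.

## Validation suite and problem sizes

The test suite validates each operation against independent oracles
(brute-force per-voxel/per-timepoint least squares, a textbook
sums-of-squares partition for the ANOVA, flood-fill component labelling,
first-principles paired t) and the whole pipeline against the generator's
ground truth. The heavier checks, with the sizes chosen for a desk-scale
run:

* **FWE error control** — 200 replicate null studies on an 8^3 grid,
  $N = 10$, equal run lengths of 30 volumes, 6 mm smoothing, 500
  permutations of the interaction family; the rejection proportion at
  $\alpha = 0.05$ must land in the exact binomial 95% interval around
  0.05. Smoothing matters here: on unsmoothed white noise at this grid
  size the max-cluster-size null is concentrated on sizes 0–1 and the
  test becomes markedly conservative (measured rate ~0.01); with the
  pipeline's smoothing the measured rates are 0.025–0.035 across all
  three relabelling schemes. The equal run lengths keep beta variances
  homogeneous across conditions, which is the regime the F statistic
  assumes.
* **Planted-effect recovery** — 24^3 grid (see above), $N = 17$, default
  run lengths, amplitude $3\times$ noise SD in a 27-voxel cluster, 1000
  permutations: the leading cluster must survive Bonferroni, overlap
  truth with Dice $\ge 0.5$, and its simple main effects must reproduce
  the audio-only pattern.
* **Exhaustive-enumeration oracle** — at $N = 2$ the condition sign-flip
  group has 4 elements; the routine switches to exact enumeration and the
  p-values must match an independent enumeration to machine precision.

## Numerical choices and degenerate inputs

* Unit-SD scaling uses the population ($1/T$) denominator everywhere.
* A zero-variance voxel in stage 2 yields zero betas (not NaN); a
  zero-variance stage-1 series or rank-deficient template set is a named
  `singular design` error.
* A constant template within the mask is a `degenerate template` error;
  an empty analysis mask is an `invalid mask` error; an incomplete design
  names its missing cells.
* F statistics with a vanishing error term are set to 0 rather than NaN.
* Cluster label maps order labels by decreasing size; ties in peak F are
  broken by the first voxel in column-major order.
* All randomness (generator, permutations) flows from explicit integer
  seeds; permutation draws derive a per-effect stream from the scheme
  seed so single-effect runs are reproducible regardless of which other
  effects are requested.

## Known limitations

Within-run temporal autocorrelation is not modelled (plain OLS in both
stages); this is deliberate, since inference happens at the group level
through permutation. The interaction relabelling scheme (within-subject
residual cell permutation) is asymptotically exact rather than exact in
finite samples; its measured type-I rate is slightly conservative at desk
scale. Voxel-peak FWE, TFCE and parametric random-field corrections are
out of scope, as are covariates.
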