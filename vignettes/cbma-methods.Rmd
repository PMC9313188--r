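---
title: "Coordinate-based meta-analysis with cbma: models, parameters, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coordinate-based meta-analysis with cbma}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Functional neuroimaging studies report their results as peak coordinates
("foci") in a standard stereotaxic space. A coordinate-based meta-analysis
asks where, across a corpus of independently conducted experiments, these
peaks converge more than chance would allow. `cbma` implements the two
complementary analyses used in meta-analyses of intentional-forgetting
fMRI experiments — activation likelihood estimation (ALE), which tests
*convergence*, and a latent factor analysis of the foci by latent
Dirichlet allocation (LDA), which describes *divergence* — together with
the corpus ingestion, grid handling, and synthetic-data machinery needed
to validate both with no external data.

## The ALE model

Each reported focus is an uncertain observation of a true activation
location. ALE models that uncertainty as an isotropic 3D Gaussian centred
on the focus. The kernel standard deviation combines a between-template
term and a between-subject term scaled by the study's sample size $n$:

$$\sigma(n) = \sqrt{\sigma_{\mathrm{template}}^2 +
  \sigma_{\mathrm{subject}}^2 / n},$$

so foci from larger studies are modelled by tighter kernels. The defaults
($\sigma_{\mathrm{template}} = 5.7 / (2\sqrt{2/\pi}) \approx 3.57$ mm,
$\sigma_{\mathrm{subject}} = 11.6 / (2\sqrt{2/\pi}) \approx 7.27$ mm)
derive from the widely used estimates of between-template and
between-subject Euclidean displacement in stereotaxic normalisation; both
are `kernel_spec()` parameters, because the appropriate widths are a
modelling choice, not a constant of nature. Kernels are expressed as
per-voxel probability mass (trivariate normal density times voxel
volume) and truncated at 5 standard deviations. Foci are snapped to the
nearest voxel centre (half-up per axis) before kernel placement, which
makes the kernel maximum exactly the probability mass of one voxel at
distance zero.

A study's focus kernels are combined voxel-wise into a modelled
activation (MA) map. The default combination is the voxel-wise
**maximum** — the non-additive rule of the revised algorithm, under which
several nearby peaks from one experiment cannot pretend to be convergent
evidence — with the probabilistic union available behind
`kernel_spec(combine = "union")`.

The ALE score is the union across experiments,

$$\mathrm{ALE}(v) = 1 - \prod_e \bigl(1 - \mathrm{MA}_e(v)\bigr),$$

the probability that at least one experiment's modelled activation covers
voxel $v$.

### The analytic null and its discretisation

The null hypothesis is random spatial association: each experiment
contributes the MA value of one uniformly drawn in-mask voxel, and the
union of those draws is formed exactly as above. Because the draws are
independent, the null distribution can be computed exactly by histogram
convolution. `cbma` performs the convolution in the log-complement
domain: with $L = -\log(1 - \mathrm{MA})$, the union becomes a plain sum,
so per-experiment histograms of $L$ on a lattice of step `bin_width`
(default $10^{-5}$) are convolved iteratively by FFT (padded to highly
composite lengths) and the result is mapped back to a survival function on
the ALE axis. At the ALE magnitudes that occur in practice ($<0.1$),
$dL$ and $d\mathrm{ALE}$ agree to second order, so the lattice step is
effectively the requested ALE bin width. The test suite checks this
construction against a $10^6$-draw Monte-Carlo voxel-sampling oracle and
against an exactly enumerable two-point distribution.

Voxel p-values are the null survival at the observed score; z-scores are
one-sided standard-normal quantiles with p floored at the smallest
strictly positive survival value, so z never becomes infinite at the
resolution limit of the discretised null.

### Cluster-level inference

Voxels with $p < 0.001$ (the cluster-forming threshold) are grouped into
26-connected components. The null distribution of the maximum cluster
size is built by relocating every focus of every experiment to an
independent uniform in-mask voxel, recomputing MA and ALE maps, and
thresholding at the *same* analytic-null cutoff — legitimate because the
MA value histogram, and hence the null, is invariant under uniform
relocation up to mask-boundary truncation. A cluster's family-wise error
p is the add-one permutation estimate $(b + 1)/(R + 1)$, and clusters
with $p < 0.05$ are reported with their size, volume, ALE-weighted
centroid, peak (maximal z, ties broken by lowest linear voxel index), and
hemisphere (sign of peak x; exactly 0 is labelled M). One master seed
drives everything; permutation $r$ uses seed $+ r$, so a cluster table is
bit-reproducible from its configuration echo.

## The latent factor model

For the LDA analysis, studies are documents and in-mask voxels are words.
Documents are built on a grid downsampled to 4 mm: every in-mask voxel
within 10 mm of *any* focus of an experiment receives count 1 (binary per
experiment, so overlapping spheres never double-count). Radius, spacing,
and the binary rule are configuration values. The vocabulary is the union
of the documents' voxels — not the whole mask — which both matches the
support semantics of the factor maps (a one-factor fit covers exactly the
voxels any document touched) and keeps the BIC parameter count meaningful.

Inference is zeroth-order collapsed variational Bayes (CVB0) with
symmetric priors, defaults $\alpha = 100$ per factor on
Pr(Factor|Study) and $\eta = 0.01$ on Pr(Voxel|Factor). Per-token
responsibilities are updated as

$$\gamma_{dwk} \propto
 (\alpha + \hat N_{dk}^{-dw}) \,
 \frac{\eta + \hat N_{kw}^{-dw}}{V\eta + \hat N_{k}^{-dw}},$$

with counts excluding the token's own contribution. Updates are applied
in token chunks with counts refreshed between chunks: a practical
vectorisation of the per-token sweep that preserved the monotone climb of
the monitored likelihood in every test case. The monitored quantity is
the token log-likelihood under the current smoothed point estimates
$\theta_{dk} = (\alpha + \hat N_{dk})/\sum_{k'}(\alpha + \hat N_{dk'})$
and $\beta_{kw} = (\eta + \hat N_{kw})/(V\eta + \hat N_k)$; iteration
stops when its relative change drops below `tol` (default $10^{-6}$).
Responsibilities are initialised from seeded flat-Dirichlet noise, so a
fit is deterministic given its seed. $K = 1$ has a closed-form posterior
and skips iteration.

Whether a reported $\alpha$ of 100 means per-component or total
concentration is ambiguous in common usage; `cbma` treats it as
per-component (as passed to the inference), with `alpha_per_k = TRUE`
available to rescale by $1/K$.

### Model selection

For each candidate $K$, `model_selection()` runs `n_seeds` restarts
(default 100; validation suites use 20) and keeps the highest-likelihood
fit; the number of factors maximises

$$\mathrm{BIC}(K) = \log L - \tfrac12\,\bigl(K(V-1) + D(K-1)\bigr)\,
  \ln W,$$

with $W$ the total token count and ties going to the smaller $K$. The
parameter count is the free-parameter dimension of the $K$ voxel
distributions and $D$ study loadings; BIC names a family of such
penalised criteria, and this variant is pinned by tests so it cannot
drift silently.

A consequence worth knowing: on binary-support documents the penalty
grows linearly in the vocabulary size $V$, so scattered noise foci —
each contributing ~65 singleton-support voxels on the 4 mm grid —
inflate the penalty much faster than they can inflate the likelihood
gain of an extra factor. The model-selection validation corpora are
therefore built noise-free; the noise-robustness of the *inference* (as
opposed to the selection criterion) is exercised separately by the
planted-partition recovery tests.

## Corpus handling

Sleuth-style text and CSV dialects are parsed into a validated corpus
(unique study labels, ≥1 focus per experiment outside metadata-tolerant
mode, finite coordinates under a 200 mm sanity bound). Talairach
experiments are converted to MNI through the pooled Lancaster-style
affine — stored as the published MNI→Talairach matrix and inverted — and
MNI experiments pass through bit-identically; the transform is
configurable because which conversion (if any) a given meta-analysis
applied is rarely stated. Coordinates are RAS mm; voxel indices are
0-based; mm→index uses nearest-voxel rounding, half-up per axis.

The bundled `included_studies()` table transcribes the 23
intentional-forgetting studies (sample sizes, paradigm, stimuli,
contrast). Ages are stored as the published text and never parsed. The
table prints no per-study coordinates, so no test asserts the corpus-wide
focus count; only the study count (23) and subject total (466) are
checkable, and both are asserted exactly.

The default analysis grid is a synthetic MNI-like lattice (91×109×91 at
2 mm, RAS affine with origin (−90, −126, −72)) with an ellipsoidal brain
mask (centre (0, −17, 8) mm, semi-axes (72, 86, 78) mm, ~253k voxels —
the scale of a real 2 mm brain mask), so the package installs, runs, and
tests with no atlas download; any NIfTI-1 mask can replace it.

## The synthetic-data generator

`generate_corpus()` emulates the structure of the real corpus: 10–35
studies, sample sizes resampled from the included-study table's n column
(11–32, mean 466/23), a handful of foci per experiment, planted
ground-truth centers emitted with per-study probability
`center_participation` plus isotropic Gaussian jitter (in-mask rejection
sampling, at most 100 redraws), and uniformly scattered noise foci placed
at voxel centres so generator and sampling null share one support.
`generate_null_corpus()` draws every focus i.i.d. uniform over in-mask
voxels — the random-association hypothesis as a generative model.

With `participation_exact = TRUE` each center is emitted by exactly
`ceiling(participation × n_studies)` studies. The recovery validation
uses this mode: its target property is stated for corpora in which every
center actually appears in at least 60% of experiments, and independent
Bernoulli draws at p = 0.6 regularly violate that premise (a center can
fall to ~35% participation by chance).

What the generator does *not* emulate: publication bias, correlation
between sample size and focus count, anisotropic spatial uncertainty,
and within-study clustering of sub-peaks. Passing recovery tests on this
generator therefore demonstrates algorithmic correctness under the
stated model, not robustness to the full messiness of published
coordinate data.

## Validation design and problem sizes

The validation suite runs on one CPU with these sizes, chosen as the
smallest that leave the checked properties comfortably identified:

* **Null-oracle equivalence** — 3 experiments on an 18×20×18 grid,
  analytic null vs a $10^6$-draw sampling oracle, agreement within 3
  binomial standard errors at every probed score.
* **Planted recovery** — 23 studies on the full 2 mm grid, 4 centers at
  the meta-analytic peak coordinates of the intentional-forgetting
  corpus, exact 60% participation, 8 mm jitter, 5 noise foci/study,
  200 permutations. With 8 mm per-axis jitter the two closest centers
  (32 mm apart) sit near the resolution limit of any kernel width:
  narrower kernels localise noisily, wider ones merge the pair. The
  suite runs this check at the default kernel and a fixed seed;
  across seeds the all-four-distinct event is variable by design, and
  the acceptance script reports the realized recovery count at
  whatever seed it is given.
* **FWE calibration** — 50 null corpora (15 studies × 8 foci) on a 4 mm
  grid, 100 permutations each; the fraction with any significant cluster
  must fall in the central 95% binomial band around the nominal 0.05.
* **Factor selection** — noise-free one- and two-pattern corpora
  (20 + 20 studies, patterns of two centers each), 20 restarts per K,
  K ∈ 1..4; BIC must pick 1 and 2 respectively and matched factor maps
  must correlate > 0.9 with the planted uniform distributions.

## Numerical choices and degenerate inputs

* Survival lookups and thresholds share one binning convention (half-up
  on the $L$ lattice), so "p < threshold" and "score ≥ cutoff" are the
  same set of voxels by construction.
* FFT convolution can produce tiny negative masses; they are clamped to
  zero and the pmf renormalised.
* Kernel mass is capped at $1 - 10^{-12}$ so degenerate spacing cannot
  produce MA > 1.
* An empty suprathreshold set yields an empty cluster list, not an error;
  an experiment with no foci, a non-invertible affine, and an empty mask
  are errors.
* Peak ties inside a cluster are broken by lowest linear voxel index;
  hemisphere at exactly x = 0 is "M".

## Known limitations

* No anatomical labelling: the cluster table's structure column is
  deliberately empty.
* No subgroup contrast or conjunction analyses between paradigms.
* The analytic null is exact only up to its lattice discretisation;
  p-values below the resolution of the value histogram are floored.
* CVB0 is the zeroth-order approximation; no variance terms are carried,
  and the monitored objective is the smoothed-likelihood surrogate, not
  a true bound.
* BIC on binary-support documents is vocabulary-dominated (see above);
  selecting K on corpora with heavy uniform noise will be conservative.
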