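---
title: "Quantifying glymphatic function and its downstream effects: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying glymphatic function and its downstream effects: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glymphr)
```

# Overview

`glymphr` quantifies glymphatic (brain fluid-clearance) function from
MRI-derived inputs and propagates those measurements into a statistical
cascade linking glymphatic markers, white-matter-hyperintensity (WMH)
burden, and cognition. The package covers both sides of the circulation:

* **Inflow markers** — choroid plexus (ChP) volume relative to the lateral
  ventricles and to intracranial volume, and the coupling between the
  global gray-matter BOLD signal and CSF inflow signal.
* **Outflow markers** — the DTI-ALPS perivascular diffusivity index and
  meningeal-lymphatic-vessel (MLV) contrast kinetics from DCE-MRI.
* **Downstream structure** — WMH lesion morphometry with the
  periventricular/deep partition, covariate-adjusted group statistics,
  bootstrap mediation, and a latent-variable structural equation model
  (SEM).

Because the measurement chain is long, every stage has a matching
synthetic-data generator with analytic ground truth, so each operator can
be validated by recovery rather than by eyeballing.

# Measurement operators

## DTI-ALPS index

Diffusivity along the scanner axes is averaged over four regions of
interest: a projection-fiber ROI and an association-fiber ROI per
hemisphere, each a 3 x 3-voxel in-plane square (nine voxels; about 5.4 mm
per side at the 1.8-mm acquisition this emulates) on one slice at the
level of the deep medullary veins. The index is

$$\mathrm{ALPS} = \frac{D_{x,\mathrm{proj}} + D_{x,\mathrm{assoc}}}
{D_{y,\mathrm{proj}} + D_{z,\mathrm{assoc}}},$$

the ratio of diffusivity along the perivascular direction (x, perpendicular
to both fiber populations) to diffusivity perpendicular to it within each
fiber population. Isotropic diffusion gives exactly 1; impaired
perivascular transport lowers the index. ROI placement is operator
configuration (voxel coordinates), not atlas lookup: standard practice places these ROIs manually on
color-coded maps, and no slice-selection rule is standardized, so
automating placement would invent one. The index is
scale invariant and strictly monotone in each component; both properties
are tested.

## Global BOLD-CSF coupling

Raw series are trimmed (first 10 volumes), converted to percent change
about the temporal mean, and band-pass filtered with a zero-phase
Butterworth at 0.01-0.1 Hz. The upper edge reflects the low-frequency
vasomotor band that drives CSF pulsatility; filter bands for this analysis are rarely standardized, so the band is an
explicit, configurable default. The
lagged Pearson cross-correlation profile is computed on the overlapping
support (no padding, which would bias long lags relative to short ones)
over a +/-20 s window at TR = 2 s multiples. Sign convention: positive lag
means BOLD leads CSF. Reported metrics are the signed correlation of
largest magnitude (ties broken toward lag 0), the correlations read at
+2 s and -6 s, and the coupling of the negative BOLD derivative at lag 0.

One caveat is documented deliberately: the "maximum strength" statistic is
an extremum over 21 lags and is therefore magnitude-inflated at realistic
coupling levels (|r| ~ 0.2); the profile value at a fixed lag is the
unbiased read. The package reports both, and its recovery tests use the
fixed-lag read for weak plants and the extremum for strong ones, where the
selection bias is negligible.

## DCE time-intensity curves and extended Tofts kinetics

The sampling grid is 23 series of 16.78 s with the contrast bolus arriving
at the end of the second series; samples before the bolus define the
baseline. Enhancement is $e(t) = (S(t) - S_0)/S_0$ with $S_0$ the baseline
mean. Semiquantitative descriptors:

* **wash-in** — maximum forward-difference slope of $e$ between injection
  and peak, per second;
* **TTP** — time from injection to the peak sample, in minutes (dural lymphatic enhancement peaks on the
  minutes scale);
* **AUC** — trapezoidal integral of $e$ over a fixed 120-s post-injection
  window divided by the window length, hence dimensionless.

Reporting conventions for these quantities vary by vendor and are rarely
stated, so these conventions are explicit stand-ins, chosen so typical values land in the
0.05-0.15 range reported for dural lymphatics.

Kinetics use the extended Tofts model
$$e(t) = v_p\,C_a(t) + K^{\mathrm{trans}} \int_0^t C_a(\tau)
e^{-k_{ep}(t - \tau)}\,d\tau, \qquad k_{ep} = K^{\mathrm{trans}}/V_e,$$
with a bi-exponential population arterial input function
$C_a(t) = A_1 e^{-m_1 t} + A_2 e^{-m_2 t}$ after the arrival delay. The
convolution is evaluated in closed form (sums of exponential
convolutions), which is exact on the coarse 16.78-s grid where numerical
quadrature would dominate the error budget. Fitting is seeded multi-start
(7 starts) Levenberg-Marquardt with parameters bounded below by zero;
boundary solutions are flagged. The fit deviation is the RMS residual
normalized by peak enhancement — vendor "fitting deviation" metrics are
not publicly defined, so this definition is explicit and configurable — and the quality
filter retains fits with deviation strictly below 0.05. The identity
$V_e k_{ep} = K^{\mathrm{trans}}$ holds exactly in every report. Clinical workflows often treat the measured curve as its own input
function; a simulator must replace that with a parametric form, hence the AIF default
(rates 1.2 and 8 per minute, opposite amplitudes) that rises and decays
with curves peaking at ~1 min, matching the reported TTP scale.

## Lesion morphometry and the 8-mm partition

Lesions are connected components of the binary WMH mask under
26-connectivity (the standard for 3-D lesion masks; documented
because conventions vary), labelled by descending
volume. Per lesion: center of mass (mm, voxel-centre convention), minimum
Euclidean distance to the ventricular system, and principal axis lengths.
Distance is computed from the exact anisotropic Euclidean distance
transform of the ventricle mask (separable lower-envelope algorithm)
evaluated at lesion voxels — i.e., surface-to-surface for extended
lesions, which keeps the 8-mm rule meaningful for large confluent lesions;
a centroid-distance mode would misclassify any large periventricular cap.
Lesions within 8 mm (inclusive: "within" plus the complementary "more
than" reading) are periventricular, the rest deep; per-class volumes are
exact voxel-count sums, so the partition conserves total volume by
construction.

Principal axes are reported as the full axis lengths of the
moment-equivalent ellipsoid, $2\sqrt{5\lambda_i}$ for eigenvalues
$\lambda_i$ of the voxel-coordinate covariance: for a solid ellipsoid this
recovers the true axis dimensions in the continuum limit, which makes
planted-shape recovery testable.

## ChP ratios and reliability

ChP and lateral-ventricle volumes are voxel counts times voxel volume;
the ratios ChP/LatVent and ChP/ICV are exact quotients. Whether the
lateral-ventricle volume should exclude ChP voxels is a convention
choice; the default keeps them (a `subtract_chp` switch exists). Inter-method
reliability uses ICC(A,1) — two-way model, single measure, absolute
agreement — computed from the ANOVA mean squares:
$$\mathrm{ICC}(A,1) = \frac{MS_R - MS_E}
{MS_R + (k-1)MS_E + \tfrac{k}{n}(MS_C - MS_E)}.$$
Only this form is offered, preventing a silent mismatch with other ICC
variants.

# Statistical cascade

Group comparisons use one-way ANOVA with Tukey HSD post hoc tests
(continuous) or the chi-squared test (categorical, no continuity
correction by default since the design is 3-group). Covariate-adjusted
comparisons (ANCOVA, and rank ANCOVA for a monotone-invariant variant)
model `outcome ~ group + age + sex + education`, test the group effect by
a partial F-test, and Bonferroni-adjust the three pairwise adjusted-mean
contrasts (the family is the per-outcome contrast set; comparison
families are a convention choice). Effect sizes are pooled-SD Cohen's
d with $r = d/\sqrt{d^2 + 4}$ — the conversion that reproduces the
reported (d, r) pairs, implying pooled (not Glass) d. Robust regression is
RANSAC (minimal samples, inliers within 1.5 x MAD of the OLS residuals,
largest consensus set refit by least squares) after residualizing
age/sex/education out of predictors and outcome; consensus-refit standard
errors are rescaled by the normal truncation consistency factor so
confidence intervals keep nominal coverage despite the trimming.

Mediation is the standard three-regression decomposition on standardized
variables with a percentile bootstrap for the indirect effect
$a \times b$; $c = c' + ab$ holds to machine precision by OLS algebra.
Partial mediation requires the indirect CI to exclude zero while the
direct effect stays significant.

## Structural equation model

The SEM has four latents: Inflow (ChP/LatVent, maximum coupling strength),
Outflow (average ALPS, dorsal TTP, dorsal AUC, dorsal kep), WMH
(periventricular volume, deep volume, total Fazekas score) and Cognition
(MMSE, MoCA). Structural part: WMH on Outflow (and, by default, also on
Inflow — path diagrams for designs like this are often reported with
magnitudes only, so the Inflow path is included but toggleable), Cognition on WMH, Inflow correlated with
Outflow. Estimation is normal-theory maximum likelihood on the covariance
of internally standardized indicators, in a RAM parameterization with
marker-variable identification (first loading per latent fixed to 1),
quasi-Newton optimization with an analytic gradient, and log-parameterized
variances so improper negative variances cannot occur (a variance
collapsing to the boundary is flagged as a Heywood-type case instead).
Indicators are oriented so that better glymphatic function means higher
ALPS and a negative Outflow-to-WMH path; TTP loads negatively by
construction (longer time-to-peak = worse outflow).

Fit statistics follow the conventional definitions:
$\chi^2 = (n-1)F_{ML}$; CFI against the uncorrelated-indicator baseline;
GFI from the ML discrepancy $1 - \mathrm{tr}[(\hat\Sigma^{-1}S - I)^2] /
\mathrm{tr}[(\hat\Sigma^{-1}S)^2]$; RMSEA
$\sqrt{\max(\chi^2 - df, 0)/(df\,(n-1))}$. The $\chi^2/df$ ratio is always
computed from its parts, never stored separately. Missing data are handled
by listwise deletion: cohorts with partial DCE coverage make complete-case
analysis the natural default, and n is whatever the supplied cohort
provides. Bootstrap path
intervals are percentile intervals over row-resampled refits warm-started
at the full-sample solution; the run aborts if more than 5% of resamples
fail to converge.

# The synthetic-data generator

The generator produces every input the pipeline consumes, with ground
truth recorded:

* **Diffusivity fields** — constant background (0.7 x 10^-3 mm^2/s) with
  planted ROI means and optional Gaussian noise; the noiseless field
  reproduces the planted index exactly.
* **BOLD/CSF pairs** — band-limited (0.01-0.1 Hz) stochastic BOLD; CSF
  mixes the lagged BOLD (or its negative derivative) with independent
  band-limited noise, weighted so the planted profile peak equals the
  requested strength. Band-limited noise is used so the preprocessing
  band-pass leaves the planted correlation intact.
* **DCE curves** — the analytic extended-Tofts forward model on the
  23-sample grid with Gaussian or Rician signal noise; verified against an
  independent fine-grid numerical convolution to ~10^-7 relative error.
* **Lesion scenes** — a central ventricular slab plus axis-aligned solid
  ellipsoids, so intended class, centroid, axes, volume and surface gap
  are all analytic.
* **Cohort tables** — standardized latent draws (Inflow/Outflow
  correlated 0.4; WMH = -0.20 Inflow - 0.572 Outflow + noise; Cognition =
  -0.705 WMH + noise) mapped to the 11 indicators with anchor loadings
  0.646 (ChP/LatVent) and 0.712 (ALPS), then affinely rescaled to
  plausible observed units. Fazekas totals are cut from the continuous
  severity indicator at fixed normal quantiles emulating a ~35/34/31%
  HC/mild/severe composition; demographics are independent by default,
  with configurable linear confounding so covariate adjustment can be
  tested against known truth.

The defaults are the study conditions throughout: coupling -0.227 at +2 s,
kinetics K^trans = 0.05/min, kep = 0.5/min, vp = 0.01 (V_e = 0.1), and the
latent structure above.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: WMH volumes in real cohorts are zero-inflated
and heavily right-skewed, cognitive scores are bounded integers with
ceiling effects, and measurement noise distributions are unknown (Gaussian
is an assumption, documented as such). Gaussian indicators are kept
deliberately: they make the implied covariance analytic, so estimator
consistency can be tested exactly; the cost is that robustness to real
skew is untested here. Bounded columns (ratios, scores, volumes) are
clamped only in the far tail (< 0.5% of draws at the default scales),
which perturbs the implied covariance by well under 10^-3. No MR physics
(k-space, motion, aliasing of cardiac pulsation into the slow band) is
simulated.

# Numerical choices and degenerate inputs

* ALPS with a zero denominator is NA with a warning, never silently
  dropped. Requested negative diffusivities are errors.
* Percent change with a near-zero temporal mean is an error (undefined),
  as is filtering a series shorter than 30 volumes after trimming.
* Coupling metrics refuse off-grid lag reads (no interpolation): TR must
  divide the requested lags.
* A flat DCE curve short-circuits to zero kinetics with a degenerate flag;
  a peak at the injection sample zeroes wash-in/TTP with the same flag.
* Tofts fits at a parameter bound are flagged; `ktrans = 0` truth pins the
  estimate at the bound and reports `ve = 0`.
* The SEM optimizer is multi-start (3 seeded starts cold, warm start for
  bootstrap refits); non-positive-definite sample covariances and
  constant indicators are errors, boundary variances are warnings.
* Ties in the coupling extremum break toward lag 0; component-label ties
  break by lexicographic centroid.

# Validation problem sizes

The test suite and the acceptance script use these sizes, chosen to give
stable estimates at interactive runtimes: 27-point noiseless Tofts grid
plus 100 noisy seeds (noise at 2% of curve dynamic range); 300 coupling
subjects at SNR 5 with lags drawn from -6..+6 s; 25 lesion scenes / 200
lesions with >= 1.2 mm margin from the 8-mm boundary; 500 null + 200
alternative mediation replicates at n = 100 with 500 bootstrap draws; SEM
bias as the mean of 4 replicates at n = 20000 (a single replicate of the
two-indicator Inflow loading has sampling sd ~0.015, so averaging is
required to measure bias rather than variance) and percentile-CI coverage
over 150 replicates at n = 117 with 120 bootstrap draws. Measured
coverage is ~92-93% per structural path against the 95% nominal level —
typical percentile-bootstrap undercoverage at this n — so coverage checks
near a 90% threshold retain a few percent of binomial flake by nature.

# Known limitations

* ROI placement, masks and visual scores are inputs; no segmentation,
  registration or rating is performed.
* The SEM assumes linear-Gaussian indicators; ordinal Fazekas scores are
  treated as continuous (their 7-level discretization attenuates that one
  loading by ~1-2% and is part of the generator's realism, not a bug).
* Percentile (not BCa) bootstrap intervals throughout; BCa would likely
  close most of the coverage gap at n ~ 117.
* The semiquantitative DCE conventions (AUC window, wash-in units) are
  stand-ins for unpublished vendor definitions; comparisons across
  software should use the same conventions on both sides.
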