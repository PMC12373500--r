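---
title: "Models and methods behind pdxmet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pdxmet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdxmet)
```

# The question

Patient-derived xenografts (PDXs) are the workhorse pre-clinical model for
melanoma, but engrafting a human tumour into an immunodeficient mouse and
passaging it for years raises an obvious worry: does the model still
metabolically resemble the tumour it came from? `pdxmet` implements a
pipeline for answering that question from bulk metabolomics: it quantifies
which metabolites differ because of the host species, which carry a stable
patient-specific "fingerprint", whether a PDX can be traced back to its
patient of origin by that fingerprint, and how the profile drifts with
serial passaging (P0 = patient tumour, P1–P6 = successive mouse passages).
A companion set of ¹³C isotope-tracing utilities covers the labelling side
of the same comparison.

Every stage is exercised against a synthetic cohort generator with
recorded ground truth, so the statistical machinery is testable without
access to patient data.

# Preprocessing

Raw inputs are metabolite × sample intensity tables in arbitrary ion-count
units with missing values. The processing chain is:

1. **Detection filter.** Metabolites missing in more than
   `max_missing_fraction` (default 0.9) of samples are removed. The
   conventional phrase "not detected in more than 90% of the samples"
   admits a second reading (detected in fewer than 90%); we implement the
   first and expose the threshold, so the second is reachable by setting
   `max_missing_fraction = 0.1`.
2. **Median-of-ratios normalization.** Reference metabolites are those
   detected in *every* sample with median log10 intensity between 5
   and 10 (high-abundance, well-measured signals). Each reference
   metabolite is scaled by its own median across samples and the
   per-sample factor is the median of those ratios within the sample — a
   robust estimate of total signal abundance, insensitive to the handful
   of metabolites that genuinely change. Factors are computed on raw
   (pre-log) intensities; the window is evaluated on log10 medians.
   Medians use R's midpoint convention for even counts.
3. **log10 transform, then minimum imputation.** Missing values are
   assumed missing-low (left-censored at the detection limit), so each
   missing cell is imputed with the minimum observed log10 value of its
   metabolite. The imputation mask is kept, so downstream rank-based
   tests can be chosen where imputation density is high.

The order matters: normalize → log → impute. Imputation never creates a
value below the metabolite's observed minimum, and the pipeline is
idempotent on already-normalized data with unit factors.

# Differential models

**Univariate and multivariate moderated models.** Per metabolite, ordinary
least squares on the chosen factor(s) via `limma::lmFit`, followed by
empirical-Bayes variance moderation (`limma::eBayes`): residual variances
are shrunk toward a prior estimated by method of moments on log residual
variances, the posterior being the convex combination
$\tilde s^2 = (d_0 s_0^2 + d s^2)/(d_0 + d)$ with moderated t on
$d_0 + d$ degrees of freedom. Two-level factors and numeric covariates
report a signed effect (on the native log10 scale and as
$\log_2\mathrm{FC} = \beta_{\log 10}/\log_{10}2$); factors with more
levels report a joint moderated F. P values are BH-adjusted across
metabolites within a factor, never across factors.

**Variance partitioning.** Each categorical factor enters as a random
intercept and each numeric factor (passage) as a fixed slope. A
component's share is its variance over the total: random components
contribute their REML variance, a fixed slope contributes the sample
variance of its fitted values, and the residual closes the sum to 1.
Constant metabolites are reported as all-zero with a `degenerate` flag
rather than 0/0. Designs with a single categorical factor use the
in-package profiled-REML engine (below); designs with several fall back
to `lme4::lmer`.

**Species-agnostic selection.** The patient-vs-PDX contrast must not be
confounded by which patient a sample comes from, so host is tested in a
linear mixed model with a random intercept per origin:
$y = \beta_0 + \beta_h \,\mathbb{1}\{\text{host}=\text{mouse}\} + b_{origin} + \varepsilon$.
The model is fitted by REML with the variance ratio
$\gamma = \sigma^2_{origin}/\sigma^2_\varepsilon$ profiled over a log
grid after a single eigendecomposition of the grouping design — which
makes fitting 300 metabolites essentially free, since the decomposition
is shared. Inference on $\beta_h$ is a Wald t with nlme-style denominator
df (observation-level df for within-origin covariates). This reproduces
`nlme::lme` to ~5 decimals on matched fits, and under a simulated null
the host P value is uniform to within Monte-Carlo error. A metabolite is
**species-agnostic** when its host P exceeds 0.1 (raw, by construction of
the screen: we want metabolites *without* evidence of host dependence;
the threshold is a tunable argument). Note the deliberate asymmetry:
P > 0.1 is absence of evidence, not evidence of absence — the flag is a
screening device for building a cross-species metric, not an equivalence
test.

# Fingerprint matching

Metabolites are z-transformed (sample SD, $n-1$) across the pooled
analysis set of patient and PDX samples; the standardization population
is an explicit argument since reasonable alternatives exist (per-batch,
patients-only). The distance between a PDX $x$ and a patient tumour $y$
is plain Euclidean over the selected metabolite panel,

$$D_{total} = \sqrt{\sum_{k=1}^{n} (x_k - y_k)^2},$$

and a PDX is assigned the origin of its nearest patient tumour. A match
is correct when the assigned origin equals the true origin; exact
distance ties (measure-zero in real data) are broken by lexicographic
patient id and flagged. When one origin contributed several patient
tumours, each remains its own column and correctness is judged on the
origin.

The per-metabolite decomposition uses $d_k = (x_k - y_k)^2$, so
$\sum_k d_k = D_{total}^2$ exactly (asserted to 1e−9 in tests). For each
PDX, $\Delta d_k = d_k^{match} - \bar d_k^{non\text{-}match}$ compares the
contribution against the true-origin patient tumour with the mean over
all other patient tumours; $\Delta d_k < 0$ means metabolite $k$ pulls
the matched pair together. The matched pair is defined by *true* origin
regardless of whether the assignment was correct, and $\Delta d_k = 0$
counts as non-negative. With several same-origin patient tumours the
matched contribution is their mean.

# Fidelity and stability

* **Passage trends**: per PDX line, the OLS slope of metabolite level on
  passage number over P1–P6 (closed form, vectorized); lines spanning
  fewer than three distinct passages are excluded with a warning. The
  pooled passage effect comes from the joint passage + origin model.
* **P0–P6 correlation**: per metabolite, Pearson r across origins between
  the patient value and the late-passage value, with a two-sided P from
  $t = r\sqrt{(n-2)/(1-r^2)}$. P6 replicates are averaged within origin
  by default (`p6 = "mean"`) — the estimator with the smaller variance —
  with `p6 = "pooled"` available since the choice is not forced by the
  method.
* **Characteristic metabolites**: the strict conjunction
  origin-variance-fraction > 0.30 AND r > 0.3 (both thresholds exposed).
  These are the metabolites that are simultaneously patient-specific and
  stable under passaging — the fingerprint's backbone.

# Isotope tracing

For a measured fragment (typically a TBDMS-silylated GC–MS ion, hence Si
and S support), the correction matrix column $j$ is the mass-shift
distribution of a molecule carrying exactly $j$ tracer ¹³C atoms: the
convolution of the natural-abundance patterns of all atoms not fixed by
the tracer — including the $n-j$ unlabelled tracer-position carbons —
shifted by $j$ and truncated at $n$. The matrix is lower triangular with
positive diagonal; untruncated columns sum to 1, truncated columns to
≤ 1. Default abundances (¹³C 0.0107, ²H 0.000115, ¹⁵N 0.00364,
¹⁷O/¹⁸O 0.00038/0.00205, ²⁹Si/³⁰Si 0.04685/0.03092, ³³S/³⁴S
0.0075/0.0425) ship both in code and as an editable TSV. Tracer purity
below 1 replaces the deterministic shift with a binomial over the
labelled positions; default 1.

Correction solves $Mx = m$ by Lawson–Hanson nonnegative least squares
(default; robust to noise) or by exact triangular solve with clipping,
then renormalizes to sum 1 and reports the fit residual. Matrices with
condition number above 1e12 are rejected outright. The forward map
(`simulate_mid`) is the same convolution, so convolve-then-correct is the
identity to 1e−8 on noiseless inputs — a round trip the acceptance suite
checks for random fragments up to 6 carbons, with exhaustive
isotopologue enumeration as the oracle for small fragments.

Derived summaries: total labelling $1 - M{+}0$; normalization of
labelling by glucose M+6 in patient plasma (cross-cohort comparability)
or in the same tumour sample (tracer-dilution adjustment); and the
CitM2/PyrM3 ratio as a pyruvate-dehydrogenase surrogate (error when
pyruvate M+3 is 0).

# Set enrichment

Over-representation by hypergeometric upper tail $P[X \ge hits]$, with
the detected metabolome as the background universe and each set
intersected with the background before its size is counted. The
"≥ observed" convention is the standard one for over-representation and
is documented here because either tail is defensible; no multiplicity
adjustment by default (BH optional), matching common practice for small
curated pathway collections.

# The synthetic cohort: what it states, and what a green test means

The generator plants, on the log10 scale, per-metabolite baselines
(mean 6, SD 1.2 — a realistic dynamic range for ion counts), per-origin
fingerprint offsets (SD 0.3), host shifts on 33% of metabolites
(magnitude 0.4), passage drift slopes (SD 0.02 per passage),
pigmentation shifts on 15 metabolites, per-sample scale factors
(SD 0.15), and residual noise (SD 0.15), then exponentiates and censors
below log10 intensity 4. Default layout: 13 origins × (1 patient +
2 PDXs × 6 passages) ≈ 169 samples and 305 metabolites, mirroring the
scale of a serially passaged melanoma PDX metabolomics cohort (~305
metabolites, ~200 samples, 8–13 origins). These values were chosen once
as a realistic stated world and are not tuned against test outcomes.

Two deliberate deviations from a naive "everything Gaussian" generator:

* Host and pigmentation shifts have **fixed magnitude and random sign**
  rather than a Gaussian draw, so conditions phrased as
  "planted-shift-to-residual-SD ratio = 5" are exact rather than
  averages over a distribution that includes near-zero shifts.
* Missingness is **left-censoring at a detection threshold** — the
  mechanism that justifies minimum imputation. The real data's
  missingness mechanism is unknown; if it were not missing-low, minimum
  imputation (and this generator) would both be misspecified in the same
  direction, which is exactly what a synthetic test cannot detect.

Other real-data features the generator does not attempt: chromatographic
batch effects beyond a scalar per-sample factor, correlated metabolite
blocks (pathway co-regulation), heavy-tailed noise, adducts/peak-picking
artifacts. A green matching test therefore establishes that the
*machinery* recovers planted structure at realistic effect sizes — not
that real patient–PDX matching will reach any particular accuracy. With
the default stated world the fingerprint is strong (origin SD twice the
residual SD): synthetic matching is near-perfect and most metabolites
classify as characteristic, which is cleaner than the ~60% matching and
102/305 characteristic metabolites reported on real tumours — real data
carry weaker fingerprints and all of the unmodelled features above.

# Numerical choices

* REML profiling searches $\log\gamma \in [-14, 14]$ and snaps to the
  zero-variance boundary when the boundary is within 1e−8 of the
  optimum, so null variance components are reported as exactly 0.
* Wald df: group-level for origin-constant covariates, observation-level
  ($n - q - p_{within}$) for within-origin covariates, floored at 1.
* Distance computations use the Gram-matrix identity with clipping at 0
  before the square root; the decomposition identity is asserted at 1e−9.
* Zero-SD metabolites are an error in `zscore_metabolites` (the caller
  decides whether to drop), zero intensities are an error before log10,
  and metabolites with no observed values are an error in imputation —
  all name the offending row/cell.
* Characteristic/species-agnostic thresholds are strict inequalities
  applied to raw values; boundary jitter flips exactly the jittered
  metabolite (tested).

# Limitations

* The mixed-model screen inherits the usual caveats of accepting a null
  (P > 0.1): low-information metabolites are more likely to pass.
* Variance fractions from REML are shrinkage estimates; with few origins
  the origin fraction is noisy, and the >0.30 rule should be read as a
  screen, not an estimate with coverage.
* The enrichment module assumes the caller's metabolite identifiers match
  the set collection's vocabulary; no ontology mapping is attempted.
* No batch correction: separate acquisition batches should be analyzed
  separately (the species-agnostic screen exists precisely to bridge
  batches via metabolite selection rather than value harmonization).
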