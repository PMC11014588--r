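---
title: "Structurally informed effective connectivity: model, priors and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structurally informed effective connectivity: model, priors and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hebdcm)
```

## The problem

Effective connectivity — the directed, causal influence one neuronal
population exerts on another — is inferred from resting-state fMRI by
inverting a generative model of the BOLD signal. Structural
connectivity — the anatomical network of nerve tracts estimated by
tractography — is measured independently. `hebdcm` implements a
hierarchical empirical Bayes approach in which anatomy does not fix
which connections exist but scales how *variable* group-level
effective connectivity is allowed to be: strongly tracted region pairs
receive a larger prior variance, weakly tracted pairs are shrunk
harder toward zero.

## The subject-level model

Each subject's regional dynamics follow the linear state-space model

$$\dot{x}(t) = A\,x(t) + v(t), \qquad y(t) = h(x(t), \theta_h) + e(t),$$

with $A \in \mathbb{R}^{n\times n}$ the effective connectivity in Hz
(diagonal entries are self-inhibition rate constants), $h$ a
linearized hemodynamic (balloon) observation model and $v, e$
power-law noise processes. In the frequency domain this model predicts
the cross-spectral density

$$\hat G_y(\omega) = H(\omega)\,(i\omega I - A)^{-1} G_v(\omega)
  (-i\omega I - A^\top)^{-1} H(\omega)^\dagger + G_e(\omega),$$

which is fitted to *empirical* cross-spectra obtained by evaluating
the parametric spectrum of an MVAR model (default order 8) fitted to
the detrended time series. Inversion is by variational Laplace: a
Gauss–Newton ascent on the free energy
$F = E_q[\ln p(y\mid\theta)] - \mathrm{KL}(q\,\|\,p)$ with adaptive
Levenberg–Marquardt damping, which returns a Gaussian posterior over
all parameters and $F$ as an approximation to the log model evidence.

### Parameterization and priors

* Off-diagonal couplings $A_{ij}$: prior $\mathcal N(0, 1/64)$ (Hz).
* Self-connections: $A_{ii} = -\tfrac12 e^{a_{ii}}$ with
  $a_{ii} \sim \mathcal N(0, 1/64)$, guaranteeing a negative diagonal.
* Hemodynamics: two unitless log-scaling factors per region (signal
  decay rate, transit time) around the canonical constants in
  `hemo_constants`, prior $\mathcal N(0, 1/16)$.
* Noise spectra: per-region log-amplitudes and one shared log-exponent
  for each of $G_v$ and $G_e$ (`g(\omega) = e^{a}\omega^{-e^{b}}`),
  priors $\mathcal N(0, 1/16)$. The flat-spectrum (white) limit is the
  convention $b \to -\infty$.
* Observation-noise log-precision in the feature space: a single
  hyperparameter per subject with hyperprior $\mathcal N(0, 9)$. The
  wide variance is deliberate: the feature-residual scale varies over
  decades between datasets, and a log-precision that cannot move by
  more than a factor of ~2 (as a 1/16 variance would imply) pins the
  likelihood weight at an arbitrary value and destroys parameter
  recovery. The same reasoning sets the hyperprior of the group-level
  random-effects log-precision $\gamma$ below.

Because the noise-amplitude priors are tight, the data cross-spectra
are first scaled so that their mean diagonal power matches the
prior-mean prediction (`rescale = TRUE` in `invert_dcm()`); this is
the standard scaling convention for spectral features and affects no
correlation-based result.

### Numerical choices

The forward model is evaluated through the eigendecomposition
$A = V\Lambda V^{-1}$, so each frequency costs two small complex
matrix products; a per-frequency linear solve is the automatic
fallback when $A$ is (near-)defective. Jacobian columns for the
connectivity block use the exact resolvent derivative
$\partial (i\omega I - A)^{-1}/\partial A_{ij} = R\,E_{ij}\,R$;
hemodynamic and noise columns use forward finite differences with
step $10^{-4}$. Convergence is declared after three consecutive
accepted steps improving $F$ by less than 0.05 nats — just above the
numerical noise floor of the mixed analytic/finite-difference scheme,
and negligible against the $\ge 3$-nat scale at which evidence
comparisons operate — with a cap of 128 iterations; accepted steps never decrease $F$ (rejected trial steps
raise the damping). The inversion is deterministic.

## The hierarchy

Subject-level posterior *means* of the connectivity block are stacked
into $A^{(1)} = [\mathrm{vec}\,A^{(1)}_1; \dots; \mathrm{vec}\,A^{(1)}_S]$
and modeled as

$$A^{(1)} = (\mathbf{1}\otimes I)\,A^{(2)} + \varepsilon^{(2)}, \qquad
  A^{(2)} = \mu^{(3)} + \varepsilon^{(3)},$$

with $\varepsilon^{(2)} \sim \mathcal N(0, e^{-\gamma} I)$ (a single
scaled precision component, $\gamma \sim \mathcal N(0, 9)$) and the
third-level prior $\varepsilon^{(3)} \sim \mathcal N(0, \Sigma_3)$.
Subject posterior covariances are *not* part of this level's
likelihood — the random-effects model treats the MAP means as data —
and re-enter only through the downward Bayesian-model-reduction step.
Conditional on $\gamma$ the model decouples into $n^2$ scalar
problems with exact conjugate posteriors; $\gamma$ itself is optimized
by a one-dimensional variational Laplace step. Vectorization is
column-major throughout, exposed by `a_index()`.

Structure enters through the third-level covariance:

$$\tilde C = \frac{C \circ (1 - I)}{\max C \circ (1 - I)}, \qquad
  \sigma^2_{ij} = \beta\,\tilde c_{ij} + \alpha \;(i \neq j), \qquad
  \sigma^2_{ii} = \delta,$$

so $\alpha$ is the structure-free baseline variance, $\beta$ the gain
of variance with normalized structural weight, and $\delta$ (default
$1/64$) the self-connection variance on the log-scaled
parameterization. The *uninformed* reference model is
$\beta = 0, \alpha = 1/2, \delta = 1/64$. Exact-zero variances
($\alpha = 0$ on an absent edge) clamp the connection to the prior
mean; the model-reduction code realizes the clamp through a
near-dogmatic precision whose closed-form limit is finite.

## Scoring transforms: BMR, the grid, and BMA

Once the group model is inverted under the uninformed prior, any
alternative $(\alpha, \beta)$ regime is scored *analytically* by
Bayesian model reduction: with reduced-prior precision
$\tilde\Pi_0$, the reduced posterior has precision
$\Pi_q + \tilde\Pi_0 - \Pi_0$, its mean is the corresponding
precision-weighted combination, and the free-energy change follows
from log-determinant and quadratic terms alone. The identical routine
(`bmr_gaussian()`) also performs the downward update in which the
group posterior becomes each subject's empirical prior — model
reduction is agnostic to the hierarchical level.

The default grid samples $\alpha$ at 30 equidistant points over
$[-1/2, 1/2]$ and, per $\alpha$, $\beta$ at 30 equidistant points over
$[0, 1/2 - \alpha]$, then filters to $\alpha \ge 0$ and
$\alpha + \beta \ge 10^{-5}$; the retained regime count follows from
the resolution and is never hard-coded. Regime free energies are
softmax-weighted after subtracting the maximum (spreads of hundreds of
nats would otherwise overflow), giving model probabilities $p_k$ and
the evidence-weighted transform
$\bar\lambda = \sum_k p_k (\alpha_k, \beta_k)$. Uncertainty is
summarized by the weighted 2.5/97.5 percentiles of
$\sigma^2(\tilde c)$ over regimes on 101 equidistant $\tilde c$
values (the definition of the plotted confidence envelope is a package
choice; evidence weights are used directly).

## The synthetic-data generator

`sim_config()` fixes the in-silico study conditions: $n = 6$ regions,
50 instantiations by default, 1200 samples at 0.72 s, signal-to-noise
ratio 1. Ground truth is drawn hierarchically: a sparse symmetric
connectome (density 0.5, uniform weights, connected support, fixed
across instantiations), group couplings
$A^{(2)}_{ij} = \sqrt{\beta_{\rm true}\tilde c_{ij} + \alpha_{\rm true}}\; z_{ij}$
with independent standard Gaussian $z$ per *directed* edge
($\alpha_{\rm true} = 0.02$, $\beta_{\rm true} = 0.25$), subject
deviations of standard deviation 0.1 Hz, self-connections $-0.5$ Hz,
and a scalar diagonal deepening whenever the largest real eigenvalue
part exceeds $-0.05$ Hz. BOLD series are produced by Euler integration
of the state equation driven by one-pole low-pass-filtered Gaussian
fluctuations (time constant 2 s, so the in-band spectrum has an
average slope near the model's $1/f$ prior), passed through the same
linearized hemodynamics, decimated to the sampling interval, and
corrupted by white observation noise calibrated so that per-region
signal-sd / noise-sd equals the configured SNR.

Two mismatches with the inference model are deliberate and worth
knowing about: the simulated fluctuations are Lorentzian rather than
power-law, and the observation noise is white while the model's error
spectrum family is $a\,\omega^{-b}$ with $b > 0$. Passing tests
therefore show robustness to mild spectral misspecification — they do
not certify performance on real fMRI, where hemodynamic variability,
measurement artifacts and parcellation effects are all richer than
anything generated here.

In the specificity arm of the validation (no structural scaling,
$\beta_{\rm true} = 0$) the baseline variance is raised to
$\alpha_{\rm true} = 0.15$, matching the average off-diagonal variance
of the structured arm, so the two arms differ in structure-dependence
but not in overall coupling strength.

## The in-silico experiment and what it reports

`run_insilico()` executes the full loop per instantiation — generate,
extract MVAR cross-spectra, invert subjects, invert the uninformed
group model, score the grid, average, re-reduce the group model under
$\bar\lambda$, update subjects — plus the comparison method: a
structurally *masked* MVAR model in which directed functional
connectivity $i \to j$ is estimated only where a structural connection
exists (order 1, per-target least squares, lag-summed weights). The
baseline's coefficients are unitless, so comparisons against the truth
use correlation and sign agreement rather than cross-method RMSE.

The report (a tibble; `tidy()`/`glance()`/`autoplot()` methods are
provided) contains per instantiation: group-level parity (Pearson r,
RMSE over off-diagonal couplings) for both methods, mean subject-level
correlations, the log-Bayes factor of the structure-informed versus
uninformed group model, $\bar\alpha, \bar\beta$, envelope coverage of
the true variance function at $\tilde c \in \{0, 0.5, 1\}$, and sign
macro-F1 scores (threshold 0.05 Hz). Pooled parity concatenates all
instantiations into one scatter; per-instantiation statistics are kept
alongside because the two summaries differ slightly and both are
informative.

Problem sizes used by the shipped validation runs — 20 instantiations
of 10 subjects in the acceptance script and main test run, and 8
instantiations of 10 subjects in the specificity arm — are
reduced-scale replicates of the 50-instantiation design; pooled
parity statistics are stable well before 50 instantiations.

## Known limitations

* The subject-level estimates are shrunk by their tight priors, so the
  recovered transform gain $\bar\beta$ systematically underestimates
  $\beta_{\rm true}$ (apparent between-subject variance scales with
  the squared shrinkage factor). Correlation-based recovery metrics
  are unaffected; absolute variance calibration is not attempted.
* The IID Gaussian likelihood over stacked real/imaginary CSD entries
  weights low-frequency (large-magnitude) features most; a
  heteroscedastic feature noise model would be more efficient but is
  outside the declared model family.
* Symmetric structural input implies equal prior variances for
  efferent and afferent connections of a pair; the effective
  connectivity itself remains directed.
* Networks beyond a few dozen regions are computationally out of reach
  of the dense spectral likelihood used here.
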