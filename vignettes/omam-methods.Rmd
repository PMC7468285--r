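---
title: "Models, fitting strategy and design choices in omam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, fitting strategy and design choices in omam}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omam)
```

## The models

The operational model of agonism describes the functional response of a
receptor–effector system to an orthosteric agonist A with three constants:
the system maximum $E_{MAX}$ (response units), the agonist equilibrium
dissociation constant $K_A$ (molar) and the operational efficacy $\tau_A$
(dimensionless), which couples receptor occupancy to response:

$$Resp = \frac{[A]\,\tau_A\,E_{MAX}}{[A](\tau_A+1) + K_A}.$$

The curve is a rectangular hyperbola with
$EC_{50} = K_A/(\tau_A+1)$ and upper asymptote
$E'_{MAX} = \tau_A E_{MAX}/(\tau_A+1)$, hence the linear relation
$E'_{MAX} = E_{MAX}\,(1 - EC_{50}/K_A)$ between the two observables of any
one curve.

An allosteric ligand B binds a topographically distinct site.  In the
ternary complex ARB it rescales the agonist's affinity by the binding
cooperativity $\alpha$ and its operational efficacy by the operational
cooperativity $\beta$; if it has intrinsic activity it carries its own
efficacy $\tau_B$.  `omam_response()` implements the resulting forward
model (see the README for the formula); `om_response()`,
`allosteric_agonist_response()` and the pure-modulator case are its exact
nested reductions at $[B]=0$, $[A]=0$ and $\tau_B=0$.

As printed, all forward models return zero response at zero ligand; the
system basal is handled as an additive offset carried by
`system_params()` (default 0).  "Fold-over-basal" readouts are represented
by choosing the corresponding response scale (e.g. `e_max = 98`,
`basal = 1`), not by a hidden transform.

## Derived observables

At fixed $[B]$ the curve in $[A]$ is still a ratio of linear forms
$(pA+q)/(rA+s)$, so its descriptors are closed forms.  Writing the curve's
lower asymptote $R_0 = q/s$ (the allosteric ligand's own response) and
upper asymptote $E'_{MAX} = p/r$, the concentration at the midpoint
between the asymptotes solves $(pA+q)/(rA+s) = (q/s + p/r)/2$, which
simplifies to $A = s/r$ exactly:

$$EC'_{50} = \frac{K_A\,(K_B + [B](1+\tau_B))}
  {K_B + \alpha[B] + \tau_A(K_B + \alpha\beta[B])},\qquad
E'_{MAX} = \frac{(K_B+\alpha\beta[B])\,\tau_A E_{MAX}}
  {K_B + \alpha[B] + \tau_A(K_B+\alpha\beta[B])}.$$

Two structural facts follow and are exploited by the workflow:

* $E'_{MAX}$ contains no $\tau_B$ — an allosteric agonist raises the
  baseline, never the ceiling.  This makes the apparent maximum a clean
  probe of $\beta$.
* the dose ratio $EC_{50}/EC'_{50}$ has the saturating limit
  $\alpha(\beta\tau_A+1)/((\tau_A+1)(\tau_B+1))$, implemented once in
  `dose_ratio_limit()`; every restricted case (pure modulator, neutral
  affinity or efficacy, pure allosteric agonist) is a specialization and
  is kept in the test suite as a regression oracle rather than as a
  separate code path.

The package also provides the analytic inversions used for parameter
extraction: $\beta$ from the saturating apparent maximum
(`beta_from_emax()`), $\beta$ at a finite concentration given $\alpha$
(`beta_from_emax_at_b()`), and $\alpha$ from a dose ratio and apparent
maximum (`alpha_from_dose_ratio()`, which eliminates $\beta$).  At
$[B]=0$ the inversions are $0/0$; both return 1 by continuity, the
no-modulation value.  No iteration is involved anywhere in these
extractions.

A deliberate property of the model worth noting: the response in $[A]$ is
*not* always increasing.  When the allosteric ligand is a strong agonist
($\tau_B$ large) with strongly negative operational cooperativity
($\beta$ small), the orthosteric agonist pulls receptors out of highly
active RB complexes into weakly active ARB complexes and the curve
descends from its elevated baseline.  The monotone direction is the sign
of $E'_{MAX} - R_0$.

## Why fitting is staged

A noise-free hyperbolic curve determines exactly two numbers.  One
agonist curve therefore cannot determine $(E_{MAX}, K_A, \tau_A)$; a
family of curves under a modulator cannot determine all of
$(E_{MAX}, K_A, \tau_A, K_B, \alpha, \beta, \tau_B)$.  Any fit that frees
them together wanders along exact-fit ridges, and its linearized
covariance explodes.  The package surfaces this rather than hiding it:
every fit carries an `identifiable` flag that turns off when the
condition number of $J^\top W J$ exceeds $10^8$ or a positive parameter's
standard error exceeds 10× its estimate.

`fit_om_two_step()` handles the single-agonist case with a batch of
agonists spanning efficacies:

1. logistic fit per agonist → $(EC_{50,i}, E'_{MAX,i})$;
2. $E_{MAX}$ from the apparent-maximum/EC50 relation.  With per-agonist
   $K_{A,i}$ supplied (typically inhibition constants from competition
   binding) this is a one-parameter fit and is identifiable for any
   batch; without them the relation is fitted with a common $K_A$
   (intercept $E_{MAX}$), which is exact only for a batch sharing one
   affinity and is documented as an approximation.  At least three
   agonists are required;
3. per-agonist refit of the operational model with $E_{MAX}$ fixed; the
   pair $(K_A, \tau_A)$ is then exactly identifiable.

`run_omam_workflow()` implements the allosteric analysis in the order
logistic fits → ligand-alone constants ($K_B$, $\tau_B$, fitted with
$E_{MAX}$ fixed, or supplied from binding analysis) → $\beta$ by
inversion → $\alpha$ by inversion → a final global fit with **only**
$\alpha$ and $\beta$ free, initialized at the inversion values.  The
final stage refuses to release more than `max_free = 2` parameters unless
explicitly overridden (`also_free`).

Even the two-parameter stage has a known weak direction: the independent
(non-$\beta$-mediated) effect of $\alpha$ on the curves scales roughly as
$1/(\tau_A\beta)$, so for a high-efficacy agonist with strong positive
$\beta$ the data constrain the product $\alpha\beta$ far better than
$\alpha$ itself; at 5% noise the likelihood optimum can sit on the
$\alpha\to 0$ ridge.  Such fits are reported with
`identifiable = FALSE` and NA intervals — the practical remedy is the one
the workflow's design anticipates: predetermine $\alpha$ from binding
experiments.

## Numerical choices

* Least squares uses Levenberg–Marquardt (`minpack.lm::nls.lm`) with cost
  tolerances of $10^{-15}$.  Strictly positive parameters
  (concentration constants, efficacies, cooperativities, Hill
  coefficients) are fitted as $\log_{10}$ values with bounds of ±8 log
  units around the start; response-scale parameters (basal, maxima) stay
  on the natural scale.  The Hill coefficient is additionally bounded to
  $[0.1, 10]$.
* Standard errors come from $s^2 (J^\top W J)^{-1}$ with the Jacobian
  recomputed at the solution by central differences; log-scale parameters
  are back-transformed by the delta method and get log-symmetric Wald
  intervals.
* Weights are $1/SD^2$ when per-point SDs are available, with zero SDs
  (the zero-concentration anchor under proportional noise) floored to the
  smallest positive SD; otherwise unweighted.
* Logistic fits start from the geometric mean of tested concentrations
  (EC50), the observed extremes (maximum, basal) and slope 1.  Flat data
  return `converged = FALSE` instead of an arbitrary EC50.
* Saturation of the modulator effect (stage 3) is declared when the two
  highest modulator concentrations give apparent maxima whose two-sided
  z-test p-value exceeds `saturation_p = 0.05`; otherwise the
  finite-concentration inversion is used.  The threshold is a package
  decision, configurable per call.
* Stage 5 runs a small deterministic multistart (the inversion pair plus
  neutral fallbacks), preferring identifiable fits, then lower RSS.
* One-site versus two-site competition binding is chosen by corrected
  AIC; the more complex model must improve AICc by `aicc_margin = 2`.
* Modulator-present curves that flatten into the noise (possible under
  strong negative cooperativity with an allosteric agonist) are excluded
  from the closed-form stages with a warning but still contribute raw
  points to the global fit.

## The synthetic generator

`omam_scenario()`/`simulate_curveset()` emulate a functional assay read
out as concentration–response curves: a log-spaced agonist grid (default
nine half-log steps centred on the control EC50, plus a zero-concentration
anchor), one curve per modulator concentration, `n_replicates = 3`, and
additive Gaussian noise with SD = `noise_floor + noise_cv · |signal|`
(default 5% proportional, no floor).  The generated tables carry the
model SD per point, as experimental "mean ± SD" data would, which the
fitting stages use as weights.  Ground truth travels with the data as an
attribute.  `simulate_binding()` produces the corresponding binding
designs with the tracer at 1 nM.

Presets (`omam_presets()`) cover the canonical qualitative regimes —
affinity-only and efficacy-only modulation in both directions, their four
combinations, pure and modulating allosteric agonists — on a normalized
scale ($E_{MAX}=1$, $\tau_A=3$, $K_A=K_B=1\,\mu M$, $\tau_B=1$ for
agonists) with representative cooperativities from
$\{0.1, 0.3, 3, 10\}$; they are labelled representative, not calibrated to
any particular published figure.  Two presets use a fold-over-basal scale
($E_{MAX}=98$, basal 1) with modulator arms at 30/100/300 µM and
1/3/10 µM respectively, matching common designs for a high-µM positive
modulator and a sub-µM allosteric agonist.

What the generator does **not** emulate: non-unit Hill slopes, assay
clipping or floor effects, receptor depletion, non-equilibrium kinetics,
plate/batch effects, and error in the predetermined constants fed to the
workflow.  Recovery results on synthetic data therefore demonstrate the
correctness and conditioning of the estimation procedure, not robustness
to model misspecification.

## Problem sizes used in the characterization studies

The test suite and the acceptance script use: 1000 random parameter sets
for the closed-form/oracle comparison; 50 noisy repeats of a four-agonist
batch (efficacies 0.3–10, affinities 0.1–3 µM) for two-step recovery; 100
random allosteric scenarios ($\alpha \in [0.1,30]$, $\beta \in [0.1,10]$,
$\tau_A \in [0.5,10]$, $\tau_B \in [0,3]$, modulator arm at
$\{1,10,100\}\times K_B$) for workflow recovery, interval coverage and the
identifiability contrast.  Slope-sensitivity of the logistic extraction is
characterized on a dense wide design (five decades, quarter-log steps)
where both asymptotes are well sampled, summarized by the median over
seeds.

## Known limitations

* $E_{MAX}$ estimation without predetermined affinities assumes a batch
  with a common $K_A$; the package reports but cannot overcome the
  structural underdetermination otherwise.
* Confidence intervals are linearized (Wald); for parameters near an
  identifiability ridge they understate uncertainty, which is why the
  `identifiable` flag accompanies every fit.
* Binding models assume equilibrium, no ligand depletion, and
  pre-subtracted nonspecific binding.
* The receptor-state (two-state/cubic ternary) description of allosteric
  activation is out of scope; $\alpha$, $\beta$, $\tau$ are operational
  summaries, not microscopic constants.
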