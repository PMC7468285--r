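# omam — operational model of allosterically-modulated agonism

`omam` is an R package for quantitative receptor pharmacology: it
implements the operational model of agonism, its extension to allosteric
modulators and allosteric agonists, the closed-form relations between the
model constants and the observable curve descriptors, and a staged fitting
workflow that estimates cooperativity factors without ever fitting
inter-dependent parameters together.

## The problem

The response of a cell or tissue to an orthosteric agonist A follows the
operational model

    Response = [A] τ_A E_MAX / ([A](τ_A + 1) + K_A)

where E_MAX is the maximal response the system can produce, K_A the
agonist's equilibrium dissociation constant and τ_A its operational
efficacy.  An allosteric ligand B binds a distinct site, forms a ternary
complex ARB, changes agonist affinity by a binding-cooperativity factor α,
changes operational efficacy by an operational-cooperativity factor β, and
may activate the receptor itself with efficacy τ_B:

    Resp = E_MAX (τ_A [A](K_B + αβ[B]) + τ_B [B] K_A) /
           ([A]K_B + K_A K_B + [B]K_A + α[A][B]
              + τ_A [A](K_B + αβ[B]) + τ_B [B] K_A)

The observable descriptors of a curve at fixed [B] are closed forms:

    EC′50 = K_A (K_B + [B](1 + τ_B)) / (K_B + α[B] + τ_A(K_B + αβ[B]))
    E′MAX = (K_B + αβ[B]) τ_A E_MAX / (K_B + α[B] + τ_A(K_B + αβ[B]))

with the dose ratio EC50/EC′50 → α(βτ_A + 1)/((τ_A + 1)(τ_B + 1)) at
saturating [B].  E′MAX is independent of τ_B: an allosteric agonist raises
the curve's lower asymptote, never its upper one.

These parameters are inter-dependent: a hyperbolic curve exposes only two
observables (EC50, E′MAX), so direct nonlinear regression of the full model
is ill-posed.  The package's workflow therefore determines parameters in
stages — logistic description of each curve, allosteric-ligand constants
from a ligand-alone titration, β by analytic inversion of the
apparent-maximum relation, α by analytic inversion of the dose-ratio
relation — and only then runs a global fit in which everything but α and β
is fixed.  Radioligand-binding models (saturation, two-site competition
with Cheng–Prusoff correction, allosteric tracer shift) are included to
predetermine binding constants.

## Worked example

```r
library(omam)

# closed forms
ag  <- agonist_params(k_a = 1e-6, tau_a = 3)
mod <- modulator_params(k_b = 1e-6, alpha = 10, beta = 3)
om_ec50(ag)                 # 2.5e-07  (M) agonist-alone EC50
omam_ec50(1e-5, ag, mod)    # 1.095618e-08  EC'50 at 10 uM modulator
dose_ratio_limit(ag, mod)   # 25  maximal potency shift

# simulate a modulator experiment with known truth and analyse it
sc     <- preset_scenario("mod_pp")   # alpha = 10, beta = 3, tau_A = 3
curves <- simulate_curveset(sc, seed = 42)
wf <- run_omam_workflow(curves,
                        sys = system_params(e_max = 1),
                        ag  = agonist_params(k_a = 1e-6, tau_a = 3),
                        k_b = 1e-6, tau_b = 0)
print(wf)
#> Staged allosteric-modulation workflow
#>   5 curves; saturation of modulator effect: yes
#>   alpha = 10.62 (SE 0.714, init 10.4)
#>   beta  = 2.843 (SE 0.177, init 2.564)
#>   final global fit: RSS = 142.7, identifiable = TRUE
confint(wf)
#>           2.5%     97.5%
#> alpha 9.305202 12.113614
#> beta  2.515309  3.212599
```

The closed-form stage-3/4 inversions land within a few percent of the
truth (inits 10.4 and 2.56 for true 10 and 3) and the final two-parameter
global fit brackets both truths in its 95% intervals.  Releasing the
predetermined constants instead (`fit_global()` with everything free)
yields an `identifiable = FALSE` flag — the failure mode the staging
exists to avoid.

A thin command-line wrapper is installed with the package:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "omam", package = "omam"))')
Rscript $CLI simulate --preset mod_aff_pos --seed 4 --out out/
Rscript $CLI fit-omam --curves out/curves.csv --config config.yaml --out out/
```

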