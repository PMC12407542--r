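---
title: "Equilibrium models of RAF paradoxical activation and its modulation by 14-3-3"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Equilibrium models of RAF paradoxical activation and its modulation by 14-3-3}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rafpa)
```

## The phenomenon and the model family

ATP-competitive RAF inhibitors can *increase* RAF pathway output at
sub-saturating doses before inhibiting it at higher doses — paradoxical
activation (PA).  `rafpa` implements a family of equilibrium models of this
phenomenon built from four ingredients:

1. **Conformational autoinhibition (CA).**  Monomeric RAF interconverts
   between an autoinhibited conformation `A`, which can neither dimerize nor
   bind drug, and an open conformation `M`.  The equilibrium ratio is
   `K_A = [A]/[M]`; larger `K_A` means stronger autoinhibition.
2. **Dimerization.**  Open monomers dimerize with dissociation constant
   `K_dim`.  Dimers are the signaling species.
3. **Drug binding.**  The inhibitor binds the open monomer and each dimer
   protomer independently with a single dissociation constant `K_d`.  A
   drug-bound protomer cannot return to the autoinhibited conformation
   without first releasing the drug, so there is no drug-bound autoinhibited
   species.
4. **Two roles of dimeric 14-3-3.**  A 14-3-3 dimer can clamp the
   autoinhibited monomer (conformational autoinhibition stabilization, CAS;
   dissociation constant `K_Smon`) or bridge a RAF dimer (dimer
   stabilization, DS; dissociation constant `K_Sdim`).  14-3-3 is counted
   in dimer units throughout: each engagement is one 14-3-3 dimer binding
   two phosphoserines, and only the unbound and doubly-bound states are
   modeled.

The four model variants (`"CA"`, `"CAS"`, `"DS"`, `"CAS_DS"`) enable none,
one or both of the 14-3-3 couplings.  RAS-GTP is required implicitly and is
not a species; MEK/ERK and transcriptional feedback are outside the model,
which describes the equilibrium reached before slow feedback acts.

**Active RAF** is the sum of all RAF protomers that are inside a dimer and
not drug-bound, as a fraction of total RAF.  Protomers in 14-3-3-bridged
dimers count as active when drug-free — this is what lets the DS role raise
baseline signaling.

### Species and conventions

With `d` free drug and `s` free 14-3-3 (both µM), the mass-action relations
are

```
A    = K_A * M             AS   = A * s / K_Smon
Md   = M * d / K_d         D00  = M^2 / K_dim
D01  = 2 * M * Md / K_dim  D11  = Md^2 / K_dim
DxyS = Dxy * s / K_Sdim
```

`D01` carries the statistical factor 2 because the singly-drugged dimer
exists in two orientations; equivalently, the per-site association steps are
`D00 + d = D01` with constant `2/K_d` and `D01 + d = D11` with `1/(2 K_d)`.
These factors are forced by thermodynamic consistency:
`check_detailed_balance()` enumerates the independent reaction cycles
(drug-then-dimerize vs dimerize-then-drug, 14-3-3-then-drug vs
drug-then-14-3-3) and verifies every cycle's equilibrium-constant product
is 1.  The two dimer sites share one `K_d` with no cooperativity; users
modeling inhibitors with strong negative cooperativity at the second site
should treat the high-dose region of these curves with caution.

## Closed-form solutions

Substituting the relations above into RAF conservation gives a quadratic in
`M`, and the active fraction takes one common shape across variants.  With
the dimensionless groups `RAF_rel = R_total/K_dim`, `d_rel = d/K_d`,
`s_rel = s/K_Sdim`, `S_rel = s/K_Smon`, define the variant's monomer and
dimer intermediates

```
E = 1 + K_A * (1 + S_rel) + d_rel        # S_rel term only with CAS
F = 8 * RAF_rel * (1 + d_rel)^2 * (1 + s_rel)   # s_rel term only with DS
```

Then

```
active  = (sqrt(E^2 + F) - E)^2 / (F * (1 + d_rel))
baseline = (sqrt(1 + E0) - 1)^2 / E0,  E0 = F0 / E(d=0)^2
dimers/protomer = (1 + d_rel)/2 * active
```

`analytic_intermediates()` exposes these as the `E1`–`E10` abbreviations.
Both families are evaluated in cancellation-free form
(`F / ((sqrt(E^2+F) + E)^2 (1+d_rel))`), which matters: the naive
`sqrt(E^2+F) - E` loses all significant digits once `F/E^2` approaches
machine precision, as it does in strongly autoinhibited corners of the
sweeps.

Every closed form is validated against a brute-force path that never touches
them: `solve_free_clamped()` finds `M` by bracketed root finding on the
conservation residual (in log-`M`, which keeps full relative precision when
`M` is many orders of magnitude below `R_total`) and sums species.
`verify_analytic()` reports the worst relative deviation over random
parameter sets drawn log-uniformly across three or more decades per
parameter; it is routinely at the 1e-14 level.

### PA conditions

PA occurs exactly when the dose response has positive initial slope.
Differentiating the common shape at `d_rel = 0` gives one criterion for all
four variants:

```
(3*c0 - 2) * (c0 - 2) > f0
c0 = 1 + K_A * (1 + S_rel)     f0 = 8 * RAF_rel * (1 + s_rel)
```

Specialised per variant this yields the familiar inequalities — for the base
model `RAF_rel < (1 + 3 K_A)(K_A - 1)/8`, for CAS the bound grows with
`S_rel` (14-3-3 *relaxes* the constraint), for DS the bound shrinks by
`1/(1 + s_rel)` (14-3-3 *tightens* it), and for CAS+DS the criterion is most
naturally read as a bound on `K_A`:

```
K_A > K_Smon / (3 (K_Smon + s)) * (1 + 2 sqrt(1 + 6 RAF_rel (K_Sdim + s)/K_Sdim))
```

`pa_condition()` returns a signed margin oriented so that positive always
predicts PA (`bound - RAF_rel`, or `K_A - bound` for CAS+DS).  The
inequalities hold exactly under clamped free ligands; with full
conservation they are the excess-14-3-3 limits, and the suite checks
numerically that the margin's sign predicts detected PA across a
`K_A x RAF_rel` grid at 1000-fold 14-3-3 excess everywhere outside a 1%
boundary band.

Note the regime qualifier: the claim "the CAS bound only grows with 14-3-3"
concerns the autoinhibition-biased regime `K_A > 1` where PA is possible at
all.  Below `K_A (1 + S_rel) = 1/3` the CAS bound is decreasing — but it is
negative there, so no PA arises either way.

### An ambiguity resolved by the oracle

Two conventions are defensible for the CAS term in the baseline: `S_rel`
computed from *free* or from *total* 14-3-3.  They coincide when 14-3-3 is
in excess over RAF (the regime in which the closed forms are exact), and
both are exposed via the `s_convention` argument rather than silently
choosing one.  Oracle equivalence fixes the mechanism itself: the CAS term
must use `K_Smon` (not `K_Sdim`), i.e. `E5 = 8 RAF_rel/(1 + K_A + K_A S_rel)^2`.

## Parameters

| Field | Meaning | Default | Units |
|---|---|---|---|
| `K_A` | autoinhibited/open monomer ratio | 10 | — |
| `K_d` | drug–protomer dissociation | 0.1 | µM |
| `K_dim` | dimerization dissociation | 0.1 | µM |
| `K_Smon` | 14-3-3–autoinhibited monomer dissociation | 0.2 | µM |
| `K_Sdim` | 14-3-3–dimer dissociation | 0.02 | µM |
| `R_total` | total RAF protomer | 0.04 | µM |
| `S_total` | total 14-3-3 dimer | 1.0 | µM |
| `D_total` | total drug | 0 | µM |

These defaults are the reference set used in all descriptive simulations:
an autoinhibition-biased monomer pool (`K_A = 10`), sub-`K_dim` RAF
(`RAF_rel = 0.4`), and 14-3-3 in 25-fold excess over RAF protomers.  All
concentrations are µM with no unit-conversion layer.

The meta-parameter `alpha` (`apply_alpha()`) trades the two 14-3-3 roles
against each other: `K_Sdim -> alpha * K_Sdim`, `K_Smon -> K_Smon / alpha`.
Small `alpha` is DS-dominant, large `alpha` CAS-dominant.  For the sweep
axis `S_total` up to 100 µM, the disabled coupling's residual term falls
below 1% only once `|log10 alpha|` exceeds about 5.5 (at `alpha = 1e3` the
residual DS term is still `s_rel = 5` at the top of the axis), so the
limit-recovery checks exercise `alpha = 1e6` and `1e-6`.

## Dose-response modes and PA observables

`dose_response()` supports two dose semantics.  In `total_drug` mode (the
default, matching how dose responses are plotted against total inhibitor)
each dose enters the full conservation solve `solve_totals()`: nested
bracketed root finding, outer on `d_free` in `[0, D_total]`, inner on
`s_free` in `[0, S_total]`, innermost `M` in stable closed form, with
conservation residuals verified below 1e-10 relative.  In `free_drug` mode
both free ligands are clamped; this is the regime in which the closed forms
and PA inequalities are exact, with `s_free` defaulting to `S_total` (the
excess clamp).  Full-conservation sweeps make no assumption about the
relative levels of 14-3-3 and RAF.

The two PA observables are:

* **PA fold change** — peak active RAF over its drug-free baseline.  The
  grid argmax is refined by golden-section search in log-dose (climbing
  beyond the grid's edge when the peak lies outside it), making the value
  grid-independent to about 1e-6 relative.
* **PA range (crossover dose)** — the dose above the peak at which the curve
  returns to baseline, i.e. where the drug stops being a net activator.
  The lower end of the PA window is 0+ whenever PA occurs (the initial
  slope is positive), so a scalar captures the window.  Found by expanding
  an upper bracket by decades from the refined peak (at most 10 orders of
  magnitude) and root finding in log-dose.

A dose counts as above baseline only beyond a relative excess of 1e-9,
guarding floating-point equality where the curve is tangent to baseline at
zero dose.  The default dose grid is 121 log-spaced points over
1e-4–1e2 µM.

At the reference parameters the models order as the theory predicts: the
CAS-only model widens and amplifies PA relative to the base model, the
DS-only model narrows and dampens it, and the full CAS+DS model sits in
between (fold changes 11.5 ≥ 3.3 ≥ 1.02 across CAS ≥ CAS+DS ≥ DS, with the
base model at 2.37; crossovers 146 ≥ 6.7 ≥ 0.074 µM vs 4.1 µM).  No
monotonicity in `S_total` is asserted for the full model — the dual roles
produce a genuinely non-monotone net effect, and the sweep drivers exist
precisely to map it.

## The synthetic readout generator

Real PA measurements read RAF activity through downstream ERK
phosphorylation quantified from immunoblots.  That readout is monotone but
saturable in kinase activity, which compresses fold changes while leaving
the *crossing dose* intact — a crossing of two equal readouts is preserved
by any strictly increasing link.  `readout_model()` makes this explicit:

```
readout = v_max * a^hill / (a^hill + k_half^hill) * lognormal noise
```

with `a` the active fraction.  Design choices, stated as conventions since
no quantitative noise characterization of densitometry is available:
multiplicative lognormal noise parameterized by its CV (blot ratios are
positive and right-skewed), `n_replicates = 3` mirroring triplicate
independent experiments, and a fixed integer seed making fixtures
byte-reproducible.

`estimate_pa_from_noisy()` estimates the baseline (dose-0 mean), the
crossover (last dose whose mean exceeds the baseline mean, log-interpolated
to the crossing) and the fold change of means.  Uncertainty comes from a
percentile bootstrap (no BCa).  The bootstrap pools log-residuals across
doses rather than resampling within each dose: with 3 replicates per dose a
within-dose bootstrap sees at most 10 distinct resamples of 3 values and
its intervals undercover badly (~79% where ~90% is nominal), whereas the
generator's own noise model is iid across doses, so the pooled residuals
(replicates × doses of them) estimate the noise law well.  The calibration
test in the suite measures ~87% coverage of the true crossover at CV = 0.1
with 3 replicates, 2000 resamples and 200 simulated experiments.

What passing these tests shows — and does not show — about real data: the
generator emulates saturation, positivity and multiplicative noise, but not
between-blot normalization drift, correlated replicate structure, or
readout nonlinearity beyond a monotone link.  Crossover estimates inherit
only the monotonicity assumption; fold-change estimates are
saturation-compressed by construction and should be read as lower bounds.

## Numerical choices and degenerate inputs

* Root finding uses Brent's method (`stats::uniroot`) on provably
  monotone, bracketed residuals; tolerances are set to machine-precision
  level (`tol = 1e-15`–`1e-18`), and each bound-species total is monotone
  in its free concentration, making the nested brackets safe.
* `R_total = 0` returns the empty state; `S_total = 0` or the CA variant
  leaves all 14-3-3 free; `D_total = 0` skips the outer solve.
* `K_A = 0` (no autoinhibition) is a valid boundary: curves are monotone
  decreasing and fold change is exactly 1.
* Zero dissociation constants are rejected at construction — they have no
  thermodynamic meaning here.
* Ties at the PA threshold resolve to "no PA" (strict inequality, 1e-9
  relative guard).

## Problem sizes

The test suite draws 500 random parameter sets per variant for oracle
equivalence, 1000 random states for the dimer identity, a 20×20 grid for
condition/behavior agreement, 7 points per axis for the alpha-limit
recovery, and 200 simulated experiments × 2000 bootstrap resamples for
readout calibration; these sizes are the package's own choices balancing
coverage against a test run of a few minutes.

## Known limitations

Equilibrium only — no kinetics, no time courses, no feedback; no explicit
RAS-GTP or MEK binding; RAF protomers are untyped (no BRAF/CRAF
heterodimer distinctions); a single drug-binding constant per protomer with
no inter-site cooperativity; 14-3-3 modeled only in its doubly-engaged
dimeric mode.  The closed-form PA inequalities are exact under free-ligand
clamping and excess 14-3-3; away from that regime use the conservation
solve and the numeric PA metrics.
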