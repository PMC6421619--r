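---
title: "A six-field reaction-diffusion model of cartilage regeneration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A six-field reaction-diffusion model of cartilage regeneration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cartregen)
```

## The biological problem

Chondral defects — cartilage lesions that do not penetrate the subchondral
bone — heal poorly on their own. Cell therapies implant either cultured
chondrocytes (autologous chondrocyte implantation) or mesenchymal stem
cells (MSCs) into the debrided defect. Implanted MSCs must first
differentiate into chondrocytes before new extracellular matrix (ECM) can
be laid down, and in vitro co-culture work suggests the two cell types talk
to each other through growth factors: FGF-1, secreted by MSCs, stimulates
chondrocyte proliferation, while BMP-2, secreted by chondrocytes, promotes
chondrogenic differentiation of MSCs. `cartregen` simulates this feedback
loop in a continuum model of a defect of thickness ~2 mm, resolved along
the depth coordinate only (the defect is much wider than deep), and asks
how much the growth-factor cross-talk accelerates matrix deposition after a
pure stem-cell implantation.

## Model

Six fields evolve on the scaled depth $\bar x \in [0,1]$ ($\bar x = 0$ is
the bone interface, $\bar x = 1$ faces the synovial nutrient reservoir):
stem cells $\bar C_S$, chondrocytes $\bar C_C$ (both scaled by the maximum
packing density $10^6$ cells/mm$^3$), matrix $\bar m$ (scaled by
$m_{max} = 10^{-4}$ g/mm$^3$), nutrient (oxygen) $\bar n$, and the growth
factors $\bar g$ (FGF-1) and $\bar b$ (BMP-2), each scaled by a reference
concentration. All are governed by reaction–diffusion equations:

* **Stem cells** migrate with a matrix-dependent motility
  $\bar D_S(\bar m) = \bar D_{S0}\,\bar m/(\bar m^2+\bar m_1^2)$ (cells
  need some matrix to crawl on; dense matrix immobilises them), proliferate
  logistically at a matrix-mediated, nutrient-limited rate when
  $\bar n > \bar n_1$, die when starved ($\bar n < \bar n_1$), and
  differentiate into chondrocytes at rate $\bar p_2$ once their density
  exceeds a threshold
  $\bar C_{S0}(\bar b) = (\bar C_{S0,max}-\bar C_{S0,min})
  e^{-\bar\alpha \bar b} + \bar C_{S0,min}$ — BMP-2 lowers the bar from
  0.35 towards 0.315.
* **Chondrocytes** gain the differentiation flux one-to-one, proliferate
  with an extra FGF-1 term $\bar p_{400}\,\bar g/(\bar g+1)$, and die under
  starvation.
* **Nutrient** diffuses in from the reservoir ($\bar n = 1$ at
  $\bar x = 1$) and is consumed by both cell types with Michaelis–Menten
  saturation $\bar n/(\bar n + \bar n_0)$.
* **Matrix** is deposited by chondrocytes at rate
  $\bar p_8 = (1-\bar p_{81}\bar m)(1 + \bar p_{800}\,\bar g/(\bar g+1))$,
  which stalls as $\bar m \to 1$; $\bar p_{800} = 0$ by default (FGF-1 acts
  through proliferation, not directly on deposition).
* **Growth factors** are produced proportionally to their source cell type,
  decay with a 12 h half-life, and leak out of the top of the defect
  through Robin conditions $-\bar D\,\partial_x u = \mathrm{coef}\cdot u$.

Everything else is no-flux. Time is scaled by the matrix-production
timescale $m_{max}/(p_{80} C_{total,max0})$:

```{r timescale}
matrix_timescale_hours()        # hours per unit of scaled time; ~11 days
tbar_per_month()                # scaled time units per (30.44-day) month
```

## Parameters

`default_dimensional()` carries the tabulated laboratory-unit estimates;
`default_dimensionless()` carries the published dimensionless set that the
simulations actually use. `nondimensionalize()` implements the scaling
formulas, and `params_consistency()` reports which tabulated dimensionless
values are reproducible from the dimensional table — several are not
(notably $\bar p_{10}$, $\bar p_{40}$, $\bar D_g$, $\bar D_b$, $\bar p_6$,
$\bar p_7$, $\bar\alpha$), and the package deliberately flags rather than
resolves the clashes, always simulating with the published dimensionless
values:

```{r consistency}
tab <- params_consistency()
tab[!tab$consistent, c("field", "recomputed", "tabulated")]
```

Choices the source tables leave open, fixed here once:

* stem-cell motility at the top of its reported range
  ($\bar D_{S0} = 10^{-2}$, ten times the chondrocyte value) — the stem
  front is described as the faster one;
* nutrient reservoir $N_0 = 9.5\times10^{-11}$ moles/mm$^3$ (top of the
  oxygen range, giving $\bar n_0 = 0.24$);
* $\bar D_n = 306.7$ and $\bar D_m = 1.67\times10^{-3}$, the values implied
  by the tabulated dimensional diffusivities;
* the dimensional matrix-degradation constant set to $p_{80}/m_{max}$ so
  that deposition stalls exactly at the packing density (the printed value
  has inconsistent units and cannot reproduce the published
  $\bar p_{81} = 1$);
* dimensional thresholds $C_{S0,max} = 3.5\times10^5$ cells/mm$^3$ (the
  published dimensionless 0.35 rather than the half-packing guess) with
  $C_{S0,min}$ at 90% of it;
* initial chondrocyte density $\bar C_C(0) = 10^{-4}$ (the value used in
  the published runs; one table prints an impossible $10^4$).

Validation is strict by default (positivity, threshold ordering,
$\bar C_{S,max0}+\bar C_{C,max0}=1$, $\bar p_{800}\in[0,1]$); sweeps that
deliberately leave the ranges pass `.force = TRUE`.

## Numerics

Space is discretised by conservative second-order central differences on a
uniform grid (default 101 nodes), with the matrix-dependent motility
evaluated at cell faces from the arithmetic mean of $\bar m$ on adjacent
nodes — this preserves second order and the degeneracy at $\bar m = 0$.
Boundaries are closed by ghost-node elimination: reflection for no-flux,
direct substitution for the pinned nutrient ($\bar n = 1$ at the reservoir,
implemented by zeroing that node's derivative so the ODE system stays
non-singular), and ghost elimination of the Robin growth-factor outflow.
The semi-discrete system is stiff (the nutrient uptake groups are
$\sim 10^4$), so time integration uses `deSolve::ode.1D` with `lsoda` and
a banded Jacobian, `rtol = 10^{-6}`, `atol = 10^{-9}`. No negativity
clipping is applied anywhere; tests require all fields to stay above
$-10\,\mathrm{atol}$.

The threshold switches (differentiation, proliferation, starvation) are
Heaviside gates in the model statement. They are regularised by
$H_\varepsilon(z) = \tfrac12(1+\tanh(z/\varepsilon))$ with a single width
$\varepsilon = 10^{-2}$ for all gates, so the right-hand side is smooth for
the implicit integrator; event-located integration of the sharp system is
out of scope. The smoothed kinetics converge pointwise to the sharp rates
away from the switching surfaces (verified in the test suite at
$\varepsilon = 10^{-2}, 10^{-3}, 10^{-4}$).

**A caveat that matters for interpretation:** the 2-month observables sit
essentially *on* the differentiation transition of the baseline scenario,
and quantities evaluated there are sensitive to $\varepsilon$ (the
baseline 2-month matrix mean moves by tens of percent when $\varepsilon$
is halved, while the 6-month value moves by under 4%). This is a property
of evaluating a switched system at its switching time, not a convergence
failure; profiles at times away from the transition are
$\varepsilon$-robust, and the spatial scheme shows its design order (the
Richardson estimate on the full model at 2 months is ≈ 2.08 on grids
51/101/201). Early-time percent differences between scenarios should be
read with that sensitivity in mind.

Verification built into the suite: an independently coded fixed-step RK4
integration of the pointwise kinetics (step $10^{-4}$) matches the PDE
solver under uniform, diffusion-free, closed-domain conditions to better
than $10^{-4}$ relative in all six fields; the flux-form Laplacian
conserves trapezoidal mass exactly in closed domains; a pure-diffusion
cosine mode decays at second order; the nutrient obeys its maximum
principle ($\bar n \le 1$); the spatial-mean matrix density is
nondecreasing; $\bar m$ never overshoots its packing bound.

## Scenarios and the seeding profile

`scenario_spec()` names four growth-factor configurations: `none`,
`fgf_only`, `bmp_only`, `both`. Excluded factors have both their
production constant and initial concentration zeroed, so no residual
initial pulse leaks in; the baseline is bit-for-bit identical to the full
model with those four parameters zeroed (tested).

The implanted stem cells are seeded against the bone as a Gaussian layer
$\bar C_S(\bar x, 0) = 0.25\,e^{-(\bar x/\bar w)^2}$ with width
$\bar w = 0.1$. The published study inherits its seeding profile from a
predecessor model without restating it; the Gaussian is peak-normalised
(the tabulated 0.25 is a density, and the published initial profiles peak
at that value), and $\bar w$ is exposed as configuration. A small uniform
chondrocyte density and matrix density ($10^{-4}$ each) pre-exist in the
defect; the nutrient column starts full. Months are mean calendar months
(30.44 days); with the default timescale, 2 months ≈ 5.48 time units.

```{r run, eval = FALSE}
none <- run_scenario(scenario_spec("none", duration_months = 4,
                                   cadence_months = 0.25))
both <- run_scenario(scenario_spec("both", duration_months = 4,
                                   cadence_months = 0.25))
percent_difference(both, none, "m", 2)   # ~ +45% matrix at 2 months
```

## What the simulations show

At the default conditions the baseline run reproduces the published
narrative: stem cells proliferate near the bone while the local nutrient
declines, the peak density crosses the 0.35 differentiation threshold
between months 1.5 and 2, chondrocytes then form rapidly and deposit
matrix, and two cell fronts migrate up the defect with the stem front
ahead (it has the higher motility). With growth factors enabled, the
chondrocyte-BMP-2 feedback pins the differentiation threshold at its 0.315
floor wherever chondrocytes accumulate, differentiation starts earlier,
and matrix and chondrocyte densities at 2 months exceed the baseline by
tens of percent (≈ +45% and +87% at the defaults; the published run
reports +65% and +66%), declining to ≈ +21% and +23% at 4 months
(published: +34% and +19%). BMP-2 alone is indistinguishable from both
factors together (< 2% maximum relative matrix difference at 2 months),
and FGF-1 alone contributes about 1% of the combined effect — the
asymmetry the study emphasises. The residual quantitative gaps against the
published percentages trace to the unpublished seeding profile and gate
handling: the effect sizes at 2 months depend on exactly when the baseline
crosses its threshold relative to the 2-month stamp, which is the same
$\varepsilon$-sensitivity discussed above. One published figure the model
does not reproduce at these conditions is the 4-month *decrease* in mean
stem-cell density (we find a small increase instead, because the
faster-moving growth-factor fronts add stem cells ahead of the baseline at
that stamp), and full defect coverage at 90% matrix density is not reached
within 24 months (the defect bottom stays nutrient-starved; the top does
fill, max $\bar m \approx 0.995$).

Parameter sensitivity (one-at-a-time, via `sweep_parameter()`): raising
BMP-2 production tenfold ($\bar p_{12} = 267$), slowing its degradation a
hundredfold ($\bar p_{13} = 0.154$), or lowering the threshold floor
($\bar C_{S0,min} = 0.28$) each make differentiation begin earlier —
visible as more chondrocytes and matrix formed by 2 months — while
weakening the threshold response ($\bar\alpha = 1$) delays it the most,
giving the least 2-month matrix of all five runs. The stem-cell density at
the bone is *not* a monotone readout of this ordering in our runs: earlier
matrix deposition feeds back into faster stem-cell proliferation, which
can leave the accelerated variants with more stem cells at the 2-month
stamp even though they differentiated earlier.

## What the model does not capture

No mechanical loading, no chondrocyte hypertrophy or endochondral
ossification, no 2-D/3-D defect geometry, no moving defect boundary, no
co-implantation of mixed MSC/chondrocyte populations, and no bottom-boundary
stem-cell influx from the marrow. The synthetic scenarios emulate the
idealised surgical situation — a clean 1-D column with a fixed nutrient
reservoir — so agreement with the tests says nothing about patient-level
variability, defect shape effects, or the in vivo growth-factor milieu.

## Problem sizes used in the checks

The bundled tests and the acceptance script run the paired scenario
comparisons on the default 101-node grid to 4 months (0.25-month output
cadence), the front/threshold checks to 6 months, one baseline run to 24
months, the sensitivity set (base plus four variants) to 2 months, and
the order-of-accuracy triple on 51/101/201 nodes; these sizes resolve the
fronts (width $\sim \bar m_1 = 0.1$) while keeping the whole suite at
desk scale.
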