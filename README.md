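# cartregen

Deterministic simulation of cartilage regeneration in a chondral defect
after mesenchymal stem cell (MSC) implantation, with growth-factor-mediated
cross-talk between MSCs and chondrocytes.

## What it models, and for whom

Cell therapies for cartilage lesions implant cultured chondrocytes or MSCs
into the debrided defect. MSCs must differentiate into chondrocytes before
new extracellular matrix (ECM) forms, and co-culture experiments suggest a
feedback loop: MSCs secrete FGF-1, which stimulates chondrocyte
proliferation, while chondrocytes secrete BMP-2, which promotes MSC
differentiation. `cartregen` is aimed at modellers and experimentalists who
want a tested, scriptable implementation of the continuum description of
this process: six coupled reaction–diffusion fields on the scaled defect
depth $\bar x \in [0,1]$ — stem cells $\bar C_S$, chondrocytes $\bar C_C$,
matrix $\bar m$, nutrient $\bar n$, FGF-1 $\bar g$ and BMP-2 $\bar b$.
The core equations (dimensionless form) are

$$
\partial_{\bar t} \bar C_S =
  \partial_{\bar x}\!\big(\bar D_S(\bar m)\,\partial_{\bar x}\bar C_S\big)
  + \bar p_1 \tfrac{\bar n}{\bar n + \bar n_0}\,\bar C_S\,H(\bar n-\bar n_1)
  - \bar p_2\,\bar C_S\,H\!\big(\bar C_S - \bar C_{S0}(\bar b)\big)
  - \bar p_3\,\bar C_S\,H(\bar n_1-\bar n),
$$

with the differentiation flux appearing as a source in the chondrocyte
equation, Michaelis–Menten nutrient uptake, matrix deposition
$\bar p_8(\bar m,\bar g)\,\tfrac{\bar n}{\bar n+\bar n_0}\bar C_C$, and
production–decay dynamics for both growth factors. BMP-2 acts by lowering
the differentiation threshold,
$\bar C_{S0}(\bar b) = (\bar C_{S0,max}-\bar C_{S0,min})e^{-\bar\alpha\bar b}
+ \bar C_{S0,min}$, from 0.35 towards 0.315. The Heaviside gates $H$ are
smoothed ($\tfrac12(1+\tanh(z/\varepsilon))$, $\varepsilon = 10^{-2}$), the
spatial operator is a conservative second-order finite-difference scheme
(101 nodes by default), and time integration is stiff (`deSolve::ode.1D`,
`lsoda`). One unit of scaled time is the matrix-production timescale,
about 11 days. See the methods vignette
(`vignettes/cartilage-regeneration-model.Rmd`) for the full model,
parameter provenance and numerical choices.

## Worked example

Compare 4 months of healing with and without the growth-factor loop:

```r
library(cartregen)

matrix_timescale_hours()
#> [1] 266.6667            # hours per scaled time unit (~11 days)

none <- run_scenario(scenario_spec("none", duration_months = 4,
                                   cadence_months = 0.25))
both <- run_scenario(scenario_spec("both", duration_months = 4,
                                   cadence_months = 0.25))

percent_difference(both, none, "m", 2)
#> [1] 44.77032            # +45% mean matrix at 2 months with growth factors
percent_difference(both, none, "m", 4)
#> [1] 20.83911            # effect subsides by 4 months
percent_difference(both, none, "cc", 2)
#> [1] 87.27539            # chondrocytes, boosted by earlier differentiation
fill_time(run_scenario(scenario_spec("none")), threshold = 0.9)
#> [1] NA                  # bottom of the defect stays nutrient-starved
```

The first two numbers say that enabling FGF-1/BMP-2 cross-talk raises the
spatial-mean matrix density 2 months after implantation by about 45%
relative to the growth-factor-free baseline, an advantage that decays to
about 21% by 4 months — the cross-talk accelerates early healing rather
than changing the endpoint. The chondrocyte surplus at 2 months (+87%)
is the mechanism: BMP-2 produced by the first chondrocytes lowers the
stem-cell differentiation threshold to its floor, so differentiation
starts earlier and feeds matrix deposition sooner.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/cartregen.R run --scenario both --months 24 --grid 101 --out out/
Rscript inst/cli/cartregen.R compare --a both --b none --months 6
Rscript inst/cli/cartregen.R sweep --scenario both --param p12 --values 26.67,267 --months 2
Rscript inst/cli/cartregen.R convergence --months 2
```

Runs are deterministic; results directories contain `profiles.csv`,
`means.csv`, `params.json` and a checksummed manifest, and reproduce
themselves from their own `params.json`.

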