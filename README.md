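# cmldyn

Deterministic models of clonal competition between imatinib-resistant
BCR-ABL1 mutant clones in chronic myelogenous leukemia (CML) during
second-line tyrosine kinase inhibitor (dasatinib/nilotinib) therapy —
a simulator, bifurcation-analysis toolkit and least-squares fitting
workbench for sparse per-clone BCR-ABL1/GUS follow-up series.

It is written for modellers of hematologic malignancies and for anyone
who wants to reproduce, stress or extend this family of stem-cell
competition models: each resistant clone *i* has a cycling stem pool
*x*<sub>si</sub> and a differentiated pool *x*<sub>di</sub> obeying

```
dx_si/dt = (1 - ν2 - ν3) ζ_i(x_s) α_i x_si - δ_i x_si        (+ mutation influx for clones 2, 3)
dx_di/dt = p(x_d) a_i x_si - d_i x_di
ζ_i(x_s) = exp(-Σ_j ω_ij x_sj / θ_si),   p(x_d) = exp(-Σ_j x_dj / θ_d)
```

with exponential negative-feedback growth functions and a clone-specific
niche-competition matrix ω. Model **A** is this system alone; model
**B** adds a quiescent clone-1 stem pool *x*<sub>q1</sub> draining into
the cycling pool at rate ν<sub>q1</sub>; model **C** additionally
deactivates cycling clone-1 cells at rate ν<sub>c1</sub> whenever the
total differentiated burden exceeds a threshold θ<sub>q1</sub> (hard
step or steep sigmoid switch). The package also implements the analytic
rescaling of the surviving two-clone stem system — selection parameters
γ = (α−δ)/δ, characteristic values g<sup>−1</sup>(γ) with
g(u) = e<sup>u</sup>−1, regime classification (axis / coexistence /
bistable saddle), closed-form bifurcation points and the focal
(co-dimension-two) point — plus bounded multi-start nonlinear
least-squares fitting of model parameterizations to sparse clinical
series, and a synthetic-profile generator with detection-limit
censoring and multiplicative noise.

## Worked example

Load a shipped three-clone test parameterization (clone-2 feedback
threshold θ<sub>s2</sub> = 10), classify its long-term regime, and
simulate 500 days of therapy:

```r
library(cmldyn)

fx <- cml_fixture("table2_theta_s2_10")
analyze_2d(fx$params)
#> reduced 2D equilibrium analysis (clones 2, 3)
#>   gamma        : 0.25, 0.25
#>   characteristic: 0.223144, 0.223144
#>   discriminants : w1*ys = 2.23144, w2*xs = 0.0111572
#>   regime        : line_equilibrium_y_axis

traj <- simulate_model(fx$params, fx$state0, horizon = 500)
find_crossing(traj, "xd1", 1e6, "down")
#> [1] 37.1  (days: the initially dominant clone's differentiated pool
#>            falls below 1e6 cells/ml)
traj$states[nrow(traj$states), 4:6]
#> xd1 ~ 1e-34, xd2 ~ 5e-138, xd3 ~ 2.23e7
```

The analysis says that with this parameterization only clone 3 can
persist (its axis equilibrium is the stable regime: γ = 0.25 for both
surviving clones, but clone 2's characteristic value 0.223 is far below
the competition pressure ŵ1·ŷs = 2.231 it faces), and the simulation
agrees: after 500 days clones 1 and 2 are extinct and clone 3 sits at
its predicted equilibrium (2.23×10⁷ = p·a·θ·ln(1.25)/d cells/ml).

Fitting works on sparse, noisy per-clone series (here synthetic, one
free rate constant, truth δ₁ = 1):

```r
p  <- cml_params("A", alpha = c(1, 1), delta = c(1, 0.8),
                 a = c(1e6, 1e6), d = c(1, 1),
                 theta_s = c(100, 100), theta_d = 1e10,
                 omega = matrix(c(1, 1, 0.5, 1), 2, 2, byrow = TRUE))
s0 <- cml_state(xs = c(100, 5), xd = c(7e7, 0))
ds <- generate_profile(p, s0, grid_days = seq(0, 150, 30),
                      noise_cv = 0.05, seed = 42)
tpl <- p; tpl$delta[1] <- 1.3
cml_fit(ds, tpl, s0, free = "delta1", n_starts = 5, seed = 7)
#> cml_fit: model A, 2 clones; SSR = 3.84254e+13; converged
#>   fitted: delta1=0.99663
#>   R^2 per clone: clone1=0.8746, clone2=0.8848
```

A thin command-line front end (`inst/cli/cmldyn`) exposes the same
functionality as `simulate`, `scan`, `classify`, `fit` and `synth`
subcommands, each writing its artifacts plus a reproducibility
manifest.

The methods vignette (`vignettes/cmldyn-methods.Rmd`) documents the
model equations and assumptions, parameter units and defaults, the
numerical treatment of the discontinuous quiescence switch, the
rescaled two-clone analysis, and what the synthetic-data generator does
and does not emulate.

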