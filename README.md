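# immunedyn

Equilibrium, stability and bifurcation analysis for a deterministic
within-host model of the fight between the human immune system and a
replicating pathogen.

## The model

Three immunity compartments — innate, humoral and cellular immunity, at
levels `x1(t)`, `x2(t)`, `x3(t)` — grow logistically toward their carrying
capacities `a_i/b_i` and are killed by a pathogen whose load `v(t)`
proliferates exponentially and is cleared by each immunity type:

    dx_i/dt = a_i x_i − b_i x_i² − c_i x_i v        (i = 1, 2, 3)
    dv/dt   = p4 v − (p1 x1 + p2 x2 + p3 x3) v

with all rates strictly positive. The biologically meaningful region is the
closed positive orthant, whose coordinate hyperplanes are invariant
manifolds of the flow. The package provides:

- **Equilibria.** The full catalogue in closed form, indexed by support
  pattern: 15 points for three immunity types (`E0`, `E11`…`E13`,
  `E212`…`E223`, `E3`, `E41`…`E43`, `E512`…`E523`, `E6`), and
  `2^(n+1) − 1` points for `n` immunity types generally (63 for the
  five-type, six-dimensional analogue).
- **Stability.** Numeric eigenvalue classification
  (attractor/repeller/saddle, with scale-free nonhyperbolicity detection),
  the Routh–Hurwitz quartic criterion, analytic characteristic-polynomial
  coefficients at `E512` and `E6`, explicit eigenvalues at `E41`, and the
  analytic verdicts they imply: the origin is a repeller, the virus-free
  coexistence point `E3` is an attractor exactly when
  `p4 < k := Σ p_i a_i / b_i`, and every other admissible equilibrium is a
  saddle.
- **Bifurcations.** The transcritical surfaces where `E6` collides with
  `E3`, `E5ij` or `E4i`, numerical verification of Sotomayor's three
  transcritical conditions at `E3` on `p4 = k`, bisection location of the
  stability exchange, and a certificate excluding a Hopf–Hopf bifurcation
  at the interior point (`A3 > 0`, `A0 < 0`).
- **Medical controls.** Two intervention variants adding `α x1 x2 x3`-type
  (product) or `α x1 (x2 + x3)`-type (pairwise-sum) boosts to the immunity
  equations, a seeded multi-start solver for their equilibria, closed-form
  boundary spectra, and attractor predicates showing how sufficiently
  strong interventions can stabilize boundary equilibria that are saddles
  in the uncontrolled system.
- **Dynamics.** Adaptive trajectory integration with an escape event,
  long-run outcome classification (converged / escaping / undetermined)
  and a positive-orthant invariance audit.

Everything user-facing takes and returns tibbles, so results compose with
the usual dplyr/ggplot2 workflow (`autoplot()`, `tidy()`, `glance()`).

## Worked example

```r
library(immunedyn)

m <- immune_model(a = c(1, 1, 1), b = c(1, 1, 1), c = c(1, 1, 1),
                  p = c(1, 1, 1), p4 = 0.5)
classify_stability(m)
#> # A tibble: 15 × 7
#>    label    x1    x2    x3     v in_sigma_plus classification
#>  1 E0    0     0     0     0     TRUE          repeller
#>  8 E3    1     1     1     0     TRUE          attractor_node
#> 11 E512  0.25  0.25  0     0.75  TRUE          saddle
#> 15 E6    0.167 0.167 0.167 0.833 TRUE          saddle
#>  ... (the remaining 11 rows are all saddles)
```

At unit rates the joint clearance at capacity is `k = 3 > p4 = 0.5`, so the
virus-free coexistence point attracts: the immune system wins whenever all
three immunities start near their normal levels. Every other admissible
equilibrium is a saddle — one repeller, one attractor, 13 saddles.

A nearby orbit indeed converges to `E3`:

```r
classify_outcome(simulate_model(m, c(0.9, 1.1, 1.0, 0.2), t_end = 200))
#> # A tibble: 1 × 5
#>   outcome   label  time  distance     speed
#> 1 converged E3      200 4.22e-140 1.05e-139
```

On the collision surface `p4 = k = 3` the interior point `E6` merges with
`E3` in a transcritical bifurcation; Sotomayor's conditions evaluate to

```r
sotomayor_at_e3(immune_model(rep(1, 3), rep(1, 3), rep(1, 3), rep(1, 3), p4 = 3))
#> <sotomayor_check> mu = 0  k = 3
#>   cond1 (w.F_mu)      = 0.000e+00
#>   cond2 (w.DF_mu v)   = 1.000000
#>   cond3 (w.D2F(v,v))  = 6.000000
#>   transcritical conditions met: TRUE
```

where `cond3 = 2 Σ p_i c_i / b_i = 6` at unit rates.

A thin command-line front end over the same functions ships in
`inst/cli/immunedyn.R` (`analyze`, `simulate`, `scan`, `sample`
subcommands driven by YAML/JSON configs).

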