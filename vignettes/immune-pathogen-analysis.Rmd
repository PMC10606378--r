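---
title: "Local analysis of an immune-pathogen interaction model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Local analysis of an immune-pathogen interaction model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(immunedyn)
```

## The model and its assumptions

The package analyses a four-dimensional deterministic system coupling three
immunity compartments — innate, humoral and cellular immunity at levels
$x_1, x_2, x_3$ — to a single pathogen load $v$:

$$\dot x_i = a_i x_i - b_i x_i^2 - c_i x_i v, \qquad
  \dot v = p_4 v - \textstyle\sum_i p_i x_i v .$$

The construction rests on three modelling assumptions. First, in the
absence of the pathogen each immunity level follows a logistic law: it can
be present before infection and saturates at the carrying capacity
$a_i/b_i$ rather than growing without bound (the closed form is exposed as
`logistic_solution()`). Second, the immunity types do not attack each
other — there is no autoimmunity — so the only loss term in each immunity
equation is predation by the pathogen, at rate $c_i$. Third, without any
immune response the pathogen multiplies exponentially at rate $p_4$, and
each immunity type clears it at rate $p_i$. The three compartments are
treated as acting independently; the very real cross-regulation between
innate and acquired immunity is deliberately outside the model.

All rates are strictly positive, which `immune_model()` enforces at
construction. The state space with biological meaning is the closed
positive orthant; each coordinate hyperplane is an invariant manifold (the
per-capita structure of every equation guarantees it), so orbits cannot
cross from the meaningful region to the meaningless one. This is both a
model property and a numerical obligation checked by `invariance_audit()`.

The immunity equations generalize verbatim to $n$ types; the package keeps
$n$ free (`n_types`) because the equilibrium combinatorics — the point of
the generic enumeration — grows as $2^{n+1}-1$, reaching 63 points for the
five-type model of all white-blood-cell classes. The two control variants
are defined for three types only.

## The equilibrium catalogue

Every equilibrium is indexed by its *support pattern*: which immunity
types are at a positive level, and whether the viral load is on. Setting
each factored equation to zero gives, per pattern, either the carrying
capacities (virus off) or the virus-on levels
$x_i = (a_i - c_i v_T)/b_i$ with the viral load

$$v_T = \frac{\sum_{i\in T} p_i a_i/b_i - p_4}{\sum_{i\in T} p_i c_i/b_i}.$$

For $n = 3$ this is the canonical 15-point catalogue (`equilibria()`),
labelled `E0` through `E6`. The empty virus-on pattern is impossible
because $p_4 > 0$.

Two semantics deserve a note. `in_sigma_plus` flags *admissibility*: the
point lies in the closed orthant and every supported coordinate is
strictly positive (for the full-support point `E6` this coincides with
membership in the open orthant). Coordinates are exact closed-form ratios,
so positivity is tested against a `1e-12` tolerance purely to guard
round-off. Second, enumeration is by pattern, so degenerate parameter sets
in which two patterns share coordinates (for example $v_T = 0$) keep both
rows; `distinct_equilibria()` flags the coincidence instead of silently
dropping a label.

## Stability classification and its analytic cross-checks

`classify_stability()` computes Jacobian eigenvalues numerically and reads
off the class from the sign pattern of the real parts. Hyperbolicity is
decided scale-free: a real part below $10^{-9}\max(1, \rho)$ (spectral
radius $\rho$) marks the point nonhyperbolic, in which case the function
reports `nonhyperbolic` rather than forcing a verdict — linearization says
nothing there, and the package never applies center-manifold arguments.

The classification is cross-checked against analytic results implemented
as independent oracles:

- `theorem_verdicts()` encodes the closed-form analysis: `E0` is always a
  repeller; `E3` is an attractor iff $p_4 < k := \sum_i p_i a_i/b_i$ and a
  saddle for $p_4 > k$; every other admissible equilibrium is a saddle.
- `charpoly_e512()` and `charpoly_e6()` evaluate the printed-form quartic
  coefficients $A_3,\dots,A_0$ at the mixed and interior points, compared
  in the tests against `charpoly_from_eigenvalues()` (the product
  expansion of the numeric spectrum — the characteristic polynomial is
  built from eigenvalues rather than determinant recursion, since the
  eigenvalues are needed anyway and conditioning is a non-issue at
  $4\times4$). At `E512`, $A_0 = x_1 x_2 x_4 (a_3 - c_3 x_4)(b_1 p_2 c_2 +
  p_1 c_1 b_2)$, so the saddle verdict follows from the sign of
  $a_3 - c_3 x_4$ together with the deflated cubic
  ($B_2, B_1, B_0$) when $A_0 > 0$.
- `e41_eigenvalues()` returns the explicit spectrum at the single-type
  virus-on points, including the in-plane pair
  $(-p_4 b_i \pm \sqrt\Delta)/(2p_i)$; admissibility forces
  $\sqrt\Delta > p_4 b_i$, hence a saddle.
- `routh_hurwitz_quartic()` implements the quartic stability inequalities,
  validated against `polyroot()` on random coefficient draws with a
  $10^{-9}$ boundary band excluded (strict inequalities cannot be decided
  on the boundary in floating point).

One measure-zero case is documented rather than resolved: at `E512` with
$x_4 = a_3/c_3$ the constant term vanishes and a zero eigenvalue appears.
The analytic deflation argument still yields a saddle, and
`theorem_verdicts()` says so, but the numeric classifier reports
`nonhyperbolic` there; the two disagree on that boundary by design.

## Transcritical bifurcations

`surface_residuals()` evaluates the four collision hyperplanes: on $S$
($k - p_4 = 0$) the interior point collides with `E3`; on $S_{12}$,
$S_{13}$, $S_{23}$ (where $v_6$ reaches the omitted type's threshold
$a_k/c_k$) it collides with the corresponding `E5ij`, subject to the
printed feasibility side-conditions; on the pairwise intersections
$\pi_1, \pi_2, \pi_3$ it collides with `E41`, `E42`, `E43`.

`sotomayor_at_e3()` verifies the three transcritical conditions at `E3` on
$S$, with $\mu = p_4 - k$ as the bifurcation parameter. The null vectors
are computed numerically as the smallest-magnitude eigenpairs of the
Jacobian and its transpose, normalized so the last component is $+1$ —
that sign convention makes the analytic values exact:
$w^T F_\mu = 0$ (the $\mu$-gradient is $(0,0,0,x_4)$ and the viral load
vanishes at `E3`), $w^T (DF_\mu) v = v_4 = 1$, and
$w^T D^2F(v,v) = 2\sum_i p_i c_i/b_i$. The $\mu$-derivatives are analytic;
the second differential is taken by central second differences with step
$h = 10^{-4}\,\mathrm{scale}$, which is near-exact because the vector
field is quadratic. The same machinery applies along the other surfaces
with $p_4$ as the varied parameter; there the verdict is numeric — no
printed calculation exists to check against, and the scan reports
collision and eigenvalue crossing only.

`crossing_scan()` brackets and bisects the critical eigenvalue
$\lambda_4(E_3) = p_4 - k$ to $10^{-10}$ and reports the exchange: below
$k$, `E3` attracts and `E6` is an admissible saddle; above $k$, `E3` is a
saddle and `E6` leaves the orthant ($v_6 < 0$). `hopf_hopf_exclusion_e6()`
certifies that two pure-imaginary pairs are impossible at an admissible
interior point, because they would force eigenvalue sum $0$ and product
$> 0$ while $A_3 > 0$ and $A_0 < 0$.

## The controlled systems

Two intervention patterns add terms to the immunity equations only (a
medical intervention boosts immunity; it does not directly attack the
pathogen): the *product* control $(\alpha, \beta, \gamma)\,x_1x_2x_3$ and
the *pairwise-sum* control $\alpha x_1(x_2{+}x_3)$, $\beta x_2(x_3{+}x_1)$,
$\gamma x_3(x_1{+}x_2)$, with control constants of any sign.

The boundary equilibria keep closed forms whose spectra are printed-form
explicit (`boundary_eigenvalues()`), and three attractor predicates encode
the analytic criteria: under the product control `E212` is an attractor
iff $p_4 < p_1 a_1/b_1 + p_2 a_2/b_2$ and
$a_3 b_1 b_2 + \gamma a_1 a_2 < 0$; under the pairwise-sum control `E11`
is an attractor iff $p_4 < p_1 a_1/b_1$ and both transverse combinations
$a_j b_1 + g_j a_1$ are negative; and the pairwise-sum `E212` (closed form
$x_1^* = (a_1b_2 + a_2\alpha)/(b_1b_2 - \alpha\beta)$, …) is an attractor
iff the factorized characteristic polynomial
$(X - \lambda_3)(X - \lambda_v)(X^2 + q_1 X + q_0)$ has $\lambda_3 =
a_3 + \gamma(x_1^*{+}x_2^*) < 0$, $\lambda_v = p_4 - p_1x_1^* - p_2x_2^* <
0$, $q_1 > 0$ and $q_0 > 0$. The $\gamma$ condition is stated in the
source material in a typographically ambiguous form; the package adopts
the reading $\gamma(x_1^*+x_2^*) + a_3 < 0$, which is the one consistent
with both the accompanying prose bound and the polynomial factorization
(the alternative reading would detach the condition from the third
eigenvalue it controls). Equality cases are reported as `NA`: the criteria
are strict and linearization is silent on the threshold.

The medical upshot mirrored by these predicates: a sufficiently strong
boost ($\gamma < -a_3 b_1 b_2 / (a_1 a_2) < 0$, and its analogues) turns a
boundary saddle into an attractor, so the immune system can win even with
one or two compartments depleted.

`solve_equilibria()` handles the coordinates that lose their closed forms
(`E3`, `E6` and, under the pairwise-sum control, the virus-on points). Per
support pattern it solves the *divided* system — each equation divided by
its own positive state variable, which is polynomial and avoids spurious
convergence onto smaller supports — by Levenberg–Marquardt from 32 seeded
starts drawn log-uniformly in $[10^{-3}, 10]$ times the carrying-capacity
scale, plus the uncontrolled closed-form point. Roots must pass a
$10^{-9}$ residual check on the full vector field and are deduplicated at
relative distance $10^{-7}$. Two caveats are worth recording. The start
box is centred on biologically plausible scales, so the reported count
reflects roots reachable from that region; for the cubic interaction terms
of the product control, additional real roots exist far outside it (at
unit rates with $\alpha=\beta=\gamma=0.05$, a second virus-free
full-support root sits near $x_i \approx 18.9$, an order of magnitude
beyond the carrying capacity), so the familiar 15-point count is a
statement about small controls and physiological scales, not an algebraic
identity. Likewise, whether the pairwise-sum two-type points exist at all
is decided numerically — no closed existence criterion is implemented.

## Trajectories and outcomes

`simulate_model()` integrates with `deSolve::lsodar`, which switches
automatically between non-stiff and stiff formulas (relevant when $p_4$ or
the controls dwarf the immunity rates) and supports root-triggered
stopping. "Escape to infinity" needs a finite proxy: the escape event
fires when any component exceeds $10^6 \max(\max_i a_i/b_i, 1)$.
`classify_outcome()` declares convergence only when the final state is
within $10^{-6}$ (max norm) of a catalogued equilibrium *and* the vector
field there is below the same threshold — the derivative check prevents
slow saddle passages from masquerading as convergence. Everything else is
`undetermined`, including honest truncations.

Default tolerances are `rtol = 1e-8`, `atol = 1e-10`; with these the
invariance audit's worst boundary violation stays above $-10^{-7}$ and
virus-free trajectories match the logistic closed form to $10^{-6}$.

## The parameter sampler

`sample_params()` is the package's synthetic-data generator: there is no
empirical data in this problem, so "data" means parameter sets. Rates are
drawn log-uniformly in $[0.1, 10]$ — a scale-free choice spanning two
decades around unity, appropriate for rate constants whose units are
arbitrary (the model is never fitted to measurements); control constants
are drawn uniformly in $[-3, 3]$, wide enough to place draws on both
sides of every attractor criterion. Draws are reproducible from an integer
seed. The reference study conditions used throughout the examples and
checks are unit rates $a_i=b_i=c_i=p_i=1$ with $p_4 = 0.5$ (all 15 points
admissible, `E3` attracting) and $p_4 = 3$ (on the collision surface).

What passing the randomized checks shows — and does not show: agreement of
the numeric classifier with the analytic verdicts across sampled
parameters supports the implementation's correctness over generic
parameter space, but says nothing about measure-zero boundaries (excluded
by explicit bands of $10^{-6}$), about global dynamics (no Lyapunov
analysis is attempted), or about the model's fidelity to any real immune
response, which would require data the model deliberately does not use.

## Problem sizes and runtime choices

The test suite runs 200-draw sweeps for the classifier/verdict and
predicate/classifier agreements, 1000 random quartics for Routh–Hurwitz,
50 on-surface draws for the Sotomayor conditions, and 20–50 draws for the
charpoly and factorization identities; the whole suite completes in about
a minute on one core. These sizes were chosen to exercise every sign
combination of the criteria comfortably while keeping the checks quick to
rerun; the agreement rates are exact (every compared case must match), not
statistical summaries.

## Known limitations

- Local analysis only: no Lyapunov functions, basins of attraction, or
  stable-manifold computation.
- Center manifolds are never computed; nonhyperbolic points are flagged,
  with the `E512` boundary case documented above.
- Controls are implemented for three immunity types only, matching their
  definition; the uncontrolled combinatorics are generic in `n`.
- The controlled root census is a numerical search, with the start-box
  caveat described earlier; no symbolic solution of the controlled
  systems is attempted.
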