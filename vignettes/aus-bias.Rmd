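---
title: "Methods: isotherm estimation, AUS bias, and bootstrap inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: isotherm estimation, AUS bias, and bootstrap inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ausnmr)
```

## The model

For a weak 1:1 complex $A + D \rightleftharpoons AD$ observed by
proton-NMR under fast exchange, the upfield shift of an acceptor proton
at initial concentrations $a_0$ (acceptor) and $d_0$ (donor) is

$$\Delta = f(K; a_0, d_0)\,\Delta_C, \qquad
f = \frac{(Ka_0 + Kd_0 + 1) - \sqrt{(Ka_0 + Kd_0 + 1)^2 - 4K^2a_0d_0}}{2a_0K},$$

with $f$ the complexed fraction of acceptor, $K$ the association
constant (M$^{-1}$) and $\Delta_C$ the complexation shift (ppm). The
package stores shifts with the positive-upfield convention
$\Delta = \delta_A - \delta$; raw-shift input is converted on read.
Units are molar and ppm throughout — no unit inference.

Excess free donor also shields acceptor protons through non-complexing
collisions (*additional unspecific shielding*, AUS). With coefficients
$a_1$ (free acceptor) and $a_2$ (complexed acceptor), both in ppm/M,
the references move upfield with $d_0$ and the observed shift becomes

$$\Delta = f \,(\Delta_C - a_1 d_0 + a_2 d_0) + a_1 d_0 .$$

Neither $a_1$ nor $a_2$ is estimable from a titration in the usual
0.1–0.9 M donor range (that would need donor concentrations of order
1–10 M, which perturb the solvent and the internal reference), so the
package never fits them; it *simulates* their consequences. Both
coefficients are capped by the mean collision-shielding coefficient of
the donor — 0.088 ppm/M for mesitylene, rounded to 0.09 as the sweep
maximum (`cap` argument). The occasionally quoted ordering
$a_1 \ge a_2$ is *not* enforced: the individual-effect sweeps
deliberately set one coefficient to zero while the other varies.

## Estimation

`fit_binding()` minimises
$\sum_i (\Delta_i - \hat\Delta_i)^2$ over $(K, \Delta_C)$ by variable
projection: at fixed $K$ the model is linear in $\Delta_C$, so
$\Delta_C(K)$ has a closed form and the search is one-dimensional. A
deterministic log-spaced candidate scan ($K$ from $10^{-4}$ to
$10^{2.7}$, plus a negative branch down to $-1$ and the scale-free
start $K_0 = 1/\mathrm{median}(d_0)$) brackets the minimum of the
profiled sum of squares and `stats::optimize()` polishes it to a
$10^{-11}$ tolerance, so results are grid-limited only in pathological
cases and carry no dependence on starting values. Noise-free data are
recovered to better than $10^{-6}$ in both parameters (asserted in the
tests).

Numerical choices worth recording:

* **Small and negative $K$.** The textbook root
  $(b - \sqrt{\cdot})/(2a_0K)$ cancels catastrophically as
  $K \to 0$. The bound fraction is therefore evaluated in the
  rationalised form $2Kd_0 / (b + \sqrt{b^2 - 4K^2a_0d_0})$, exact at
  $K = 0$ and stable for the small negative $K$ that unconstrained
  least squares must be able to visit (weak protons genuinely produce
  negative bootstrap draws). Far enough below zero the quadratic loses
  its real root; such candidates get an infinite objective rather than
  an error.
* **No parameter bounds by default.** Near-zero-$K$ protons are a
  diagnostic signal, not a failure; `positive = TRUE` is opt-in.
* **Standard errors** come from the Jacobian-based covariance
  $s^2 (J^\top J)^{-1}$ with the $\Delta_C$ column exact ($=f$) and the
  $K$ column by central difference on $f$.
* **Degenerate inputs.** Fewer than 3 points, fewer than 2 distinct
  positive $d_0$, duplicated $d_0$, or inconsistent $a_0$ within a
  series are rejected with the series named.

## The AUS bias simulation

`aus_bias()` generates *noiseless* shifts from the AUS-extended model
and refits the plain isotherm — a deterministic experiment isolating
the structural bias; no noise is added because the characterised effect
is systematic, not stochastic. Defaults are the conditions under which
the package's reference values are defined: $a_0 = 0.001$ M, true
$K = 0.8$ M$^{-1}$, and a donor grid of 0.1–1.0 M in 0.1 M steps
(`sim_d0_grid()`). The experimental titration design spans 0.1–0.9 M;
the simulation grid carries one extra point at 1.0 M. The choice
matters only in the third decimal of the bias surfaces except in the
extreme weak-shift corner (set $\Delta_C = 0.01$ ppm at
$a_2 = 0.09$ ppm/M), where the fit is a long flat valley in $(K,
\Delta_C)$ and the apparent $\Delta_C$ is sensitive to the grid; the
10-point grid is the discretisation the package's reference values are
stated under. The collective sweep uses set
$\Delta_C \in \{0.8, 0.75, 0.7, 0.6, 0.3, 0.1, 0.05, 0.01\}$ ppm —
dense enough to cover every tabulated lookup — and
$a_2 = 0.01$–$0.09$ ppm/M at fixed $a_1 = 0.09$; a denser grid is a
single argument away.

Two structural facts drive the downstream rules, both asserted as
properties over the full sweep: $a_2 > 0$ only ever *depresses* the
apparent $K$ (the more so the smaller the true $\Delta_C$), and AUS
only ever *inflates* the apparent $\Delta_C$. Hence max-$K$ selection
(`select_best_k()`): among the per-proton estimates of one complex the
largest is the least biased. And hence the geometry readout
(`rank_protons()`): the apparent-$K$ order tracks proton distance from
the donor ring, while the apparent-$\Delta_C$ order can invert
(`aus_tradeoff_traces()` exhibits both a preserved and an inverted
ordering from monotone truths).

## Bootstrap inference

Titration designs fix $d_0$, so `bootstrap_binding()` resamples
*residuals* at the fixed design points (fixed-x bootstrap): draw
$e^*_i$ with replacement from the fitted-model residuals, form
$\Delta^*_i = \hat\Delta_i + e^*_i$, refit from the point estimate.
Failed refits are discarded and redrawn (up to $2B$ attempts) so the
sample length is exactly $B$ (default 10 000), with the failure count
reported.

One correction is applied by default: least-squares residuals
underestimate the error scale by $\sqrt{(n-p)/n}$, which is material at
$n = 9$, $p = 2$ (12%). Residuals are therefore inflated by
$\sqrt{n/(n-2)}$ before resampling — the standard variance correction
for the residual bootstrap. Without it the percentile intervals
demonstrably undercover and the z-route type-I rate is structurally
inflated to $2\Phi(-1.96\sqrt{7/9}) \approx 0.084$;
`scale_residuals = FALSE` restores the raw-residual variant.

Pairwise comparison (`compare_bootstraps()`, `compare_protons()`)
follows a gated procedure: both draw vectors are tested for normality
by the composite Anderson–Darling test; if both pass, a two-sided
z-test on bootstrap means with bootstrap standard deviations decides
(the natural normal-theory choice at $B = 10^4$, where the bootstrap sd
is an accurate standard-error estimate); otherwise the Mann–Whitney
test with the normal approximation and tie correction. Decisions use
$\alpha = 0.05/n$ with $n$ the number of pairwise comparisons per
acceptor by default (`adjust_by = "groups"` divides by the number of
protons instead — the convention is genuinely ambiguous, so both are
supported).

A property of the gated procedure worth knowing (tested, and visible in
the bundled worked-example decisions, which are almost uniformly
"reject" with $p \approx 0$): the Mann–Whitney route treats the $B$
bootstrap draws as its sample, so its effective power grows with $B$,
and *any* difference between two point estimates — including the
sampling fluctuation between two runs on identically-generated data —
is eventually declared significant. The z route does not share this
defect (its statistic is independent of $B$) and is verified to hold
its nominal type-I rate. Comparisons that route through Mann–Whitney
should be read as "the point estimates differ", not as a calibrated
test at $\alpha$. Percentile intervals use linear-interpolation
quantiles (type 7); an interval entirely below zero flags a physically
meaningless $K$.

## Diagnostics

`stamm_diagnostic()` regresses $\Delta/d_0$ on $\Delta$. In the
dilute-acceptor limit the isotherm gives the exact line
$\Delta/d_0 = K\Delta_C - K\Delta$, so genuine complexation shows a
negative slope $\approx -K$; pure collision shielding
($\Delta = a_1 d_0$) gives a horizontal line, and convex shift data a
positive slope — both symptoms of a near-zero or negative $K$, and
grounds for excluding the proton from max-$K$ selection. "Horizontal"
is declared when the two-sided $t$-test of zero slope is not rejected
at $\alpha = 0.05$; numerically perfect lines (zero residual variance,
where the $t$-statistic is undefined) are classified by the slope
directly. Tie grouping in `rank_protons()` prefers supplied pairwise
test decisions and falls back to an absolute tolerance (default
0.005 M$^{-1}$); chemically equivalent protons are merged by their
`equivalent` label, never by value.

## Synthetic data

`offset_complex_scenario()` encodes the offset-stacking structure the
analysis assumes: one shared true $K$, per-proton $\Delta_C$ falling
and $a_2$ rising linearly with distance from the donor ring, shared
$a_1$. `simulate_titration()` adds iid Gaussian noise on $\Delta$ —
peak-position error at fixed acquisition settings is well approximated
as additive and homoscedastic — with default
$\sigma = 0.002$ ppm, consistent with the near-perfect fit quality
($R^2 \ge 0.999$) the 9-point experimental design achieves; the default
$d_0$ grid is that experimental design, 0.1–0.9 M in 0.1 M steps.

What the generator does *not* emulate: spectrometer physics (lineshape,
shimming, referencing drift), solvent-property changes at high donor
concentration, heteroscedastic peak-picking error for overlapping
multiplets, and any donor self-association. Passing tests on this
generator therefore validate the estimation and inference machinery
under the stated statistical model, not the model's adequacy for any
particular real chemical system.

Problem sizes used by the validation suite were chosen to keep the
whole battery comfortably reproducible on a laptop: interval-coverage
checks use 200 synthetic replicates at $B = 1000$; order-recovery and
type-I checks use 100 replicates at $B = 400$; the reference bias grid
is $8 \times 9$ settings.

## Known limitations

* Only 1:1 stoichiometry; no global multi-proton shared-$K$ fit (the
  per-proton variation is the signal here, and a shared-$K$ fit would
  average the AUS bias rather than expose it).
* The bias is characterised, not inverted: no estimator of the true
  $K$ from an AUS-contaminated one is offered beyond max-$K$ selection.
* Geometry output is an ordering with labels, not coordinates.
* The Mann–Whitney route's $B$-dependence (above) is inherited from
  the published procedure rather than repaired; repair would mean
  comparing estimates, not draw vectors.
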