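---
title: "Methods: a multi-delay model of oncolytic virotherapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a multi-delay model of oncolytic virotherapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oncodelay)
```

## The model

Oncolytic virotherapy treats tumors with viruses that replicate in and lyse
tumor cells. `oncodelay` implements a three-compartment model of this
process: uninfected tumor cells $x(t)$, infected tumor cells $y(t)$ and free
virus $v(t)$, all in units of $10^6$ cells or virions (one mm$^3$ of tumor
volume is taken as $10^6$ cells, so the state is also a volume). Time is in
days; the time unit affects labels only, not any computed quantity.

$$
\begin{aligned}
\dot x &= r x \left(1 - \frac{x+y}{K}\right) - \beta x v - \rho x y,\\
\dot y &= \sum_{i} \beta_i\, x(t-\tau_i)\, v(t-\tau_i) - \delta y,\\
\dot v &= b \delta y - \gamma v - \beta x v .
\end{aligned}
$$

Uninfected cells grow logistically (rate $r$, capacity $K$) and are lost to
free-virus infection ($\beta x v$) and to fusion with infected cells into
syncytia ($\rho x y$). The gain of infected cells is distributed over the
stages of the viral *lytic cycle*: each transmission term $(\beta_i,
\tau_i)$ contributes infections initiated $\tau_i$ days ago, so cells that
entered the cycle at $t - \tau_i$ become productively infected at $t$.
Infected cells die at rate $\delta$, each releasing $b$ virions (the burst
size); free virus is cleared at rate $\gamma$ and consumed by new
infections. The total infection pressure uses $\beta = \sum_i \beta_i$.

### The transmission-list convention

The package carries one ordered list of $(\beta_i, \tau_i)$ pairs, in which
at most one term may have $\tau = 0$ (instantaneous transmission) and
$\beta$ sums over *all* terms, including the instantaneous one. This single
convention is used in the loss terms, in $R_0$, and in every stability
quantity. It is the only reading under which the benchmark scenarios below
reproduce their stated reproduction numbers: e.g. the subthreshold scenario
requires $\beta = 1.1\times10^{-3} = \beta_0 + \beta_1 + \dots + \beta_4$.

### Reference parameters

The preset scenarios use $r = 0.206$/day, $K = 2139$, $\rho = 0.2145$,
$\delta = 0.5115$/day, $\gamma = 0.001$/day. The burst size is never given
directly; scenarios fix the basic reproduction number

$$R_0 = \frac{\beta K b}{\beta K + \gamma}$$

and `burst_size_for_r0()` inverts this for $b$. $R_0$ is the expected
number of new virions produced by one virion introduced into a tumor at
carrying capacity, and $R_0 = 1$ is the sharp threshold of the model.

## Equilibria and their stability

Three steady states exist: extinction $E_0 = (0,0,0)$ (complete tumor
eradication — always unstable, since a tumor-free state regrows), therapy
failure $E_1 = (K, 0, 0)$, and, exactly when $R_0 > 1$, the endemic
coexistence state $E^*$ with $x^* = \gamma/(\beta(b-1))$ and closed forms
for $y^*, v^*$ (see `equilibria()`). Every returned equilibrium is verified
against the steady-state equations to a residual below $10^{-9}$, and the
closed form is additionally cross-checked in the test suite against an
independent multi-start Newton root-find of the right-hand side.

At $E_1$ with all delays zero the spectrum is explicit
(`dfe_spectrum()`): $\lambda_1 = -r$ and $\lambda_{2,3} =
(-(\gamma+\beta K+\delta) \mp \sqrt{\Delta})/2$, with the leading
eigenvalue changing sign exactly at $R_0 = 1$. For arbitrary delays, a
purely imaginary characteristic root at $E_1$ would have to satisfy a
quartic in $\omega$ whose coefficients ($a_1$, the delay-dependent
cross-term $a_2(\omega) \ge 0$, and $a_3 \propto 1 - R_0^2$) are all
positive when $R_0 < 1$ — so no crossing exists for any delays, and
stability of $E_1$ is delay-independent (`dfe_delay_robustness()`). With
$R_0 < 1$, $E_1$ is in fact globally stable; the package certifies this
trajectory-wise through the Lyapunov functional below rather than by formal
proof.

At $E^*$ the characteristic equation is transcendental:

$$\lambda^3 + A\lambda^2 + \tilde B \lambda + C +
\sum_i \beta_i e^{-\lambda\tau_i} (D\lambda + E) = 0 .$$

The coefficients are *derived from the determinant expansion* of the
delayed Jacobian, not transcribed: `characteristic_value()` evaluates
$\det(J(\lambda)-\lambda I)$ exactly, and the test suite asserts that the
coefficient form agrees with it at random complex $\lambda$ to $10^{-9}$
relative. This derivation route was chosen deliberately because transcribed
textbook coefficient strings are error-prone; the derived $\tilde B$ is
$a(\delta+e_1)+\delta e_1-\beta^2 x^* v^*$ with $a = r x^*/K$, $e_1 =
\gamma + \beta x^*$.

With all delays zero the equation collapses to a cubic, and
`endemic_tau0_stability()` applies the Routh–Hurwitz criterion ($b_1, b_2,
b_3, H_2 = b_1 b_2 - b_3$ all positive $\iff$ stable). Any quantity within
$10^{-9}$ of zero yields the verdict `"marginal"` rather than a sign call.
For nonzero delays, `endemic_delay_condition()` evaluates the crossing
polynomial coefficients $K_1$, $K_2(\omega)$, $K_3(\omega)$ (frequency
dependent when several distinct delays interact); positivity of all three
for every frequency rules out imaginary-axis crossings and makes the
zero-delay verdict delay-independent.

### Grid semantics for the certificates

The "for all $\omega$" quantifier in both certificates is implemented as a
check on a finite grid — by default $10^4$ points on $(0, \omega_{max}]$,
with $\omega_{max} = 10\max(1, A, \sqrt{|K_1|})$ at $E^*$ and the analogous
quartic scale $10\max(1, \sqrt{a_1})$ at $E_1$. This is an explicit
sufficient-check semantics, recorded in the certificate object; the grid
range and size are overridable. For the $E_1$ certificate the grid is
actually immaterial ($a_2 \ge 0$ identically); it is evaluated and reported
for transparency.

## Hopf bifurcation in the single-delay case

With exactly one positive delay $\tau_1$ (plus optionally an instantaneous
term $\beta_0$), a purely imaginary root $i\omega$ requires
$h(\omega^2) = 0$ for the cubic $h(u) = u^3 + K_1 u^2 + K_2 u + K_3$. The
package takes $\omega_0$ as the square root of the *largest* positive real
root (all positive roots and their principal delays are reported). When
$K_3 < 0$ a positive root always exists. The analysis is restricted to one
positive delay; multi-delay critical surfaces are out of scope.

Two numerical choices matter here:

* **Quadrant recovery.** The crossing condition gives a linear system for
  $\cos\omega_0\tau$ and $\sin\omega_0\tau$; solving for both and using the
  two-argument angle $\theta = \mathrm{atan2}(\sin, \cos) \in [0, 2\pi)$
  removes the sign ambiguity an arccos alone would leave. The residual
  $\cos^2+\sin^2-1$ must vanish to $10^{-6}$ or the analysis aborts.
* **Branch enumeration.** Candidate delays are $\tau_j = (\theta + 2\pi
  j)/\omega_0$ for $j = 0, 1, 2, \dots$; the critical delay $\tau^*$ is the
  smallest positive candidate, which for the benchmark scenario lies on the
  principal ($j = 0$) branch.

Transversality — whether the eigenvalue pair genuinely crosses into the
right half-plane as $\tau$ grows through $\tau^*$ — is computed as
$\mathrm{sign}\,h'(\omega_0^2)$ and *always cross-validated* by numerically
continuing the characteristic root across $\tau^*$ with Newton steps on the
exact transcendental function: the tracked real part must change sign
consistently, and a disagreement aborts rather than returning a guess. A
repeated root of $h$ ($h'(\omega_0^2) \approx 0$) is flagged degenerate
with sign 0.

```{r hopf-example, eval = FALSE}
p <- virotherapy_params(
  r0 = 1.5,
  transmission = data.frame(beta = c(1e-5, 1e-4), tau = c(0, 7)))
hopf_analysis(p)
#> omega0 = 0.157283 rad/day, tau* = 8.83645 days, transversality +1
```

## Integrating the delay system

`simulate_virotherapy()` adopts the **constant-history** reading of point
initial conditions: the state on $[-\tau_{max}, 0]$ equals $(x_0, y_0,
v_0)$. This is the standard interpretation when only an initial point is
stated, and it is recorded prominently because it changes transients
(though not equilibria or any stability quantity). Integration uses
`deSolve::dede` — an adaptive multistep solver with dense interpolation of
the computed past — with defaults `rel_tol = 1e-8`, `abs_tol = 1e-10`. The
first-generation derivative discontinuities at $t = \tau_1, \dots, \tau_n$
are forced onto the output mesh; deeper generations are left to adaptive
step control, which is adequate at the smoothness the analyses need (the
test suite verifies that halving tolerances moves terminal states by far
less than ten times the tighter tolerance).

Two failure modes abort loudly instead of being corrected silently:
negative excursions beyond `abs_tol` (no clamping — negativity signals
solver misconfiguration) and blow-up past $10^6 K$. Dense evaluation at
arbitrary times uses cubic splines on the storage grid (default spacing
0.25 days, which resolves the $\approx$ 40-day cycles of the oscillatory
scenarios by two orders of magnitude); evaluation outside the span is an
error.

## Trajectory diagnostics

`lyapunov_value()` evaluates the functional
$V(t) = b y(t) + v(t) + b\sum_i \beta_i \int_{t-\tau_i}^t x v\,ds$
by adaptive quadrature on the dense trajectory, its derivative by central
differences (step $10^{-3}$), and the applicable algebraic decay bound:
$\dot V \le b\beta K(1-1/R_0)v$ when $b \ge 1$, and $\dot V \le -\gamma v$
when $b < 1$ (the carrying-capacity bound needs $b \ge 1$; subthreshold
scenarios here typically have $b < 1$). `lyapunov_monotone_check()` is
gated on $R_0 < 1$ — above threshold the theory makes no claim and the
verdict is "not applicable".

`eradication_time()` reports the first time the tumor load $x+y$ drops to
one cell (threshold 1 in the $10^6$ unit convention), by bisection on the
dense trajectory. `summarize_trajectory()` labels the attractor: an
equilibrium when the terminal state is within $10^{-3} K$ (max norm, a
scale-aware tolerance), a cycle when the last late-window peak-to-trough
amplitudes agree within 5%.

## Classifying dynamics around the critical delay

`classify_delay()` perturbs $E^*$ by a deterministic relative $10^{-2}$ —
small enough to stay near the linear regime that the Hopf analysis
describes, large enough to be resolved at the solver tolerances — and
integrates over 3000 days, discarding the first 20% as transient.
Amplitudes are measured **peak-to-trough about the equilibrium**: raw peak
values sit on top of $x^* \approx 18$ and would mask a decay that is large
relative to the oscillation but small relative to the offset.

* decay of at least 1% per cycle, monotonically → `"damped"`;
* last five amplitudes within 5% of each other → `"sustained"` (this
  includes trajectories that grew onto the limit cycle within the horizon);
* still growing at the horizon → `"growing-then-bounded"`;
* fewer than four peaks: `"damped"` if the deviation from $E^*$ has
  contracted by at least a factor of ten across the analysis window
  (oscillation died out entirely), otherwise `"inconclusive"`.

The 1%-per-cycle and 5% thresholds tie the verdicts to the local growth
rate: within a few percent of $\tau^*$ the per-cycle change passes through
1, so the damped/sustained flip localizes the bifurcation to a few percent
in $\tau$, which is exactly what `find_hopf_transition()` exploits by
bisection. Very close to $\tau^*$ the horizon matters: a trajectory just
above threshold may still be growing after 3000 days and classify as
growing-then-bounded rather than sustained.

## Preset scenarios and synthetic fixtures

The five presets cover the model's qualitative regimes: subthreshold
failure (`fig3`, $R_0 = 0.7$, four delays), endemic convergence (`fig4`,
$R_0 = 1.5$, same delays), and the single-delay Hopf family (`fig5`–`fig7`
with $\tau = 7$, $8.8368$, $10$). The `fig6` preset stores the *printed*
critical delay as a fixed, citable input; `hopf_analysis()` reports the
internally computed $\tau^*$ and the `hopf` CLI subcommand reports both and
their discrepancy, separating reproduction of a published value from
internal consistency.

`random_scenario()` generates seeded fixtures for property tests: rates
jittered $\pm 20\%$ around the reference values, log-uniform transmission
rates, uniform delays on $[0.1, 10]$, and a burst size solved for a target
$R_0$ drawn from a requested range — so fixtures can be placed on either
side of the threshold by construction. The generator emulates the
*structure* of the benchmark parameterization, not biological variability:
it makes no claim about realistic joint distributions of rates, uses only
constant histories, and stays in the deterministic, well-mixed,
immune-free setting of the model. Passing property tests therefore
demonstrate internal mathematical consistency (threshold behavior, residual
identities, Lyapunov monotonicity) across the parameter region around the
reference values, not robustness on real tumor data.

Problem sizes used in the shipped tests were chosen to exercise each
property at meaningful scale while keeping the suite quick: 100 random
fixtures for threshold/residual properties, 20 subthreshold fixtures (300-
or 250-day horizons, 20–25 point Lyapunov grids) for monotonicity, full
2000/3000-day horizons for the five presets.

## Known limitations

* The Hopf machinery handles exactly one positive delay; the multi-delay
  certificates bound crossings but do not locate critical surfaces.
* The direction of the bifurcation and the stability of the emitted
  periodic orbit are not computed (no center-manifold reduction);
  "sustained" classifications are simulation-based.
* Certificates quantified over frequency are grid-checked, not proved.
* Constant history is the only supported history class; state-dependent or
  distributed delays are out of scope.
* No spatial structure, stochasticity, or immune response — the model is a
  well-mixed deterministic caricature whose value is its analyzable
  threshold and bifurcation structure.
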