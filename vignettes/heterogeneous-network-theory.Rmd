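---
title: "Order-chaos transitions in heterogeneous random rate networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Order-chaos transitions in heterogeneous random rate networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(hetnetdyn)
```

## The model

Each neuron carries two variables: an activity $x_i$ and a slow auxiliary
variable $a_i$ fed back into the activity,

$$\dot x_i = -x_i + a_i + \sum_{j=1}^N J_{ij}\,\phi(x_j) + I_i(t), \qquad
  \dot a_i = -\gamma_i a_i + \beta_i x_i,$$

with $\phi = \tanh$. The intrinsic pair $(\gamma_i, \beta_i)$ spans three
single-cell phenotypes:

* **normal** — large $\gamma$: the auxiliary variable barely charges, and
  activity decays promptly when input stops;
* **graded persistent activity (GPA)** — $\gamma$ slightly above
  $\beta > 0$: the near-marginal slow mode (rate
  $\approx -(\gamma-\beta)/(1+\gamma)$, e.g. $-0.00665$ for
  $\gamma = 0.51,\ \beta = 0.5$) holds a plateau for hundreds of time units
  and steps it up or down with depolarizing or hyperpolarizing pulses, as
  observed in entorhinal cortex neurons;
* **adaptation** — $\beta < 0$: negative feedback, the regime studied in
  earlier work on heterogeneous adaptation.

Single-neuron non-divergence requires $\gamma_i > \beta_i$; the constructors
enforce it and an `allow_unstable` flag exists only for deliberate
experimentation. Couplings are quenched disorder:
$J_{ij} \sim \mathcal N(0, g^2/N)$ i.i.d. off the diagonal, $J_{ii} = 0$.

```{r model}
net <- build_network(dist_two_point(p = 0.5, low = 1, high = 10),
                     dist_constant(0.5), N = 300, g = 0.5, seed = 1)
net
```

## The transition-point theory

In the large-$N$ limit the recurrent input acts as a self-consistent
Gaussian field, and each neuron filters it linearly near the quiescent
state. The squared-magnitude frequency response of the two-variable neuron
is the transfer gain

$$G(\omega;\gamma,\beta) =
  \frac{\omega^2+\gamma^2}{\omega^4+(\gamma^2+2\beta+1)\,\omega^2+(\gamma-\beta)^2},$$

which links the activity power spectral density of neuron $i$ to the
population-mean spectrum of $\phi(x)$:
$S_{x_i}(\omega) = g^2\, G(\omega;\gamma_i,\beta_i)\, \bar S_\phi(\omega)$.
Averaging over neurons is legitimate *in frequency space* even when the
intrinsic parameters differ — this is the step that fails if one instead
tries to absorb intrinsic heterogeneity into an extra Gaussian mean field —
and yields $\bar S_x = g^2\,\bar G(\omega)\,\bar S_\phi$ with
$\bar G(\omega) = \langle G(\omega;\gamma,\beta)\rangle_{\gamma,\beta}$.
Because $|\phi(x)| \le |x|$ forces $\int \bar S_\phi \le \int \bar S_x$, a
nonzero spectrum is only self-consistent when $g^2 \max_\omega \bar
G(\omega) \ge 1$; the critical coupling is

$$g_c = \Big(\max_\omega \bar G(\omega)\Big)^{-1/2}.$$

For $\gamma > \beta \ge 0$ on the whole support the maximum sits at
$\omega = 0$ and, for a two-point decay-rate distribution
($\gamma_{\rm low}$ w.p. $p$, else $\gamma_{\rm high}$, constant $\beta$),

$$g_c = \left(p\,\tfrac{\gamma_{\rm low}^2}{(\gamma_{\rm low}-\beta)^2} +
 (1-p)\,\tfrac{\gamma_{\rm high}^2}{(\gamma_{\rm high}-\beta)^2}\right)^{-1/2},$$

strictly decreasing in $p$: adding slow GPA neurons always enlarges the
dynamic regime. At $p = 0$ it reduces to $1-\beta/\gamma_{\rm high}$ and to
the classical $g_c = 1$ as $\gamma_{\rm high}\to\infty$ or $\beta\to 0$.

```{r theory}
tidy(critical_coupling_two_point(0.5, 1, 10, 0.5))
# continuous feedback heterogeneity: gamma = 3, beta ~ U[0, 2.9]
tidy(critical_coupling(dist_constant(3), dist_uniform(0, 2.9)))
```

With adaptation ($\beta < 0$) the gain is maximised at a *nonzero*
frequency, so `critical_coupling()` always scans $\{0\} \cup$ a log-spaced
grid $\omega \in [10^{-3}, 10^3]$ (200 points) refined by `optimize()`
around the best candidate, ties broken toward smaller $\omega$; the
self-consistency $g_c^2 \bar G(\omega^\*) = 1$ is exact by construction.
Expectations over continuous parameter distributions use 64-node
Gauss-Legendre quadrature per dimension (tensor product for joint
heterogeneity); doubling the node count changes the uniform-feedback
$g_c$ by less than $10^{-10}$, and the tests assert agreement with
Monte-Carlo averages and with the closed forms above.

`naive_critical_coupling()` implements the earlier Gaussian-mean-field
approximation for adaptation heterogeneity
$\beta \sim \mathcal N(\mu_\beta, \sigma_\beta^2)$,

$$G_\beta(\omega) = \frac{G(\omega;\gamma,\mu_\beta)}
 {1 - \tfrac{\sigma_\beta^2}{\gamma^2+\omega^2} G(\omega;\gamma,\mu_\beta)},
 \qquad \hat g_c = \big(\max_\omega G_\beta\big)^{-1/2}.$$

Its prediction *decreases* with $\sigma_\beta$, while the averaged-gain
$g_c$ (with a truncated-normal $\beta$ kept negative) *increases* — the two
theories disagree in direction, and the simulated transition follows the
averaged-gain one:

```{r fig7}
sapply(c(0.2, 0.4, 0.6), function(s) c(
  gc   = critical_coupling(dist_constant(0.5),
                           dist_truncnorm(-0.5, s, -0.5 - 4*s, -1e-3))$gc,
  ghat = naive_critical_coupling(0.5, -0.5, s)$gc))
```

When $\sigma_\beta$ grows large enough that the denominator of
$G_\beta$ crosses zero, the naive theory has no prediction; the package
raises a structured error rather than extrapolating, since that breakdown
region is uncharacterised.

## Numerical diagnostics

**Integration.** Fixed-step explicit Euler with `dt = 0.02` (Euler-Maruyama
under white-noise drive, per-step increment $w\,u_n$ with
$u_n \sim \mathcal N(0, \sigma_{in}^2\,dt)$). A fixed-step scheme keeps the
noise-path construction exact and makes runs bit-reproducible from the
seed; adaptive steppers would break both. Convergence is first order
(verified by `dt`-halving against the matrix-exponential solution of the
uncoupled linear neuron). Any state beyond $10^6$ aborts with a structured
divergence error carrying the first bad step.

**Order parameter.** The transition is located numerically by
$\max_\omega \bar S_x(\omega)$ from a free-running simulation
($x(0) \sim \mathcal N(0,1)$, $a(0)=0$ — the initial condition is a design
choice; published work rarely states one). Two estimator details matter and
are deliberate:

1. *The raw, not mean-removed, spectrum is used.* At moderate $N$ these
   positive-feedback networks often escape the origin onto *frozen nonzero*
   states whose power is purely at zero frequency; a demeaned spectrum is
   blind to them and would misplace the boundary. The general-purpose
   `estimate_psd()` demeans by default (fluctuation spectra for
   autocorrelation and transfer-gain checks); `max_power_order_parameter()`
   sets `demean = FALSE`.
2. *Classification requires stationarity.* Slightly below $g_c$ the decay
   to the origin is slow, and residual transient power sits many orders of
   magnitude above any numerical floor. A grid cell is classified dynamic
   only when the final-half order parameter both exceeds the silent
   threshold (5x the max PSD of a matched $g=0$ run's final quarter, floored
   at $10^{-12}$) and is at least $0.2\times$ the first-half value. Decaying
   transients keep shrinking across the window; chaos and frozen states do
   not. The factor 0.2 only needs to separate "orders of magnitude decay"
   from "order one": anywhere in $[0.05, 0.5]$ behaves identically away
   from a narrow ambiguous band $|g-g_c|/g_c \lesssim 0.03$.

Spectra are Welch estimates: Hann window, segments of $2^{10}$ samples, 50%
overlap, all recorded in the result. Runs within 10% of the analytic $g_c$
automatically double their duration. With these choices a $6\times 12$
phase diagram at $N = 500$ ($\gamma_{\rm low}=1$, $\gamma_{\rm high}=5$,
$\beta = 0.5$; 150 post-transient time units per cell) recovers the
closed-form boundary within 7% at every GPA fraction — the acceptance suite
asserts 15%, allowing finite-size scatter across seeds.

**Linear stability.** `jacobian_origin()` builds the $2N\times 2N$ block
matrix $\bigl(\begin{smallmatrix} J-I & I \\ \mathrm{diag}(\beta) &
-\mathrm{diag}(\gamma)\end{smallmatrix}\bigr)$ (tanh slope 1 at the
origin); `eigenspectrum()` takes its dense spectrum (guarded at
$N \le 5000$). The spectral abscissa changes sign at the same coupling the
order parameter turns on.

**Maximum Lyapunov exponent.** Classical tangent-vector estimation: the
exact Jacobian along the trajectory is applied to a tangent vector,
renormalised every 1.0 time units, log-growth averaged per unit time, over
(by default) ten random initial conditions. The tangent is co-evolved and
renormalised *during the transient* with its growth discarded, so
accumulation starts from the aligned leading direction — without that
warm-up the estimate carries an $O(\log c / T)$ bias from the initial
misalignment, visible against the linear-network oracle where
$\lambda_{\max}$ must equal the spectral abscissa (the suite checks
agreement to $10^{-3}$). Near $g_c$ at a few hundred neurons the leading
exponent of the *attractor* is close to zero (weakly chaotic, quasiperiodic
or frozen depending on the realisation), so its sign stabilises only well
above the transition; the zero crossing of the mean curve, found by linear
interpolation between bracketing grid points, approaches the analytic $g_c$
from above as $N$ grows — the finite-size trend the acceptance suite tests
between $N = 100$ and $N = 1000$.

**Memory capacity.** The network is driven by one shared white-noise signal
through fixed $\mathcal N(0,1)$ input weights; for each delay $k$ (multiples
of 0.2 time units up to 20) a ridge readout ($10^{-6}\times$
trace-normalised penalty) is fit from $x(t)$ to $u(t-k)$ on the first half
of the drive and scored as the squared Pearson correlation on the held-out
second half; `mc_total` sums over delays. The readout is cross-checked in
the tests against an independent QR solution of the augmented least-squares
system, and a synthetic delay-line state scores 1 on represented delays and
~0 beyond. Because the slow neurons ($\beta$ near $\gamma$) have
correlation times of tens of time units, short drives overfit: drives of
1200+ time units (about $3\times 10^4$ training samples) are needed before
the capacity curve is smooth in $g$. At $N = 300$, $\gamma = 3$,
$\beta \sim U[0, 2.9]$, $\sigma_{in} = 0.1$ the curve peaks below
$g_c = 0.183$ and collapses in the chaotic regime — the edge-of-chaos
picture, at reduced scale.

## What the synthetic conditions do and do not show

All inputs are generated by the package itself: Gaussian couplings,
two-point / uniform / truncated-normal intrinsic parameters, pulse trains
and shared white noise. Tests at $N = 300$-$1000$ and a few hundred time
units establish the *structure* of the theory (boundary location and its
monotonicities, diagnostic concordance, capacity peak position) but not
published large-$N$ values: headline figures at $N = 3000$-$5000$ with long
runs are not bit-reproducible here, and all grid-based checks are
property-based with stated tolerances. Finite-size effects are real and
visible — the Lyapunov crossing sits above $g_c$ at small $N$, frozen
nonzero states replace chaos just above $g_c$ — and they are part of what
the diagnostics are designed to tolerate, not artifacts to hide. Biological
realism (spiking, delays, sign-constrained synapses, learned weights) is
out of scope.

## Reproducibility choices

Every stochastic object is a pure function of a master seed split into
named streams (`gamma`, `beta`, `coupling`, `init`, `input`, one per
grid cell), so enlarging one draw never perturbs another; model metadata
records the streams. Phase diagrams draw a *fresh* coupling matrix per grid
cell, and the Lyapunov curve one matrix per $(g, \text{seed})$ — published
figures do not state either convention, so the package records its own in
the outputs. Truncated-normal sampling uses the inverse CDF on the
truncated range (no rejection loop). Trajectory containers persist as a
directory of `header.json` (full provenance) plus an RDS payload;
experiment drivers write their resolved config next to every artifact.
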