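---
title: "Methods: multi-ligand concentration sensing by a single receptor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-ligand concentration sensing by a single receptor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ligandsense)
```

# The generative model

A single receptor sits in a well-mixed bath of $m$ ligand species with
concentrations $c_i$, diffusion-limited binding rate constants $k_i$, and
unbinding rates $r_i$. The receptor alternates between unbound and bound
states:

- an **unbound interval** $\tau^u$ is exponential with rate
  $\sum_i k_i c_i$ (the first ligand to arrive binds);
- the **identity** of the binding ligand is categorical with probabilities
  $k_i c_i / \sum_j k_j c_j$;
- the following **bound interval** $\tau^b$ is exponential with that
  species' unbinding rate $r_i$.

Marginalising the (unobservable) ligand identity, the bound-interval density
is the mixture
$$
D(\mathbf{c}, \tau) \;=\; \sum_i k_i c_i\, r_i e^{-r_i \tau},
$$
up to the normalisation $\sum_i k_i c_i$. A trace of $n$ binding events
therefore has log-likelihood (dropping $\mathbf{c}$-independent terms)
$$
\log L(\mathbf{c})
  \;=\; -\,T^u \sum_i k_i c_i \;+\; \sum_{j=1}^{n} \log D(\mathbf{c}, \tau^b_j),
$$
where $T^u = \sum_j \tau^u_j$ is the total unbound time. Everything in the
package follows from this expression.

**Assumptions.** Perfect instantaneous readout of binary occupancy (every
binding and unbinding event is observed with exact interval durations); a
memoryless, well-mixed ligand bath (no rebinding correlations, no ligand
depletion); a single receptor; two-state receptor kinetics (no internal
states except where the proofreading delay models them implicitly).

**Exact simulation.** For this two-state system, exact stochastic simulation
of the continuous-time Markov process reduces to direct sequential sampling
of the three primitives above; `sample_trace()` implements it that way with
vectorised draws, which is mathematically identical to an event-driven
Gillespie simulation and much faster. Traces are parameterised by the number
of binding events `n_events`, with total time derived; `sample_trace_duration()`
provides a fixed-duration variant in which the final unbound interval wraps
around: the $n$-th unbound interval is the sum of the trailing and leading
unbound segments, $\tau^u_n = t^b_1 + (T - t^u_n)$.

**Standard normalisation.** Throughout the package's defaults and studies the
non-cognate unbinding rate sets the time unit ($r_{nc} = 1$), both binding
rate constants are diffusion-limited and equal ($k_c = k_{nc} = 1$), and the
total concentration sets the concentration unit ($c_c + c_{nc} = 1$). Only
the ratios $r_c/r_{nc}$ and $c_c/c_{nc}$ matter for the scaled results.

# Exact maximum-likelihood inference

For two species, setting $\partial \log L / \partial c_i = 0$ and combining
the two stationarity conditions yields the exact identity at any interior
optimum:
$$
k_c \hat c_c + k_{nc} \hat c_{nc} \;=\; \frac{n}{T^u}.
$$
The estimated **total on-rate** is fixed by the data alone. `solve_ml()`
exploits this to reduce the 2-D optimisation to one dimension: writing the
cognate share of the total on-rate as $f \in [0, 1]$, the profile
log-likelihood is
$$
g(f) = \sum_j \log\!\big(f\, a_j + (1 - f)\, b_j\big), \qquad
a_j = r_c e^{-r_c \tau^b_j},\; b_j = r_{nc} e^{-r_{nc} \tau^b_j}.
$$
Each term is the log of a linear function of $f$, so $g$ is concave and
$g'(f) = \sum_j (a_j - b_j) / (f a_j + (1-f) b_j)$ is monotone decreasing;
`stats::uniroot()` on $g'$ with sign checks at the endpoints finds the unique
interior optimum or detects a boundary optimum ($f = 0$ or $f = 1$, i.e. one
estimated concentration is zero). No multi-start heuristics are needed.

**Error bars.** The analytic Hessian of the log-likelihood is
$$
H_{\alpha\beta} \;=\; -\sum_j
  \frac{k_\alpha k_\beta\, r_\alpha r_\beta\,
        e^{-(r_\alpha + r_\beta)\tau^b_j}}{D(\mathbf{c}, \tau^b_j)^2},
$$
and $-H^{-1}$ evaluated at the ML point is the Cramér–Rao covariance of the
estimates. The package reports the **scaled error**
$E = n\, \sigma^2(\hat c)/c^2$ (squared coefficient of variation times the
number of events; $E = 1$ is the accuracy of a receptor sensing a single
ligand alone) and the estimate correlation $\rho$ from the same matrix.

**Numerical choices.**

- $\log D$ is evaluated with a log-sum-exp construction so that traces with
  $r \tau^b \gtrsim 700$ do not underflow.
- At boundary optima one concentration is exactly zero and the Hessian of the
  interior parameterisation is not defined there; `solve_ml()` flags such
  fits and returns `NA` covariance. `error_metrics()` excludes boundary fits
  from the inverse-Hessian average and reports how many were excluded. (In
  the extreme single-ligand regime used by the package's headline results, a
  substantial fraction of fits sits at the boundary; excluding them is what
  makes the Hessian-based $E$ well defined.)
- Whether to evaluate the Hessian at the ML point or at the true
  concentrations is a genuine design choice; the package evaluates it **at
  the ML point** (the observable quantity), with the ensemble-variance
  definition of $E$ computed alongside as a cross-check. The two agree within
  sampling error in all regimes where boundary fits are rare.

# The long-event threshold estimator

A cell cannot run `uniroot`. A biochemically plausible strategy is to count
the $n_l$ bound intervals at least as long as a cutoff $T^c$ (ties count as
long), attribute them all to the cognate ligand, and correct for the missed
short cognate events:
$$
\hat c^a_c = \frac{n_l\, e^{r_c T^c}}{k_c T^u}, \qquad
\hat c^a_{nc} = \frac{n - n_l\, e^{r_c T^c}}{k_{nc} T^u}.
$$
The pair satisfies the same total-on-rate identity as ML, exactly and by
construction. The non-cognate estimate can be negative when
$n_l e^{r_c T^c} > n$; it is returned unclipped with a flag (clipping is
available but would break the bias/variance algebra below, so summary
statistics use unclipped values).

In the validity regime $r_c \ll r_{nc}$ and $r_{nc} T^c \gtrsim 3$ (rare long
non-cognate events), with $\langle T^u\rangle = n / (k_c c_c + k_{nc} c_{nc})$:
$$
\langle \hat c^a_c \rangle = c_c +
  \frac{k_{nc} c_{nc}}{k_c} e^{-(r_{nc} - r_c) T^c}, \qquad
\sigma^2(\hat c^a_c) = \langle \hat c^a_c \rangle
  \left(c_c + \frac{k_{nc} c_{nc}}{k_c}\right) \frac{e^{r_c T^c}}{n},
$$
the bias from long non-cognate events and the variance from the Poisson
statistics of the (rare) long-event count $n_l$, inflated by the rescaling.
The loss is $L = \sigma^2 + \text{bias}^2$. The non-cognate moments follow
from the exact linear constraint:
$\text{bias}_{nc} = -(k_c/k_{nc})\,\text{bias}_c$ and
$\sigma^2_{nc} = (k_c/k_{nc})^2 \sigma^2_c$.

Minimising $L_c$ over $T^c$ (to leading order, with the true $c_c$ in the
variance) gives the closed-form **optimal cutoff**
$$
T^{c*} = \frac{\log\!\big[\,2 T^u (r_{nc}/r_c - 1)\,
  k_{nc}^2 c_{nc}^2 / (k_c c_c)\,\big]}{2 r_{nc} - r_c},
$$
which depends only logarithmically on the unknown concentrations. The fixed
**reference cutoff** $T_0$ evaluates $T^{c*}$ at the reference point
$k_c c_c = k_{nc} c_{nc} = 1/2$ with $\langle T^u \rangle = n$, simplifying
to $T_0 = \log\!\big(n\,(r_{nc}/r_c - 1)\big)/(2 r_{nc} - r_c)$; a sensing
system can commit to it in advance without knowing the concentrations, at a
modest loss relative to exact ML (the package's t1/t2 headline ratios,
roughly 1.2–1.5 depending on scale).

# Kinetic-proofreading readout

The threshold estimator maps onto biochemistry via kinetic proofreading: a
messenger A produced (at rate $k_A$, degraded at $r_A$) only during bindings
longer than $T^c$, and a messenger B produced during all bindings. At
mean-field steady state, with occupancy weights $w_i = k_i c_i / r_i$ and
$\text{denom} = 1 + \sum_i w_i$:
$$
\bar A = \frac{k_A}{r_A}\,
  \frac{\sum_i w_i\, e^{-r_i T^c}}{\text{denom}}, \qquad
\bar B = \frac{k_B}{r_B}\, \frac{\sum_i w_i}{\text{denom}}.
$$
`invert_exact()` recovers the concentrations from $(\bar A, \bar B)$ by first
inverting the occupancy: $q = \bar B / (k_B/r_B - \bar B) = \sum_i w_i$, so
$1 + q$ is the denominator; then the A branch (attributing all long events to
the cognate species) yields $\hat c_c$, and $q$ yields $\hat c_{nc}$. Under
the all-long-events-are-cognate idealisation this round trip is **exact**; with
the full non-cognate contribution the cognate recovery inherits a positive
bias with the same $e^{-(r_{nc}-r_c)T^c}$ decay as the threshold estimator.
A saturated readout ($\bar B \ge k_B/r_B$) is an explicit error.
`invert_linear()` is the small-occupancy linearisation
$\hat c^{KPR}_c = \bar A\, e^{r_c T^c} r_c r_A / (k_c k_A)$, accurate to first
order in the occupancy $\epsilon = \bar B/(k_B/r_B)$.

A stochastic per-event cutoff with mean $\bar T^c$ and variance
$\sigma^2_{T^c}$ renormalises the effective cutoff:
$$
T^c_{\text{eff}} = \bar T^c - \tfrac{1}{2} r_c\, \sigma^2_{T^c}
$$
(second-order expansion of $\langle e^{-r\,T^c}\rangle$, accurate for
$r_c \sigma_{T^c} \lesssim 1$). The A-readout's relative variance at steady
state is
$$
\frac{\sigma^2_A}{\bar A^2} \;=\;
  \frac{\text{denom}\; e^{\,r_c T^c - \frac{1}{2} r_c^2 \sigma^2_{T^c}}}
       {k_c c_c\, (1/r_c + 1/r_A)},
$$
which shares the $e^{r_c T^c}$ scaling of the threshold estimator's variance:
the messenger integrates over roughly $n \sim T/(1/r_c + 1/r_A)$ effective
events. `simulate_messengers()` provides a trace-driven birth–death simulator
(pure-R Gillespie over the gated production process) used to validate these
closed forms in the tests.

# Activator–inhibitor sequestration

An incoherent-feedforward alternative: the receptor drives a proofread
activator A (gain $k_A$, delay $T^c$) and an unproofread inhibitor I (gain
$k_I$), which bind and inactivate each other at rate $r_{AI}$:
$$
\dot A = \beta_A - r_A A - r_{AI} A I, \qquad
\dot I = \beta_I - r_I I - r_{AI} A I .
$$
With the **matched gain** $k_A = k_I e^{r_{nc} T^c}$, the drive difference
$\beta_A - \beta_I$ has a numerator independent of $c_{nc}$:
$(k_c c_c / r_c)(e^{(r_{nc}-r_c)T^c} - 1)\,k_I$, positive exactly when the
cognate ligand is present. Eliminating $I = \beta_I / (r_I + r_{AI} A)$ at
steady state gives the quadratic
$$
A^2 + \left(\frac{r_I}{r_{AI}} + \frac{\beta_I - \beta_A}{r_A}\right) A
  - \frac{\beta_A\, r_I}{r_{AI}\, r_A} = 0,
$$
whose positive root `steady_state()` evaluates in the cancellation-free form
$A = 2q/(b + \sqrt{b^2 + 4q})$ when $b \ge 0$. The elimination is exact for
$r_A \ne r_I$ too, and both stationarity residuals are returned so callers can
verify the solution to $< 10^{-9}$ relative. In the sequestration-dominated
regime ($r_A \ll r_{AI} A_{ss}$; a warning is issued outside it) this yields
**antagonism**: at fixed $c_c > 0$ the steady-state activator level strictly
decreases with $c_{nc}$, while with $c_c = 0$ the non-cognate ligand alone is
a weak agonist (increasing $A_{ss}$). `integrate_dynamics()` (adaptive
`deSolve::ode`, relative tolerance $10^{-9}$) confirms the closed form and
provides transients.

# Simulation studies and reproducibility

`sweep_config()` fixes the study design: grids over $r_c/r_{nc}$ and
$c_c/c_{nc}$ under the standard normalisation, `n_events` per trace,
`n_replicates` traces per grid point, and a single integer `master_seed`.
Per-replicate seeds are drawn once from the master seed
(`sample.int(.Machine$integer.max, n_replicates)` after `set.seed(master)`),
so every sweep is bit-for-bit reproducible and the two estimators are always
**paired** on identical traces. `run_ml_surface()` tabulates
$E_c, E_{nc}, \rho$ (Hessian-based, with the ensemble definition alongside);
`run_approx_comparison()` additionally computes the threshold estimates at the
fixed cutoff $T_0$ (evaluated per rate ratio) and the empirical losses
$L = \text{population variance} + \text{bias}^2$, reporting the ratios
$L/\sigma^2_{ML}$. `write_sweep_report()` embeds the full configuration as
provenance so identical configs reproduce artifacts exactly.

**Problem sizes.** The package's default study scale — 500 replicates of
3,000-event traces (300 × 10,000 for the near-degenerate regime) — was chosen
so the full acceptance suite runs in minutes on one CPU. All headline
quantities are ratios or means that are converged at this scale, with one
caveat: $T_0$ grows logarithmically with $n$, so the threshold-vs-ML loss
ratios drift mildly with trace length (the cognate ratio is ≈ 1.3 at 3,000
events and rises toward ≈ 1.4 at 30,000). A larger-scale run is a
configuration change, not a code change.

# Limitations

- Readout of occupancy is assumed perfect; measurement noise on interval
  durations is out of scope.
- No spatial or diffusive transport, receptor internalisation, or multiple
  receptors; cooperative and multi-receptor pooling effects are not modelled.
- The analytic threshold-estimator moments hold in the rare-long-event regime
  ($r_c/r_{nc} \lesssim 0.1$, $r_{nc} T^c \gtrsim 3$); `analytic_bias_mean()`
  warns outside it. At small $T^c$ or nearly degenerate rates only the exact
  ML machinery applies.
- The KPR mean-field formulas neglect receptor–messenger feedback; the
  birth–death simulator is the reference for finite-copy-number effects.
- The sequestration closed forms are quantitative only when sequestration
  dominates degradation; `steady_state()` warns when
  $r_A / (r_{AI} A_{ss}) > 0.1$.
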