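---
title: "Methods: the disinhibition-gated decision circuit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the disinhibition-gated decision circuit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(lddm)
```

## The model

Each choice alternative $i$ is represented by a three-unit column: an
excitatory unit $R_i$ receiving the value input $V_i$, a gain-control
(inhibitory) unit $G_i$, and a disinhibitory unit $D_i$:

$$
\tau_R \dot R_i = -R_i + \frac{V_i + \alpha R_i + B_R}{1 + G_i},\qquad
\tau_G \dot G_i = -G_i + \sum_j \omega_{ij} R_j + B_G - D_i,\qquad
\tau_D \dot D_i = -D_i + \beta R_i .
$$

$\alpha$ is recurrent self-excitation, $\omega$ the excitatory drive onto
the gain pool (local weight $w$ on the diagonal, lateral weight $v$
off-diagonal), $B_R$ and $B_G$ non-selective baselines, and $\beta$ the
gated coupling from each excitatory unit onto its own disinhibitory unit.
$\beta$ is the control knob of the whole architecture: task protocols
switch it between 0 (value representation) and its configured value
(choice).

With the gate off, the steady state is divisively normalized,
$R_i^\* = (V_i+B_R)\,/\,(1 + B_G - \alpha + \sum_j \omega_{ij} R_j^\*)$:
the only difference from the plain normalization circuit is the constant
$B_G-\alpha$, which is why those two constants are never separately
identifiable from steady-state data (the package parameterizes their
difference wherever equilibria are fit).

### Phase-plane structure

For two alternatives, eliminating $G$ and $D$ reduces the six equations to
the two excitatory nullclines
$(V_i+B_R)/R_i - (w-\beta)R_i - (1+B_G-\alpha) = v\,R_j$.
`find_equilibria()` locates their intersections by a log-spaced
sign-change scan refined with `uniroot()`, run from both nullclines'
perspectives because near the fold the mirror branch of an extreme
asymmetric equilibrium occupies a window narrower than any fixed grid.
Each intersection gets the analytic Jacobian (rows scaled by $1/\tau$ — a
true linearization; the scaling changes eigenvalue magnitudes, never
their signs) and a stability label with tolerance $10^{-6}$ on real
parts; zero-real-part cases are labelled *marginal* and resolved by the
trajectory probe in `attractor_type()`, since linearization cannot decide
the line-attractor case.

Under equal inputs, counting equilibria and their stabilities
distinguishes five territories in the $(\alpha,\beta)$ plane —
`dark_green` (1 stable: normalized coding), `blue` (2 stable + 1
unstable: bistable WTA), `green` (1 stable between 2 unstable: normalized
coding, a sliver near $\beta \gtrsim 1$, $\alpha < 1+B_G$ whose width
shrinks with the input scale), `yellow` (1 unstable: WTA), and `red` (no
equilibria: runaway WTA).  `classify_regime()` reports any tuple outside
this table as `"unclassified"` rather than forcing a label.  The default
search box is $[10^{-3}, 300]$ Hz with a 2000-point scan; regime
classification widens it to $10^4$ Hz because the symmetric equilibrium
diverges as $\beta \to 2$ at $\alpha=15$, $V=250$ (the critical weight the
acceptance script sweeps).  Boundary (clamped) states are not counted:
the analysis concerns the positive quadrant.

### Persistent activity

With inputs withdrawn the equilibrium condition is linear,
$(w-\beta)R_i^\* + v\sum_{j\ne i}R_j^\* = \alpha-1-B_G$, giving by case
analysis: no elevated activity when $\alpha \le 1+B_G$; a line attractor
with conserved total $(\alpha-1-B_G)/w$ when $v=w$ and $\beta=0$ (the
ratio of activities — hence of the preceding inputs — is preserved, since
symmetric gain keeps $G_1=G_2$ and then $\dot R_1/\dot R_2 = R_1/R_2$); a
point attractor at $(\alpha-1-B_G)/(w+(N-1)v)$ per unit when $v<w$; and
corner (winner-take-all) states when $v>w$ or $\beta>0$, with winner level
$(\alpha-1-B_G)/(w-\beta)$ for $0<\beta<w$ and unbounded growth for
$\beta>w$.  `attractor_type()` verifies these by integrating noiseless
probes from several activity ratios; the default probe set deliberately
omits the exactly symmetric start, which lies on the invariant manifold of
the interior point and would never leave it without noise.

## Numerical conventions

**Integration.** Fixed-step RK4 at `dt = 0.001` s (a 0.1-ms step is
available for convergence checks; halving the step moves noiseless
endpoints by less than $10^{-6}$ Hz in the tests).  Activities are clamped
at zero after each full step, not inside sub-stages — the simplest
contract consistent with non-negative rates.

**Noise.** Each unit receives an additive Ornstein–Uhlenbeck current
inside its $\tau$-scaled equation, updated by Euler–Maruyama
$n \leftarrow n(1-\mathrm{d}t/\tau_n) + \sigma\sqrt{\mathrm{d}t/\tau_n}\,\eta$
with $\tau_n = 2$ ms; the stationary SD approaches $\sigma/\sqrt 2$ as
$\mathrm{d}t/\tau_n \to 0$ (at the working step $\mathrm{d}t/\tau_n=0.5$
it is $\sigma/\sqrt{1.5}$, which is why the stationarity test integrates
at $\mathrm{d}t = 10^{-4}$).  An alternative convention in which the
activity itself carries the OU excursion was implemented and rejected:
at the behavioral best-fit $\sigma$ it drives threshold crossings within
milliseconds at every coherence, i.e. it is inconsistent with the
parameter values it would be used with.  Because the discretization fixes
the *meaning* of $\sigma$, all recovery experiments use the same
convention end-to-end; fitted $\sigma$ values are comparable only within
it.

**Trial initial conditions.** Reaction-time trials start the excitatory
units at 32 Hz with the gain units at their instantaneous equilibrium
$\sum_j \omega_{ij} R_j(0) + B_G$ ("matched"), $D=0$.  Starting $G$ at
zero is available (`g0_matched = FALSE`) but degenerate at realistic
input scales: with $S \approx 3000$ the un-normalized drive crosses the
70-Hz threshold within a few milliseconds at every coherence, collapsing
the RT distribution.  The 90-ms gap at stimulus onset carries zero input
with the gate off; a configurable fixed-viewing stage (`fixdur`) inserts
a stimulus-on, gate-off interval for fixed-duration paradigms.

**Decision readout.** First grid step at or above the 70-Hz threshold
(no interpolation), 30-ms motor delay, 5-s cutoff; non-crossing trials
are recorded as censored and enter the likelihood as censored mass, which
keeps the per-coherence probabilities normalized.

## Behavioral fitting

The QMLE objective bins reaction times at the nine empirical deciles per
(coherence × correctness) cell (type-7 quantiles; the choice of
interpolation rule is documented because nothing in the procedure pins it
down), computes predicted bin probabilities from Monte Carlo trials
jointly normalized over correct, error and censored mass — so choice
probability is fit implicitly — and floors probabilities at
$1/(10\,n_\text{reps})$.  At zero coherence, correctness is identified
with choosing option 1 in both the generator and the predictions; the two
cells are statistically exchangeable halves there.

The optimizer is a Latin-hypercube screen over the parameter box followed
by per-start Nelder-Mead, with the simulator re-seeded identically at
every evaluation (exact common random numbers — the objective is a
deterministic function of the parameters).  Each start runs a coarse
search at a quarter of the replications before a full-replication polish.
The likelihood surface has a genuine ridge along correlated
recurrence/time-constant directions (the recurrence and disinhibition
weights trade off against each other and against $\tau_R$), and plain
multi-start descent can settle on it; the fitting defaults therefore
stratify effort across the recurrence axis before releasing all
parameters (see `fit_model()`).

Desk-scale defaults are 1024 replications per coherence and 8 starts
(the published fits used 10,240 replications and 160 GPU starts; the
contract is the objective, not the optimizer).  Model comparison uses
$\mathrm{AIC} = 2k + 2\,\mathrm{nLL}$ with $k$ = 7 (circuit: $\alpha,
\beta, \sigma, S, \tau_R, \tau_G, \tau_D$, with $\omega=1$, $B_R=B_G=0$
fixed; $B_G$ is collinear with $\alpha$), 8 (reduced recurrent network)
or 4 (accumulator: leak, mutual inhibition, noise, threshold, with
$\tau = 100$ ms and $T_0 = 120$ ms fixed).  The reduced recurrent
network's rate threshold is fixed at 15 Hz, the canonical bound for that
model family; the accumulator's threshold is free because its activity
scale is arbitrary.

## Synthetic data: what it does and does not emulate

The trial generator's default truth is the published behavioral best fit
($\alpha=0$, $\beta=1.434$, $\sigma=25.36$, $S=3251$,
$\tau_R=.1853$, $\tau_G=.2244$, $\tau_D=.3231$), six coherences
0–51.2%.  Under the adopted noise convention this point yields an even
choice split at zero coherence, monotone psychometric and chronometric
functions, and slower errors than correct responses at low coherence —
but its psychometric function saturates at 1.0 from 12.8% coherence,
steeper than the monkey data.  Passing tests therefore certify the
dynamical and inferential machinery, not that this noise convention
reproduces empirical lapse rates.

Parameter-recovery experiments use an interior truth ($\alpha=6$,
$\beta=1.2$, $\sigma=25$, $S=3000$, $\tau=.18/.22/.28$) rather than the
best fit, because a relative recovery error is ill-posed at the best
fit's $\alpha=0$ boundary.

The firing-rate generator emits a 28-row trinary design (four levels of
the recorded option's value crossed with seven contextual pairs, values
from {0, 50, 100, 200, 250} µl, omitted targets coded 0 and still
contributing their unit to the normalization pool) with means from the
closed-form equilibrium and independent Gaussian condition-mean noise
(simplest choice; the fits operate on condition means, so no
trial-by-trial spiking structure is emulated).  The rate scale default
(`rmax = 10`) puts condition means at 13–45 Hz, the range typical of
parietal value coding; the equilibrium solver follows the convention
that the rate rescaling multiplies the value term inside the fixed-point
system, one of two readings the steady-state algebra permits.

## Inhibitory potentiation

Potentiating "the inhibitory projections" is implemented as scaling the
output synapses of the inhibitory populations — the divisive $G\to R$
gain and the $D\to G$ suppression — by a common factor $\lambda$.  Via
$G\to\lambda G$, $D\to\lambda^2 D$ this is exactly equivalent to
$\omega\to\lambda\omega$, $B_G\to\lambda B_G$,
$\beta\to\lambda^2\beta$, so the potentiated circuit stays inside the
family every analysis function handles.  The interpretation matters:
scaling only the excitatory $R \to G$ drive lowers the winner-take-all
activity ceiling to
$\bigl[(\alpha-1)+\sqrt{(\alpha-1)^2+4(\lambda\omega-\beta)V}\bigr] /
\bigl[2(\lambda\omega-\beta)\bigr] \approx 16$ Hz at the published
presets — below any realistic threshold, abolishing choices outright —
whereas the output-synapse reading reproduces the published pattern:
lower representation-stage activity, faster decisions, lower accuracy
(a speed–accuracy tradeoff), in contrast to the pooled-inhibition
recurrent network where potentiation slows decisions and leaves accuracy
unchanged.

## Problem sizes

The test suite runs the phase-plane checks analytically (seconds), the
choice-symmetry check at 2000 trials, monotonicity at 1024 trials per
coherence, the potentiation contrasts at 400 trials per coherence and
four coherences per arm, and the behavioral recovery at 1024
replications, 8 starts.  These sizes are the package's desk-scale
defaults; the full-scale settings of the original fits remain available
through the same function arguments.

## Known limitations

- The exact noise discretization used in the original simulations is not
  recoverable from the printed equations; fitted $\sigma$ is meaningful
  only within this package's convention.
- Steady-state fits cannot separate $\alpha$ from $B_G$; only their
  difference is reported.
- The `green` territory is vanishingly thin at the canonical input scale;
  mapping it requires deliberate refinement near $\beta \in [1, 1.05]$,
  $\alpha < 1$.
- Behavioral fitting is local-search based; with few starts the
  recurrence/time-constant ridge can capture fits started far from the
  truth.  The stratified default mitigates but cannot guarantee escape.
  In desk-scale recovery experiments the disinhibition weight, noise
  amplitude, input scale and time constants come back within ~10% of a
  known truth, but the recurrence weight is only marginally identified:
  refitting the six remaining parameters absorbs most of a recurrence
  change, leaving likelihood differences of tens of nats across a
  two-fold recurrence range — the same collinearity that motivates fixing
  the gain baseline at zero in the first place.  Pinning recurrence
  precisely requires full-scale optimization (the original fits used two
  orders of magnitude more starts and replications).
- Rate equations only: no spiking or conductance-based dynamics.
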