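---
title: "Concentration control by RNA inhibitors and anti-inhibitors: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Concentration control by RNA inhibitors and anti-inhibitors: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribostat)
```

## The chemical model

`ribostat` analyses a minimal RNA-only homeostasis circuit.  An active RNA
species $A$ (the *agent*: a replicase or any other ribozyme) is reversibly
sequestered by a short complementary *inhibitor* $X$, and the inhibitor is in
turn neutralised by an *anti-inhibitor* $Y$:

$$A + X \underset{k_2}{\overset{k_1}{\rightleftharpoons}} AX,
\qquad
X + Y \underset{k_4}{\overset{k_3}{\rightleftharpoons}} XY .$$

Both reactions follow mass action, giving five coupled ODEs for
$[A],[X],[Y],[AX],[XY]$ with three conserved totals
$c_A = [A]+[AX]$, $c_X = [X]+[AX]+[XY]$, $c_Y = [Y]+[XY]$.
All quantities are treated as dimensionless: the worked parameter sets carry
no units, and none are enforced.

Assumptions worth making explicit:

* binding is all-or-none (a bound agent is completely inactive, a bound
  inhibitor completely neutralised);
* the mixture is well stirred (spatial structure is handled separately by
  the multi-agent simulator);
* no molecule is consumed: the binding network conserves all three totals
  exactly.

## Equilibrium analysis

With the anti-inhibitor absent ($c_Y = 0$) the equilibrium free agent
$x$ solves the quadratic $x^2 + (c_X - c_A + K)x - Kc_A = 0$ with
$K = k_2/k_1$; the product of the roots is $-Kc_A < 0$, so exactly one root
is positive and it always lies in $(0, c_A)$.  `simple_equilibrium()`
evaluates the larger root with the numerically stable form of the quadratic
formula (the conjugate expression when the linear coefficient is positive,
avoiding cancellation when $c_X \gg c_A$).

With the anti-inhibitor present the equilibrium is the unique root in
$(0, c_A)$ of the cubic $L(x) = ax^3+bx^2+cx+d$ built by
`cubic_coefficients()`.  Because $L(0) = -K^2c_A^2 < 0$ and
$L(c_A) = k\,c_X c_A^2 > 0$, a bracketing root finder cannot fail, and a
Lyapunov argument (below) shows the equilibrium — hence the root in the
bracket — is unique.  `full_equilibrium()` therefore uses `stats::uniroot`
(Brent) on $(0, c_A)$ with absolute tolerance $10^{-12} c_A$, followed by a
few Newton iterations to polish the root to machine precision; closed-form
cubic formulas are avoided for numerical stability.  Two degenerate cases are
handled explicitly:

* $c_X = 0$: no inhibitor, the root sits on the bracket boundary;
  short-circuit to $x = c_A$ with no complexes.
* $k = K$ (equal dissociation constants, the worked scenarios' case): the
  cubic collapses to $bx^2+cx+d = 0$ with $b>0$, $d<0$, solved by the stable
  quadratic formula.

### System capacity

The *capacity* $\beta = (\partial x/\partial c_A)^{-1}$ measures buffering:
after a small change $\delta$ of the agent total, the set point moves by
about $\delta/\beta$.  Differentiating the equilibrium relation implicitly
gives closed forms — $(x^2+Kc_A)/(x^2+Kx)$ for the simple model, a ratio of
coefficient polynomials for the full model — which the test suite checks
against central finite differences of the equilibrium solvers
($h = 10^{-5}c_A$, relative agreement $10^{-4}$).  The bounds
$1 < \beta < c_A/x$ (simple) and $0 < \beta < c_A/x$ (full) hold for every
valid parameter set, and $\beta \to \infty$ as the inhibitor pool drives
$x \to 0$: strong buffering requires holding the free agent far below its
total.

At the packaged deterministic parameter set ($K=k=1$, $c_A=7$, $c_X=100$,
$c_Y=24.45$) the solver gives $x \approx 0.1$ and $\beta \approx 63.76$.
The tabulated $c_Y$ is itself the design value rounded to two decimals; with
the exact design value ($c_Y = 24.449275\ldots$) the capacity is
$63.7556$, with the rounded one $63.7549$.

### Inverse design

For a desired set point $x$ the totals satisfy $S c_X - T c_Y = U$ with
$S = x[kx + K(c_A-x)] > 0$ and $T = Kx(c_A-x) > 0$, so any set point in
$(0, c_A)$ is attainable.  `design_concentrations()` solves the relation for
either total with the other fixed and signals infeasibility when the
solution would be negative (only possible when $c_X$ is fixed too small:
with $c_X$ free, more anti-inhibitor simply demands more inhibitor).

## Deterministic dynamics

`integrate_mixture()` integrates the five ODEs by explicit forward Euler —
the direct discretisation of the equations, and the reference scheme here
because it conserves the three totals *exactly* in exact arithmetic, so any
drift observed along a trajectory is rounding (the tests admit
$10^{-9}$ per unit time at the default `dt = 0.001`).  The step 0.001 is the
worked scenarios' value; the stability limit of the fastest binding mode
($\sim k_1 c_X$) is two orders of magnitude away at those parameters.  For
convergence cross-checks at random parameters the tests scale the step to
the fastest rate themselves.  `deSolve` is suggested for users who want an
adaptive integrator for comparison; the package's own results use the Euler
scheme throughout.

Guards, chosen once:

* **Negativity.**  The continuous dynamics provably keep all concentrations
  nonnegative, so the integrator clips a negative value only when it exceeds
  $-10^{-12}$ (rounding) and otherwise aborts: real negativity indicates a
  step-size problem, not physics.  Under the self-replication forcing the
  run is instead terminated and labelled *diverged*, because there blow-up
  of $[A]$ is the expected outcome and invalidates the explicit step.
* **Divergence.**  A run is labelled diverged when $[A]$ exceeds $10^3$
  times the initial $c_A$ or any value becomes non-finite; it stops cleanly
  with the step recorded.

### Scenario forcings

* `forcing_jump_noise(p_event, lo, hi)` — at each step, with probability
  `p_event` (default 0.002), a uniform draw from `[lo, hi]` (default
  $[-0.075, 0.075]$) is added to $[A]$, clipped so $[A] \ge 0$; these
  defaults are the published perturbation protocol.  Every stochastic run
  records its seed, and identical seeds reproduce trajectories exactly.
* `forcing_ramp_noise(s)` — a constant signed rate on $d[A]/dt$.  The
  original noise-function scenario never defines its disturbance; a constant
  ramp is the minimal forcing consistent with "falling" and "rising"
  disturbances, so only orderings (more inhibitor $\Rightarrow$ smaller
  excursion) are treated as reproducible, not particular curves.
* `forcing_replication(kRR, dR)` — the agent self-replicates
  ($2A \to 3A$ at rate $k_{RR}$) and decays at rate $d_R$, adding
  $k_{RR}[A]^2 - d_R[A]$ to the agent balance.  Uncontrolled, $[A]$ escapes
  to infinity in finite time; the inhibitor pool delays the explosion by
  over an order of magnitude (about thirty-fold at the packaged parameters)
  but cannot prevent it — the control mechanism has a finite capacity.

### Lyapunov diagnostics

With deviations $x = [A]-x_0$, $y = [Y]-y_0$ from an equilibrium
$(x_0, y_0)$, the function $V = k_3y_0x^2 + k_1x_0y^2$ has the closed-form
time derivative
$$\dot V = -2k_2k_3y_0x^2 - 2k_1k_4x_0y^2 - 2k_1k_3x_0y_0(x+y)^2
          - 2k_1k_3(y_0x^2+x_0y^2)[X] \le 0,$$
zero only at the equilibrium.  `lyapunov_value()` / `lyapunov_derivative()`
expose both; the tests verify monotone decrease along trajectories and the
agreement of the closed form with finite differences of $V$ (forward
difference at $dt = 10^{-5}$, relative $10^{-3}$).  This is the certificate
that the equilibrium is unique and globally attracting, and it is exercised
numerically: integrated trajectories from random feasible starts match the
root-finder's equilibrium to $10^{-6}$.

## The multi-agent simulator

`mas_run()` simulates replicases ($R$), parasites ($P$ — RNAs that are
copied but catalyse nothing), inhibitors, anti-inhibitors and the two
complex types as point agents on a toroidal rectangle.  Defaults in
`mas_params()` are the published spatial scenario: a $1050\times675$ arena,
2250 replicases, 112 parasites, agent radius 3, crowding cap 4, decay 0.1,
affinities 0.8, folding 0.2, diffusion 400, mutation 0.1, unit step, and
binding constants $k_1=10$, $k_2=5$, $k_3=10$, $k_4=5$ converted to per-step
probabilities by $p_i = 1-e^{-k_i\Delta t}$ (Poisson waiting times,
`reaction_probability()`).

The per-step phase order is fixed for reproducibility: diffusion (Gaussian
displacement, variance $D\Delta t$ per axis; $D'$ for complexes) →
decay → replication → parasite folding → inhibition (complex dissociation,
then binding).  Two agents interact when their centre distance is at most
twice the agent radius.  A replication needs a free replicase in range and
fewer than `Nmax` RNA neighbours around the template; the offspring lands
uniformly in the interaction disk, and a replicase offspring mutates to a
parasite with probability $\delta$.  Inhibitor and anti-inhibitor counts
(free plus complexed) are conserved exactly — they never decay — and
identical seeds give identical runs.

### Interpretation decisions

The underlying base model is specified here only through its parameter
table, so several semantics had to be fixed.  Where a first reading
contradicted the model's own qualitative behaviour — a baseline in which
parasites overwhelm the replicases, and rescue that depends on the inhibitor
pool — the interpretation was revised; the decisive choices, with their
rationale:

* **The catalyst is an enzyme.**  A template is copied at most once per
  step, but a replicase may catalyse several copies within one (long) time
  step.  Requiring an exclusive replicase per copy halves per-capita
  productivity at low density and puts the published initial density exactly
  at an extinction knife-edge, where survival is a coin flip independent of
  the inhibitors; enzymatic reuse restores the published picture (reliable
  take-off, then parasite-driven collapse).
* **Folding is inhibitor resistance.**  A folded parasite hides the short
  tag region the inhibitor pairs with, so it cannot be bound; the processive
  replicase is unaffected (folded parasites remain templates) and so is
  hydrolysis (they keep decaying).  Folding is irreversible.  Readings in
  which folding blocks replication handicap the parasites so strongly that
  the no-inhibitor baseline never collapses, contradicting the model's
  central outcome; as resistance, folding instead sets the *limit* of
  parasite-directed control.
* **Complexes are not a shield.**  A bound target keeps decaying (the short
  duplex does not protect the rest of the strand from hydrolysis); the
  inhibitor survives and is released.  Without this, sequestration blocks
  birth and death in equal measure and can only delay, never stop, the
  parasites.
* **Released agents re-equilibrate immediately.**  The unit time step is
  long compared to the binding kinetics ($k_1 = 10$), so within the
  inhibition phase dissociation is processed first and the released agents
  may bind again at once — a released pair sits at zero distance and
  usually re-forms.  Sequestration is therefore effectively persistent even
  though the per-step dissociation probability is 0.993.
* Other conventions: toroidal boundaries (no edge artefacts), `Nmax`
  counts free replicases and parasites within the interaction radius,
  newborns join the world at the end of their birth step, each agent takes
  part in at most one reaction per step, initial placement is uniform, and
  an inhibitor in range of both an eligible target and an anti-inhibitor
  tries the target first.

### What the simulations show — and at what scale

Runs in the test suite use the published densities on one ninth of the
arena area (350 × 225, 250 replicases, 12 parasites, inhibitor counts scaled
by the same factor via `scale_mas_params()`) and a horizon of 2000–3000
steps, sizes chosen so the full extinction/rescue dynamics resolve in
desk-scale runs.  At those sizes:

* without inhibitors, parasites (seeded and mutation-generated) overwhelm
  the replicases and the whole population collapses within a few hundred
  steps, in essentially every seed;
* parasite-directed control (`only_P`) rescues the population throughout
  the published inhibitor sweep (8000–15000, scaled), with survival
  non-decreasing in the inhibitor count; the rescue threshold at this scale
  lies below the sweep;
* replicase-directed control (`only_R`) fails at the same counts — blocking
  the catalysts starves replicase renewal as much as parasite replication —
  so equal survival demands strictly more inhibitors than parasite-directed
  control, the model's qualitative ordering.  A genuine `only_R` rescue
  (reported for very large inhibitor pools at full scale) is *not*
  reproduced at this scale and with these interpretation decisions; only the
  ordering is.

These are statistical, population-level properties.  Individual stochastic
trajectories, exact extinction times, and threshold counts depend on the
interpretation decisions above and on arena scale, and are not meaningful
targets.

## Known limitations

* No sequence-level representation of RNA: affinities and folding are
  scalar probabilities, not structures.
* The deterministic module treats the mixture as well stirred; the
  multi-agent module has space but no compartments or membranes.
* The ramp-noise scenario reproduces orderings only, since the original
  disturbance is undefined.
* Concentrations are dimensionless throughout; mapping to molar units is
  the user's responsibility.
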