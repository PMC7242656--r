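---
title: "Methods: muscle-driven point-to-manifold reaching under optimality principles"
author: "reachopt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: muscle-driven point-to-manifold reaching under optimality principles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific question

When a person points to a vertical bar with the endpoint height left free
(a *point-to-manifold* reach), the redundancy of the task exposes which
movement cost the nervous system appears to minimize: different candidate
optimality principles predict visibly different paths, endpoints and speed
profiles. `reachopt` implements the full simulation study around that
question: a planar two-joint arm driven by six lumped Hill-type muscles, nine
candidate cost functions evaluated on simulated reaches, and a
Gaussian-process Bayesian optimizer that searches the six-dimensional space
of constant open-loop muscle stimulations \(u \in U = [0,1]^6\) for the
stimulation minimizing each cost.  Movements arise purely from the coupled
skeleton–muscle–activation dynamics; there is no planned trajectory, no
feedback, and no inverse model.

# The model

## Skeleton

Two rigid segments (upper arm, forearm+hand) in the vertical plane, shoulder
fixed at the origin, gravity on.  Coordinates: shoulder angle \(\psi\) from
the downward vertical (positive forward), elbow flexion \(\phi\) from full
extension; x forward, z up.  The start posture \(\phi = 90°, \psi = 0°\)
hangs the upper arm and points the forearm horizontally at the bar, which
stands at \(x^\star = 0.85\,(l_1+l_2)\).  The equations of motion are the
standard two-link Euler–Lagrange system \(M(\theta)\ddot\theta +
C(\theta,\dot\theta) = F\), assembled in absolute segment angles and driven
by the summed muscle-tendon torques plus soft exponential joint-limit
torques (the limits only matter for extreme stimulations; excursions are
flagged on the trajectory rather than raised, because hard stops create
integrator pathologies).

## Muscle-tendon units

Each of the six muscles (two monoarticular shoulder, two monoarticular
elbow, two biarticular) is a four-element Hill-type unit: contractile
element (CE) with a bell-shaped force–length curve
\(\exp(-|(\ell_{CE}/\ell_{opt}-1)/w|^{\nu})\) and a Hill hyperbola
force–velocity relation with a van-Soest-style eccentric continuation;
parallel elastic element (PEE) engaging at \(0.95\,\ell_{opt}\) with
power-law stiffness; serial elastic element (SEE) with a nonlinear toe
region and a linear branch; and a serial damping element (SDE) whose
coefficient scales with force.  The CE force is clamped at zero beyond the
maximal shortening velocity — a fiber cannot push — which also keeps the
internal force balance monotone in the contraction velocity.

The contraction velocity is obtained in closed form: multiplying the force
balance CE + PEE = SEE + SDE by the Hill-pole term \((b - v)\) yields an
exact quadratic in \(v\); the physical root is the one nearest zero on the
correct side of the pole (the other root belongs to the unphysical far
branch of the damping interaction).  A bisection fallback guards degenerate
coefficient configurations.  Tests verify the closed form against a
brute-force root solve of the balance on 1000 random states to below
\(10^{-8}\) m/s.

Muscle routing uses constant signed moment arms, so
\(\ell_{MTU} = \ell_{ref} - r_{sh}(\psi-\psi_{ref}) - r_{el}(\phi-\phi_{ref})\).
Constant arms are the simplest realization consistent with lumped muscles;
angle-dependent arms are an extension hook.

## Activation dynamics

Stimulation \(u\) drives a normalized free-calcium state
\(\dot\gamma = m_{act}(u-\gamma)\); activity follows the saturating,
length-dependent map
\(a = \frac{a_{min} + (\rho(\ell)\gamma)^{\nu_{act}}}{1 + (\rho(\ell)\gamma)^{\nu_{act}}}\)
with \(\rho\) increasing with CE length.  Because the map saturates, a high
stimulation reaches peak activity quickly while deactivation takes longer —
the asymmetry that shapes the right-skew of simulated speed profiles.  The
calcium state is what the ODE integrates; the exposed activity-rate
operation inverts the map in closed form and applies the chain rule at the
current length.  At exactly the rest activity the chain-rule rate is zero
(the map is flat there for \(\nu_{act}>1\)); the calcium state still rises,
so rise-from-rest is tested on the calcium rate and slightly above rest.

## Parameter fixture

The study's own muscle parameter table is not available; the shipped
defaults are a *reconstruction* with literature-scale magnitudes: 0.80 m
arm, maximum isometric forces 600–1000 N, optimal CE lengths 0.12–0.15 m,
tendon rest length 0.17 m, moment arms 2.5–5 cm, Hill constants
\(a_{rel}=0.2, b_{rel}=2\), activation rate 11.3 s\(^{-1}\).  Every value is
overridable through the YAML model configuration.  Consequently absolute
cost magnitudes and exact trajectory shapes differ quantitatively from the
original study; the package's checks are therefore structural and scaled
(see "What the tests show" below).

## Initial condition and simulation

The start state minimizes the summed stimulation subject to static
equilibrium at the start posture ("relaxed" hold): each CE at its isometric
fixed point, each activity at steady state, net joint torque zeroed first by
an escalating quadratic penalty on fast spline interpolants of the static
muscle forces, then polished by a two-variable Newton step on the exact
balance to below \(10^{-6}\) N·m.  Simulations integrate the 16-state ODE
with `deSolve::lsoda` at `rtol 1e-8 / atol 1e-10`, sampled on a uniform
1 ms grid.  In free-duration mode the run stops when the fingertip speed
falls below \(10^{-4}\) m/s — armed only after the speed first exceeds ten
times that threshold, since the start state is itself at rest — with a hard
5 s cap.  In fixed mode the run stops at exactly 1 s.  Acceleration, jerk
and torque-rate features come from centred finite differences on the output
grid, with third-order one-sided boundary stencils for first derivatives
and a direct second-difference operator for jerk: chaining two first
differences leaves a boundary error kink that the next stage amplifies by
\(1/\Delta t^2\) and visibly biases the jerk integrals.

# Costs

The nine principles are evaluated exactly as the field states them: squared
angle acceleration, hand jerk, angle jerk, torque and torque change as
trapezoidal integrals of squared signals; energy as the integral of absolute
mechanical power \(|\dot\phi\tau_1| + |\dot\psi\tau_2|\); effort as
\(\sum_i u_i^2\) with no time integral (and hence no duration dependence);
and the hybrids \(J_{JE} = J_{EN} + 10^{-3} J_{AJ}\) and
\(J_{JEE} = J_{JE} + J_{EFF}\).  The total objective adds the task term:
\(J_{total} = \|x_T - x^\star\|^2 + 0.01\,J_{opt}\), plus, in fixed-duration
mode, a terminal-speed penalty (default weight 1; the study states none) so
that movements still end at rest.  Costs consume the raw simulated signals;
the 10 Hz Butterworth filtering is applied only in the metrics module — the
original text describes filtering as data post-processing, and filtering
inside the cost would change the optimization target.

# Bayesian optimization

A zero-mean Gaussian process with the squared-exponential kernel
\(k(u,u') = \alpha \exp(-\gamma\|u-u'\|^2)\) models the cost surface; the
posterior follows the standard dense equations with a Cholesky
factorization and jitter escalation.  Targets are standardized inside the
GP (zero mean, unit variance) and mapped back, so the zero prior mean
refers to centred data — simulations are deterministic, so the observation
noise is a small jitter (\(10^{-6}\alpha\)).  The next stimulation maximizes
the upper-confidence-bound acquisition \(\beta\sigma_n(u) - \mu_n(u)\) with
\(\beta = 0.01\), by L-BFGS-B with analytic gradients from 30 uniform
restarts.  Hyperparameters \((\alpha,\gamma)\) maximize the log marginal
likelihood in log space.  The GP posterior is refit on all data every
iteration; the likelihood maximization is warm-started from the previous
optimum with a full multi-start refresh every 25 iterations, and thins to
every fifth iteration once the dataset exceeds 150 points — a pure
multi-start fit every iteration costs \(O(n^3)\) per likelihood evaluation
and dominates the runtime at \(n \approx 600\) without changing the search
trajectory measurably, and the hyperparameter estimates are stable well
before that size.  The
loop initializes with 10 uniform samples and runs for a configured number
of iterations (600 in the full experiments); a uniform random search with
the same total evaluation budget is the baseline.  Cost-evaluation failures
are recorded as the worst observed value plus one standard deviation, which
keeps the GP well-posed without catastrophically biasing the region.

# Metrics and reference data

Post-processing mirrors the experimental pipeline: zero-phase fifth-order
Butterworth filtering at 10 Hz (with odd-reflection padding, since a plain
forward–backward pass starts from zero state and corrupts the edges),
movement on/offset at 5% of peak tangential speed (linearly interpolated
crossings), plane-curve signed curvature
\((\dot x\ddot z - \dot z\ddot x)/(\dot x^2+\dot z^2)^{3/2}\) inside the
window, and a relative-peak-time skewness
\((t_{peak}-t_{on})/(t_{off}-t_{on}) - 0.5\).  The original study does not
print its curvature or skewness formulas; these standard choices are
pluggable.  Comparison metrics are absolute errors against the mean (or
median) over reference subjects.  Run comparison uses Welch's t-test by
default (the two arms have very different spreads; a pooled toggle exists),
and convergence curves report the per-iteration mean and sample standard
deviation of the running minima.

The 17 "subjects" are synthetic surrogates, not recorded data: minimum-jerk
time courses along concave-bulged paths from the model start point to
normally distributed endpoint heights on the bar (mean −0.05 m, sd 0.05 m),
with peak speeds drawn around the published 0.85 m/s (sd 0.08) and the
duration following from the minimum-jerk relation \(T = 1.875 L / v_{peak}\)
(≈1 s for these geometries).  The generator reproduces only the four
headline features (endpoint on the bar, concavity, ~1 s duration,
~0.85 m/s bell); it does not attempt to match inter-subject covariance,
path variability within subjects, or measurement noise, so agreement with
the synthetic reference says nothing about fit to real kinematics beyond
those features.

# Problem sizes and numerical choices

The experiment drivers default to the full study sizes (600 iterations, 10
initial samples, 30 restarts, 3 comparison repeats, 30 convergence
repeats).  The package's own acceptance checks run the optimization-based
blocks at reduced sizes chosen once — BO-vs-random at 3×100 iterations per
arm, the fixed-1 s hybrid run at 150 iterations, the nine-cost sweep at 150
iterations per cost (the effort model's endpoint prediction needs roughly
that budget to converge) — while `scripts/acceptance.R` recomputes the two
headline targets at 200 and 600 iterations.  Other numerical choices:
trapezoidal integration on the 1 ms grid; tie-breaks in best-k selection by
iteration order; posterior variance clamped at zero; kernel matrix jitter
escalated from \(10^{-10}\alpha\); curvature masked below a \(10^{-6}\) m/s
speed floor.

# Known limitations

Planar model only; constant moment arms; no metabolic cost; no
signal-dependent noise or variance-based principles; open-loop constant
stimulations (no feedback, no time-varying excitation); the parameter
fixture is a reconstruction, so absolute cost levels are not comparable to
the original study's printed convergence value.  Under this fixture the
jerk of any movement — dominated by a physical 10–20 Hz muscle-tendon
onset transient, invariant to integrator tolerance — is of the same order
as the endpoint penalty saved by reaching, which makes the hybrid-cost
(JE/JEE) optima sensitive to the reconstruction and can favour
near-quiescent solutions; likewise, which point on the bar the effort
principle selects is set by the cheapest static hold on the bar manifold
and hence by the reconstructed muscle geometry.  The structural
comparisons (optimizer vs random, cost-function discrimination, the
equilibrium/physics properties) are the robust outputs.
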