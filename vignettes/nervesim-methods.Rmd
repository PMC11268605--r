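---
title: "Models and numerical methods in nervesim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerical methods in nervesim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nervesim)
```

# Scope and model structure

`nervesim` simulates electrical stimulation and recording of peripheral
nerve fibers with a two-step hybrid approach under the quasi-static
approximation: extracellular potentials are computed analytically from
point-source electrodes in an infinite homogeneous (an)isotropic medium,
and applied as the extracellular drive of one-dimensional conductance-based
compartmental axon models. Each axon is independent (ephaptic coupling is
neglected, the standard assumption for peripheral fibers), so population
simulations decompose into independent per-fiber problems.

Finite-element volume conduction, geometric electrode models (cuffs,
intrafascicular electrodes) and histology import are out of scope: the
extracellular interface is a footprint per (electrode, point) pair, so a
numerical field backend could be substituted without changing the solver,
but only the analytic point-source backend is provided.

## Extracellular fields

For electrodes $k$ with currents $I_k(t)$, linearity of tissue impedance
gives $V_e(\mathbf r,t)=\sum_k I_k(t)\,F_k(\mathbf r)$ where the footprint
$F_k$ (V/A) is time-independent. For an isotropic conductivity $\sigma$,
$F = 1/(4\pi\sigma\lVert\mathbf r-\mathbf r_e\rVert)$; for a diagonal
anisotropic tensor,
$F = 1/\big(4\pi\sqrt{\sigma_{yy}\sigma_{zz}\,x_d^2+
\sigma_{xx}\sigma_{zz}\,y_d^2+\sigma_{xx}\sigma_{yy}\,z_d^2}\big)$,
which reduces to the isotropic form when the components are equal.
Footprints are evaluated once per simulation at the compartment centers and
reused at every time step (space-time decoupling). Material presets
(S/m, x longitudinal): endoneurium (0.57, 0.085, 0.085), epineurium 0.085,
perineurium 0.002, saline 2.

## Axon models

*Unmyelinated* fibers use the classic squid-axon conductance set (gates m,
h, n; 6.3 °C reference rates) on a uniform single cable. The default
spatial step is 2.5 % of the passive length constant.

*Myelinated* fibers use a double-cable representation: excitable nodes of
Ranvier (fast Na with m/h, persistent Na with mp, slow K with s, leak;
36 °C rates) alternating with passive internodes split into paranodal
(MYSA), juxtaparanodal (FLUT) and six internodal (STIN) sections. Each
internodal compartment has a passive axolemma beneath a myelin sheath whose
capacitance and conductance scale inversely with twice the lamella count,
and a thin periaxonal space with its own axial conduction pathway. Section
dimensions versus fiber diameter come from the published discrete geometry
table for 5.7–16 µm fibers, interpolated with monotone (Hyman) cubic
splines through the table plus ratio-consistent anchor rows at 1 and 20 µm.
Monotone splines guarantee strictly positive morphology over the whole
1–20 µm domain — the known failure mode of plain polynomial fits is
negative section lengths at small diameters — at the cost of not being a
single global polynomial; the interpolant reproduces the table exactly at
the tabulated diameters.

**Resting state.** The published nodal conductances do not balance exactly
at a round resting potential, so each fiber's rest is solved numerically at
construction (root of the steady-state ionic current) and the internodal
passive reversal is tied to it. The entire fiber is then an exact fixed
point of the discrete dynamics: an unstimulated simulation stays at rest to
numerical precision, which the tests assert with a 1 mV bound over 5 ms.

# The cable solver

Each time step solves the coupled axolemmal/periaxonal system implicitly
(backward Euler) with gating advanced by exponential Euler on rates frozen
at the previous step's voltage — a staggered scheme that keeps every gate
in [0, 1] unconditionally and makes the per-step voltage problem linear.
Unknowns are interleaved (V and periaxonal W per compartment; W is fixed at
zero at nodes and for unmyelinated fibers, where the periaxonal layer is
shorted to the medium), giving a banded system of half-bandwidth 3 solved
by LAPACK's pivoted banded factorization. Pivoting matters: the periaxonal
row couples to the axolemmal unknown with a coefficient that can exceed its
own diagonal by orders of magnitude, so an unpivoted elimination fails
precisely at the strong drives used in threshold searches. Boundary
conditions are sealed ends (zero axial current). Units are mV, ms, µA, µF,
mS throughout the solver.

The default `dt` is 1 µs, chosen to resolve kilohertz waveforms (a 40 kHz
sine is sampled 25 times per period); module-level experiments use 2 µs
where only pulse responses matter, and the tests check that halving `dt`
moves threshold estimates by well under 2 %. The reported per-compartment
membrane current (used for recordings) is the current delivered to the
extracellular medium — myelin displacement plus conduction current at
internodes, axolemmal plus periaxonal-return current at nodes — computed
with the same discrete time derivative as the solver, so the compartment
sum balances injected clamp currents to numerical precision (Kirchhoff
check in the tests).

# Recording

Compound action potentials at recording points are the dot product of
per-compartment membrane currents with a recorder footprint matrix, summed
over fibers. Footprints are point-source (any material) or line-source
(isotropic only). The line-source form is implemented with signed axial
offsets from both segment ends, which agrees with the usual absolute-offset
expression when the recording point lies beyond a segment end and remains
exact when it lies alongside the segment; the tests validate it against
numerical quadrature of point sources (0.5 %) and its far-field point-source
limit (0.1 %). The printed form of the line-source denominator in the
source literature mixes its segment-length term with an index typo; the
implementation uses the segment length, which is the dimensionally
consistent reading.

Amplitude–latency characterization takes each point's peak as the maximum
absolute potential and its latency as the peak time relative to activation.
When per-point propagation distances are supplied, the peak search is
restricted to arrival times consistent with conduction velocities in
[4, 80] m/s: synchronous activation produces a large transient at the
activation site that is visible at every recording point with near-zero
latency (the in-silico counterpart of a stimulation artifact), and the
velocity window excludes it on physical grounds. The first recording point
is excluded from the log–log fit by convention.

# Population generation and packing

`create_axon_population()` draws fiber types Bernoulli and diameters from
named distributions: truncated lognormal and truncated bimodal normal
mixtures, with presets *emulating* published sciatic/tibial morphometry
(bimodal myelinated distributions with modes near 4 and 9 µm on [2, 16];
unmyelinated lognormal around 0.8 µm). The presets reproduce the
qualitative shape — ranges and modes — of the cited statistics, not exact
histograms, and are fixed defaults rather than tuning knobs. Sampling is by
inverse-CDF of the truncated distribution, so populations are exactly
reproducible under a seed.

Packing moves fibers on a shuffled grid toward the origin (attraction step
proportional to distance, capped at 2 µm) unless they overlap a neighbor,
in which case a repulsion step proportional to overlap depth plus a small
clearance (0.05 µm) pushes them apart; attraction decays geometrically
(0.995 per iteration) so the configuration settles instead of jamming.
Iteration stops when no overlaps remain and the pending displacement is
below 0.01 µm. The final state is checked for zero overlapping pairs and
the fitted radius is `max(|p| + r)`. The attraction/repulsion magnitudes
are implementation choices (the algorithm family leaves them free) and are
exposed as arguments.

# Analyses

Activation thresholds use bisection on the amplitude of a fixed waveform
until the bracket satisfies `(upper - lower)/lower <= 0.1 %`, returning the
upper (activating) edge. Block thresholds use the same machinery at 1 %
tolerance on the peak-to-peak amplitude of a kilohertz sine, with the
standard replication protocol: a 51-node fiber in a 0.2 S/m isotropic
medium, a point source over the central node, HFAC applied from 3 to 23 ms,
a conduction test pulse at the first node, and block classified by the
failure of a steady-state test action potential (default at 15 ms, past a
5 ms onset-response settling window) to propagate past the electrode. The
bisection assumes a monotone response in its bracket; far above activation
threshold the flanking virtual anodes can block the response outright, so
upper bounds should stay below that overdrive regime.

Recruitment curves report the recruited fraction over an amplitude or
pulse-width sweep, with the recruitment rate defined as the slope of the
curve between 0.2 and 0.8 recruitment (least squares over sweep points in
the band, or the secant through the interpolated band crossings when fewer
than two points fall inside).

# Optimization

The cost-function formalism composes an optional filter, a static context
(never mutated; modified copies are produced per candidate), a context
modifier and a cost evaluation. The energy-plus-recruitment cost is the
literal sum-of-squares form
$\alpha_e \sum_k i^2(t_k) + \alpha_r (N_{axon} - N_{recruited})$ over the
discrete solver grid, with a separately labeled dt-weighted variant for
physical energy. Waveform parameterizations: a cathodic square pulse
(amplitude, width) and N-knot splines (2N dimensions) interpolated through
zero-pinned endpoints with a natural cubic, sampled onto a linear-
interpolation stimulus and clipped to non-positive currents; knot order is
irrelevant (knots are sorted). The particle-swarm optimizer is global-best
with inertia 0.7 and cognitive/social coefficients 1.5 (conventional
mid-range values; the choice is exposed), reflection at bounds, and a
nonincreasing best-cost trace; it is seeded and deterministic.

# Problem sizes used by the tests

The test suite and acceptance script run at deliberately modest sizes: the
synchronized-population recording experiment uses 100 myelinated fibers
over 30 mm with 8 recording points (about a minute); block thresholds use
the full 51-node, 23 ms protocol; packing is exercised at 1000 fibers;
threshold orderings use three diameters and three pulse widths on 10 mm
fibers.

# Known limitations

- Only point-source electrodes in an infinite homogeneous medium: no nerve
  boundary, perineurial sheath or electrode geometry effects.
- Recording is analytic and single-material; no electrode filtering or
  impedance model.
- The scaled-down recording experiment compresses the dynamic range of the
  compound signal: with a fifth of the full-scale fiber count, the compound
  wave shrinks proportionally while individual near-recorder fiber spikes
  do not, so the far recording points approach a single-fiber amplitude
  floor and the fitted amplitude–latency slope is shallower than the
  inverse-square decay that the near points exhibit locally. Increasing the
  population restores the compound regime point by point but the large-
  diameter cohort remains partially coherent over these distances in this
  analytic setting.
- Channel kinetics are fixed parameter sets at their reference
  temperatures; no Q10 sweeps.
- Node-of-Ranvier alignment across a population is either exact or
  uniformly random per fiber; no correlated jitter.
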