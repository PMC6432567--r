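---
title: "Methods: driven polyelectrolyte translocation through a nanopore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: driven polyelectrolyte translocation through a nanopore}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

polytrans simulates a single negatively charged bead-spring chain of $N$
monomers threading through a cylindrical pore in a rigid membrane, driven by
an electric field applied only inside the channel, in a solution of explicit
monovalent ions. Everything is expressed in reduced units: the bead diameter
$\sigma$, the bead mass $m$, the thermal energy $k_BT$, the elementary
charge $e$, and the time unit $\tau_u = \sigma\sqrt{m/k_BT}$.

Four interactions define the force field:

* **Excluded volume** between mobile beads: the purely repulsive
  Weeks-Chandler-Andersen form, a Lennard-Jones potential truncated at its
  minimum $2^{1/6}\sigma_{bb}$ and shifted to zero there, with
  $\sigma_{bb} = 1.0$, $\varepsilon_{bb} = 1.2\,k_BT$. Bead-wall repulsion
  uses the same form with $\sigma_{bw} = 1.5$,
  $\varepsilon_{bw} = 2.5\,k_BT$.
* **Connectivity**: harmonic bonds $U = \tfrac{k}{2}(r - r_0)^2$ with
  $k = 600\,k_BT/\sigma^2$, $r_0 = 1.0\,\sigma$. Bonded neighbours are
  excluded from the WCA term (the stiff spring already prevents overlap;
  double-counting the contact repulsion would stretch every bond by a few
  percent), but they do interact electrostatically.
* **Electrostatics**: $U = k_BT\,\lambda_B Z_iZ_j/r$ with Bjerrum length
  $\lambda_B = 3.0\,\sigma$, summed over the fully periodic box by smooth
  Ewald summation (below). Each monomer carries $-e$; one $+e$ counterion
  per monomer plus 256 cations and 256 anions of added salt keep the system
  neutral and set a finite ionic strength.
* **Driving field**: $\vec E = -E\hat z$ exactly inside the cylindrical
  channel volume and zero outside — a step function, with no taper; every
  *charged* bead inside the channel feels $Z_ie\vec E$, ions included. The
  discontinuity at the channel boundary is intentional and documented: the
  field model is a uniform in-pore field, not a solution of the Poisson
  problem.

The membrane is four layers of immobile beads on a triangular lattice
(lattice constant $1.0\,\sigma$; the default $48.0 \times 49.36\,\sigma$
cross-section holds exactly $48 \times 57$ sites per layer, which is what
makes the printed box commensurate), spaced $1.5\,\sigma$ apart so the slab
spans the pore length $4.5\,\sigma$, with a pore of radius $2.25\,\sigma$
punched along $z$ through the box center. Buried beads of the two interior
layers — those farther from the pore axis than the bead-wall interaction
range plus a margin — are removed; no mobile bead can reach them, so the
removal is exactly free. Wall beads are rigid scaffolding: they exert WCA
forces on mobile beads but receive no updates, and wall-wall pairs are
skipped.

Space is partitioned by $z$ alone into cis (I), pore (II, the closed
interval between the two wall faces) and trans (III). Because the field
$-E\hat z$ pushes the $-e$ monomers toward $+z$, the cis compartment is the
low-$z$ side and trans the high-$z$ side; boundary ties belong to region II.
Classification by $z$ only (rather than the full cylinder test) matches the
one-dimensional monomer bookkeeping $N_{m,\mathrm{I/II/III}}$; off-axis
positions at channel $z$ are sterically blocked by the wall anyway.

## Electrostatics: smooth Ewald with an accuracy contract

The periodic Coulomb sum uses the classical Ewald decomposition — real-space
complementary-error-function pairs, a reciprocal-space sum over an ellipsoid
of modes, and the self term — under tin-foil boundary conditions. Parameters
$(\alpha, r_c, k_{\max})$ are derived from a single accuracy target
(default $10^{-3}$ relative RMS force error) via
$s = \sqrt{-\ln \delta}$, $r_c = \min(\text{box})/2$, $\alpha = s/r_c$,
$k_{\max} = 2\alpha s$. The contract is the accuracy, not the algorithm:
tests verify that the result is independent of the real/reciprocal split and
that energies agree with a direct lattice-sum oracle to within the target on
dozens of random neutral configurations.

The oracle sums the bare Coulomb form over periodic images in spherical
shells, averaging the last two partial sums to damp the oscillation of the
conditionally convergent series. Spherically ordered direct sums converge to
the vacuum boundary condition, so the comparison adds the surface-dipole
term $2\pi|\vec M|^2/(3V)$ to the Ewald side; dynamics never uses that term.

A smooth (non-mesh) Ewald is an $O(n^{3/2}\!-\!n^2)$ method, which is the
right trade at this package's scale (at most ~1300 charges): the
particle-mesh machinery would buy nothing. For the same reason the
short-range pair search is a plain $O(n^2)$ loop with a cheap $z$-rejection
rather than a maintained cell list — profiling at these sizes favours the
simple loop, and its results are trivially identical to the all-pairs
reference. The static wall does use a precomputed grid, since it has several
thousand beads and only mobile beads near the slab ever query it.

## Langevin dynamics

The equation of motion
$m\ddot{\vec r}_i = -\zeta\dot{\vec r}_i - \nabla_i U + Z_ie\vec E(\vec r_i) + \vec\eta_i$
with $\langle\vec\eta_i(t)\cdot\vec\eta_j(t')\rangle = 6 k_BT\zeta\,
\delta_{ij}\delta(t-t')$ is integrated with the Gronbech-Jensen/Farago
discretization, a Verlet-family scheme chosen because it reproduces
configurational (Boltzmann) statistics essentially without time-step bias
across the whole production range $\Delta t \in [10^{-4}, 5\times10^{-3}]$
and reduces exactly to velocity Verlet at $\zeta = 0$ (the limit used by the
energy-conservation tests). Friction is $\zeta = 1.0\,m/\tau_u$ and
$k_BT = 1$.

The time-step policy ties $\Delta t$ to the field strength — $5\times10^{-3}$
for $E \le 1$, $10^{-3}$ for $1 < E \le 10$, $5\times10^{-4}$ beyond — and
is overridable per run; every run records the $\Delta t$ it used. Noise
comes from a per-run xoshiro256++ stream seeded by the run's seed, so a
(configuration, seed) pair reproduces its trajectory bit-for-bit on one
platform; cross-platform bit-identity is not claimed.

## Protocol of one translocation experiment

1. **Assembly.** Monomer 1 sits on the pore axis $0.25\,\sigma$ beyond the
   trans-side opening; the next monomers continue down the axis through the
   channel; the remainder grows into the cis compartment as a self-avoiding
   persistent walk (below). Counterions start in a $1$–$4\,\sigma$
   dissociation shell around the chain — the physical picture of ions
   dissociated from the chain, and the only initialization from which the
   condensation equilibrium is reachable in desk-scale runs (uniformly
   scattered counterions would have to diffuse tens of $\sigma$ against
   nothing but their own gradient). Salt ions are uniform over both
   compartments, excluding the wall slab and channel. All placements respect
   a $0.85\,\sigma$ minimum separation.
2. **Tethered equilibration at zero field.** Monomer 1 is frozen; everything
   else evolves. The leading fraction (default 55%) of the equilibration runs
   at reduced friction $\zeta = 0.15$: static equilibrium averages are
   independent of $\zeta$, and the slowest chain modes — which at
   $\zeta = 1$ relax on the Rouse scale of $10^3$–$10^4\,\tau_u$, far beyond
   desk budgets — are near critical damping at $\zeta \approx 0.15$, which
   accelerates conformational relaxation several-fold without biasing any
   configuration-space observable. The remaining steps run at the production
   friction and provide every frame that enters reported averages. The
   equilibration records its $t̃ = 0$ anchors (mean bond length, kinetic
   temperature, cis-side radius-of-gyration series) and flags
   non-convergence by a split-half comparison of the $R_{g,I}$ series.
3. **Driven run.** The tether is released and the in-pore field switched
   on. A purely repulsive LJ plane at the exit ($\sigma = 1$,
   $\varepsilon = 1.2\,k_BT$), visible only to monomer 1, prevents
   back-threading; it arms only after monomer 1 first clears its interaction
   range, because the threaded starting position is inside that range and an
   always-on plane would kick the chain at release. The run ends at first
   passage — the step in which the last monomer's $z$ crosses the exit
   plane — with $\tau$ interpolated linearly inside the crossing step, so the
   frame cadence cannot bias it. Runs that hit the step cap are returned
   marked incomplete, never dropped.

### The starting coil

The persistence length of the initial walk is set to the Debye screening
length of the free-ion cloud, $\kappa^{-1} = (4\pi\lambda_B\sum_i c_i)^{-1/2}
\approx 4.4\,\sigma$ at study conditions: below that scale intra-chain
repulsion is unscreened and stiffens the chain, and the competing
Odijk-Skolnick-Fixman estimate with the Manning-reduced charge
($\approx 2.6\,\sigma$) is documented in the polyelectrolyte literature to
understate the stiffness of flexible, strongly charged chains. Walks that
reach the box floor or the wall clearance reflect specularly, which preserves
their persistence. This choice matters and is stated prominently: the global
coil size of a 128-mer is a soft mode whose equilibrium fluctuations span
several $\sigma$ with correlation times of order $10^2\,\tau_u$, so
desk-scale averages retain memory of the initial ensemble. The initializer
is therefore built to *be* a sample of the expected equilibrium coil
statistics, and the equilibration stages then relax local structure, bonds
and the ion atmosphere, which do converge at desk scale.

## Analysis pipeline

All ensemble curves live on a normalized-time grid $t̃ = t/\tau \in [0,1]$
with 101 points (spacing 0.01, reused as the window width of the
distribution analyses); each run is interpolated linearly onto the grid
before averaging, and curves carry the per-point standard deviation as their
spread.

* **First-passage statistics**: mean $\langle\tau\rangle$; $P(\tau)$ as a
  Gaussian-kernel density estimate with Silverman's bandwidth; the width $w$
  is the span of the region where the density exceeds $1/e$ of its peak,
  with the crossings interpolated on the density grid (a histogram-bin-free
  definition; for a Gaussian, $w \to 2\sqrt2\,s$).
* **Scaling fits**: $\alpha$ from $\log\langle\tau\rangle$ vs $\log N$,
  $\delta$ per field regime (weak $E \le 1$, intermediate $1 \le E \le 10$,
  strong $E \ge 10$; boundary points belong to both neighbours), $\beta$
  from the translocation-coordinate MSD on $0.5 \le t̃ \le 1$. All fits are
  unweighted least squares on log-log points with residual standard errors —
  the source data report parenthetical uncertainties without stating
  weights, so the unweighted choice is recorded here.
* **Conformation**: region-resolved $R_g$ (center of mass taken over the
  monomers of that region; empty regions propagate as missing, never as
  zero) and chain-end $z$ positions relative to the exit plane.
* **Ion condensation**: an ion is condensed if its minimum-image distance to
  the nearest monomer is below $\lambda_B$; it is attributed to the region
  of that nearest monomer (condensation is a chain-relative property, so the
  chain's region, not the ion's own $z$, decides the bookkeeping — a choice,
  recorded here, that the source leaves open). $Q_c = e N_c^{(+1)} -
  e N_c^{(-1)}$, the neutralized fraction is $|Q_c/Ne|$, and the effective
  line charge density $|(-Ne + Q_c)/\ell|$ uses the instantaneous contour
  length $\ell = \sum \text{bond lengths}$. The Manning benchmark is
  $e/\lambda_B$.
* **Spatial distributions**: species-resolved $z$ histograms (bin
  $0.5\,\sigma$ — fine enough to resolve near-wall peaks against the
  $4.5\,\sigma$ pore, coarse enough not to starve counts) within
  $t̃$-windows of width 0.01, and monomer density maps on a
  $1\,\sigma \times 1\,\sigma$ $(y,z)$ grid viewed along $x$. Bin widths are
  design choices recorded in the output metadata. Profile-peak locations
  are estimated per run (with a short moving-average smoothing of the
  histogram) and then averaged: the argmax of a histogram pooled across
  runs is dominated by the densest — most compact — run, not the
  ensemble-typical one, whenever run-to-run conformational variance is
  large.

## Synthetic-data generators

The fixtures module emulates only the statistical structure the analyses
assume, never the force-field physics: translocation times are lognormal
(positive support, single peak, near-Gaussian at small coefficient of
variation) with median $c_0 N^{\alpha}E^{-\delta}$; translocation
coordinates are monotone-on-average integer series $1 \to N$ with drift
$s = 1 + (N-1)\,t̃^{\beta/2}$ plus bounded zigzag noise, so their ensemble
MSD grows as $t̃^{\beta}$; condensation test frames place prescribed numbers
of ions inside and outside the Bjerrum shell of a straight chain. Every
generator is deterministic given its seed. Passing recovery tests on these
fixtures demonstrates that the estimators are correct and unbiased at the
study's noise scales; it does not, by itself, validate the dynamics — that
is what the property gates (force consistency, Ewald accuracy,
thermostatting, conservation) and the equilibrium anchors are for.

## Problem sizes, tolerances, degenerate inputs

The shipped test suite and the reproduction script run complete
translocations at $N = 8$–$16$ with reduced salt, short partial-threading
runs at $N = 128$ at full ion content, and tethered equilibrations of the
full $N = 128$ system (768 mobile charges) over a few times $10^4$ steps and
a handful of seeds — sizes chosen so each stage exercises the production
code path on one desk CPU. Exponent tables over $N$ up to 384 with hundreds
of runs per condition are cluster-scale ensembles; the scaling estimators
are therefore validated on calibrated synthetic ensembles at exactly the
reported exponents, and the simulated trend checks stay at reduced scale.

Numerical edge handling, in one place: pair separations below $10^{-6}$ are
a singular-configuration error naming the beads; non-finite coordinates
abort with the step, bead and $\Delta t$; empty analysis regions yield
missing values; empty $t̃$-windows yield a warning and a missing profile;
region counts that fail to sum to $N$ are a fatal internal error, never
silently repaired. Incomplete driven runs return `completed = FALSE` with
whatever frames exist.

## Known limitations

* No hydrodynamic interactions, by construction of the Langevin dynamics —
  the relevant regime is Rouse-like dynamics.
* The desk-scale equilibrium anchors inherit the initial-coil ensemble for
  the global chain size, as discussed above; bond-scale structure, the ion
  atmosphere and condensation statistics equilibrate fully.
* A single chain, a chemically featureless pore, monovalent ions only, and
  no bond breaking or angular terms.
* Trajectory bulk storage uses R's native serialization rather than a
  cross-language array container; XYZ/PDB text exports cover interchange.
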