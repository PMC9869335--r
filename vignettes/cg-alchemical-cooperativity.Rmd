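---
title: "Coarse-grained alchemical modelling of PROTAC binding cooperativity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-grained alchemical modelling of PROTAC binding cooperativity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgalchemy)
```

## The problem

A PROTAC (proteolysis targeting chimera) is a heterobifunctional molecule:
two protein-binding warheads joined by a flexible linker.  By binding a
target protein and an E3 ligase simultaneously it induces a non-native
target--PROTAC--E3 ternary complex.  How strongly the presence of one
protein helps (or hinders) the PROTAC's binding to the other is the *binding
cooperativity*,

$$\alpha \;=\; \exp(\Delta\Delta G / RT), \qquad
\Delta\Delta G \;=\; \Delta G^{\mathrm{binary}} - \Delta G^{\mathrm{ternary}},$$

where the two $\Delta G$ are the free energies of the PROTAC binding one
protein in the absence and in the presence of the other.  Positive
$\Delta\Delta G$ means positive cooperativity.  Because the linker is
flexible, the two proteins are not locked at a fixed interface: the
protein--protein interactions (PPIs) that generate cooperativity are weak,
transient, and strongly modulated by the *configurational entropy* of the
linker.  Sampling that ensemble at atomistic resolution is prohibitive,
which motivates a coarse-grained (CG) model simple enough to converge
alchemical free-energy calculations in which an *entire protein* is coupled
or decoupled.

## The coarse-grained model

Two resolutions are used:

* **Proteins**: three consecutive amino acids per bead, diameter
  $\sigma = 0.8$ nm (about the Kuhn length of a polypeptide).  The bead
  sits at the heavy-atom center of mass of its residue triplet; a trailing
  partial triplet forms its own bead.  The folded shape is maintained by an
  elastic network model (ENM): harmonic springs between every bead pair
  within a cutoff (default 1.1 nm, spring constant 500 kT/nm²),
  rest lengths equal to the input-structure distances.
* **PROTAC**: each warhead is one $\sigma = 0.8$ nm bead; the linker is a
  chain of $N$ beads of diameter $\sigma_s = 0.35$ nm (one PEG unit, three
  heavy atoms).  Linker lengths of 1--6 beads span contour lengths of
  roughly 3.5--21 Å and correspond to the PROTAC (1), (3), (5), (6), (8),
  (10) compound series.  Adjacent beads are bonded by stiff harmonic
  springs with rest length equal to the sum of their radii.  Linker beads
  carry no charge and no attractive affinity.

Bead charges are the summed formal residue charges of the triplet
(Asp/Glu $-1$, Lys/Arg $+1$, His and all others 0, termini ignored) --- the
standard pH-7 assignment.

The nonbonded force field is minimal:

* **Volume exclusion** between molecules: the Weeks--Chandler--Andersen
  (WCA) potential, $4\varepsilon[(\sigma_{ij}/r)^{12} -
  (\sigma_{ij}/r)^6] + \varepsilon$ for $r < 2^{1/6}\sigma_{ij}$, with
  $\sigma_{ij}$ the sum of the bead radii and $\varepsilon = 1\,kT$.
* **Nonspecific attraction** (optional): a Lennard-Jones well of depth
  $\varepsilon_{\mathrm{LJ}}$ (explored at 0.125--0.25 kT) acting only
  between protein beads of the *two different proteins*, truncated at
  $3\sigma_{ij}$; a CG stand-in for van der Waals attraction.
* **Electrostatics** (optional): Debye--Hückel,
  $U = \ell_B q_i q_j e^{-r/\lambda_D}/r$ in kT, with Bjerrum length
  0.7 nm and Debye length 1.0 nm (roughly physiological screening) by
  default.  A `screening_scale` multiplier on $\lambda_D$ implements
  weakened-screening experiments (e.g. tenfold).

**Exclusion topology.**  The force-field terms the model does *not* include
are as important as those it does.  Intra-protein nonbonded interactions are
excluded (the ENM already maintains shape); PROTAC-internal bead pairs
separated by at least two chain bonds keep WCA volume exclusion; directly
bonded pairs are excluded, and a warhead bead has no nonbonded interaction
with the protein it is anchored into --- the warhead is treated as part of
the bound pocket moiety whose geometry the anchor springs maintain.  This
last choice (the source model is silent on it) removes a large
binary/ternary-identical insertion energy from both legs of the
thermodynamic cycle; its dummy-state contribution would cancel in
$\Delta\Delta G$ anyway, but excluding it reduces the variance of each leg.

## Assembly

A ternary complex needs: the two CG proteins, their binding-pocket beads,
and the linker length.  Pockets come either from an experimental structure
(all beads containing a residue with a heavy atom within 4--5 Å of the
bound warhead; default 0.45 nm, the midpoint) or, for synthetic proteins,
by designation.  Each protein is rotated so its pocket-centroid axis faces
the other protein; warheads are placed at the pocket centroids, the PROTAC
fully extended between them.  Every pocket bead is tied to its warhead by a
harmonic *anchor* spring (default 1000 kT/nm²) with rest length equal to
the placement distance.  A short deterministic steepest-descent shake on a
nearly fully coupled soft-core potential relieves any residual clash;
assembly aborts if cross-protein beads remain closer than half their summed
radii.  Binary complexes are derived by deleting one protein (with its ENM
and anchors) from the assembled ternary complex, leaving all other
coordinates untouched.

## The alchemical thermodynamic cycle

Instead of simulating binding and unbinding, $\Delta\Delta G$ is obtained
from two *coupling* legs.  In both, the protein of interest (say the
target, $T$) starts as a **dummy**: its internal ENM and the pocket anchor
springs are retained, but every nonbonded term between it and the rest of
the system is off.  Coupling $T$ to the PROTAC alone (binary leg) and to
the PROTAC--E3 complex (ternary leg) gives

$$\Delta\Delta G = \Delta G^{\mathrm{binary}}_{\mathrm{couple}}
 - \Delta G^{\mathrm{ternary}}_{\mathrm{couple}}.$$

The dummy attachment is unphysical, but its term in the configurational
partition function factorizes --- the anchors touch the physical system
through a single warhead bead and are never $\lambda$-scaled --- and is
*identical* in the two legs, so it cancels in $\Delta\Delta G$.  The
mirrored cycle (coupling the E3 instead) must give the same answer; the
package checks this cycle closure statistically
(`cycle_closure_check()`).

Coupling proceeds in stages:

1. **Sterics** (WCA plus any nonspecific attraction, one combined stage):
   soft-core $\lambda$-scaling in the Beutler form, with
   $t = (r/\sigma_{ij})^6$ and $\alpha = 0.5$:
   $$U(\lambda) = 4\lambda\varepsilon\!\left[
     \big(\alpha(1-\lambda) + t\big)^{-2} -
     \big(\alpha(1-\lambda) + t\big)^{-1}\right],$$
   finite at $r = 0$ for $\lambda < 1$.  The WCA variant is truncated at
   its minimum $t = 2 - \alpha(1-\lambda)$ and shifted by
   $\lambda\varepsilon$, so both endpoints are exact: $\lambda = 1$
   reproduces the plain potential to machine precision and $\lambda = 0$
   vanishes.  The schedule is dense near $\lambda = 0$ where most of the
   free-energy change occurs:
   $\{0, 0.005, 0.01, 0.015, 0.02, 0.04, 0.06, 0.08, 0.1, 0.2, 0.3,
   0.5, 0.7, 0.9, 1\}$ (15 states).
2. **Electrostatics**, only on top of full volume exclusion (the
   Debye--Hückel singularity at contact makes a bare charged state
   unstable): linear interpolation $U(\lambda_{\mathrm{elec}}) =
   \lambda_{\mathrm{elec}} U_{\mathrm{DH}}$ on a uniform 9-state schedule
   (step 0.125).

Both the exact soft-core form and the electrostatic interpolation are
deliberately isolated behind single functions (`pair_softcore()`, the
Debye--Hückel scaling) so they can be swapped; they are modelling
assumptions, not derived facts.

## Sampling

Configurations are generated by overdamped Langevin (Brownian) dynamics,

$$\Delta x = \frac{D}{kT} F \,\Delta t + \sqrt{2 D \Delta t}\;\xi,
\qquad \xi \sim \mathcal N(0, 1),$$

with one diffusion coefficient for all beads (production default
$D = 253$ nm²/s) and $\Delta t = 30$ ns, no hydrodynamic interactions, no
periodic boundaries.  Every alchemical state is sampled by independent
trajectories started from the assembled geometry, each with its own
deterministic seed derived from (base seed, state index, trajectory
index); the leading fraction of each trajectory (default 20%) is discarded
as equilibration, either as a fixed fraction or by a block-mean
changepoint detector.  Per-frame observables are $\partial U/\partial
\lambda$ at the sampling state and the $\lambda$-scaled cross-group energy
re-evaluated at *every* state of the stage, from which all
$\Delta U_{ij}$ follow.

**Desk-scale protocol.**  The production protocol (64 trajectories of 6 s,
i.e. $2\times10^8$ steps per trajectory per state) is cluster-scale.  The
package's tests and the acceptance script instead run toy systems
(8--15-bead proteins) with 4--8 trajectories of $10^5$--$4\times10^5$
steps per state, and rescale the diffusion coefficient tenfold
($D = 2530$ nm²/s).  For overdamped dynamics $D$ only sets the clock: the
stationary (Boltzmann) distribution is independent of it, so the rescaling
is a pure mixing-speed choice.  The stability constraint is
$k_{\max} D \Delta t / kT \ll 1$; at the stiffest default spring
(1000 kT/nm²) the rescaled product is 0.076.  The slowest relevant mode at
desk scale is the rigid-body reorientation of an anchored protein
(relaxation on the order of $3\times10^4$ steps after rescaling), which
sets the trajectory lengths above.

## Free-energy estimation

Three estimators are computed from the same sample sets:

* **TI**: trapezoid integration of $\langle\partial U/\partial\lambda
  \rangle$ (chosen over quadrature schemes for robustness; it slightly
  overestimates strongly curved integrands).
* **BAR**: the Bennett acceptance-ratio implicit equation per adjacent
  state pair, solved by monotone root finding to a residual below
  $10^{-10}$ kT.
* **MBAR**: the multistate self-consistency equations over all $K$ states
  (self-consistent iteration, with a BFGS pass on the convex MBAR
  objective if iteration stalls, then a polish back to $10^{-10}$), state
  1 pinned at zero.  The weight matrix also yields the row-stochastic
  phase-space overlap matrix; a minimum nearest-neighbour overlap around
  0.03 or less warrants a denser schedule.

Uncertainties are $\pm 1$ standard deviation across per-trajectory
replicate estimates, propagated in quadrature into stage sums and
$\Delta\Delta G$.  Convergence is assessed by re-estimating on the first
and last $f\%$ of every trajectory ($f = 10, \ldots, 100$): the
calculation is declared converged when both curves stay within
$\pm 0.1$ kT of the full-data estimate for $f \ge 50\%$ (the band and the
midpoint rule are configurable).  Samples are decorrelated by the frame
stride rather than an autocorrelation analysis.

The estimators are validated against oracles computed by independent code
paths: a 3-D harmonic well whose stiffness is switched $k_1 \to k_2$ by
linear interpolation ($\Delta G = \tfrac32 \ln(k_2/k_1)$ exactly, from the
Gaussian partition function) and a WCA bead radially tethered near a fixed
bead, whose coupling free energy is obtained by direct 3-D midpoint
quadrature of the configuration integral, refined until it changes by less
than $10^{-3}$ kT.

## What the synthetic generator does and does not emulate

`make_toy_protein()` builds deterministic bead clusters (spherical shells,
rods, discs) with ENM springs, assignable charges and a designated pocket;
`make_toy_ternary()` assembles two of them with a PROTAC.  These fixtures
reproduce the *structure* of the real calculation --- anchored pockets,
flexible linker, excluded volume, staged coupling --- at sizes where the
whole pipeline runs on one CPU in minutes.  They do not mimic real protein
shapes, surface complementarity, charge distributions, or the
order-of-magnitude larger bead counts of real target/E3 pairs (a 261-residue
kinase domain maps to 87 beads).  A passing toy-scale test therefore
demonstrates the correctness of the machinery and the qualitative physics
(steric penalties decaying with linker length, cycle closure), not
quantitative agreement with any experimental cooperativity --- which the
minimal force field is in any case not parametrized to deliver.

## Numerical choices and edge cases

* Units: nm, kT = 1, elementary charges, seconds.  Conversions (e.g. to
  kcal/mol) belong at the reporting layer.
* The sterics schedule implements the printed 13 intermediate values plus
  endpoints (15 states).
* Nonbonded attraction truncated at $3\sigma_{ij}$ without shift or
  long-range correction; Debye--Hückel is evaluated without cutoff (the
  systems are small and screening is exponential).
* $r = 0$: the plain WCA/LJ/DH forms refuse it (they diverge); the
  soft-core form is finite there for $\lambda < 1$, which is exactly why
  coupling uses it.
* Trailing partial residue triplets form their own bead rather than being
  dropped.
* The assembly shake runs at $\lambda = 0.98$ soft-core so that deep
  overlaps cannot produce unbounded forces; anchor rest lengths are fixed
  at placement, before the shake.
* Seeds: every trajectory seed is a deterministic function of (base seed,
  state index, trajectory index), kept below $2^{31}$.
* Trajectory persistence uses R's native serialization plus a plain-text
  observable export; the sample containers keep float64 observables and
  float64 coordinates (coordinates are cheap at toy scale).

## Known limitations

* No hydrophobic/implicit-solvation term and no angular or dihedral linker
  potentials (exit vectors, linker rigidity) --- the model cannot encode
  warhead-specific geometry, and nonspecific attraction alone is known not
  to reproduce experimentally optimal short linkers.
* ENM spring constants are not fitted bottom-up from atomistic data here;
  the defaults keep fixture proteins near-rigid and are fully
  configurable.
* BAR/MBAR need phase-space overlap; with the default schedule the
  overlap diagnostic should be inspected for any new system.
* Replicate uncertainties require at least two trajectories per state and
  understate the error when trajectories are shorter than the slowest
  relevant relaxation.
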