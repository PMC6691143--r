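---
title: "Dual-boost accelerated MD on desk-scale model systems: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-boost accelerated MD on desk-scale model systems: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boostmd)
```

## The method

Plain molecular dynamics spends almost all of its time inside free-energy
basins; transitions over barriers of several $k_BT$ are exponentially rare,
which is why processes such as peptide folding are out of reach of short
unbiased trajectories. Accelerated MD (aMD) attacks this without choosing a
reaction coordinate: wherever an energy $V$ falls below a threshold $E$, a
non-negative boost

$$\Delta V(V) = \frac{(E - V)^2}{\alpha + E - V}, \qquad V < E,$$

is added to the potential, raising basin floors while leaving everything at
or above $E$ untouched. The strength $\alpha$ (kcal/mol) controls how
aggressively the landscape is flattened beneath $E$: small $\alpha$ pushes
the modified surface toward a plateau at $E$, large $\alpha$ approaches
plain MD. The force on the modified surface is the unbiased force scaled by

$$\frac{dV'}{dV} = \frac{\alpha^2}{(\alpha + E - V)^2} \in (0, 1],$$

continuous at $V = E$.

`boostmd` implements the *dual-boost* variant: one boost on the dihedral
(torsion) energy $V_D$ with parameters $(E_D, \alpha_D)$ — torsional
rearrangement is the slow degree of freedom in folding — and a second,
gentler boost on the total potential $V$ with $(E_P, \alpha_P)$. The two
terms are composed additively,

$$\Delta V = \Delta V_P(V) + \Delta V_D(V_D),$$

and the integrator uses the exact analytic gradient of $V + \Delta V$:
$\nabla V' = s_P(V)\,\nabla V + (s_D(V_D) - 1)\,\nabla V_D$ with the two
scale factors $s_P, s_D$ as above. An alternative composition used by some
production codes — the dihedral-boosted energy fed into the total-potential
boost — is available as `dual_composition = "nested"`; the additive form is
the default because it is the bias the reweighting formula assumes, term by
term. Both compositions are finite-difference-checked against their own
$V'$ in the test suite.

### Threshold parameterization

The four parameters come from a short *unbiased* pre-run:

$$E_D = E_D' + a_1 N_{res}/5, \quad \alpha_D = a_1 N_{res}/5, \qquad
  E_P = E_P' + a_2 N_{atom}, \quad \alpha_P = a_2 N_{atom},$$

where $E_P'$ and $E_D'$ are the mean total and dihedral energies of the
pre-run and the conventional increments are $a_1 = 3.5$ and $a_2 = 0.2$
kcal/mol. Both thresholds sit exactly $\alpha$ above the sampled mean, so
the boost is active in the typical region and switches itself off during
high-energy excursions. The averaging window is a design choice the formulas
leave open: `average_energies()` discards the first half of the pre-run by
default (`burn_in_frac = 0.5`), since a pre-run that follows a heating ramp
needs equilibration; for a stationary series the choice is immaterial (a
property test asserts this).

For one-particle analytic systems the residue/atom counts have no physical
meaning, so `estimate_thresholds()` takes *effective* counts from the
caller. The double-well protocol below uses $N_{atom} = 25$
($\alpha_P = 5$ kcal/mol, comparable to the 6 kcal/mol barrier so the boost
flattens without erasing it) and the total-potential boost only, since
$V_D \equiv 0$ there and a dihedral boost would add a constant.

### Reweighting

Averages on the boosted ensemble are reweighted back to the canonical one
with the Boltzmann factor of the bias: frame $i$ carries weight
$w_i \propto \exp(\Delta V_i / k_B T)$. `frame_weights()` works in log
space with max-subtraction, so arbitrarily large finite biases cannot
overflow. For a single boosted trajectory the weighted-histogram estimator
reduces to exactly this one-window weighted histogram, which is what
`weighted_fes()` builds over two collective variables (canonically RMSD to
the native structure and radius of gyration $R_g$); multiple trajectories
are combined by concatenating series and bias energies. The free energy is
$F = -k_BT \ln p$, shifted so the occupied minimum is zero; empty bins are
`NA`, deliberately distinct from merely high-energy bins.

Exponential reweighting is noisy when $\mathrm{Var}(\Delta V) \gg (k_BT)^2$:
a few frames dominate. The package therefore reports Kish's effective
sample size $n_{\mathrm{eff}} = (\sum w)^2 / \sum w^2$ per bin and overall, and
accuracy statements are conditioned on per-bin $n_{\mathrm{eff}}$. Note that
$n_{\mathrm{eff}}$ does not discount time correlation between frames; the
trajectory-length and saving-interval defaults below were chosen with that
in mind. A second-order cumulant-expansion estimator (`cumulant_weights()`)
is available for high-variance cases; it is an extension, not part of the
source method.

## Model systems

The package's scope is the aMD machinery itself, verified end to end on
systems small enough that exact answers are available:

* **Double well** (`make_double_well`): $V(x) = h\,((x/w)^2-1)^2$, the
  minimal two-state system. Its canonical density is known by quadrature,
  so reweighting accuracy is checkable exactly.
* **Harmonic oscillator** (`make_harmonic`): Gaussian reference for
  integrator accuracy (equipartition, energy conservation) and for the
  plain-histogram limit of the FES builder.
* **Coarse-grained helix** (`make_cg_helix`): one bead per residue, a
  Gō-like model biased toward an ideal $\alpha$-helix C$_\alpha$ trace
  (radius 2.3 Å, rise 1.5 Å, twist 100°/residue). The energy decomposes
  into harmonic bonds ($r_0 = 3.8$ Å), harmonic pseudo-angles, periodic
  pseudo-dihedral terms $k_t(1 - \cos(\phi - \phi_0))$ with the minimum at
  the ideal-helix pseudo-dihedral — these torsions constitute $V_D$ — 12-10
  attractive wells on the native contacts of the reference (depth
  $\varepsilon$ at the native distance), and inverse-12 excluded-volume
  repulsion on all other non-adjacent pairs. Native contacts are derived
  from the reference with the same 7.0 Å / non-adjacent rule as the
  analysis module, so model and metrics are internally consistent.

No reduced model is prescribed by the dual-boost formulas themselves; all
CG parameters are this package's own choices. The defaults
($k_b = 100$ kcal/mol/Å$^2$, $k_a = 20$ kcal/mol/rad$^2$,
$k_t = 2$ kcal/mol, $\varepsilon = 3$ kcal/mol, $\sigma_{rep} = 4$ Å,
bead mass 110 amu) were fixed once, at design time, by two requirements: the
native helix must be thermally stable at 300 K (folded-basin RMSD
fluctuations ≈ 1 Å, $Q \approx 0.95$), and folding from the fully extended
chain must be observable within a few million 5-fs steps. A weaker first
guess ($\varepsilon = 1$, $k_t = 1$) left the native marginally stable at
300 K and was rejected during model design. With attraction restricted to
native contacts the model folds by a helix-zipper mechanism; its funnel is
far smoother than a real protein's, so passing the folding demo shows the
*pipeline* (thresholds → boost → dynamics → reweighting → metrics) is
correct, not that aMD folds real proteins — that claim belongs to all-atom
force fields outside this package's scope.

One caveat the distance-based model makes vivid: bonds, angles and contacts
are all mirror-symmetric, so the left-handed mirror helix satisfies every
contact ($Q = 1$) at RMSD ≈ 3 Å. Only the torsion term breaks chirality.
This is why the torsion gradient is finite-difference-checked exhaustively
in the tests: with a sign error there, every trajectory folds into the
mirror image.

## Dynamics

The integrator is BAOAB Langevin splitting — half-kick, half-drift,
Ornstein–Uhlenbeck velocity refresh, half-drift, half-kick — chosen for its
superior configurational sampling accuracy at practical timesteps. With
collision frequency $\gamma = 0$ and no boost it reduces exactly to
velocity-Verlet (a test asserts the one-step identity). Units are Å,
kcal/mol, ps, K, amu with $k_B = 0.0019872041$ kcal/mol/K and the standard
acceleration conversion 418.4 Å² amu ps⁻² per kcal/mol. The default
collision frequency is 1.0 ps⁻¹.

Heating is a linear ramp of the *thermostat target* from 0 K to the run
temperature over `heat_ramp_steps`, starting from zero velocities. (A
per-step velocity rescale to the instantaneous ramp temperature would pin
the kinetic energy to its mean and suppress the thermal fluctuations the
thermostat exists to maintain, so the ramped-target form was preferred.)

Timestep stability is governed by the stiffest term; for the CG helix the
bond frequency is $\omega = \sqrt{2 k_b \cdot 418.4 / m} \approx 28$
ps⁻¹, and the 0.005 ps default used in the helix protocols resolves that
period ~45-fold. The double-well protocols use 0.002 ps. Runs that exceed
the configurable energy ceiling abort with a truncated trajectory and a
diagnostic status rather than propagating non-finite coordinates.

Degenerate inputs: an exactly collinear chain start has undefined
pseudo-dihedrals; the torsion force there is exactly zero (both plane
normals vanish) and thermal noise immediately lifts the degeneracy. The
near-collinear transient produces briefly large torsion forces that the
friction and the default timestep absorb; all folding runs start this way
by design, and divergence has not been observed at the defaults.

`minimize()` follows the conventional two-phase protocol: a backtracking
steepest-descent phase into the local basin, then conjugate-gradient (with
a BFGS polish if the gradient norm target is still unmet). Energy is
non-increasing across accepted steps, and the result reports the achieved
gradient max-norm and convergence flag.

Determinism: the trajectory is a pure function of (seed, config, system).
All randomness flows from the single config seed through R's RNG, which the
compiled integrator also consumes; identical seeds give bit-identical
trajectories, and an aMD run whose thresholds lie below every sampled
energy is bit-identical to the unbiased run (both properties are asserted
in the tests).

## Analysis conventions

* **RMSD** (`superpose_rmsd`): Kabsch least-squares superposition with a
  proper rotation enforced ($\det R = +1$; mirror images are *not*
  superimposable). Near-collinear selections are computed with a warning
  since the rotation is ill-determined. Whether to fit on all beads or a
  sub-selection is a configuration choice; the CG protocols fit all beads.
* **Native contacts** (`native_contacts`): pairs of non-adjacent residues
  ($|i-j| \ge 2$; stricter separations selectable) strictly closer than
  7.0 Å in the reference. The fraction formed, $Q$, applies the same strict
  cutoff to each frame.
* **Radius of gyration**: mass-weighted RMS distance from the selection's
  center of mass.
* **Helix content** (`helix_content`): fraction of consecutive-quadruple
  pseudo-dihedrals within ±30° (circular) of the ideal-helix value. This is
  an operational trace-level definition chosen here — not a hydrogen-bond
  (DSSP-style) assignment, which a bead model cannot support.
* **Clustering** (`cluster_trajectory`): average-linkage agglomerative
  clustering on the pairwise superposed-RMSD matrix, populations sorted
  descending, representative = member minimizing mean RMSD to its cluster
  (ties to the earliest frame). Deterministic given frame order; the
  linkage name is recorded in the result.

## The frozen study protocols

The quantities reported by `scripts/acceptance.R` come from these
fixed protocols (sizes chosen once so each stage is statistically
meaningful at desk scale):

1. **Canonical recovery.** Double well $h = 6$ kcal/mol, $w = 2$ Å, 300 K:
   a 50 000-step unbiased pre-run parameterizes the boost
   ($N_{atom,\mathrm{eff}} = 25$); a $10^7$-step total-boost run saved
   every 50 steps is reweighted onto 70 bins over $[-3.5, 3.5]$ Å and
   compared with the quadrature PMF on bins with $n_{\mathrm{eff}} \ge 100$
   (observed agreement ≈ 0.2–0.4 $k_BT$; the *unweighted* boosted histogram
   underestimates the 10 $k_BT$ barrier by ≈ 4.3 $k_BT$, which is the
   flattening the reweighting must undo).
2. **Acceleration.** Mean first-passage steps from $x = -w$ to $x = +w$
   over 20 seeds, unbiased vs boosted: means differ by a factor of ~50–70
   with non-overlapping 95% confidence intervals.
3. **Folding demo.** 15-residue CG helix from the extended chain:
   minimization, 300-K heat ramp, unbiased pre-run for thresholds
   (defaults $a_1 = 3.5$, $a_2 = 0.2$), then five dual-boost runs of
   $2 \times 10^6$ steps. Success = median RMSD < 1.5 Å *and* median
   $Q > 0.8$ over the final 20% of frames; the reweighted (RMSD, $R_g$)
   surface must place the lowest free-energy state below 1.5 Å RMSD.
4. **Clustering recovery.** A planted 80/15/5 three-conformer mixture with
   0.15 Å jitter and random rigid placements must be recovered within 3
   percentage points per cluster.

## Known limitations

* The CG helix is a funneled Gō model: no non-native attractions, no
  solvent, no side chains. It validates the machinery, not protein folding.
* Exponential reweighting concentrates weight; for the helix demo the
  overall $n_{\mathrm{eff}}$ is a few percent of the frame count, which is
  typical of aMD and the reason the lowest-state criterion, not bin-wise
  PMF accuracy, is asserted there.
* Kish's $n_{\mathrm{eff}}$ ignores time correlation; qualifying-bin
  thresholds are conservative but not exact.
* The real-structure $R_g$ benchmark requires PDB files the package cannot
  redistribute; supply them locally (see the test file) to run it.
* No constraints, periodic boundaries, or long-range electrostatics: the
  model systems need none of them.
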