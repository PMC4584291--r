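---
title: "Ranking bilayer models against diffuse-scattering form factors"
author: "bilayerff"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking bilayer models against diffuse-scattering form factors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bilayerff)
```

## The model

A fluid lipid bilayer projected onto its normal is described by a
scattering-density-profile style decomposition: the total electron density
is

$$\rho(z) = \rho_W + \sum_g g(z) + (\rho_{HC} - \rho_W)\, s(z),$$

where each $g(z)$ is a mirrored pair of Gaussians (areal excess $a_g$,
center $\pm c_g$, width $\sigma_g$) describing one component group — the
phosphatidylcholine and phosphatidylethanolamine headgroups, the
carbonyl-glycerol backbone, the terminal-methyl trough (a *negative*
excess), and optionally a peptide — and $s(z)$ is an error-function slab of
half-width $D_C$ (the hydrocarbon half-thickness) and interfacial width
$\sigma_s$. Water is treated as excluded from the hydrocarbon slab and
unperturbed elsewhere: the solvent component is $\rho_W (1 - s(z))$ and the
Gaussian groups are *water-excess* densities that do not displace solvent.
This convention makes the density decomposition exactly consistent with the
closed-form transform below and pins the far field at $\rho_W$; treating
the Gaussian groups as solvent-displacing instead would cancel the
hydrocarbon contrast wherever the fill saturates, because the chain plateau
($\approx 0.30\ e/\text{Å}^3$) lies *below* bulk water
($0.333\ e/\text{Å}^3$).

The continuous cosine transform of the water-subtracted density has the
closed form

$$F(q_z) = \sum_g 2 a_g e^{-\sigma_g^2 q_z^2/2} \cos(q_z c_g)
  + 2(\rho_{HC} - \rho_W)\,\frac{\sin(q_z D_C)}{q_z}\, e^{-\sigma_s^2 q_z^2/2},$$

with $F(0)$ equal to the total areal electron excess. `model_form_factor()`
implements this expression; `profile_form_factor()` implements the same
transform by trapezoid quadrature of any binned profile. Their agreement —
relative error below $10^{-6}$ over random models, in practice
$\sim 10^{-13}$ — is the package's central oracle test, since the two paths
share no code.

## Scoring against experiment

Experimental diffuse-scattering form factors carry an unknown overall
scale. Following standard practice, an experimental curve is first
normalized so that the maximum of its *second* scattering lobe equals one
(`normalize_experimental()`), after which fixed uncertainties are assigned:
$\Delta = 0.05$ for $q_z < 0.6\ \text{Å}^{-1}$ and $0.1$ at or above it.
Lobes are numbered from low $q_z$; the leading interval truncated by the
beamstop cutoff is lobe 1. A minimum qualifies when a local minimum of
$|F|$ falls below a fraction (default 0.2) of the global maximum, because
diffuse data never reach exact zeros.

Each candidate model is interpolated linearly onto the experimental $q_z$
points, scaled by the weighted least-squares factor $a^{sim}$, and scored
by the reduced chi-square

$$\chi^2 = \frac{1}{N-1} \sum_{i=1}^N
  \left( \frac{|F^{exp}_i| - a^{sim} |F^{sim}_i|}{\Delta_i} \right)^2 .$$

$\chi^2$ is computed exactly as written (sum of squared weighted residuals
over $N-1$, no square root); because the printed typography of such
statistics is occasionally ambiguous, `chi_squared(variant = "root")`
exposes the square-root variant for sensitivity checks, and the analytic
two-point example ($a^{sim} = 1.1$, $\chi^2 = 16.0$) fixes the intended
reading. $\chi^2$ is invariant under any rescaling of the simulation (the
scale factor compensates exactly) and under joint rescaling of the
experimental amplitudes and their $\Delta$.

`scan_grid()` evaluates a candidate set over the standard grid —
$A_L \in \{62, 64, \ldots, 76\}\ \text{Å}^2$ and peptide depth
$z \in \{0, 5, 8, 10, 12, 14, 16, 18\}\ \text{Å}$ — aggregates replicates
by mean, flags cells with $\chi^2 \le 3.4$ (the cutoff is inclusive), and
reports the best cell, breaking exact ties toward smaller $z$ then smaller
$A_L$ so reporting is deterministic. For display, the best-fitting
simulation keeps absolute units ($e/\text{Å}^2$), the experiment is divided
by the best $a^{sim}$, and other simulations are multiplied by
$a^{sim}/a^{sim}(\text{best})$ (`scale_for_display()`).

## The synthetic-data generator

No deposited trajectories or reduced scattering curves accompany the
problem this package addresses, so the generator stands in for both, and
its defaults *are* the study conditions:

* **Composition**: 128 lipids (1:1 PC:PE), 2 or 4 peptides (mole fractions
  $x = 2/130 \approx 0.015$ and $4/132 \approx 0.030$), fixed transverse
  box $L_x L_y = (n_{lipids}/2) A_L$ as in a constant-area ensemble.
* **Geometry** (`dopc_dope_model()`): hydrocarbon volume per lipid fixed at
  $V_C = 973.5\ \text{Å}^3$, so $D_C = V_C / A_L$ — at
  $A_L = 66\ \text{Å}^2$, $2D_C = 29.5\ \text{Å}$ — with headgroup
  Gaussians riding $3.95\ \text{Å}$ above the hydrocarbon interface and the
  PC peak 2 Å further out than PE. These choices put the head-to-head
  spacing near $36.7\ \text{Å}$ at $A_L = 66\ \text{Å}^2$ and headgroup
  maxima near $0.44\ e/\text{Å}^3$, typical of fluid PC/PE bilayers.
  Component amplitudes (0.30/0.30/0.12/−0.28 $e/\text{Å}^2$) were set once
  to reproduce those features and are configurable.
* **Peptide**: a Gaussian of width 3 Å carrying 200 water-excess electrons
  per peptide (an arginine-rich 11-mer displaces roughly its own volume of
  water), centered at the prescribed depth. In trajectories the peptide is
  an 11-bead cluster whose center of mass jitters frame-to-frame with
  $\sigma = 1\ \text{Å}$ about the restraint target — emulating a stiff
  center-of-mass restraint with ~0.1 nm average displacement — rather than
  simulating the restraint dynamics.
* **Noise**: synthetic experiments add zero-mean Gaussian noise with the
  $\Delta$ magnitudes *in lobe-2-normalized units* (so 0.05/0.1 retain
  their meaning), floor the result at zero, and multiply by an arbitrary
  scale. The recorded `delta` is the applied standard deviation in output
  units.
* **Undulations**: a single bending mode along $x$,
  $u(x) = a\,\sin(2\pi x/L_x + \varphi)$, whose amplitude $a$ is drawn per
  frame from a zero-mean Gaussian with the configured RMS and whose phase
  is random — a thermally excited mode. The time-averaged smearing kernel
  then damps the form factor by
  $e^{-s} I_0(s)$ with $s = q_z^2 A^2/4$, which is strictly decreasing in
  the RMS amplitude $A$ at every $q_z$. A *fixed*-amplitude mode would
  instead give the oscillatory factor $J_0(q_z A)$, making the fit quality
  non-monotone beyond $q_z A \approx 2.4$; the fluctuating mode is both the
  physical picture and the simplest field that makes the
  artifact-diagnostic monotone.
* **Ions and water**: water beads (10 e) fill $\rho_W(1-s)$; chloride-like
  ions (18 e) sample the water distribution. Bead masses are proportional
  to electron counts (ratio 1.8, as for water and methylene), so mass- and
  electron-weighted profiles share peak positions by construction.

What the generator does *not* emulate: chain conformational disorder and
its order parameters, asymmetric leaflets, peptide aggregation, solvent
electrostriction, and the $q_z$-dependent correlations of real reduced
diffuse data (noise is independent per point). Passing tests therefore
demonstrate the correctness of the *pipeline* — transforms, scaling,
ranking, metrics — on data whose ground truth is known, not force-field
realism.

## Density profiles and structural metrics

Trajectory frames are recentered on the hydrocarbon (CH2+CH3) center of
mass before binning — computed as a circular mean over the periodic box, so
bilayers split across the boundary recenter correctly. The hydrocarbon
reference was chosen over the full-system center because it is insensitive
to peptide and solvent asymmetry. The leading fraction of frames (default
0.5) is discarded as equilibration; binned densities (default
$0.25\ \text{Å}$, fine enough to resolve sub-Å spacing shifts) are averaged
over the remainder, and `symmetrize_profile()` performs implicit leaflet
averaging before the cosine transform. Raw asymmetric profiles remain
available for diagnostics.

* $D_{HH}$ (`measure_dhh()`): distance between the two highest local maxima
  on opposite sides of the center, read from the symmetrized total profile;
  exact plateau ties resolve to the plateau midpoint. Resolution is one bin.
* $2D_C$ (`measure_hc_thickness()`): distance between the two half-plateau
  crossings of the hydrocarbon profile, with the plateau defined as the
  mean over the central 50% of the region between the crossings and solved
  self-consistently. For an error-function slab this recovers the
  generating half-width exactly (the erf is symmetric about its
  half-height); a deep central methyl trough biases the plateau estimate
  low and the crossings outward by a few tenths of an Å — a known
  limitation of half-height estimators, noted when interpreting absolute
  values. A Gibbs-dividing-surface integral would be the alternative
  estimator.
* $V_C$ = $A_L \cdot D_C$ (`hydrocarbon_volume()`), the hydrocarbon reading
  of the area–volume–thickness relation.
* Peptide depth (`peptide_depth()`): per-molecule time average of the
  absolute center-of-mass $z$ after recentering — the realized depth, not
  the restraint target, which is stored as metadata.
* Core occupancy (`core_occupancy()`): per-frame count of beads of a
  species with $|z|$ *strictly* below the threshold (default 5 Å), plus the
  fraction of frames with at least one such bead.

## Numerical choices

* Simulation form factors are evaluated on $q_z \in [0, 0.8]\ \text{Å}^{-1}$
  in steps of 0.005 (covering lobes L1–L4) and interpolated linearly to
  experimental points; extrapolation is refused. Synthetic experiments use
  $[0.1, 0.78]$, starting above a beamstop-like cutoff so that the first
  detected minimum is the physical M1.
* Trapezoid quadrature on profiles whose contrast decays smoothly to zero
  at the box edges is spectrally accurate; oracle tests use 0.05 Å bins
  and boxes with $\ge 8\sigma$ margins. Discontinuous (sharp-slab) profiles
  lose that accuracy — tests of sinc zeros use fine grids and loose
  tolerances accordingly.
* The amplitude, not signed $F$, is stored and compared throughout, and
  amplitudes are non-negative by construction.
* Degenerate inputs error loudly: grids that do not span the box,
  asymmetric grids fed to the symmetrizing transform, monotone form
  factors with no qualifying minima, unimodal profiles fed to
  `measure_dhh()`, all-zero simulation amplitudes, extrapolation requests,
  empty candidate sets.
* All randomness flows through one explicit seed per call
  (`generate_trajectory()`, `synthesize_experiment()`,
  `candidate_grid(jitter_sd > 0)`), restoring the caller's RNG state;
  identical seed and configuration give bit-identical output.

## Problem sizes

The shipped tests and the acceptance script run the whole study at sizes a
laptop handles in well under a minute per stage: 100 random models for the
oracle bound; 100 seeded replicates of the full $8\times 8$ grid recovery;
50 random models for estimator recovery; 10 paired replicates × 12 frames
per undulation amplitude (one seed shared across amplitudes, so the
thermal-mode amplitude scales proportionally within a replicate — a paired
design that removes almost all between-replicate variance from the rank
comparison); 40-frame trajectories of ~8500 beads for the density stages.

## Known limitations

* The toy trajectory is a sampling model, not dynamics: frames are
  independent draws, so autocorrelation-driven convergence questions (the
  reason repeat simulations matter for real MD) appear only through the
  explicit replicate machinery, not within a trajectory.
* Terminal-methyl beads sample the full slab (the sampling model carries no
  methyl trough), so trajectory-derived hydrocarbon profiles are
  flat-topped; the trough exists only in the parametric scattering models.
* The candidate family ties headgroup position rigidly to $D_C$; real
  bilayers decouple these somewhat under peptide stress.
* Ion beads follow the water distribution, so spontaneous core occupancy is
  essentially absent in toy data; the occupancy metric is exercised against
  hand-built and brute-force cases instead.
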