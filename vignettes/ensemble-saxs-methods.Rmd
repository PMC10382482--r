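---
title: "Methods: ensemble SAXS analysis of a metal-dependent oligomer equilibrium"
author: "saxsens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ensemble SAXS analysis of a metal-dependent oligomer equilibrium}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

A tagged single-chain antibody fragment (scFv) carrying a C-terminal
sortase/6xHis/TwinStrep extension populates, in the presence of Co^2+^,
an equilibrium between three structural states: a *closed* monomer with
the two variable domains (V~H~/V~L~) associated, an *open* monomer with
the domains dissociated, and a cobalt-stabilised *tetramer* held
together by a polyhistidine coordination core.  Small-angle X-ray
scattering (SAXS) measures the population-weighted average of these
states; the task of this package is to invert that average: given a
measured curve and a pool of candidate conformers, estimate which states
are present and in what proportions, and quantify the structural
features (metal sites, interfaces, hydrodynamic radii) that characterise
each state.

# The model

## Forward scattering

The orientation-averaged intensity of a rigid particle with scatterers
at positions $r_i$ and scattering lengths $f_i$ is the Debye sum

$$ I(q) \;=\; \sum_i \sum_j f_i f_j\,
     \frac{\sin(q\,r_{ij})}{q\,r_{ij}}, $$

with $I(0) = (\sum_i f_i)^2$.  `debye_profile()` evaluates this exactly
for small scatterer sets and through a pair-distance histogram
(bin width 0.1 Å, weighted mean distance per bin) for large ones; the
two paths agree to better than 0.1% over the default grid and the
binned path is itself tested against an independently coded brute-force
double sum.  Bead-level models use q-independent unit form factors.
Excluded-volume and hydration-shell contrast — the corrections an
atomistic predictor applies — are deliberately out of scope, which is a
known systematic difference from atomistic profiles and one reason
absolute goodness-of-fit values against experimental curves are
method-dependent.

## Ensemble optimisation

A measured curve from an equilibrium mixture is a weighted average of
state curves.  `run_eom()` selects a small sub-ensemble whose mean
theoretical profile best fits the target, using a genetic algorithm over
*multisets* of conformer indices: a chromosome is `ensemble_size`
(default 20) slots, each holding one pool member, so a conformer picked
$k$ times carries weight $k/20$ — weights are quantised at 1/20 = 5%.
Fitness is the reduced $\chi$ of the multiset-mean curve after a
closed-form scale/offset fit (2x2 normal equations).  Operators are
tournament selection (k = 3), per-slot uniform crossover (rate 0.5),
per-slot mutation to a uniform random pool member (rate 0.1), and
2-chromosome elitism, with early stopping after 100 stagnant
generations; `repeats` independent runs (default 10) are made and the
best kept.  On every instance small enough to enumerate, the GA optimum
is required to come within 2% of the exhaustive multiset optimum
(`eom_exhaustive()`), which is the package's primary correctness oracle
for the optimiser.

State populations are then simple arithmetic on the winning multiset:
the fraction of a state is the summed multiplicity of its conformers
over `ensemble_size`.  Confidence intervals come from a bootstrap over
the independent GA repeats, which captures selection stochasticity —
the dominant uncertainty — rather than per-point measurement noise.

## Primary reduction

* **Guinier.** Weighted least squares of $\ln I$ on $q^2$ over an
  automatic window grown from the lowest usable $q$ while
  $q_{\max} R_g \le$ 1.3 (configurable), then trimmed from the low-q
  side until a Wald–Wolfowitz runs test on the residual signs is
  non-significant at 5%; failure to stabilise flags the result rather
  than discarding it.
* **p(r) inversion.** `ift_pr()` solves the linear model
  $I(q) = \sum_k p(r_k)\,\mathrm{sinc}(q r_k)\,\Delta r$ with a
  second-difference smoothness penalty, fixed zeros at $r = 0$ and
  $r = D_{\max}$, and (by default) non-negativity through
  Lawson–Hanson NNLS on the stacked system.  The automatic
  regularisation weight is 0.01 times the ratio of the data-term to the
  penalty-term norms, which recovers the analytic sphere distance
  distribution to 0.2% L2 and keeps $\chi$ monotone in the weight.
* **D~max~ selection.** Scanning candidate supports and taking the
  smallest one whose unconstrained solution has no forced negative lobe
  proved insufficient on its own: a support 30% too small can keep
  p(r) positive while fitting the low-q region badly.  `select_dmax()`
  therefore also requires the candidate's $\chi$ to be within a factor
  2 of the best $\chi$ in the scan.  A user-supplied D~max~ always
  wins.
* **Molecular weight.** The volume of correlation
  $V_c = I(0) / \int q I\,dq$ needs no absolute calibration; mass is
  $V_c^2 / R_g$ divided by a protein-class constant.  Which estimator
  produced the reference MW values this analysis style usually reports
  is generally not stated by experimental papers, so the package
  documents its estimator explicitly, exposes a Porod-volume
  alternative behind a flag, and provides
  `calibrate_mw_constant()` to re-derive the constant for bead-level
  (unit form factor) profiles from solid-sphere models of known mass.
* **SEC-SAXS.** Frames are buffer-subtracted against the
  lowest-integral contiguous window (or a user range), Guinier-fitted
  frame by frame, and frames above 50% of the peak $I(0)$ are averaged
  with propagated uncertainties.  The 50% threshold is a simple,
  monotone, testable stand-in for the manual frame-range choices of
  interactive tools.

## Structure analysis

Metal sites are detected as N/O/S atoms within 2.8 Å of a metal ion
(typical first-shell Co^2+^–donor bonds are ~2.0–2.3 Å; the cutoff is
configurable), deduplicated into unique classes by their sorted
(residue name, atom name) donor signatures, and their coordination
geometry labelled by the ideal polyhedron (trigonal pyramidal, trigonal
bipyramidal, octahedral) minimising the donor–metal–donor angle RMSD
under the optimal donor-to-vertex assignment — enumerated exhaustively,
which is exact for coordination numbers up to 7 — with "other" beyond
25° RMSD.  Interface burial uses Shrake–Rupley SASA on a deterministic
Fibonacci sphere lattice (960 points/atom by default, converged to 1%
against a 10^4^-point reference) and reports the per-side buried area
$(S_A + S_B - S_{AB})/2$.  Hydrogen bonds use D–A ≤ 3.5 Å plus a
D–H···A ≥ 120° angle whenever the donor hydrogen is placeable from
ideal backbone geometry; side-chain donors, whose hydrogen positions
are rotamer-dependent, are accepted on distance alone, and all criteria
are echoed in the output because reported interface H-bond counts are
notoriously criteria-sensitive.  The His-motif scan reports maximal
runs of ≥ 4 consecutive histidines in author numbering (gaps in the
modelled sequence break runs), their metal contacts, and whether the
attached sites' coordinating residues fall within a 10-residue sequence
window (a *linear* motif, following the 3–10-residue convention for
short linear motifs) or not (*three-dimensional*).

Because the deposited crystallographic entry cannot be redistributed
with the package, the test bed for this machinery is
`synthetic_tetrhis_assembly()`: a geometric instantiation — explicitly
synthetic, not deposited coordinates — of the published coordination
*topology* of the cobalt tetramerisation motif: eight Co^2+^ in four
unique site classes (3/4/5/3 protein residues; trigonal bipyramidal
with two waters, octahedral with a bidentate glutamate and one water,
octahedral bridging three chains, trigonal pyramidal), all tag
histidines engaged except His271 of the first chain class, twofold
symmetry relating the two halves.  Donors sit exactly on ideal
polyhedron vertices, so detection, deduplication, geometry labels and
the His-contact pattern have unambiguous expected values.

## Hydrodynamics

`hull_rh()` reduces a model to one or two points per residue (beads
pass through; all-atom residues contribute CA plus the side-chain
centroid), takes the 3-D convex hull (quickhull, implemented in the
package and validated against analytic solids), converts the hull
volume to an equivalent-sphere radius, and multiplies by a single
hydration/shape expansion factor.  The factor (1.252) is calibrated
once, on a compact 269-residue bead globule whose reference R~h~ comes
from the empirical globular-protein scaling
$R_h(\mathrm{nm}) = 0.774\,M(\mathrm{kDa})^{1/3}$ (reproducing
lysozyme), and is recorded in every result; `calibrate_hull_expansion()`
re-derives it.  A single multiplicative constant was chosen over a full
empirical recipe because published hull-based recipes vary by version;
the cost is that absolute R~h~ values carry ~10% systematic
uncertainty, while state *ordering* (closed < open < tetramer) is
robust.  `stokes_einstein()` interconverts R~h~ and the translational
diffusion coefficient.

# The synthetic-data generator

`generate_pool()` emulates the statistical structure of an MD-derived
conformer pool at bead level (one bead per residue), which is all the
ensemble-optimisation stage consumes:

* two self-avoiding 115-residue globular domains at protein packing
  density (134 Å^3^/residue), giving domain radii of ~15.4 Å and
  domain R~g~ of ~12 Å, Ig-domain scale;
* a closed state generated at 25 Å centroid separation and an open
  state at 50 Å (each with ±10% per-conformer jitter, centroids
  re-centred exactly), on opposite sides of the 30/45 Å classifier
  thresholds with a deliberate gap so ground-truth labels are
  unambiguous;
* a 39-residue self-avoiding C-terminal tail with fixed 3.8 Å virtual
  bonds (mean end-to-end ~34 Å, cross-checked against an independent
  walk-simulation oracle and above the freely-jointed baseline, i.e.
  mostly extended — the disordered-tail behaviour seen in such
  constructs);
* tetramers as four copies of a closed protomer around a z axis
  (C2-symmetric by construction), tails drifting toward the axis under
  a hard cylindrical bound that leaves an axial channel; the default
  channel width of 12 Å sits in the experimentally indicated 10–20 Å
  range and, together with the domain dimensions, yields tetramer
  model R~g~ of ~33–34 Å, inside the 32–36 Å band expected for the
  completed crystallographic tetramer;
* measurement noise $\sigma(q) = (a + b I(q))(1 + c q)$ with defaults
  $a = 0.002\,I(q_{\min})$, $b = 0.01$, $c = 2$ Å — a simple
  monotone-in-q relative error like synchrotron data.

Every generator is a pure function of (spec, seed); per-conformer seeds
are drawn once from the pool seed and recorded in the manifest.

What the generator does **not** emulate: atomistic side-chain packing,
force-field energetics, metal-site chemistry (the tetramer is rigid by
construction, not held by modelled coordination), interparticle
interference, and the concentration-dependent aggregation visible in
real titrations.  Passing tests on this pool therefore demonstrate that
the *analysis chain* is correct and well-calibrated on data with the
right geometric and statistical structure, not that any particular
experimental curve would be fit with a given $\chi$.

# Numerical choices and degenerate inputs

* Distances in double precision; the exact O(n²) Debye path remains
  available as an oracle at any size.
* Altloc handling on reading: highest occupancy wins, ties broken
  alphabetically.  Assembly chain renaming: the first operator keeps
  original identifiers, the n-th appends "-n"; PDB output remaps
  multi-character chains to letters with a warning, mmCIF preserves
  them.
* Improper rotations (det ≠ +1 within 1e-6) are rejected as assembly
  operators; degenerate (coplanar) point sets are rejected by the hull
  with a named error; constant model curves are rejected by the
  scale/offset fit; an ill-conditioned p(r) system reports its
  condition number.
* The Guinier shape bias: for conformers with long disordered tails the
  Guinier estimand at any window with $qR_g \le 1$ sits up to ~3–5%
  below the mass-weighted coordinate R~g~ (verified against the
  coordinate oracle; the bias persists as the window shrinks, so it is
  the approximation itself, not range selection).  Class means agree
  with coordinate R~g~ within 2%; individual tailed conformers within
  5–7%.  Recovery under the noise model is unbiased where the Guinier
  model is exact.
* Closed-versus-open population splits from ensemble optimisation carry
  roughly ±0.1 uncertainty at SEC-SAXS-like noise, because mixtures of
  closed and open monomer curves are nearly colinear at these noise
  levels; the tetramer fraction, whose curve differs strongly in both
  I(0) and shape, is recovered essentially exactly.  The planted-weight
  monotonicity of the tetramer fraction is exact (Spearman 1) across
  the 0–0.5 grid.

# Problem sizes

The shipped tests and the acceptance script run on deliberately modest
sizes chosen to exercise every code path at full fidelity: pools of
60–100 conformers (30/15/15 to 50/25/25 across the three states, about
1/30 of an MD-scale pool), 301-point q grids over 0.005–0.5 Å^-1^,
GA settings of 2–5 repeats and 200–400 generation caps (the
exhaustive-oracle instances use pool 12, ensemble 3), 20-seed ensembles
for model R~g~/R~h~ means, and 70-frame SEC series.  All stochastic
stages take explicit seeds and reproduce bitwise.

# Known limitations

* Bead-level forward scattering cannot reproduce atomistic
  goodness-of-fit values; $\chi$ values are comparable within this
  package's conventions (reduced $\chi$, free scale and offset) only.
* The synthetic cobalt assembly reproduces a coordination topology for
  testing detection logic; it is not a substitute for deposited
  coordinates, and quantities that depend on real atomic detail
  (interface areas and hydrogen-bond counts of a specific crystal) are
  validated on analytic and constructed fixtures instead.
* Absolute hull R~h~ carries the calibration uncertainty of the single
  expansion factor (~10%); comparisons across states are much tighter.
* The fraction estimator quantises at 1/ensemble_size; fractions should
  be reported to no better than ~5% with the default ensemble size.
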