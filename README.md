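# saxsens

Ensemble-based small-angle X-ray scattering (SAXS) analysis of
metal-dependent protein oligomerisation, in R.

## The problem

Single-chain antibody fragments (scFvs) carrying a C-terminal
sortase/6xHis/TwinStrep tag can populate an equilibrium between a
*closed* monomer (V_H and V_L domains associated), an *open* monomer
(domains dissociated, disordered tail extended), and a cobalt-stabilised
*tetramer* held together by a polyhistidine coordination core.  A SAXS
curve measured on such a sample is the population-weighted average of
the state curves.  `saxsens` inverts that average and quantifies the
states themselves.  It is aimed at structural biologists who have (a)
1-D SAXS profiles (batch or SEC-SAXS), (b) a pool of candidate
conformers (from MD, modelling, or the package's own generator), and
optionally (c) crystallographic coordinates of an oligomeric assembly.

## What is inside

* **Forward scattering** — Debye-equation profiles from coordinates,
  `I(q) = sum_ij f_i f_j sinc(q r_ij)`, with an exact path and a
  histogram-binned fast path (agreeing to 0.1%); coordinate-space Rg
  and p(r).
* **Ensemble optimisation** — a genetic algorithm over *multisets* of
  pool conformers (size-K chromosome = weights quantised at 1/K);
  fitness is the reduced chi of the multiset-mean curve after a
  closed-form scale/offset fit; exhaustive multiset search as an
  independent optimum oracle on small instances; population fractions
  with bootstrap confidence intervals over GA repeats.
* **Primary reduction** — Guinier fits with automatic window selection
  (runs-test residual screening), Kratky transform, regularised
  non-negative p(r) inversion with Dmax scanning, volume-of-correlation
  molecular weight, buffer subtraction, SEC-SAXS frame analysis.
* **Synthetic data** — a bead-level generator for labelled conformer
  pools (closed/open two-domain monomers with self-avoiding 39-residue
  tails, C2-symmetric tetramers with an axial channel) and noisy
  mixture curves with known ground truth, so the whole chain is
  testable end to end.
* **Structure analysis** — metal coordination-site detection and
  geometry classification (angle-RMSD versus ideal polyhedra under
  optimal assignment), unique-site deduplication by donor signature,
  Shrake-Rupley buried interface areas, hydrogen bonds, polyhistidine
  motif scanning.
* **Hydrodynamics** — convex-hull (quickhull) hydrodynamic radii and
  Stokes-Einstein conversion.
* **Pipeline** — `run_pipeline()` drives pool -> target -> ensemble
  optimisation -> state populations (plus structure/hydro reports) from
  one YAML config with full seed provenance; a thin CLI wrapper lives
  in `inst/cli/saxsens.R`.

## Worked example

Simulate a known 55/15/30 closed/open/tetramer mixture and recover it:

```r
library(saxsens)

pool <- generate_pool(c(closed_monomer = 30, open_monomer = 15,
                        tetramer = 15), seed = 7)
#> <ensemble_pool> 60 conformers (closed_monomer: 30, open_monomer: 15,
#>                 tetramer: 15), profiles precomputed

truth  <- mixture_truth(c(closed_monomer = 0.55, open_monomer = 0.15,
                          tetramer = 0.30), seed = 2)
target <- simulate_experiment(pool, truth)

guinier_fit(target)
#> <guinier_result> Rg = 33.05 +/- 0.36 A, I(0) = 3.99e+05, 19 pts,
#>                  q [0.0100, 0.0396]

fit <- run_eom(pool, target,
               ga_params(ensemble_size = 20, repeats = 5,
                         generations = 400, patience = 80, seed = 3))
#> <eom_result> chi_EOM = 1.0617 (best of 5 repeats), 16 distinct model(s)

population_fractions(fit, classify_pool(pool), seed = 4)
#> <population_estimate>
#>   closed_monomer   60%  [52%, 60%]
#>   open_monomer     10%  [10%, 18%]
#>   tetramer         30%  [30%, 30%]

hull_rh(build_tetramer(seed = 1))
#> <hydro_result> Rh = 4.84 nm (hull volume 241638 A^3)
```

Reading of the numbers: the mixture's apparent Rg (33 A) sits between
the monomer (~20-23 A) and tetramer (~34 A) values, as expected for an
average; the ensemble fit reaches chi_EOM ~ 1 (noise-level agreement)
and returns the tetramer fraction exactly (weights are quantised at
1/20); the closed/open split is the soft direction, recovered here to
within 5 percentage points.  The tetramer model's hydrodynamic radius
(~4.8 nm) exceeds the closed monomer's (~2.7 nm), the ordering a
cobalt titration by dynamic light scattering shows.

Structure reports run the same way on any PDB/mmCIF model:

```r
m <- synthetic_tetrhis_assembly()     # synthetic test assembly
sites <- find_metal_sites(m, cutoff = 2.8)
length(sites)                          # 8 cobalt ions
length(attr(sites, "classes"))         # 4 unique site classes
his_motif_scan(m)                      # His271-276 runs + contacts
```

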