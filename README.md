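# hydrodecomp

Component-wise analysis of hydration free energies for rigid non-polar
solutes, aimed at people who work with explicit-solvation free-energy
decompositions or parameterize the non-polar term of implicit
(Poisson–Boltzmann style) solvation models.

The central object is the additive decomposition, all terms in kcal/mol:

```
ΔA_hyd = E_reorg + ΔA_ES + ΔA_disp + ΔA_cav
       = E_reorg + ΔA_ES + ΔA_nonES,      ΔA_nonES = ΔA_disp + ΔA_cav
```

with `E_reorg` the solute's internal reorganization energy, `ΔA_ES` the
electrostatic solute–water contribution, `ΔA_disp` attractive van der
Waals, and `ΔA_cav` the cavity-formation cost. Around that identity the
package provides:

- **Component tables** — a fixed CSV schema, a loader that normalizes
  typeset minus signs, exact recomposition (`compose()`), and a
  consistency check against printed totals (`check_consistency()`); an
  eight-solute aromatic-hydrocarbon table ships as a fixture.
- **Linear-response fits** — origin-constrained (`fit_through_origin()`,
  slope `Σxy/Σx²`) and ordinary (`fit_ordinary()`) regressions of
  free-energy components on ensemble-averaged interaction energies, plus
  the scaling rule `lrt_scale()` (α = 0.5 theoretical, 0.41 global fit,
  1 for dispersion).
- **Surface areas** — a deterministic Shrake–Rupley engine
  (`shrake_rupley_asa()`; golden-spiral lattice, Bondi radii, 1.4 Å probe)
  with XYZ/PDB readers.
- **Non-electrostatic models** — frozen ASA-linear parameterizations
  `pb_original_model()` (`0.005·ASA + 1.09`) and `pb_modified_model()`
  (`−0.0131·ASA + 4.92`, the refit line `−0.0131·ASA + 3.56` with a
  +1.36 kcal/mol electrostatic-offset correction), refitting
  (`refit_non_es()`), electrostatic rescaling between linear-response
  coefficients (`rescale_es()`), full prediction
  (`predict_hydration()`), and MAE/RMSE scoring (`score_predictions()`).
- **WCA splitting** — `wca_split()` divides a Lennard-Jones potential at
  its minimum into purely repulsive and purely attractive branches, the
  protocol that separates cavitation from dispersion.
- **Synthetic data** — a seeded generator (`generate_solute_set()`) that
  emulates the statistical structure of explicit-solvation component
  tables, so every estimator is validated by parameter recovery.
- **Pipeline** — `run_pipeline()` ties the stages together and writes
  deterministic CSV/JSON artifacts; a thin CLI with subcommands
  (`asa`, `check`, `fit-lrt`, `simulate`, `predict`, `run`) is installed
  at `system.file("cli", "hydrodecomp", package = "hydrodecomp")`.

## Worked example

```r
library(hydrodecomp)

tab <- load_component_table(system.file("extdata",
  "aromatic_components.csv", package = "hydrodecomp"))
check_consistency(tab)
#> <consistency_report> 8 record(s), tol 0.015 kcal/mol: 0 flagged, max deviation 0.0100
#>           name dA_hyd_printed dA_hyd_computed deviation flagged
#> 1      Benzene          -1.14           -1.13 1.000e-02   FALSE
#> ...
#> 7       Pyrene          -4.67           -4.67 1.776e-15   FALSE
```

Every solute's components recompose to its printed total within 0.015
kcal/mol; the 0.01 deviations are exactly what independent rounding of the
columns to 0.01 kcal/mol produces, so the table is internally consistent.

```r
benz <- assign_radii(read_coordinates(system.file("extdata",
  "geometries", "benzene.xyz", package = "hydrodecomp")))
shrake_rupley_asa(benz)
#> <asa_result> benzene: total ASA 243.35 A^2 (probe 1.40 A, 960 points, 12 atoms)
```

243 Å² is benzene's accessible area under Bondi radii and a 1.4 Å water
probe. Feeding package-computed areas into the refit non-electrostatic
line *without* the offset correction reproduces the table's
explicit-solvation totals to about half a kcal/mol:

```r
geoms <- system.file("extdata", "geometries", package = "hydrodecomp")
tab$asa <- asa_for_files(file.path(geoms,
  paste0(tolower(tab$name), ".xyz")))$asa
p <- predict_hydration(tab, non_es_model(-0.0131, 3.56, "uncorrected"))
score_predictions(p$dA_hyd_pred, tab$dA_hyd)
#> <error_report> MAE 0.4960, RMSE 0.5563 kcal/mol (n = 8)
```

The offset-corrected `pb_modified_model()` (intercept 4.92) is the right
choice when the electrostatic component comes from a continuum solver,
whose systematic offset the correction is built to cancel; here `dA_es`
is an explicit-solvation value, so the uncorrected intercept applies.
The residual half-kcal/mol reflects that the packaged geometries and this
ASA engine are not the (unpublished) ones behind the frozen coefficients.

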