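# osteofa

Bilateral asymmetry analysis of developing long bones: geometric
measurement of paired left/right 3D bone surfaces, estimation and
classification of fluctuating / directional asymmetry / antisymmetry, the
FA6 developmental-instability index, and stage-wise trajectory analyses —
with a synthetic-data generator so the whole pipeline is testable without
scan data.

## Who this is for

Morphologists and evo-devo researchers quantifying left–right asymmetry in
paired skeletal elements (the motivating system is the prenatal bat
humerus, measured for bone elongation and cross-sectional thickening), and
anyone who needs a reproducible, scriptable version of the classical
sides-ANOVA / FA-index workflow starting from STL surface models or plain
paired-trait CSV tables.

## The model in brief

For each specimen and trait with right/left values $R, L$:

- signed asymmetry $D = R - L$ (sign = directionality);
- size-corrected asymmetry $a = (R - L) / (0.5\,(R + L))$;
- FA6 index $= \operatorname{var}(a)$ across a population (sample
  variance), the size-controlled magnitude of fluctuating asymmetry used
  as a developmental-instability index;
- sides ANOVA `value ~ individual * side`: the *side* main effect tests
  directional asymmetry (DA), the *individual × side* interaction carries
  fluctuating asymmetry (FA), with mixed-model F ratios
  ($F_{side} = MS_{side}/MS_{int}$);
- distribution-based classification of the asymmetry regime:
  FA = normal, mean 0; DA = normal, mean ≠ 0; AS = bimodal (two-component
  normal mixture preferred by BIC margin ≥ 6 with separated modes);
- stage-wise trajectories: per-stage FA6, one-way ANOVA of $|a|$ on
  developmental stage, OLS decoupling test of cross-sectional vs
  longitudinal $|a|$, and sampling-bias regressions.

Geometry from meshes: rigid principal-axes alignment → bounding-box
humeral length (HL) → midshaft (50% HL) plane section → mirror right
sections across the antero-posterior axis (matching symmetry) → 16
equiangular radial landmarks from the area centroid → cortical thickness
(CT) = mean of the 8 opposite-landmark diameters.

## Worked example

```r
library(osteofa)

# a cohort with a known directional asymmetry: mu_a = 0.05, sigma_a = 0.02
cfg <- sim_config(asym_mode = "DA", mu_a = 0.05, sigma_a = 0.02,
                  replicates = 2, seed = 42)
sim <- simulate_measurement_table(cfg)

sides_anova(sim$table, "hl_mm")
#>              term  Df        SS        MS       Rsq         F         p
#> 1      individual  59 1.721e+03 2.917e+01 9.969e-01        NA        NA
#> 2            side   1 3.725e+00 3.725e+00 2.157e-03 1.312e+02 1.246e-16
#> 3 individual:side  59 1.675e+00 2.839e-02 9.701e-04 3.533e+27 0.000e+00
#> 4       residuals 120 9.643e-28 8.036e-30 5.585e-31        NA        NA
```

The individual term absorbs ~99.7% of raw variation (specimens differ in
size), and the side effect is decisively significant
(p ≈ 1e-16): the injected DA is detected. The interaction F is enormous
only because the simulated replicates carry zero measurement error.

```r
p <- paired_from_table(sim$table, "hl_mm")
classify_asymmetry(p$a)
#> <asymmetry_classification> DA (n = 60, mean = 0.05172, t p = 4.88e-30,
#>                            SW p = 0.625, dBIC = -7.26)
fa6_index(p$a)
#> [1] 0.0003341033   # ~ sigma_a^2 = 4e-04
decoupling_analysis(sim$table)
#> slope -0.047, R^2 0.002, p 0.712, n 60  (traits independent, as simulated)
```

The classifier recovers the regime (normal, mean ≈ 0.05 → DA), FA6
recovers $\sigma_a^2$ up to sampling noise, and the decoupling regression
is flat because the per-trait asymmetries were drawn independently.

## Command line

```sh
Rscript inst/exec/osteofa simulate --seed 1 --out out/            # cohort CSVs
Rscript inst/exec/osteofa measure  --manifest pairs.csv --out out/ # STL -> CSV
Rscript inst/exec/osteofa analyze  --input out/measurements.csv --out out/
Rscript inst/exec/osteofa report   --input out/measurements.csv --out out/
```

(after installation the script is at `system.file("exec", "osteofa",
package = "osteofa")`). `analyze` writes the two sides-ANOVA tables, the
per-stage series, the classification JSON and a combined `report.json`;
`report` adds box/bar plots.

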