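# aeromode

Eigenmode feature extraction and supervised classification of exhaled
aerosol images for grading small-airway obstruction.

## What it does

An exhaled-aerosol breath test reads lung structure from the deposition
pattern that inhaled tracer particles leave after a breath maneuver: a
constriction in the seventh- to ninth-generation bronchioles perturbs
the expiratory flow and leaves a weak, condition-entangled signature on
the exhaled image. `aeromode` implements the image-analysis pipeline
for a five-class grading of that signature (classes A0 normal through
A4 near-total occlusion, parameterized by the minimum bronchiolar
cross-section):

* **Snapshot assembly** — images are flattened to columns and stacked
  in disease-progression order A0→A4 within each (flow rate, particle
  size, replicate) condition group, so disease growth is treated as a
  five-step dynamical process: `X'' ≈ A X'` with `X'` the stage-0..3
  and `X''` the stage-1..4 columns.
* **Four SVD-based mode extractors** — POD (left singular vectors of
  the raw matrix), PCA (after mean removal), exact DMD (eigenmodes
  `Φ = X'' V Σ⁻¹ W` of the fitted progression operator, with discrete
  eigenvalues `λ` and continuous eigenvalues `ω = log(λ)/(2π)`), and
  DMDC (`X'' ≈ A X' + C Y`, separating intrinsic dynamics from the
  effect of the controls: particle size, flow rate, constriction
  severity).
* **Feature tables** — least-squares projections of every image onto
  the leading `r` modes (σ-ranked for POD/PCA, amplitude-ranked for
  DMD/DMDC), swept over r ∈ {3, 5, 10, 25, 50, 75, 100}.
* **Classification** — random forest (1000 trees) and radial-kernel
  SVM under stratified ten-fold cross-validation with repeats,
  reporting mean accuracy, dispersion, pooled confusion matrices and
  pairwise misclassification rates that sum exactly to one minus the
  accuracy.
* **Synthetic data generator** — the study's image database is not
  available in machine-readable form, so the package ships a generator
  that reproduces its structure (405 images = 5 classes × 3 flow rates
  × 9 particle sizes × 3 replicates) with *planted* linear latent
  dynamics, known control operator, and factor periodicities 3/5/9
  recoverable as DMD spectrum peaks — giving every stage of the
  pipeline an exact ground truth to be tested against.

## Worked example

```r
library(aeromode)

# a reproducible synthetic dataset with planted dynamics
# (default 128 x 128 pixels, 405 images)
cfg <- generator_config(seed = 11)
d   <- generate_dataset(cfg)
nrow(d$manifest)
#> [1] 405

# snapshot arrangement and transition split
snap  <- assemble_snapshots(d)
split <- split_transitions(snap)
y     <- build_control_matrix(split)

# dynamic mode decomposition of the disease progression: the three
# dominant amplitude peaks sit at the planted factor periods 5, 9, 3
b <- dmd(split$x_prime, split$x_dprime, r = 100)
spectrum_peaks(b)
#>    frequency    period amplitude
#> 1 0.19900774  5.024930 0.2725916
#> 2 0.09289121 10.765282 0.2451039
#> 3 0.32817378  3.047166 0.2406823

# noiseless data recover the planted eigenvalues to machine precision
cfg0 <- generator_config(image_height = 48, image_width = 48, seed = 5,
                         noise_sd = 0, group_sd = 0)
d0 <- generate_dataset(cfg0)
s0 <- assemble_snapshots(d0)
s0$values <- s0$values - d0$ground_truth$mean_pattern
sp0 <- split_transitions(s0)
fit <- dmdc(sp0$x_prime, sp0$x_dprime, build_control_matrix(sp0), r = 8)
max(abs(sort(Mod(fit$basis$eigenvalues)) -
        sort(Mod(d0$ground_truth$eigenvalues))))
#> [1] 8.881784e-16

# classification sweep (5 repeats of stratified ten-fold CV)
cv  <- cv_config(repeats = 5, seed = 7)
rep <- mode_sweep(d, methods = c("pod", "dmd"),
                  classifiers = c("rf", "svm"),
                  r_list = c(25, 100), config = cv)
rep[, c("method", "classifier", "r", "mean_acc", "sd")]
#>   method classifier   r  mean_acc          sd
#> 1    pod         rf  25 0.8859259 0.006148099
#> 2    pod         rf 100 0.8780247 0.011659969
#> 3    pod        svm  25 0.8790123 0.006295086
#> 4    pod        svm 100 0.8632099 0.009968706
#> 5    dmd         rf  25 0.9555556 0.003904046
#> 6    dmd         rf 100 0.9698765 0.002065827
#> 7    dmd        svm  25 0.9091358 0.005352959
#> 8    dmd        svm 100 0.8479012 0.006895921
```

The mode projections of the dynamic extractors carry markedly more
class signal than the static ones (DMD-RF 0.97 vs POD-RF 0.88 at
r = 100 above), the random forest outperforms the SVM for every
feature method, and misclassification concentrates on the
neighbouring severe classes (A2–A3 and A3–A4) — the pairs whose
airway dimensions differ least (1.13 vs 0.87 mm diameter, a 23%
difference, for A2–A3) — while the normal class A0 is essentially
never confused with a diseased one.

An end-to-end run (generate → decompose → classify → report, with
figures, CSV/JSON reports and a run manifest) is one call:

```r
cfg <- pipeline_config(out_dir = "run1", seed = 1,
                       generator = list(), profile = "quick")
run_pipeline(cfg)
```

or, from a shell, via the thin CLI wrapper
`inst/cli/aeromode.R <run|generate|decompose|classify|report>
--config cfg.yaml --seed 1 --out run1`.

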