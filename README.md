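# pectseg

Uncertainty-aware semi-supervised segmentation of the pectoral muscle in
medio-lateral-oblique mammograms, exercised end to end on synthetic
phantom mammograms.

## The problem and the method

The pectoral muscle appears as a bright wedge in the upper-left corner of
an MLO mammogram and must be removed before most computer-aided breast
analyses. Its boundary is crisp on some image rows and blurred or
invisible on others, and models trained at one imaging center degrade at
another. `pectseg` implements a consistency-regularization scheme that
uses unlabeled images from the shifted domain while protecting the
student from its teacher's mistakes:

* **Mean teacher.** A student U-Net `f(., theta)` minimizes
  `L = E_xs ||f(A(xs), theta) - ys||^2 + E_xu ||f(A(xu), theta) - ybar||^2`,
  where `A` is a random intensity perturbation and the teacher weights
  `theta'` are an exponential moving average of the student's.
* **Row-based confidence.** The pectoral boundary crosses each properly
  oriented row at most once, so confidence is per row: snapshots of the
  teacher saved every few epochs predict each unlabeled image, the binary
  Shannon entropy of their vote marks disagreement, and a white top-hat +
  coherence-enhancing shock filter + largest-connected-component chain
  selects the thin ridge of a clearly visible boundary. Rows crossing the
  ridge are high-confidence (`beta_h`); the rest are low-confidence
  (`beta_l`).
* **Low-confidence refinement.** A conditional generator (input: the
  high-confidence prediction `yu * beta_h`, the row indicator, and a
  coarse breast mask) learned the pectoral shape prior from annotations
  with random row erasures, adversarially against a Wasserstein critic
  with gradient penalty
  (`D(fake) - D(real) + 10 (||grad D(xhat)|| - 1)^2`). The composed
  target is `ybar = yu * beta_h + g * beta_l`.

Evaluation uses Dice, IoU, the exact Hausdorff distance, and the
unacceptable-segmentation ratio (fraction of cases with Dice < 85%).

Everything — including the phantom generator whose blurred rows genuinely
lose their boundary evidence, the networks, and their gradients — is
implemented in the package; no training data or framework downloads are
involved.

## Worked example

```r
library(pectseg)

# a phantom with an invisible boundary on rows 20-40
ph <- generate_phantom(phantom_spec(seed = 7, blur_rows = 20:40, gland_n = 2))
table(ph$clarity)
#> blurred   sharp
#>      21      43

# the full three-regime comparison at desk scale (a few minutes on 1 CPU)
ex <- run_experiment(experiment_config(), seed = 1)
ex$comparison
#> # A tibble: 3 × 7
#>   regime       mean_dice mean_iou mean_hausdorff ousr_count ousr_ratio     n
#>   <chr>            <dbl>    <dbl>          <dbl>      <int>      <dbl> <int>
#> 1 supervised       0.826    0.706           19.3          5      0.625     8
#> 2 mean_teacher     0.849    0.738           33.1          4      0.5       8
#> 3 ours             0.850    0.740           17.1          3      0.375     8
```

The test split is heavily blurred (emulating a second data center), so
the supervised baseline misses the invisible boundary segments; the
mean teacher learns from the unlabeled blurred images but inherits some
of its own errors through consistency training (note its occasional
large Hausdorff outliers); the uncertainty-aware regime replaces
low-confidence teacher rows with shape-prior fills, matching or beating
the mean teacher on overlap while cutting the worst-case boundary
distance and the number of unacceptable (Dice < 85%) cases. Exact
numbers vary with the seed; `autoplot(ex)` draws the comparison,
`tidy(ex$states$ours)` returns the per-epoch loss table.

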