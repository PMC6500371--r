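# sargnet

Pixel-level detection of pelagic *Sargassum* along Caribbean coastlines
from MODIS corrected reflectances.

Massive drifting mats of the brown macroalgae *Sargassum fluitans* /
*S. natans* have been washing ashore in the Mexican Caribbean since 2015,
with serious ecological and economic consequences. At 1-km MODIS
resolution a coastal pixel's spectrum barely changes when *Sargassum* is
present — the separability lives in small shifts of the 859 and 1240 nm
bands — so presence/absence calling is a genuinely hard classification
problem. This package implements, as plain R with no deep-learning
framework dependency, the classifier suite used to attack it:

* **ERISNet** — a 1D convolutional-recurrent network over the 14-element
  reflectance vector (surface reflectance ρs and top-of-atmosphere
  reflectance ρt at 412, 469, 555, 645, 859, 1240, 2130 nm): nine conv
  blocks repeating the (64 filters × 8), (128 × 5), (128 × 3) motif, each
  conv → ReLU → batch norm → dropout with an L2 kernel penalty, then two
  64-unit LSTM blocks (sequence, then final state) each with batch norm,
  then a 2-unit softmax head. 487,618 trainable parameters.
* **Baselines** — a 3×500 ReLU multilayer perceptron with dropout
  (0.2, 0.2, 0.3) and 509,502 parameters, and a fully convolutional
  network (128×8, 256×5, 128×3; conv → BN → ReLU; global average
  pooling).
* **Evaluation harness** — stratified 50/50 split for the baselines,
  stratified k-fold cross-validation (k = 5) for ERISNet, aggregated by
  the mean per-fold fraction correct
  `MPCE_k = (1/k) Σ e_i / c_i`,
  with seeded, bit-reproducible training (Adam, cross-entropy, 3,000
  epochs × batch 100 in the full protocol).
* **Floating Algae Index** — `FAI = R_859 − [R_645 + (R_1240 − R_645) ·
  (859−645)/(1240−645)]`, the NIR departure from a red→SWIR linear
  baseline, with per-class summary tables.
* **Synthetic pixel generator** — correlated-Gaussian classes around the
  published per-class band means, with a closed-form Bayes-accuracy
  oracle, so every stage of the pipeline is testable offline.

The underlying 1D-conv / LSTM / batch-norm engine (forward, reverse-mode
gradients, Adam) is implemented in base R matrix operations and is
finite-difference-tested.

## Worked example

```r
library(sargnet)

ds <- simulate_pixels(sim_config(seed = 1, n_per_class = 400))
summary(ds)
#> Instances: 800
#>   with Sargassum:    400
#>   without Sargassum: 400
#> Per-class band means:
#>                  412      469      555      645      859     1240     2130
#> rhos_class0 0.131055 0.134905 0.142115 0.124561 0.227569 0.207909 0.087113
#> rhos_class1 0.114761 0.119433 0.133187 0.116153 0.246615 0.232079 0.084815
#> ...
```

The class-1 sample means concentrate on the published per-class averages
(0.247237 at 859 nm, 0.233480 at 1240 nm), which are the generator's
configured means. FAI separates the classes in the mean but the
distributions overlap heavily:

```r
fai_by_class(ds)
#> FAI index per class (rhos bands)
#>        FAI Sargassum FAI without Sargassum
#> pixels    400.000000            400.000000
#> mean        0.088767              0.073031
#> std         0.018234              0.017529
#> ...
```

(0.0888 vs 0.0730 here; because FAI is linear in its three bands, the
expected per-class FAI means equal FAI of the per-class band means:
0.088595 and 0.072790.)

Train the conv-recurrent classifier at smoke scale and compare with the
analytic optimum for these simulation settings:

```r
bayes_accuracy(sim_config(1))
#> [1] 0.9805475

fit <- sarg_fit("erisnet", ds,
                config = training_config(epochs = 15, batch_size = 100,
                                         seed = 1,
                                         standardize_inputs = TRUE))
fit
#> <sarg_fit> erisnet: 15 epochs x batch 100 on 400 train / 400 test pixels
#>   final train accuracy 0.9825 | final test accuracy 0.9450 (best 0.9450)
plot(fit)                      # learning curves
predict(fit, ds[1:5, ])        # per-pixel class probabilities
```

Fifteen epochs already brings a 487k-parameter network to within a few
points of the 0.98 ceiling; the full 3,000-epoch protocol is the
`training_config()` default. `kfold_cv("erisnet", ds, k = 5, ...)` runs
the cross-validated protocol and reports per-fold accuracies and MPCE,
and `compare_models()` reproduces the three-way comparison layout.

A thin command-line wrapper over these functions is installed at
`system.file("cli", "sargnet", package = "sargnet")` with subcommands
`simulate`, `stats`, `fai`, `describe`, `train`, `compare`, `predict`;
every run directory carries a JSON manifest sufficient to re-run it.

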