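# spotdecode

Emitter counting and nanometer localization for **sub-diffraction-limited
spots** in single-molecule localization microscopy (SMLM/STORM).

When two or more fluorophores closer than the diffraction limit
(λ/(2·NA) ≈ 240 nm for AF647 at NA 1.4) emit in the same camera frame, they
produce a single apparent spot that conventional localization treats as one
molecule — under-counting events and misplacing emitters in dense
structures. `spotdecode` resolves such spots with a two-stage model:

1. a **classification network** predicts the emitter count *I* behind each
   15×15 px crop (softmax over counts, cross-entropy loss);
2. a count-specific **localization network** regresses the 2*I* emitter
   coordinates in nm, trained with the per-spot mean-square loss
   *L* = 1/(2*I*) Σᵢ [(xᵢ−x̄ᵢ)² + (yᵢ−ȳᵢ)²].

Training data come from **superposition**: single-emitter 7×7 spots (with
Gaussian-fitted positions) are translated sub-pixel so their fitted emitters
land on target coordinates drawn inside a 240 nm disk, then summed — every
multi-emitter spot therefore carries exact ground truth. Localization
quality is reported as the per-spot RMS
√(Σᵢ [(xᵢ−x̄ᵢ)² + (yᵢ−ȳᵢ)²] / 2*I*) after minimum-cost matching of
predictions to truths.

The package is self-contained for study and testing: it ships a synthetic
single-emitter spot generator (pixel-integrated Gaussian PSF, σ = 102 nm at
160 nm/px; Poisson shot noise, camera background and read noise; broad
truncated-lognormal photon yields; two-state blinking), spot detection and
Levenberg–Marquardt Gaussian fitting, the dataset builder, a compact
convolutional backbone implemented in C++ (Adam, cosine-annealed learning
rate, L2 penalty), frame-level inference emitting ThunderSTORM-dialect
localization tables, evaluation metrics (confusion-matrix statistics,
RMS with distance binning, displacement maps, SSIM reconstruction
comparison), and a STORM simulator of dense non-uniform ultrastructures.
Real data plug in through multi-page TIFF stacks and ThunderSTORM CSV.

## Worked example

A miniature end-to-end run (a full-quality run uses a 4000-molecule library,
20k spots and the default schedules; see the vignette):

```r
library(spotdecode)

# 1. synthetic single-emitter spot library, Gaussian-fitted
lib <- build_synthetic_library(1500, seed = 7)
#> <spot_library of 1500 single-emitter spots (160 nm/px)>

# 2. labeled one- and two-emitter spots by sub-pixel superposition
ds <- build_dataset(lib, n_per_class = 4000, classes = c(1, 2), seed = 8)
#> <labeled_dataset: 8000 spots (test:800, train:7200), classes {1,2}>

# 3. train the two-stage model (shortened schedule for the example)
cfg <- train_config(epochs = 20, seed = 9)
clf  <- train_network(build_model("classify", 2, cfg), ds)
loc2 <- train_network(build_model("localize", 2, cfg), ds)

# 4. held-out evaluation
test <- which(ds$labels$split == "test")
pred <- clf$classes[apply(predict_counts(clf, ds$images[test, ]), 2, which.max)]
round(classification_metrics(confusion_matrix(pred, ds$labels$count[test])), 3)
#> precision    recall  accuracy
#>     0.997     0.995     0.996

test2 <- test[ds$labels$count[test] == 2]
coords <- predict_positions(loc2, ds$images[test2, ])
rms <- mapply(function(p, i) rms_error(p, label_coords(ds$labels, i)),
              coords, test2)
summary(rms)
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#>    3.63   20.81   30.75   33.66   43.38   86.98

midpoint_baseline_rms(30)   # the trivial lower bar at d = 30 nm, in nm
#> [1] 10.6066
```

Even this abbreviated schedule separates one- from two-emitter spots with
99.6% held-out accuracy; the per-spot RMS (here in nm, over all pair
separations up to 240 nm) tightens substantially under the full training
schedule, and is smallest for the closest pairs, where the ambiguity of the
label ordering vanishes. `midpoint_baseline_rms()` gives the RMS of the
do-nothing strategy that puts both emitters of a pair at their midpoint —
any useful two-emitter localizer must beat it at resolvable separations.

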