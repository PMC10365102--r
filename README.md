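# lungfields

Segmentation of the lung fields in frontal chest radiographs, built for
pediatric archives where images come from many machines with inconsistent
intensity ranges. The package implements the full pipeline as tested,
seeded R code:

1. **Grayscale truncation.** For an image of size *x*×*y*, the central
   quarter window *A_c* (rows [*x*/4, 3*x*/4), cols [*y*/4, 3*y*/4))
   supplies bounds *V*min, *V*max; every pixel is clipped into
   [*V*min, *V*max], min-max normalized to [0,1] and resized to *S*×*S*.
   The result is invariant to per-machine affine intensity maps
   *aI* + *b* (*a* > 0).
2. **TransResUNet.** A hybrid encoder-decoder: residual CNN encoder
   producing a feature pyramid F1/F2/F3 at *S*/2, *S*/4, *S*/8; patch +
   learned position embedding of F3 into tokens; an *L*-layer transformer
   bottleneck (multi-head self-attention + MLP, pre-normalization) giving
   F_t; and a skip-connected residual decoder ending in a per-pixel
   two-class softmax head. Forward *and* backward passes are implemented
   natively on BLAS matrix operations (no deep-learning framework
   dependency); gradients are finite-difference checked in the tests.
3. **Training.** RMSprop (lr 0.001), batch size 2, 20 epochs, 70:10:20
   train/validation/test split (the rounding rule yields 810/116/232 at
   n = 1158), pixelwise cross-entropy, best-validation-Dice selection.
4. **Post-processing.** Connected-component filtering (keep ≤ 2 large
   components — the two-lung prior), enclosed-hole filling, and
   morphological opening.
5. **Evaluation.** AC = (TP+TN)/total, SE = TP/(TP+FN), SP = TN/(TN+FP),
   and Dice DI(e,f) = 2|e∩f|/(|e|+|f|).
6. **Synthetic phantoms.** A seeded generator of chest phantoms (dark lung
   ellipses in a brighter thorax, mediastinal band, rib stripes crossing
   the lungs, lung-intensity distractor blobs, noise, and a random affine
   "machine" transform per image) replaces clinical data, which cannot be
   redistributed.

See the methods vignette (`vignettes/lung-field-segmentation.Rmd`) for the
model, all tunable parameters, and the design decisions.

## Worked example

Desk-scale end-to-end run — 60 phantoms, model side 64, channels 8/16/32,
2 transformer layers, embedding 64, 4 heads — takes about two minutes on
one CPU:

```r
library(lungfields)

ds     <- generateDataset(60, PhantomConfig(side = 128, seed = 1))
images <- lapply(ds$images, preprocessImage, side = 64)
masks  <- lapply(ds$masks, resizeNearest, side = 64)
sp     <- splitDataset(1:60, c(70, 10, 20), seed = 1)
lengths(sp)
#> train   val  test
#>    42     6    12

model <- TransResUNet(ModelConfig(side = 64, channels = c(8, 16, 32),
                                  layers = 2, embedDim = 64, heads = 4),
                      seed = 1)
model <- trainModel(model, images, masks, split = sp,
                    config = TrainConfig(epochs = 20, seed = 1))
tail(trainHistory(model), 1)
#>    epoch train_loss  val_dice
#> 20    20  0.1096766 0.8980570

ev <- evaluateSplit(model, images, masks, ids = sp$test,
                    postprocConfig = PostprocConfig(openingRadius = 1))
round(ev$aggregate, 4)
#>     AC     SE     SP     DI DI_raw
#> 0.9674 0.9242 0.9797 0.9248 0.9110
```

The aggregate row is the unweighted mean over the 12 held-out phantoms:
accuracy, sensitivity and specificity of the lung class, Dice after
post-processing (`DI`), and Dice of the raw 0.5-binarized prediction
(`DI_raw`) — post-processing recovers the rib-shadow holes and strips
spurious components, lifting Dice from 0.911 to 0.925 here.

A command-line interface wraps the same steps
(`inst/scripts/lungfields-cli.R` with subcommands `simulate`,
`preprocess`, `train`, `predict`, `evaluate`); every output directory
carries a manifest with the config hash and seed needed to replay it.

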