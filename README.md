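# colonytda

Classify human induced pluripotent stem cell (hiPSC) colonies by
differentiation treatment from the spatial layout of their cells alone.

During early differentiation, colonies given different morphogen
treatments (WT, BMP4, CHIR, dual SMAD inhibition, DS+CHIR) organise their
cells into distinct spatial motifs — a sparse boundary fringe, low-density
"rosette" voids, an enlarged footprint. `colonytda` tests whether those
motifs alone identify the treatment: it converts each colony's
cell-centroid point cloud into a topological summary and trains a small
feedforward classifier on it, frame by frame over a time series. The
package is aimed at computational biologists studying multicellular
organisation and at anyone who wants a compact, fully seeded pipeline for
topological classification of planar point patterns.

## Method

1. **Persistent homology.** For each colony frame, the Vietoris–Rips
   filtration of the point cloud is computed and summarised as a barcode:
   bars `[b, d)` for connected components (H0) and loops (H1). H0 is
   computed by a union-find sweep (its finite deaths equal the Euclidean
   MST edge weights); H1 by boundary-matrix reduction over GF(2) in
   compiled code.
2. **Persistence landscapes.** Each bar contributes a tent function
   `f_(b,d)(t) = max(0, min(t − b, d − t))`; the k-th landscape function
   `λ_k(t)` is the k-th largest tent value. Sampling `λ_i(t_j)` on the
   grid `t = 1, …, 40` for the first 40 functions (20 per dimension when
   H0 and H1 are combined) gives a fixed-size 40×40 matrix per colony.
3. **Classifier.** "TDANet": three dense 20-neuron ReLU hidden layers and
   a softmax output, categorical cross-entropy loss, Adam, 70/30
   train/validation split, early stopping on validation accuracy, best
   checkpoint returned. With an 800-dimensional input this is exactly
   16,965 trainable parameters.
4. **Evaluation.** Accuracy, per-class precision/recall/F1, averaged
   confusion matrices, randomized-label controls, cross-timepoint
   accuracy grids `Acc_T(S)`, and the time-differential metric
   `⟨T,S⟩ = Acc_T(S) − Acc_{S*}(S)` with `S*` a nearby earlier frame.

A synthetic colony generator stands in for the original microscopy-derived
dataset: 78 labelled colonies over the five treatments by default, with
class-specific motifs that emerge linearly up to a configurable
differentiation time. See `vignettes/methods.Rmd` for models, parameters
and design decisions.

## Worked example

```r
library(colonytda)

# four corners of the unit square: three unit MST merges, one loop [1, √2)
compute_diagram(data.frame(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1)), threshold = 3)
#> <persistence_diagram> 5 bars (H0: 4, H1: 1), threshold 3
#>   dimension birth  death
#> 1         0     0   1
#> 2         0     0   1
#> 3         0     0   1
#> 4         0     0 Inf
#> 5         1     1   1.41

# synthetic colonies with fully expressed motifs, landscape features, training
ds    <- generate_dataset(setNames(rep(6, 5), treatment_classes()),
                          n_timepoints = 1, master_seed = 7,
                          differentiation_time = 0)
feats <- compute_features(ds)
x     <- do.call(rbind, feats$features)
fit   <- train_tdanet(x, feats$class, training_config(seed = 3),
                      ids = feats$colony_id)
glance(fit)
#>   n_parameters n_train n_validation epochs_run best_epoch best_val_accuracy
#> 1        32965      21            9        200         19             0.778

val <- feats$colony_id %in% fit$split$validation
cm  <- confusion(predict(fit, x[val, ], type = "class"), feats$class[val],
                 classes = sort(unique(feats$class)))
class_metrics(cm)
#>   class   precision recall    f1 degenerate
#> 1 BMP4        0.667  0.667 0.667 FALSE
#> 2 CHIR        0      0     0     TRUE
#> 3 DS          1      1     1     FALSE
#> 4 DS+CHIR     1      1     1     FALSE
#> 5 WT          1      1     1     FALSE
```

Seven of nine held-out colonies are classified correctly from topology
alone; the one error confuses the two fringe classes (BMP4 vs CHIR), whose
motifs differ only in annulus width and density — the same pair that is
hardest to separate in practice. `autoplot()` methods exist for diagrams,
landscape matrices and accuracy grids, and `run_pipeline()` /
`inst/cli/colonytda` orchestrate the whole workflow (synthesize → persist
→ landscape → train → evaluate → crosstime) with file artifacts and a
reproducibility manifest.

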