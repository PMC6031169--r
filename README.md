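# LayerFusion

Privacy-preserving recognition of coarse whole-body postures —
standing/walking, sitting, stooping, and lying — from synchronized,
uncalibrated multiview 8-bit depth-image streams. These four
"profile-based" actions are the building blocks of activity monitoring in
healthcare settings (a fall is standing → lying without sitting in
between), and depth silhouettes carry enough shape to recognize them
without ever recording an identifiable RGB image.

## The model

Each depth frame (values 0–255, 0 = near) is segmented against a per-pixel
background model, denoised morphologically, and reduced to the subject's
*depth profile*: the masked depth values inside a tight bounding box
`(X_h, Y_h, W_h, H_h)`, with thin arm parts rejected by a scaled
morphological opening.

The box is split into `L = 2N + 1` equal-height horizontal **layers**
`k = −N … +N`, with row bounds

    y_T[k] = ⌊H_h (k + N) / (2N + 1)⌋ + 1,   y_B[k] = ⌊H_h (k + N + 1) / (2N + 1)⌋.

Per view, each layer yields:

- **density** ρ′[k] = foreground pixel count; ρ[k] = ρ′[k] / max_j ρ′[j];
- **real-range depth** D′[k]: the mean foreground depth value of the layer
  mapped to centimeters by a fitted degree-6 polynomial f_c′(x)
  (f_c′(0) = 567.59 cm), then max-normalized to D[k];
- **inverse depth** D_i[k] = (D[k] − max D) / (min D − max D), highlighting
  layers nearest the camera — the "hidden volume" of thighs when sitting or
  the back when stooping;
- **weighted depth density** Z[k] = (1 − α) Q[k] + α ρ[k] with
  Q[k] = D_i[k] ρ[k] (defaults L = 3, α = 0.9);
- a global **proportion value** P_v = W_h / H_h separating horizontal
  postures.

Views are fused without calibration by per-layer products and a maximum
rule:

    ω[k] = Π_v ρ_v[k],   ω̄[k] = Π_v Z_v[k],   P_m = max_v P_v,

giving the length-(2N+2) feature vectors `[ω̄−N … ω̄+N, P_m]` ("depth"
flavor) or `[ω−N … ω+N, P_m]` ("nondepth"), classified by a
single-hidden-layer neural network (20 hidden nodes) or an RBF-kernel
C-SVC.

A seeded synthetic scene generator renders labeled multiview depth
sequences with the geometry the method assumes (cameras 2 m high tilted
30° down, subject at 3–5.5 m, ≥ 40 leading background frames per
sequence), so the entire pipeline is testable with no dataset download.

## Worked example

```r
library(LayerFusion)

cfg    <- sceneConfig(viewAngles = c(0, 90))          # two cameras, 90 deg apart
corpus <- generateCorpus(cfg, samplesPerClass = 50L, seed = 42L)
res    <- runPipeline(corpus, method = "ann", seed = 42L)
res$report
```

```
EvalReport: macro-average precision 100.00%
                  predicted
true               standing_walking sitting stooping lying
  standing_walking               15       0        0     0
  sitting                         0      15        0     0
  stooping                        0       0       15     0
  lying                           0       0        0    15
standing_walking          sitting         stooping            lying
         100.00%          100.00%          100.00%          100.00%
```

200 multiview samples (50 per class) are rendered, segmented, and fused;
a stratified 70/30 split trains the ANN and the held-out 60 samples are all
classified correctly — the synthetic classes are well separated at the
default noise levels (1% silhouette flips, 2-step depth jitter). The
confusion matrix rows are true classes, columns predictions; per-class
precision is TP/(TP+FP). The first fused feature vectors look like

```
     layer-1 layer+0 layer+1     Pm
[1,]  1.0000  0.8994    0.81 0.2778
```

— a standing sample: near-uniform layer masses and a small width/height
ratio.

`sweepParameters()` reproduces the layer-count and α evaluation grids, and
`inst/scripts/layerfusion.R` exposes `simulate`, `extract`, `run`, and
`sweep` subcommands for shell use.

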