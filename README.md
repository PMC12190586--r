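# gazecam

Gaze-supervised attention training for lesion image classification.

Expert eye gaze recorded while clinicians read medical images is a free,
annotation-less signal of where the diagnostic evidence sits. `gazecam`
implements the full pipeline that turns this signal into classifier
supervision:

1. **Gaze-attention maps** — eye-tracker fixation logs are spread with a
   Gaussian field-of-view model
   `G(x, y) = exp(-((x - x_c)^2 + (y - y_c)^2) / (2 sigma^2)) / (sqrt(2 pi) sigma)`,
   smoothed with a separable discrete kernel (defaults sigma = 30 px, 199
   taps) and max-normalized to [0, 1]. The pixel scale of `sigma` can be
   calibrated from viewing geometry via
   `sigma = (theta / 360) * pi * R * sqrt(Hp * Wp / (H * W))`.
2. **Attention-consistency training** — a convolutional classifier (feature
   extractor + global average pooling + linear head) is trained on the joint
   objective `LOSS = CE + lambda * MSE`, where MSE compares the network's
   sigmoid-activated class-activation map (CAM) for the predicted class,
   `A_raw(i,j) = sum_c relu(W_kc) F(i,j,c)` upsampled to image resolution,
   against the (range-matched) human gaze map. `lambda = 0` is the no-gaze
   ablation baseline.
3. **One-vs-rest evaluation** — confusion matrices (predictions in rows),
   per-class and macro Accuracy / Precision / Recall / F1 / MCC, Cohen's
   kappa, rank-based one-vs-rest AUC, and an attention-to-lesion
   intersection-over-union (IoU) score that quantifies whether the model
   looks where the lesion is.
4. **Synthetic phantoms** — a generator of elliptical-lesion phantom images
   (three texture-defined classes), ground-truth masks, simulated ~90 Hz
   scanpaths concentrated on the lesion, and patient-level 60/20/20 splits,
   so the entire method runs and tests with no eye tracker and no clinical
   data.

The intended audience is researchers in medical image analysis who want a
small, fully inspectable, CPU-only reference implementation of CAM-based gaze
supervision — every gradient is closed-form and checked against finite
differences, and every metric against brute-force oracles.

## Worked example

```r
library(gazecam)

# a synthetic cohort: 30 patients, ~8 images each, 64x64 phantoms
data <- synthesize_polyp_data(phantom_spec(n_patients = 30), seed = 100)
data
#> <polyp_data> 242 images (64x64 px), 30 patients
#>        class
#> split    0  1  2
#>   test  17 21 15
#>   train 48 36 56
#>   val   14 18 17

# gaze-supervised model and the no-gaze ablation baseline
fit1 <- gazecam(data, lambda_gaze = 1,
                control = gazecam_control(max_epochs = 30), seed = 0)
fit0 <- gazecam(data, lambda_gaze = 0,
                control = gazecam_control(max_epochs = 30), seed = 0)
fit1
#> <gazecam> 3-class gaze-supervised classifier (lambda_gaze = 1)
#>   trained 30 epochs; best validation accuracy 0.9592 (epoch 18)

evaluate_model(fit1, data, "test")
#> <metric_report> split 'test', n = 53 (macro average)
#>   Acc 0.9623  Pre 0.9606  Rec 0.9683  F1 0.9631  MCC 0.9455  Kappa 0.9431  AUC 1.0000
#>   mean attention-lesion IoU 0.3600
#>   confusion matrix (rows = predicted, cols = true):
#>          true
#> predicted class0 class1 class2
#>    class0     17      1      0
#>    class1      0     19      0
#>    class2      0      1     15
evaluate_model(fit0, data, "test")$mean_attention_iou
#> [1] 0.3138423
```

Reading the report: 51 of 53 held-out images are classified correctly
(two class-1 lesions are confused, one each with classes 0 and 2), the
one-vs-rest metrics are macro means over the three classes, and the attention
IoU says the gaze-supervised model's class-activation map overlaps the true
lesion better than the no-gaze baseline's (0.360 vs 0.314 at this seed;
averaged over seeds 0–2 the gap is 0.355 vs 0.327 at identical mean
accuracy). Inspect the attention visually with:

```r
att <- predict(fit1, data$images[, , , 1, drop = FALSE], type = "attention")
write_overlay_png(data$images[, , , 1], att[, , 1], "overlay.png")
```

Lower-level entry points mirror the pipeline stages: `render_gaze_map()` /
`overlay_heatmap()` / `effective_sigma()` (gaze maps), `tiny_backbone()` /
`forward_bundle()` / `network_attention()` / `cross_entropy()` /
`attention_mse()` / `total_loss()` (model), `augment_pair()` /
`scheduler_lr()` (training protocol), `confusion_matrix()` through
`ovr_auc()` and `attention_alignment()` (metrics), `load_manifest()` /
`load_gaze_log()` / `write_polyp_data()` (I/O).

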