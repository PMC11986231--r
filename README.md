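# hepafuse

Liver tumors are heterogeneous both in appearance (size, boundary
irregularity, contrast on tomographic slices) and at the molecular level
(expression subtypes). Predicting a tumor's subtype well therefore needs
both modalities: imaging alone captures morphology, genomics alone captures
molecular class, and in general neither determines the subtype by itself.
hepafuse is an R implementation of an attention-guided radiogenomic
pipeline for this problem, aimed at methods researchers who want a fully
inspectable, CPU-scale reference implementation with planted-ground-truth
benchmarks.

The pipeline has three learned stages:

1. **Attention-guided segmenter.** A U-shaped convolutional network with a
   spatial attention module (SAM), `As = σ(f1(X) ⊙ f2(X))`, a channel
   attention module (CAM), `Ac = σ(W2 · ReLU(W1 · GAP(X)))`, combined as
   `A_final = α·As + β·Ac` (defaults α = 0.6, β = 0.4) and applied as an
   element-wise feature gate. Training minimizes the hybrid objective
   `L = λ1·L_Dice + λ2·L_CE + λ3·L_SSIM` with (0.5, 0.3, 0.2) and optional
   SSIM-based depth supervision of the feature pyramid. The SSIM here is
   the global-statistics form
   `SSIM(P,G) = (2μPμG + C1)(2σPG + C2) / ((μP² + μG² + C1)(σP² + σG² + C2))`.
2. **Genomic autoencoder.** A four-layer fully connected autoencoder
   compresses the samples × markers matrix to a latent code
   (`Z = f_enc(X)`, linear decoder output), trained on the mean per-sample
   squared reconstruction error; latent codes are clustered by k-means and
   markers ranked by an F-statistic-weighted correlation saliency.
3. **Fusion classifier.** Pooled bottleneck imaging features and latent
   genomic codes are projected into a shared space, blended by a trainable
   convex weight `F_fusion = α·F_img + (1−α)·F_gen`, refined by a learned
   sigmoid gate, and classified by softmax.

Everything trains on a small reverse-mode autodiff tape built into the
package (RcppArmadillo kernels for convolution, pooling and batch
normalization), so there is no deep-learning framework dependency. A
synthetic generator produces paired phantom images, masks and genomic
cohorts with planted subtype structure — including a `joint_xor` rule under
which either modality alone caps at 0.75 accuracy but both together
determine the label — so every stage is testable against known ground
truth.

## Worked example

```r
library(hepafuse)

# paired cohort with the joint labeling rule: 4 genomic clusters x 2 size strata
cohort <- generate_paired_cohort(
  phantom_spec(seed = 1),
  cohort_spec(n_samples = 80, n_subtypes = 4, seed = 1),
  joint_rule = "joint_xor")

# imaging branch: train on 64 samples, hold out 16
arrs <- cohort_image_array(cohort, 1:64)
seg <- build_segmenter(seed = 1)
seg <- train_segmenter(seg, arrs$images, arrs$masks, epochs = 8,
                       batch_size = 16, seed = 1)
seg
#> attention-guided segmenter: 3 levels, channels 16/32/64, alpha/beta 0.60/0.40
#>   52 parameter tensors (61414 values)
#>   trained 8 epochs, final hybrid loss 0.6964

hold <- cohort_image_array(cohort, 65:80)
pred <- predict_mask(seg, hold$images)
mean(sapply(1:16, function(j) dice_coefficient(pred[, , j], hold$masks[, , j])))
#> [1] 0.768

# genomic branch
ae <- build_autoencoder(m = 200, k = 16, seed = 1)
ae <- train_autoencoder(ae, cohort$genomic_matrix[1:64, ], epochs = 100, seed = 1)
glance(ae)
#>       m     k hidden dropout n_params epochs_trained final_recon
#>     200    16     57     0.3    24954            100        34.1

# fusion
fit <- train_joint(cohort, seg, ae, train_idx = 1:64, epochs = 300, seed = 1)
pr <- predict_subtypes(fit$model, fit$img[65:80, ], fit$gen[65:80, ])
mean(pr$predicted_subtype == cohort$labels[65:80])
#> [1] 1
fusion_alpha(fit$model)
#> [1] 0.54
```

After only 8 training epochs the segmenter reaches a held-out Dice of 0.77
(it passes 0.99 at the benchmark's 30 epochs); the autoencoder compresses
200 markers to 16 latent dimensions; and the fused classifier reaches
accuracy 1.0 on held-out samples — above the 0.75 ceiling either modality
permits alone, with the learned fusion weight at 0.54, i.e. drawing on
both branches. `tidy()`, `glance()` and `autoplot()` methods summarize and
plot fitted models; `run_simulate()`, `run_train()` and `run_evaluate()`
(or the `inst/cli/hepafuse.R` script) drive the cross-validated pipeline
from a YAML configuration.

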