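# fundusformer

Hierarchical local–global attention screening for retinal fundus images.

Screening programs for diabetic retinopathy and other ophthalmic disease
photograph the retina at population scale. The diagnostic evidence lives at
two scales at once: focal lesions a few pixels wide (microaneurysms,
exudates, hemorrhages) and whole-image anatomy (vessels, optic disc,
illumination). `fundusformer` implements a patch-token transformer built
around that tension, together with everything needed to exercise it end to
end on synthetic fundus-like images with exact lesion ground truth: a
generator, preprocessing, a seeded training loop with analytic gradients,
screening metrics, a degradation-robustness harness, and attention-map
interpretability analyses.

## The model

An image is standardized per channel, masked to its circular field of view
(FOV), resized, and cut into non-overlapping `P x P` patches, each embedded
as `t_i = W_p z_i + p_i`. A stack of `L` transformer layers refines the
tokens; in layer `l`, each head computes from the same scaled dot-product
logits both a **global** attention (softmax over all `N` tokens) and a
**local** attention (softmax restricted to the Chebyshev neighborhood
`N_i` on the patch grid), mixed convexly with a depth-increasing
coefficient:

```
a~_ij(l) = alpha(l) * a_ij,global + (1 - alpha(l)) * a_ij,local,
alpha(l) = l / L  (default; learnable monotone schedule available)
```

Both terms are row-stochastic, so the mixture is row-stochastic with no
renormalization. Values are aggregated with the mixed weights, heads merged,
and a position-wise feed-forward block applied inside a single residual
update. Token means from several depths are fused,
`h = sum_k beta_k h^(k)` with `beta = softmax(logits)`, and a bias-free
head produces independent per-class sigmoid probabilities
`y_c = sigmoid(w_c . W_s h)` — single-disease screening is the one-class
special case, multi-label screening needs no mutual-exclusivity assumption.
Training minimizes summed binary cross-entropy with AdamW and an exponential
learning-rate schedule `eta_t = eta_0 * gamma^t`, with early stopping on
validation loss; decision thresholds are picked on validation data by
Youden's J.

## Worked example

```r
library(fundusformer)

rc  <- load_run_config(preset = "table4_desk", seed = 1)  # 64 px desk scale
ds  <- generate_dataset(synthetic_config(seed = 1), 512, seed = 1)
model <- fundus_model(rc$encoder, n_classes = 2, screen_dim = 32, seed = 1)
fit <- train_model(model, ds, train_config(epochs = 30, lr0 = 1e-3, seed = 1))

evaluate_model(fit$model, ds$test, fit$stats, fit$thresholds)
#> metrics: accuracy 0.892 | macro-F1 0.818 | sens 0.709 | spec 1.000 | AUROC 0.948

al <- alignment_suite(fit$model, ds$test, fit$stats)
round(c(coverage = al$relevant_region_coverage,
        uniform_baseline = al$lesion_patch_fraction), 3)
#> coverage uniform_baseline
#>    0.173            0.130
```

The metrics line says the trained desk-scale model classifies held-out
synthetic images with ~89% accuracy and ~0.95 mean AUROC over the two lesion
classes (per-class AUROC 0.968 and 0.927); the Youden thresholds chosen on
the small validation split trade sensitivity for specificity here, which is
what the threshold-free AUROC numbers make visible. The alignment pair says
the attention the model pays to lesion patches (17.3% of its saliency mass)
exceeds what uniform attention would give them (13.0%), i.e. the model looks
where the planted pathology is.

The same pipeline is scriptable from a shell via the thin CLI in
`inst/cli/fundusformer`:

```sh
Rscript inst/cli/fundusformer simulate --out run --data run/data --seed 1
Rscript inst/cli/fundusformer train    --data run/data --out run
Rscript inst/cli/fundusformer evaluate --data run/data --out run
Rscript inst/cli/fundusformer robustness --data run/data --out run
Rscript inst/cli/fundusformer attend   --data run/data --out run
```

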