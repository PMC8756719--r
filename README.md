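# dnmap — Deep Neural Maps for miRNA expression stratification

`dnmap` stratifies tissue samples by their miRNA expression profiles with
a **Deep Neural Map**: a symmetric autoencoder (AE) jointly fine-tuned
with a self-organizing map (SOM), producing a two-dimensional,
topology-preserving map of a cohort in which nearby lattice nodes hold
molecularly similar samples. Training is fully unsupervised; labels
(tissue-of-origin and neoplasticity status) are used only afterwards, to
label map nodes by strict majority vote and to score held-out samples.
An **activation-gradient** method attributes the latent representation
to individual miRNAs, identifying the markers that drive each cluster
and explaining nodes where several classes co-locate.

It is aimed at computational biologists who want unsupervised,
interpretable structure in bulk (or pseudo-bulk) small-RNA expression
cohorts — e.g. tumour vs normal stratification across organs — rather
than a supervised classifier.

## The model

Three training phases over a samples × miRNA matrix (total-count
normalized, min–max scaled per feature):

1. **AE pre-training** — layer widths in geometric series
   (d₀ → √(d₀·d_L) → d_L, default latent d_L = 25), tanh hidden layers,
   linear output; loss `mean((x − x̂)²) + β·Σ‖W‖²`, mini-batch Adam.
2. **SOM pre-training** — on the frozen latent embedding, classical SOM
   updates `w ← w + η·h·(z − w)` with a Gaussian neighbourhood
   `h = exp(−d_grid²/2σ(t)²)` whose width decays over epochs.
3. **Joint fine-tuning** — the AE loss gains `λ·‖z − w_bmu‖²` (the
   winning node is a constant within each step), while SOM updates
   continue at a reduced rate; the latent space is tailored to the map.

Attribution scores each input as `s_i = Σ_j |∂z_j/∂x_i|` (encoder
Jacobian, computed analytically); class profiles are means of per-sample
profiles, and "key features" are the minimal top-ranked set covering
75% of a profile's total attribution.

## Worked example

The package ships a synthetic-cohort generator that emulates the
structure of a real miRNA atlas (marker miRNAs per class, shared
high-abundance miRNAs, library-size variation, planted QC failures), so
the whole workflow runs without any download:

```r
library(dnmap)

coh <- generate_cohort(synth_config(seed = 1))   # 240 samples, 6 classes
pp  <- preprocess_pipeline(coh$expression, coh$ontology, seed = 1)
pp
#> dnm_preprocess: 235 samples x 300 features retained
#>   removed: iqr_outlier=2, low_depth=3
#> split_assignment: 111 train / 30 validation / 94 test

fit <- dnm(pp$expression[pp$split$train_ids, ], som_dim = c(5, 5),
           ae_epochs = 300, som_epochs = 150, joint_epochs = 100, seed = 1)
fit
#> Deep Neural Map
#>   autoencoder: 300 - 87 - 25 - 87 - 300 (tanh)
#>   SOM lattice: 5 x 5
#>   epochs: AE 300, SOM 150, joint 100; lambda = 0.1; seed = 1
#>   final AE loss 0.03196; final quantization error 0.04681

labels <- label_nodes(fit$train_assignment, pp$ontology)
classify_samples(map_samples(fit, pp$expression[pp$split$test_ids, ]),
                 labels, pp$ontology)
#> Deep Neural Map evaluation
#>   combined accuracy:     1.0000
#>   tissue accuracy:       1.0000
#>   neoplasticity accuracy: 1.0000
#>   sensitivity 1.0000 / specificity 1.0000 (neoplastic positive)
#>   94 samples scored; 0 on unlabelled nodes (misclassify)
```

The preprocessing report shows the five planted QC failures (three
low-depth samples, two composition-skewed outliers) being removed — and
nothing else. On this clean, well-separated cohort the held-out
accuracies reach 1.0; real cohorts are noisier and score lower. The
three accuracies always obey combined ≤ tissue ≤ neoplasticity, because
a combined prediction is correct only if both its projections are.

Attribution then names the miRNAs behind a class
(`class_average_activation()` + `top_features()`), and
`find_multiclass_nodes()` / `multiclass_node_report()` summarize nodes
where three or more classes co-locate — with a cohort carrying a planted
cross-tissue signature, those nodes' shared key features contain the
signature miRNAs.

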