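# pnet: pathway-constrained sparse neural networks for cancer genomics

`pnet` is an R implementation of biologically informed sparse neural
networks for classifying tumour state — primary versus
metastatic/castration-resistant prostate cancer — from gene-level somatic
mutation and copy-number profiles, with complete interpretability of
every node in the network. It is aimed at computational cancer-genomics
researchers who want a predictive model whose internal structure *is* the
biology: genes wired to the pathways that contain them, pathways wired to
their parent processes, and nothing else.

## The model

Each network layer computes

```
y = f[ (M ∘ W)ᵀ x + b ],        f = tanh
```

where the binary mask `M` (Hadamard-multiplied into the trainable weights
`W`) encodes curated relations: three feature nodes per gene (mutation,
high amplification, deep deletion), a gene→pathway membership mask from
GMT gene sets, and pathway→parent masks from a Reactome-style relation
table stratified into layers of increasing abstraction. A 1-unit sigmoid
head follows every hidden layer; the model score is the mean of the head
probabilities. Training is Adam on class-weighted binary cross-entropy
(class weights `N / (2 n_c)`), with the learning rate starting at 0.001
and decaying every 50 epochs.

Interpretation propagates DeepLIFT rescale-rule multipliers through all
layers against an all-zeros (no-alteration) reference: sample-level node
contributions `C_i^{l,s}` satisfy per-layer completeness, aggregate as
`C_i^l = |Σ_s C_i^{l,s}|`, and are divided by node degree for extreme
hubs (degree > layer mean + 5 SD) to counter over-annotation bias.

The package also ships the surrounding protocol: stratified 80/10/10
splits and k-fold CV, AUC/AUPRC/F1 metrics, DeLong and 2,000-resample
bootstrap model comparisons with Benjamini–Hochberg correction,
sparse-versus-dense learning curves, classical baselines (logistic
regression, linear/RBF SVM, decision tree, dense networks), Yates-
corrected chi-squared and log-rank tests, and a synthetic cohort
generator with planted driver pathways so everything is testable without
any download.

## Worked example

```r
library(pnet)

cohort <- generate_cohort(sim_config(n_samples = 500, seed = 42))
cohort
#> synthetic cohort: 500 samples ( 165 class 1 / 335 class 0 ), 108 genes, 3 driver pathways

net <- cohort$net
net
#> layered network: features(324) -> genes(108) -> pathway1(18) -> pathway2(6) -> pathway3(2)
#> sparse parameters: 590 | dense equivalent: 37190

splits <- make_splits(cohort$labels, seed = 42)
X <- as_input_matrix(cohort$tensor)
model <- train_pnet(pnet_model(net, seed = 42),
                    X[splits$train, ], cohort$labels[splits$train],
                    pnet_config(epochs = 150, seed = 42),
                    x_val = X[splits$validation, ],
                    y_val = cohort$labels[splits$validation])

compute_metrics(cohort$labels[splits$test], predict(model, X[splits$test, ]))
#>      auc     auprc  accuracy        f1 precision    recall
#>   0.9908    0.9828    0.9400    0.9091    0.8824    0.9375
```

The masked model separates the held-out test set almost perfectly
(AUC 0.99) from 590 effective parameters — the dense network over the
same nodes would need 37,190. Attribution then recovers the planted
biology; the three top-ranked pathways in the gene-adjacent layer are
exactly the three planted drivers:

```r
imp <- pnet_importance(model, X[splits$test, ])
head(subset(imp$table, layer == "pathway1"), 4)   # ordered by rank
#>  node_id degree        C adjusted_C rank
#> SP3_0011      7 5.334516   5.334516    1
#> SP3_0016      7 4.492356   4.492356    2
#> SP3_0008      7 3.554935   3.554935    3
#> SP3_0006      7 0.248824   0.248824    4
cohort$truth$driver_pathways
#> [1] "SP3_0008" "SP3_0011" "SP3_0016"
```

Real data enter through `parse_relations()` + `parse_gmt()` (Reactome
dialects), `load_mutations()` (MAF or gene×sample matrix, nonsynonymous
filter applied), `load_cnv()` (GISTIC calls; only ±2 count) and
`assemble_profiles()`. A thin command-line front end with
`simulate` / `train` / `explain` / `evaluate` subcommands lives at
`inst/cli/pnet.R`.

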