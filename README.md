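# ecembed

Hierarchy-aware contrastive embeddings for Enzyme Commission (EC) placement.

## The problem

High-throughput sequencing produces enzyme sequences faster than biochemists
can characterize them, and many of these enzymes perform activities that have
no exact four-field EC number in any training corpus. A classifier that can
only reproduce known EC4 labels is of limited use for such proteins. What
*is* useful is accurate placement in known function space: predicting the
EC3 family (reaction mechanism), EC2 subclass (substrate/group) and EC1 class
(reaction type) of a protein whose precise serial number has never been seen,
which narrows the experimental hypotheses required to characterize it.

`ecembed` learns a function-aware representation space in which
nearest-neighbour label transfer achieves exactly this. It is aimed at
computational biologists who have fixed protein embeddings (for example from
a frozen protein language model) and an EC-annotated training corpus, and who
want a reproducible pipeline from raw annotations to hierarchical evaluation.

## The method

Starting from a frozen base embedding $h(x) \in \mathbb{R}^d$ per protein, a
small MLP projection head $f_\theta$ produces the working representation

$$z = \mathrm{norm}(f_\theta(h(x))) \in \mathbb{R}^D,$$

where $\mathrm{norm}(\cdot)$ is $\ell_2$ normalization, so inner products are
cosine similarities. The head is trained with **HiNCE**, a hierarchical
exemplar contrastive objective combining two terms:

**Instance-level supervised contrastive loss.** For an anchor $z_a$ with
sampled same-EC4 positives $\mathcal{P}_a$ and different-EC4 negatives
$\mathcal{N}_a$ ($\mathcal{S}_a = \mathcal{P}_a \cup \mathcal{N}_a$):

$$\mathcal{L}_{\mathrm{inst}}(a) = -\frac{1}{|\mathcal{P}_a|}
\sum_{p \in \mathcal{P}_a} \log
\frac{\exp(z_a^\top z_p / \tau)}
     {\sum_{u \in \mathcal{S}_a} \exp(z_a^\top z_u / \tau)}.$$

**Hierarchical exemplar NCE.** For each prefix depth
$\ell \in \{1,2,3,4\}$, class centroids
$\mu_c^{(\ell)} = \frac{1}{|\mathcal{I}_c^{(\ell)}|}\sum_{i \in \mathcal{I}_c^{(\ell)}} z_i$
are recomputed from the minibatch; the anchor is classified against all
centroids at that depth, with a leave-one-out centroid
$\tilde\mu_{c_a}^{(\ell)}$ in the numerator to avoid self-attraction:

$$\mathcal{L}_{\mathrm{exem}}^{(\ell)}(a) = -\log
\frac{\exp(z_a^\top \tilde\mu_{c_a}^{(\ell)} / \tau)}
     {\sum_c \exp(z_a^\top \mu_c^{(\ell)} / \tau)},
\qquad
\mathcal{L}_{\mathrm{exem}}(a) = \frac{1}{4}\sum_{\ell=1}^4
\mathcal{L}_{\mathrm{exem}}^{(\ell)}(a).$$

The combined batch objective is

$$\mathcal{L} = \frac{1}{B}\sum_{a=1}^{B}
\left[\lambda_{\mathrm{inst}}\,\mathcal{L}_{\mathrm{inst}}(a) +
\lambda_{\mathrm{exem}}\,\mathcal{L}_{\mathrm{exem}}(a)\right],$$

with temperature $\tau = 0.1$ and $\lambda_{\mathrm{inst}} =
\lambda_{\mathrm{exem}} = 1$ by default. Negatives are biased toward *hard*
negatives via a periodically refreshed distance map (per-protein shortlist of
the most similar different-EC4 proteins in the current space), and EC4
classes with a single sequence contribute a positive pair through a
mask-augmented view of their sequence. Optimization is mini-batch Adam with
analytic gradients (verified against finite differences in the test suite).

At test time a query is projected and assigned the EC label of its nearest
training neighbour (extensible to k-NN voting); evaluation reports accuracy
and macro precision/recall/F1 on EC1–EC3 prefixes with a nonparametric
bootstrap (1,000 resamples, 95% percentile interval, reported as mean ±
half-width).

The package also implements the full data machinery around the objective:
deterministic EC cleaning (multifunction removal, invalid/99-field removal,
EC–sequence deduplication), the unseen-EC4 grouped split (largest EC4 group
per EC3 family to train, remaining groups ascending by size to test), the
random seen split, BLAST-tabular identity/coverage filtering, experimental
evidence filtering, and a synthetic hierarchical fixture generator so that
everything runs offline.

## Worked example

Everything below is synthetic and seeded, so the numbers reproduce exactly.

```r
library(ecembed)

ds <- generate_dataset(synthetic_spec(seed = 42))
ds
#> Synthetic dataset: 546 proteins, 36 EC4 classes (3x2x2x3 hierarchy), dim 32 (16 nuisance)

cleaned <- clean_records(ds$records)
split <- build_unseen_split(cleaned$records, test_fraction = 0.2)
split
#> EC unseen split: 433 train / 113 test records (24 / 12 unique EC4)

fit <- hince_train(
  ds$embeddings[split$train$entry, ], split$train$ec,
  sequences = setNames(ds$records$sequence, ds$records$entry),
  provider  = synthetic_provider(ds),
  config    = train_config(epochs = 30, seed = 1)
)
fit
#> Hierarchical contrastive fit: 30 epochs, final loss 2.2248 (instance 1.6907, exemplar 0.5342)

index <- build_reference_index(fit$projector,
                               ds$embeddings[split$train$entry, ], split$train$ec)
preds <- predict_nn(index, ds$embeddings[split$test$entry, ])
head(preds, 3)
#> # A tibble: 3 x 4
#>   query    predicted_ec neighbor similarity
#>   <chr>    <chr>        <chr>         <dbl>
#> 1 SYN00021 1.1.1.1      SYN00003      0.980
#> 2 SYN00022 1.1.1.1      SYN00007      0.972
#> 3 SYN00023 1.1.1.1      SYN00014      0.970

metrics <- bootstrap_metrics(preds$predicted_ec, split$test$ec,
                             depths = 1:3, n_resamples = 1000, seed = 1)
metrics
#> Prefix metrics on 113 test proteins (1000 bootstrap resamples, 95% CI)
#>  depth          metric  estimate           summary
#>      1        accuracy 1.0000000 1.0000 +/- 0.0000
#>      1        macro_f1 1.0000000 1.0000 +/- 0.0000
#>      1 macro_precision 1.0000000 1.0000 +/- 0.0000
#>      1    macro_recall 1.0000000 1.0000 +/- 0.0000
#>      2        accuracy 1.0000000 1.0000 +/- 0.0000
#>      2        macro_f1 1.0000000 1.0000 +/- 0.0000
#>      2 macro_precision 1.0000000 1.0000 +/- 0.0000
#>      2    macro_recall 1.0000000 1.0000 +/- 0.0000
#>      3        accuracy 0.8495575 0.8498 +/- 0.0664
#>      3        macro_f1 0.6050618 0.6300 +/- 0.0916
#>      3 macro_precision 0.6274510 0.6575 +/- 0.0850
#>      3    macro_recall 0.6010787 0.6296 +/- 0.0913
```

Every test protein carries an EC4 label absent from training, yet EC1 and
EC2 placement is perfect and 85% of queries land in the correct EC3 family —
the learned space has preserved the functional hierarchy well above the
EC3 chance level of 1/12 ≈ 0.083. `tidy()`, `glance()` and `autoplot()`
methods are available on the cleaning, split, fit and metrics objects.

A command-line wrapper over the same functions is installed at
`system.file("cli", "ecembed.R", package = "ecembed")` with subcommands
`simulate`, `clean`, `split-unseen`, `split-seen`, `filter`, `stats`,
`train`, `predict` and `evaluate`.

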