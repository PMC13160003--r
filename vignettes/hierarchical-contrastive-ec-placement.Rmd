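---
title: "Hierarchy-aware contrastive embeddings for EC placement: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchy-aware contrastive embeddings for EC placement: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecembed)
```

## Scope and model

`ecembed` addresses the *unseen-EC4* regime of enzyme function prediction:
test proteins whose full four-field EC number never occurs in training, but
whose EC3 family does. The quantity of interest is therefore not EC4
classification accuracy but the quality of EC1–EC3 *placement* under
nearest-neighbour transfer in a learned representation space.

The model is deliberately small. Base embeddings are treated as frozen
features supplied by an external provider (in production, a pretrained
protein language model; in this package's tests, the synthetic generator).
Only an MLP projection head is trained. Its output is always
$\ell_2$-normalized, so all similarity computations — the contrastive loss,
the hard-negative distance map, and nearest-neighbour transfer — operate on
cosine similarity. This normalization is an assumption baked into the whole
pipeline: centroids of unit vectors generally lie *inside* the unit ball,
and we intentionally do **not** renormalize them (the per-depth exemplar
loss is defined on raw class means).

The training objective combines, per anchor, an instance-level supervised
contrastive term over sampled same-EC4 positives and different-EC4
negatives, and an exemplar NCE term that classifies the anchor against the
class centroids at each of the four EC depths, averaged over depths. The
numerator of the exemplar term uses a leave-one-out centroid so that an
anchor in a small class is not attracted to itself; the denominator sums
over the *full* centroids of all classes present in the batch, including
the anchor's own class. An alternative reading would use the leave-one-out
centroid in the denominator as well; we implement the definition as stated
and expose the alternative behind `loo_denominator = TRUE` in
`exemplar_loss_at_depth()`, documented as an interpretation rather than the
reference behaviour (its gradient path is not implemented, as it is not used
in training).

Two further scoping choices matter. Centroids are recomputed from the
*current minibatch's anchor embeddings only*: sampled positives and
negatives do not enter the centroids. And positives/negatives are projected
with the current parameters in the same forward pass as the anchors; using
stale projections would silently detach part of the gradient.

## Gradients and optimization

No automatic differentiation framework is used: the gradient of the batch
objective with respect to every embedding row is derived analytically and
backpropagated through the $\ell_2$ normalization and the MLP by hand. Two
details are easy to get wrong and are therefore pinned by tests:

* the leave-one-out centroid $\tilde\mu = (\sum_{j} z_j - z_a)/(n-1)$ has
  *zero* derivative with respect to the anchor, because the class sum
  contains $z_a$;
* every anchor's loss contributes gradient to every batch member through
  the per-depth centroids, including the anchor's own class in the
  denominator.

All softmax terms use overflow-safe log-sum-exp, keeping the losses finite
for temperatures down to 0.01 on unit-norm inputs. The test suite checks
the vectorized losses against independent scalar-loop oracles on 50 random
batches (tolerance $10^{-6}$) and the analytic gradient against central
finite differences (step $10^{-4}$, relative tolerance $10^{-4}$).
Optimization is plain Adam ($\beta_1 = 0.9$, $\beta_2 = 0.999$,
$\epsilon = 10^{-8}$).

## Tunable parameters

| Parameter | Default | Meaning and rationale |
|---|---|---|
| `tau` | 0.1 | Softmax temperature of both loss terms; the standard value for supervised contrastive enzyme-embedding training. |
| `lambda_inst`, `lambda_exem` | 1, 1 | Trade-off between local instance discrimination and hierarchical organization. Equal weighting is the neutral default; tune on a validation split. |
| `output_dim` (D) | 128 (capped at d) | Projection dimension. The head architecture (two hidden layers of width `max(D, d/2)`, tanh) is an engineering default, not a canonical choice; all of it is configurable. |
| `n_positives`, `n_negatives` | 2, 8 | Sampled contrastive pairs per anchor per iteration; re-sampled fresh every iteration. |
| `p_hard` | 0.7 | Probability that a negative is drawn from the anchor's mined hard-negative class pool rather than uniformly. The pool is the set of EC4 labels on the anchor's shortlist; a draw picks a pool class uniformly, then a uniform member of that class. This reconciles a protein-level shortlist with class-level negative mining. |
| `shortlist_k` | 20 | Distance-map shortlist length (most similar different-EC4 proteins, descending cosine, ties by entry id). |
| `refresh_interval` | 5 epochs | Distance-map refresh cadence. The map's epoch stamp never lags the current epoch by more than this interval; an interval larger than the epoch count means the map is built once from the initial projection. |
| `learning_rate` | 1e-3 | Adam step size. |
| `batch_size` | 32 anchors | Every protein in the minibatch is an anchor. |

Sampling counts, shortlist size, hard fraction and refresh cadence are
exposed precisely because they are *not* canonical: they are reasonable
engineering defaults for desk-scale corpora.

## Data preparation semantics

**Cleaning** applies three ordered rules, each record receiving exactly one
disposition: (1) any entry associated with two or more distinct EC strings
is removed entirely — the grouping key is the entry id, and a record whose
field lists several ECs (`;`/`,`-separated) counts as multifunction even if
some of those ECs are malformed; (2) records whose EC fails validation
(fewer than four fields; non-digit fields after stripping an optional `EC`
prefix and whitespace; any field equal to 99) are removed — note the
99-rule matches a whole field, not the substring "99", so a subclass of 199
is valid; (3) among records sharing an identical (canonical EC, sequence)
pair, the first in input order is kept. Rule order is fixed, making
cleaning deterministic and idempotent.

**Unseen split.** Per EC3 family the largest EC4 group (ties broken by
lexicographic EC order) goes to training as the established class; the
remaining EC4 groups, ascending by size, are appended *whole* to the test
candidate set until it first reaches `ceiling(test_fraction * N)` — the
last group may overshoot, since groups move atomically. The target is
computed from the total cleaned record count, not from the post-head
remainder. The construction guarantees EC4-disjointness of train and test
and full EC3 coverage of test by train, and contains no randomness.

**Similarity filter.** A test record is removed when any of its query-side
hits against the training database has identity at or above the threshold
*and* alignment coverage at or above 80% of either the full query or the
full subject sequence length. Coverage denominators are the full unaligned
sequence lengths, and the alignment length is used as reported (gaps
included); the hit table's own coverage conventions are deliberately not
second-guessed. Hits where a test id appears only as subject are ignored.
Lower identity thresholds remove supersets, so surviving sets nest across
10/30/50%.

**Evidence filter.** Only records flagged as experimentally supported are
retained; a missing flag means unsupported. The join key for evidence is
(entry, canonical EC, exact sequence).

**Evaluation.** Macro precision/recall/F1 are averaged over the *union* of
ground-truth and predicted prefix classes, with the zero-division
convention P/R/F1 = 0; the union convention penalizes spurious predicted
classes symmetrically (the truth-only convention is available via
`class_set = "truth"`). Bootstrap intervals are percentile intervals
(1,000 resamples, 95% by default), reported as mean ± half-width. With
1-NN transfer, macro precision is not inflated by abstention: every query
receives a label.

## The synthetic generator

`synthetic_spec()` / `generate_dataset()` plant a known four-level
hierarchical cluster structure: each EC4 class mean is a sum of per-level
Gaussian offsets with strictly decreasing scales
$\sigma_1 > \sigma_2 > \sigma_3 > \sigma_4$, each protein is its class mean
plus isotropic noise, half of the embedding dimensions carry pure noise
(nuisance dimensions), and all embeddings are unit-normalized. Per EC3
family, the first EC4 class is pinned to the top of the size range so the
unseen split always has an unambiguous head class, mirroring the long-tailed
label-frequency distributions of real EC corpora.

Default scales are $\sigma = (1.0, 0.5, 0.3, 0.15)$ with within-class and
nuisance noise $\sigma_e = 0.45$, dimension 32 with 16 nuisance dimensions,
and 6–20 proteins per EC4 class over a 3×2×2×3 hierarchy (36 EC4 classes,
12 EC3 families, ~550 proteins). These were chosen once, at design time, to
sit in a realistic middle regime: raw-embedding EC3 transfer is well above
chance (the hierarchy is real) but clearly below ceiling (the noise and
nuisance dimensions matter), so there is headroom for the learned projection
to demonstrate an improvement. The benchmark in `run_pipeline()` and
`scripts/acceptance.R` uses these defaults with ~30 training epochs — a
problem size chosen so the whole chain runs in tens of seconds on one CPU
while keeping ≥100 test proteins for stable accuracy estimates.

What the generator does *not* emulate: real protein-language-model embedding
statistics (anisotropy, heavy tails), sequence homology (sequences are
i.i.d. random amino acids; the synthetic hit table correlates identity with
embedding similarity instead), annotation noise, and multi-label proteins.
Passing the synthetic benchmark therefore demonstrates that the objective,
sampling machinery and transfer pipeline recover planted hierarchical
structure through noise — not that any particular accuracy will be attained
on real corpora.

The synthetic embedding provider returns the stored vector for an original
sequence, and for a mask-augmented variant the owner's vector plus a small
deterministic perturbation (pre-normalization norm ≤ 0.05, seeded from the
sequence text), making the masked view a near-duplicate positive with
cosine ≥ 0.99 — a stand-in for re-encoding a masked sequence with a frozen
encoder.

## Numerical and determinism choices

* All ties are broken deterministically: entry-id order in the distance map
  and nearest-neighbour transfer, lexicographic EC order in the split
  construction, first-in-input-order in deduplication.
* Every stochastic stage (seen split, batch sampling, training, bootstrap,
  generator) is driven by an explicit seed; `run_pipeline()` expands one
  global seed into fixed per-stage seeds, so the entire chain — including
  every metric digit — is a pure function of the seed. The test suite
  asserts bit-identical metrics JSON across repeated runs.
* Projector persistence uses JSON with doubles printed at 17 significant
  digits, which round-trips IEEE doubles exactly; embedding tables are
  written the same way and parsed with base R's correctly rounded reader.
* Degenerate inputs fail loudly: a zero-norm pre-normalization projection
  raises an error rather than dividing by zero; an anchor whose EC4 class
  has no positive source directs the user to mask augmentation; a hit table
  referencing an unknown id names it.
* Augmented (mask-view) embeddings join the positive pool only — never
  anchors, negatives or centroid members. This is the minimal reading of
  "treated as a positive pair" and keeps the anchor set equal to the actual
  training proteins.

## Known limitations

* Single-label setting only: multifunction enzymes are removed during
  cleaning, and prediction transfers exactly one EC4 label per query.
* No calibrated uncertainty or abstention; the similarity score of the
  nearest neighbour is reported but not calibrated.
* The exemplar term assumes every anchor's prefix classes are present in
  the batch (guaranteed when centroids come from anchors); very small
  batches make the depth-1 term nearly vacuous when only one EC1 class is
  present — it is included as defined (the depth average does not skip such
  depths).
* Training is plain R matrix algebra: entirely adequate for desk-scale
  corpora (hundreds to tens of thousands of proteins) but not tuned for
  millions.
* The EC parser validates structure, not nomenclature: it does not check
  that a label exists in the official classification.
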