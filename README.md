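# tempemo

Measure the **temporal orientation** (past / present / future) and the
**emotion** (joy / sadness / anger / fear, with a continuous intensity in
[0, 1]) of short social-media texts, and relate the two at the user level —
without any hand-labelled temporal training data.

The package is aimed at computational behavioural scientists who want
tweet-level psycholinguistic measurements aggregated into per-user profiles:
how much of a user's feed looks backward or forward, which emotions dominate
it, and whether orientation and emotion co-vary across a population.

## The method

The pipeline has two layers:

**1. A generative labelling layer (weak supervision).** Several cheap,
noisy labelling functions assign each tweet a temporal label or abstain
(code 0): temporal-keyword lexicons, a verb-tense heuristic over PoS tags,
and two trainable weak classifiers (a linear SVM over tf-idf features and a
bidirectional recurrent classifier). Their outputs form a label matrix
Λ ∈ {0, 1, …, K}^{M×L}. A factor-graph model over (Λ, latent true labels y)
uses three dependency types per labelling function *q*:

- accuracy φ^Acc_{p,q} = 1{Λ_{p,q} = y_p}
- labelling propensity φ^Lab_{p,q} = 1{Λ_{p,q} ≠ 0}
- pairwise correlation φ^Corr_{p,q,r} = 1{Λ_{p,q} = Λ_{p,r}} for pairs
  (q, r) in an estimated dependence set S

with ρ_z(Λ_p, y) ∝ exp(w·φ_p(Λ_p, y)). The weights ŵ minimise the exact
negative log marginal likelihood −Σ_p log Σ_y ρ_z(Λ_p, y) (the normaliser is
enumerated exactly over all (K+1)^L rows × K classes; tweets factorise). The
posterior ρ_ŵ(y | Λ_p) then supplies probabilistic training labels, from
which a class-balanced training set is selected by posterior confidence.

**2. A discriminative layer (multi-task network).** A shared encoder —
word embeddings into a Bi-GRU and a width-7 CNN, concatenated and passed
through a shared MLP (hard parameter sharing) — feeds three heads: temporal
softmax (3), emotion softmax (4), and a sigmoid intensity regressor.
Training alternates mini-batches between the generatively-labelled temporal
task and an emotion-annotated corpus (categorical cross-entropy; squared
error for intensity), with rmsprop, dropout 0.2, input word dropout, batch
size 64 and up to 100 epochs. The whole network is implemented in base R
with analytic gradients, so runs are bit-reproducible under a seed.

**User level.** Predictions aggregate per user as fractions
orientation_x(u) = |tweets_x(u)| / |tweets_all(u)| over temporal classes,
emotion classes, and emotion × intensity-bin cells (VLI [0, 0.25),
LI [0.25, 0.5), MI [0.5, 0.75), HI [0.75, 1]). Associations between
user-level measures are Pearson correlations with a t-test on n − 2 df.
Ordinal emotion-intensity annotations (0–3) convert to the unit interval via
`intensity = ordinal × 0.25 + 0.125`.

A synthetic-corpus module generates marker-token tweet populations with a
planted orientation–emotion association (or none), plus a Monte-Carlo oracle
for the implied user-level correlations, so the full pipeline is testable
offline.

## Worked example

Fuse four simulated labelling functions — accuracies 0.9 / 0.75 / 0.75 /
0.55, the third copying the second 95% of the time — over 1500 tweets:

```r
library(tempemo)
set.seed(42); truth <- sample(1:3, 1500, TRUE)
lam <- simulate_lf_matrix(truth,
         list(lf_spec(0.9, 0.8), lf_spec(0.75, 0.9),
              lf_spec(0.75, 0.9, copy_of = 2, agreement = 0.95),
              lf_spec(0.55, 0.7)), seed = 42)
S <- estimate_structure(lam)   # pairs whose agreement exceeds independence
w <- fit_generative(lam, S)
w
#> factor_weights over 4 labeling functions, 3 correlation pair(s)
#>   acc: 1.953 0.705 0.968 0.944
#>   lab: -1.009 0.155 -0.016 -0.624
#>   corr: 0.11 0.176 4.419
post <- posterior_labels(w, lam)
mean(post$hard == truth)       # 0.864  (majority vote: 0.776)
```

The most accurate source gets the largest accuracy weight (1.95), and the
planted copy pair carries a large correlation weight (4.42), so the model
stops double-counting the duplicated source — which is why the fused labels
(0.864) beat majority vote (0.776).

A full experiment — simulate a 300-user population, weak-label it, fit the
generative model, train the discriminator, predict, aggregate and
correlate — is one call:

```r
cfg <- default_pipeline_config("my_run", seed = 1)
out <- run_pipeline(cfg)
subset(out$correlations, x == "frac_future" & y == "frac_joy")
#>             x        y         r      p_value   n significant
#> 3 frac_future frac_joy 0.7307810 2.416838e-51 300        TRUE
```

or from a shell: `exec/tempemo run --seed 1`.

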