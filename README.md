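# disbrnn

Per-residue prediction of **short intrinsically-disordered regions** —
runs of 3–30 consecutive residues without stable structure — in protein
chains, for structural bioinformaticians who need disorder calls with very
few false positives at proteome scale.

## The model

The predictor is a **two-stage bidirectional recurrent neural network**
(BRNN).  Stage one labels each position from its input encoding plus
recurrent context in both directions:

    o_j = N^O(i_j, h_j^F, h_j^B)
    h_j^F = N^F(i_j, h_{j-1}^F, ..., h_{j-S}^F)      h_0^F = 0
    h_j^B = N^B(i_j, h_{j+1}^B, ..., h_{j+S}^B)      h_{N+1}^B = 0

where each `N` is a two-layered feed-forward net and `S` is a shortcut
span.  Stage two is a filter network that re-reads the first stage's
output at `j` together with `2p+1` window averages over windows of width
`2w+1` anchored at `k_f = j + f (2w+1)`, `f = -p..p` — roughly 300 residues
of semi-global context (defaults `w = 7`, `p = 10`).

The per-residue input `i_j = (i^E, i^S, i^A, i^T)` combines an MSA
frequency profile (21 channels, gaps included), predicted secondary
structure (3), predicted solvent accessibility (4), and order/disorder
annotations transferred from homologous template structures weighted by
the **cube** of their sequence identity:

    T_j = [ sum_p V_{p,j} I_p^3 / sum_p I_p^3 ,  sum_p I_p^4 / sum_p I_p^3 ]

Four variants are supported: `MSA` (21 inputs/residue), `MSA-SS-SA` (28),
`MSA-Templ` (24), `MSA-SS-SA-Templ` (31).  Positions without template
coverage are left blank, so one model serves queries with and without
templates.

Training minimises cross-entropy by gradient descent with
backpropagation through structure (no momentum, no weight decay), shuffles
each epoch into batch blocks, halves the learning rate on validation
plateaus, and ensemble-averages the nine best checkpoints per
cross-validation fold (45 models in the merged five-fold predictor).
Evaluation covers MCC, balanced accuracy, ROC/PR curves and AUCs,
thresholds anchored at a target false-positive rate, termini trimming and
template-identity-binned AUC.  A synthetic-corpus generator with planted
compositional, conservation, structural and template signals makes the
whole pipeline runnable offline.

## Worked example

```r
library(disbrnn)

cfg    <- synthetic_config(n_chains = 40, seed = 7)
corpus <- generate_corpus(cfg)

fit <- disbrnn(corpus, variant = "MSA-Templ",
               config = train_config(epochs = 40, batches_per_epoch = 20,
                                     learning_rate = 0.5,
                                     n_best_checkpoints = 3, seed = 7),
               k = 5, state_width = 6, hidden_width = 6, span = 1)
print(fit)
summary(fit)
```

```
Two-stage bidirectional recurrent disorder predictor
  variant: MSA-Templ  (input width 24)
  ensemble: 15 member(s) from 5 fold(s)
  decision threshold: 0.0004804 (anchored at 5% FPR)
  held-out chains: 40
<eval_report> 7948 residues at threshold 0.0004804
SE 1.000  SP 0.950  Prec 0.561  Acc 0.975  MCC 0.730
AUC-ROC 0.9999  AUC-PR 0.9991
```

Every number is computed on pooled *out-of-fold* predictions: each chain
is scored by the ensemble of the fold that never saw it.  AUC-ROC 0.9999
says the template-informed model ranks disordered above ordered residues
almost perfectly on this synthetic corpus (templates carry only 5%
annotation noise, so this is expected).  The stored decision threshold is
the smallest score whose held-out false-positive rate stays at or below
5%; because the score distribution is sharply bimodal here, that threshold
is tiny.  At it, sensitivity is 1.000 at specificity 0.950 — precision
0.561 reflects the 6% class imbalance.

```r
p <- predict(fit, corpus[[1]])     # per-residue disorder probabilities
predict(fit, corpus[[1]], type = "class")  # 0/1 calls at the threshold
```

A shell interface wraps the same pipeline
(`inst/cli/disbrnn simulate|train|predict|evaluate`); see the script
header for flags.

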