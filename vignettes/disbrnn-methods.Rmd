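---
title: "Predicting short disordered regions with two-stage bidirectional recurrent networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting short disordered regions with two-stage bidirectional recurrent networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(disbrnn)
```

## The problem

Short intrinsically-disordered regions — runs of roughly 3 to 30
consecutive residues that adopt no stable structure — are abundant in
crystallographic data and functionally important, yet per-residue disorder
prediction is a heavily imbalanced classification problem: only about 6% of
residues in a typical X-ray-derived corpus are disordered, so useful
predictors must combine good recall with a very low false-positive rate.

`disbrnn` implements a per-residue sequence labeller for this problem: a
two-stage bidirectional recurrent neural network (BRNN) over four
complementary per-residue encodings, trained by cross-entropy gradient
descent with backpropagation through structure, evaluated with the
imbalance-robust machinery standard in the disorder-prediction community
(MCC, balanced accuracy, ROC and precision-recall curves, FPR-anchored
decision thresholds).

## The model

### Recurrent stage

A stage consists of three two-layered feed-forward subnets.  At position
$j$ of a chain of length $N$ with input encoding $i_j$:

$$
o_j = N^{(O)}\!\left(i_j, h_j^{(F)}, h_j^{(B)}\right), \qquad
h_j^{(F)} = N^{(F)}\!\left(i_j, h_{j-1}^{(F)}, \dots, h_{j-S}^{(F)}\right), \qquad
h_j^{(B)} = N^{(B)}\!\left(i_j, h_{j+1}^{(B)}, \dots, h_{j+S}^{(B)}\right)
$$

with $h^{(F)}_{0} = h^{(B)}_{N+1} = 0$ (extended over the whole shortcut
span $S$).  The forward chain carries N-terminal context, the backward
chain C-terminal context, and the shortcut span feeds each transition net
the $S$ most recent states, shortening gradient paths along the chain.
Hidden layers use $\tanh$; the output layer is a softmax over $m = 2$
classes (ordered, disordered).

### Second-stage filter

Raw per-position outputs of a single BRNN are noisy and ignore the strongly
segmental nature of disorder.  A second stage — itself a BRNN — therefore
reads, at each position $j$, the first-stage output $c_j$ concatenated with
$2p+1$ averages of first-stage outputs over contiguous windows of width
$2w+1$ anchored at $k_f = j + f\,(2w+1)$ for $f = -p, \dots, p$, i.e. a
semi-global context of $(2p+1)(2w+1)$ residues.  The filter input width is
$m(2p+2)$.  Defaults are $w = 7$, $p = 10$ (15-residue windows, 21 windows,
315 residues of context, 44 filter inputs).  Window aggregates are
*averages* with out-of-range positions dropped from the divisor; this keeps
terminal positions on the same scale as interior ones, and differs from a
plain windowed sum only by constants absorbable into the second-stage input
weights.  (The descriptive prose that usually accompanies this filter
geometry — 18 windows of 18 residues, $19m$ inputs — is inconsistent with
the defining formula at these defaults; the formula is authoritative here.)

### Input encodings

Four per-residue blocks, concatenated in fixed order (E, S, A, T):

| block | width | content |
|---|---|---|
| E | 21 | amino-acid frequency profile over the MSA column (20 residues + gap) |
| S | 3 | predicted secondary structure one-hot (helix, strand, coil) |
| A | 4 | predicted solvent accessibility one-hot (completely buried, partly buried, partly exposed, exposed) |
| T | 3 | template transfer: cubed-identity-weighted order/disorder state + significance score |

yielding the four system variants MSA (21), MSA-SS-SA (28), MSA-Templ (24)
and MSA-SS-SA-Templ (31 inputs per residue).

The template block at position $j$ is

$$
T_j = \left[\frac{\sum_p V_{p,j}\, I_p^3}{\sum_p I_p^3},\;
\mathrm{score}_j\right], \qquad
\mathrm{score}_j = \frac{\sum_p I_p^4}{\sum_p I_p^3}
$$

where $I_p$ is the sequence identity of template $p$ to the query,
$V_{p,j}$ is $(1,0)$ for an ordered and $(0,1)$ for a disordered template
residue, and all sums run over the hits covering $j$.  Cubing the identity
makes a 90%-identity template weigh about two orders of magnitude more
than a 20% one.  The score is a weighted mean of identities and so always
lies between the smallest and largest covering identity.  Positions no hit
covers (and chains with no hits at all) are left blank — all-zero — so a
single trained network serves queries with and without templates.  Because
hits may cover only fragments, both the weighted state and the score are
computed per position over the covering hits; a per-protein score would be
ill-defined for fragment templates.  Hits above 95% identity are removed
before encoding (`filter_hits_by_identity()`), with a 50% cap available for
low-homology evaluation protocols.

Profiles count the query row (so singleton alignments give exact one-hots),
drop alignment columns where the query is gapped (query coordinates define
positions), and spread nonstandard letters uniformly over the 20 amino-acid
channels.

### Baseline

`nn_baseline()` provides the conventional fixed-window feed-forward
comparator: a single-hidden-layer softmax network over a sliding window of
21 residues with 20 hidden units (a 441-wide fan-in on the 21-channel
profile encoding).  It is a forward-pass reference model for architecture
comparisons, not part of the training pipeline.

## Training

The loss is the summed per-residue cross-entropy of *both* stages — the
final output plus an auxiliary term on the stage-1 output — and its exact
gradient is computed by backpropagation through structure, including the
path from the second stage through the window filter back into the first.
The auxiliary term gives the first stage a direct training signal from the
start; without it, early learning depends entirely on gradients diluted
through the window averages.  Optimisation is plain gradient descent with
no momentum and no weight decay: each epoch the training chains are
reshuffled and cut into `batches_per_epoch` contiguous blocks (500 at full
scale, so 500 weight updates per epoch), gradients are summed over all
residues of a block and applied once, scaled by `learning_rate /
residues-in-block`.

After every epoch the validation cross-entropy is recorded; it drives two
mechanisms:

* **learning-rate halving** — the rate is halved whenever no new best
  validation error has been seen for `lr_halving_patience` epochs
  (default 500);
* **checkpoint ensembling** — the `n_best_checkpoints` (default 9)
  parameter snapshots with the best validation error are retained, and the
  returned predictor is their unweighted probability average.  Averaging
  probabilities can only improve the expected cross-entropy (Jensen's
  inequality), and with five cross-validation folds the merged final
  predictor holds 45 members.

Under five-fold cross-validation (`crossvalidate()`, or `disbrnn()` with
`folds`), each fold's model is trained on the other four folds with an
eighth of those chains carved out — deterministically under the run seed —
as the validation set for halving and checkpoint ranking.  The held-out
fold is never touched during training, so the pooled out-of-fold
predictions are honest estimates for every chain.

### Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `state_width` | 11 | width of each hidden-state chain |
| `hidden_width` | 11 | hidden layer width of every subnet |
| `span` | 2 | shortcut span $S$ |
| `w`, `p` | 7, 10 | filter window half-width / half-count |
| `epochs` | 2000 | full-scale training length |
| `batches_per_epoch` | 500 | weight updates per epoch |
| `learning_rate` | 0.05 | per-residue step size |
| `lr_halving_patience` | 500 | epochs without improvement before halving |
| `n_best_checkpoints` | 9 | ensemble members per training |

The hidden sizes are deliberately small — the architecture's capacity comes
from recurrence and the two-stage composition, not width — and everything
is configurable.  Weights start uniform in $\pm 1/\sqrt{\text{fan-in}}$
under the run seed; the whole training path is reproducible from
`train_config(seed = )`.

**Scaled-down schedule.**  The package's own experiments (test suite,
`scripts/acceptance.R`) train 100 epochs of 50 blocks with 6-wide stages,
span 1 and learning rate 0.5 on a 200-chain synthetic corpus.  The larger
step compensates for the 20-fold shorter schedule: at 0.05 the optimiser
has not yet left the predict-the-majority-class regime after 100 epochs,
while at 0.5 both variants converge; the full-scale defaults above remain
the documented reference configuration.  These problem sizes (200 chains of
80–300 residues, five folds, two variants) complete in a few minutes on one
CPU core.

## Corpus handling

`filter_chains()` applies the selection rules for a short-disorder corpus:
length strictly greater than 50; at least one maximal disordered run of
length ≥ 3; **no** maximal run longer than 30 (a chain carrying both a
short and a long run is rejected — the target is chains whose disorder is
short); X-ray resolution strictly below 2.0 Å where recorded.
`redundancy_reduce()` removes, greedily, the lesser-quality member of any
pair above 30% mutual identity; quality is resolution when available
(missing resolution ranks below any measured one), then chain length,
then lexicographic id.  Identity comes from an external matrix or, as a
fallback, a built-in global-alignment identity (matches divided by the
shorter length).  `make_folds()` assigns chains to five folds uniformly at
random under a seed; at realistic corpus sizes residue counts balance
themselves, and the observed spread is reported.

## Evaluation

`binary_metrics()` implements the standard confusion-based measures —
sensitivity, specificity, precision, balanced accuracy $(SE+SP)/2$ and
MCC — with a residue called disordered when its probability is **greater
than or equal to** the threshold.  Conventions where the definitions run
out: any zero denominator inside MCC yields 0; undefined ratios are `NA`.
ROC curves sweep all distinct scores; the trapezoidal area equals the
Mann–Whitney pair-counting statistic with ties worth one half, and the test
suite verifies this equality exhaustively on small instances.
Precision-recall areas use the trapezoid over recall, documented as an
approximation since PR curves are not monotone and admit several
interpolation conventions.  `threshold_at_fpr()` anchors the decision
threshold at a target training-set FPR (default 5%): the smallest observed
score whose FPR does not exceed the target, which with untied scores
realizes the target to within one negative count.  `trim_termini()` drops a
fixed flank (conventionally 10 residues) from each chain end to isolate
internal-disorder performance, removing chains that trimming would exhaust.
`auc_by_identity_bins()` stratifies chains by best-template identity into
10% bins (half-open, top bin closed) to show where template transfer helps.

## The synthetic corpus

Real corpora require structure databases, sequence searches and external
structure-prediction servers.  So that every stage of the pipeline is
exercisable — and testable — offline, `generate_corpus()` builds a corpus
with the statistical features the predictor exploits:

* chains of 80–300 residues with disordered runs of 3–30 residues planted
  at ~6% residue prevalence, runs separated by at least one ordered
  residue;
* a compositional signal: disordered segments are enriched in P/E/S/K/Q/G
  and depleted in W/C/F/I/Y/V, ordered segments the reverse;
* MSAs whose non-query rows mutate at 10% per residue in ordered and 40%
  in disordered columns (disorder is less conserved), with 2% gaps so the
  21st profile channel is exercised; zero-divergence alignments are
  emitted gap-free;
* secondary-structure and accessibility strings emitting coil/exposed for
  disordered and helix-strand/buried for ordered residues with probability
  0.85;
* template hits at chosen identities whose annotations flip the true label
  with a chosen noise rate (defaults: identities 0.80–0.95, 5% noise); the
  first hit covers the whole chain, later hits may cover only fragments.

What this does **not** emulate: real amino-acid composition, long-range
structural correlations, alignment depth heterogeneity, correlated errors
in predicted structure, or any relationship between templates beyond
identity and noise.  Passing the learning tests therefore shows that the
architecture, encodings, gradients and training loop work end to end and
that template information is integrated usefully — not that real-data
accuracies are reproduced.  On this synthetic corpus the sequence-only
variant reaches out-of-fold AUC above 0.99 and the template variant above
it again; both margins are far clearer than on real data, where the
corresponding signals are weaker and noisier.

## Numerical choices

* Probabilities are floored at $10^{-12}$ inside cross-entropy.
* Softmax columns are max-shifted before exponentiation.
* Gradient correctness is enforced by test: central finite differences on
  random small instances agree with the analytic gradient to relative
  error below $10^{-5}$.
* Model containers serialize every parameter as JSON at 17 significant
  digits, so write–read round trips reproduce predictions bit-exactly.
* Ties in ROC sweeps are collapsed into single threshold steps (the ½
  convention); ties in redundancy reduction and checkpoint ranking break
  deterministically (lexicographic id, earlier epoch).

## Known limitations

* PR-AUC interpolation is a convention, not a canonical quantity; values
  from other packages may differ in the third decimal.
* The built-in alignment identity is a fallback for small corpora; large
  corpora should supply a precomputed identity matrix.
* The feed-forward baseline is inference-only.
* Training is single-threaded; fold-level parallelism is possible but not
  built in.
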