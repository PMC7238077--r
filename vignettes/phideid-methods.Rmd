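---
title: "Methods: collaborative privacy-preserving training of a PHI tagger"
author: "phideid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: collaborative privacy-preserving training of a PHI tagger}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Clinical free text cannot be shared for research until protected health
information (PHI) — names, dates, contact details, identifiers, locations,
ages, professions — has been removed. Supervised taggers do this well, but
they need annotated clinical notes to train on, and those notes are exactly
the data that cannot be pooled. `phideid` implements a per-token PHI tagger
and four ways of training it across data silos, from the nonprotective pooled
baseline to a privacy-preserving protocol in which sites exchange only small,
censored fractions of their parameter updates.

## The tagger

Each input fragment is a token sequence $T = (t_1, \dots, t_n)$. Tokens are
embedded twice:

* **Word channel.** A fixed, pretrained embedding table maps the lower-cased
  token to $x_i \in \mathbb{R}^{300}$ (out-of-vocabulary tokens map to the
  zero vector, which is neutral under concatenation with the learned
  character embedding). When no pretrained table is supplied, a seeded random
  table with entries uniform on $[-0.1, 0.1]$ keeps words distinguishable.
* **Character channel.** Every character becomes a 128-dim one-hot vector:
  code points below 127 get their own slot, everything else shares the last
  slot. A bidirectional LSTM runs over the character sequence and the two
  final hidden states are kept. Unlike the word channel, no case folding is
  applied here — capitalization is signal for PHI detection.

The token embedding is the concatenation
$e_i = (x_i, h^{for}_{len}, h^{back}_{len})$, of length 556 at the published
sizes. A second bidirectional LSTM runs over $(e_1, \dots, e_n)$ and its
per-position states $d_i$ (length 200) feed a position-shared feedforward
head $l_i = \tanh(W_1 d_i + b_1)$, $a_i = \mathrm{softmax}(W_2 l_i + b_2)$
over the 29 labels (28 PHI subclasses + non-PHI). The softmax subtracts the
row maximum before exponentiating; argmax ties break toward the lowest label
index. The training loss is the summed cross-entropy
$E(p) = -\sum_i \log a_i[\mathrm{class}(t_i)]$.

All recurrent cells are the **coupled-gate LSTM** variant: the forget gate is
$1 - i_t$, and a constant $+1$ is added inside the input-gate sigmoid,

$$i_t = \sigma(W_i\,[z_t; h_{t-1}] + b_i + 1),$$

which biases the cell toward retaining memory early in training (the analogue
of the common unit forget-gate bias). This exact form — not the textbook
LSTM — is implemented, and the backward pass is derived for it; the gradient
is validated against central finite differences on tiny configurations in the
test suite.

Two printed-formula details were resolved as typos: the label-layer
definitions $d_i = \mathrm{concat}(h^{for}_1, h^{back}_1)$ and
$l_i = \tanh(W_1 d_1 + b_1)$ use a constant subscript 1 where the position
index $i$ is clearly intended (a constant $d$ would make every token receive
the same label); both are implemented with index $i$.

### Dropout and initialization

Inverted dropout with rate 0.5 is applied to the token-embedding sequence
$(e_1, \dots, e_n)$ during training only, with a fresh seeded mask per
training sequence; inference applies no dropout. Hidden and cell states start
at zero. Weight matrices initialize uniform on $(-r, r)$ with
$r = \sqrt{6/(\text{fan}_{in} + \text{fan}_{out})}$; biases start at zero.
Dropout is not optional decoration here: in desk-scale pilots the tagger
reliably collapses onto the majority (non-PHI) class without it.

### The SGD step

Training is strictly per-sample stochastic gradient descent: one gradient
step per fragment, fragments shuffled each epoch, fixed learning rate
$\eta = 0.9$. The step uses the token-averaged gradient,
$p \leftarrow p - (\eta / n)\,\partial E/\partial p$: the summed
cross-entropy makes the raw gradient scale linearly with fragment length, and
a raw step at $\eta = 0.9$ diverges within an epoch or two at any scale we
tried, while the token-mean step (the standard normalization, and what a
`reduce_mean` cross-entropy computes) converges smoothly. The loss and
gradient functions themselves report the unnormalized sum.

## Training regimes

* **Centralized (A).** All data pooled, sequential SGD epochs. The
  nonprotective gold standard.
* **Round robin (B).** Workers hold their data; the single model is passed
  from worker to worker in fixed order, each running one local epoch. Data
  stay local but the full model circulates.
* **DSSGD (C).** Each worker keeps a local model; a parameter server keeps
  global weights and a per-weight update counter. Per local epoch a worker
  (1) downloads the $\lfloor\theta_d\,\mathrm{len}(p)\rfloor$ most-updated
  global weights (ties toward the lowest index) and overwrites its local
  copies, (2) runs one local SGD epoch, (3) forms the cumulative weight
  change since the post-download state, and (4) uploads a censored selection
  of it: values with $|\Delta| \le \tau$ are withheld, survivors are clamped
  to $[-\gamma, \gamma]$, and if more than
  $\lfloor\theta_u\,\mathrm{len}(p)\rfloor$ survive, a uniform random subset
  of that size is sent. The server adds uploaded values immediately and
  increments their counters.
* **Local only (D).** Independent training per worker, no exchange.

Seed conventions make the regimes commensurable: the SGD seed of worker $k$
in epoch $e$ is a fixed function of the run seed, so round robin with one
subset, and single-worker DSSGD with $\theta_d = \theta_u = 1$, $\tau = 0$,
$\gamma = \infty$, reproduce the centralized trajectory exactly — both are
asserted to 1e-10 in the tests.

Design points that the protocol description leaves open, and what this
package does:

* *Update unit.* The shared "update" is the cumulative parameter delta over
  one local epoch measured from the post-download weights — the
  once-per-epoch exchange cadence rules out per-sample gradient sharing.
* *$\theta_u$ base.* The upload cap is a fraction of the **total** parameter
  count, not of the survivors; fewer survivors are all sent.
* *Order of censoring.* Threshold (strict $>\tau$) first, then clamping,
  then uniform subsampling.
* *Downloads overwrite.* Downloaded global values replace local values
  rather than blending.
* *Asynchrony.* Simulated in-process: each round, workers run in a seeded
  random permutation, each seeing the server exactly as the previous worker
  left it. True lock-free behavior is out of scope; this keeps runs bitwise
  reproducible.
* *$\theta_d = 0$.* Allowed as "skip the download". This is the natural
  degenerate endpoint and makes silent workers ($\theta_u = 0$,
  $\theta_d = 0$) coincide exactly with isolated local training; with any
  $\theta_d > 0$ and no uploads, downloads would keep re-injecting initial
  weights into a drifting local model.
* *First-round downloads.* With all-zero counters the tie-break hands every
  worker the same lowest-index slice; a randomized variant would differ.

## Evaluation

Scoring is binary at the token level: a predicted PHI token is a true
positive iff the gold label is any PHI class — confusing a patient name with
a clinician name still counts, because the downstream action (redaction) is
the same. Precision, recall and F1 follow from the counts; the corpus is
micro-averaged over the concatenated test tokens. The degenerate all-negative
case (no gold PHI, none predicted) is defined as 1.0 so PHI-free fragments do
not poison per-fragment diagnostics; corpus-level scores are unaffected.
Multi-worker learning curves aggregate per epoch into mean/min/max over
workers.

## The synthetic corpus generator

The study corpus (1,304 longitudinal records of 296 patients from the 2014
de-identification challenge) is access-restricted, so the package bundles a
seeded generator that emulates its statistical shape rather than its content:

* filler prose from a seeded bigram sampler over a clinical core vocabulary
  extended with pseudo-words (vocabulary size configurable, default 2000);
* PHI entities from surrogate lexicons (names, cities, hospitals, ...) and
  per-class format grammars for digit-bearing classes (phones, dates in five
  dialects, record numbers, zips), so the character channel carries real
  signal — the reason character embeddings help;
* class-typical non-PHI cue words ("on" before dates, "Dr ." before
  clinicians) with probability 0.6, giving the label LSTM context to use;
* a target PHI token rate of 0.028 (≈17,000 PHI in ≈598,000 training
  tokens), calibrated by solving the per-token entity-insertion probability
  from the estimated mean entity and cue lengths;
* uniform weights over the 23 PHI classes attested in the published data
  (the class histogram is unpublished; the five footnoted-absent classes
  never appear);
* 50 patients × 2–6 records × 100–400 tokens by default, records cut into
  6–18-token lines (one line = one training fragment; the fragment
  definition is this package's choice, with a 100-token cap available for
  externally supplied corpora), recurring patient names across a patient's
  records, and a patient-disjoint train/test split targeting the study's
  0.39 test token share.

What the generator does **not** emulate: real clinical syntax and semantics,
the true PHI class histogram, annotation-guideline edge cases, surrogate
consistency across institutions, and document-level structure. Passing the
package's experiments therefore shows that the architecture and the protocols
behave as described on data of this shape — it does not certify performance
on real clinical text.

## Desk-scale experiment sizes

The published experiments (full topology, ≈615k parameters, 598k training
tokens, 200 epochs, GPU) are out of desk scope. The package's experiments use
a scaled profile chosen once: word vectors of length 32, hidden sizes 16
(≈23k parameters), ≈30k training tokens over 50 patients split across 5
workers, 20 epochs at $\eta = 0.9$. At this scale a single training run takes
on the order of 1–2 minutes on one CPU. The robust qualitative structure of
the full-scale comparison reproduces: centralized and round robin are nearly
identical and best, collaboration through DSSGD at $\theta_d = 0.1$ clearly
beats isolated local training (the acceptance run and the replicate-seed test
both show double-digit mean-F1 gaps), and centralized training stays at or
above DSSGD. Finer-grained relations are noisy at 1/20 of the training data
and 1/10 of the epochs: the per-worker DSSGD band can be wide, and the
relative order of the $\theta_d = 0.1$ and $\theta_d = 0.5$ variants varies
with the seed rather than consistently favoring the low download rate. The
full-scale headline F1 values are properties of the restricted corpus and
full-scale training and are not reproduction targets here.

## Numerical and degenerate-input choices

* Softmax with max-subtraction; probabilities sum to 1 within 1e-9.
* Argmax tie-break: lowest label index.
* Empty documents, empty token strings, unknown labels, length mismatches
  and out-of-range upload indices are errors, not warnings.
* $|\Delta| = \tau$ exactly is withheld (strict threshold).
* `floor()` in both exchange-rate counts; $\theta_u$ small enough to floor
  to zero uploads nothing.
* Checkpoints round-trip bitwise (RDS container holding config, label
  scheme, index map, flat values, and the embedding table).

## Known limitations

* The tokenizer is a deterministic regex (words and numbers with internal
  hyphens/periods kept whole, other punctuation split); it is not a clinical
  tokenizer and differs from toolkit tokenizers on edge cases.
* OOV handling (zero vector) and lower-cased word lookup are conventions the
  original description leaves open.
* No CRF head, no minibatching, no GPU path, no differential-privacy noise,
  no defense against dishonest participants (the protocol assumes
  honest-but-curious parties).
* The i2b2 XML converter is a declared stub; restricted data must be
  converted to the token/label format externally.
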