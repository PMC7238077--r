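# phideid

Privacy-preserving collaborative training of a clinical PHI tagger.

## The problem

Clinical notes cannot be shared until protected health information (PHI) —
names, dates, phone numbers, identifiers, locations, ages, professions — has
been removed. The best de-identification systems are supervised sequence
taggers, but their training data are annotated clinical notes: exactly the
records that sites are not allowed to pool. `phideid` is for researchers who
want to study this dilemma empirically. It implements:

* a **character-enhanced bidirectional LSTM token tagger**: each token
  $t_i$ is embedded as $e_i = (x_i, h^{for}, h^{back})$, the
  concatenation of a pretrained word vector $x_i \in \mathbb{R}^{300}$ with
  the final states of a bi-LSTM over the token's 128-dim one-hot encoded
  characters; a second bi-LSTM over $(e_1,\dots,e_n)$ feeds a
  $\tanh$/softmax head that assigns each token one of 29 labels (28 PHI
  subclasses + non-PHI). All recurrent cells are the coupled-gate variant
  $i_t = \sigma(W_i[z_t;h_{t-1}] + b_i + 1)$,
  $c_t = i_t \odot c_{t-1} + (1-i_t) \odot \tanh(W_c[z_t;h_{t-1}] + b_c)$,
  with full backpropagation implemented in C++ over a single flattened
  parameter vector;
* **four training regimes** over data silos: centralized SGD (the
  nonprotective baseline), round-robin cyclic weight transfer, **DSSGD**
  (distributed selective stochastic gradient descent: workers exchange only
  thresholded ($\tau$), clamped ($\gamma$), randomly subsampled
  ($\theta_u$) parameter updates through a server that serves each worker
  the $\theta_d$-fraction of most-updated weights), and isolated local
  training;
* a **seeded synthetic corpus generator** producing annotated pseudo-clinical
  text with the statistical shape of the 2014 de-identification challenge
  data (~2.8% PHI tokens over the 23 attested PHI classes, multiple records
  per patient, patient-disjoint splits), so every experiment runs at desk
  scale with no restricted data;
* **binary PHI scoring**: token-level precision/recall/F1 on the
  PHI-vs-non-PHI decision, ignoring the specific PHI class, plus
  learning-curve aggregation (mean/min/max over workers).

## Worked example

```r
library(phideid)

# 1. synthetic annotated corpus: 50 patients, ~50k tokens, ~2.8% PHI tokens
spec <- corpus_spec(seed = 5)
corpus <- generate_corpus(spec)
split <- split_train_test(corpus, test_fraction = 0.39, seed = 2)

# 2. desk-scale network + seeded random word vectors over the train vocabulary
net <- network_profile("desk")
vocab <- unique(tolower(unlist(lapply(split$train, `[[`, "tokens"))))
table <- make_random_table(vocab, dim = net$word_dim, seed = 3)
params <- init_parameters(net, seed = 4)

# 3. twenty epochs of centralized SGD at the study's learning rate
fit <- train_centralized(params, split$train, table, epochs = 20,
                         eta = 0.9, seed = 9, keep_trajectory = FALSE)

# 4. binary PHI scoring on the patient-disjoint test set
evaluate_tagger(fit$params, split$test, table)
#> <phi_metrics: tp 465 fp 3 fn 22 tn 19773 | P 0.9936 R 0.9548 F1 0.9738>
```

The counts are over the ~20k test tokens: 465 of the 487 gold PHI tokens were
flagged (recall 0.955) with only 3 false alarms (precision 0.994), giving a
binary PHI F1 of 0.974. Swapping step 3 for `train_dssgd()` or
`train_local_only()` over a `partition_by_patient()` of the training set
reproduces the collaborative-vs-isolated comparison; `worker_config()` holds
the DSSGD exchange parameters (`theta_d`, `theta_u`, `gamma`, `tau`).

The same pipeline is scriptable from a shell via `inst/scripts/phideid`
(subcommands `generate`, `train` — with presets `A`, `B`, `C_0.1`, `C_0.5`,
`D` for the five study configurations — `evaluate`, and `curves`).

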