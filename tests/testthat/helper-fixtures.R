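# Shared fixtures: tiny network configurations, small corpora and the
# finite-difference oracle used to check backpropagation.

tiny_config <- function(dropout_rate = 0) {
  network_config(word_dim = 5L, char_hidden = 4L, label_hidden = 3L,
                 ff_hidden = 3L, dropout_rate = dropout_rate)
}

tiny_table <- function(words = c("alpha", "beta", "gamma", "x1"),
                       dim = 5L, seed = 3L) {
  make_random_table(words, dim = dim, seed = seed)
}

# A small deterministic hand-built corpus: 6 documents over 3 patients.
tiny_corpus <- function() {
  mk <- function(doc, pat, toks, labs) labeled_document(doc, pat, toks, labs)
  list(
    mk("d1", "p1", c("Patient", "Alice", "Smith", "seen", "today"),
       c("non-PHI", "patient", "patient", "non-PHI", "non-PHI")),
    mk("d2", "p1", c("Followup", "on", "2010-03-14", "went", "well"),
       c("non-PHI", "non-PHI", "date", "non-PHI", "non-PHI")),
    mk("d3", "p2", c("Admitted", "to", "Salem", "General", "Hospital"),
       c("non-PHI", "non-PHI", "hospital", "hospital", "hospital")),
    mk("d4", "p2", c("Call", "(", "555", ")", "123-4567", "anytime"),
       c("non-PHI", "phone", "phone", "phone", "phone", "non-PHI")),
    mk("d5", "p3", c("Labs", "were", "unremarkable", "again"),
       rep("non-PHI", 4)),
    mk("d6", "p3", c("Age", "67", ",", "works", "as", "carpenter"),
       c("non-PHI", "age", "non-PHI", "non-PHI", "non-PHI", "profession"))
  )
}

# Random labeled document over a fixed small vocabulary.
random_doc <- function(n_tokens, doc_id = "r1", patient_id = "pr1") {
  scheme <- build_label_scheme()
  toks <- sample(c("alpha", "beta", "Gamma", "x1", "42", "zz-9", "."),
                 n_tokens, replace = TRUE)
  labs <- sample(c(scheme$present_phi_labels, rep("non-PHI", 40)),
                 n_tokens, replace = TRUE)
  labeled_document(doc_id, patient_id, toks, labs)
}

# Seeded random corpus with patients of varying size (for property tests).
random_corpus <- function(n_docs, n_patients = max(2L, n_docs %/% 2L)) {
  lapply(seq_len(n_docs), function(i) {
    random_doc(sample(2:9, 1), doc_id = paste0("doc", i),
               patient_id = paste0("pat", sample(n_patients, 1)))
  })
}

# Central finite differences of the tagger loss, the module's gradient
# oracle. Independent of the backpropagation path.
fd_gradient <- function(params, doc, table, idx, eps = 1e-4,
                        dropout_seed = NULL) {
  vapply(idx, function(j) {
    pp <- params; pp$values[j] <- pp$values[j] + eps
    pm <- params; pm$values[j] <- pm$values[j] - eps
    (tagger_loss(pp, doc, table, dropout_seed = dropout_seed) -
       tagger_loss(pm, doc, table, dropout_seed = dropout_seed)) / (2 * eps)
  }, numeric(1))
}

# Relative disagreement with a floor that absorbs the floating-point noise of
# the finite-difference quotient on near-zero coordinates.
rel_err <- function(a, b, floor = 1e-6) abs(a - b) / pmax(abs(a) + abs(b), floor)

total_tokens <- function(corpus) {
  sum(vapply(corpus, function(d) length(d$tokens), integer(1)))
}

# Copy of the internal value-replacement helper for use in tests.
set_values_test <- function(params, values) {
  params$values <- as.numeric(values)
  params
}
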