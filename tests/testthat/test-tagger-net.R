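# Unit tests for the network core. The gradient itself is checked against
# finite differences in test-acceptance.R; here the focus is on the cell
# arithmetic, shapes, and the probabilistic contracts of the forward pass.

zero_lstm <- function(hid, inp) {
  list(W_i = matrix(0, hid, inp + hid), W_c = matrix(0, hid, inp + hid),
       W_o = matrix(0, hid, inp + hid), b_i = numeric(hid),
       b_c = numeric(hid), b_o = numeric(hid))
}

test_that("coupled-gate cell matches direct evaluation of its formulas", {
  # all-zero parameters and states: tanh(0) = 0 forces h = c = 0
  P <- zero_lstm(3, 2)
  st <- lstm_step(c(1, -2), numeric(3), numeric(3), P)
  expect_identical(st$h, c(0, 0, 0))
  expect_identical(st$c, c(0, 0, 0))

  # scalar cell, zero weights, c_prev = 1: the +1 inside the input gate
  # gives i = sigma(1), c = sigma(1), h = sigma(0) * tanh(c)
  # (values computed by direct evaluation of the printed formulas)
  P1 <- zero_lstm(1, 1)
  st1 <- lstm_step(0, 0, 1, P1)
  expect_equal(st1$c, 0.7310585786300049, tolerance = 1e-12)
  expect_equal(st1$h, 0.3118562749129378, tolerance = 1e-12)

  # general case against an independent R transcription of the equations
  set.seed(11)
  hid <- 4L; inp <- 3L
  P2 <- list(W_i = matrix(rnorm(hid * (inp + hid)), hid),
             W_c = matrix(rnorm(hid * (inp + hid)), hid),
             W_o = matrix(rnorm(hid * (inp + hid)), hid),
             b_i = rnorm(hid), b_c = rnorm(hid), b_o = rnorm(hid))
  z <- rnorm(inp); h0 <- rnorm(hid); c0 <- rnorm(hid)
  zh <- c(z, h0)
  i_t <- plogis(drop(P2$W_i %*% zh) + P2$b_i + 1)
  c_t <- i_t * c0 + (1 - i_t) * tanh(drop(P2$W_c %*% zh) + P2$b_c)
  o_t <- plogis(drop(P2$W_o %*% zh) + P2$b_o)
  st2 <- lstm_step(z, h0, c0, P2)
  expect_equal(st2$c, c_t, tolerance = 1e-12)
  expect_equal(st2$h, o_t * tanh(c_t), tolerance = 1e-12)

  expect_error(lstm_step(z, rnorm(2), rnorm(2), P2), "hidden size")
})

test_that("bilstm respects sequence symmetry and zero propagation", {
  set.seed(21)
  hid <- 3L; inp <- 2L
  rnd_lstm <- function() list(
    W_i = matrix(rnorm(hid * (inp + hid), sd = 0.4), hid),
    W_c = matrix(rnorm(hid * (inp + hid), sd = 0.4), hid),
    W_o = matrix(rnorm(hid * (inp + hid), sd = 0.4), hid),
    b_i = rnorm(hid, sd = 0.2), b_c = rnorm(hid, sd = 0.2),
    b_o = rnorm(hid, sd = 0.2))
  Pf <- rnd_lstm(); Pb <- rnd_lstm()

  # length-1 sequences: "last" and "full"[, 1] coincide
  z1 <- matrix(rnorm(inp), ncol = 1)
  expect_equal(bilstm(z1, Pf, Pb, "last"), drop(bilstm(z1, Pf, Pb, "full")))

  # zero parameters give zero output
  Z <- matrix(rnorm(inp * 4), inp)
  expect_identical(bilstm(Z, zero_lstm(hid, inp), zero_lstm(hid, inp),
                          "last"), numeric(2 * hid))

  # reversing the input swaps the roles of the two directions
  for (rep in 1:5) {
    Z <- matrix(rnorm(inp * sample(2:6, 1)), inp)
    Zr <- Z[, rev(seq_len(ncol(Z))), drop = FALSE]
    out <- bilstm(Z, Pf, Pb, "last")
    out_rev <- bilstm(Zr, Pb, Pf, "last")
    expect_equal(out, c(out_rev[(hid + 1):(2 * hid)], out_rev[1:hid]),
                 tolerance = 1e-12)
  }
  expect_error(bilstm(matrix(0, inp, 0), Pf, Pb), "nonempty")
})

test_that("token embeddings have the published length and are reproducible", {
  params <- init_parameters(network_config(), seed = 2)
  cf <- lstm_params_from_vector(params, "char_fwd")
  cb <- lstm_params_from_vector(params, "char_bwd")
  tab <- make_random_table("alpha", dim = 300, seed = 1)

  e <- token_embedding("Unseen-Word", tab, cf, cb)
  expect_length(e, 556L) # 300 + 2 * 128
  expect_identical(e, token_embedding("Unseen-Word", tab, cf, cb))

  # zero char parameters and an OOV token give the all-zero embedding
  z <- zero_lstm(128, 128)
  expect_identical(token_embedding("xyz", tab, z, z), numeric(556))

  cfg <- network_config()
  expect_identical(cfg$e_dim, 556L)
  expect_identical(cfg$d_dim, 200L)
})

test_that("parameter vector layout is disjoint, covering, and seeded", {
  cfg <- tiny_config()
  layout <- param_layout(cfg)
  covered <- unlist(Map(function(s, l) s:(s + l - 1), layout$start,
                        layout$length))
  expect_identical(sort(covered), seq_len(n_parameters(cfg)))

  p1 <- init_parameters(cfg, seed = 5)
  p2 <- init_parameters(cfg, seed = 5)
  p3 <- init_parameters(cfg, seed = 6)
  expect_identical(p1$values, p2$values)
  expect_false(identical(p1$values, p3$values))
  expect_length(p1$values, n_parameters(cfg))
  expect_true(all(abs(p1$values) < 1))
  # biases start at zero
  expect_identical(param_slice(p1, "char_fwd.b_i"), numeric(cfg$char_hidden))
  expect_identical(param_slice(p1, "b_2"), numeric(29))
  # published topology size: 4 LSTMs + feedforward head
  expect_identical(n_parameters(network_config()),
                   2L * (3L * 128L * 256L + 3L * 128L) +
                     2L * (3L * 100L * 656L + 3L * 100L) +
                     100L * 200L + 100L + 29L * 100L + 29L)
})

test_that("forward pass yields proper per-token distributions", {
  cfg <- tiny_config()
  tab <- tiny_table()
  params <- init_parameters(cfg, seed = 8)
  withr::local_seed(31)
  for (rep in 1:5) {
    doc <- random_doc(sample(1:8, 1))
    probs <- tagger_forward(doc, params, tab)$probabilities
    expect_identical(dim(probs), c(length(doc$tokens), 29L))
    expect_true(all(probs >= 0))
    expect_equal(rowSums(probs), rep(1, nrow(probs)), tolerance = 1e-9)
  }

  # zero parameters: uniform 1/29 everywhere, argmax tie-break at label 1
  pz <- init_parameters(cfg, seed = 1)
  pz$values[] <- 0
  doc <- random_doc(4)
  probs <- tagger_forward(doc, pz, tab)$probabilities
  expect_equal(unname(probs), matrix(1 / 29, 4, 29), tolerance = 1e-12)
  scheme <- build_label_scheme()
  expect_identical(predict_labels(doc, pz, tab),
                   rep(scheme$labels[1], 4))
})

test_that("token order matters to the label layer", {
  cfg <- tiny_config()
  tab <- tiny_table()
  params <- init_parameters(cfg, seed = 12)
  doc <- labeled_document("o1", "p", c("alpha", "beta", "x1", "42"),
                          rep("non-PHI", 4))
  rev_doc <- labeled_document("o2", "p", rev(doc$tokens), doc$labels)
  d1 <- tagger_forward(doc, params, tab, want_states = TRUE)$label_states
  d2 <- tagger_forward(rev_doc, params, tab, want_states = TRUE)$label_states
  expect_false(isTRUE(all.equal(d1[1, ], d2[4, ])))
})

test_that("loss matches its closed forms and prediction is argmax", {
  cfg <- tiny_config()
  tab <- tiny_table()
  scheme <- build_label_scheme()

  # uniform output: E = n * ln(29)
  pz <- init_parameters(cfg, seed = 1); pz$values[] <- 0
  withr::local_seed(17)
  for (n in c(1, 3, 7)) {
    doc <- random_doc(n)
    expect_equal(tagger_loss(pz, doc, tab), n * log(29), tolerance = 1e-9)
  }

  # loss reads only the true-class coordinate; prediction follows the max
  params <- init_parameters(cfg, seed = 3)
  doc <- random_doc(5)
  probs <- tagger_forward(doc, params, tab)$probabilities
  gold <- label_index(scheme, doc$labels) + 1L
  expect_equal(tagger_loss(params, doc, tab),
               -sum(log(probs[cbind(1:5, gold)])), tolerance = 1e-9)
  expect_identical(predict_labels(doc, params, tab),
                   scheme$labels[apply(probs, 1, which.max)])
})

test_that("C++ forward agrees with the R-composed reference network", {
  cfg <- tiny_config()
  tab <- tiny_table()
  params <- init_parameters(cfg, seed = 23)
  withr::local_seed(23)
  params$values <- params$values +
    stats::runif(length(params$values), -0.02, 0.02)
  doc <- labeled_document("ref", "p", c("Alpha", "42", "zz-9"),
                          c("patient", "age", "non-PHI"))

  # reference path: R bilstm over characters, then R bilstm over embeddings,
  # then the feedforward head in plain R
  cf <- lstm_params_from_vector(params, "char_fwd")
  cb <- lstm_params_from_vector(params, "char_bwd")
  lf <- lstm_params_from_vector(params, "label_fwd")
  lb <- lstm_params_from_vector(params, "label_bwd")
  E <- vapply(doc$tokens, function(tk) token_embedding(tk, tab, cf, cb),
              numeric(cfg$e_dim))
  D <- bilstm(E, lf, lb, mode = "full")
  W1 <- param_slice(params, "W_1"); b1 <- param_slice(params, "b_1")
  W2 <- param_slice(params, "W_2"); b2 <- param_slice(params, "b_2")
  S <- W2 %*% tanh(W1 %*% D + b1) + b2
  ref <- t(apply(S, 2, function(s) { e <- exp(s - max(s)); e / sum(e) }))

  got <- tagger_forward(doc, params, tab)$probabilities
  expect_equal(unname(got), unname(ref), tolerance = 1e-12)
})

test_that("checkpoints reproduce predictions bitwise", {
  cfg <- tiny_config()
  tab <- tiny_table()
  params <- init_parameters(cfg, seed = 31)
  doc <- random_doc(6)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(params, tab, path)
  ck <- load_checkpoint(path)
  expect_identical(tagger_forward(doc, ck$params, ck$table)$probabilities,
                   tagger_forward(doc, params, tab)$probabilities)
  expect_identical(ck$params$values, params$values)
})
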