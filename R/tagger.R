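#' One step of the coupled-gate LSTM cell
#'
#' The recurrent cell used throughout the tagger couples the forget gate to
#' the input gate (forget = 1 - input) and adds a constant +1 inside the
#' input-gate sigmoid, biasing the cell toward retaining memory:
#' \deqn{i_t = \sigma(W_i [z_t; h_{t-1}] + b_i + 1)}
#' \deqn{c_t = i_t \odot c_{t-1} + (1 - i_t) \odot \tanh(W_c [z_t; h_{t-1}] + b_c)}
#' \deqn{o_t = \sigma(W_o [z_t; h_{t-1}] + b_o)}
#' \deqn{h_t = o_t \odot \tanh(c_t)}
#'
#' @param z input vector.
#' @param h_prev,c_prev previous hidden and memory state (length = hidden).
#' @param lstm_params list with `W_i`, `W_c`, `W_o` (hidden x (input+hidden))
#'   and `b_i`, `b_c`, `b_o` (length hidden), e.g. from an initialized
#'   parameter vector.
#' @return list with elements `h` and `c`.
#' @export
lstm_step <- function(z, h_prev, c_prev, lstm_params) {
  P <- lstm_params
  hid <- length(P$b_i)
  if (length(h_prev) != hid || length(c_prev) != hid)
    stop_phideid("state length %d does not match hidden size %d",
                 length(h_prev), hid)
  if (length(z) + hid != ncol(P$W_i))
    stop_phideid("input length %d incompatible with weight shape %dx%d",
                 length(z), nrow(P$W_i), ncol(P$W_i))
  res <- cpp_lstm_step(as.numeric(z), as.numeric(h_prev), as.numeric(c_prev),
                       P$W_i, P$W_c, P$W_o,
                       as.numeric(P$b_i), as.numeric(P$b_c),
                       as.numeric(P$b_o))
  list(h = as.numeric(res$h), c = as.numeric(res$c))
}

#' Bidirectional LSTM over a sequence
#'
#' Runs two independent coupled-gate LSTMs over the sequence and its
#' reversal, starting from zero states. In `"last"` mode the concatenation of
#' the two final hidden states is returned (the token-embedding use); in
#' `"full"` mode, for every position i the forward state at i is concatenated
#' with the backward state at i (the label-layer use).
#'
#' @param inputs matrix with one column per sequence position.
#' @param forward_params,backward_params LSTM parameter lists as in
#'   [lstm_step()].
#' @param mode `"last"` or `"full"`.
#' @return `"last"`: numeric vector of length 2*hidden; `"full"`: matrix
#'   (2*hidden x positions).
#' @export
bilstm <- function(inputs, forward_params, backward_params,
                   mode = c("last", "full")) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(inputs))
  m <- ncol(inputs)
  if (m == 0L) stop_phideid("bilstm requires a nonempty sequence")
  run_dir <- function(Z, P) {
    hid <- length(P$b_i)
    h <- numeric(hid); c <- numeric(hid)
    H <- matrix(0, hid, ncol(Z))
    for (t in seq_len(ncol(Z))) {
      st <- lstm_step(Z[, t], h, c, P)
      h <- st$h; c <- st$c
      H[, t] <- h
    }
    H
  }
  Hf <- run_dir(inputs, forward_params)
  Hb <- run_dir(inputs[, rev(seq_len(m)), drop = FALSE], backward_params)
  if (mode == "last") c(Hf[, m], Hb[, m])
  else rbind(Hf, Hb[, rev(seq_len(m)), drop = FALSE])
}

#' Character-enhanced token embedding
#'
#' Concatenates the (fixed, pretrained) word vector of a token with the final
#' states of a bidirectional LSTM run over the token's one-hot encoded
#' characters. Unlike a corpus-dependent word embedding alone, the character
#' half yields a reproducible vector for any token, including ones never seen
#' in the embedding vocabulary.
#'
#' @param token non-empty character scalar.
#' @param table an [embedding_table()].
#' @param char_fwd_params,char_bwd_params character-LSTM parameter lists
#'   (see [lstm_params_from_vector()] via `lstm_params_from`), input
#'   dimension 128.
#' @return numeric vector of length `word_dim + 2*char_hidden` (556 at the
#'   published sizes).
#' @export
token_embedding <- function(token, table, char_fwd_params, char_bwd_params) {
  onehots <- encode_token_chars(token)
  c(lookup_word(table, token),
    bilstm(onehots, char_fwd_params, char_bwd_params, mode = "last"))
}

# Assemble the C++ call inputs for one document.
doc_inputs <- function(doc, table) {
  list(X = lookup_words(table, doc$tokens),
       codes = lapply(doc$tokens, function(tk) as.integer(char_code(tk))))
}

dropout_mask_for <- function(config, n, dropout_seed) {
  if (is.null(dropout_seed) || config$dropout_rate <= 0) return(NULL)
  keep <- 1 - config$dropout_rate
  with_seed(dropout_seed, {
    matrix(rbinom(config$e_dim * n, 1L, keep) / keep,
           nrow = config$e_dim, ncol = n)
  })
}

run_tagger <- function(doc, params, table, dropout_seed = NULL,
                       gold = NULL, want_grad = FALSE, want_states = FALSE) {
  cfg <- params$config
  inp <- doc_inputs(doc, table)
  mask <- dropout_mask_for(cfg, length(doc$tokens), dropout_seed)
  cpp_tagger_run(inp$X, inp$codes, params$values,
                 cfg$word_dim, cfg$char_onehot_dim, cfg$char_hidden,
                 cfg$label_hidden, cfg$ff_hidden, cfg$n_labels,
                 mask, gold, want_grad, want_states)
}

#' Forward pass of the tagger over one document
#'
#' Computes per-token posterior label probabilities: character-enhanced token
#' embeddings, (optional) dropout, label bi-LSTM in full mode, tanh hidden
#' layer and softmax output.
#'
#' @param doc a [labeled_document()].
#' @param params a `parameter_vector` (see [init_parameters()]).
#' @param table an [embedding_table()].
#' @param dropout_seed `NULL` for inference (no dropout) or an integer seed
#'   for the training-mode dropout mask on the token-embedding sequence.
#' @param want_states if TRUE, also return the token embeddings `e_i` and
#'   label-LSTM states `d_i` as diagnostics.
#' @return list with `probabilities` (n_tokens x n_labels matrix, rows sum to
#'   1, columns in scheme label order) and optionally `embeddings`,
#'   `label_states`.
#' @export
tagger_forward <- function(doc, params, table, dropout_seed = NULL,
                           want_states = FALSE) {
  out <- run_tagger(doc, params, table, dropout_seed = dropout_seed,
                    want_states = want_states)
  out[intersect(c("probabilities", "embeddings", "label_states"),
                names(out))]
}

#' Predict per-token labels
#'
#' Inference-mode forward pass followed by an argmax over the label
#' posteriors; ties break toward the lowest label index.
#'
#' @inheritParams tagger_forward
#' @param scheme the label scheme (defines the label order).
#' @return character vector of label names, one per token.
#' @export
predict_labels <- function(doc, params, table,
                           scheme = build_label_scheme()) {
  probs <- tagger_forward(doc, params, table)$probabilities
  scheme$labels[max.col(probs, ties.method = "first")]
}

#' Cross-entropy loss of the tagger on one document
#'
#' \eqn{E(p) = -\sum_i \log a_i[class(t_i)]}, the summed negative
#' log-probability of the true label of every token.
#'
#' @inheritParams tagger_forward
#' @param scheme the label scheme used to index `doc$labels`.
#' @return non-negative scalar.
#' @export
tagger_loss <- function(params, doc, table, dropout_seed = NULL,
                        scheme = build_label_scheme()) {
  gold <- label_index(scheme, doc$labels)
  run_tagger(doc, params, table, dropout_seed = dropout_seed,
             gold = gold)$loss
}

#' Gradient of the cross-entropy loss
#'
#' Full backpropagation through the softmax/tanh output layers, the label
#' bi-LSTM, dropout and the per-token character bi-LSTMs, with respect to
#' every entry of the flattened parameter vector.
#'
#' @inheritParams tagger_loss
#' @return list with `gradient` (numeric vector, same length as
#'   `params$values`) and `loss`.
#' @export
tagger_gradient <- function(params, doc, table, dropout_seed = NULL,
                            scheme = build_label_scheme()) {
  gold <- label_index(scheme, doc$labels)
  out <- run_tagger(doc, params, table, dropout_seed = dropout_seed,
                    gold = gold, want_grad = TRUE)
  list(gradient = out$gradient, loss = out$loss)
}

#' Save / load a tagger checkpoint
#'
#' The checkpoint container holds the network configuration, the label
#' scheme, the parameter index map and flat value vector, and the embedding
#' table; a save followed by a load reproduces predictions bitwise.
#'
#' @param params a `parameter_vector`.
#' @param table the [embedding_table()] used with the model.
#' @param path file path (`.rds`).
#' @param scheme the label scheme.
#' @return `save_checkpoint`: `path` invisibly. `load_checkpoint`: list with
#'   `params`, `table`, `scheme`.
#' @export
save_checkpoint <- function(params, table, path,
                            scheme = build_label_scheme()) {
  obj <- list(format = "phideid-checkpoint-1",
              config = params$config,
              layout = params$layout,
              values = params$values,
              scheme = scheme,
              table = table)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "phideid-checkpoint-1"))
    stop_phideid("'%s' is not a phideid checkpoint", path)
  params <- structure(list(values = obj$values, layout = obj$layout,
                           config = obj$config),
                      class = "parameter_vector")
  list(params = params, table = obj$table, scheme = obj$scheme)
}

#' LSTM parameter list for one named LSTM of a parameter vector
#'
#' Convenience accessor returning the `W_i/W_c/W_o/b_i/b_c/b_o` list of one
#' of the four LSTMs, as consumed by [lstm_step()], [bilstm()] and
#' [token_embedding()].
#'
#' @param params a `parameter_vector`.
#' @param which one of `"char_fwd"`, `"char_bwd"`, `"label_fwd"`,
#'   `"label_bwd"`.
#' @return list of three matrices and three bias vectors.
#' @export
lstm_params_from_vector <- function(params,
                                    which = c("char_fwd", "char_bwd",
                                              "label_fwd", "label_bwd")) {
  which <- match.arg(which)
  lstm_params_from(params, which)
}
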