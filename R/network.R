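#' Network configuration for the tagger
#'
#' Defaults reproduce the published topology: 300-dim word vectors, 128-dim
#' character one-hots, character LSTMs of hidden size 128 (so token
#' embeddings have length 300 + 2*128 = 556), a label bi-LSTM of hidden size
#' 100 (per-token states of length 200), a 100-unit tanh hidden layer and a
#' 29-way softmax. Smaller values give desk-scale models for experimentation;
#' see [network_profile()].
#'
#' @param word_dim word-embedding dimension.
#' @param char_hidden hidden size of the character LSTMs.
#' @param label_hidden hidden size of the label bi-LSTM.
#' @param ff_hidden size of the feedforward tanh layer.
#' @param n_labels number of output labels (29).
#' @param dropout_rate dropout probability applied to the token-embedding
#'   sequence during training (inverted dropout; 0 disables).
#' @return object of class `network_config`. The character one-hot dimension
#'   is fixed at 128 by the encoding.
#' @export
network_config <- function(word_dim = 300L, char_hidden = 128L,
                           label_hidden = 100L, ff_hidden = 100L,
                           n_labels = 29L, dropout_rate = 0.5) {
  stopifnot(word_dim >= 1, char_hidden >= 1, label_hidden >= 1,
            ff_hidden >= 1, n_labels >= 2,
            dropout_rate >= 0, dropout_rate < 1)
  cfg <- list(word_dim = as.integer(word_dim),
              char_onehot_dim = 128L,
              char_hidden = as.integer(char_hidden),
              label_hidden = as.integer(label_hidden),
              ff_hidden = as.integer(ff_hidden),
              n_labels = as.integer(n_labels),
              dropout_rate = dropout_rate)
  cfg$e_dim <- cfg$word_dim + 2L * cfg$char_hidden
  cfg$d_dim <- 2L * cfg$label_hidden
  class(cfg) <- "network_config"
  cfg
}

#' Named network size profiles
#'
#' `"paper"` is the published topology (about 6.1e5 parameters); `"desk"` is
#' the scaled-down profile used for the package's desk-scale experiments
#' (word_dim 32, hidden sizes 16; about 2.3e4 parameters).
#'
#' @param name `"paper"` or `"desk"`.
#' @param dropout_rate passed through to [network_config()].
#' @return a `network_config`.
#' @export
network_profile <- function(name = c("desk", "paper"), dropout_rate = 0.5) {
  name <- match.arg(name)
  switch(name,
    paper = network_config(dropout_rate = dropout_rate),
    desk = network_config(word_dim = 32L, char_hidden = 16L,
                          label_hidden = 16L, ff_hidden = 16L,
                          dropout_rate = dropout_rate))
}

#' @export
print.network_config <- function(x, ...) {
  cat(sprintf(paste0("<network_config: word %d + 2x%d char -> e_dim %d; ",
                     "label LSTM %d -> d_dim %d; ff %d -> %d labels; ",
                     "%d parameters>\n"),
              x$word_dim, x$char_hidden, x$e_dim, x$label_hidden, x$d_dim,
              x$ff_hidden, x$n_labels, n_parameters(x)))
  invisible(x)
}

#' Layout of the flattened parameter vector
#'
#' Names every component of the flat vector `p` and its contiguous index
#' range: the three weight matrices and three biases of each of the four
#' LSTMs (character forward/backward, label forward/backward), then `W_1`,
#' `b_1`, `W_2`, `b_2` of the feedforward layers. Matrices are stored
#' column-major.
#'
#' @param config a [network_config()].
#' @return data.frame with columns `name`, `nrow`, `ncol`, `start`, `length`
#'   (1-based, ranges disjoint and covering the vector exactly).
#' @export
param_layout <- function(config) {
  stopifnot(inherits(config, "network_config"))
  comps <- list()
  add_lstm <- function(prefix, hid, inp) {
    for (g in c("W_i", "W_c", "W_o"))
      comps[[paste(prefix, g, sep = ".")]] <<- c(hid, inp + hid)
    for (g in c("b_i", "b_c", "b_o"))
      comps[[paste(prefix, g, sep = ".")]] <<- c(hid, 1L)
  }
  add_lstm("char_fwd", config$char_hidden, config$char_onehot_dim)
  add_lstm("char_bwd", config$char_hidden, config$char_onehot_dim)
  add_lstm("label_fwd", config$label_hidden, config$e_dim)
  add_lstm("label_bwd", config$label_hidden, config$e_dim)
  comps[["W_1"]] <- c(config$ff_hidden, config$d_dim)
  comps[["b_1"]] <- c(config$ff_hidden, 1L)
  comps[["W_2"]] <- c(config$n_labels, config$ff_hidden)
  comps[["b_2"]] <- c(config$n_labels, 1L)
  nr <- vapply(comps, `[`, integer(1), 1L)
  nc <- vapply(comps, `[`, integer(1), 2L)
  len <- nr * nc
  data.frame(name = names(comps), nrow = nr, ncol = nc,
             start = cumsum(c(1L, len[-length(len)])), length = len,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Total number of network parameters
#' @param config a [network_config()].
#' @return integer parameter count.
#' @export
n_parameters <- function(config) {
  sum(param_layout(config)$length)
}

#' Initialize a parameter vector
#'
#' Weight matrices are drawn uniformly from (-r, r) with
#' r = sqrt(6 / (fan_in + fan_out)) per matrix; biases start at zero.
#'
#' @param config a [network_config()].
#' @param seed integer seed (same seed, same vector).
#' @return object of class `parameter_vector`: list with `values` (flat
#'   numeric vector), `layout` (the index map, see [param_layout()]) and
#'   `config`.
#' @export
init_parameters <- function(config, seed = 1L) {
  layout <- param_layout(config)
  values <- numeric(sum(layout$length))
  with_seed(derive_seed(seed, 389L), {
    for (i in seq_len(nrow(layout))) {
      if (layout$ncol[i] == 1L) next # biases stay zero
      r <- sqrt(6 / (layout$nrow[i] + layout$ncol[i]))
      idx <- layout$start[i] + seq_len(layout$length[i]) - 1L
      values[idx] <- runif(layout$length[i], -r, r)
    }
  })
  structure(list(values = values, layout = layout, config = config),
            class = "parameter_vector")
}

#' Extract one named component of a parameter vector
#'
#' @param params a `parameter_vector`.
#' @param name a component name from `params$layout$name`
#'   (e.g. `"char_fwd.W_i"`, `"W_2"`).
#' @return the component as a matrix (or plain vector for biases).
#' @export
param_slice <- function(params, name) {
  i <- match(name, params$layout$name)
  if (is.na(i)) stop_phideid("unknown parameter component '%s'", name)
  v <- params$values[params$layout$start[i] +
                       seq_len(params$layout$length[i]) - 1L]
  if (params$layout$ncol[i] == 1L) v
  else matrix(v, nrow = params$layout$nrow[i])
}

# Replace the flat values, keeping layout/config.
set_values <- function(params, values) {
  stopifnot(length(values) == length(params$values))
  params$values <- as.numeric(values)
  params
}

#' @export
print.parameter_vector <- function(x, ...) {
  cat(sprintf("<parameter_vector: %d parameters in %d components>\n",
              length(x$values), nrow(x$layout)))
  invisible(x)
}

# LstmParams list for the R-level reference ops (lstm_step / bilstm).
lstm_params_from <- function(params, prefix) {
  list(W_i = param_slice(params, paste(prefix, "W_i", sep = ".")),
       W_c = param_slice(params, paste(prefix, "W_c", sep = ".")),
       W_o = param_slice(params, paste(prefix, "W_o", sep = ".")),
       b_i = param_slice(params, paste(prefix, "b_i", sep = ".")),
       b_c = param_slice(params, paste(prefix, "b_c", sep = ".")),
       b_o = param_slice(params, paste(prefix, "b_o", sep = ".")))
}
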