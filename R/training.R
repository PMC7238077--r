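# Seed conventions: the epoch-level SGD seed for worker k in epoch e of a run
# seeded with `seed` is derive_seed(seed, e, k). Centralized training is
# worker 1, so round-robin with a single subset and single-worker DSSGD with
# full sharing reproduce the centralized trajectory exactly.

sgd_epoch_seed <- function(seed, epoch, worker) derive_seed(seed, epoch, worker)

#' One epoch of per-sample stochastic gradient descent
#'
#' Visits every document once in a seeded shuffled order and applies one
#' plain gradient step per document. The step uses the token-averaged
#' gradient, `p <- p - (eta / n_tokens) * dE/dp`, the standard normalization
#' of a summed sequence cross-entropy: it makes the step size independent of
#' fragment length, without which a learning rate of 0.9 diverges on long
#' fragments. A fresh seeded dropout mask is drawn for each training
#' sequence (if the network config has a nonzero dropout rate).
#'
#' @param params a `parameter_vector`.
#' @param docs nonempty list of [labeled_document()]s.
#' @param table an [embedding_table()].
#' @param eta fixed learning rate.
#' @param seed integer seed for the shuffle and the dropout masks.
#' @param scheme label scheme.
#' @return the updated `parameter_vector`.
#' @export
sgd_epoch <- function(params, docs, table, eta, seed,
                      scheme = build_label_scheme()) {
  if (length(docs) == 0L) stop_phideid("sgd_epoch: empty document set")
  ord <- with_seed(derive_seed(seed, 631L), sample(length(docs)))
  values <- params$values
  for (j in seq_along(ord)) {
    doc <- docs[[ord[j]]]
    ds <- if (params$config$dropout_rate > 0)
      derive_seed(seed, 7919L, j) else NULL
    g <- tagger_gradient(set_values(params, values), doc, table,
                         dropout_seed = ds, scheme = scheme)$gradient
    values <- values - (eta / length(doc$tokens)) * g
  }
  set_values(params, values)
}

#' Centralized (nonprotective) training
#'
#' The gold-standard baseline: all data pooled, sequential SGD epochs over
#' the full corpus.
#'
#' @param params initial `parameter_vector`.
#' @param corpus list of labeled documents.
#' @param table an [embedding_table()].
#' @param epochs number of epochs (0 returns the initial parameters).
#' @param eta learning rate (the study uses 0.9).
#' @param seed integer run seed.
#' @param eval_hook optional `function(epoch, worker, params)` invoked after
#'   every epoch (worker is always 1).
#' @param keep_trajectory if TRUE (default), record the flat parameter values
#'   after each epoch.
#' @param scheme label scheme.
#' @return list with `params` (final `parameter_vector`) and `trajectory`
#'   (list of flat value vectors, one per epoch).
#' @export
train_centralized <- function(params, corpus, table, epochs, eta = 0.9,
                              seed = 1L, eval_hook = NULL,
                              keep_trajectory = TRUE,
                              scheme = build_label_scheme()) {
  stopifnot(is_count(epochs), epochs >= 0)
  traj <- list()
  for (e in seq_len(epochs)) {
    params <- sgd_epoch(params, corpus, table, eta,
                        sgd_epoch_seed(seed, e, 1L), scheme = scheme)
    if (keep_trajectory) traj[[e]] <- params$values
    if (!is.null(eval_hook)) eval_hook(e, 1L, params)
  }
  list(params = params, trajectory = traj)
}

#' Round-robin (cyclic weight transfer) training
#'
#' Per global epoch, each worker in fixed order 1..K runs one local SGD epoch
#' on the current weights and hands them to the next worker; local data never
#' move. With a single subset this reduces exactly to
#' [train_centralized()].
#'
#' @param params initial `parameter_vector`.
#' @param partition a `corpus_partition` (see [partition_by_patient()]).
#' @param table an [embedding_table()].
#' @param epochs number of global epochs (each = K local epochs).
#' @param eta learning rate.
#' @param seed integer run seed.
#' @param eval_hook optional `function(epoch, worker, params)` invoked once
#'   per global epoch (worker = K, the last trainer).
#' @param keep_trajectory record parameters after each global epoch.
#' @param scheme label scheme.
#' @return list with `params` and `trajectory` as in [train_centralized()].
#' @export
train_round_robin <- function(params, partition, table, epochs, eta = 0.9,
                              seed = 1L, eval_hook = NULL,
                              keep_trajectory = TRUE,
                              scheme = build_label_scheme()) {
  stopifnot(inherits(partition, "corpus_partition"), is_count(epochs),
            epochs >= 0)
  k <- length(partition$subsets)
  traj <- list()
  for (e in seq_len(epochs)) {
    for (w in seq_len(k)) {
      params <- sgd_epoch(params, partition$subsets[[w]], table, eta,
                          sgd_epoch_seed(seed, e, w), scheme = scheme)
    }
    if (keep_trajectory) traj[[e]] <- params$values
    if (!is.null(eval_hook)) eval_hook(e, k, params)
  }
  list(params = params, trajectory = traj)
}

#' Isolated local training (no collaboration)
#'
#' Every worker trains an independent copy of the initial network on its own
#' subset only; nothing is ever exchanged.
#'
#' @inheritParams train_round_robin
#' @param eval_hook optional `function(epoch, worker, params)` invoked after
#'   every local epoch of every worker.
#' @return list with `workers` (list of final `parameter_vector`s) and
#'   `trajectories` (per worker, list of flat value vectors per epoch).
#' @export
train_local_only <- function(params, partition, table, epochs, eta = 0.9,
                             seed = 1L, eval_hook = NULL,
                             keep_trajectory = TRUE,
                             scheme = build_label_scheme()) {
  stopifnot(inherits(partition, "corpus_partition"), is_count(epochs),
            epochs >= 0)
  k <- length(partition$subsets)
  workers <- vector("list", k)
  trajectories <- rep(list(list()), k)
  for (w in seq_len(k)) {
    pw <- params
    for (e in seq_len(epochs)) {
      pw <- sgd_epoch(pw, partition$subsets[[w]], table, eta,
                      sgd_epoch_seed(seed, e, w), scheme = scheme)
      if (keep_trajectory) trajectories[[w]][[e]] <- pw$values
      if (!is.null(eval_hook)) eval_hook(e, w, pw)
    }
    workers[[w]] <- pw
  }
  list(workers = workers, trajectories = trajectories)
}
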