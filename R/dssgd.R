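# Distributed selective stochastic gradient descent (DSSGD): workers keep
# their data local, train with plain SGD, and exchange only selected,
# thresholded, clamped parameter updates through a server that tracks how
# often every parameter has been updated.

#' Per-worker DSSGD hyperparameters
#'
#' @param theta_d download rate: fraction of the parameter vector fetched
#'   from the server each epoch (the floor(theta_d * len(p)) most-updated
#'   parameters). 0 skips the download entirely (fully isolated input side).
#' @param theta_u upload rate: cap on the shared fraction of the parameter
#'   vector per epoch, as a fraction of the *total* parameter count.
#' @param gamma clamp bound: shared update values are clamped to
#'   `[-gamma, gamma]` (`Inf` disables clamping).
#' @param tau threshold: updates with `|value| <= tau` are withheld.
#' @param eta local learning rate.
#' @param seed integer seed for this worker's update subsampling (and its
#'   share of the SGD shuffles, via the run seed conventions).
#' @return object of class `worker_config`.
#' @export
worker_config <- function(theta_d = 0.1, theta_u = 0.5, gamma = 10,
                          tau = 1e-4, eta = 0.9, seed = 1L) {
  stopifnot(theta_d >= 0, theta_d <= 1, theta_u >= 0, theta_u <= 1,
            gamma > 0, tau >= 0, eta > 0)
  structure(list(theta_d = theta_d, theta_u = theta_u, gamma = gamma,
                 tau = tau, eta = eta, seed = as.integer(seed)),
            class = "worker_config")
}

#' Initialize the parameter-server state
#'
#' @param values initial flat global parameter vector `p_glo` (the topology
#'   all parties agreed on).
#' @return object of class `server_state`: `p_glo`, per-parameter
#'   `update_counts`, and the total number of uploads received.
#' @export
server_state <- function(values) {
  structure(list(p_glo = as.numeric(values),
                 update_counts = integer(length(values)),
                 n_uploads = 0L),
            class = "server_state")
}

#' @export
print.server_state <- function(x, ...) {
  cat(sprintf("<server_state: %d parameters, %d uploads, %d ever updated>\n",
              length(x$p_glo), x$n_uploads, sum(x$update_counts > 0L)))
  invisible(x)
}

#' Select the updates a worker shares
#'
#' Applies the three selection rules in order: (1) keep only updates whose
#' absolute value strictly exceeds the threshold `tau`; (2) clamp survivors
#' to `[-gamma, +gamma]`; (3) subsample uniformly at random down to
#' floor(theta_u * len(p)) entries if more survive (fewer survivors are all
#' kept).
#'
#' @param delta flat vector of candidate updates (the worker's cumulative
#'   parameter change over one local epoch).
#' @param cfg a [worker_config()].
#' @param seed seed for the uniform subsampling (default: the worker seed).
#' @return object of class `sparse_update`: list with strictly increasing
#'   1-based `indices` and clamped `values`.
#' @export
select_updates <- function(delta, cfg, seed = cfg$seed) {
  surv <- which(abs(delta) > cfg$tau)
  cap <- floor(cfg$theta_u * length(delta))
  if (length(surv) > cap) {
    surv <- if (cap == 0L) integer(0)
    else sort(with_seed(derive_seed(seed, 40507L), sample(surv, cap)))
  }
  vals <- pmin(pmax(delta[surv], -cfg$gamma), cfg$gamma)
  structure(list(indices = as.integer(surv), values = as.numeric(vals)),
            class = "sparse_update")
}

#' Server download: the most-updated global parameters
#'
#' Returns the floor(theta_d * len(p_glo)) parameters with the highest
#' update counts (ties broken toward the lowest index), with their current
#' global values.
#'
#' @param state a [server_state()].
#' @param theta_d download rate in `[0, 1]`.
#' @return a `sparse_update` whose values are current global weights.
#' @export
server_download <- function(state, theta_d) {
  stopifnot(theta_d >= 0, theta_d <= 1)
  kcnt <- floor(theta_d * length(state$p_glo))
  if (kcnt == 0L)
    return(structure(list(indices = integer(0), values = numeric(0)),
                     class = "sparse_update"))
  ord <- order(-state$update_counts, seq_along(state$update_counts))
  idx <- sort(ord[seq_len(kcnt)])
  structure(list(indices = as.integer(idx), values = state$p_glo[idx]),
            class = "sparse_update")
}

#' Server upload: apply a worker's sparse update
#'
#' Adds each shared value onto the corresponding global parameter and
#' increments its update counter; counters never decrease.
#'
#' @param state a [server_state()].
#' @param update a `sparse_update` from [select_updates()].
#' @return the updated `server_state`.
#' @export
server_upload <- function(state, update) {
  idx <- update$indices
  if (length(idx) > 0L &&
      (min(idx) < 1L || max(idx) > length(state$p_glo)))
    stop_phideid("upload contains out-of-range parameter indices")
  state$p_glo[idx] <- state$p_glo[idx] + update$values
  state$update_counts[idx] <- state$update_counts[idx] + 1L
  state$n_uploads <- state$n_uploads + 1L
  state
}

#' One local DSSGD epoch of a single worker
#'
#' The local procedure: download the theta_d most-updated global parameters
#' into the local copy (overwriting), run one local SGD epoch, form the
#' cumulative update relative to the post-download weights, and select the
#' thresholded/clamped/subsampled portion to upload.
#'
#' @param params the worker's local `parameter_vector`.
#' @param state the current [server_state()] (read for the download; the
#'   caller applies the returned update with [server_upload()]).
#' @param docs the worker's local documents.
#' @param cfg the worker's [worker_config()].
#' @param table an [embedding_table()].
#' @param epoch 1-based local epoch index (seeds the shuffle/subsampling).
#' @param worker 1-based worker index (seed convention only).
#' @param scheme label scheme.
#' @return list with `params` (updated local parameters), `update` (the
#'   `sparse_update` to upload) and `diagnostics` (one-row data.frame:
#'   survivors, cap, selected, clamped counts and the download size).
#' @export
dssgd_worker_epoch <- function(params, state, docs, cfg, table, epoch,
                               worker = 1L, scheme = build_label_scheme()) {
  stopifnot(inherits(cfg, "worker_config"), inherits(state, "server_state"))
  n_down <- 0L
  if (cfg$theta_d > 0) {
    dl <- server_download(state, cfg$theta_d)
    params$values[dl$indices] <- dl$values
    n_down <- length(dl$indices)
  }
  p_start <- params$values
  params <- sgd_epoch(params, docs, table, cfg$eta,
                      sgd_epoch_seed(cfg$seed, epoch, worker),
                      scheme = scheme)
  delta <- params$values - p_start
  upd <- select_updates(delta, cfg,
                        seed = derive_seed(cfg$seed, 3571L, epoch, worker))
  diag <- data.frame(
    epoch = epoch, worker = worker,
    n_download = n_down,
    n_survivors = sum(abs(delta) > cfg$tau),
    cap = floor(cfg$theta_u * length(delta)),
    n_selected = length(upd$indices),
    n_clamped = sum(abs(delta[upd$indices]) > cfg$gamma),
    max_abs_selected = if (length(upd$values)) max(abs(upd$values)) else 0,
    min_abs_preclamp = if (length(upd$indices))
      min(abs(delta[upd$indices])) else NA_real_)
  list(params = params, update = upd, diagnostics = diag)
}

#' Collaborative privacy-preserving training with DSSGD
#'
#' Simulates the asynchronous protocol in-process: per round, the workers run
#' their local epochs in a seeded random order, each seeing the server state
#' exactly as the previous worker left it, and the server applies every
#' upload immediately.
#'
#' @param params initial `parameter_vector` (the agreed topology; also
#'   initializes the global weights).
#' @param partition a `corpus_partition` with one subset per worker.
#' @param worker_cfgs list of [worker_config()]s, one per subset, or a single
#'   `worker_config` recycled to all workers.
#' @param table an [embedding_table()].
#' @param epochs number of rounds (local epochs per worker).
#' @param schedule_seed seed for the per-round worker permutation.
#' @param eval_hook optional `function(epoch, worker, params)` invoked after
#'   every local epoch of every worker.
#' @param keep_trajectory record each worker's parameters after each round.
#' @param scheme label scheme.
#' @return list with `workers` (final local `parameter_vector`s), `server`
#'   (final `server_state`), `trajectories` (per worker), and `diagnostics`
#'   (data.frame, one row per exchange).
#' @export
train_dssgd <- function(params, partition, worker_cfgs, table, epochs,
                        schedule_seed = 1L, eval_hook = NULL,
                        keep_trajectory = TRUE,
                        scheme = build_label_scheme()) {
  stopifnot(inherits(partition, "corpus_partition"), is_count(epochs),
            epochs >= 0)
  k <- length(partition$subsets)
  if (inherits(worker_cfgs, "worker_config"))
    worker_cfgs <- rep(list(worker_cfgs), k)
  if (length(worker_cfgs) != k)
    stop_phideid("need one worker_config per subset (%d != %d)",
                 length(worker_cfgs), k)
  locals <- rep(list(params), k)
  state <- server_state(params$values)
  trajectories <- rep(list(list()), k)
  diags <- vector("list", epochs * k)
  di <- 0L
  for (r in seq_len(epochs)) {
    order_r <- with_seed(derive_seed(schedule_seed, 5077L, r), sample(k))
    for (w in order_r) {
      res <- dssgd_worker_epoch(locals[[w]], state,
                                partition$subsets[[w]], worker_cfgs[[w]],
                                table, epoch = r, worker = w,
                                scheme = scheme)
      locals[[w]] <- res$params
      state <- server_upload(state, res$update)
      di <- di + 1L
      diags[[di]] <- res$diagnostics
      if (keep_trajectory) trajectories[[w]][[r]] <- res$params$values
      if (!is.null(eval_hook)) eval_hook(r, w, res$params)
    }
  }
  list(workers = locals, server = state, trajectories = trajectories,
       diagnostics = do.call(rbind, diags[seq_len(di)]))
}
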