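#' @useDynLib phideid, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats runif rbinom setNames
#' @importFrom utils head tail
NULL

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

#' Derive a reproducible sub-seed from a base seed
#'
#' Mixes a base seed with any number of non-negative integer tags (epoch
#' index, worker index, ...) into a new seed in `[1, 2^31 - 2]`. Every source
#' of randomness in the package draws its seed through this function, so a
#' single experiment seed pins down the entire run.
#'
#' @param seed integer base seed.
#' @param ... integer tags mixed in sequentially.
#' @return a single integer seed.
#' @export
derive_seed <- function(seed, ...) {
  m <- 2147483647 # 2^31 - 1, prime
  x <- as.double(seed %% m)
  for (tag in c(...)) {
    x <- (x * 48271 + as.double(tag) * 16807 + 12345) %% m
  }
  as.integer(x %% (m - 1L) + 1L)
}

stop_phideid <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x == floor(x)
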