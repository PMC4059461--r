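# Internal helpers: classed conditions, seed derivation, step-function
# evaluation shared by the censoring and inference code.

crc_abort <- function(message, class) {
  cond <- structure(
    class = c(class, "crcindex_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  )
  stop(cond)
}

crc_validation_error <- function(message) crc_abort(message, "crcindex_validation_error")
crc_config_error <- function(message) crc_abort(message, "crcindex_config_error")
crc_undefined_estimate <- function(message) crc_abort(message, "crcindex_undefined_estimate")
crc_precondition_error <- function(message) crc_abort(message, "crcindex_precondition_error")
crc_fit_error <- function(message) crc_abort(message, "crcindex_fit_error")
crc_unsupported_method <- function(message) crc_abort(message, "crcindex_unsupported_method")

#' Derive a reproducible child seed
#'
#' Counter-based derivation of substream seeds from a master seed, so that
#' component draws (covariates, latent event times, censoring times) and
#' replication streams are independently reproducible and adding cells to a
#' study never perturbs existing ones. Linear congruential mixing modulo
#' 2^31 - 1; all intermediates stay below 2^53 so the arithmetic is exact in
#' doubles.
#'
#' @param seed integer master seed.
#' @param key integer counter / stream key.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, key) {
  m <- 2147483647
  s <- ((abs(seed) %% m) * 48271 + (abs(key) %% m) * 69621 + 12345) %% m
  # avoid the degenerate 0 seed
  as.integer(s + (s == 0))
}

# Evaluate expr with a temporary RNG seed, restoring the caller's RNG state.
# seed = NULL runs expr against the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Right-continuous step function defined by sorted jump times and the value
# reached at each jump; value before the first jump is `init`.
# side = "right": value at t (largest jump <= t); side = "left": value at t-
# (largest jump strictly < t).
step_eval <- function(t, jump_times, values, init = 1, side = c("right", "left")) {
  side <- match.arg(side)
  if (length(jump_times) == 0L) return(rep(init, length(t)))
  idx <- findInterval(t, jump_times, left.open = (side == "left"))
  out <- c(init, values)[idx + 1L]
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
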