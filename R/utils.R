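# Internal helpers: seed scoping, substreams, assertions.

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards. seed = NULL leaves the RNG stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Derive a named substream seed from a master seed
#'
#' All randomness in a pipeline run flows from one master seed; each stage
#' draws from a substream whose seed is a deterministic hash of the master
#' seed and the stage name. Re-running a single stage in isolation with its
#' substream seed reproduces it exactly.
#'
#' @param seed Master seed (single integer-valued number).
#' @param stage Stage name (character scalar).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' substream_seed(42, "simulate")
substream_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stage))
  m <- 2147483647 # 2^31 - 1, keeps every intermediate below 2^53 in doubles
  h <- abs(seed) %% m
  for (ch in utf8ToInt(stage)) {
    h <- (h * 69069 + ch) %% m
  }
  as.integer(h)
}

abort_param <- function(msg) {
  rlang::abort(msg, class = "iblt_parameter_error")
}

abort_state <- function(msg) {
  rlang::abort(msg, class = "iblt_state_error")
}

abort_generation <- function(msg) {
  rlang::abort(msg, class = "iblt_generation_error")
}

abort_validation <- function(msg, diagnostics = NULL) {
  rlang::abort(msg, class = "iblt_validation_error", diagnostics = diagnostics)
}

check_scalar_prob <- function(x, name, open = TRUE) {
  ok <- is.numeric(x) && all(is.finite(x)) &&
    if (open) all(x > 0 & x < 1) else all(x >= 0 & x <= 1)
  if (!ok) {
    bound <- if (open) "(0, 1)" else "[0, 1]"
    abort_param(sprintf("`%s` must lie in %s.", name, bound))
  }
  invisible(x)
}
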