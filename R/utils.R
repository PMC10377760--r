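# internal helpers shared across modules

# evaluate `expr` under a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# round-half-up (base round() is round-half-even)
round_half_up <- function(x) floor(x + 0.5)

# derive a stream-specific 31-bit seed from a master seed and a text salt
derive_seed <- function(seed, salt) {
  h <- as.double(seed %% 2147483647L)
  for (ch in utf8ToInt(salt)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

#' Stable fingerprint of a parameter collection
#'
#' A 31-bit rolling polynomial hash over tensor shapes and IEEE-754 byte
#' patterns, rendered as 8 hex digits. Used in client block logs to audit
#' which global model state a node held, without storing full copies.
#' Identical tensors always hash identically; any bit-level change almost
#' surely changes the fingerprint.
#'
#' @param params A [model_parameters()] object or plain list of numeric
#'   arrays.
#' @return Character scalar, e.g. `"0a1b2c3d"`.
#' @export
param_fingerprint <- function(params) {
  tensors <- if (inherits(params, "model_parameters")) params$tensors
             else params
  bytes <- unlist(lapply(tensors, function(t)
    c(writeBin(as.integer(dim(t) %||% length(t)), raw(), size = 4L),
      writeBin(as.vector(as.numeric(t)), raw(), size = 8L))))
  b <- as.integer(bytes)
  p <- 2147483629  # largest prime < 2^31 minus a few; doubles stay exact
  h1 <- 17; h2 <- 19
  for (i in seq_along(b)) {
    h1 <- (h1 * 131 + b[i]) %% p
    h2 <- (h2 * 137 + b[i]) %% p
  }
  sprintf("%04x%04x", as.integer(h1 %% 65536), as.integer(h2 %% 65536))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
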