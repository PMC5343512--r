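#' @title Deterministic substreams
#' @name substreams
#' @description Every random draw in the package flows through a substream
#'   seed derived from one root seed plus a string key, so reruns are
#'   bit-identical and components (models, variables, run segments) have
#'   independent, order-insensitive streams.
#' @keywords internal
NULL

# polynomial string hash folded into [0, 2^31 - 2]; exact in doubles
hash_key <- function(...) {
  key <- paste(c(...), collapse = "\r")
  h <- 0
  for (x in utf8ToInt(key)) h <- (h * 31 + x) %% 2147483647
  h
}

#' Derive a substream seed from a root seed and a key
#'
#' @param root_seed integer root seed.
#' @param ... key components (coerced to character).
#' @return an integer in `[0, 2^31 - 2]`, usable with [set.seed()].
#' @keywords internal
substream_seed <- function(root_seed, ...) {
  root <- as.double(root_seed) %% 2147483647
  as.integer((root * 48271 + hash_key(...)) %% 2147483647)
}

# Evaluate `code` under `seed`, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}
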