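# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible substream seed from a master seed and a string key
#'
#' One global integer seed governs every source of randomness in the package;
#' per-sample streams are keyed by strings (patient id, tissue, chain, stage
#' name) so that adding patients or chains to a simulation never perturbs the
#' draws of existing samples.
#'
#' @param seed master integer seed.
#' @param ... character or numeric key components, concatenated with "/".
#' @return an integer seed in [0, 2^31 - 60).
#' @keywords internal
substream_seed <- function(seed, ...) {
  key <- paste(vapply(list(...), as.character, character(1)), collapse = "/")
  m <- 2147480009  # largest prime < 2^31 we stay under
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 131 + ch) %% m
  as.integer((abs(as.numeric(seed)) %% m + h * 7919) %% m)
}

# Evaluate `expr` under a keyed substream seed, restoring RNG state afterwards.
with_substream <- function(seed, keys, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(do.call(substream_seed, c(list(seed), as.list(keys))))
  expr
}

# Hamming distance between two equal-length strings.
hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
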