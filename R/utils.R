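# internal helpers shared across modules

logit <- function(p) log(p / (1 - p))

inv_logit <- function(x) 1 / (1 + exp(-x))

#' Derive a reproducible substream seed
#'
#' Maps a global seed and a stream label to a deterministic 32-bit seed so
#' that independent simulation stages can be regenerated in isolation.
#'
#' @param seed Integer global seed.
#' @param stream Character label of the substream.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((abs(seed) %% 65536L) * 32749 + (h %% 32749)) %% 2147483646L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_finite <- function(x, what) {
  if (any(!is.finite(x))) {
    stop(sprintf("non-finite value in %s", what), call. = FALSE)
  }
  invisible(x)
}
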