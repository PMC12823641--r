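#' Derive a reproducible substream seed
#'
#' Maps a master seed plus an arbitrary sequence of labels (architecture
#' name, delta-hat value, replicate index, cohort role, ...) to a 32-bit
#' integer seed. One master seed thus spawns named, decorrelated substreams,
#' so any single replicate of a large grid can be re-run in isolation.
#'
#' The hash is a Lehmer-style accumulator over the UTF-8 bytes of the label
#' string, computed modulo 2^31 - 1 so every intermediate product stays exact
#' in double precision.
#'
#' @param master integer master seed.
#' @param ... further labels (coerced to character) naming the substream.
#' @return a single integer in `[1, 2^31 - 2]`, usable with [set.seed()].
#' @examples
#' derive_seed(1, "train")
#' derive_seed(1, "additive", 0.002, 7, "test")
#' @export
derive_seed <- function(master, ...) {
  label <- paste(c(format(master), vapply(list(...), format, "")), collapse = "/")
  bytes <- utf8ToInt(label)
  m <- 2147483647 # 2^31 - 1, prime
  h <- 17
  for (b in bytes) h <- (h * 48271 + b) %% m
  as.integer(h %% (m - 2L) + 1L)
}

# Run `expr` under a temporary RNG state seeded with `seed` (NULL = use the
# current stream untouched).
with_seed_or_current <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(seed, expr)
}
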