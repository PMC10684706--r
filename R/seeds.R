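#' Derive a reproducible child seed from a master seed
#'
#' The study is seeded hierarchically: one master seed, from which per-patient,
#' per-reviewer and per-assessment substream seeds are derived, so that any
#' single cell of the study can be regenerated in isolation. The derivation is
#' a deterministic integer mix (multiplicative congruential step per index,
#' modulo 2^31 - 1) and always returns a value in [1, 2^31 - 2], safe to pass
#' to [set.seed()].
#'
#' @param seed Integer master seed.
#' @param ... Integer indices identifying the substream (e.g. patient,
#'   reviewer, assessment, stage). Order matters.
#' @return A single integer seed.
#' @export
#' @examples
#' derive_seed(1, 3, 2, 1)
derive_seed <- function(seed, ...) {
  idx <- c(...)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  m <- 2147483647 # 2^31 - 1, prime
  x <- (abs(as.double(seed)) %% m)
  for (k in as.double(idx)) {
    # all intermediates stay below 2^53, so double arithmetic is exact
    x <- (x * 69069 + (k + 1) * 2654435) %% m
    x <- (x * 997 + 101) %% m
  }
  as.integer(x %% (m - 2)) + 1L
}

# Evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
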