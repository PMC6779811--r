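#' Derive a reproducible sub-seed
#'
#' Deterministically maps a master seed, a stream label and an index to an
#' integer seed in `[1, 2^31 - 2]`. Every stochastic component of the package
#' draws its seed through this function so that adding a processing step never
#' shifts the random streams of other steps.
#'
#' @param master integer master seed.
#' @param label character stream label (typically the module or purpose).
#' @param index nonnegative integer distinguishing repeated draws of a stream.
#' @return an integer seed.
#' @export
#' @examples
#' derive_seed(1, "theta-noise", 1)
derive_seed <- function(master, label, index = 0L) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master))
  stopifnot(is.character(label), length(label) == 1L)
  stopifnot(is.numeric(index), length(index) == 1L, index >= 0)
  m <- 2147483647 # 2^31 - 1, prime
  h <- abs(master) %% m
  for (b in utf8ToInt(label)) h <- (h * 31 + b) %% m
  h <- (h * 1009 + (index %% m)) %% m
  as.integer(h %% (m - 1) + 1)
}

# Evaluate `expr` with the global RNG seeded to `seed`, restoring the caller's
# RNG state afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
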