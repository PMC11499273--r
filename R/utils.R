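## Evaluate expr under a temporary RNG state seeded with `seed`,
## restoring the caller's RNG state afterwards.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Derive a stage seed from a global seed
#'
#' Deterministically maps a global integer seed and a stage label to a
#' stage-specific seed below 2^31, so that every stochastic stage of a run
#' is reproducible from one number.
#'
#' @param seed global integer seed.
#' @param stage character stage label (e.g. `"split"`, `"resample"`).
#' @param k optional integer sub-index (e.g. Monte Carlo refit number).
#' @return Integer seed.
#' @export
deriveSeed <- function(seed, stage, k = 0L) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.double(seed) * 48271 + h * 1009 + k * 7919) %% 2147483629)
}

## Geometric mean with positivity clamp (growth rates are non-negative by
## construction; the clamp only guards exact zeros).
geomMean <- function(x, eps = 1e-6) {
  exp(mean(log(pmax(x, eps))))
}
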