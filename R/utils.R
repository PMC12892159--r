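# Seed plumbing: every stochastic operation takes an explicit integer seed and
# runs under a fixed RNG (Mersenne-Twister / inversion), restoring the caller's
# RNG state afterwards, so identical inputs give bit-identical outputs.

withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("seed must be a single finite integer", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  suppressWarnings(set.seed(as.integer(seed), kind = "Mersenne-Twister",
                            normal.kind = "Inversion",
                            sample.kind = "Rejection"))
  expr
}

# Derive a stream of sub-seeds (< 2^31) from one master seed.
deriveSeed <- function(master, index) {
  as.integer((as.numeric(master) %% 2147483629 * 7919 + index) %% 2147483629)
}

stopData <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("cortiStar_insufficient_data",
                                "cortiStar_error")))
}

stopConfig <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("cortiStar_config_error", "cortiStar_error")))
}

stopDomain <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("cortiStar_domain_error", "cortiStar_error")))
}
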