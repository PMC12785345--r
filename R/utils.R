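#' Derive a deterministic child seed from a root seed and stage name
#'
#' Every stochastic stage of the pipeline draws its own seed from the run's
#' root seed via this function, so that (a) the whole pipeline is reproducible
#' from one integer and (b) changing the draw count of one stage never
#' perturbs another. The derivation is a 31-multiplier polynomial hash of the
#' stage label folded into the root seed, reduced modulo 2^31 - 1 (R's
#' integers are 32-bit).
#'
#' @param seed integer root seed.
#' @param stage character scalar naming the stage (e.g. `"noise"`).
#' @return an integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage),
            length(stage) == 1L)
  m <- 2147483647
  s <- as.double(seed %% m)
  for (code in utf8ToInt(stage)) {
    s <- (s * 31 + code) %% m
  }
  as.integer(s)
}

# run `expr` under a local RNG state seeded from (seed, stage); restores the
# caller's RNG afterwards so library code never disturbs user simulations
with_stage_seed <- function(seed, stage, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(derive_seed(seed, stage))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_nirauth <- function(...) stop(..., call. = FALSE)
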