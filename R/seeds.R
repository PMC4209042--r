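# Hierarchical seeding: one master seed spawns independent child seeds for
# the separate stochastic stages (noise, missingness, imputation, bootstraps)
# so that stages can be aligned or varied independently across runs.

#' Derive child seeds from a master seed
#'
#' @param seed integer master seed.
#' @param n number of child seeds.
#' @return integer vector of length `n`, each usable with [set.seed()].
#' @export
derive_seeds <- function(seed, n) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample.int(2147483646L, n)
}

# Set the RNG only when a seed is supplied; NULL means "continue the caller's
# stream", which is how nested stages inherit reproducibility from the top.
maybe_seed <- function(seed) {
  if (!is.null(seed)) set.seed(seed)
  invisible(NULL)
}
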