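# Deterministic seed derivation: every random stage of the pipeline draws its
# seed from a master seed plus a context label, so module-level streams are
# independent and reproducible under any call order.

#' Derive a module seed from a master seed
#'
#' Hashes the master seed together with one or more context labels into an
#' integer in `[1, 2^31 - 2]` suitable for [set.seed()]. All randomness in
#' the package flows through seeds derived this way, so a single master seed
#' fixes every stage (population generation, entrant cohorts, per-cycle event
#' draws, relative-risk draws) independently.
#'
#' @param seed Master seed (single integer).
#' @param ... Context labels (characters or numbers) identifying the stream,
#'   e.g. `derive_seed(7, "population")`, `derive_seed(7, "cycle", 3)`.
#' @return A single integer seed.
#' @examples
#' derive_seed(7, "population")
#' derive_seed(7, "cycle", 1) != derive_seed(7, "cycle", 2)
#' @export
derive_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  m <- 2147483647 # 2^31 - 1, Mersenne prime
  h <- as.numeric(seed) %% m
  label <- paste(c(...), collapse = "/")
  for (code in utf8ToInt(label)) {
    h <- (h * 31 + code) %% m
  }
  # multiplicative scramble (Lehmer step) so nearby seeds decorrelate
  h <- (h * 48271) %% m
  as.integer(h %% (m - 2) + 1)
}

# run `expr` under a temporary RNG state seeded with `seed`; restores the
# caller's RNG state afterwards so library code never disturbs user RNG.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
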