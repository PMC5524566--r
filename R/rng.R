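#' Derive a deterministic substream seed
#'
#' Every stochastic operation in the package draws its random numbers from a
#' substream seed derived from one master seed plus a sequence of labels
#' (e.g. condition label, trial index, input name).  The same master seed and
#' labels always give the same substream, so any component of a simulated
#' experiment can be regenerated in isolation.
#'
#' The hash is a 31-bit polynomial rolling hash of the label characters,
#' seeded by the master seed.  All arithmetic stays below 2^53 so the result
#' is exact in double precision.
#'
#' @param seed master seed (single number).
#' @param ... labels (coerced to character) identifying the substream.
#' @return an integer in `[0, 2^31 - 2]`, usable with [set.seed()].
#' @export
#' @examples
#' substream_seed(1, "blank", 3, "c1")
substream_seed <- function(seed, ...) {
  m <- 2147483647  # 2^31 - 1
  h <- as.numeric(seed) %% m
  for (lab in unlist(lapply(list(...), as.character))) {
    for (code in utf8ToInt(lab)) {
      h <- (h * 31 + code + 1) %% m
    }
  }
  as.integer(h)
}

# Evaluate expr with a local RNG state: set the substream seed, restore the
# caller's .Random.seed afterwards.
with_substream <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
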