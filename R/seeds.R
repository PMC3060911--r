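#' Derive a child seed from a master seed and a tag
#'
#' All randomness in the package flows from a single integer seed.  Stages
#' that need independent random streams derive a child seed from the master
#' seed and a short stage tag, so that re-running any stage with the same
#' master seed reproduces its output exactly, and adding a stage never
#' perturbs the streams of the others.
#'
#' @param seed integer master seed.
#' @param tag character tag naming the consumer (e.g. `"topology"`).
#' @return an integer in `[0, 2^31 - 2]`, usable with [set.seed()].
#' @export
#' @examples
#' derive_seed(1L, "topology")
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  m <- 2147483647  # 2^31 - 1, keeps results inside R's integer range
  h <- abs(as.double(seed)) %% m
  for (ch in utf8ToInt(tag)) h <- (h * 69069 + ch) %% m
  as.integer(h)
}

# Evaluate `expr` under `set.seed(seed)` without disturbing the caller's RNG
# state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}
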