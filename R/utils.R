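#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor cor.test isoreg lm optim p.adjust prcomp pt rbinom
#'   rnorm runif sd setNames var complete.cases
#' @importFrom utils read.csv write.csv head
NULL

# Run `expr` under a fixed RNG seed without touching the caller's RNG state.
# All stochastic operations in the package take an explicit integer seed and
# route through this helper; nothing relies on the global random stream.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old_seed <- if (had_seed) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old_seed, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Spread one user seed into k reproducible child seeds (kept < 2^31).
derive_seeds <- function(seed, k) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, k))
}

stop_if_not_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must be a single value in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}
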