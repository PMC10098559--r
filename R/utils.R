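#' @keywords internal
"_PACKAGE"

# Run `expr` under a temporary RNG seed, restoring the caller's RNG state.
# Keeps helper draws (splits, fixtures) from perturbing an optimizer's stream.
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
  force(expr)
}

# Counter-based sub-seed derivation: a fixed affine map modulo a Mersenne
# prime so adding consumers never shifts existing streams. Result < 2^31.
derive_seed <- function(seed, counter) {
  m <- 2147483647
  s <- (as.numeric(seed) %% m) * 48271 + as.numeric(counter) * 10007
  as.integer(s %% m)
}

clamp01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

# Round half away from zero (R's round() is banker's rounding).
round_half_up <- function(x) floor(x + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_param <- function(...) stop(..., call. = FALSE)
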