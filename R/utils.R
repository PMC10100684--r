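#' Derive a reproducible sub-stream seed
#'
#' Derives a deterministic 31-bit seed from a master seed and a stage label,
#' so that each stochastic stage of a run consumes an independent, documented
#' random stream. The scheme is a simple polynomial string hash combined with
#' the master seed modulo 2^31 - 1.
#'
#' @param seed master integer seed.
#' @param label character scalar naming the stage (e.g. `"simulate"`).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  m <- 2147483647  # 2^31 - 1
  h <- (as.numeric(seed) %% m)
  for (k in utf8ToInt(label)) {
    h <- (h * 131 + k) %% m
  }
  as.integer(h)
}

# run fn with a local RNG state seeded by `seed`; restores the caller's RNG
with_seed <- function(seed, fn) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  fn()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_scalar_in <- function(x, name, lo, hi, open_lo = FALSE, open_hi = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (open_lo) x > lo else x >= lo) &&
    (if (open_hi) x < hi else x <= hi)
  if (!ok) {
    stop(sprintf("'%s' must be a single number in %s%g, %g%s",
                 name, if (open_lo) "(" else "[", lo, hi,
                 if (open_hi) ")" else "]"), call. = FALSE)
  }
  invisible(x)
}
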