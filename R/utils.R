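## Internal helpers shared across modules.

## Evaluate expr under a private RNG state: seeds deterministically,
## restores the caller's .Random.seed afterwards. Every seeded op in the
## package goes through this, so no op disturbs global RNG state.
.withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

## Deterministic per-stage seed derivation from one top-level seed.
## Keeps derived seeds in [0, 2^31): splitmix-style integer hash.
.deriveSeed <- function(seed, stage) {
  h <- as.double(seed)
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

## Root-mean-square of a vector, NA-safe.
.rms <- function(x) sqrt(mean(x^2, na.rm = TRUE))

## round() half-up at `digits` decimals (base R rounds half to even);
## matches how the reported trial percentages are printed.
.roundHalfUp <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

.stopIfNot <- function(cond, ...) if (!cond) stop(..., call. = FALSE)
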