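# shared internal helpers

# Derive k reproducible sub-seeds (< 2^31) from one master seed without
# disturbing the caller's RNG state.
derive_seeds <- function(seed, k) {
  withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, k))
}

# Stable 31-bit polynomial string hash; platform-independent (pure integer
# arithmetic in double space, values stay below 2^52).
stable_hash <- function(s) {
  vapply(s, function(x) {
    h <- 0
    for (ch in utf8ToInt(enc2utf8(x))) h <- (h * 31 + ch) %% 2147483647
    h
  }, numeric(1), USE.NAMES = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

sigmoid <- function(x) 1 / (1 + exp(-x))

# truncated normal draw (simple resampling-free clamp at minimum)
rnorm_trunc <- function(n, mean, sd, min) {
  pmax(round(stats::rnorm(n, mean, sd)), min)
}
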