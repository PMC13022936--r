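# Internal helpers shared across modules.

# Evaluate expr with a local RNG seeded at `seed`, restoring the caller's
# RNG state afterwards. All stochastic generators route through this so a
# master seed fully determines every output.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, globalenv())
    } else if (exists(".Random.seed", globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic per-subject seed derived from a master seed and a subject
# index; kept below 2^31 so it is a valid R integer.
derive_seed <- function(master_seed, index) {
  as.integer((as.numeric(master_seed) * 1000003 + as.numeric(index) * 7919) %% 2147483647)
}

# 1/f ("pink") amplitude-shaped Gaussian noise with a deterministic
# variance calibration (no per-draw renormalization, so averaging n
# independent draws equals one draw scaled by 1/sqrt(n) in distribution).
pink_noise <- function(n, sd = 1) {
  if (n < 2L || sd <= 0) return(rep(0, n))
  w <- stats::rnorm(n)
  k <- 0:(n - 1)
  fr <- pmin(k, n - k)
  sc <- ifelse(fr == 0, 0, 1 / sqrt(fr))
  x <- Re(stats::fft(stats::fft(w) * sc, inverse = TRUE)) / n
  # E[var(x)] = mean(sc^2) for unit-variance white input
  x * sd / sqrt(mean(sc^2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
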