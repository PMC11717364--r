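# deterministic child seeds below 2^31, so a single cohort seed
# reproduces every subject-day stream independently of evaluation order
derive_seed <- function(seed, ...) {
  ix <- c(seed, ...)
  s <- 0
  for (v in ix) s <- (s * 69069 + as.numeric(v) + 1) %% 2147483647
  as.integer(s)
}

# moving average with edge padding, used for envelopes and rectified events
moving_mean <- function(x, width) {
  width <- max(1L, as.integer(width))
  if (width %% 2L == 0L) width <- width + 1L
  half <- (width - 1L) %/% 2L
  xp <- c(rep(x[1], half), x, rep(x[length(x)], half))
  as.numeric(stats::filter(xp, rep(1 / width, width), sides = 2))[
    (half + 1L):(half + length(x))]
}

local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
}
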