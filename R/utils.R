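#' @keywords internal
"_PACKAGE"

#' @importFrom stats approx coef lm median pnorm qnorm rnorm runif sd var fft
#' @importFrom utils head read.csv tail write.csv
NULL

# Derive per-unit sub-seeds from one master seed so parallel streams never
# share state. Kept below 2^31 - 1 (R integers are 32-bit).
derive_seeds <- function(master_seed, n) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L, n >= 1)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(master_seed %% .Machine$integer.max))
  sample.int(.Machine$integer.max - 1L, n)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

# Indices of strict local maxima of a numeric vector (plateau-free signals
# assumed; ties broken toward the earlier sample).
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  which(x[2:(n - 1L)] > x[1:(n - 2L)] & x[2:(n - 1L)] >= x[3:n]) + 1L
}

local_minima <- function(x) local_maxima(-x)

# Steady-state amplitude of a sinusoid at known frequency, by least squares
# on a sine/cosine basis over the analysed stretch.
fit_sine_amplitude <- function(x, fs, freq) {
  t <- seq_along(x) / fs
  s <- sin(2 * pi * freq * t)
  c_ <- cos(2 * pi * freq * t)
  fit <- lm(x ~ s + c_)
  sqrt(sum(coef(fit)[c("s", "c_")]^2))
}

# Truncated normal sampling via inverse-CDF; vectorised over n.
rtruncnorm <- function(n, mean, sd, lower, upper) {
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
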