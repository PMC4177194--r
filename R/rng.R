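# Reproducible named RNG streams and the model's elementary random draws.
#
# Every stochastic choice in the simulation goes through one of the kernels
# below, drawing from an `rng_stream`: a self-contained Mersenne-Twister state
# keyed by (seed, label). Identical (seed, label) pairs replay identical draw
# sequences; distinct labels behave as independent streams. The engine opens
# one substream per patient per pathway, so enlarging a cohort never perturbs
# the trajectories of patients already in it.

# 32-bit FNV-1a over the label bytes, folded with the user seed.
# Kept below 2^31 so the result is always a valid set.seed() argument.
.stream_seed <- function(seed, label) {
  h <- 2166136261
  for (b in utf8ToInt(label)) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2^31
  }
  as.integer((h + (as.numeric(seed) %% 2^31) * 2654435761) %% 2147483647)
}

#' Create a named reproducible RNG stream
#'
#' A stream is an independent Mersenne-Twister state identified by a base
#' seed and a text label (e.g. `"run01/patient0017/outpatient"`). The same
#' `(seed, label)` pair always replays the same draw sequence, and draws from
#' one stream never advance any other stream or the global RNG state.
#'
#' @param seed Integer base seed.
#' @param label Character label naming the substream.
#' @return An object of class `rng_stream`.
#' @examples
#' s <- rng_stream(1, "demo")
#' draw_bernoulli(0.5, s)
#' @export
rng_stream <- function(seed, label = "") {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(label))
  st <- new.env(parent = emptyenv())
  st$seed <- as.integer(seed)
  st$label <- label
  old <- get0(".Random.seed", globalenv())
  set.seed(.stream_seed(seed, label), kind = "Mersenne-Twister")
  st$state <- get(".Random.seed", globalenv())
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  st$buf <- numeric(0)
  st$pos <- 0L
  class(st) <- "rng_stream"
  st
}

#' @export
print.rng_stream <- function(x, ...) {
  cat(sprintf("<rng_stream seed=%d label=%s>\n", x$seed, x$label))
  invisible(x)
}

# Draw n uniforms from the stream, swapping its state in and out of the
# global RNG. Invalidates any single-draw buffer.
stream_runif <- function(stream, n = 1L) {
  old <- get0(".Random.seed", globalenv())
  assign(".Random.seed", stream$state, envir = globalenv())
  x <- stats::runif(n)
  stream$state <- get(".Random.seed", globalenv())
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  stream$buf <- numeric(0)
  stream$pos <- 0L
  x
}

# Buffered single uniform: refills in blocks to amortize the state swap.
stream_next <- function(stream) {
  if (stream$pos >= length(stream$buf)) {
    old <- get0(".Random.seed", globalenv())
    assign(".Random.seed", stream$state, envir = globalenv())
    stream$buf <- stats::runif(256L)
    stream$state <- get(".Random.seed", globalenv())
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    stream$pos <- 0L
  }
  stream$pos <- stream$pos + 1L
  stream$buf[[stream$pos]]
}

#' Convert a per-period event probability to a daily hazard
#'
#' Solves `1 - (1 - h)^period_days = p` for `h`, bridging probabilities
#' reported per reference period (e.g. hospitalization per 6-month follow-up)
#' to the simulation's one-day time step.
#'
#' @param p Event probability over the whole period, in `[0, 1]`.
#' @param period_days Length of the reference period in days (>= 1).
#' @return The equivalent per-day probability.
#' @examples
#' daily_hazard_from_period_prob(0.3208, 182)
#' @export
daily_hazard_from_period_prob <- function(p, period_days) {
  if (!is.numeric(p) || any(p < 0) || any(p > 1)) {
    stop("`p` must be a probability in [0, 1]", call. = FALSE)
  }
  stopifnot(period_days >= 1)
  1 - (1 - p)^(1 / period_days)
}

#' Bernoulli draw from a stream
#'
#' @param p Success probability in `[0, 1]`.
#' @param rng An [rng_stream()].
#' @return `TRUE` with probability `p`; consumes exactly one uniform.
#' @export
draw_bernoulli <- function(p, rng) {
  if (!is.numeric(p) || length(p) != 1 || is.na(p) || p < 0 || p > 1) {
    stop("`p` must be a probability in [0, 1]", call. = FALSE)
  }
  stream_next(rng) < p
}

#' Categorical draw from a stream
#'
#' @param weights Nonnegative weights, at least one positive; they are
#'   normalised internally.
#' @param rng An [rng_stream()].
#' @return An integer index into `weights`; consumes exactly one uniform.
#' @export
draw_categorical <- function(weights, rng) {
  if (!is.numeric(weights) || any(weights < 0) || sum(weights) <= 0) {
    stop("`weights` must be nonnegative with at least one positive entry",
         call. = FALSE)
  }
  cw <- cumsum(weights) / sum(weights)
  u <- stream_next(rng)
  which(u <= cw + 1e-15)[1]
}

#' Sample an integer length of stay
#'
#' Hospital length-of-stay data are right-skewed and the input tables report
#' medians only, so stays are drawn from a log-normal parameterised by its
#' continuous median (`exp(meanlog) = median_days`) with log-scale standard
#' deviation `dispersion`, then rounded up to whole days (minimum 1).
#' `dispersion = 0` degenerates to a fixed stay of `ceiling(median_days)`,
#' used for deterministic testing.
#'
#' @param median_days Median stay in days (>= 1, may be fractional, e.g. 6.5).
#' @param dispersion Log-scale sigma (>= 0); default in the packaged
#'   scenarios is 0.5.
#' @param rng An [rng_stream()].
#' @return An integer number of days, >= 1.
#' @export
sample_los <- function(median_days, dispersion, rng) {
  if (!is.numeric(median_days) || median_days < 1) {
    stop("`median_days` must be >= 1", call. = FALSE)
  }
  stopifnot(dispersion >= 0)
  u <- stream_next(rng)
  if (dispersion == 0) {
    return(as.integer(ceiling(median_days)))
  }
  x <- stats::qlnorm(u, meanlog = log(median_days), sdlog = dispersion)
  max(1L, as.integer(ceiling(x)))
}

#' Draw a one-step NYHA class transition
#'
#' Moves the class down one grade (improvement), keeps it, or moves it up one
#' grade (worsening) according to a probability triple, clamped to the 1-4
#' range: improvement at class 1 and worsening at class 4 both leave the
#' class unchanged.
#'
#' @param current Current NYHA class, integer 1-4.
#' @param transition_probs Numeric triple `(improve, stay, worsen)` summing
#'   to 1.
#' @param rng An [rng_stream()].
#' @return The new NYHA class (integer 1-4).
#' @export
sample_nyha_transition <- function(current, transition_probs, rng) {
  current <- as_nyha(current)
  if (!is.numeric(transition_probs) || length(transition_probs) != 3 ||
      any(transition_probs < 0) ||
      abs(sum(transition_probs) - 1) > 1e-9) {
    stop("`transition_probs` must be three nonnegative values summing to 1",
         call. = FALSE)
  }
  move <- draw_categorical(transition_probs, rng) - 2L  # -1, 0, +1
  min(4L, max(1L, current + move))
}

#' Empirical per-period hospitalization probability from daily draws
#'
#' Calibration check for the hazard conversion: converts a per-period event
#' probability to its daily hazard, simulates `n_periods` independent
#' periods of daily Bernoulli draws, and returns the fraction of periods
#' with at least one event. For large `n_periods` this recovers `p` within
#' binomial sampling error.
#'
#' @param n_periods Number of simulated patient-periods.
#' @param p Per-period event probability.
#' @param period_days Period length in days.
#' @param rng An [rng_stream()].
#' @return Fraction of periods with at least one event.
#' @export
simulate_period_hospitalizations <- function(n_periods, p, period_days, rng) {
  hazard <- daily_hazard_from_period_prob(p, period_days)
  hits <- 0L
  remaining <- as.integer(n_periods)
  chunk <- max(1L, min(5000L, remaining))
  while (remaining > 0L) {
    m <- min(chunk, remaining)
    u <- matrix(stream_runif(rng, m * period_days), nrow = m)
    hits <- hits + sum(rowSums(u < hazard) > 0L)
    remaining <- remaining - m
  }
  hits / n_periods
}
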