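# Stochastic kernels: stream reproducibility, hazard conversion, draw
# distributions.

test_that("streams replay identically for identical (seed, label) and differ across labels", {
  a1 <- rng_stream(11, "patient-1/outpatient")
  a2 <- rng_stream(11, "patient-1/outpatient")
  b <- rng_stream(11, "patient-2/outpatient")
  x1 <- replicate(50, stream_next(a1))
  x2 <- replicate(50, stream_next(a2))
  y <- replicate(50, stream_next(b))
  expect_identical(x1, x2)
  expect_false(identical(x1, y))

  # interleaving another stream does not perturb a stream's sequence
  c0 <- rng_stream(11, "interleave")
  ref <- replicate(20, stream_next(c0))
  c1 <- rng_stream(11, "interleave")
  got <- numeric(20)
  for (i in 1:20) {
    stream_next(b)
    got[i] <- stream_next(c1)
  }
  expect_identical(got, ref)
})

test_that("streams leave the global RNG state untouched", {
  set.seed(99)
  expected <- runif(3)
  set.seed(99)
  s <- rng_stream(1, "isolation")
  stream_runif(s, 100)
  stream_next(s)
  expect_identical(runif(3), expected)
})

test_that("hazard conversion matches the closed form and round-trips", {
  expect_equal(daily_hazard_from_period_prob(0, 365), 0)
  expect_equal(daily_hazard_from_period_prob(1, 7), 1)
  # independent closed-form evaluation of 1-(1-h)^182 = 0.3208
  expect_equal(daily_hazard_from_period_prob(0.3208, 182),
               1 - exp(log(1 - 0.3208) / 182), tolerance = 1e-12)
  expect_equal(daily_hazard_from_period_prob(0.3208, 182), 0.002123,
               tolerance = 1e-3)
  # round trip over a grid
  for (p in c(0.001, 0.1, 0.3208, 0.5, 0.9, 0.999)) {
    for (period in c(1, 7, 30, 182, 365)) {
      h <- daily_hazard_from_period_prob(p, period)
      expect_lt(abs(1 - (1 - h)^period - p), 1e-12)
    }
  }
  expect_error(daily_hazard_from_period_prob(1.2, 10), "probability")
})

test_that("daily draws at the converted hazard reproduce the period probability", {
  s <- rng_stream(5, "period-mc")
  frac <- simulate_period_hospitalizations(20000, 0.3208, 182, s)
  expect_binomial(frac, 0.3208, 20000, "period hospitalization")
})

test_that("bernoulli draws have the right mean and respect extremes", {
  s <- rng_stream(3, "bern")
  expect_false(any(replicate(100, draw_bernoulli(0, s))))
  expect_true(all(replicate(100, draw_bernoulli(1, s))))
  n <- 1e5
  hits <- mean(stream_runif(s, n) < 0.126)  # same construction as the kernel
  expect_binomial(hits, 0.126, n, "bernoulli mean")
  m <- mean(replicate(20000, draw_bernoulli(0.126, s)))
  expect_binomial(m, 0.126, 20000, "draw_bernoulli mean")
  expect_error(draw_bernoulli(-0.1, s), "probability")
  expect_error(draw_bernoulli(1.1, s), "probability")
})

test_that("categorical draws follow normalised weights", {
  s <- rng_stream(4, "cat")
  expect_true(all(replicate(50, draw_categorical(c(1, 0, 0), s)) == 1L))
  n <- 5e4
  draws <- replicate(n, draw_categorical(c(2, 1, 1), s))
  expect_binomial(mean(draws == 1), 0.50, n, "weight 2 index")
  expect_binomial(mean(draws == 2), 0.25, n, "weight 1 index")
  expect_binomial(mean(draws == 3), 0.25, n, "weight 1 index")
  draws2 <- replicate(n, draw_categorical(c(1, 1), s))
  expect_binomial(mean(draws2 == 1), 0.5, n, "even split")
  expect_error(draw_categorical(c(0, 0), s), "positive")
  expect_error(draw_categorical(c(-1, 2), s), "nonnegative")
})

test_that("length-of-stay draws hit the configured median", {
  s <- rng_stream(6, "los")
  expect_true(all(replicate(50, sample_los(10, 0, s)) == 10L))
  expect_true(all(replicate(50, sample_los(6.5, 0, s)) == 7L))
  n <- 1e5
  x10 <- replicate(n, sample_los(10, 0.5, s))
  expect_true(abs(stats::median(x10) - 10) <= 1)
  x65 <- replicate(n, sample_los(6.5, 0.5, s))
  expect_true(abs(stats::median(x65) - 7) <= 1)  # ceil(6.5) under rounding up
  expect_true(min(x10) >= 1)
  expect_error(sample_los(0.5, 0.5, s), ">= 1")
})

test_that("NYHA transitions move one step and clamp at the boundary grades", {
  s <- rng_stream(7, "nyha")
  expect_identical(sample_nyha_transition(2, c(0, 1, 0), s), 2L)
  expect_identical(sample_nyha_transition(1, c(1, 0, 0), s), 1L)  # clamp low
  expect_identical(sample_nyha_transition(4, c(0, 0, 1), s), 4L)  # clamp high
  n <- 5e4
  draws <- replicate(n, sample_nyha_transition(3, c(0.2, 0.6, 0.2), s))
  expect_binomial(mean(draws == 2), 0.2, n, "improve")
  expect_binomial(mean(draws == 3), 0.6, n, "stay")
  expect_binomial(mean(draws == 4), 0.2, n, "worsen")
  expect_error(sample_nyha_transition(2, c(0.5, 0.5, 0.5), s), "summing to 1")
  expect_error(sample_nyha_transition(5, c(0, 1, 0), s), "NYHA")
})
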