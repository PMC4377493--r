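test_that("feedback score matches the worked example and identities", {
  expect_equal(feedback_score(-0.2, -0.6), 25)
  # any unchanged correlation scores zero
  for (x in c(-1, -0.37, 0, 0.51, 1)) expect_equal(feedback_score(x, x), 0)
  expect_equal(feedback_score(1, 0), 100)
  expect_equal(feedback_score(-1, 0), -100)
  expect_error(feedback_score(1.2, 0), "\\[-1, 1\\]")
})

test_that("positive reward is given in all three correlation-increase cases", {
  expect_gt(feedback_score(0.6, 0.2), 0)   # positive grows
  expect_gt(feedback_score(0.2, -0.2), 0)  # negative turns positive
  expect_gt(feedback_score(-0.2, -0.6), 0) # negative shrinks in magnitude
})

test_that("score is bounded by 100 on an exhaustive grid and attains it", {
  g <- expand.grid(ri = seq(-1, 1, by = 0.01), r0 = seq(-1, 1, by = 0.01))
  s <- feedback_score(g$ri, g$r0)
  expect_lte(max(abs(s)), 100)
  expect_equal(max(s), 100)
  expect_equal(min(s), -100)
  # attained at admissible endpoints, e.g. nonpositive baseline, r_i = 1
  expect_equal(feedback_score(1, -1), 100)
})

test_that("trial window drops the first imagery volume and appends feedback", {
  expect_equal(assemble_trial_window(1:7, 99), c(2:7, 99))
  expect_length(assemble_trial_window(1:7, 99), 7)
  expect_error(assemble_trial_window(1:6, 99, expected_n = 7), "expected 7")
  # generalized rule at other timings
  expect_length(assemble_trial_window(1:10, 0), 10)
})

test_that("schedule volume counts follow the trial timing", {
  s <- trial_schedule()
  expect_equal(s$imagery_n, 7)
  expect_equal(s$rest_n, 7)
  expect_error(trial_schedule(imagery_s = 15, tr_s = 2), "integer multiple")
  expect_equal(trial_schedule(imagery_s = 20, tr_s = 2)$imagery_n, 10)
})

test_that("trial correlation handles identity, negation and degenerate windows", {
  w <- c(1, 3, 2, 5, 4, 6, 7)
  expect_equal(trial_correlation(w, w), 1)
  expect_equal(trial_correlation(w, -w), -1)
  expect_error(trial_correlation(rep(1, 7), w), class = "cf_degenerate_trial")
  expect_error(trial_correlation(w, w[1:5]), "length")
})

test_that("baseline is the arithmetic mean of raw trial correlations", {
  expect_equal(compute_baseline(c(-0.5, -0.3)), -0.4)
  expect_equal(compute_baseline(0.2), 0.2)
  expect_error(compute_baseline(numeric(0)), "no valid")
})

test_that("high-pass filter removes DC and matches its analytic response", {
  y <- highpass_filter(rep(5, 300), mode = "online")
  expect_lt(max(abs(tail(y, 100))), 1e-6)
  # closed-form gain of the digital filter at a given frequency
  filt <- signal::butter(5, 0.06 / 0.25, type = "high")
  gain_at <- function(f, fs = 0.5) {
    w <- 2 * pi * f / fs
    num <- sum(filt$b * exp(-1i * w * (seq_along(filt$b) - 1)))
    den <- sum(filt$a * exp(-1i * w * (seq_along(filt$a) - 1)))
    Mod(num / den)
  }
  tt <- seq(0, 4000, by = 2)
  for (f in c(0.10, 0.08)) {
    y <- highpass_filter(sin(2 * pi * f * tt), mode = "online")
    amp <- sqrt(2 * mean(tail(y, 400)^2))
    expect_equal(amp, gain_at(f), tolerance = 0.01)
  }
  y <- highpass_filter(sin(2 * pi * 0.01 * tt), mode = "online")
  expect_lt(sqrt(2 * mean(tail(y, 400)^2)), 0.2)
  expect_error(highpass_filter(rnorm(100), cutoff_hz = 0.3, tr_s = 2),
               "Nyquist")
  expect_error(highpass_filter(rnorm(4)), "too short")
})

test_that("offline filtering is zero-phase where online is causal", {
  tt <- seq(0, 1000, by = 2)
  x <- sin(2 * pi * 0.1 * tt)
  yoff <- highpass_filter(x, mode = "offline")
  mid <- 150:350
  # zero-phase: peak alignment with the input
  expect_gt(cor(x[mid], yoff[mid]), 0.999)
})

test_that("sham yoking is an injective assignment without self-pairs", {
  donors <- paste0("nf", 1:12)
  asg <- yoke_sham_scores(donors, paste0("sh", 1:12), seed = 1)
  expect_setequal(asg$donor, donors) # bijection
  # overlapping pools: never self-assigned, over many seeds
  for (s in 1:20) {
    a <- yoke_sham_scores(paste0("s", 1:5), paste0("s", 1:5), seed = s)
    expect_false(any(a$recipient == a$donor))
  }
  expect_error(yoke_sham_scores("d1", c("r1", "r2"), seed = 1),
               "fewer donors")
  expect_identical(yoke_sham_scores(donors, paste0("sh", 1:12), seed = 7),
                   yoke_sham_scores(donors, paste0("sh", 1:12), seed = 7))
})
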