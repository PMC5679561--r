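tone <- function(f0, n = 400, fs = 4000, amp = 1, offset = 2, phase = 0) {
  offset + amp * sin(2 * pi * f0 * (seq_len(n) - 1) / fs + phase)
}

test_that("pixel-to-metric conversion uses the sex-specific fold length", {
  px <- trajectory_pair(c(12.5, 10, 11), c(9, 11, 10), unit = "px")
  m <- pixel_to_metric(px, axis_length_px = 160, sex = "male")
  expect_equal(m$px_scale, 0.01)
  expect_equal(m$left[1], 0.125)
  f <- pixel_to_metric(px, axis_length_px = 100, sex = "female")
  expect_equal(f$px_scale, 0.01)
  expect_equal(f$unit, "cm")
  expect_error(pixel_to_metric(px, 0, "male"), "axis_length_px")
  # linearity: scaling the input scales the output
  px2 <- trajectory_pair(px$left * 3, px$right * 3, unit = "px")
  m2 <- pixel_to_metric(px2, 160, "male")
  expect_equal(m2$left, m$left * 3)
})

test_that("rest geometry comes from the mean edge distance of both sides", {
  const <- trajectory_pair(rep(0.0179, 100), rep(0.0179, 100))
  g <- estimate_rest_geometry(const, std_fixture)
  expect_equal(g$x01, 0.0179)
  expect_equal(g$a01, 2 * 1.4 * 0.0179)
  expect_equal(g$a01, 0.0501, tolerance = 1e-3)
  sine <- trajectory_pair(tone(200, offset = 0.02, amp = 0.01),
                          tone(200, offset = 0.02, amp = 0.01))
  expect_equal(estimate_rest_geometry(sine, std_fixture)$x01, 0.02)
  lr <- trajectory_pair(rep(0.01, 50), rep(0.03, 50))
  expect_equal(estimate_rest_geometry(lr, std_fixture)$x02, 0.02)
  zero <- trajectory_pair(rep(0, 50), rep(0, 50))
  expect_error(estimate_rest_geometry(zero, std_fixture), "degenerate")
})

test_that("fundamental frequency is exact on-grid and refined off-grid", {
  expect_equal(fundamental_frequency(tone(200), 4000), 200)
  expect_lt(abs(fundamental_frequency(tone(147.5), 4000) - 147.5), 2)
  expect_error(fundamental_frequency(rep(1, 400), 4000), "no oscillation")
})

test_that("frequency error stays below one bin width across [50, 500] Hz", {
  for (f0 in seq(52.3, 498.3, by = 13.7)) {
    for (ph in c(0, 1.1)) {
      est <- fundamental_frequency(tone(f0, phase = ph), 4000)
      expect_lt(abs(est - f0), 10)
    }
  }
})

test_that("harmonic selection applies the 25% rule plus neighbors", {
  n <- 400
  t <- (seq_len(n) - 1) / 4000
  x <- 2 + 1.0 * sin(2 * pi * 200 * t) + 0.3 * sin(2 * pi * 400 * t) +
    0.1 * sin(2 * pi * 600 * t)
  sel <- select_harmonics(x, 4000)
  expect_equal(sel$indices, c(19, 20, 21, 39, 40, 41))
  expect_equal(sel$dominant, 20)
  pure <- select_harmonics(tone(200), 4000)
  expect_equal(pure$indices, c(19, 20, 21))
  # two near-equal peaks: both selected with their neighbors
  x2 <- sin(2 * pi * 200 * t) + sin(2 * pi * 400 * t)
  sel2 <- select_harmonics(x2 + 3, 4000)
  expect_true(all(c(19, 20, 21, 39, 40, 41) %in% sel2$indices))
  # exact magnitude tie (impulse: flat spectrum): lowest index wins
  expect_equal(select_harmonics(c(1, rep(0, 399)), 4000)$dominant, 1)
  # amplitude invariance of the relative threshold
  expect_equal(select_harmonics(17.3 * x, 4000)$indices, sel$indices)
  expect_error(select_harmonics(rep(0.2, 400), 4000), "no oscillation")
})

test_that("cycle statistics recover per-cycle peaks and periods", {
  cs <- cycle_statistics(tone(200), 4000)
  expect_lt(diff(cs$amp_range) / mean(cs$peaks), 0.01)
  expect_equal(mean(cs$periods_ms), 5, tolerance = 1e-3)
  # stationary signal: per-cycle peak variation well below 2%
  expect_lt(sd(cs$peaks) / mean(cs$peaks), 0.02)
  # amplitude-modulated signal: the envelope shows up in the range
  n <- 400
  t <- (seq_len(n) - 1) / 4000
  am <- (0.9 + 0.1 * sign(sin(2 * pi * 100 * t))) * sin(2 * pi * 200 * t)
  cs <- cycle_statistics(am + 3, 4000)
  expect_equal(cs$amp_range[1], 3 + 0.8, tolerance = 0.02)
  expect_equal(cs$amp_range[2], 3 + 1.0, tolerance = 0.02)
  expect_error(cycle_statistics(tone(10), 4000), "insufficient cycles")
})

test_that("closure detection thresholds on the total-gap waveform", {
  clipped <- generate_analytic_pair(200, amp = c(0.05, 0.05), offset = 0)
  expect_true(detect_closure(clipped))
  open <- generate_analytic_pair(200, amp = c(0.02, 0.02), offset = 0.06)
  expect_false(detect_closure(open))
  # boundary case: minimum exactly 5% of the median peak counts as closed
  g <- tone(200, amp = 0.475, offset = 0.525) / 2
  pair <- trajectory_pair(g, g)
  expect_true(detect_closure(pair))
})
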