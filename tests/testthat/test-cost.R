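# DFT oracle used to freeze expected values independently of the cost
# implementation: one-sided coefficients of the mean-centered signal.
dft_oracle <- function(x) {
  n <- length(x)
  ft <- fft(x - mean(x))
  ft[2:(1 + (n - 1) %/% 2)]
}

pair_tone <- function(f0 = 200, amp = c(0.05, 0.05), offset = 0.1,
                      phase = 0, n = 400) {
  generate_analytic_pair(f0, amp = amp, offset = offset, phase = phase,
                         n_samples = n)
}

test_that("all costs vanish when model equals experiment", {
  E <- pair_tone()
  expect_equal(gamma1(E, E)$value, 0)
  expect_equal(gamma2(E, E)$value, 0)
  expect_equal(gamma3(E, E)$value, 0)
  expect_equal(gamma_final(E, E), 0)
  M <- generate_model_subject(synthetic_spec(fit_vars(1, 1, 8), seed = 1),
                              std_fixture)
  expect_equal(gamma_final(M, M), 0)
})

test_that("gamma1 separates magnitude and phase discrepancies", {
  E <- pair_tone(amp = c(0.05, 0.05))
  M <- pair_tone(amp = c(0.025, 0.025))  # half oscillation amplitude
  cv <- gamma1(E, M, s = 1)
  ek <- dft_oracle(E$left)
  sel <- select_harmonics(E$left, 4000)$indices
  mag_expected <- sqrt(sum((Mod(ek[sel]) - Mod(dft_oracle(M$left)[sel]))^2))
  expect_equal(cv$components$mag_left, mag_expected)
  expect_equal(cv$components$phase_left, 0, tolerance = 1e-8)
  expect_equal(cv$value,
               cv$components$mag_left + cv$components$mag_right)

  # half-period delay: magnitudes identical, fundamental phase flips by pi
  Md <- pair_tone(phase = pi)
  cvd <- gamma1(E, Md, s = 1)
  expect_equal(cvd$components$mag_left, 0, tolerance = 1e-9)
  expect_equal(cvd$components$phase_left, pi, tolerance = 1e-6)
})

test_that("gamma2 is the summed per-side Euclidean distance", {
  E <- pair_tone()
  expect_equal(gamma2(E, E, align = FALSE)$value, 0)
  M <- trajectory_pair(E$left + 0.01, E$right + 0.01)
  expect_equal(gamma2(E, M, align = FALSE)$value, 2 * 0.01 * sqrt(400))
  M1 <- E
  M1$left[7] <- M1$left[7] + 0.3
  expect_equal(gamma2(E, M1, align = FALSE)$value, 0.3)
  # triangle inequality per side
  A <- pair_tone(amp = c(0.05, 0.05))
  B <- pair_tone(amp = c(0.03, 0.03))
  C <- pair_tone(amp = c(0.01, 0.01))
  expect_lte(gamma2(A, C, align = FALSE)$value,
             gamma2(A, B, align = FALSE)$value +
               gamma2(B, C, align = FALSE)$value + 1e-12)
  Mbad <- trajectory_pair(E$left[1:200], E$right[1:200])
  expect_error(gamma2(E, Mbad), "equal length")
})

test_that("gamma3 normalizes harmonic structure and regularizes amplitude", {
  E <- pair_tone()
  M <- trajectory_pair(0.5 * E$left, 0.5 * E$right)
  cv <- gamma3(E, M)
  # uniform scaling cancels in the normalized magnitudes ...
  expect_equal(cv$components$mag_left, 0, tolerance = 1e-9)
  expect_equal(cv$components$phase_left, 0, tolerance = 1e-8)
  # ... and the whole value is the joint fundamental-magnitude gap
  doml <- max(Mod(dft_oracle(E$left)))
  domr <- max(Mod(dft_oracle(E$right)))
  expect_equal(cv$value, sqrt((0.5 * doml)^2 + (0.5 * domr)^2),
               tolerance = 1e-8)

  # doubled second harmonic at matched fundamental: regularization stays 0
  n <- 400
  t <- (seq_len(n) - 1) / 4000
  mk <- function(h2) 0.2 + 0.05 * sin(2 * pi * 200 * t) +
    h2 * sin(2 * pi * 400 * t)
  E2 <- trajectory_pair(mk(0.02), mk(0.02))
  M2 <- trajectory_pair(mk(0.04), mk(0.04))
  cv2 <- gamma3(E2, M2)
  expect_equal(cv2$components$regularization, 0, tolerance = 1e-9)
  expect_gt(cv2$components$mag_left, 0)
})

test_that("gamma_final matches its closed-form anchors", {
  E <- pair_tone()
  expect_equal(gamma_final(E, trajectory_pair(rep(0, 400), rep(0, 400))), 1)
  expect_equal(gamma_final(E, trajectory_pair(2 * E$left, 2 * E$right)), 1)
  # scale invariance under joint rescaling
  M <- pair_tone(amp = c(0.04, 0.05))
  g1 <- gamma_final(E, M)
  E2 <- trajectory_pair(3 * E$left, 3 * E$right)
  M2 <- trajectory_pair(3 * M$left, 3 * M$right)
  expect_equal(gamma_final(E2, M2), g1)
  zeroE <- trajectory_pair(rep(0, 400), E$right)
  expect_error(gamma_final(zeroE, E), "zero-energy")
})

test_that("spectral costs ignore sub-threshold content at unselected bins", {
  E <- pair_tone()
  M <- pair_tone()
  n <- 400
  t <- (seq_len(n) - 1) / 4000
  # add content far from the selected bins, tiny relative to the dominant
  M2 <- trajectory_pair(M$left + 1e-9 * sin(2 * pi * 1000 * t),
                        M$right, sample_rate = 4000)
  expect_equal(gamma1(E, M2)$value, gamma1(E, M)$value, tolerance = 1e-6)
  expect_equal(gamma3(E, M2)$value, gamma3(E, M)$value, tolerance = 1e-6)
})

test_that("circular alignment finds the shift and gamma1/gamma2 agree at 0", {
  E <- pair_tone()
  tau <- 37
  idx <- ((seq_len(400) - 1 + tau) %% 400) + 1
  M <- trajectory_pair(E$left[idx], E$right[idx])
  aligned <- align_phase(E, M)
  expect_equal(aligned$left, E$left)
  expect_equal(gamma2(E, M)$value, 0, tolerance = 1e-10)
  expect_equal(gamma_final(E, M), 0, tolerance = 1e-12)
  # identical selected support: both costs vanish together after alignment
  expect_equal(gamma1(E, aligned)$value, 0, tolerance = 1e-8)
})
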