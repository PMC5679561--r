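eff1 <- apply_scaling(std_fixture, fit_vars(1, 1, 8))

test_that("glottal areas follow the rest-area plus displacement rule", {
  a <- glottal_areas(model_state(), eff1)
  expect_equal(unname(a), c(eff1$a01, eff1$a02))
  # closure onset: displacements cancel the rest area
  x_close <- -eff1$a01 / (2 * eff1$l)
  a <- glottal_areas(model_state(x1l = x_close, x1r = x_close), eff1)
  expect_equal(unname(a[["a1"]]), 0)
  a <- glottal_areas(model_state(x1l = 0.01, x1r = 0.02), eff1)
  expect_equal(unname(a[["a1"]]), eff1$a01 + 1.4 * 0.03)
  expect_equal(unname(a[["a1"]]), 0.092, tolerance = 2e-3)
})

test_that("Bernoulli driving force gates on the area configuration", {
  # rectangular open glottis: the Bernoulli term cancels the pressure
  expect_equal(driving_force(0.05, 0.05, eff1)$force, 0)
  # upper section closed: full subglottal pressure acts on the lower masses
  f <- driving_force(0.05, -0.01, eff1)
  expect_equal(f$P1, eff1$Ps_internal)
  expect_equal(f$force, eff1$Ps_internal * 1.4 * 0.25)
  expect_equal(f$force, 2.746e-3, tolerance = 1e-3)
  # lower section closed: no force at all
  expect_equal(driving_force(-0.01, 0.05, eff1)$force, 0)
  expect_equal(driving_force(0, 0.05, eff1)$force, 0)
})

test_that("collision accelerations restore only while a section is closed", {
  expect_equal(unname(impact_accelerations(0.05, 0.05, eff1)),
               rep(0, 4))
  im <- impact_accelerations(-0.014, 0.05, eff1)
  # -(c1/m1) * a1/(2l) = (0.24/0.125) * 0.014/2.8
  expect_equal(unname(im[["I1l"]]), 0.0096)
  expect_gt(im[["I1l"]], 0)  # restoring, pushes outward
  expect_equal(unname(im[["I2l"]]), 0)
  # symmetric parameters give symmetric impacts
  im <- impact_accelerations(0.05, -0.01, eff1)
  expect_equal(im[["I2l"]], im[["I2r"]])
})

test_that("equilibrium and driven derivatives match hand arithmetic", {
  # Ps = 0, origin: true equilibrium
  eff0 <- apply_scaling(std_fixture, fit_vars(1, 1, 1e-12))
  expect_equal(max(abs(tmm_derivatives(model_state(), eff0))), 0)
  # Ps = 8 at the origin: the glottis is rectangular (a1 = a2), so the
  # Bernoulli bracket vanishes and the origin is still force-free
  expect_equal(max(abs(tmm_derivatives(model_state(), eff1))), 0)
  # upper section closed, lower open: full pressure drives the lower mass
  st <- model_state(x2l = -0.02, x2r = -0.02)
  d <- tmm_derivatives(st, eff1)
  f <- driving_force(glottal_areas(st, eff1)[["a1"]],
                     glottal_areas(st, eff1)[["a2"]], eff1)
  expect_equal(unname(d[["v1l"]]),
               (eff1$left$kc * -0.02) / eff1$left$m1 +
                 f$force / eff1$left$m1)
  # pure lower-mass displacement, Ps = 0, glottis open: Eq-matrix row
  d <- tmm_derivatives(model_state(x1l = 0.01), eff0)
  expect_equal(unname(d[["v1l"]]), -(0.08 + 0.025) / 0.125 * 0.01)
  expect_equal(unname(d[["x1l"]]), 0)
})

test_that("C++ integrator agrees with the pure-R right-hand side", {
  # one-step RK4 in R against the compiled path over a short window
  eff <- apply_scaling(std_fixture, fit_vars(1.3, 0.8, 12))
  state <- model_state(x1l = 0.01, x2l = 0.01, x1r = 0.01, x2r = 0.01)
  dt <- 0.01
  rk4 <- function(s) {
    k1 <- tmm_derivatives(s, eff)
    k2 <- tmm_derivatives(s + dt / 2 * k1, eff)
    k3 <- tmm_derivatives(s + dt / 2 * k2, eff)
    k4 <- tmm_derivatives(s + dt * k3, eff)
    s + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  s_r <- state
  for (i in 1:200) s_r <- rk4(s_r)
  sim <- simulate_tmm(fit_vars(1.3, 0.8, 12), std_fixture, total_ms = 2.25,
                      transient_ms = 0, output_rate = 4000, dt = dt,
                      init = state)
  # the 9th output sample sits at t = 2 ms = 200 internal steps
  expect_equal(sim$time[9], 2)
  expect_equal(unname(sim$state[9, ]), unname(s_r), tolerance = 1e-12)
})

test_that("passive system decays and symmetric drive stays symmetric", {
  sim0 <- simulate_tmm(fit_vars(1, 1, 1e-9), std_fixture)
  expect_lt(max(abs(sim0$state[201:400, c("x1l", "x2l", "x1r", "x2r")])),
            1e-6)
  sim <- sim_standard()
  expect_lt(max(abs(sim$trajectories$left - sim$trajectories$right)), 1e-9)
  # sustained oscillation with nonzero amplitude after the transient
  expect_gt(diff(range(sim$trajectories$left)), 1e-2)
})

test_that("an oscillation threshold in Ps exists and brackets reproducibly", {
  amp_at <- function(Ps) {
    s <- simulate_tmm(fit_vars(1, 1, Ps), std_fixture)
    diff(range(s$state[, "x1l"]))
  }
  expect_lt(amp_at(0.5), 1e-6)
  expect_gt(amp_at(8), 1e-2)
  expect_equal(amp_at(8), amp_at(8))  # deterministic integrator
})

test_that("area series reconstruct exactly from the state series", {
  sim <- sim_standard()
  a1 <- std_fixture$a01 +
    std_fixture$l * (sim$state[, "x1l"] + sim$state[, "x1r"])
  a2 <- std_fixture$a02 +
    std_fixture$l * (sim$state[, "x2l"] + sim$state[, "x2r"])
  expect_equal(sim$a1, a1)
  expect_equal(sim$a2, a2)
})

test_that("visible edge takes the more medial mass and clamps at zero", {
  expect_equal(visible_edge(0.03 - 0.0179, 0.05 - 0.0179, 0.0179, 0.0179),
               0.03)
  expect_equal(visible_edge(-0.1, -0.2, 0.0179, 0.0179), 0)
  sim <- sim_standard()
  expect_equal(sim$trajectories$left,
               pmax(0, pmin(std_fixture$x01 + sim$state[, "x1l"],
                            std_fixture$x02 + sim$state[, "x2l"])))
  expect_gte(min(sim$trajectories$left), 0)
})

test_that("integration blowup is reported with the failure time", {
  # an absurd pressure with an asymmetric start accelerates the lower
  # masses beyond any physical displacement within a few steps
  expect_error(
    simulate_tmm(fit_vars(1, 1, 1e9), std_fixture,
                 init = model_state(x1l = 0.05)),
    "blew up at t")
})
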