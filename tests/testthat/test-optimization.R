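quad <- function(p) (p[1] - 1)^2 + (p[2] - 2)^2 + ((p[3] - 20) / 10)^2
space3 <- search_space()

test_that("initial grid search ranks points by objective", {
  obj <- function(p) sum((p - c(2, 2, 20))^2)
  g <- initial_grid_search(obj, space3)
  expect_equal(as.numeric(g[1, c("Ql", "Qr", "Ps")]), c(2, 2, 20))
  # off-grid target: the nearest grid point wins (exhaustive oracle)
  obj2 <- function(p) sum((p - c(2.2, 1.9, 18))^2)
  g2 <- initial_grid_search(obj2, space3)
  grid <- expand.grid(Ql = seq(0.5, 6, 0.5), Qr = seq(0.5, 6, 0.5),
                      Ps = seq(5, 50, 5))
  oracle <- grid[which.min(apply(grid, 1, obj2)), ]
  expect_equal(as.numeric(g2[1, c("Ql", "Qr", "Ps")]), as.numeric(oracle))
  expect_true(all(g$Ql >= 0.5 & g$Ql <= 6 & g$Ps >= 5 & g$Ps <= 50))
  expect_error(initial_grid_search(function(p) NaN, space3),
               "no finite objective")
})

test_that("symmetric-axis sweep and asymmetry fan stay inside the bounds", {
  obj <- function(p) sum((p - c(1.2, 1.1, 15))^2)
  sw <- symmetric_axis_search(obj, space3, Q_step = 0.1)
  expect_true(all(sw$Ql == sw$Qr))
  expect_equal(sw$value[1], min(sw$value))
  fan <- asymmetry_fan(obj, space3, sw, n_top = 3)
  expect_true(all(fan$Ql >= 0.5 & fan$Qr <= 6))
  expect_true(all(abs(fan$Ql - fan$Qr) > 0))
})

test_that("Nelder-Mead reaches the analytic minimum of a convex quadratic", {
  nm <- nelder_mead(quad, c(3, 3, 40), space3$lower, space3$upper,
                    budget = 2000)
  expect_lt(max(abs(nm$par - c(1, 2, 20)) / c(1, 1, 10)), 1e-4)
  expect_lte(nm$evals, 2000)
  # starting at the minimum returns it unchanged
  nm0 <- nelder_mead(quad, c(1, 2, 20), space3$lower, space3$upper,
                     budget = 500)
  expect_lt(max(abs(nm0$par - c(1, 2, 20))), 1e-6)
})

test_that("particle swarm is seeded, reproducible, and convergent", {
  p1 <- particle_swarm(quad, space3, seed = 1, budget = 2000)
  expect_lt(max(abs(p1$par - c(1, 2, 20)) / c(1, 1, 10)), 1e-3)
  p1b <- particle_swarm(quad, space3, seed = 1, budget = 2000)
  expect_identical(p1$par, p1b$par)
  expect_identical(p1$value, p1b$value)
  p2 <- particle_swarm(quad, space3, seed = 99, budget = 2000)
  expect_lt(max(abs(p2$par - c(1, 2, 20)) / c(1, 1, 10)), 1e-3)
  expect_true(all(p1$par >= space3$lower & p1$par <= space3$upper))
})

test_that("bee colony is seeded, reproducible, and convergent", {
  b1 <- bee_colony(quad, space3, seed = 1, budget = 2000)
  expect_lt(max(abs(b1$par - c(1, 2, 20)) / c(1, 1, 10)), 1e-3)
  b1b <- bee_colony(quad, space3, seed = 1, budget = 2000)
  expect_identical(b1$par, b1b$par)
  expect_true(all(b1$par >= space3$lower & b1$par <= space3$upper))
})

test_that("bee colony abandons exhausted sources and scouts anew", {
  # on a flat objective no probe ever improves, so every source's trial
  # counter passes the limit and scouting re-draws fresh uniform positions;
  # scout draws are recognizable because they differ from all previously
  # probed points in every coordinate (neighbor probes change exactly one)
  probes <- list()
  flat <- function(p) { probes[[length(probes) + 1]] <<- p; 1 }
  invisible(bee_colony(flat, space3, seed = 5, budget = 400,
                       n_sources = 5, limit = 3))
  pts <- do.call(rbind, probes)
  init <- pts[1:5, ]
  later <- pts[-(1:5), , drop = FALSE]
  n_changed <- apply(later, 1, function(p)
    min(apply(init, 1, function(q) sum(abs(p - q) > 1e-12))))
  # neighbor probes share two coordinates with a source; scouts share none
  expect_true(any(n_changed >= 3))
})

test_that("doubling the budget never worsens the incumbent", {
  for (alg in c("nm", "pso", "sbc")) {
    run <- function(b) switch(alg,
      nm = nelder_mead(quad, c(3, 3, 40), space3$lower, space3$upper,
                       budget = b)$value,
      pso = particle_swarm(quad, space3, seed = 7, budget = b)$value,
      sbc = bee_colony(quad, space3, seed = 7, budget = b)$value)
    expect_lte(run(600), run(300))
  }
})

test_that("the nine-run pipeline recovers a noiseless synthetic subject", {
  truth <- fit_vars(1.2, 1.1, 15)
  subj <- generate_model_subject(synthetic_spec(truth, sex = "male",
                                                seed = 11), std_fixture)
  fit <- fit_subject(subj, std_fixture, space = small_space(),
                     config = fit_config(budget = 150), seed = 2)
  expect_length(fit$runs, 9)
  combos <- unique(vapply(fit$runs,
                          function(r) paste(r$algorithm, r$cost),
                          character(1)))
  expect_length(combos, 9)  # full algorithm x cost cross product
  gammas <- vapply(fit$runs, function(r) r$gamma, numeric(1))
  expect_equal(fit$best$gamma, min(gammas))
  for (r in fit$runs) {
    expect_true(r$fit$Ql >= 0.9 && r$fit$Ql <= 1.4)
    expect_true(r$fit$Ps >= 10 && r$fit$Ps <= 20)
    expect_lte(r$evals, 150)
  }
  # parameter recovery within 5% on Q, 20% on Ps; near-perfect waveform
  expect_lt(abs(fit$best$fit$Ql - 1.2) / 1.2, 0.05)
  expect_lt(abs(fit$best$fit$Qr - 1.1) / 1.1, 0.05)
  expect_lt(abs(fit$best$fit$Ps - 15) / 15, 0.20)
  expect_lte(fit$best$gamma, 0.05)
  expect_true(fit$best$success$overall)
})

test_that("fit_subject is deterministic given a seed", {
  subj <- generate_model_subject(synthetic_spec(fit_vars(1.2, 1.1, 15),
                                                noise = 0.02, jitter = 0.005,
                                                sex = "male", seed = 4),
                                 std_fixture)
  cfg <- fit_config(budget = 60, algorithms = c("PSO", "SBC"),
                    costs = "gamma2")
  f1 <- fit_subject(subj, std_fixture, space = small_space(), config = cfg,
                    seed = 9)
  f2 <- fit_subject(subj, std_fixture, space = small_space(), config = cfg,
                    seed = 9)
  expect_identical(f1$best$fit, f2$best$fit)
  expect_identical(vapply(f1$runs, function(r) r$gamma, numeric(1)),
                   vapply(f2$runs, function(r) r$gamma, numeric(1)))
})
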