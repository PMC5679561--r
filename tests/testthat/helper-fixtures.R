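# Shared fixtures: the reference parameter set, a cached standard
# simulation, and a small search space that keeps optimizer-driven tests
# fast while exercising the full pipeline.

std_fixture <- standard_parameters()

sim_standard <- local({
  sim <- NULL
  function() {
    if (is.null(sim)) sim <<- simulate_tmm(fit_vars(1, 1, 8), std_fixture)
    sim
  }
})

small_space <- function() {
  search_space(Ql = c(0.9, 1.4), Qr = c(0.9, 1.4), Ps = c(10, 20),
               Q_step = 0.25, Ps_step = 5)
}

# Minimal fit_result-shaped object for summary tests.
mock_fit <- function(Ql, Qr, Ps, gamma, success = TRUE) {
  structure(list(best = list(
    fit = fit_vars(Ql, Qr, Ps), gamma = gamma,
    Qlr = symmetry_quotient(Ql, Qr),
    success = list(overall = success))), class = "fit_result")
}
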