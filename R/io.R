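#' Write / read a fit result as JSON
#'
#' Serializes a `fit_result` -- subject metadata, all nine run records, the
#' selected best parameter set with frequencies and success criteria, and
#' the configuration echo -- to a self-contained JSON document, and reads
#' it back. The component breakdown per run makes the selection auditable
#' with standard tooling.
#'
#' @param fit A `fit_result` from [fit_subject()].
#' @param path Output file path.
#' @return `write_result_json()` invisibly returns `path`;
#'   `read_result_json()` returns a `fit_result`-shaped list (without the
#'   model trajectory samples, which are recomputable from the parameters).
#' @export
write_result_json <- function(fit, path) {
  stopifnot(inherits(fit, "fit_result"))
  runs <- lapply(fit$runs, function(r) {
    list(algorithm = r$algorithm, cost = r$cost,
         Ql = r$fit$Ql, Qr = r$fit$Qr, Ps_cmH2O = r$fit$Ps,
         cost_value = r$cost_value, gamma = r$gamma, evals = r$evals,
         seed = r$seed, converged = r$converged)
  })
  b <- fit$best
  doc <- list(
    software = list(package = "glottofit",
                    version = as.character(utils::packageVersion("glottofit"))),
    subject = fit$subject,
    seed = fit$seed,
    config = fit$config[c("profile", "budget", "algorithms", "costs",
                          "n_pso_starts", "total_ms", "transient_ms", "dt")],
    space = list(lower = as.list(fit$space$lower),
                 upper = as.list(fit$space$upper)),
    runs = runs,
    selected = list(
      run = b$run, algorithm = b$algorithm, cost = b$cost,
      Ql = b$fit$Ql, Qr = b$fit$Qr, Ps_cmH2O = b$fit$Ps,
      gamma = b$gamma, Qlr = b$Qlr,
      f_Ml = b$f_Ml, f_Mr = b$f_Mr, f_El = b$f_El, f_Er = b$f_Er,
      success = list(frequency = b$success$frequency_ok,
                     closure = b$success$closure_ok,
                     amplitude = b$success$amplitude_ok,
                     overall = b$success$overall)))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_result_json
#' @export
read_result_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  for (f in c("runs", "selected"))
    if (is.null(doc[[f]]))
      stop("not a fit-result JSON: missing '", f, "'", call. = FALSE)
  doc
}
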