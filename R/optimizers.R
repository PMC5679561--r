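# Run expr with a temporarily seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(),
                       inherits = FALSE))
              rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

#' Search space for the inverse problem
#'
#' Box bounds and initial-search grid steps for (Ql, Qr, Ps). The defaults
#' cover the parameter ranges observed when fitting the model to healthy
#' young and elderly adult recordings (Q roughly 0.8-4.9, Ps roughly
#' 10-46 cmH2O) with margin on both ends.
#'
#' @param Ql,Qr Length-2 bounds for the scaling factors (dimensionless).
#' @param Ps Length-2 bounds for subglottal pressure (cmH2O).
#' @param Q_step,Ps_step Grid steps of the initial value search.
#' @return Object of class `search_space`.
#' @export
search_space <- function(Ql = c(0.5, 6), Qr = c(0.5, 6), Ps = c(5, 50),
                         Q_step = 0.5, Ps_step = 5) {
  for (b in list(Ql, Qr, Ps))
    if (length(b) != 2 || b[1] >= b[2])
      stop("bounds must be length-2 with lower < upper", call. = FALSE)
  structure(list(lower = c(Ql = Ql[1], Qr = Qr[1], Ps = Ps[1]),
                 upper = c(Ql = Ql[2], Qr = Qr[2], Ps = Ps[2]),
                 Q_step = Q_step, Ps_step = Ps_step),
            class = "search_space")
}

#' Initial value search on a regular grid
#'
#' Evaluates the objective on a regular (Ql, Qr, Ps) grid and returns the
#' grid points ranked by objective value. The best points seed the
#' deterministic optimizers (Nelder-Mead start; injected particles for the
#' particle swarm); the bee colony starts from random sources instead.
#'
#' @param objective Function of a numeric triple `c(Ql, Qr, Ps)`.
#' @param space A [search_space()].
#' @return `data.frame` with columns Ql, Qr, Ps, value, sorted ascending by
#'   value (non-finite values last).
#' @export
initial_grid_search <- function(objective, space) {
  stopifnot(inherits(space, "search_space"))
  grid <- expand.grid(
    Ql = seq(space$lower["Ql"], space$upper["Ql"], by = space$Q_step),
    Qr = seq(space$lower["Qr"], space$upper["Qr"], by = space$Q_step),
    Ps = seq(space$lower["Ps"], space$upper["Ps"], by = space$Ps_step))
  grid$value <- apply(grid, 1, function(p) objective(as.numeric(p)))
  if (!any(is.finite(grid$value)))
    stop("initial search failed: no finite objective value on the grid",
         call. = FALSE)
  grid[order(grid$value), , drop = FALSE]
}

#' Fine sweep along the symmetric axis
#'
#' Supplementary initial search evaluating the objective on symmetric
#' parameter sets (Ql = Qr = Q) over a fine Q grid crossed with the Ps
#' grid. Because the model's fundamental frequency is monotone in the
#' common scaling factor Q, this cheap one-dimensional sweep locates the
#' narrow frequency-matching region that a coarse three-dimensional grid
#' steps over: matching the fundamental within the spectral resolution of
#' a 100 ms window (10 Hz) requires Q within about 0.05, far below any
#' affordable 3-D grid step.
#'
#' @inheritParams initial_grid_search
#' @param Q_step Fine step for the common scaling factor (default 0.05).
#' @param Ps_step Step for the subglottal pressure grid (defaults to the
#'   space's Ps grid step).
#' @return `data.frame` with columns Ql, Qr, Ps, value, sorted ascending.
#' @export
symmetric_axis_search <- function(objective, space, Q_step = 0.05,
                                  Ps_step = space$Ps_step) {
  stopifnot(inherits(space, "search_space"))
  grid <- expand.grid(
    Q = seq(space$lower["Ql"], space$upper["Ql"], by = Q_step),
    Ps = seq(space$lower["Ps"], space$upper["Ps"], by = Ps_step))
  value <- mapply(function(q, ps) objective(c(q, q, ps)), grid$Q, grid$Ps)
  out <- data.frame(Ql = grid$Q, Qr = grid$Q, Ps = grid$Ps, value = value)
  out[order(out$value), , drop = FALSE]
}

#' Asymmetry fan around the best symmetric candidates
#'
#' Coupled left-right oscillators lock to a common frequency governed
#' mainly by the geometric mean of the two scaling factors, so a symmetric
#' candidate (Q, Q, Ps) can be split into (Q s, Q / s, Ps) without leaving
#' the frequency-matching region. This supplementary search evaluates such
#' splits (both assignments) for a range of split factors around the top
#' symmetric candidates, giving the local optimizers asymmetric starting
#' points for subjects with marked left-right asymmetry.
#'
#' @inheritParams initial_grid_search
#' @param sweep Ranked output of [symmetric_axis_search()].
#' @param n_top Number of top symmetric candidates to fan out.
#' @param splits Split factors s > 1 to apply.
#' @return `data.frame` with columns Ql, Qr, Ps, value, sorted ascending.
#' @export
asymmetry_fan <- function(objective, space, sweep, n_top = 10,
                          splits = c(1.05, 1.1, 1.15, 1.2)) {
  stopifnot(inherits(space, "search_space"))
  top <- utils::head(sweep, n_top)
  rows <- list()
  for (i in seq_len(nrow(top))) {
    q <- top$Ql[i]; ps <- top$Ps[i]
    for (s in splits) {
      for (pair in list(c(q * s, q / s), c(q / s, q * s))) {
        p <- pmin(pmax(c(pair, ps), space$lower), space$upper)
        rows[[length(rows) + 1]] <-
          data.frame(Ql = p[1], Qr = p[2], Ps = p[3],
                     value = objective(p))
      }
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$value), , drop = FALSE]
}

# Penalized objective: out-of-bounds points are evaluated at their
# projection onto the box, plus a quadratic penalty on the (range-scaled)
# violation, so simplex/swarm steps outside the box are pushed back in.
penalized <- function(objective, lower, upper, weight = 1e4) {
  rng <- upper - lower
  function(p) {
    q <- pmin(pmax(p, lower), upper)
    objective(q) + weight * sum(((p - q) / rng)^2)
  }
}

opt_result <- function(par, value, evals, converged) {
  list(par = par, value = value, evals = evals, converged = converged)
}

#' Nelder-Mead simplex optimization
#'
#' Standard simplex method (reflection 1, expansion 2, contraction 0.5,
#' shrink 0.5) on the box-penalized objective, with periodic restarts from
#' the incumbent. Deterministic given the start point. Terminates when the
#' simplex value spread or size falls below the tolerances, or when the
#' evaluation budget is exhausted (the incumbent is returned and flagged
#' non-converged).
#'
#' @param objective Function of a numeric triple.
#' @param start Numeric start vector inside the bounds.
#' @param lower,upper Box bounds.
#' @param budget Maximum objective evaluations.
#' @param tol_f,tol_x Value-spread and simplex-size tolerances.
#' @param step Initial simplex step as a fraction of each bound range
#'   (scalar or one value per dimension).
#' @param stage_evals Evaluations per restart stage: after each
#'   `stage_evals` evaluations the simplex is rebuilt around the incumbent
#'   with a halved initial step, which prevents simplex collapse in narrow
#'   curved valleys. Stage boundaries depend only on the evaluation count,
#'   so a larger budget extends (never alters) the search sequence.
#' @return List with `par`, `value`, `evals`, `converged`.
#' @export
nelder_mead <- function(objective, start, lower, upper, budget = 2000,
                        tol_f = 1e-10, tol_x = 1e-8, step = 0.05,
                        stage_evals = 100) {
  n <- length(start)
  evals <- 0L
  fpen <- penalized(objective, lower, upper)
  f <- function(p) { evals <<- evals + 1L; fpen(p) }

  step <- rep(step, length.out = n)
  new_simplex <- function(at, st) {
    sx <- matrix(rep(at, n + 1), nrow = n + 1, byrow = TRUE)
    for (i in seq_len(n))
      sx[i + 1, i] <- sx[i + 1, i] + st[i] * (upper[i] - lower[i])
    sx
  }
  simplex <- new_simplex(start, step)
  fv <- apply(simplex, 1, f)

  # Restart stages: every `stage_evals` evaluations the simplex is rebuilt
  # around the incumbent with a smaller initial step. In narrow curved
  # valleys (the frequency-matching ridge of the inverse problem) a single
  # simplex collapses and stalls; periodic restarts recover progress. The
  # stage boundaries depend only on the evaluation count, never on the
  # budget, so truncating the budget truncates the same search sequence.
  stage <- 1L
  converged <- FALSE
  while (evals < budget) {
    if (evals >= stage * stage_evals) {
      stage <- stage + 1L
      best <- which.min(fv)
      simplex <- new_simplex(simplex[best, ],
                             pmax(step / 2^(stage - 1), 0.002))
      fv <- apply(simplex, 1, function(p) if (evals < budget) f(p) else Inf)
      next
    }
    ord <- order(fv)
    simplex <- simplex[ord, , drop = FALSE]
    fv <- fv[ord]
    size <- max(apply(simplex[-1, , drop = FALSE], 1,
                      function(v) max(abs(v - simplex[1, ]))))
    if (fv[n + 1] - fv[1] <= tol_f * (abs(fv[1]) + tol_f) || size <= tol_x) {
      converged <- TRUE
      break
    }
    centroid <- colMeans(simplex[-(n + 1), , drop = FALSE])
    worst <- simplex[n + 1, ]
    xr <- centroid + (centroid - worst)        # reflection
    fr <- f(xr)
    if (fr < fv[1]) {
      xe <- centroid + 2 * (centroid - worst)  # expansion
      fe <- if (evals < budget) f(xe) else Inf
      if (fe < fr) { simplex[n + 1, ] <- xe; fv[n + 1] <- fe }
      else { simplex[n + 1, ] <- xr; fv[n + 1] <- fr }
    } else if (fr < fv[n]) {
      simplex[n + 1, ] <- xr; fv[n + 1] <- fr
    } else {
      xc <- centroid + 0.5 * ((if (fr < fv[n + 1]) xr else worst) - centroid)
      fc <- if (evals < budget) f(xc) else Inf
      if (fc < min(fr, fv[n + 1])) {
        simplex[n + 1, ] <- xc; fv[n + 1] <- fc
      } else {                                  # shrink toward the best
        for (i in 2:(n + 1)) {
          simplex[i, ] <- simplex[1, ] + 0.5 * (simplex[i, ] - simplex[1, ])
          fv[i] <- if (evals < budget) f(simplex[i, ]) else Inf
        }
      }
    }
  }
  best <- which.min(fv)
  par <- pmin(pmax(simplex[best, ], lower), upper)
  opt_result(par, fv[best], evals, converged)
}

#' Particle swarm optimization
#'
#' Global-best particle swarm with inertia 0.72 and cognitive = social
#' acceleration 1.49, velocities clamped to half the bound range per
#' dimension and positions reflected at the bounds. Seeded and fully
#' reproducible; optionally a set of good starting points (from the initial
#' grid search) is injected into the initial swarm.
#'
#' @inheritParams nelder_mead
#' @param space A [search_space()].
#' @param seed Integer seed.
#' @param n_particles Swarm size.
#' @param inertia,accel Velocity update coefficients.
#' @param init_points Optional matrix (rows = points) injected as initial
#'   particle positions.
#' @return List with `par`, `value`, `evals`, `converged`.
#' @export
particle_swarm <- function(objective, space, seed, budget = 2000,
                           n_particles = 30, inertia = 0.72, accel = 1.49,
                           init_points = NULL) {
  stopifnot(inherits(space, "search_space"))
  lower <- space$lower; upper <- space$upper
  rng <- upper - lower
  n <- length(lower)
  vmax <- rng / 2
  with_seed(seed, {
    pos <- matrix(runif(n_particles * n, lower, upper),
                  nrow = n_particles, byrow = TRUE)
    if (!is.null(init_points)) {
      k <- min(nrow(init_points), n_particles)
      pos[seq_len(k), ] <- init_points[seq_len(k), , drop = FALSE]
    }
    vel <- matrix(runif(n_particles * n, -vmax, vmax),
                  nrow = n_particles, byrow = TRUE) / 2
    evals <- 0L
    fval <- rep(Inf, n_particles)
    for (i in seq_len(n_particles)) {
      if (evals >= budget) break
      fval[i] <- objective(pos[i, ]); evals <- evals + 1L
    }
    pbest <- pos; pbest_f <- fval
    g <- which.min(pbest_f)
    gbest <- pbest[g, ]; gbest_f <- pbest_f[g]

    while (evals < budget) {
      for (i in seq_len(n_particles)) {
        if (evals >= budget) break
        r1 <- runif(n); r2 <- runif(n)
        vel[i, ] <- inertia * vel[i, ] +
          accel * r1 * (pbest[i, ] - pos[i, ]) +
          accel * r2 * (gbest - pos[i, ])
        vel[i, ] <- pmin(pmax(vel[i, ], -vmax), vmax)
        p <- pos[i, ] + vel[i, ]
        below <- p < lower; above <- p > upper
        p[below] <- pmin(2 * lower[below] - p[below], upper[below])
        p[above] <- pmax(2 * upper[above] - p[above], lower[above])
        p <- pmin(pmax(p, lower), upper)
        vel[i, below | above] <- -vel[i, below | above]
        pos[i, ] <- p
        fi <- objective(p); evals <- evals + 1L
        if (fi < pbest_f[i]) { pbest[i, ] <- p; pbest_f[i] <- fi }
        if (fi < gbest_f) { gbest <- p; gbest_f <- fi }
      }
    }
    opt_result(gbest, gbest_f, evals, evals <= budget)
  })
}

#' Bee colony optimization
#'
#' Artificial bee colony search: employed bees perturb one dimension of
#' their food source toward/away from a random partner; onlooker bees
#' re-sample sources with probability proportional to fitness; sources that
#' fail to improve for `limit` trials are abandoned and re-scouted uniformly
#' at random. No initial grid injection: the colony starts from random
#' sources. Seeded and fully reproducible.
#'
#' @inheritParams particle_swarm
#' @param n_sources Number of food sources.
#' @param limit Abandonment limit (failed trials before scouting).
#' @return List with `par`, `value`, `evals`, `converged`.
#' @export
bee_colony <- function(objective, space, seed, budget = 2000,
                       n_sources = 30, limit = 20) {
  stopifnot(inherits(space, "search_space"))
  lower <- space$lower; upper <- space$upper
  n <- length(lower)
  with_seed(seed, {
    pos <- matrix(runif(n_sources * n, lower, upper),
                  nrow = n_sources, byrow = TRUE)
    evals <- 0L
    fval <- rep(Inf, n_sources)
    for (i in seq_len(n_sources)) {
      if (evals >= budget) break
      fval[i] <- objective(pos[i, ]); evals <- evals + 1L
    }
    trial <- integer(n_sources)
    g <- which.min(fval)
    gbest <- pos[g, ]; gbest_f <- fval[g]

    probe <- function(i) {
      j <- sample.int(n, 1)
      k <- sample.int(n_sources - 1, 1)
      if (k >= i) k <- k + 1
      v <- pos[i, ]
      v[j] <- v[j] + runif(1, -1, 1) * (pos[i, j] - pos[k, j])
      pmin(pmax(v, lower), upper)
    }

    while (evals < budget) {
      for (i in seq_len(n_sources)) {        # employed phase
        if (evals >= budget) break
        v <- probe(i)
        fv <- objective(v); evals <- evals + 1L
        if (fv < fval[i]) { pos[i, ] <- v; fval[i] <- fv; trial[i] <- 0L }
        else trial[i] <- trial[i] + 1L
        if (fv < gbest_f) { gbest <- v; gbest_f <- fv }
      }
      fit <- ifelse(fval >= 0, 1 / (1 + fval), 1 + abs(fval))
      prob <- fit / sum(fit)
      for (b in seq_len(n_sources)) {        # onlooker phase
        if (evals >= budget) break
        i <- sample.int(n_sources, 1, prob = prob)
        v <- probe(i)
        fv <- objective(v); evals <- evals + 1L
        if (fv < fval[i]) { pos[i, ] <- v; fval[i] <- fv; trial[i] <- 0L }
        else trial[i] <- trial[i] + 1L
        if (fv < gbest_f) { gbest <- v; gbest_f <- fv }
      }
      for (i in seq_len(n_sources)) {        # scout phase
        if (evals >= budget) break
        if (trial[i] > limit) {
          pos[i, ] <- runif(n, lower, upper)
          fval[i] <- objective(pos[i, ]); evals <- evals + 1L
          trial[i] <- 0L
          if (fval[i] < gbest_f) { gbest <- pos[i, ]; gbest_f <- fval[i] }
        }
      }
    }
    opt_result(gbest, gbest_f, evals, evals <= budget)
  })
}
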