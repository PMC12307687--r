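#' Find equilibria at fixed conserved quantities
#'
#' Solves `0 = nu r(x)` under `t(D) x = eta` by damped Newton iteration in
#' the full state, using the analytic rate Jacobian, from `n_starts` random
#' positive initializations. Solutions are deduplicated and annotated with
#' their loop flux coefficients (`r(x) = C mu`) and a stability verdict from
#' the reduced-Jacobian spectrum.
#'
#' @param model a `kinetic_model`.
#' @param eta conserved values (length Q; `numeric(0)` when Q = 0).
#' @param n_starts number of random starts.
#' @param seed RNG seed (deterministic result for fixed seed).
#' @param tol residual tolerance on `||H||_inf`.
#' @param x_scale typical concentration used to scale random starts.
#' @return List of equilibrium points: `x`, `eta`, `mu`, `stability`
#'   (`"stable"`/`"unstable"`), `eigenvalues`, `residual`. Empty if no root
#'   found.
#' @export
find_equilibria <- function(model, eta = numeric(0), n_starts = 24L, seed = 0L,
                            tol = 1e-10, x_scale = NULL, x_seeds = list()) {
  nu <- model$nu
  V <- image_basis(nu)
  D <- cokernel_basis(nu)
  C <- kernel_basis(nu)
  Q <- ncol(D)
  if (length(eta) != Q) stop(sprintf("eta must have length %d", Q))
  Vdag <- pseudo_inverse(V)
  Dt <- t(D)
  base <- if (Q > 0) as.numeric(t(pseudo_inverse(D)) %*% eta) else
    rep(0, nrow(nu))
  if (is.null(x_scale)) {
    x_scale <- if (Q > 0) max(mean(abs(eta)), 0.5) else 1
  }
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  # starts: user seeds first, then conservation-respecting random points
  # (equal-split baseline displaced along the stoichiometric subspace, which
  # reaches the corners of each conservation simplex)
  starts <- lapply(x_seeds, function(s) pmax(as.numeric(s), 1e-3 * x_scale))
  for (trial in seq_len(n_starts)) {
    x0 <- if (trial %% 2 == 1L || ncol(V) == 0) {
      pmax(base, 0) + stats::runif(nrow(nu), 0.02, 1) * x_scale
    } else {
      pmax(pmax(base, 0.1 * x_scale) +
             as.numeric(V %*% stats::rnorm(ncol(V))) * x_scale,
           0.02 * x_scale)
    }
    starts[[length(starts) + 1L]] <- x0
  }
  sols <- list()
  for (x0 in starts) {
    x <- .newton_equilibrium(model, x0, eta, Vdag, Dt, tol)
    if (is.null(x)) next
    dup <- any(vapply(sols, function(s) {
      max(abs(s$x - x)) < 1e-6 * (1 + max(abs(x)))
    }, logical(1)))
    if (dup) next
    jac <- evaluate_jacobians(model, x, V = V)
    ev <- eigen(jac$Jg, only.values = TRUE)$values
    r <- rate_values(model, x)
    mu <- if (ncol(C) > 0) as.numeric(solve(crossprod(C), t(C) %*% r)) else
      numeric(0)
    sols[[length(sols) + 1L]] <- list(
      x = stats::setNames(x, model$net$species$id),
      eta = if (Q > 0) as.numeric(Dt %*% x) else numeric(0),
      mu = mu,
      stability = if (max(Re(ev)) < 0) "stable" else "unstable",
      eigenvalues = ev,
      residual = max(abs(nu %*% r))
    )
  }
  ord <- order(vapply(sols, function(s) s$x[[1]], numeric(1)))
  sols[ord]
}

.newton_equilibrium <- function(model, x0, eta, Vdag, Dt, tol,
                                max_iter = 60L) {
  x <- x0
  Hfun <- function(x) {
    r <- rate_values(model, x)
    c(as.numeric(Vdag %*% (model$nu %*% r)),
      if (nrow(Dt) > 0) as.numeric(Dt %*% x - eta))
  }
  H <- Hfun(x)
  for (it in seq_len(max_iter)) {
    if (max(abs(H)) < tol) {
      if (any(x < 0)) return(NULL)  # boundary equilibria (zeros) are kept
      return(x)
    }
    drdx <- rate_jacobian(model, x)
    J <- rbind(Vdag %*% (model$nu %*% drdx), Dt)
    step <- tryCatch(solve(J, -H), error = function(e) NULL)
    if (is.null(step)) return(NULL)
    alpha <- 1
    ok <- FALSE
    while (alpha > 1e-6) {
      xn <- x + alpha * step
      if (all(xn > -1e-12)) {
        xn <- pmax(xn, 0)
        Hn <- Hfun(xn)
        if (max(abs(Hn)) < (1 - 1e-4 * alpha) * max(abs(H))) { ok <- TRUE; break }
      }
      alpha <- alpha / 2
    }
    if (!ok) return(NULL)  # line search stalled: start did not converge
    x <- xn
    H <- Hn
  }
  NULL
}

.save_seed <- function() {
  if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
}

.restore_seed <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
}

#' Integrate the concentration ODE
#'
#' Adaptive Cash-Karp Runge-Kutta integration of `dx/dt = nu r(x)`.
#' Conserved quantities are preserved to integrator tolerance.
#'
#' @param model a `kinetic_model`.
#' @param x0 initial state.
#' @param t_end final time.
#' @param rtol,atol local error tolerances.
#' @return List `x` (final state), `ok` (logical), `steps`.
#' @export
integrate_ode <- function(model, x0, t_end, rtol = 1e-7, atol = 1e-9) {
  f <- function(x) as.numeric(model$nu %*% rate_values(model, pmax(x, 0)))
  a <- c(0.2, 0.3, 0.6, 1, 0.875)
  b <- list(
    c(0.2),
    c(3 / 40, 9 / 40),
    c(0.3, -0.9, 1.2),
    c(-11 / 54, 2.5, -70 / 27, 35 / 27),
    c(1631 / 55296, 175 / 512, 575 / 13824, 44275 / 110592, 253 / 4096))
  c5 <- c(37 / 378, 0, 250 / 621, 125 / 594, 0, 512 / 1771)
  c4 <- c(2825 / 27648, 0, 18575 / 48384, 13525 / 55296, 277 / 14336, 0.25)
  t <- 0; x <- as.numeric(x0); h <- t_end / 100
  steps <- 0L
  while (t < t_end) {
    if (steps > 100000L) return(list(x = x, ok = FALSE, steps = steps))
    h <- min(h, t_end - t)
    k <- list(f(x))
    for (i in 1:5) {
      xi <- x
      for (j in seq_len(i)) xi <- xi + h * b[[i]][[j]] * k[[j]]
      k[[i + 1]] <- f(xi)
    }
    x5 <- x; x4 <- x
    for (i in 1:6) {
      x5 <- x5 + h * c5[[i]] * k[[i]]
      x4 <- x4 + h * c4[[i]] * k[[i]]
    }
    err <- max(abs(x5 - x4) / (atol + rtol * pmax(abs(x), abs(x5))))
    if (is.na(err) || !is.finite(err)) return(list(x = x, ok = FALSE, steps = steps))
    if (err <= 1) {
      t <- t + h
      x <- x5
    }
    h <- h * min(5, max(0.1, 0.9 * (1 / max(err, 1e-10))^0.2))
    steps <- steps + 1L
  }
  list(x = x, ok = TRUE, steps = steps)
}

#' Stability by randomized conserved perturbations
#'
#' Perturbs an equilibrium along the stoichiometric subspace (so conserved
#' quantities are unchanged), integrates forward, and reports `"stable"` iff
#' the state returns in every trial. Agrees with the reduced-Jacobian
#' eigenvalue test on hyperbolic equilibria.
#'
#' @param model a `kinetic_model`.
#' @param point equilibrium point (from [find_equilibria()]) or a state
#'   vector.
#' @param eps perturbation magnitude (relative to state norm).
#' @param n_trials number of random perturbation directions.
#' @param seed RNG seed.
#' @param t_end integration horizon.
#' @return `"stable"` or `"unstable"`; attribute `distances` holds final
#'   distances per trial.
#' @export
perturbation_stability <- function(model, point, eps = 0.02, n_trials = 4L,
                                   seed = 0L, t_end = 400) {
  xbar <- if (is.list(point)) point$x else point
  V <- image_basis(model$nu)
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  scale <- eps * (1 + max(abs(xbar)))
  dists <- numeric(0)
  for (i in seq_len(n_trials)) {
    z <- stats::rnorm(ncol(V))
    dx <- as.numeric(V %*% z)
    dx <- dx / max(abs(dx)) * scale
    x0 <- pmax(as.numeric(xbar) + dx, 1e-9)
    res <- integrate_ode(model, x0, t_end)
    if (!res$ok) {
      warning("integration failure in a perturbation trial; trial excluded")
      next
    }
    dists <- c(dists, max(abs(res$x - xbar)))
  }
  verdict <- if (length(dists) > 0 && all(dists < 0.25 * scale)) "stable"
             else "unstable"
  attr(verdict, "distances") <- dists
  verdict
}

.apply_sweep_param <- function(model, param, value) {
  if (param$type == "rate") {
    set_law_param(model, param$reaction, param$name, value)
  } else {
    model  # eta sweeps pass the value through find_equilibria
  }
}

#' Bifurcation diagram over a swept parameter
#'
#' Sweeps either a rate-law parameter (`param = list(type = "rate",
#' reaction =, name =)`) or a conserved-quantity value (`param = list(type =
#' "eta", index =)`) over a grid, collects equilibria at each grid point,
#' assembles branches by nearest-neighbor continuation, and brackets branch
#' birth/death thresholds by bisection.
#'
#' @param model a `kinetic_model`.
#' @param param swept parameter spec (see above).
#' @param range length-2 numeric range.
#' @param n_grid number of grid points.
#' @param eta baseline conserved values (the swept component is overridden
#'   for eta sweeps).
#' @param n_starts,seed passed to [find_equilibria()].
#' @param threshold_tol bisection precision on the parameter.
#' @return Object of class `sba_diagram`: `points` data frame (`param`,
#'   `branch`, `stability`, one column per species), `thresholds` (numeric
#'   vector of branch birth/death parameter values), `param`, `range`.
#' @export
sweep_diagram <- function(model, param, range, n_grid = 50L,
                          eta = numeric(0), n_starts = 16L, seed = 0L,
                          threshold_tol = 1e-3) {
  grid <- seq(range[[1]], range[[2]], length.out = n_grid)
  eqs_at <- function(p, starts = n_starts, sd = seed, x_seeds = list()) {
    m <- .apply_sweep_param(model, param, p)
    e <- eta
    if (param$type == "eta") e[[param$index]] <- p
    find_equilibria(m, e, n_starts = starts, seed = sd, x_seeds = x_seeds)
  }
  # warm-started march across the grid: every grid point retries from the
  # previous point's equilibria in addition to its random starts
  all_eqs <- vector("list", n_grid)
  for (gi in seq_along(grid)) {
    seeds_prev <- if (gi > 1) lapply(all_eqs[[gi - 1]], `[[`, "x") else list()
    all_eqs[[gi]] <- eqs_at(grid[[gi]], x_seeds = seeds_prev)
  }
  sid <- model$net$species$id
  # jump tolerance: half the median distance between coexisting equilibria
  # (fallback: a quarter of the typical state norm)
  seps <- unlist(lapply(all_eqs, function(eqs) {
    if (length(eqs) < 2) return(NULL)
    xs <- do.call(rbind, lapply(eqs, `[[`, "x"))
    as.numeric(stats::dist(xs))
  }))
  typical <- mean(unlist(lapply(all_eqs, function(eqs) {
    vapply(eqs, function(e) sqrt(sum(e$x^2)), numeric(1))
  })), na.rm = TRUE)
  jump_tol <- if (length(seps) > 0) 0.5 * stats::median(seps)
              else 0.25 * (1 + typical)
  # branch assembly: nearest-neighbor continuation with the jump tolerance
  branches <- list()   # each: list(rows = list of (param, eq)), open flag
  rows <- list()
  for (gi in seq_along(grid)) {
    eqs <- all_eqs[[gi]]
    open_idx <- which(vapply(branches, function(b) b$open, logical(1)))
    used <- rep(FALSE, length(eqs))
    # match open branches to nearest new point
    for (bi in open_idx) {
      tail_x <- branches[[bi]]$tail
      if (length(eqs) == 0) { branches[[bi]]$open <- FALSE; next }
      d <- vapply(eqs, function(e) sqrt(sum((e$x - tail_x)^2)), numeric(1))
      d[used] <- Inf
      j <- which.min(d)
      if (is.finite(d[[j]]) && d[[j]] < jump_tol) {
        used[[j]] <- TRUE
        branches[[bi]]$tail <- eqs[[j]]$x
        branches[[bi]]$last_param <- grid[[gi]]
        rows[[length(rows) + 1L]] <- c(list(param = grid[[gi]],
                                            branch = bi,
                                            stability = eqs[[j]]$stability),
                                       as.list(eqs[[j]]$x))
      } else {
        branches[[bi]]$open <- FALSE
      }
    }
    for (j in which(!used)) {
      branches[[length(branches) + 1L]] <- list(
        open = TRUE, tail = eqs[[j]]$x,
        first_param = grid[[gi]], last_param = grid[[gi]])
      rows[[length(rows) + 1L]] <- c(list(param = grid[[gi]],
                                          branch = length(branches),
                                          stability = eqs[[j]]$stability),
                                     as.list(eqs[[j]]$x))
    }
  }
  pts <- do.call(rbind, lapply(rows, function(r) {
    as.data.frame(r, stringsAsFactors = FALSE)
  }))
  # thresholds: branches that are born after the first or die before the
  # last grid point; bisection on existence of a nearby equilibrium
  thresholds <- numeric(0)
  exists_near <- function(p, xref) {
    eqs <- eqs_at(p, x_seeds = list(xref))
    any(vapply(eqs, function(e) {
      sqrt(sum((e$x - xref)^2)) < jump_tol
    }, logical(1)))
  }
  for (bi in seq_along(branches)) {
    b <- branches[[bi]]
    sub <- pts[pts$branch == bi, , drop = FALSE]
    if (nrow(sub) == 0) next
    xs <- as.matrix(sub[, sid, drop = FALSE])
    if (b$last_param < grid[[n_grid]] - 1e-12) {
      lo <- b$last_param
      hi <- grid[[min(which(grid > b$last_param + 1e-12))]]
      xref <- as.numeric(xs[which.max(sub$param), ])
      while (hi - lo > threshold_tol) {
        mid <- (lo + hi) / 2
        if (exists_near(mid, xref)) lo <- mid else hi <- mid
      }
      thresholds <- c(thresholds, (lo + hi) / 2)
    }
    if (b$first_param > grid[[1]] + 1e-12) {
      hi <- b$first_param
      lo <- grid[[max(which(grid < b$first_param - 1e-12))]]
      xref <- as.numeric(xs[which.min(sub$param), ])
      while (hi - lo > threshold_tol) {
        mid <- (lo + hi) / 2
        if (exists_near(mid, xref)) hi <- mid else lo <- mid
      }
      thresholds <- c(thresholds, (lo + hi) / 2)
    }
  }
  structure(list(points = pts, thresholds = sort(unique(thresholds)),
                 param = param, range = range, seed = seed),
            class = "sba_diagram")
}

#' @export
print.sba_diagram <- function(x, ...) {
  cat(sprintf("sba_diagram: %d points, %d branches over [%g, %g]\n",
              nrow(x$points), length(unique(x$points$branch)),
              x$range[[1]], x$range[[2]]))
  if (length(x$thresholds) > 0) {
    cat(sprintf("  thresholds: %s\n",
                paste(signif(x$thresholds, 6), collapse = ", ")))
  }
  invisible(x)
}

#' Chemicals that actually vary across coexisting branches
#'
#' For every swept-parameter value with at least two coexisting equilibrium
#' branches, measures each chemical's spread across branches; chemicals whose
#' maximal spread exceeds `tol` are the observed bifurcating set.
#'
#' @param diagram an `sba_diagram`.
#' @param tol absolute spread threshold.
#' @return Named numeric vector of maximal spreads (all species).
#' @export
branch_spread <- function(diagram, tol = 1e-3) {
  pts <- diagram$points
  sid <- setdiff(names(pts), c("param", "branch", "stability"))
  spread <- stats::setNames(rep(0, length(sid)), sid)
  for (p in unique(pts$param)) {
    sub <- pts[pts$param == p, sid, drop = FALSE]
    if (nrow(sub) < 2) next
    spread <- pmax(spread, apply(sub, 2, function(v) max(v) - min(v)))
  }
  spread
}

#' Consistency of a diagram with the structural prediction
#'
#' Checks that the set of chemicals varying across coexisting branches is a
#' subset of the bifurcating chemicals predicted by the six-step report.
#'
#' @param diagram an `sba_diagram`.
#' @param report an `sba_report` for the same network.
#' @param tol spread threshold for "varies".
#' @return List: `consistent` (logical), `observed` (chemicals that vary),
#'   `predicted` (union over report conditions), `spread`.
#' @export
predicted_vs_observed <- function(diagram, report, tol = 1e-3) {
  spread <- branch_spread(diagram, tol)
  observed <- names(spread)[spread > tol]
  predicted <- sort(unique(unlist(lapply(report$conditions,
                                         `[[`, "bifurcating_chemicals"))))
  list(consistent = all(observed %in% predicted),
       observed = sort(observed), predicted = predicted, spread = spread)
}
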