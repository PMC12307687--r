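#' Kinetic models on a reaction network
#'
#' Attaches a rate law to every reaction of a network. Supported law kinds
#' (parameters in concentration-consistent units):
#'
#' * `constant`: `r = k` (inflow from the reservoir).
#' * `mass_action`: `r = k * prod(x_reactant^coeff)`.
#' * `mass_action_mod`: mass action times `prod(x_modifier^e)` for annotated
#'   regulators with positive exponents `e`.
#' * `ma_poly`: `r = sum_j coef_j * x_s^pow_j`, a polynomial in one species.
#' * `hill_inhibited`: `r = k * prod(x_reactant^coeff) /
#'   (1 + sum_i a_i * x_i^h_i)`, Hill-type inhibition by annotated negative
#'   regulators.
#' * `hill_activated`: `r = prod(x_reactant) * (k0 + k1 * x_a^h /
#'   (theta^h + x_a^h))`, saturating activation by a positive regulator.
#' * `sigmoid_activated`: `r = k * prod(x_reactant) *
#'   (eps + 1 / (1 + exp(-(x_a - theta) / tau)))`, logistic activation.
#'
#' Every law's dependency set must match the network annotation exactly
#' (reactants plus regulators), so the signed symbol pattern of the
#' structural matrix and the analytic Jacobian always agree.
#'
#' @param net a `reaction_network`.
#' @param laws named list (by reaction id) of `list(kind = ..., params...)`.
#' @return Object of class `kinetic_model`.
#' @export
kinetic_model <- function(net, laws) {
  rid <- vapply(net$reactions, `[[`, character(1), "id")
  missing <- setdiff(rid, names(laws))
  if (length(missing) > 0) {
    stop(sprintf("no rate law for reaction '%s'", missing[[1]]))
  }
  sg <- rate_dependency_signs(net)
  for (id in rid) {
    law <- laws[[id]]
    deps <- .law_dependencies(law, net, id)
    want <- colnames(sg)[sg[id, ] != 0 | is.na(sg[id, ])]
    if (!setequal(deps, want)) {
      stop(sprintf("law for '%s' depends on {%s} but network declares {%s}",
                   id, paste(deps, collapse = ","), paste(want, collapse = ",")))
    }
  }
  structure(list(net = net, laws = laws,
                 nu = stoichiometric_matrix(net)),
            class = "kinetic_model")
}

.law_dependencies <- function(law, net, id) {
  r <- net$reactions[[match(id, vapply(net$reactions, `[[`, character(1), "id"))]]
  switch(law$kind,
    constant = character(0),
    mass_action = names(r$reactants),
    mass_action_mod = c(names(r$reactants), names(law$modifiers)),
    ma_poly = law$species,
    hill_inhibited = c(names(r$reactants), law$inhibitors$species),
    hill_activated = c(names(r$reactants), law$activator),
    sigmoid_activated = c(names(r$reactants), law$activator),
    stop(sprintf("unknown rate-law kind '%s'", law$kind))
  )
}

#' Rate vector and analytic rate Jacobian
#'
#' @param model a `kinetic_model`.
#' @param x positive concentration vector (named or in species order).
#' @return `rate_values()`: length-N vector; `rate_jacobian()`: N x M matrix
#'   of partial derivatives of rates with respect to concentrations.
#' @export
rate_values <- function(model, x) {
  x <- .as_state(model, x)
  stats::setNames(
    vapply(model$net$reactions, function(r) {
      .law_eval(model$laws[[r$id]], r, x)$value
    }, numeric(1)),
    vapply(model$net$reactions, `[[`, character(1), "id"))
}

#' @rdname rate_values
#' @export
rate_jacobian <- function(model, x) {
  x <- .as_state(model, x)
  sid <- model$net$species$id
  out <- matrix(0, nrow = length(model$net$reactions), ncol = length(sid),
                dimnames = list(vapply(model$net$reactions, `[[`,
                                       character(1), "id"), sid))
  for (r in model$net$reactions) {
    g <- .law_eval(model$laws[[r$id]], r, x)$grad
    if (length(g) > 0) out[r$id, names(g)] <- g
  }
  out
}

.as_state <- function(model, x) {
  sid <- model$net$species$id
  if (!is.null(names(x))) x <- x[sid]
  if (length(x) != length(sid) || anyNA(x)) {
    stop("state vector does not match species")
  }
  stats::setNames(as.numeric(x), sid)
}

# value and gradient (named, only over dependencies) of one rate law
.law_eval <- function(law, r, x) {
  pow_prod <- function(expo) {
    # value and gradient of prod(x^expo), safe on the orthant boundary
    xs <- x[names(expo)]
    v <- prod(xs^expo)
    g <- vapply(seq_along(expo), function(i) {
      expo[[i]] * xs[[i]]^(expo[[i]] - 1) * prod(xs[-i]^expo[-i])
    }, numeric(1))
    list(v = v, g = stats::setNames(g, names(expo)))
  }
  prod_reac <- function() {
    if (length(r$reactants) == 0) return(list(v = 1, g = numeric(0)))
    pow_prod(r$reactants)
  }
  switch(law$kind,
    constant = list(value = law$k, grad = numeric(0)),
    mass_action = {
      pr <- prod_reac()
      list(value = law$k * pr$v, grad = law$k * pr$g)
    },
    mass_action_mod = {
      pr <- prod_reac()
      mod <- pow_prod(law$modifiers)
      list(value = law$k * pr$v * mod$v,
           grad = c(law$k * mod$v * pr$g, law$k * pr$v * mod$g))
    },
    ma_poly = {
      xs <- x[[law$species]]
      v <- sum(law$coef * xs^law$pow)
      dv <- sum(law$coef * law$pow * xs^(law$pow - 1))
      list(value = v, grad = stats::setNames(dv, law$species))
    },
    hill_inhibited = {
      pr <- prod_reac()
      inh <- law$inhibitors
      terms <- inh$a * x[inh$species]^inh$h
      den <- 1 + sum(terms)
      v <- law$k * pr$v / den
      g <- law$k * pr$g / den
      gi <- stats::setNames(
        -law$k * pr$v * inh$a * inh$h * x[inh$species]^(inh$h - 1) / den^2,
        inh$species)
      # an inhibitor can also be a reactant only via combined roles; sum then
      for (s in names(gi)) {
        if (s %in% names(g)) g[[s]] <- g[[s]] + gi[[s]] else g[[s]] <- gi[[s]]
      }
      list(value = v, grad = g)
    },
    hill_activated = {
      pr <- prod_reac()
      xa <- x[[law$activator]]
      hh <- law$h
      act <- xa^hh / (law$theta^hh + xa^hh)
      f <- law$k0 + law$k1 * act
      dact <- hh * law$theta^hh * xa^(hh - 1) / (law$theta^hh + xa^hh)^2
      g <- f * pr$g
      g[[law$activator]] <- sum(g[law$activator], na.rm = TRUE) +
        pr$v * law$k1 * dact
      list(value = pr$v * f, grad = g)
    },
    sigmoid_activated = {
      pr <- prod_reac()
      xa <- x[[law$activator]]
      s <- 1 / (1 + exp(-(xa - law$theta) / law$tau))
      eps <- if (is.null(law$eps)) 0 else law$eps
      f <- eps + s
      ds <- s * (1 - s) / law$tau
      g <- law$k * f * pr$g
      g[[law$activator]] <- sum(g[law$activator], na.rm = TRUE) +
        law$k * pr$v * ds
      list(value = law$k * pr$v * f, grad = g)
    },
    stop(sprintf("unknown rate-law kind '%s'", law$kind))
  )
}

#' Read a kinetics configuration document
#'
#' JSON with one entry per reaction id: `{"kind": ..., params...}` following
#' the schema of [kinetic_model()]. `hill_inhibited` inhibitors are given as
#' parallel arrays `species`, `a`, `h`.
#'
#' @param net the host `reaction_network`.
#' @param path JSON file path (or a JSON string).
#' @return A `kinetic_model`.
#' @export
kinetics_from_config <- function(net, path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  laws <- lapply(doc, function(l) {
    if (!is.null(l$modifiers)) l$modifiers <- unlist(l$modifiers)
    l
  })
  kinetic_model(net, laws)
}

#' Update one rate-law parameter
#'
#' @param model a `kinetic_model`.
#' @param reaction reaction id.
#' @param name parameter name inside the law (e.g. `"k"`, `"tau"`).
#' @param value new value.
#' @return The updated model.
#' @export
set_law_param <- function(model, reaction, name, value) {
  if (is.null(model$laws[[reaction]][[name]])) {
    stop(sprintf("reaction '%s' has no parameter '%s'", reaction, name))
  }
  model$laws[[reaction]][[name]] <- value
  model
}

#' Standard and reduced Jacobians at a state
#'
#' `Jf = nu %*% dr/dx` is the Jacobian of the concentration ODE; with Q > 0
#' conserved quantities it is always singular (`t(D) %*% Jf = 0` exactly).
#' `Jg = pseudo_inverse(V) %*% Jf %*% V` is the Jacobian of the dynamics in
#' reduced coordinates on the stoichiometric subspace, free of the forced
#' zero eigenvalues; its nonzero-sector spectrum equals that of `Jf`.
#'
#' @param model a `kinetic_model`.
#' @param x positive state vector.
#' @param V optional image basis (default [image_basis()] of the model's nu).
#' @return List with `Jf`, `Jg`, `drdx`, `V`.
#' @export
evaluate_jacobians <- function(model, x, V = NULL) {
  x <- .as_state(model, x)
  if (any(x < 0)) stop("domain error: state outside the positive orthant")
  drdx <- rate_jacobian(model, x)
  Jf <- model$nu %*% drdx
  if (is.null(V)) V <- image_basis(model$nu)
  Jg <- pseudo_inverse(V) %*% Jf %*% V
  list(Jf = Jf, Jg = Jg, drdx = drdx, V = V)
}

#' Signed symbol values of a model at a state
#'
#' Maps each structural symbol `r(n,m)` to the analytic partial derivative of
#' the model at `x`, for numeric instantiation of the structural matrix.
#'
#' @param A an `amatrix` built from the model's network.
#' @param model a `kinetic_model`.
#' @param x state vector.
#' @return Named numeric vector keyed by symbol.
#' @export
symbol_values_at <- function(A, model, x) {
  drdx <- rate_jacobian(model, x)
  keys <- names(A$signs)
  vals <- vapply(keys, function(k) {
    m <- regmatches(k, regexec("^r\\((.+),(.+)\\)$", k))[[1]]
    drdx[m[[2]], m[[3]]]
  }, numeric(1))
  stats::setNames(vals, keys)
}

#' Residual of the determinant identity
#'
#' Computes `|det A - det(t(D) D) * det(t(C) C) / det(Lambda) * det Jg|`
#' relative to `max(1, |det A|)` at a state. The identity holds for any
#' choice of bases; with the loop bases of the bundled conserved example the
#' prefactor is exactly 1.
#'
#' @param model a `kinetic_model`.
#' @param x positive state (need not be an equilibrium).
#' @param C,D,V optional bases (defaults: automatic).
#' @return Scalar residual; attributes `detA`, `detJg`, `prefactor`.
#' @export
theorem1_residual <- function(model, x, C = NULL, D = NULL, V = NULL) {
  nu <- model$nu
  if (is.null(C)) C <- kernel_basis(nu)
  if (is.null(D)) D <- cokernel_basis(nu)
  if (is.null(V)) V <- image_basis(nu)
  A <- build_A(model$net, C = C, D = D)
  Anum <- instantiate_A(A, symbol_values_at(A, model, x))
  detA <- det(Anum)
  jac <- evaluate_jacobians(model, x, V = V)
  detJg <- det(jac$Jg)
  lam <- build_lambda(nu, C, D)
  pref <- .gram_det(D) * .gram_det(C) / det_exact(lam)
  res <- abs(detA - pref * detJg) / max(1, abs(detA))
  attr(res, "detA") <- detA
  attr(res, "detJg") <- detJg
  attr(res, "prefactor") <- pref
  res
}

.gram_det <- function(B) {
  if (ncol(B) == 0) return(1)
  det_exact(crossprod(B))
}

#' Instability criterion from the structural determinant
#'
#' At an equilibrium `x`, if `sign(det(Lambda) * det A at x)` differs from
#' `(-1)^(M - L)` — `M` species, `L` independent conserved quantities — the
#' equilibrium cannot be stable. The test is one-sided: agreement does not
#' certify stability. Eigenvalues of the reduced Jacobian are returned for
#' cross-checking.
#'
#' @param model a `kinetic_model`.
#' @param x equilibrium state (checked; tolerance
#'   `||nu r||_inf < tol * (1 + ||r||_inf)`).
#' @param C,D optional bases.
#' @param tol equilibrium tolerance.
#' @return List of class `sba_stability`: `verdict` (`"not_stable"` or
#'   `"possibly_stable"`), `detA`, `detLambda`, `M`, `L`, `eigenvalues`.
#' @export
stability_check <- function(model, x, C = NULL, D = NULL, tol = 1e-9) {
  x <- .as_state(model, x)
  r <- rate_values(model, x)
  resid <- max(abs(model$nu %*% r))
  if (resid >= tol * (1 + max(abs(r)))) {
    stop(sprintf("precondition error: not an equilibrium (residual %.3g)", resid))
  }
  nu <- model$nu
  if (is.null(C)) C <- kernel_basis(nu)
  if (is.null(D)) D <- cokernel_basis(nu)
  A <- build_A(model$net, C = C, D = D)
  Anum <- instantiate_A(A, symbol_values_at(A, model, x))
  detA <- det(Anum)
  detL <- det_exact(build_lambda(nu, C, D))
  M <- nrow(nu); L <- ncol(D)
  jac <- evaluate_jacobians(model, x)
  want <- (-1)^(M - L)
  verdict <- if (sign(detL * detA) != want) "not_stable" else "possibly_stable"
  structure(list(verdict = verdict, detA = detA, detLambda = detL,
                 M = M, L = L, x = x,
                 eigenvalues = eigen(jac$Jg, only.values = TRUE)$values),
            class = "sba_stability")
}
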