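num_grad <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    xp <- x; xm <- x
    xp[i] <- xp[i] + h; xm[i] <- xm[i] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1))
}

test_that("analytic rate Jacobians agree with finite differences for all law kinds", {
  net <- reaction_network(c("A", "B", "C"), list(
    reaction("R1", products = c(A = 1)),
    reaction("R2", reactants = c(A = 1), products = c(B = 1),
             regulators = c(C = "-")),
    reaction("R3", reactants = c(B = 1), products = c(C = 1),
             regulators = c(A = "+")),
    reaction("R4", reactants = c(C = 1), regulators = c(B = "+")),
    reaction("R5", reactants = c(B = 2)),
    reaction("R6", reactants = c(A = 1), regulators = c(B = "+"))
  ))
  model <- kinetic_model(net, list(
    R1 = list(kind = "constant", k = 2),
    R2 = list(kind = "hill_inhibited", k = 1.3,
              inhibitors = list(species = "C", a = 0.7, h = 2)),
    R3 = list(kind = "mass_action_mod", k = 0.8, modifiers = c(A = 1)),
    R4 = list(kind = "sigmoid_activated", k = 1.1, activator = "B",
              theta = 1, tau = 0.4, eps = 0.05),
    R5 = list(kind = "mass_action", k = 0.6),
    R6 = list(kind = "hill_activated", k0 = 0.1, k1 = 2, activator = "B",
              h = 2, theta = 1.5)
  ))
  set.seed(8)
  for (i in 1:5) {
    x <- runif(3, 0.2, 3)
    J <- rate_jacobian(model, x)
    for (n in seq_len(6)) {
      fd <- num_grad(function(xx) rate_values(model, xx)[[n]], x)
      expect_equal(unname(J[n, ]), fd, tolerance = 1e-5)
    }
  }
})

test_that("ma_poly laws differentiate correctly including at the boundary", {
  net <- reaction_network("B", list(
    reaction("R1", products = c(B = 1)),
    reaction("R2", reactants = c(B = 1))
  ))
  model <- kinetic_model(net, list(
    R1 = list(kind = "constant", k = 1),
    R2 = list(kind = "ma_poly", species = "B", coef = c(1, 0.5), pow = c(1, 2))
  ))
  expect_equal(rate_values(model, 2)[["R2"]], 1 * 2 + 0.5 * 4)
  expect_equal(rate_jacobian(model, 2)["R2", "B"], 1 + 0.5 * 2 * 2)
  expect_equal(rate_jacobian(model, 0)["R2", "B"], 1)
  expect_true(all(is.finite(rate_jacobian(model, 0))))
})

test_that("law dependencies must match the network annotation", {
  net <- load_fixture("example1")$network
  laws <- load_fixture("example1")$kinetics$pitchfork$laws
  laws$R2 <- list(kind = "mass_action", k = 1)  # drops the B dependency
  expect_error(kinetic_model(net, laws), "declares")
})

test_that("model partial-derivative signs match the structural annotation", {
  for (nm in c("conserved_example", "macrophage_wt")) {
    model <- fixture_model(nm)
    sg <- sban:::rate_dependency_signs(model$net)
    set.seed(21)
    for (i in 1:10) {
      x <- runif(n_species(model$net), 0.1, 4)
      J <- rate_jacobian(model, x)
      pos <- !is.na(sg) & sg > 0
      neg <- !is.na(sg) & sg < 0
      zer <- !is.na(sg) & sg == 0
      expect_true(all(J[pos] > 0), label = nm)
      expect_true(all(J[neg] < 0), label = nm)
      expect_true(all(J[zer] == 0), label = nm)
    }
  }
})

test_that("conserved rows annihilate the standard Jacobian exactly", {
  for (nm in c("conserved_example", "macrophage_wt")) {
    model <- fixture_model(nm)
    D <- cokernel_basis(model$nu)
    set.seed(31)
    for (i in 1:5) {
      jac <- evaluate_jacobians(model, runif(n_species(model$net), 0.1, 3))
      expect_true(all(t(D) %*% jac$Jf == 0))
    }
  }
})

test_that("the standard Jacobian determinant vanishes identically with conserved quantities", {
  model <- fixture_model("conserved_example")
  set.seed(17)
  for (i in 1:10) {
    jac <- evaluate_jacobians(model, runif(5, 0.1, 5))
    expect_equal(det(jac$Jf), 0, tolerance = 1e-12)
  }
})

test_that("the determinant identity holds with any basis choice", {
  set.seed(19)
  for (nm in c("example1", "conserved_example", "macrophage_wt")) {
    model <- fixture_model(nm)
    M <- n_species(model$net)
    for (i in 1:10) {
      x <- runif(M, 0.1, 3)
      expect_lt(as.numeric(theorem1_residual(model, x)), 1e-8)
    }
  }
})

test_that("the conserved-example prefactor is exactly one with the loop bases", {
  fx <- load_fixture("conserved_example")
  model <- fixture_model("conserved_example")
  res <- theorem1_residual(model, rep(1, 5), C = fx$C, D = fx$D)
  expect_equal(attr(res, "prefactor"), 1)
  expect_lt(as.numeric(res), 1e-10)
  # det A = det Jg exactly in that gauge
  expect_equal(attr(res, "detA"), attr(res, "detJg"), tolerance = 1e-9)
})

test_that("without conserved quantities the identity reduces to det Jf", {
  model <- chain_model()
  nu <- model$nu
  C <- kernel_basis(nu)
  lam <- build_lambda(nu, C, cokernel_basis(nu))
  set.seed(23)
  for (i in 1:5) {
    x <- runif(2, 0.2, 3)
    jac <- evaluate_jacobians(model, x)
    A <- build_A(model$net, C = C)
    detA <- det(instantiate_A(A, symbol_values_at(A, model, x)))
    pref <- det_exact(crossprod(C)) / det_exact(lam)
    expect_equal(detA, pref * det(jac$Jf), tolerance = 1e-10)
  }
})

test_that("det Jg is invariant under a change of image basis", {
  model <- fixture_model("macrophage_wt")
  V <- image_basis(model$nu)
  set.seed(29)
  x <- runif(8, 0.3, 3)
  d0 <- det(evaluate_jacobians(model, x, V = V)$Jg)
  for (i in 1:5) {
    B <- matrix(rnorm(16), 4, 4)
    while (abs(det(B)) < 0.1) B <- matrix(rnorm(16), 4, 4)
    d1 <- det(evaluate_jacobians(model, x, V = V %*% B)$Jg)
    expect_equal(d1, d0, tolerance = 1e-9 * max(1, abs(d0)))
  }
})

test_that("scalar decay network satisfies the stability sign relation", {
  model <- decay_model(k1 = 2, k2 = 1)
  # equilibrium A = k1/k2; stable; M = 1, L = 0 so sign(detL * detA) must be -1
  sc <- stability_check(model, 2)
  expect_equal(sc$verdict, "possibly_stable")
  expect_equal(sign(sc$detLambda * sc$detA), (-1)^(sc$M - sc$L))
  expect_true(all(Re(sc$eigenvalues) < 0))
})

test_that("stability_check rejects non-equilibrium states", {
  model <- decay_model()
  expect_error(stability_check(model, 5), "not an equilibrium")
})

test_that("structural instability verdicts never contradict the eigenvalue test", {
  model <- fixture_model("macrophage_wt")
  eqs <- find_equilibria(model, macrophage_eta(8), n_starts = 20, seed = 2)
  expect_gte(length(eqs), 3L)
  for (e in eqs) {
    sc <- stability_check(model, e$x, tol = 1e-6)
    if (max(Re(e$eigenvalues)) < 0) {
      expect_equal(sc$verdict, "possibly_stable")
    } else {
      expect_equal(sc$verdict, "not_stable")
    }
  }
})

test_that("kinetics configs round-trip through JSON", {
  fx <- load_fixture("conserved_example")
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(fx$kinetics$default$laws, path, auto_unbox = TRUE,
                       digits = NA)
  model <- kinetics_from_config(fx$network, path)
  ref <- fixture_model("conserved_example")
  x <- c(1.2, 0.7, 2, 0.4, 0.9)
  expect_equal(rate_values(model, x), rate_values(ref, x))
})
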