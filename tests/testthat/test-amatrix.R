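# expected nonzero rate-derivative entries of the wild-type polarization
# network, transcribed from its structural matrix: reactant derivatives plus
# the nine regulation arrows
macrophage_symbols <- c(
  "r(R1,S1)", "r(R1,S3p)", "r(R1,S6p)",
  "r(R2,S1p)",
  "r(R3,S1p)", "r(R3,S3)", "r(R3,S3p)", "r(R3,Np)",
  "r(R4,S3p)",
  "r(R5,S1p)", "r(R5,S6)",
  "r(R6,S6p)",
  "r(R7,S3p)", "r(R7,S6p)", "r(R7,N)", "r(R7,Np)",
  "r(R8,Np)"
)

test_that("the wild-type structural matrix has the published pattern", {
  fx <- load_fixture("macrophage_wt")
  A <- build_A(fx$network, C = fx$C, D = fx$D)
  expect_equal(dim(A$sym), c(12L, 12L))
  expect_setequal(A$sym[nzchar(A$sym)], macrophage_symbols)
  # block layout: C top right, t(D) bottom left, empty bottom right
  expect_identical(unname(A$const[1:8, 9:12]), unname(fx$C * 1.0))
  expect_identical(unname(A$const[9:12, 1:8]), unname(t(fx$D) * 1.0))
  expect_true(all(A$const[9:12, 9:12] == 0))
  # regulation arrows are negative, reactant derivatives positive
  expect_equal(unname(A$signs[["r(R7,Np)"]]), -1)
  expect_equal(unname(A$signs[["r(R7,N)"]]), 1)
  expect_equal(sum(A$signs == -1), 9)
})

test_that("deletions zero exactly the stated symbols", {
  fx <- load_fixture("macrophage_wt")
  A <- build_A(fx$network, C = fx$C, D = fx$D)
  Ad <- apply_deletion(A, list(c("R3", "Np"), c("R3", "S1p"), c("R3", "S3p")))
  expect_setequal(Ad$sym[nzchar(Ad$sym)],
                  setdiff(macrophage_symbols,
                          c("r(R3,Np)", "r(R3,S1p)", "r(R3,S3p)")))
  # and equals the mutant fixture's own pattern
  fxd <- load_fixture("macrophage_socs3d")
  Am <- build_A(fxd$network, C = fxd$C, D = fxd$D)
  expect_identical(Ad$sym, Am$sym)
  # idempotent on already-zero entries
  expect_identical(apply_deletion(Ad, list(c("R3", "Np")))$sym, Ad$sym)
  # zeroing a reactant derivative warns
  expect_warning(apply_deletion(A, list(c("R2", "S1p"))), "reactant")
})

test_that("symbolic block determinants reproduce the printed factorizations", {
  ex1 <- load_fixture("example1")
  A1 <- build_A(ex1$network, C = ex1$C, D = ex1$D)
  # the interconversion block: det = r2B - r3B
  gamma <- symbolic_det(A1, rows = c("R2", "R3"), cols = c("B", "loop2"))
  expect_spoly_equal(gamma, make_spoly(list(1, "r(R2,B)"), list(-1, "r(R3,B)")),
                     up_to_sign = TRUE)
  # full determinant factorizes as (r2B - r3B) * r4A
  full <- symbolic_det(A1)
  expect_spoly_equal(full, make_spoly(
    list(1, "r(R2,B)", "r(R4,A)"), list(-1, "r(R3,B)", "r(R4,A)")),
    up_to_sign = TRUE)

  # conserved example, full 7x7 determinant
  cons <- load_fixture("conserved_example")
  Ac <- build_A(cons$network, C = cons$C, D = cons$D)
  expect_spoly_equal(symbolic_det(Ac), make_spoly(
    list(1, "r(R2,A)", "r(R4,C)", "r(R3,B)", "r(R5,D)"),
    list(1, "r(R2,A)", "r(R4,C)", "r(R3,B)", "r(R5,E)"),
    list(1, "r(R2,A)", "r(R4,C)", "r(R3,E)", "r(R6,B)")),
    up_to_sign = TRUE)
})

test_that("SOCS3-deleted blocks give the three printed polynomials", {
  fx <- load_fixture("macrophage_socs3d")
  rep <- six_step_report(fx$network)
  labels <- lapply(rep$blocks, `[[`, "chemicals")
  b_nfkb <- rep$blocks[[which(vapply(labels, function(ch) "Np" %in% ch, logical(1)))]]
  b_stat16 <- rep$blocks[[which(vapply(labels, function(ch) "S1p" %in% ch, logical(1)))]]
  b_stat3 <- rep$blocks[[which(vapply(labels, function(ch) "S3p" %in% ch, logical(1)))]]

  expect_spoly_equal(b_nfkb$determinant, make_spoly(
    list(1, "r(R7,Np)"), list(-1, "r(R7,N)"), list(-1, "r(R8,Np)")),
    up_to_sign = TRUE)
  expect_spoly_equal(b_stat16$determinant, make_spoly(
    list(1, "r(R1,S1)", "r(R5,S6)"),
    list(1, "r(R1,S1)", "r(R6,S6p)"),
    list(-1, "r(R1,S6p)", "r(R5,S1p)"),
    list(1, "r(R2,S1p)", "r(R5,S6)"),
    list(1, "r(R2,S1p)", "r(R6,S6p)")),
    up_to_sign = TRUE)
  expect_spoly_equal(b_stat3$determinant, make_spoly(
    list(1, "r(R3,S3)"), list(1, "r(R4,S3p)")),
    up_to_sign = TRUE)

  expect_equal(b_nfkb$sign_class, "always_negative")
  expect_equal(b_stat16$sign_class, "indeterminate")
  expect_true(b_stat3$sign_class %in% c("always_positive", "always_negative"))
})

test_that("sign classification follows the monomial-sign test", {
  signs <- c("p1" = 1, "p2" = 1, "n1" = -1, "u1" = NA)
  expect_equal(classify_sign(make_spoly(list(1, "p1"), list(1, "p2")), signs),
               "always_positive")
  expect_equal(classify_sign(make_spoly(list(1, "n1"), list(-1, "p1")), signs),
               "always_negative")
  expect_equal(classify_sign(make_spoly(list(1, "p1"), list(-1, "p2")), signs),
               "indeterminate")
  expect_equal(classify_sign(make_spoly(list(1, "u1")), signs), "indeterminate")
  expect_equal(classify_sign(sban:::spoly_zero(), signs), "identically_zero")
  # product of two negatives is positive
  expect_equal(classify_sign(make_spoly(list(1, "n1", "n1")), signs),
               "always_positive")
})

test_that("symbolic determinants match LU determinants numerically", {
  set.seed(11)
  for (nm in c("example1", "conserved_example", "macrophage_wt")) {
    fx <- load_fixture(nm)
    A <- build_A(fx$network, C = fx$C, D = fx$D)
    poly <- symbolic_det(A)
    for (i in 1:5) {
      v <- random_symbol_values(A)
      expect_equal(sban:::spoly_eval(poly, v), det(instantiate_A(A, v)),
                   tolerance = 1e-9, label = nm)
    }
  }
})

test_that("definite sign classes hold for random positive magnitudes", {
  fx <- load_fixture("macrophage_socs3d")
  rep <- six_step_report(fx$network)
  A <- rep$A
  set.seed(13)
  for (i in 1:200) {
    keys <- names(A$signs)
    v <- stats::setNames(runif(length(keys), 0.05, 5) * A$signs, keys)
    for (b in rep$blocks) {
      val <- sban:::spoly_eval(b$determinant, v)
      if (b$sign_class == "always_positive") expect_gt(val, 0)
      if (b$sign_class == "always_negative") expect_lt(val, 0)
    }
  }
})

test_that("sensitivity responses localize inside buffering structures", {
  fx <- load_fixture("example1")
  A <- build_A(fx$network)
  set.seed(3)
  for (i in 1:10) {
    v <- random_symbol_values(A)
    Anum <- instantiate_A(A, v)
    # R2 and R3 sit inside the buffering structure {B, R2, R3}: no effect on A
    expect_equal(sensitivity_solve(Anum, "R2")[["A"]], 0, tolerance = 1e-10)
    expect_equal(sensitivity_solve(Anum, "R3")[["A"]], 0, tolerance = 1e-10)
    # R1 is outside: generically both chemicals respond
    expect_gt(abs(sensitivity_solve(Anum, "R1")[["A"]]), 1e-8)
  }
})

test_that("identity-patterned structural matrix returns the unit response", {
  net <- reaction_network(c("A", "B"), list(
    reaction("R1", reactants = c(A = 1)),
    reaction("R2", reactants = c(B = 1))
  ))
  A <- build_A(net)
  v <- stats::setNames(c(1, 1), c("r(R1,A)", "r(R2,B)"))
  resp <- sensitivity_solve(instantiate_A(A, v), "R1")
  expect_equal(unname(resp), c(-1, 0))
})

test_that("inflow-only networks are structurally singular", {
  net <- reaction_network("A", list(reaction("R1", products = c(A = 1))))
  A <- build_A(net)
  expect_error(block_triangularize(A), "structurally degenerate")
  expect_error(sensitivity_solve(instantiate_A(A, numeric(0)), "R1"),
               "singular")
})
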