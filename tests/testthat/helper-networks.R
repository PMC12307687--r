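# shared builders for small test networks and models

chain_network <- function() {
  # reservoir -> A -> B -> reservoir, all mass action: unique equilibrium
  reaction_network(
    c("A", "B"),
    list(
      reaction("R1", products = c(A = 1)),
      reaction("R2", reactants = c(A = 1), products = c(B = 1)),
      reaction("R3", reactants = c(B = 1))
    )
  )
}

chain_model <- function(k1 = 1, k2 = 2, k3 = 4) {
  kinetic_model(chain_network(), list(
    R1 = list(kind = "constant", k = k1),
    R2 = list(kind = "mass_action", k = k2),
    R3 = list(kind = "mass_action", k = k3)
  ))
}

decay_network <- function() {
  # reservoir -> A -> reservoir: scalar case, M = 1, L = 0
  reaction_network("A", list(
    reaction("R1", products = c(A = 1)),
    reaction("R2", reactants = c(A = 1))
  ))
}

decay_model <- function(k1 = 2, k2 = 1) {
  kinetic_model(decay_network(), list(
    R1 = list(kind = "constant", k = k1),
    R2 = list(kind = "mass_action", k = k2)
  ))
}

# polynomial built from a list of (coef, symbols...) terms
make_spoly <- function(...) {
  acc <- sban:::spoly_zero()
  for (term in list(...)) {
    coef <- term[[1]]
    syms <- unlist(term[-1])
    mono <- if (length(syms) == 0) sban:::spoly_const(coef) else {
      p <- sban:::spoly_const(coef)
      for (s in syms) p <- sban:::spoly_mul_entry(p, s, 0)
      p
    }
    acc <- sban:::spoly_add(acc, mono)
  }
  acc
}

expect_spoly_equal <- function(got, want, up_to_sign = FALSE) {
  ok <- if (up_to_sign) sban:::spoly_equal_up_to_sign(got, want)
        else sban:::spoly_equal(got, want)
  expect_true(ok, label = sprintf("polynomial %s vs expected %s",
                                  sban:::format_spoly(got),
                                  sban:::format_spoly(want)))
}

buffering_keys <- function(sets) {
  sort(vapply(sets, function(b) {
    paste0("{", paste(sort(b$chemicals), collapse = ","), "}|{",
           paste(sort(b$reactions), collapse = ","), "}")
  }, character(1)))
}
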