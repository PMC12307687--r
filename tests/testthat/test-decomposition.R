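block_key <- function(b) {
  paste0("{", paste(sort(b$chemicals), collapse = ","), "}|{",
         paste(sort(b$reactions), collapse = ","), "}")
}

test_that("fixture decompositions match the published memberships", {
  # conserved example: {A,R2}, {C,R4}, {B,D,E,R3,R5,R6}, {R1}
  dec <- block_triangularize(build_A(load_fixture("conserved_example")$network))
  expect_setequal(vapply(dec$blocks, block_key, character(1)),
                  c("{A}|{R2}", "{C}|{R4}", "{B,D,E}|{R3,R5,R6}", "{}|{R1}"))

  # SOCS3 deletion: the three structures of the mutant analysis
  decd <- block_triangularize(build_A(load_fixture("macrophage_socs3d")$network))
  expect_setequal(vapply(decd$blocks, block_key, character(1)),
                  c("{N,Np}|{R7,R8}",
                    "{S1,S1p,S6,S6p}|{R1,R2,R5,R6}",
                    "{S3,S3p}|{R3,R4}"))

  # wild type: a single irreducible block
  decw <- block_triangularize(build_A(load_fixture("macrophage_wt")$network))
  expect_equal(length(decw$blocks), 1L)
})

test_that("diagonal networks split into singleton blocks", {
  net <- reaction_network(c("A", "B", "C"), list(
    reaction("R1", reactants = c(A = 1)),
    reaction("R2", reactants = c(B = 1)),
    reaction("R3", reactants = c(C = 1))
  ))
  dec <- block_triangularize(build_A(net))
  expect_equal(length(dec$blocks), 3L)
  g <- influence_graph(dec)
  expect_equal(sum(g$adjacency), 0L)
})

test_that("permutations reproduce an exact upper block-triangular form", {
  for (nm in c("conserved_example", "macrophage_socs3d")) {
    A <- build_A(load_fixture(nm)$network)
    dec <- block_triangularize(A)
    nz <- nonzero_pattern(A)[dec$row_order, dec$col_order]
    sizes <- vapply(dec$blocks, function(b) length(b$rows), integer(1))
    offs <- cumsum(c(0, sizes))
    for (i in seq_along(sizes)) {
      for (j in seq_len(i - 1)) {
        blockij <- nz[(offs[i] + 1):offs[i + 1], (offs[j] + 1):offs[j + 1],
                      drop = FALSE]
        expect_false(any(blockij),
                     label = sprintf("%s: lower block (%d,%d)", nm, i, j))
      }
    }
    expect_true(dec$perm_sign %in% c(-1, 1))
  }
})

test_that("influence edges of the conserved example match the coupling blocks", {
  dec <- block_triangularize(build_A(load_fixture("conserved_example")$network))
  g <- influence_graph(dec)
  key <- vapply(dec$blocks, block_key, character(1))
  lab <- function(k) dec$blocks[[match(k, key)]]$label
  edges <- which(g$adjacency == 1L, arr.ind = TRUE)
  edge_set <- apply(edges, 1, function(e) {
    paste(g$labels[e[[1]]], g$labels[e[[2]]], sep = "->")
  })
  expect_setequal(edge_set, c(
    paste(lab("{C}|{R4}"), lab("{A}|{R2}"), sep = "->"),
    paste(lab("{}|{R1}"), lab("{A}|{R2}"), sep = "->"),
    paste(lab("{}|{R1}"), lab("{C}|{R4}"), sep = "->"),
    paste(lab("{}|{R1}"), lab("{B,D,E}|{R3,R5,R6}"), sep = "->")
  ))
})

test_that("influence graphs are acyclic and buffering sets descendant-closed", {
  for (s in 1:20) {
    net <- random_network(seed = 1000 + s)
    dec <- block_triangularize(build_A(net))
    g <- influence_graph(dec)  # errors internally on a cycle
    bs <- buffering_structures(dec, g, max_sets = 2048)
    adj <- g$adjacency
    for (b in bs) {
      members <- b$block_idx
      downstream <- unique(unlist(lapply(members, function(i) which(adj[i, ] == 1))))
      expect_true(all(downstream %in% members))
    }
  }
})

test_that("buffering structures match the published lists", {
  # example 1: {B, R2, R3} plus its closure and the trivial structure
  rep1 <- six_step_report(load_fixture("example1")$network)
  expect_true("{B}|{R2,R3}" %in% buffering_keys(rep1$buffering))

  # conserved example: Gamma1, Gamma1 u Gamma2, Gamma3 are all present
  repc <- six_step_report(load_fixture("conserved_example")$network)
  keys <- buffering_keys(repc$buffering)
  expect_true(all(c("{A}|{R2}", "{A,C}|{R2,R4}", "{B,D,E}|{R3,R5,R6}") %in% keys))

  # wild type: only the trivial whole-network structure
  repw <- six_step_report(load_fixture("macrophage_wt")$network)
  expect_equal(length(repw$buffering), 1L)
  expect_true(repw$buffering[[1]]$is_trivial)

  # SOCS3 deletion: Gamma1 and Gamma1 u Gamma2 as named structures
  repd <- six_step_report(load_fixture("macrophage_socs3d")$network)
  expect_setequal(buffering_keys(repd$buffering), c(
    "{N,Np}|{R7,R8}",
    "{N,Np,S1,S1p,S6,S6p}|{R1,R2,R5,R6,R7,R8}",
    "{N,Np,S1,S1p,S3,S3p,S6,S6p}|{R1,R2,R3,R4,R5,R6,R7,R8}"
  ))

  # KLF4 double deletion frees the STAT1/STAT6 block
  repk <- six_step_report(load_fixture("macrophage_socs3d_klf4d")$network)
  expect_true("{S1,S1p,S6,S6p}|{R1,R2,R5,R6}" %in% buffering_keys(repk$buffering))
})

test_that("inducing parameters follow influence reachability", {
  # example 1: the interconversion block is induced by every reaction
  rep1 <- six_step_report(load_fixture("example1")$network)
  cond <- rep1$conditions[[1]]
  expect_true("R2" %in% cond$inducing_reactions)

  # wild type: the single whole-network condition includes eta1
  repw <- six_step_report(load_fixture("macrophage_wt")$network)
  expect_equal(length(repw$conditions), 1L)
  expect_true("eta1" %in% repw$conditions[[1]]$inducing_conserved)
  expect_setequal(repw$conditions[[1]]$bifurcating_chemicals,
                  load_fixture("macrophage_wt")$network$species$id)

  # conserved example: Gamma3's own reactions plus the inflow, never R2/R4
  repc <- six_step_report(load_fixture("conserved_example")$network)
  cond <- repc$conditions[[1]]
  expect_setequal(cond$inducing_reactions, c("R1", "R3", "R5", "R6"))
  expect_setequal(cond$inducing_conserved, "eta1")
  expect_setequal(cond$bifurcating_chemicals, c("B", "D", "E"))
})

test_that("bifurcating chemicals match the three mutant analyses", {
  repd <- six_step_report(load_fixture("macrophage_socs3d")$network)
  expect_equal(length(repd$conditions), 1L)
  expect_setequal(repd$conditions[[1]]$bifurcating_chemicals,
                  c("N", "Np", "S1", "S1p", "S6", "S6p"))
  repk <- six_step_report(load_fixture("macrophage_socs3d_klf4d")$network)
  expect_setequal(repk$conditions[[1]]$bifurcating_chemicals,
                  c("S1", "S1p", "S6", "S6p"))
})

test_that("det A equals the signed product of diagonal block determinants", {
  set.seed(5)
  for (nm in c("example1", "conserved_example", "macrophage_socs3d")) {
    fx <- load_fixture(nm)
    A <- build_A(fx$network)
    dec <- block_triangularize(A)
    v <- random_symbol_values(A)
    Anum <- instantiate_A(A, v)
    prod_blocks <- prod(vapply(dec$blocks, function(b) {
      det(Anum[b$rows, b$cols, drop = FALSE])
    }, numeric(1)))
    expect_equal(det(Anum), dec$perm_sign * prod_blocks,
                 tolerance = 1e-9, label = nm)
  }
})

test_that("closure-derived buffering structures equal brute-force enumeration", {
  for (s in 1:40) {
    net <- random_network(n_species = c(3L, 5L), n_reactions = c(3L, 5L),
                          seed = 2000 + s)
    if (n_species(net) + n_reactions(net) > 12) next
    dec <- block_triangularize(build_A(net))
    bs <- buffering_structures(dec, influence_graph(dec), max_sets = 4096)
    expect_identical(buffering_keys(bs),
                     buffering_keys(enumerate_buffering_bruteforce(net)),
                     label = paste("seed", 2000 + s))
  }
})

test_that("no diagonal block admits a further block-triangular split", {
  for (s in 1:10) {
    net <- random_network(seed = 3000 + s)
    A <- build_A(net)
    dec <- block_triangularize(A)
    for (b in dec$blocks) {
      if (length(b$rows) < 2) next
      # the matched column digraph of the block must be strongly connected
      # (matching-invariant, so any perfect matching of the block will do)
      nz <- nonzero_pattern(A)[b$rows, b$cols, drop = FALSE]
      mr <- sban:::.perfect_matching(nz)
      expect_false(anyNA(mr))
      n <- ncol(nz)
      adj <- matrix(0, n, n)
      for (cc in seq_len(n)) {
        adj[cc, setdiff(which(nz[mr[[cc]], ]), cc)] <- 1
      }
      sub <- igraph::graph_from_adjacency_matrix(adj, mode = "directed")
      expect_equal(igraph::components(sub, mode = "strong")$no, 1L)
    }
  }
})
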