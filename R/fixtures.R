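#' Bundled example networks and kinetic presets
#'
#' The catalog ships the networks used throughout the documentation and
#' tests:
#'
#' * `example1` — two chemicals A, B; inflow to A, interconversion
#'   A <-> B with B positively regulating its own production, outflow from A.
#'   Has the buffering structure \{B, R2, R3\}.
#' * `conserved_example` — five chemicals A..E, six reactions, with one
#'   conserved quantity `x_D - x_E`. The network body is reconstructed from
#'   its printed stoichiometric matrix and the two described loops
#'   (B -> (D+E) -> B over R5, R6 and reservoir -> A -> B -> C -> reservoir
#'   over R1..R4); the regulator arrows C -| R2 and E -| R3 are inferred from
#'   the printed determinant expansions, which contain the corresponding
#'   partial derivatives.
#' * `macrophage_wt` — the 8-species M1/M2 polarization network:
#'   inactive/phosphorylated pairs of STAT1, STAT3, STAT6 and NFkB, each pair
#'   an activation/deactivation loop with a conserved total, and nine
#'   negative regulation arrows (SOCS3-mediated inhibition of STAT3
#'   activation, mutual STAT1/STAT6 antagonism, KLF4-mediated and
#'   autoregulatory inhibition of NFkB activation).
#' * `macrophage_socs3d` — wild type minus the three SOCS3-mediated arrows
#'   on R3 (derivatives with respect to NFkB+, STAT1+, STAT3+ zeroed).
#' * `macrophage_socs3d_klf4d` — additionally removes the STAT6+ arrow on R7.
#'
#' Each entry returns the network, the canonical (hand-picked loop) bases
#' where the documentation pins printed constants to them, the kinetic preset
#' laws, and for mutants the deletion list relative to the wild type.
#'
#' @param name fixture name, see above.
#' @return List with `network`, `C`, `D` (canonical bases or NULL),
#'   `kinetics` (named list of law sets), `deletions`.
#' @export
load_fixture <- function(name) {
  fixtures <- list(
    example1 = .fixture_example1,
    conserved_example = .fixture_conserved,
    macrophage_wt = function() .fixture_macrophage("wt"),
    macrophage_socs3d = function() .fixture_macrophage("socs3d"),
    macrophage_socs3d_klf4d = function() .fixture_macrophage("socs3d_klf4d")
  )
  if (!name %in% names(fixtures)) {
    stop(sprintf("unknown fixture '%s' (known: %s)", name,
                 paste(names(fixtures), collapse = ", ")))
  }
  fx <- fixtures[[name]]()
  .validate_fixture(fx)
  fx
}

#' @rdname load_fixture
#' @export
fixture_names <- function() {
  c("example1", "conserved_example", "macrophage_wt",
    "macrophage_socs3d", "macrophage_socs3d_klf4d")
}

.validate_fixture <- function(fx) {
  nu <- stoichiometric_matrix(fx$network)
  if (!is.null(fx$C)) validate_basis(nu, fx$C, "kernel")
  if (!is.null(fx$D)) validate_basis(nu, fx$D, "cokernel")
  invisible(fx)
}

.fixture_example1 <- function() {
  net <- reaction_network(
    species = c("A", "B"),
    reactions = list(
      reaction("R1", products = c(A = 1)),
      reaction("R2", reactants = c(A = 1), products = c(B = 1),
               regulators = c(B = "+")),
      reaction("R3", reactants = c(B = 1), products = c(A = 1)),
      reaction("R4", reactants = c(A = 1))
    ),
    metadata = list(fixture = "example1")
  )
  # canonical loop basis: the reservoir loop R1->R2->R3->R4 and the
  # interconversion loop R2->R3
  C <- cbind(c(1, 1, 1, 1), c(0, 1, 1, 0))
  rownames(C) <- c("R1", "R2", "R3", "R4")
  colnames(C) <- c("c1", "c2")
  D <- matrix(0, nrow = 2, ncol = 0, dimnames = list(c("A", "B"), NULL))
  kin <- list(
    # pitchfork: logistic activation of R2 by B, tuned so the equilibrium
    # B = theta keeps odd symmetry; steepness tau is the sweep parameter
    # (critical tau = 0.5 given k2 = 2, k3 = theta = 1)
    pitchfork = list(
      laws = list(
        R1 = list(kind = "constant", k = 1),
        R2 = list(kind = "sigmoid_activated", k = 2, activator = "B",
                  theta = 1, tau = 0.3, eps = 0),
        R3 = list(kind = "mass_action", k = 1),
        R4 = list(kind = "mass_action", k = 1)
      ),
      sweep = list(type = "rate", reaction = "R2", name = "tau"),
      range = c(0.2, 0.8)
    ),
    # transcritical: bilinear activation vs linear-plus-quadratic removal;
    # branches B = 0 and B = (k2 - 1)/0.5 exchange stability at k2 = 1
    transcritical = list(
      laws = list(
        R1 = list(kind = "constant", k = 1),
        R2 = list(kind = "mass_action_mod", k = 1.4, modifiers = c(B = 1)),
        R3 = list(kind = "ma_poly", species = "B", coef = c(1, 0.5),
                  pow = c(1, 2)),
        R4 = list(kind = "mass_action", k = 1)
      ),
      sweep = list(type = "rate", reaction = "R2", name = "k"),
      range = c(0.5, 1.5)
    ),
    # saddle-node: basal-plus-Hill activation of R2 by B; bistable window in
    # the basal rate k0 with folds at its ends
    saddle_node = list(
      laws = list(
        R1 = list(kind = "constant", k = 1),
        R2 = list(kind = "hill_activated", k0 = 0.06, k1 = 1, activator = "B",
                  h = 2, theta = 1),
        R3 = list(kind = "mass_action", k = 0.5),
        R4 = list(kind = "mass_action", k = 1)
      ),
      sweep = list(type = "rate", reaction = "R2", name = "k0"),
      range = c(0.01, 0.15)
    )
  )
  list(network = net, C = C, D = D, kinetics = kin, deletions = NULL)
}

.fixture_conserved <- function() {
  net <- reaction_network(
    species = c("A", "B", "C", "D", "E"),
    reactions = list(
      reaction("R1", products = c(A = 1)),
      reaction("R2", reactants = c(A = 1), products = c(B = 1),
               regulators = c(C = "-")),
      reaction("R3", reactants = c(B = 1), products = c(C = 1),
               regulators = c(E = "-")),
      reaction("R4", reactants = c(C = 1)),
      reaction("R5", reactants = c(D = 1, E = 1), products = c(B = 1)),
      reaction("R6", reactants = c(B = 1), products = c(D = 1, E = 1))
    ),
    metadata = list(fixture = "conserved_example")
  )
  C <- cbind(c(0, 0, 0, 0, 1, 1), c(1, 1, 1, 1, 0, 0))
  rownames(C) <- paste0("R", 1:6)
  colnames(C) <- c("c1", "c2")
  D <- matrix(c(0, 0, 0, 1, -1), ncol = 1,
              dimnames = list(c("A", "B", "C", "D", "E"), "d1"))
  kin <- list(
    default = list(
      laws = list(
        R1 = list(kind = "constant", k = 1),
        R2 = list(kind = "hill_inhibited", k = 1,
                  inhibitors = list(species = "C", a = 0.5, h = 1)),
        R3 = list(kind = "hill_inhibited", k = 1,
                  inhibitors = list(species = "E", a = 0.8, h = 1)),
        R4 = list(kind = "mass_action", k = 1),
        R5 = list(kind = "mass_action", k = 1),
        R6 = list(kind = "mass_action", k = 0.7)
      ),
      sweep = list(type = "eta", index = 1),
      range = c(0.2, 2)
    )
  )
  list(network = net, C = C, D = D, kinetics = kin, deletions = NULL)
}

# the three SOCS3-mediated regulations, and the KLF4-mediated one
.socs3_deletions <- list(c("R3", "Np"), c("R3", "S1p"), c("R3", "S3p"))
.klf4_deletions <- list(c("R7", "S6p"))

.fixture_macrophage <- function(variant) {
  drop <- switch(variant,
    wt = list(),
    socs3d = .socs3_deletions,
    socs3d_klf4d = c(.socs3_deletions, .klf4_deletions)
  )
  reg <- function(rid, full) {
    keep <- !vapply(names(full), function(s) {
      any(vapply(drop, function(d) d[[1]] == rid && d[[2]] == s, logical(1)))
    }, logical(1))
    full[keep]
  }
  species <- data.frame(
    id = c("S1", "S1p", "S3", "S3p", "S6", "S6p", "N", "Np"),
    name = c("STAT1", "STAT1+", "STAT3", "STAT3+", "STAT6", "STAT6+",
             "NFkB", "NFkB+"),
    stringsAsFactors = FALSE
  )
  net <- reaction_network(
    species = species,
    reactions = list(
      reaction("R1", reactants = c(S1 = 1), products = c(S1p = 1),
               regulators = reg("R1", c(S3p = "-", S6p = "-"))),
      reaction("R2", reactants = c(S1p = 1), products = c(S1 = 1)),
      reaction("R3", reactants = c(S3 = 1), products = c(S3p = 1),
               regulators = reg("R3", c(S1p = "-", S3p = "-", Np = "-"))),
      reaction("R4", reactants = c(S3p = 1), products = c(S3 = 1)),
      reaction("R5", reactants = c(S6 = 1), products = c(S6p = 1),
               regulators = reg("R5", c(S1p = "-"))),
      reaction("R6", reactants = c(S6p = 1), products = c(S6 = 1)),
      reaction("R7", reactants = c(N = 1), products = c(Np = 1),
               regulators = reg("R7", c(S3p = "-", S6p = "-", Np = "-"))),
      reaction("R8", reactants = c(Np = 1), products = c(N = 1))
    ),
    metadata = list(fixture = paste0("macrophage_", variant))
  )
  # canonical bases: one activation/deactivation loop per protein pair, one
  # conserved total per pair
  C <- matrix(0, 8, 4, dimnames = list(paste0("R", 1:8), paste0("c", 1:4)))
  C[cbind(1:8, rep(1:4, each = 2))] <- 1
  D <- matrix(0, 8, 4, dimnames = list(species$id, paste0("d", 1:4)))
  D[cbind(1:8, rep(1:4, each = 2))] <- 1
  laws <- .macrophage_laws(variant)
  list(network = net, C = C, D = D,
       kinetics = list(default = list(laws = laws,
                                      sweep = list(type = "eta", index = 1),
                                      range = c(6, 8.5))),
       deletions = if (length(drop) == 0) NULL else drop)
}

# Qualitative preset for the polarization model: activations are Hill-type
# inhibited rates (exponent 2), deactivations mass action. Calibrated once so
# that the wild type is bistable over the upper part of eta1 in [6, 8.5]
# (STAT1 total) with the M1-like branch (high STAT1+/NFkB+) lost at low eta1.
.macrophage_laws <- function(variant) {
  inh <- function(...) {
    v <- c(...)
    list(species = names(v), a = unname(v), h = rep(2, length(v)))
  }
  socs3 <- !variant %in% c("socs3d", "socs3d_klf4d")
  klf4 <- variant != "socs3d_klf4d"
  laws <- list(
    R1 = list(kind = "hill_inhibited", k = 1,
              inhibitors = inh(S3p = 0.05, S6p = 1.5)),
    R2 = list(kind = "mass_action", k = 1),
    R3 = if (socs3) {
      list(kind = "hill_inhibited", k = 1,
           inhibitors = inh(S1p = 1, S3p = 0.05, Np = 0.1))
    } else list(kind = "mass_action", k = 1),
    R4 = list(kind = "mass_action", k = 1),
    R5 = list(kind = "hill_inhibited", k = 1, inhibitors = inh(S1p = 2)),
    R6 = list(kind = "mass_action", k = 1),
    R7 = list(kind = "hill_inhibited", k = 1,
              inhibitors = if (klf4) inh(S3p = 0.1, S6p = 0.3, Np = 0.05)
                           else inh(S3p = 0.1, Np = 0.05)),
    R8 = list(kind = "mass_action", k = 1)
  )
  laws
}

#' Default conserved values for the macrophage presets
#'
#' Totals for the STAT3, STAT6 and NFkB pairs (the STAT1 total is the usual
#' sweep parameter).
#'
#' @param eta1 STAT1 total.
#' @return Numeric vector of length 4.
#' @export
macrophage_eta <- function(eta1 = 8) c(eta1, 8, 8, 8)

#' Build the kinetic model of a fixture preset
#'
#' @param name fixture name.
#' @param preset preset name within the fixture (default the first).
#' @return A `kinetic_model`; attributes `sweep` and `range` carry the
#'   preset's recommended sweep.
#' @export
fixture_model <- function(name, preset = NULL) {
  fx <- load_fixture(name)
  if (is.null(preset)) preset <- names(fx$kinetics)[[1]]
  kp <- fx$kinetics[[preset]]
  if (is.null(kp)) stop(sprintf("unknown preset '%s'", preset))
  m <- kinetic_model(fx$network, kp$laws)
  attr(m, "sweep") <- kp$sweep
  attr(m, "range") <- kp$range
  m
}

#' Random reaction networks for property tests
#'
#' Draws a connected random network: inflows, outflows, conversions,
#' reversible conversion pairs (which induce conserved totals when a pair of
#' species only interconverts), and regulatory arrows with random signs.
#' Deterministic for a fixed seed.
#'
#' @param n_species range (length 2) for the species count.
#' @param n_reactions range for the reaction count (before the reversible
#'   completion).
#' @param reg_density probability of adding a regulator per reaction.
#' @param rev_frac fraction of conversions completed into reversible pairs.
#' @param seed RNG seed.
#' @param require_nonsingular retry until the structural matrix admits a
#'   perfect matching (up to `max_tries`, then error).
#' @param max_tries bounded retries.
#' @return A `reaction_network`.
#' @export
random_network <- function(n_species = c(4L, 8L), n_reactions = c(4L, 8L),
                           reg_density = 0.2, rev_frac = 0.35, seed = 0L,
                           require_nonsingular = TRUE, max_tries = 60L) {
  old <- .save_seed(); on.exit(.restore_seed(old))
  for (attempt in seq_len(max_tries)) {
    set.seed(seed + 7919L * (attempt - 1L))
    net <- .draw_network(n_species, n_reactions, reg_density, rev_frac)
    if (!require_nonsingular) return(net)
    ok <- tryCatch({
      A <- build_A(net)
      dec <- block_triangularize(A)
      TRUE
    }, error = function(e) FALSE)
    if (ok) return(net)
  }
  stop("generation error: no structurally nonsingular network after bounded retries")
}

# Well-formed draws in the style of signaling models: conserved quantities
# come from dedicated activation/deactivation pairs (a species pair that only
# interconverts), every flow-through species is both produced and consumed,
# and no two reactions share a stoichiometric column. Dead-end chains or
# duplicated reactions would make equilibria degenerate and are not drawn.
.draw_network <- function(n_species, n_reactions, reg_density, rev_frac) {
  M <- sample(n_species[[1]]:n_species[[2]], 1)
  sids <- paste0("X", seq_len(M))
  n_pairs <- min(floor(rev_frac * M / 2 + stats::runif(1)), floor(M / 2))
  pair_sp <- if (n_pairs > 0) sids[seq_len(2 * n_pairs)] else character(0)
  flow_sp <- setdiff(sids, pair_sp)
  reactions <- list()
  rid <- 0L
  add <- function(reactants = integer(), products = integer()) {
    rid <<- rid + 1L
    reactions[[length(reactions) + 1L]] <<-
      reaction(paste0("R", rid), reactants = reactants, products = products)
  }
  one <- function(s) stats::setNames(1L, s)
  for (p in seq_len(n_pairs)) {
    a <- pair_sp[[2 * p - 1]]; b <- pair_sp[[2 * p]]
    add(one(a), one(b))
    add(one(b), one(a))
  }
  if (length(flow_sp) > 0) {
    # backbone: reservoir -> chain through all flow species -> reservoir
    chain <- sample(flow_sp, length(flow_sp))
    add(products = one(chain[[1]]))
    for (i in seq_along(chain)[-1]) add(one(chain[[i - 1]]), one(chain[[i]]))
    add(one(chain[[length(chain)]]))
    # extra conversions among flow species, skipping duplicate columns
    N0 <- sample(n_reactions[[1]]:n_reactions[[2]], 1)
    tries <- 0L
    while (length(reactions) < N0 && tries < 20L && length(flow_sp) > 1) {
      tries <- tries + 1L
      ab <- sample(flow_sp, 2)
      dup <- any(vapply(reactions, function(r) {
        identical(names(r$reactants), ab[[1]]) &&
          identical(names(r$products), ab[[2]])
      }, logical(1)))
      if (!dup) add(one(ab[[1]]), one(ab[[2]]))
    }
  }
  # regulators: any species not already driving the reaction
  reactions <- lapply(reactions, function(r) {
    if (stats::runif(1) < reg_density) {
      cand <- setdiff(sids, c(names(r$reactants), names(r$products)))
      if (length(cand) > 0) {
        s <- sample(cand, 1)
        r$regulators <- c(r$regulators,
                          stats::setNames(sample(c("+", "-"), 1), s))
      }
    }
    r
  })
  reaction_network(sids, reactions)
}
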