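#' Finest block-triangular decomposition of the structural matrix
#'
#' Finds permutations `P_r`, `P_c` rearranging the structural matrix into its
#' finest upper block-triangular form. The diagonal blocks are the
#' *determinant structures*: the units into which the bifurcation condition
#' `det A = 0` factorizes. The construction is the standard one: a perfect
#' matching on the nonzero pattern pairs every column (chemical or loop) with
#' a row (reaction or conserved quantity); strongly connected components of
#' the matched column digraph give the blocks; the condensation's topological
#' order gives the block ordering (ties broken by smallest original column
#' index).
#'
#' @param A an `amatrix` from [build_A()].
#' @return An object of class `sba_decomposition` with fields `blocks` (list
#'   of determinant structures, each with `chemicals`, `reactions`,
#'   `loop_cols`, `conserved_rows`, `rows`, `cols`), `row_order`,
#'   `col_order`, `perm_sign` (`det(P_r) * det(P_c)`), and the source `A`.
#' @export
block_triangularize <- function(A) {
  nz <- nonzero_pattern(A)
  n <- nrow(nz)
  match_row <- .perfect_matching(nz)
  if (anyNA(match_row)) {
    stop("structurally degenerate network: det A == 0 for every kinetics")
  }
  # column digraph: c -> c' when the row matched to c also hits c'
  edges <- integer(0)
  for (cc in seq_len(n)) {
    hits <- setdiff(which(nz[match_row[[cc]], ]), cc)
    if (length(hits) > 0) edges <- c(edges, rbind(cc, hits))
  }
  g <- igraph::make_graph(edges = edges, n = n, directed = TRUE)
  comp <- igraph::components(g, mode = "strong")
  min_col <- vapply(seq_len(comp$no),
                    function(b) min(which(comp$membership == b)), numeric(1))
  # topological order of the condensation (Kahn), ties broken by smallest
  # original column index so the ordering is deterministic
  adj <- vector("list", comp$no)
  indeg <- integer(comp$no)
  for (b in seq_len(comp$no)) {
    outs <- setdiff(unique(unlist(lapply(which(comp$membership == b), function(cc) {
      comp$membership[setdiff(which(nz[match_row[[cc]], ]), cc)]
    }))), b)
    adj[[b]] <- outs
    for (o in outs) indeg[[o]] <- indeg[[o]] + 1L
  }
  ord <- integer(0)
  ready <- which(indeg == 0L)
  while (length(ready) > 0) {
    b <- ready[[which.min(min_col[ready])]]
    ord <- c(ord, b)
    ready <- setdiff(ready, b)
    for (o in adj[[b]]) {
      indeg[[o]] <- indeg[[o]] - 1L
      if (indeg[[o]] == 0L) ready <- c(ready, o)
    }
  }
  stopifnot(length(ord) == comp$no)
  blocks <- vector("list", comp$no)
  col_order <- integer(0)
  row_order <- integer(0)
  for (k in seq_along(ord)) {
    b <- ord[[k]]
    cols <- sort(which(comp$membership == b))
    rows <- sort(match_row[cols])
    col_order <- c(col_order, cols)
    row_order <- c(row_order, rows)
    blocks[[k]] <- list(
      label = paste0("Gamma", k),
      chemicals = colnames(A$sym)[cols[A$col_kind[cols] == "species"]],
      loop_cols = colnames(A$sym)[cols[A$col_kind[cols] == "loop"]],
      reactions = rownames(A$sym)[rows[A$row_kind[rows] == "reaction"]],
      conserved_rows = rownames(A$sym)[rows[A$row_kind[rows] == "conserved"]],
      rows = rows, cols = cols
    )
  }
  structure(list(
    A = A, blocks = blocks,
    row_order = row_order, col_order = col_order,
    perm_sign = .perm_parity(row_order) * .perm_parity(col_order)
  ), class = "sba_decomposition")
}

# Kuhn's augmenting-path bipartite matching; returns, per column, its matched
# row (NA if no perfect matching exists).
.perfect_matching <- function(nz) {
  n <- ncol(nz)
  row_of <- rep(NA_integer_, n)   # per column
  col_of <- rep(NA_integer_, nrow(nz))
  for (cc in seq_len(n)) {
    seenv <- rep(FALSE, nrow(nz))
    aug <- function(c0) {
      for (rr in which(nz[, c0])) {
        if (!seenv[[rr]]) {
          seenv[[rr]] <<- TRUE
          if (is.na(col_of[[rr]]) || aug(col_of[[rr]])) {
            row_of[[c0]] <<- rr
            col_of[[rr]] <<- c0
            return(TRUE)
          }
        }
      }
      FALSE
    }
    if (!aug(cc)) return(rep(NA_integer_, n))
  }
  row_of
}

.perm_parity <- function(p) {
  # sign of the permutation taking sort(p) to p
  n <- length(p)
  visited <- rep(FALSE, n)
  r <- rank(p)
  sgn <- 1
  for (i in seq_len(n)) {
    if (!visited[[i]]) {
      j <- i; len <- 0
      while (!visited[[j]]) {
        visited[[j]] <- TRUE
        j <- r[[j]]
        len <- len + 1
      }
      if (len %% 2 == 0) sgn <- -sgn
    }
  }
  sgn
}

#' @export
print.sba_decomposition <- function(x, ...) {
  cat(sprintf("sba_decomposition: %d determinant structures (perm sign %+d)\n",
              length(x$blocks), x$perm_sign))
  for (b in x$blocks) {
    cat(sprintf("  %s: chemicals {%s} reactions {%s}%s%s\n", b$label,
                paste(b$chemicals, collapse = ", "),
                paste(b$reactions, collapse = ", "),
                if (length(b$loop_cols) > 0)
                  paste0(" loops {", paste(b$loop_cols, collapse = ", "), "}") else "",
                if (length(b$conserved_rows) > 0)
                  paste0(" conserved {", paste(b$conserved_rows, collapse = ", "), "}") else ""))
  }
  invisible(x)
}

#' Influence graph among determinant structures
#'
#' Directed graph with one node per determinant structure and an edge
#' `Gamma_i -> Gamma_j` whenever the off-diagonal coupling block of the
#' rearranged matrix (rows of `Gamma_j`, columns of `Gamma_i`) is nonzero:
#' parameter perturbations in `Gamma_i` can then shift equilibria in
#' `Gamma_j`. The graph is acyclic by construction of the finest
#' decomposition.
#'
#' @param dec an `sba_decomposition`.
#' @return An object of class `sba_influence` with fields `adjacency` (0/1
#'   matrix, rows influence columns) and `labels`.
#' @export
influence_graph <- function(dec) {
  nz <- nonzero_pattern(dec$A)
  S <- length(dec$blocks)
  adj <- matrix(0L, S, S,
                dimnames = list(vapply(dec$blocks, `[[`, character(1), "label"),
                                vapply(dec$blocks, `[[`, character(1), "label")))
  for (i in seq_len(S)) {
    for (j in seq_len(S)) {
      if (i != j &&
          any(nz[dec$blocks[[j]]$rows, dec$blocks[[i]]$cols])) {
        adj[i, j] <- 1L  # Gamma_i influences Gamma_j
      }
    }
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "directed")
  if (!igraph::is_dag(g)) {
    stop("internal contract violation: influence graph has a cycle")
  }
  structure(list(adjacency = adj, labels = rownames(adj)),
            class = "sba_influence")
}

#' @export
print.sba_influence <- function(x, ...) {
  cat("influence graph:\n")
  idx <- which(x$adjacency == 1L, arr.ind = TRUE)
  if (nrow(idx) == 0) cat("  (no edges)\n")
  for (k in seq_len(nrow(idx))) {
    cat(sprintf("  %s -> %s\n", x$labels[idx[k, 1]], x$labels[idx[k, 2]]))
  }
  invisible(x)
}

.descendant_closure <- function(adj, seeds) {
  members <- rep(FALSE, nrow(adj))
  frontier <- seeds
  while (length(frontier) > 0) {
    members[frontier] <- TRUE
    nxt <- unique(unlist(lapply(frontier, function(i) which(adj[i, ] == 1L))))
    frontier <- setdiff(nxt, which(members))
  }
  which(members)
}

#' Buffering structures
#'
#' A buffering structure is an output-complete subnetwork with zero index
#' (`#chemicals - #reactions + #loops - #conserved = 0`, counting loops and
#' conserved quantities by the dimensions of the kernel/cokernel restricted
#' to the subnetwork's reactions/chemicals). Perturbations of parameters
#' inside a buffering structure do not propagate outside it. In terms of the
#' influence graph they are exactly the unions of determinant structures
#' closed under outgoing influence edges; enumeration walks that lattice with
#' a cap, but the minimal buffering structure containing each determinant
#' structure (all that prediction needs) is always exact.
#'
#' @param dec an `sba_decomposition`.
#' @param graph the matching [influence_graph()]; computed if missing.
#' @param max_sets enumeration cap; when hit, the result carries
#'   `truncated = TRUE`.
#' @return List of class `sba_buffering_list`; each element has `chemicals`,
#'   `reactions`, `blocks`, `is_trivial` (whole network),
#'   `join_irreducible` (closure of a single determinant structure).
#' @export
buffering_structures <- function(dec, graph = NULL, max_sets = 512L) {
  if (is.null(graph)) graph <- influence_graph(dec)
  adj <- graph$adjacency
  S <- nrow(adj)
  principal <- lapply(seq_len(S), function(i) .descendant_closure(adj, i))
  key <- function(s) paste(s, collapse = ",")
  sets <- list()
  irr <- character(0)
  for (p in principal) {
    sets[[key(p)]] <- p
    irr <- c(irr, key(p))
  }
  truncated <- FALSE
  # all closed sets are unions of principal closures
  frontier <- sets
  while (length(frontier) > 0 && length(sets) < max_sets) {
    nxt <- list()
    for (s in frontier) {
      for (p in principal) {
        u <- sort(union(s, p))
        k <- key(u)
        if (is.null(sets[[k]])) {
          sets[[k]] <- u
          nxt[[k]] <- u
          if (length(sets) >= max_sets) { truncated <- TRUE; break }
        }
      }
      if (truncated) break
    }
    frontier <- nxt
  }
  out <- lapply(names(sets), function(k) {
    s <- sets[[k]]
    bl <- dec$blocks[s]
    str <- list(
      blocks = vapply(bl, `[[`, character(1), "label"),
      block_idx = s,
      chemicals = sort(unlist(lapply(bl, `[[`, "chemicals"))),
      reactions = sort(unlist(lapply(bl, `[[`, "reactions"))),
      is_trivial = length(s) == S,
      join_irreducible = k %in% irr
    )
    .validate_buffering(dec$A, str)
    str
  })
  # order by size, trivial (whole network) last
  sizes <- vapply(out, function(s) length(s$block_idx), numeric(1))
  out <- out[order(sizes)]
  structure(out, class = "sba_buffering_list", truncated = truncated)
}

.validate_buffering <- function(A, str) {
  chk <- is_output_complete(A$net, str$chemicals, str$reactions) &&
    subnetwork_index(A$net, str$chemicals, str$reactions) == 0
  if (!chk) {
    stop("internal contract violation: influence-closed set fails the buffering definition")
  }
  invisible(TRUE)
}

#' @export
print.sba_buffering_list <- function(x, ...) {
  cat(sprintf("%d buffering structure(s)%s:\n", length(x),
              if (isTRUE(attr(x, "truncated"))) " (truncated)" else ""))
  for (s in x) {
    cat(sprintf("  {%s} = chemicals {%s}, reactions {%s}%s\n",
                paste(s$blocks, collapse = ", "),
                paste(s$chemicals, collapse = ", "),
                paste(s$reactions, collapse = ", "),
                if (s$is_trivial) "  [trivial: whole network]" else ""))
  }
  invisible(x)
}

#' Output-completeness and index of a subnetwork
#'
#' `is_output_complete()` checks that every reaction whose rate depends on a
#' chemical of the subnetwork (as reactant or regulator) belongs to it.
#' `subnetwork_index()` returns
#' `#chemicals - #reactions + #loops - #conserved`. Loops are counted by the
#' dimension of the kernel restricted to the subnetwork's reactions (flux
#' modes runnable entirely inside it). A conserved quantity belongs to the
#' subnetwork as soon as its support *touches* the subnetwork's chemicals —
#' its constraint row is then tied to the subnetwork — so the count is
#' `Q - dim(cokernel restricted to the complement chemicals)`. Both counts
#' are basis-independent; a buffering structure has index zero.
#'
#' @param net a `reaction_network`.
#' @param chemicals,reactions character vectors of member ids.
#' @return Logical / integer.
#' @export
is_output_complete <- function(net, chemicals, reactions) {
  sg <- rate_dependency_signs(net)
  dep <- !is.na(sg) & sg != 0 | is.na(sg)
  for (s in chemicals) {
    regulated <- rownames(sg)[dep[, s]]
    if (!all(regulated %in% reactions)) return(FALSE)
  }
  TRUE
}

#' @rdname is_output_complete
#' @export
subnetwork_index <- function(net, chemicals, reactions) {
  nu <- stoichiometric_matrix(net)
  rsub <- match(reactions, colnames(nu))
  csub <- match(chemicals, rownames(nu))
  loops <- if (length(rsub) == 0) 0 else {
    length(rsub) - .int_rref(nu[, rsub, drop = FALSE])$rank
  }
  Q <- nrow(nu) - .int_rref(nu)$rank
  comp <- setdiff(seq_len(nrow(nu)), csub)
  cons_outside <- if (length(comp) == 0) 0 else {
    length(comp) - .int_rref(t(nu[comp, , drop = FALSE]))$rank
  }
  length(chemicals) - length(reactions) + loops - (Q - cons_outside)
}

#' Brute-force buffering-structure enumeration (oracle)
#'
#' Enumerates every (chemical subset, reaction subset) pair that is
#' output-complete with zero index, by exhaustive search. Exponential in
#' M + N; intended as the independent oracle for property tests on small
#' networks, not for analysis.
#'
#' @param net a `reaction_network` (use only when `M + N` is small).
#' @return List of `list(chemicals, reactions)` sorted canonically.
#' @export
enumerate_buffering_bruteforce <- function(net) {
  sids <- net$species$id
  rids <- vapply(net$reactions, `[[`, character(1), "id")
  sg <- rate_dependency_signs(net)
  dep <- (!is.na(sg) & sg != 0) | is.na(sg)
  out <- list()
  for (cmask in seq_len(2^length(sids)) - 1L) {
    chems <- sids[bitwAnd(cmask, bitwShiftL(1L, seq_along(sids) - 1L)) != 0]
    required <- if (length(chems) == 0) character(0) else {
      rids[rowSums(dep[, chems, drop = FALSE]) > 0]
    }
    optional <- setdiff(rids, required)
    for (omask in seq_len(2^length(optional)) - 1L) {
      extra <- optional[bitwAnd(omask, bitwShiftL(1L, seq_along(optional) - 1L)) != 0]
      reacs <- rids[rids %in% c(required, extra)]
      if (length(chems) + length(reacs) == 0) next
      if (subnetwork_index(net, chems, reacs) == 0) {
        out[[length(out) + 1L]] <- list(chemicals = sort(chems),
                                        reactions = sort(reacs))
      }
    }
  }
  keys <- vapply(out, function(s) {
    paste(paste(s$chemicals, collapse = ","), "|",
          paste(s$reactions, collapse = ","))
  }, character(1))
  out[order(keys)]
}

#' Inducing parameters and bifurcating chemicals of a determinant structure
#'
#' When the determinant of `Gamma_beta`'s block can reach zero, the
#' parameters able to drive it there are the rate parameters of reactions
#' (and the values of conserved quantities) in every determinant structure
#' from which `Gamma_beta` is reachable in the influence graph, including
#' itself; equivalently, all parameters outside any buffering structure
#' disjoint from `Gamma_beta`. The chemicals that can exhibit the resulting
#' bifurcation are those of the minimal buffering structure containing
#' `Gamma_beta`: its descendant closure.
#'
#' @param dec an `sba_decomposition`.
#' @param graph the matching influence graph.
#' @param beta block label (e.g. `"Gamma2"`) or index.
#' @return `inducing_parameters()`: list with `reactions` and
#'   `conserved`; `bifurcating_chemicals()`: character vector of species ids.
#' @export
inducing_parameters <- function(dec, graph, beta) {
  b <- .block_index(dec, beta)
  adj <- graph$adjacency
  anc <- .descendant_closure(t(adj), b)  # blocks that can reach b, plus b
  bl <- dec$blocks[sort(anc)]
  list(
    reactions = sort(unlist(lapply(bl, `[[`, "reactions"))),
    conserved = sort(unlist(lapply(bl, `[[`, "conserved_rows")))
  )
}

#' @rdname inducing_parameters
#' @export
bifurcating_chemicals <- function(dec, graph, beta) {
  b <- .block_index(dec, beta)
  desc <- .descendant_closure(graph$adjacency, b)
  sort(unlist(lapply(dec$blocks[desc], `[[`, "chemicals")))
}

.block_index <- function(dec, beta) {
  if (is.character(beta)) {
    b <- match(beta, vapply(dec$blocks, `[[`, character(1), "label"))
    if (is.na(b)) stop(sprintf("unknown block '%s'", beta))
    b
  } else as.integer(beta)
}

#' Full structural bifurcation report (the six-step procedure)
#'
#' Runs the whole topology-level analysis: (1) build the structural matrix,
#' (2) rearrange it to finest upper block-triangular form, (3) construct the
#' influence graph, (4) expand each diagonal block's determinant, (5)
#' classify which determinants can change sign and collect the inducing
#' parameters, (6) determine the bifurcating chemicals per condition.
#'
#' @param net a `reaction_network`.
#' @param C,D optional bases passed to [build_A()].
#' @param deletions optional list of `c(reaction, species)` pairs zeroed in A
#'   before the analysis (gene-deletion mutants).
#' @return Object of class `sba_report`.
#' @export
six_step_report <- function(net, C = NULL, D = NULL, deletions = NULL) {
  A <- build_A(net, C = C, D = D)
  if (!is.null(deletions)) A <- apply_deletion(A, deletions)
  dec <- block_triangularize(A)
  graph <- influence_graph(dec)
  buff <- buffering_structures(dec, graph)
  conditions <- list()
  blocks <- lapply(seq_along(dec$blocks), function(k) {
    b <- dec$blocks[[k]]
    poly <- symbolic_det(A, b$rows, b$cols)
    cls <- classify_sign(poly, A$signs)
    list(label = b$label, chemicals = b$chemicals, reactions = b$reactions,
         loop_cols = b$loop_cols, conserved_rows = b$conserved_rows,
         determinant = poly, determinant_text = format_spoly(poly),
         sign_class = cls)
  })
  for (k in seq_along(blocks)) {
    if (blocks[[k]]$sign_class %in% c("indeterminate", "identically_zero")) {
      ip <- inducing_parameters(dec, graph, k)
      conditions[[length(conditions) + 1L]] <- list(
        block = blocks[[k]]$label,
        condition = sprintf("det A_%s = %s = 0", blocks[[k]]$label,
                            blocks[[k]]$determinant_text),
        inducing_reactions = ip$reactions,
        inducing_conserved = ip$conserved,
        bifurcating_chemicals = bifurcating_chemicals(dec, graph, k)
      )
    }
  }
  structure(list(network = net, A = A, decomposition = dec,
                 influence = graph, buffering = buff,
                 blocks = blocks, conditions = conditions),
            class = "sba_report")
}

#' @export
print.sba_report <- function(x, ...) {
  cat("Structural bifurcation analysis\n")
  cat(sprintf("  network: %d species, %d reactions\n",
              n_species(x$network), n_reactions(x$network)))
  print(x$decomposition)
  print(x$influence)
  cat("block determinants:\n")
  for (b in x$blocks) {
    cat(sprintf("  det A_%s = %s   [%s]\n", b$label, b$determinant_text,
                b$sign_class))
  }
  if (length(x$conditions) == 0) {
    cat("no block determinant can change sign: no topology-permitted bifurcation\n")
  } else {
    cat("bifurcation conditions:\n")
    for (cond in x$conditions) {
      cat(sprintf("  %s\n    inducing parameters: reactions {%s}%s\n    bifurcating chemicals: {%s}\n",
                  cond$condition,
                  paste(cond$inducing_reactions, collapse = ", "),
                  if (length(cond$inducing_conserved) > 0)
                    paste0(", conserved {",
                           paste(cond$inducing_conserved, collapse = ", "), "}")
                  else "",
                  paste(cond$bifurcating_chemicals, collapse = ", ")))
    }
  }
  invisible(x)
}
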