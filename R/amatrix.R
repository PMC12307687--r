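#' Build the augmented structural matrix A
#'
#' The structural matrix is the square symbolic matrix
#' `[[dr/dx, C], [t(D), 0]]`: one row per reaction followed by one row per
#' conserved quantity, one column per chemical followed by one column per
#' reaction loop. The rate-derivative block holds one symbol `r(n,m)` per
#' (reaction, species) dependency, with a sign known from topology: positive
#' when the species is a reactant, the regulation sign when it is an
#' annotated regulator, unknown for combined or `"?"` roles. Its determinant
#' vanishes exactly where the reduced Jacobian determinant does, which makes
#' it a topology-level bifurcation indicator even when conserved quantities
#' force the standard Jacobian determinant to vanish identically.
#'
#' @param net a `reaction_network`.
#' @param C kernel basis; default automatic (localized primitive columns).
#' @param D cokernel basis; default automatic.
#' @param localize whether to localize automatic bases toward minimal
#'   supports before use (recommended; see [block_triangularize()]).
#' @return An object of class `amatrix`.
#' @export
build_A <- function(net, C = NULL, D = NULL, localize = TRUE) {
  nu <- stoichiometric_matrix(net)
  if (is.null(C)) {
    C <- kernel_basis(nu)
    if (localize) C <- localize_basis(C)
  } else {
    validate_basis(nu, C, "kernel")
  }
  if (is.null(D)) {
    D <- cokernel_basis(nu)
    if (localize) D <- localize_basis(D)
  } else {
    validate_basis(nu, D, "cokernel")
  }
  M <- nrow(nu); N <- ncol(nu); P <- ncol(C); Q <- ncol(D)
  if (M + P != N + Q) {
    stop("internal contract violation: structural matrix would not be square")
  }
  sid <- net$species$id
  rid <- colnames(nu)
  loop_ids <- if (P > 0) paste0("loop", seq_len(P)) else character(0)
  cons_ids <- if (Q > 0) paste0("eta", seq_len(Q)) else character(0)
  n_rows <- N + Q
  n_cols <- M + P
  sym <- matrix("", n_rows, n_cols)
  const <- matrix(0, n_rows, n_cols)
  rownames(sym) <- rownames(const) <- c(rid, cons_ids)
  colnames(sym) <- colnames(const) <- c(sid, loop_ids)
  sg <- rate_dependency_signs(net)
  signs <- numeric(0)
  for (i in seq_len(N)) {
    for (j in seq_len(M)) {
      if (sg[i, j] != 0 || is.na(sg[i, j])) {
        key <- sprintf("r(%s,%s)", rid[[i]], sid[[j]])
        sym[i, j] <- key
        signs[[key]] <- sg[i, j]
      }
    }
  }
  if (P > 0) const[seq_len(N), M + seq_len(P)] <- C
  if (Q > 0) const[N + seq_len(Q), seq_len(M)] <- t(D)
  structure(list(
    sym = sym, const = const, signs = signs,
    net = net, nu = nu, C = C, D = D,
    row_kind = c(rep("reaction", N), rep("conserved", Q)),
    col_kind = c(rep("species", M), rep("loop", P))
  ), class = "amatrix")
}

#' @export
print.amatrix <- function(x, ...) {
  cat(sprintf("amatrix: %d x %d (%d reactions + %d conserved rows; %d species + %d loop columns)\n",
              nrow(x$sym), ncol(x$sym),
              sum(x$row_kind == "reaction"), sum(x$row_kind == "conserved"),
              sum(x$col_kind == "species"), sum(x$col_kind == "loop")))
  cat(format_amatrix(x), sep = "\n")
  invisible(x)
}

#' Pretty-print the structural matrix
#'
#' @param A an `amatrix`.
#' @param latex render LaTeX array source instead of aligned text.
#' @return Character vector of lines.
#' @export
format_amatrix <- function(A, latex = FALSE) {
  ent <- matrix("", nrow(A$sym), ncol(A$sym))
  for (i in seq_len(nrow(ent))) {
    for (j in seq_len(ncol(ent))) {
      ent[i, j] <- if (nzchar(A$sym[i, j])) A$sym[i, j]
        else if (A$const[i, j] != 0) as.character(A$const[i, j])
        else if (latex) "" else "."
    }
  }
  if (latex) {
    body <- apply(ent, 1, paste, collapse = " & ")
    c(sprintf("\\begin{array}{%s}", paste(rep("c", ncol(ent)), collapse = "")),
      paste0(body, " \\\\"), "\\end{array}")
  } else {
    w <- apply(nchar(rbind(ent, colnames(A$sym))), 2, max)
    hdr <- paste(mapply(formatC, c("", colnames(A$sym)),
                        width = c(max(nchar(rownames(A$sym))), w)),
                 collapse = " ")
    rows <- vapply(seq_len(nrow(ent)), function(i) {
      paste(mapply(formatC, c(rownames(A$sym)[i], ent[i, ]),
                   width = c(max(nchar(rownames(A$sym))), w)),
            collapse = " ")
    }, character(1))
    c(hdr, rows)
  }
}

#' Zero-pattern of the structural matrix
#'
#' @param A an `amatrix`.
#' @return Logical matrix, `TRUE` where an entry is structurally nonzero.
#' @export
nonzero_pattern <- function(A) {
  nzchar(A$sym) | A$const != 0
}

#' Delete regulations by zeroing rate-derivative entries
#'
#' Models gene deletions that remove regulatory arrows: the listed symbols
#' `r(reaction, species)` are replaced by structural zeros; everything else
#' is untouched. Zeroing a reactant-derivative entry is allowed but warned
#' about, since it asserts a rate that ignores its own substrate.
#'
#' @param A an `amatrix`.
#' @param zeroed a list of `c(reaction_id, species_id)` pairs (or a 2-column
#'   character matrix).
#' @return The modified `amatrix`.
#' @export
apply_deletion <- function(A, zeroed) {
  if (is.matrix(zeroed)) {
    zeroed <- lapply(seq_len(nrow(zeroed)), function(i) zeroed[i, ])
  }
  for (pair in zeroed) {
    i <- match(pair[[1]], rownames(A$sym))
    j <- match(pair[[2]], colnames(A$sym))
    if (is.na(i) || is.na(j)) {
      stop(sprintf("unknown entry (%s, %s)", pair[[1]], pair[[2]]))
    }
    key <- A$sym[i, j]
    if (nzchar(key)) {
      if (!is.na(A$signs[[key]]) && A$signs[[key]] > 0) {
        warning(sprintf("zeroing reactant/activator derivative %s", key))
      }
      A$sym[i, j] <- ""
      A$signs <- A$signs[names(A$signs) != key]
      # keep the embedded network consistent: a zeroed regulator arrow is
      # removed from the topology (reactant roles cannot be removed)
      ri <- match(pair[[1]],
                  vapply(A$net$reactions, `[[`, character(1), "id"))
      regs <- A$net$reactions[[ri]]$regulators
      if (pair[[2]] %in% names(regs)) {
        A$net$reactions[[ri]]$regulators <- regs[names(regs) != pair[[2]]]
      }
    }
  }
  A
}

#' Symbolic determinant of a block of A
#'
#' Expands the determinant of the sub-matrix of `A` given by `rows` and
#' `cols` (in A's own ordering) into a fully expanded polynomial over the
#' rate-derivative symbols with integer coefficients. Expansion is recursive
#' along the sparsest column, which is fast for the sparse patterns
#' structural matrices have.
#'
#' @param A an `amatrix`.
#' @param rows,cols row/column indices or names of the block; default the
#'   whole matrix.
#' @return Named numeric vector polynomial (see [classify_sign()]), with the
#'   symbol sign table attached as attribute `signs`.
#' @export
symbolic_det <- function(A, rows = NULL, cols = NULL) {
  if (is.null(rows)) rows <- seq_len(nrow(A$sym))
  if (is.null(cols)) cols <- seq_len(ncol(A$sym))
  if (is.character(rows)) rows <- match(rows, rownames(A$sym))
  if (is.character(cols)) cols <- match(cols, colnames(A$sym))
  if (length(rows) != length(cols)) stop("block not square")
  poly <- .det_rec(A$sym, A$const, rows, cols)
  attr(poly, "signs") <- A$signs
  poly
}

.det_rec <- function(sym, const, rows, cols) {
  n <- length(rows)
  if (n == 0) return(spoly_const(1))
  nz <- nzchar(sym[rows, cols, drop = FALSE]) |
    const[rows, cols, drop = FALSE] != 0
  counts <- colSums(nz)
  j <- which.min(counts)
  if (counts[[j]] == 0) return(spoly_zero())
  col <- cols[[j]]
  rest_cols <- cols[-j]
  acc <- spoly_zero()
  sgn <- 1
  for (ii in seq_len(n)) {
    row <- rows[[ii]]
    if (nz[ii, j]) {
      minor <- .det_rec(sym, const, rows[-ii], rest_cols)
      term <- spoly_mul_entry(minor, sym[row, col], const[row, col])
      parity <- if ((ii + j) %% 2 == 0) 1 else -1
      acc <- spoly_add(acc, spoly_scale(term, parity))
    }
  }
  acc
}

#' Numeric instantiation of the structural matrix
#'
#' Replaces each symbol by a supplied signed value (for example the partial
#' derivatives of a kinetic model at a state, or random draws).
#'
#' @param A an `amatrix`.
#' @param values named numeric vector keyed by symbol id `r(n,m)`.
#' @return Numeric matrix of the same shape.
#' @export
instantiate_A <- function(A, values) {
  out <- A$const
  idx <- which(nzchar(A$sym))
  keys <- A$sym[idx]
  miss <- setdiff(keys, names(values))
  if (length(miss) > 0) {
    stop(sprintf("missing value for symbol %s", miss[[1]]))
  }
  out[idx] <- values[keys]
  out
}

#' Random signed symbol values
#'
#' Draws positive magnitudes uniformly on (0.1, 2) and applies each symbol's
#' known sign; unknown signs get a random sign. Used by the numeric
#' cross-checks of the symbolic layer.
#'
#' @param A an `amatrix`.
#' @return Named numeric vector of signed values.
#' @export
random_symbol_values <- function(A) {
  keys <- names(A$signs)
  mags <- stats::runif(length(keys), 0.1, 2)
  sg <- A$signs
  sg[is.na(sg)] <- sample(c(-1, 1), sum(is.na(sg)), replace = TRUE)
  stats::setNames(mags * sg, keys)
}

#' Structural sensitivity: response to a localized parameter change
#'
#' Solves `A %*% response = -e_source` for a numerically instantiated
#' structural matrix: the chemical components of `response` are the
#' steady-state concentration shifts per unit change of a parameter of the
#' source reaction (or of the source conserved quantity), the loop components
#' the flux-coefficient shifts. Responses vanish outside the minimal
#' buffering structure containing the source.
#'
#' @param A_num numeric matrix from [instantiate_A()] (row/col names kept).
#' @param source a reaction id or conserved-row id naming the perturbed row.
#' @return Named numeric response vector over chemicals and loop columns.
#' @export
sensitivity_solve <- function(A_num, source) {
  i <- match(source, rownames(A_num))
  if (is.na(i)) stop(sprintf("unknown source '%s'", source))
  e <- numeric(nrow(A_num)); e[i] <- 1
  resp <- tryCatch(solve(A_num, -e),
                   error = function(err) {
                     stop("structural matrix singular: at bifurcation or structurally degenerate")
                   })
  stats::setNames(as.numeric(resp), colnames(A_num))
}
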