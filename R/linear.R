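#' @name linear-structure
#' @title Exact linear structure of a stoichiometric matrix
#' @description
#' Kernel (reaction loops) and cokernel (conserved moieties) bases, the image
#' basis on the stoichiometric subspace, and the constant block matrix
#' Lambda = `[[nu, D], [C^T, 0]]`. All bases are computed by exact
#' fraction-free integer elimination, scaled to primitive integer columns
#' (entry gcd 1) with the first nonzero entry positive, so determinants and
#' Gram matrices are reproducible integers. User-supplied bases (for example
#' hand-picked loop vectors) are accepted everywhere a basis is taken and are
#' validated, never altered.
NULL

.gcd2 <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0) { t <- a %% b; a <- b; b <- t }
  a
}

.gcdv <- function(v) {
  g <- 0
  for (x in v) {
    g <- .gcd2(g, x)
    if (g == 1) break
  }
  g
}

# Integer row echelon with full reduction (above and below pivots).
# Rows are cross-multiplied and re-divided by their gcd at every step, so all
# entries stay exact integers. Returns the reduced matrix, pivot columns and
# the originating pivot row of each.
.int_rref <- function(m) {
  m <- matrix(as.numeric(m), nrow = nrow(m))
  nr <- nrow(m); nc <- ncol(m)
  pivots <- integer(0)
  row <- 1L
  for (col in seq_len(nc)) {
    if (row > nr) break
    sel <- which(m[row:nr, col] != 0)
    if (length(sel) == 0) next
    p <- row + sel[[1]] - 1L
    if (p != row) m[c(row, p), ] <- m[c(p, row), ]
    pv <- m[row, col]
    for (i in seq_len(nr)) {
      if (i != row && m[i, col] != 0) {
        m[i, ] <- pv * m[i, ] - m[i, col] * m[row, ]
        g <- .gcdv(m[i, ])
        if (g > 1) m[i, ] <- m[i, ] / g
      }
    }
    if (m[row, col] < 0) m[row, ] <- -m[row, ]
    g <- .gcdv(m[row, ])
    if (g > 1) m[row, ] <- m[row, ] / g
    pivots <- c(pivots, col)
    row <- row + 1L
  }
  list(m = m, pivots = pivots, rank = length(pivots))
}

# Primitive integer nullspace basis of an integer matrix, one column per free
# column of the RREF; deterministic for fixed input.
.int_nullspace <- function(m) {
  nc <- ncol(m)
  if (nc == 0) return(matrix(0, nrow = 0, ncol = 0))
  if (nrow(m) == 0) {
    return(diag(nc))
  }
  rr <- .int_rref(m)
  free <- setdiff(seq_len(nc), rr$pivots)
  basis <- matrix(0, nrow = nc, ncol = length(free))
  if (length(free) == 0) return(basis)
  for (j in seq_along(free)) {
    f <- free[[j]]
    # rational solution with x[f] = 1: x[pivcol_i] = -m[i, f] / m[i, pivcol_i]
    dens <- vapply(seq_along(rr$pivots),
                   function(i) rr$m[i, rr$pivots[[i]]], numeric(1))
    scale <- 1
    for (d in dens) scale <- scale * d / .gcd2(scale, d)  # lcm
    v <- numeric(nc)
    v[f] <- scale
    for (i in seq_along(rr$pivots)) {
      v[rr$pivots[[i]]] <- -rr$m[i, f] * scale / dens[[i]]
    }
    g <- .gcdv(v)
    if (g > 1) v <- v / g
    fn <- v[which(v != 0)[1]]
    if (!is.na(fn) && fn < 0) v <- -v
    basis[, j] <- v
  }
  basis
}

#' Kernel and cokernel bases
#'
#' `kernel_basis()` returns an integer N x P matrix `C` with `nu %*% C == 0`;
#' its columns are steady-state flux modes, realizable as closed loops of the
#' reaction graph when the external reservoir is taken as a node.
#' `cokernel_basis()` returns an integer M x Q matrix `D` with
#' `t(nu) %*% D == 0`; the conserved quantities of the dynamics are
#' `eta = t(D) %*% x`.
#'
#' @param nu integer stoichiometric matrix (species x reactions).
#' @return Integer matrix with attribute `provenance = "automatic"`. Zero
#'   columns (P or Q equal to 0) give a matrix with zero columns.
#' @export
kernel_basis <- function(nu) {
  b <- .int_nullspace(nu)
  if (nrow(b) > 0) rownames(b) <- colnames(nu)
  if (ncol(b) > 0) colnames(b) <- paste0("c", seq_len(ncol(b)))
  attr(b, "provenance") <- "automatic"
  b
}

#' @rdname kernel_basis
#' @export
cokernel_basis <- function(nu) {
  b <- .int_nullspace(t(nu))
  if (nrow(b) > 0) rownames(b) <- rownames(nu)
  if (ncol(b) > 0) colnames(b) <- paste0("d", seq_len(ncol(b)))
  attr(b, "provenance") <- "automatic"
  b
}

#' Validate a user-supplied basis
#'
#' Checks that `basis` has full column rank, annihilates `nu` on the correct
#' side, and spans the full kernel (or cokernel).
#'
#' @param nu stoichiometric matrix.
#' @param basis candidate integer basis matrix.
#' @param side `"kernel"` or `"cokernel"`.
#' @return The basis, invisibly, with `provenance = "user-supplied"`.
#' @export
validate_basis <- function(nu, basis, side = c("kernel", "cokernel")) {
  side <- match.arg(side)
  m <- if (side == "kernel") nu else t(nu)
  if (ncol(basis) > 0 && max(abs(m %*% basis)) != 0) {
    stop(sprintf("invalid %s basis: does not annihilate the matrix", side))
  }
  expected <- ncol(m) - .int_rref(m)$rank
  if (ncol(basis) != expected) {
    stop(sprintf("invalid %s basis: %d columns, expected %d",
                 side, ncol(basis), expected))
  }
  if (ncol(basis) > 0 && .int_rref(t(basis))$rank != ncol(basis)) {
    stop(sprintf("invalid %s basis: columns not independent", side))
  }
  attr(basis, "provenance") <- "user-supplied"
  invisible(basis)
}

#' Exact determinant of an integer matrix
#'
#' Fraction-free Bareiss elimination; exact for integer input whose
#' intermediate values stay below 2^53 (always true for the network sizes
#' this package targets).
#'
#' @param m square integer matrix.
#' @return The determinant as a (integer-valued) double.
#' @export
det_exact <- function(m) {
  m <- matrix(as.numeric(m), nrow = nrow(m))
  n <- nrow(m)
  if (n != ncol(m)) stop("det_exact: matrix not square")
  if (n == 0) return(1)
  sign <- 1
  prev <- 1
  for (k in seq_len(n - 1)) {
    if (m[k, k] == 0) {
      sel <- which(m[(k + 1):n, k] != 0)
      if (length(sel) == 0) return(0)
      p <- k + sel[[1]]
      m[c(k, p), ] <- m[c(p, k), ]
      sign <- -sign
    }
    for (i in (k + 1):n) {
      for (j in (k + 1):n) {
        m[i, j] <- (m[i, j] * m[k, k] - m[i, k] * m[k, j]) / prev
      }
      m[i, k] <- 0
    }
    prev <- m[k, k]
  }
  sign * m[n, n]
}

#' Image basis and rational pseudo-inverses
#'
#' `image_basis()` returns `V`, the pivot columns of `nu` under exact column
#' reduction, spanning the stoichiometric subspace im(nu). Any other choice
#' of `V` with the same span yields a similar reduced Jacobian, so
#' determinants are unchanged. `pseudo_inverse()` returns
#' `(t(B) B)^{-1} t(B)`.
#'
#' @param nu stoichiometric matrix.
#' @return `image_basis()`: integer matrix M x (M - Q).
#' @export
image_basis <- function(nu) {
  piv <- .int_rref(nu)$pivots # pivot columns under row reduction span im(nu)
  v <- nu[, piv, drop = FALSE]
  storage.mode(v) <- "double"
  v
}

#' @param b matrix with independent columns.
#' @rdname image_basis
#' @export
pseudo_inverse <- function(b) {
  if (ncol(b) == 0) return(matrix(0, nrow = 0, ncol = nrow(b)))
  solve(crossprod(b), t(b))
}

#' The constant block matrix Lambda
#'
#' Assembles the square (M + P) x (N + Q) matrix `[[nu, D], [t(C), 0]]`
#' relating the structural matrix to the reduced Jacobian: the determinant
#' identity states det A = det(t(D) D) det(t(C) C) / det(Lambda) * det Jg.
#'
#' @param nu stoichiometric matrix, M x N.
#' @param C kernel basis, N x P.
#' @param D cokernel basis, M x Q.
#' @return Square numeric matrix with labeled rows and columns.
#' @export
build_lambda <- function(nu, C, D) {
  M <- nrow(nu); N <- ncol(nu)
  P <- ncol(C); Q <- ncol(D)
  if (nrow(C) != N) stop("contract violation: C must have one row per reaction")
  if (nrow(D) != M) stop("contract violation: D must have one row per species")
  if (M + P != N + Q) {
    stop("contract violation: M + P != N + Q; bases do not match nu")
  }
  top <- cbind(nu, D)
  bottom <- cbind(t(C), matrix(0, nrow = P, ncol = Q))
  lam <- rbind(top, bottom)
  lbl <- function(prefix, n) {
    if (n > 0) paste0(prefix, seq_len(n)) else character(0)
  }
  sp_lab <- if (is.null(rownames(nu))) lbl("x", M) else rownames(nu)
  rx_lab <- if (is.null(colnames(nu))) lbl("r", N) else colnames(nu)
  rownames(lam) <- c(sp_lab, lbl("loop_", P))
  colnames(lam) <- c(rx_lab, lbl("cons_", Q))
  lam
}

#' Reduced coordinates on the stoichiometric subspace
#'
#' Splits a concentration vector into dynamic coordinates `xi` along im(nu)
#' and conserved values `eta = t(D) x`, via `x = V xi + t(pseudo_inverse(D)) eta`.
#' `lift_coordinates()` inverts the split.
#'
#' @param x concentration vector of length M.
#' @param V image basis (see [image_basis()]).
#' @param D cokernel basis.
#' @return `reduce_coordinates()`: list with `xi` and `eta`;
#'   `lift_coordinates()`: the concentration vector.
#' @export
reduce_coordinates <- function(x, V, D) {
  eta <- if (ncol(D) > 0) as.numeric(t(D) %*% x) else numeric(0)
  xi <- as.numeric(pseudo_inverse(V) %*% x)
  list(xi = xi, eta = eta)
}

#' @param xi dynamic coordinates, length M - Q.
#' @param eta conserved values, length Q.
#' @rdname reduce_coordinates
#' @export
lift_coordinates <- function(xi, eta, V, D) {
  x <- as.numeric(V %*% xi)
  if (ncol(D) > 0) x <- x + as.numeric(t(pseudo_inverse(D)) %*% eta)
  x
}

# Greedy integer column reduction toward minimal supports. Replaces a column
# by an integer combination with another column whenever that strictly
# shrinks its support; the span is unchanged. Localized bases make the
# block-triangular decomposition agree with the basis-independent
# restricted-null-space counting used by the brute-force oracle.
localize_basis <- function(b) {
  if (ncol(b) < 2) return(b)
  b <- matrix(as.numeric(b), nrow = nrow(b), dimnames = dimnames(b))
  repeat {
    changed <- FALSE
    for (i in seq_len(ncol(b))) {
      for (j in seq_len(ncol(b))) {
        if (i == j) next
        supp_i <- which(b[, i] != 0)
        best <- NULL
        # try eliminating each shared entry m: cand = b[m,j]*b[,i] - b[m,i]*b[,j]
        for (m in supp_i) {
          if (b[m, j] == 0) next
          cand <- b[m, j] * b[, i] - b[m, i] * b[, j]
          if (all(cand == 0)) next
          if (sum(cand != 0) < length(supp_i)) {
            g <- .gcdv(cand)
            if (g > 1) cand <- cand / g
            if (cand[which(cand != 0)[1]] < 0) cand <- -cand
            best <- cand
            break
          }
        }
        if (!is.null(best)) {
          b[, i] <- best
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  b
}
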