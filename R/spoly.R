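# Sparse multivariate polynomials over rate-derivative symbols.
#
# A polynomial is a named numeric vector: the name is the monomial key
# (symbol ids sorted and joined by "*", "1" for the constant monomial) and
# the value its integer coefficient. Symbols stand for the signed partial
# derivatives of rate functions with respect to concentrations, exactly as
# the structural matrix uses them; their known signs live in a separate
# symbol table and are only consulted when classifying a polynomial. Symbols
# arising from the same rate function are treated as algebraically
# independent: no cancellation beyond the explicit sign structure is modeled.

spoly_zero <- function() stats::setNames(numeric(0), character(0))

spoly_const <- function(k) {
  if (k == 0) return(spoly_zero())
  stats::setNames(as.numeric(k), "1")
}

spoly_sym <- function(sym, coef = 1) {
  if (coef == 0) return(spoly_zero())
  stats::setNames(as.numeric(coef), sym)
}

spoly_add <- function(a, b) {
  if (length(a) == 0) return(b)
  if (length(b) == 0) return(a)
  keys <- union(names(a), names(b))
  v <- stats::setNames(numeric(length(keys)), keys)
  v[names(a)] <- a
  v[names(b)] <- v[names(b)] + b
  v[v != 0]
}

spoly_scale <- function(a, k) {
  if (k == 0) return(spoly_zero())
  a * k
}

# multiply polynomial by a single matrix entry (symbol or constant)
spoly_mul_entry <- function(a, sym, const) {
  if (length(a) == 0) return(a)
  if (nzchar(sym)) {
    keys <- vapply(names(a), function(k) {
      parts <- if (k == "1") character(0) else strsplit(k, "*", fixed = TRUE)[[1]]
      paste(sort(c(parts, sym)), collapse = "*")
    }, character(1))
    out <- stats::setNames(as.numeric(a), keys)
    # duplicate keys are impossible when each matrix entry symbol is distinct,
    # but collapse defensively
    if (anyDuplicated(keys)) out <- tapply(out, names(out), sum)
    out[out != 0]
  } else {
    spoly_scale(a, const)
  }
}

spoly_equal <- function(a, b) {
  a <- a[a != 0]; b <- b[b != 0]
  length(a) == length(b) && setequal(names(a), names(b)) &&
    all(a[names(b)] == b)
}

# TRUE if a == b or a == -b (block determinants are pinned up to the
# permutation-pair sign)
spoly_equal_up_to_sign <- function(a, b) {
  spoly_equal(a, b) || spoly_equal(a, spoly_scale(b, -1))
}

format_spoly <- function(a) {
  if (length(a) == 0) return("0")
  keys <- sort(names(a))
  parts <- vapply(seq_along(keys), function(i) {
    k <- keys[[i]]; c0 <- a[[k]]
    mono <- if (k == "1") "" else gsub("*", "·", k, fixed = TRUE)
    mag <- abs(c0)
    coef <- if (mag == 1 && nzchar(mono)) "" else as.character(mag)
    body <- paste0(coef, if (nzchar(coef) && nzchar(mono)) "·" else "", mono)
    if (i == 1) {
      paste0(if (c0 < 0) "-" else "", body)
    } else {
      paste0(if (c0 < 0) " - " else " + ", body)
    }
  }, character(1))
  paste(parts, collapse = "")
}

# evaluate a polynomial given named numeric symbol values
spoly_eval <- function(a, values) {
  if (length(a) == 0) return(0)
  s <- 0
  for (k in names(a)) {
    if (k == "1") {
      s <- s + a[[k]]
    } else {
      syms <- strsplit(k, "*", fixed = TRUE)[[1]]
      s <- s + a[[k]] * prod(values[syms])
    }
  }
  s
}

#' Classify the sign of a block determinant polynomial
#'
#' Uses the monomial-sign test: each monomial's effective sign is the sign of
#' its coefficient times the product of the known signs of its symbols. If
#' every monomial is positive the polynomial is positive for all admissible
#' rate functions, and symmetrically for negative. The test is a sufficient
#' condition only: `indeterminate` means the determinant *can* change sign
#' for some kinetics, which is precisely the bifurcation condition the
#' analysis reports.
#'
#' @param poly polynomial as returned by [symbolic_det()].
#' @param signs named vector of symbol signs (+1, -1, or NA for unknown),
#'   e.g. the `signs` field of an `amatrix`.
#' @return One of `"always_positive"`, `"always_negative"`,
#'   `"indeterminate"`, `"identically_zero"`.
#' @export
classify_sign <- function(poly, signs) {
  poly <- poly[poly != 0]
  if (length(poly) == 0) return("identically_zero")
  mono_sign <- vapply(names(poly), function(k) {
    s <- sign(poly[[k]])
    if (k != "1") {
      for (sym in strsplit(k, "*", fixed = TRUE)[[1]]) {
        sg <- signs[[sym]]
        if (is.na(sg)) return(NA_real_)
        s <- s * sg
      }
    }
    s
  }, numeric(1))
  if (anyNA(mono_sign)) return("indeterminate")
  if (all(mono_sign > 0)) return("always_positive")
  if (all(mono_sign < 0)) return("always_negative")
  "indeterminate"
}
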