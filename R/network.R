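#' Reaction networks with signed regulations
#'
#' A reaction network is an ordered list of species and an ordered list of
#' reactions. Each reaction has integer reactant and product stoichiometries
#' and, optionally, regulators: species whose concentration modulates the
#' rate without being consumed or produced. Regulator signs are `"+"`
#' (activation), `"-"` (inhibition) or `"?"` (unknown). The external
#' reservoir is implicit: an inflow has an empty reactant side and an outflow
#' an empty product side; no reservoir pseudo-species is ever created.
#'
#' Species and reaction order as written define the row and column order of
#' every matrix derived from the network; no function reorders them silently.
#'
#' @param species data frame with columns `id` and (optionally) `name`, or a
#'   character vector of ids.
#' @param reactions list of objects built by [reaction()].
#' @param metadata free-form named list carried along unmodified.
#' @return An object of class `reaction_network`.
#' @examples
#' net <- reaction_network(
#'   species = c("A", "B"),
#'   reactions = list(
#'     reaction("R1", products = c(A = 1)),
#'     reaction("R2", reactants = c(A = 1), products = c(B = 1),
#'              regulators = c(B = "+")),
#'     reaction("R3", reactants = c(B = 1), products = c(A = 1)),
#'     reaction("R4", reactants = c(A = 1))
#'   )
#' )
#' stoichiometric_matrix(net)
#' @export
reaction_network <- function(species, reactions, metadata = list()) {
  if (is.character(species)) {
    species <- data.frame(id = species, name = species,
                          stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(species), "id" %in% names(species))
  if (is.null(species$name)) species$name <- species$id
  species <- species[, c("id", "name"), drop = FALSE]
  rownames(species) <- NULL
  if (any(!nzchar(species$id))) stop("schema error: empty species id")
  dup <- species$id[duplicated(species$id)]
  if (length(dup) > 0) {
    stop(sprintf("schema error: duplicate species id '%s'", dup[[1]]))
  }
  if (!is.list(reactions)) stop("schema error: reactions must be a list")
  rids <- vapply(reactions, function(r) r$id, character(1))
  dup <- rids[duplicated(rids)]
  if (length(dup) > 0) {
    stop(sprintf("schema error: duplicate reaction id '%s'", dup[[1]]))
  }
  for (r in reactions) {
    refs <- unique(c(names(r$reactants), names(r$products), names(r$regulators)))
    missing <- setdiff(refs, species$id)
    if (length(missing) > 0) {
      stop(sprintf("schema error: reaction '%s' references unknown species '%s'",
                   r$id, missing[[1]]))
    }
  }
  structure(
    list(species = species, reactions = reactions, metadata = metadata),
    class = "reaction_network"
  )
}

#' Build a single reaction
#'
#' @param id unique reaction id.
#' @param reactants,products named integer vectors, species id to positive
#'   integer coefficient. May be empty (reservoir side).
#' @param regulators named character vector, species id to `"+"`, `"-"` or
#'   `"?"`.
#' @return A list of class `rn_reaction`.
#' @export
reaction <- function(id, reactants = integer(), products = integer(),
                     regulators = character()) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id)) {
    stop("schema error: reaction id must be a nonempty string")
  }
  reactants <- .check_stoich(reactants, id)
  products <- .check_stoich(products, id)
  if (length(regulators) > 0) {
    regulators <- vapply(regulators, as.character, character(1))
    bad <- setdiff(unique(regulators), c("+", "-", "?"))
    if (length(bad) > 0) {
      stop(sprintf("schema error: reaction '%s' regulator sign '%s' (use +, -, ?)",
                   id, bad[[1]]))
    }
  } else {
    regulators <- character()
  }
  if (length(reactants) + length(products) + length(regulators) == 0L) {
    stop(sprintf("schema error: reaction '%s' is empty", id))
  }
  structure(list(id = id, reactants = reactants, products = products,
                 regulators = regulators),
            class = "rn_reaction")
}

.check_stoich <- function(v, rid) {
  if (length(v) == 0) return(integer())
  if (is.null(names(v)) || any(!nzchar(names(v)))) {
    stop(sprintf("schema error: reaction '%s' has unnamed stoichiometry", rid))
  }
  if (any(abs(v - round(v)) > 0) || any(v <= 0)) {
    stop(sprintf("schema error: reaction '%s' has non positive-integer stoichiometry",
                 rid))
  }
  stats::setNames(as.integer(v), names(v))
}

#' @export
print.reaction_network <- function(x, ...) {
  cat(sprintf("reaction_network: %d species, %d reactions\n",
              nrow(x$species), length(x$reactions)))
  for (r in x$reactions) {
    lhs <- .side_str(r$reactants)
    rhs <- .side_str(r$products)
    reg <- if (length(r$regulators) > 0) {
      paste0("  [", paste0(names(r$regulators), r$regulators, collapse = " "), "]")
    } else ""
    cat(sprintf("  %s: %s -> %s%s\n", r$id, lhs, rhs, reg))
  }
  invisible(x)
}

.side_str <- function(side) {
  if (length(side) == 0) return("0")
  paste(ifelse(side == 1L, names(side), paste0(side, " ", names(side))),
        collapse = " + ")
}

#' Number of species / reactions
#' @param net a `reaction_network`.
#' @return integer count.
#' @export
n_species <- function(net) nrow(net$species)

#' @rdname n_species
#' @export
n_reactions <- function(net) length(net$reactions)

#' Stoichiometric matrix
#'
#' Returns the M x N integer matrix whose (m, n) entry is the product
#' coefficient minus the reactant coefficient of species m in reaction n.
#' Columns generate the right-hand side of the concentration ODE; regulator
#' annotations never enter (they affect the structural matrix built by
#' [build_A()], not stoichiometry).
#'
#' @param net a `reaction_network`.
#' @return integer matrix with species ids as row names and reaction ids as
#'   column names.
#' @export
stoichiometric_matrix <- function(net) {
  sid <- net$species$id
  nu <- matrix(0L, nrow = length(sid), ncol = length(net$reactions),
               dimnames = list(sid, vapply(net$reactions, `[[`, character(1), "id")))
  for (j in seq_along(net$reactions)) {
    r <- net$reactions[[j]]
    if (length(r$products) > 0) {
      nu[names(r$products), j] <- nu[names(r$products), j] + r$products
    }
    if (length(r$reactants) > 0) {
      nu[names(r$reactants), j] <- nu[names(r$reactants), j] - r$reactants
    }
  }
  nu
}

#' Read and write the package network format
#'
#' The on-disk format is JSON with top-level keys `species` (list of
#' `{id, name}`), `reactions` (list of
#' `{id, reactants: {id: int}, products: {id: int}, regulators: {id: "+"|"-"|"?"}}`)
#' and `metadata`. Parsing and serialization are inverse to each other and
#' preserve declaration order.
#'
#' @param text JSON string, or a path to a file when `file = TRUE`.
#' @param file whether `text` names a file.
#' @return `parse_network()` a `reaction_network`; `serialize_network()` a
#'   JSON string.
#' @export
parse_network <- function(text, file = FALSE) {
  doc <- tryCatch(
    jsonlite::fromJSON(if (file) file(text) else text, simplifyVector = FALSE),
    error = function(e) stop(sprintf("schema error: invalid JSON (%s)",
                                     conditionMessage(e)))
  )
  if (is.null(doc$species)) stop("schema error: missing 'species'")
  sp <- data.frame(
    id = vapply(doc$species, function(s) as.character(s$id), character(1)),
    name = vapply(doc$species, function(s) {
      as.character(if (is.null(s$name)) s$id else s$name)
    }, character(1)),
    stringsAsFactors = FALSE
  )
  reactions <- lapply(doc$reactions, function(r) {
    to_stoich <- function(x) {
      if (length(x) == 0) return(integer())
      vals <- vapply(x, function(v) {
        if (!is.numeric(v) || abs(v - round(v)) > 0) {
          stop(sprintf("schema error: non-integer stoichiometry in reaction '%s'",
                       r$id))
        }
        as.integer(v)
      }, integer(1))
      stats::setNames(vals, names(x))
    }
    reg <- if (length(r$regulators) == 0) character() else {
      stats::setNames(vapply(r$regulators, as.character, character(1)),
                      names(r$regulators))
    }
    reaction(as.character(r$id),
             reactants = to_stoich(r$reactants),
             products = to_stoich(r$products),
             regulators = reg)
  })
  meta <- if (is.null(doc$metadata)) list() else doc$metadata
  reaction_network(sp, reactions, metadata = meta)
}

#' @param net a `reaction_network`.
#' @param path optional file path; when given the document is also written
#'   there.
#' @rdname parse_network
#' @export
serialize_network <- function(net, path = NULL) {
  doc <- list(
    species = lapply(seq_len(nrow(net$species)), function(i) {
      list(id = net$species$id[[i]], name = net$species$name[[i]])
    }),
    reactions = lapply(net$reactions, function(r) {
      list(id = r$id,
           reactants = as.list(r$reactants),
           products = as.list(r$products),
           regulators = as.list(r$regulators))
    }),
    metadata = net$metadata
  )
  txt <- jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (!is.null(path)) writeLines(txt, path)
  invisible_or <- function(x) if (is.null(path)) x else invisible(x)
  invisible_or(as.character(txt))
}

#' Read a network from a TSV edge list
#'
#' Convenience reader for hand-authored networks: one row per edge with
#' columns `reaction`, `role` (`reactant`, `product`, or `regulator`),
#' `species`, `value` (integer coefficient for stoichiometric edges; `+`,
#' `-`, `?` for regulatory edges). Species order is first appearance;
#' reaction order likewise.
#'
#' @param path TSV file path.
#' @return A `reaction_network`.
#' @export
read_network_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("reaction", "role", "species", "value")
  if (!all(need %in% names(tab))) {
    stop("schema error: TSV must have columns reaction, role, species, value")
  }
  rids <- unique(tab$reaction)
  sids <- unique(tab$species)
  reactions <- lapply(rids, function(rid) {
    rows <- tab[tab$reaction == rid, , drop = FALSE]
    pick <- function(role) {
      sel <- rows[rows$role == role, , drop = FALSE]
      if (nrow(sel) == 0) return(integer())
      v <- suppressWarnings(as.numeric(sel$value))
      if (any(is.na(v))) {
        stop(sprintf("schema error: non-integer stoichiometry in reaction '%s'", rid))
      }
      stats::setNames(v, sel$species)
    }
    regs <- rows[rows$role == "regulator", , drop = FALSE]
    reaction(rid,
             reactants = pick("reactant"),
             products = pick("product"),
             regulators = if (nrow(regs) == 0) character() else
               stats::setNames(regs$value, regs$species))
  })
  reaction_network(sids, reactions)
}

# Signed dependency pattern of rates on species: +1 reactant or positive
# regulator, -1 negative regulator, NA unknown (explicit "?" or combined
# reactant+signed-regulator roles, whose contributions can conflict), 0 none.
rate_dependency_signs <- function(net) {
  sid <- net$species$id
  rid <- vapply(net$reactions, `[[`, character(1), "id")
  sg <- matrix(0, nrow = length(rid), ncol = length(sid),
               dimnames = list(rid, sid))
  for (i in seq_along(net$reactions)) {
    r <- net$reactions[[i]]
    for (s in names(r$reactants)) sg[i, s] <- 1
    for (s in names(r$regulators)) {
      want <- switch(r$regulators[[s]], "+" = 1, "-" = -1, "?" = NA_real_)
      if (s %in% names(r$reactants)) {
        sg[i, s] <- NA_real_  # combined role: sign not determined by topology
      } else {
        sg[i, s] <- want
      }
    }
  }
  sg
}
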