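#' Create a metabolic reaction
#'
#' A reaction is a directed hyperarc: a named vector of substrate
#' coefficients (tail) and a named vector of product coefficients (head).
#' Coefficients are strictly positive reals; a compound may not appear on
#' both sides (the hyperarc model assumes disjoint sides, and net-cancelling
#' would silently change the network's semantics).
#'
#' @param id unique reaction identifier.
#' @param substrates named numeric vector, compound id -> coefficient.
#' @param products named numeric vector, compound id -> coefficient.
#' @param reversible logical; reversible reactions are split by
#'   [normalize_network()].
#' @param origin optional provenance tag (set by the transformations).
#' @return an object of class `mnet_reaction`.
#' @export
#' @examples
#' reaction("r1", c(c1 = 1, c2 = 2), c(c3 = 1))
reaction <- function(id, substrates = numeric(0), products = numeric(0),
                     reversible = FALSE, origin = NULL) {
  substrates <- unlist(substrates)
  products <- unlist(products)
  if (!is.character(id) || length(id) != 1L || !nzchar(id)) {
    stop("reaction id must be a non-empty string")
  }
  for (side in list(substrates, products)) {
    if (length(side)) {
      if (is.null(names(side)) || any(!nzchar(names(side)))) {
        stop("reaction '", id, "': coefficients must be named by compound id")
      }
      if (any(!is.finite(side)) || any(side <= 0)) {
        stop("reaction '", id, "': stoichiometric coefficients must be > 0")
      }
    }
  }
  both <- intersect(names(substrates), names(products))
  if (length(both)) {
    stop("reaction '", id, "': compound(s) ", paste(both, collapse = ", "),
         " appear on both sides; not supported")
  }
  if (anyDuplicated(names(substrates)) || anyDuplicated(names(products))) {
    stop("reaction '", id, "': duplicated compound within one side")
  }
  ord <- function(s) if (length(s)) s[order(names(s))] else stats::setNames(numeric(0), character(0))
  structure(list(id = id,
                 substrates = ord(substrates),
                 products = ord(products),
                 reversible = isTRUE(reversible), origin = origin),
            class = "mnet_reaction")
}

#' Create a metabolic network
#'
#' A network is a set of compounds, a list of reactions, and designated
#' source and target compound sets. Compounds are kept in stable first-seen
#' order (reaction substrates, then products, then sources, then targets) so
#' that matrices and enumerations are reproducible.
#'
#' @param reactions list of [reaction()] objects.
#' @param sources character vector of source compound ids.
#' @param targets character vector of target compound ids.
#' @param compounds optional explicit compound ordering; must contain every
#'   referenced id.
#' @param allow_source_target_overlap allow a compound to be both a source
#'   and a target (disallowed by default).
#' @param allow_empty_substrates accept reactions with an empty substrate
#'   side. User networks reject these (a zero-substrate reaction would make
#'   the empty set a precursor set of whatever it produces); the source-pool
#'   reactions added internally by [augment_network()] are the exception.
#' @return an object of class `metabolic_network`.
#' @export
metabolic_network <- function(reactions, sources, targets, compounds = NULL,
                              allow_source_target_overlap = FALSE,
                              allow_empty_substrates = FALSE) {
  if (!length(reactions)) reactions <- list()
  lapply(reactions, function(r) {
    if (!inherits(r, "mnet_reaction")) stop("reactions must be reaction() objects")
  })
  ids <- vapply(reactions, `[[`, "", "id")
  if (anyDuplicated(ids)) {
    stop("duplicated reaction id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  names(reactions) <- ids
  if (!allow_empty_substrates) {
    empty <- ids[vapply(reactions, function(r) length(r$substrates) == 0L,
                        logical(1))]
    if (length(empty)) {
      stop("reaction(s) with empty substrate side not allowed: ",
           paste(empty, collapse = ", "))
    }
  }
  seen <- unique(unlist(lapply(reactions, function(r)
    c(names(r$substrates), names(r$products)))))
  if (is.null(compounds)) {
    # inferred from the reactions only: a source or target id that no
    # reaction mentions is almost always a typo, so it must be declared
    # explicitly via `compounds` to be accepted
    compounds <- seen
  } else {
    missing <- setdiff(seen, compounds)
    if (length(missing)) {
      stop("compound(s) referenced but not declared: ",
           paste(missing, collapse = ", "))
    }
  }
  if (anyDuplicated(compounds)) stop("duplicated compound ids")
  bad <- setdiff(c(sources, targets), compounds)
  if (length(bad)) stop("unknown compound id(s): ", paste(bad, collapse = ", "))
  ov <- intersect(sources, targets)
  if (length(ov) && !allow_source_target_overlap) {
    stop("compound(s) both source and target: ", paste(ov, collapse = ", "),
         " (set allow_source_target_overlap = TRUE to permit)")
  }
  structure(list(compounds = compounds, reactions = reactions,
                 sources = unique(sources), targets = unique(targets)),
            class = "metabolic_network")
}

#' @export
print.mnet_reaction <- function(x, ...) {
  side <- function(s) {
    if (!length(s)) return("")
    paste(paste(format(s, trim = TRUE), names(s)), collapse = " + ")
  }
  arrow <- if (x$reversible) "<=>" else "->"
  cat(sprintf("%s: %s %s %s\n", x$id, side(x$substrates), arrow,
              side(x$products)))
  invisible(x)
}

#' @export
print.metabolic_network <- function(x, ...) {
  cat(sprintf(
    "metabolic network: %d compounds, %d reactions, %d sources, %d targets\n",
    length(x$compounds), length(x$reactions), length(x$sources),
    length(x$targets)))
  cat("  sources:", paste(x$sources, collapse = ", "), "\n")
  cat("  targets:", paste(x$targets, collapse = ", "), "\n")
  invisible(x)
}

reaction_ids <- function(net) names(net$reactions)

#' Union of substrates / products over a reaction set
#' @param net a `metabolic_network`.
#' @param rids reaction ids (defaults to all).
#' @return character vector of compound ids.
#' @export
substrates_of <- function(net, rids = reaction_ids(net)) {
  sort(unique(unlist(lapply(net$reactions[rids], function(r)
    names(r$substrates)))))
}

#' @rdname substrates_of
#' @export
products_of <- function(net, rids = reaction_ids(net)) {
  sort(unique(unlist(lapply(net$reactions[rids], function(r)
    names(r$products)))))
}

#' Normalize a network
#'
#' Brings a raw network into the canonical form every analysis in this
#' package assumes: (i) all reactions irreversible -- each reversible
#' reaction `r` is split into `r_fwd` and `r_rev`; (ii) no reaction produces
#' a source compound -- each source `x` that is produced by some reaction is
#' replaced as a source by a fresh dummy compound `x_src` together with a
#' dummy reaction `r_src_x: 1 x_src -> 1 x`, which leaves the producible
#' behaviour of every source set unchanged. Idempotent.
#'
#' @param net a `metabolic_network`.
#' @return a normalized `metabolic_network` (the same object if no change
#'   was needed).
#' @export
normalize_network <- function(net) {
  stopifnot(inherits(net, "metabolic_network"))
  changed <- FALSE
  reactions <- list()
  for (r in net$reactions) {
    if (r$reversible) {
      changed <- TRUE
      reactions[[length(reactions) + 1L]] <-
        reaction(paste0(r$id, "_fwd"), r$substrates, r$products,
                 origin = paste("fwd of", r$id))
      reactions[[length(reactions) + 1L]] <-
        reaction(paste0(r$id, "_rev"), r$products, r$substrates,
                 origin = paste("rev of", r$id))
    } else {
      reactions[[length(reactions) + 1L]] <- r
    }
  }
  produced <- unique(unlist(lapply(reactions, function(r) names(r$products))))
  sources <- net$sources
  compounds <- net$compounds
  for (x in net$sources) {
    if (x %in% produced) {
      changed <- TRUE
      xs <- paste0(x, "_src")
      if (xs %in% compounds) stop("id collision while isolating source ", x)
      compounds <- c(compounds, xs)
      reactions[[length(reactions) + 1L]] <-
        reaction(paste0("r_src_", x), stats::setNames(1, xs),
                 stats::setNames(1, x), origin = paste("source pool for", x))
      sources[sources == x] <- xs
    }
  }
  if (!changed) return(net)
  metabolic_network(reactions, sources, net$targets, compounds = compounds)
}

is_normalized <- function(net) {
  if (any(vapply(net$reactions, `[[`, FALSE, "reversible"))) return(FALSE)
  !any(net$sources %in% products_of(net))
}

#' Stoichiometric matrix of a network
#'
#' Sparse compounds-by-reactions matrix of net coefficients: products
#' positive, substrates negative. Row/column order is the network's stable
#' input order.
#'
#' @param net a `metabolic_network`.
#' @return a [Matrix::sparseMatrix()] (`dgCMatrix`) with dimnames
#'   `(compounds, reactions)`.
#' @export
#' @examples
#' net <- toy_chain_network()
#' stoich_matrix(net)
stoich_matrix <- function(net) {
  stopifnot(inherits(net, "metabolic_network"))
  i <- integer(0); j <- integer(0); x <- numeric(0)
  cidx <- stats::setNames(seq_along(net$compounds), net$compounds)
  for (k in seq_along(net$reactions)) {
    r <- net$reactions[[k]]
    i <- c(i, cidx[names(r$substrates)], cidx[names(r$products)])
    j <- c(j, rep(k, length(r$substrates) + length(r$products)))
    x <- c(x, -unname(r$substrates), unname(r$products))
  }
  Matrix::sparseMatrix(i = i, j = j, x = x,
                       dims = c(length(net$compounds), length(net$reactions)),
                       dimnames = list(net$compounds, reaction_ids(net)))
}

# dense stoichiometric matrix for the internal LP/MILP paths (avoids S4
# dispatch overhead of the sparse user-facing representation in hot loops)
.stoich_dense <- function(net) {
  S <- matrix(0, length(net$compounds), length(net$reactions),
              dimnames = list(net$compounds, reaction_ids(net)))
  for (k in seq_along(net$reactions)) {
    r <- net$reactions[[k]]
    S[names(r$substrates), k] <- -unname(r$substrates)
    S[names(r$products), k] <- S[names(r$products), k] + unname(r$products)
  }
  S
}

#' Many-to-one transformation
#'
#' Replaces every reaction with k products by k single-product copies that
#' share the full substrate side: reaction `r` with product `a` yields
#' `r_a` with `Subs(r_a) = Subs(r)` and `Prod(r_a) = {a}`. Single-product
#' reactions are copied unchanged. Minimal stoichiometric factories of the
#' original network decompose into minimal topological factories of the
#' transformed network, which is what the combinatorial enumerator exploits.
#'
#' @param net a normalized `metabolic_network`.
#' @return the transformed network, with an attribute `mto_map` (named
#'   character vector: transformed reaction id -> original reaction id).
#' @export
many_to_one <- function(net) {
  stopifnot(inherits(net, "metabolic_network"))
  if (!is_normalized(net)) stop("many_to_one() expects a normalized network")
  reactions <- list()
  map <- character(0)
  for (r in net$reactions) {
    np <- length(r$products)
    if (np <= 1L) {
      if (np == 0L) {
        warning("reaction '", r$id,
                "' has no products; copied unchanged by many_to_one()")
      }
      reactions[[length(reactions) + 1L]] <- r
      map[r$id] <- r$id
    } else {
      for (a in names(r$products)) {
        nid <- paste0(r$id, "_", a)
        if (nid %in% c(names(map), reaction_ids(net))) {
          nid <- make.unique(c(names(map), nid))[length(map) + 1L]
        }
        reactions[[length(reactions) + 1L]] <-
          reaction(nid, r$substrates, r$products[a],
                   origin = paste("psi of", r$id, "for product", a))
        map[nid] <- r$id
      }
    }
  }
  out <- metabolic_network(reactions, net$sources, net$targets,
                           compounds = net$compounds,
                           allow_source_target_overlap = TRUE)
  attr(out, "mto_map") <- map
  out
}

#' Augment a network with source pools and/or a pooled target
#'
#' Source-pool reactions (`pool_<x>`: nothing -> 1 x) model the availability
#' of each source; their flux being positive marks the source as used, which
#' is what the enumeration MILP's binary indicators latch onto. The pooled
#' target construction adds one compound `t_bar` and a reaction
#' `r_bar: 1 t1 + ... + 1 tk -> 1 t_bar` (all coefficients one), so a single
#' matrix row measures joint target production.
#'
#' @param net a normalized `metabolic_network`.
#' @param pool_sources add one pool reaction per source.
#' @param pool_target add the pooled-target compound and reaction.
#' @param sources which sources to pool (defaults to all).
#' @return a `metabolic_network` with additional class `augmented_network`
#'   and attributes `source_pool_reactions` (named character: source id ->
#'   pool reaction id), `pooled_target` (the new compound id or `NULL`) and
#'   `pooled_target_reaction`.
#' @export
augment_network <- function(net, pool_sources = TRUE, pool_target = TRUE,
                            sources = net$sources) {
  stopifnot(inherits(net, "metabolic_network"))
  if (!is_normalized(net)) stop("augment_network() expects a normalized network")
  stopifnot(all(sources %in% net$sources))
  reactions <- net$reactions
  compounds <- net$compounds
  pools <- character(0)
  if (pool_sources) {
    for (x in sources) {
      pid <- paste0("pool_", x)
      if (pid %in% names(reactions)) stop("id collision for pool reaction ", pid)
      reactions[[pid]] <- reaction(pid, numeric(0), stats::setNames(1, x),
                                   origin = paste("source pool for", x))
      pools[x] <- pid
    }
  }
  pooled <- NULL
  pooled_r <- NULL
  if (pool_target) {
    if (any(net$targets %in% net$sources)) {
      stop("cannot pool a target that is also a source")
    }
    pooled <- "t_bar"
    pooled_r <- "r_bar"
    if (pooled %in% compounds || pooled_r %in% names(reactions)) {
      stop("id collision for pooled target")
    }
    compounds <- c(compounds, pooled)
    reactions[[pooled_r]] <-
      reaction(pooled_r, stats::setNames(rep(1, length(net$targets)),
                                         net$targets),
               stats::setNames(1, pooled), origin = "pooled target")
  }
  out <- metabolic_network(reactions, net$sources, net$targets,
                           compounds = compounds,
                           allow_empty_substrates = TRUE)
  class(out) <- c("augmented_network", class(out))
  attr(out, "source_pool_reactions") <- pools
  attr(out, "pooled_target") <- pooled
  attr(out, "pooled_target_reaction") <- pooled_r
  out
}
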