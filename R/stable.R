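# Direct stable-state computation, bypassing STG construction.

#' Compute all stable states of a model
#'
#' A state is stable when every node's target level equals its current level;
#' stability does not depend on the updating scheme.  Instead of enumerating
#' the full product state space, the solver builds one local stability
#' relation per node -- the satisfying assignments over the node and its
#' regulators -- and combines them by relational joins (constraint
#' propagation), keeping intermediate relations small when regulator sets are
#' sparse.  The result is provably the same set as brute-force enumeration,
#' which the test suite checks against a reference implementation.
#'
#' @param model a [logical_model()].
#' @param perturbation optional [perturbation()] applied first.
#' @return character vector of stable-state codes, sorted; the level matrix is
#'   attached as attribute \code{"levels"}.
#' @export
compute_stable <- function(model, perturbation = NULL) {
  model <- apply_perturbation(model, perturbation)
  ids <- node_ids(model)
  rels <- lapply(ids, function(g) local_stability_relation(model, g))
  # join order: start from the smallest relation, then greedily pick the
  # relation sharing the most variables with the accumulated one
  sizes <- vapply(rels, nrow, integer(1))
  ord <- order(sizes)
  acc <- rels[[ord[1]]]
  remaining <- rels[ord[-1]]
  while (length(remaining)) {
    overlap <- vapply(remaining, function(r) length(intersect(names(r), names(acc))),
                      integer(1))
    pick <- which.max(overlap * 1000L - vapply(remaining, nrow, integer(1)))
    r <- remaining[[pick]]
    remaining <- remaining[-pick]
    common <- intersect(names(acc), names(r))
    acc <- if (length(common)) merge(acc, r, by = common) else merge(acc, r, by = NULL)
    if (!nrow(acc)) break
  }
  if (nrow(acc)) {
    mat <- as.matrix(acc[, ids, drop = FALSE])
    storage.mode(mat) <- "integer"
    codes <- apply(mat, 1L, paste, collapse = "")
    o <- order(codes)
    mat <- mat[o, , drop = FALSE]
    codes <- codes[o]
  } else {
    mat <- matrix(integer(0), 0L, length(ids), dimnames = list(NULL, ids))
    codes <- character(0)
  }
  structure(codes, levels = mat)
}

# assignments over {g} union regulators(g) for which g's target equals g's level
local_stability_relation <- function(model, g) {
  vars <- union(g, regulators(model, g))
  vars <- vars[order(match(vars, node_ids(model)))]
  domains <- lapply(vars, function(s) 0L:node_max(model, s))
  names(domains) <- vars
  grid <- expand.grid(domains, KEEP.OUT.ATTRS = FALSE)
  state0 <- stats::setNames(integer(nrow(model$nodes)), node_ids(model))
  keep <- logical(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    state <- state0
    state[vars] <- as.integer(grid[i, vars])
    keep[i] <- target_level(model, state, g) == state[[g]]
  }
  grid[keep, , drop = FALSE]
}
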