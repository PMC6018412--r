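# State transition graphs under the supported updating schemes.

#' Updating schemes
#'
#' An updating scheme decides which of the called nodes change level in one
#' transition.  \code{"asynchronous"} fires one called node per transition;
#' \code{"synchronous"} fires all of them together; \code{"complete"} fires
#' every non-empty subset of them; \code{"sequential"} sweeps the nodes once
#' in declared order, each step re-evaluating the target against the
#' partially updated state (one unit step per node per sweep).  For
#' \code{"priority"}, nodes are partitioned into classes, each with a rank
#' and an inner mode (\code{"asynchronous"} or \code{"synchronous"}): only
#' classes of the highest priority (smallest rank value) among those
#' containing a called node fire; classes sharing that rank contribute their
#' successor sets independently (asynchronously between classes).
#'
#' @param mode one of \code{"asynchronous"}, \code{"synchronous"},
#'   \code{"complete"}, \code{"sequential"}, \code{"priority"}.
#' @param classes for \code{"priority"}: a list of
#'   \code{list(nodes =, rank =, mode =)} entries partitioning the node set.
#' @return an object of class \code{updating_scheme}.
#' @export
updating_scheme <- function(mode = c("asynchronous", "synchronous", "complete",
                                     "sequential", "priority"),
                            classes = NULL) {
  mode <- match.arg(mode)
  if (mode == "priority") {
    if (is.null(classes) || !length(classes)) {
      stop("priority updating requires at least one class", call. = FALSE)
    }
    classes <- lapply(classes, function(cl) {
      list(nodes = as.character(cl$nodes), rank = as.integer(cl$rank),
           mode = match.arg(cl$mode, c("asynchronous", "synchronous")))
    })
  } else if (!is.null(classes)) {
    stop("classes are only meaningful for priority updating", call. = FALSE)
  }
  structure(list(mode = mode, classes = classes), class = "updating_scheme")
}

as_scheme <- function(scheme) {
  if (inherits(scheme, "updating_scheme")) return(scheme)
  updating_scheme(scheme)
}

check_priority_partition <- function(model, scheme) {
  all_nodes <- sort(unlist(lapply(scheme$classes, `[[`, "nodes")))
  if (anyDuplicated(all_nodes) || !identical(all_nodes, sort(node_ids(model)))) {
    stop("priority classes must partition the node set", call. = FALSE)
  }
}

step_state <- function(state, nodes, dirs) {
  state[nodes] <- state[nodes] + dirs
  state
}

#' Successor states under an updating scheme
#'
#' @param model a [logical_model()].
#' @param state a state (see [model_state()]).
#' @param scheme an [updating_scheme()] or a mode name.
#' @return list of successor states, in deterministic order (node order, then
#'   subset order for the complete scheme); empty for a stable state.
#' @export
successors <- function(model, state, scheme = "asynchronous") {
  scheme <- as_scheme(scheme)
  calls <- called_nodes(model, state)
  if (scheme$mode == "sequential") {
    cur <- state
    for (g in node_ids(model)) {
      d <- sign(target_level(model, cur, g) - cur[[g]])
      if (d != 0L) cur[[g]] <- cur[[g]] + as.integer(d)
    }
    return(if (identical(cur, state)) list() else list(cur))
  }
  if (nrow(calls) == 0L) return(list())
  switch(scheme$mode,
    asynchronous = lapply(seq_len(nrow(calls)), function(i) {
      step_state(state, calls$node[i], calls$dir[i])
    }),
    synchronous = list(step_state(state, calls$node, calls$dir)),
    complete = {
      n <- nrow(calls)
      out <- list()
      # subsets ordered by size then node order: singletons first
      for (k in seq_len(n)) {
        idx <- utils::combn(n, k, simplify = FALSE)
        for (s in idx) {
          out[[length(out) + 1L]] <- step_state(state, calls$node[s], calls$dir[s])
        }
      }
      out
    },
    priority = {
      check_priority_partition(model, scheme)
      active <- which(vapply(scheme$classes, function(cl) {
        any(calls$node %in% cl$nodes)
      }, logical(1)))
      top_rank <- min(vapply(scheme$classes[active], `[[`, integer(1), "rank"))
      out <- list()
      for (cl in scheme$classes[active]) {
        if (cl$rank != top_rank) next
        sub <- calls[calls$node %in% cl$nodes, , drop = FALSE]
        if (cl$mode == "synchronous") {
          out[[length(out) + 1L]] <- step_state(state, sub$node, sub$dir)
        } else {
          for (i in seq_len(nrow(sub))) {
            out[[length(out) + 1L]] <- step_state(state, sub$node[i], sub$dir[i])
          }
        }
      }
      unique(out)
    })
}

#' Perturbations: clamping node levels
#'
#' A perturbation constrains the target level of one or more nodes to an
#' interval.  A knock-down clamps to \code{[0, 0]}; an ectopic expression
#' clamps to \code{[max, max]} (or any range above zero for a multi-valued
#' node).  Clamps combine: at most one per node.
#'
#' @param ... named arguments; each name is a node id and each value a level
#'   (clamp to that single value) or a \code{c(low, high)} interval.
#' @return an object of class \code{perturbation}.
#' @export
perturbation <- function(...) {
  args <- list(...)
  if (!length(args) || is.null(names(args)) || any(names(args) == "")) {
    stop("perturbation() takes named node = level or node = c(low, high) arguments",
         call. = FALSE)
  }
  if (anyDuplicated(names(args))) stop("at most one clamp per node", call. = FALSE)
  clamps <- do.call(rbind, lapply(names(args), function(nm) {
    v <- as.integer(args[[nm]])
    if (length(v) == 1L) v <- c(v, v)
    if (length(v) != 2L || anyNA(v) || v[1] > v[2] || v[1] < 0L) {
      stop("bad clamp for ", nm, ": need level or c(low, high) with 0 <= low <= high",
           call. = FALSE)
    }
    data.frame(node = nm, low = v[1], high = v[2], stringsAsFactors = FALSE)
  }))
  structure(list(clamps = clamps), class = "perturbation")
}

#' Apply a perturbation to a model
#'
#' Returns a model whose target levels are clamped into the perturbation's
#' intervals; all dynamical analyses (successors, STGs, stable states,
#' attractors) then operate on the perturbed behaviour.
#'
#' @param model a [logical_model()].
#' @param p a [perturbation()] or \code{NULL} (returned unchanged).
#' @return a perturbed [logical_model()].
#' @export
apply_perturbation <- function(model, p) {
  if (is.null(p)) return(model)
  if (!inherits(p, "perturbation")) stop("not a perturbation", call. = FALSE)
  unknown <- setdiff(p$clamps$node, node_ids(model))
  if (length(unknown)) {
    stop("clamp on unknown node(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (i in seq_len(nrow(p$clamps))) {
    if (p$clamps$high[i] > node_max(model, p$clamps$node[i])) {
      stop("clamp on ", p$clamps$node[i], " exceeds its maximal level",
           call. = FALSE)
    }
  }
  keep <- !(model$clamps$node %in% p$clamps$node)
  model$clamps <- rbind(model$clamps[keep, , drop = FALSE], p$clamps)
  model
}

#' Expand an initial-state pattern
#'
#' Patterns fix some node levels and leave others free (wildcard \code{*}),
#' e.g. \code{"0*1*"}.
#'
#' @param model a [logical_model()].
#' @param pattern a digit-and-star string (one character per node) or a named
#'   list/vector of fixed levels (missing nodes free).
#' @return integer matrix of matching states (one per row).
#' @export
expand_pattern <- function(model, pattern) {
  n <- nrow(model$nodes)
  if (is.character(pattern) && length(pattern) == 1L) {
    ch <- strsplit(pattern, "")[[1]]
    if (length(ch) != n) {
      stop("pattern length ", length(ch), " != node count ", n, call. = FALSE)
    }
    fixed <- ifelse(ch == "*", NA_integer_, suppressWarnings(as.integer(ch)))
  } else {
    pattern <- unlist(pattern)
    unknown <- setdiff(names(pattern), node_ids(model))
    if (length(unknown)) stop("pattern names unknown node(s): ",
                              paste(unknown, collapse = ", "), call. = FALSE)
    fixed <- rep(NA_integer_, n)
    fixed[match(names(pattern), node_ids(model))] <- as.integer(pattern)
  }
  bad <- !is.na(fixed) & (fixed < 0L | fixed > model$nodes$max)
  if (any(bad)) {
    stop("pattern level out of bounds for: ",
         paste(model$nodes$id[bad], collapse = ", "), call. = FALSE)
  }
  domains <- lapply(seq_len(n), function(i) {
    if (is.na(fixed[i])) 0L:model$nodes$max[i] else fixed[i]
  })
  grid <- expand.grid(rev(domains), KEEP.OUT.ATTRS = FALSE)
  mat <- as.matrix(grid[, rev(seq_len(n)), drop = FALSE])
  dimnames(mat) <- list(NULL, model$nodes$id)
  storage.mode(mat) <- "integer"
  mat
}

#' Build a state transition graph
#'
#' Constructs the STG of a model under one updating scheme.  Without initial
#' patterns the full state space is enumerated; with patterns, only states
#' reachable from the pattern expansion (plus the traversed transitions) are
#' kept.  Stable states are exactly the states with no outgoing transition.
#'
#' @param model a [logical_model()].
#' @param scheme an [updating_scheme()] or mode name.
#' @param initial optional list of patterns (see [expand_pattern()]); a single
#'   pattern may be given directly.
#' @param perturbation optional [perturbation()] applied before construction.
#' @param max_states guard against state-space explosion; construction stops
#'   with an error of class \code{mvlogic_cap_error} beyond this many states.
#' @return an object of class \code{transition_graph}: list with
#'   \code{states} (codes, sorted), \code{levels} (state matrix),
#'   \code{edges} (data frame \code{from}/\code{to} of codes), \code{scheme},
#'   \code{model}.
#' @export
build_stg <- function(model, scheme = "asynchronous", initial = NULL,
                      perturbation = NULL, max_states = 2^20) {
  scheme <- as_scheme(scheme)
  model <- apply_perturbation(model, perturbation)
  cap_error <- function(n) {
    stop(structure(class = c("mvlogic_cap_error", "error", "condition"),
                   list(message = sprintf(
                     "state cap exceeded: %d states > max_states = %d", n, max_states),
                     call = NULL)))
  }
  if (is.null(initial)) {
    total <- prod(model$nodes$max + 1)
    if (total > max_states) cap_error(total)
    mat <- state_space(model)
    states <- apply(mat, 1L, paste, collapse = "")
    from <- character(0); to <- character(0)
    for (i in seq_len(nrow(mat))) {
      st <- stats::setNames(mat[i, ], colnames(mat))
      for (succ in successors(model, st, scheme)) {
        from <- c(from, states[i]); to <- c(to, state_code(succ))
      }
    }
  } else {
    if (!is.list(initial) || !is.null(names(initial))) initial <- list(initial)
    seeds <- unique(unlist(lapply(initial, function(p) {
      mat <- expand_pattern(model, p)
      apply(mat, 1L, paste, collapse = "")
    })))
    seen <- new.env(parent = emptyenv(), hash = TRUE)
    queue <- seeds
    for (s in seeds) assign(s, TRUE, envir = seen)
    from <- character(0); to <- character(0)
    lv <- list()
    while (length(queue)) {
      code <- queue[[1L]]; queue <- queue[-1L]
      st <- model_state(model, code)
      lv[[code]] <- st
      for (succ in successors(model, st, scheme)) {
        sc <- state_code(succ)
        from <- c(from, code); to <- c(to, sc)
        if (!exists(sc, envir = seen, inherits = FALSE)) {
          assign(sc, TRUE, envir = seen)
          if (length(lv) + length(queue) + 1L > max_states) cap_error(length(lv) + length(queue) + 1L)
          queue <- c(queue, sc)
        }
      }
    }
    states <- sort(ls(seen))
    mat <- do.call(rbind, lapply(states, function(s) model_state(model, s)))
    dimnames(mat) <- list(NULL, node_ids(model))
  }
  edges <- unique(data.frame(from = from, to = to, stringsAsFactors = FALSE))
  structure(list(states = states, levels = mat, edges = edges,
                 scheme = scheme, model = model),
            class = "transition_graph")
}

#' Stable states of a transition graph
#' @param stg a [build_stg()] result.
#' @return character vector of state codes with out-degree 0.
#' @export
stg_stable_states <- function(stg) {
  setdiff(stg$states, unique(stg$edges$from))
}

#' @export
print.transition_graph <- function(x, ...) {
  cat(sprintf("State transition graph (%s updating): %d state(s), %d transition(s)\n",
              x$scheme$mode, length(x$states), nrow(x$edges)))
  ss <- stg_stable_states(x)
  if (length(ss)) cat("stable state(s):", paste(ss, collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.updating_scheme <- function(x, ...) {
  cat("updating scheme:", x$mode, "\n")
  for (cl in x$classes) {
    cat(sprintf("  rank %d (%s): %s\n", cl$rank, cl$mode,
                paste(cl$nodes, collapse = ", ")))
  }
  invisible(x)
}
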