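# Evaluation semantics: literals, formulas, target levels, update calls.

#' Evaluate a rule literal
#'
#' A literal names a regulator of \code{target}, optionally with an explicit
#' interaction threshold.  It is true when the regulator's level falls in the
#' activity window of that interaction: at or above the threshold, but below
#' the next declared threshold on the same arc (or up to the regulator's
#' maximal level if there is none).  Level 0 never activates an interaction.
#' A bare literal (no threshold) is only meaningful when the arc carries a
#' single interaction; with several thresholds it is rejected as ambiguous.
#'
#' @param model a [logical_model()].
#' @param target id of the node whose rule the literal belongs to.
#' @param regulator id of the literal's node.
#' @param state a state (see [model_state()]).
#' @param threshold optional explicit threshold.
#' @return logical scalar.
#' @export
eval_literal <- function(model, target, regulator, state, threshold = NULL) {
  ths <- arc_thresholds(model, regulator, target)
  if (!length(ths)) {
    stop("literal '", regulator, "' does not name a regulator of ", target,
         call. = FALSE)
  }
  if (is.null(threshold) || is.na(threshold)) {
    if (length(ths) > 1L) {
      stop("ambiguous bare literal '", regulator, "' in a rule of ", target,
           ": the arc carries thresholds ", paste(ths, collapse = ", "),
           call. = FALSE)
    }
    threshold <- ths
  }
  w <- literal_window(model, regulator, target, as.integer(threshold))
  lv <- state[[regulator]]
  lv >= w[1] && lv <= w[2]
}

eval_formula <- function(model, target, ast, state) {
  switch(ast$op,
         lit = eval_literal(model, target, ast$node, state,
                            threshold = ast$threshold),
         not = !eval_formula(model, target, ast$x, state),
         and = eval_formula(model, target, ast$lhs, state) &&
               eval_formula(model, target, ast$rhs, state),
         or  = eval_formula(model, target, ast$lhs, state) ||
               eval_formula(model, target, ast$rhs, state),
         stop("unknown formula node: ", ast$op, call. = FALSE))
}

# rows of one rule entry are OR-ed
entry_satisfied <- function(model, g, entry, state) {
  for (f in entry$formulas) {
    if (eval_formula(model, g, f, state)) return(TRUE)
  }
  FALSE
}

# error used by check_formula_literals() below and by the parser
check_formula_literals <- function(model, g, ast) {
  if (ast$op == "lit") {
    ths <- arc_thresholds(model, ast$node, g)
    if (!length(ths)) {
      return(sprintf("literal '%s' does not name a regulator of %s", ast$node, g))
    }
    if (is.null(ast$threshold) || is.na(ast$threshold)) {
      if (length(ths) > 1L) {
        return(sprintf("ambiguous bare literal '%s' (thresholds %s)",
                       ast$node, paste(ths, collapse = ", ")))
      }
    } else if (!(ast$threshold %in% ths)) {
      return(sprintf("literal '%s:%d' names no declared interaction toward %s",
                     ast$node, ast$threshold, g))
    }
    return(NULL)
  }
  for (part in ast[setdiff(names(ast), "op")]) {
    if (is.list(part)) {
      err <- check_formula_literals(model, g, part)
      if (!is.null(err)) return(err)
    }
  }
  NULL
}

clamp_level <- function(model, node, level) {
  i <- match(node, model$clamps$node)
  if (is.na(i)) return(level)
  min(max(level, model$clamps$low[i]), model$clamps$high[i])
}

#' Target level of a node in a state
#'
#' The rules of a node define the level it is called toward: the value of the
#' unique satisfied rule entry, or 0 when no entry is satisfied (components
#' without an explicit rule therefore relax to 0).  Input nodes implicitly
#' maintain their current level.  Clamps installed by
#' [apply_perturbation()] restrict the result to the clamp interval.
#'
#' @param model a [logical_model()].
#' @param state a state (see [model_state()]).
#' @param node node id.
#' @return integer level in \code{0..max(node)}.
#' @export
target_level <- function(model, state, node) {
  if (is_input_node(model, node)) {
    return(clamp_level(model, node, state[[node]]))
  }
  entries <- model$rules[[node]]
  t <- 0L
  if (length(entries)) {
    sat <- vapply(entries, function(e) entry_satisfied(model, node, e, state),
                  logical(1))
    if (sum(sat) > 1L) {
      vals <- vapply(entries[sat], function(e) as.integer(e$value), integer(1))
      stop("rule conflict on ", node, ": target values ",
           paste(vals, collapse = " and "), " both satisfied in state ",
           state_code(state), call. = FALSE)
    }
    if (any(sat)) t <- as.integer(entries[[which(sat)]]$value)
  }
  clamp_level(model, node, t)
}

#' Nodes called for update in a state
#'
#' A node whose target level differs from its current level is called to
#' update toward it; updates are unitary, so the reported direction is the
#' sign of the difference.
#'
#' @inheritParams target_level
#' @return data frame with columns \code{node} and \code{dir} (+1 or -1), in
#'   declared node order; zero rows iff the state is stable.
#' @export
called_nodes <- function(model, state) {
  ids <- node_ids(model)
  dir <- integer(0)
  who <- character(0)
  for (g in ids) {
    d <- sign(target_level(model, state, g) - state[[g]])
    if (d != 0L) { who <- c(who, g); dir <- c(dir, as.integer(d)) }
  }
  data.frame(node = who, dir = dir, stringsAsFactors = FALSE)
}

#' @rdname called_nodes
#' @export
is_stable_state <- function(model, state) nrow(called_nodes(model, state)) == 0L
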