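# Model reduction by node elimination, with exact re-synthesis of rules and
# interactions from tabulated target-level functions.

# Tabulate g's target-level function over an explicit regulator set `vars`
# (every other node held at 0; rules only read declared regulators, and the
# caller guarantees vars covers them).  `fun` overrides the evaluation, for
# composed functions during reduction.
tabulate_function <- function(model, g, vars, fun = NULL) {
  grid <- regulator_grid(model, vars)
  state0 <- stats::setNames(integer(nrow(model$nodes)), node_ids(model))
  value <- integer(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    state <- state0
    if (length(vars)) state[vars] <- as.integer(grid[i, vars])
    value[i] <- if (is.null(fun)) target_level(model, state, g) else fun(state)
  }
  cbind(grid, value = value)
}

# Thresholds of s that matter for the tabulated function: crossing
# level th-1 -> th changes the value in at least one context.  Returns the
# observed effect sign per threshold ("+", "-", "±").
derive_thresholds <- function(tbl, s) {
  vars <- setdiff(names(tbl), c(s, "value"))
  out <- list()
  for (th in seq_len(max(tbl[[s]]))) {
    lo <- tbl[tbl[[s]] == th - 1L, , drop = FALSE]
    hi <- tbl[tbl[[s]] == th, , drop = FALSE]
    key <- function(d) if (length(vars)) do.call(paste, d[vars]) else rep("", nrow(d))
    hi <- hi[match(key(lo), key(hi)), , drop = FALSE]
    d <- sign(hi$value - lo$value)
    seen <- unique(d[d != 0L])
    if (length(seen)) {
      out[[length(out) + 1L]] <- data.frame(
        threshold = th,
        sign = if (length(seen) == 2L) "±" else if (seen == 1L) "+" else "-",
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(out, list(data.frame(threshold = integer(0), sign = character(0)))))
}

# Rebuild interactions and rule entries of g from a tabulated function.
# Regulators whose thresholds never matter are dropped.  Returns
# list(interactions =, entries =); errors if the function is a non-zero
# constant (the rule grammar has no constant-true formula).
synthesize_node <- function(model, g, tbl) {
  regs <- setdiff(names(tbl), "value")
  ths <- lapply(regs, function(s) derive_thresholds(tbl, s))
  names(ths) <- regs
  keep <- regs[vapply(ths, nrow, integer(1)) > 0L]
  if (!length(keep)) {
    if (any(tbl$value != 0L)) {
      stop("cannot synthesize rules for ", g,
           ": its target-level function is a non-zero constant", call. = FALSE)
    }
    return(list(interactions = NULL, entries = list()))
  }
  interactions <- do.call(rbind, lapply(keep, function(s) {
    data.frame(source = s, target = g, threshold = ths[[s]]$threshold,
               sign = ths[[s]]$sign, stringsAsFactors = FALSE)
  }))
  # windows per kept regulator: [0, th1-1], [th1, th2-1], ..., [thk, max]
  windows <- lapply(keep, function(s) {
    t <- ths[[s]]$threshold
    cbind(lo = c(0L, t), hi = c(t - 1L, max(tbl[[s]])))
  })
  names(windows) <- keep
  boxes <- expand.grid(lapply(windows, function(w) seq_len(nrow(w))),
                       KEEP.OUT.ATTRS = FALSE)
  names(boxes) <- keep
  # value at the lower corner of each box; constant on the box because all
  # change points of the function are captured by the derived thresholds
  box_value <- integer(nrow(boxes))
  for (b in seq_len(nrow(boxes))) {
    sel <- rep(TRUE, nrow(tbl))
    for (s in keep) {
      sel <- sel & tbl[[s]] == windows[[s]][boxes[b, s], "lo"]
    }
    dropped <- setdiff(regs, keep)
    for (s in dropped) sel <- sel & tbl[[s]] == 0L
    box_value[b] <- tbl$value[sel][1L]
  }
  entries <- list()
  for (v in sort(unique(box_value[box_value > 0L]))) {
    formulas <- lapply(which(box_value == v), function(b) {
      terms <- lapply(keep, function(s) {
        w <- boxes[b, s]
        t <- ths[[s]]$threshold
        if (w == 1L) {
          # below every derived threshold: no window literal is active
          Reduce(function(a, x) list(op = "and", lhs = a, rhs = x),
                 lapply(t, function(th) {
                   list(op = "not", x = list(op = "lit", node = s,
                                             threshold = lit_threshold(model, s, g, t, th)))
                 }))
        } else {
          list(op = "lit", node = s,
               threshold = lit_threshold(model, s, g, t, t[w - 1L]))
        }
      })
      Reduce(function(a, x) list(op = "and", lhs = a, rhs = x), terms)
    })
    entries[[length(entries) + 1L]] <- list(value = v, formulas = formulas)
  }
  list(interactions = interactions, entries = entries)
}

# bare literal when the arc has a single threshold, explicit otherwise
lit_threshold <- function(model, s, g, arc_ths, th) {
  if (length(arc_ths) == 1L) NA_integer_ else as.integer(th)
}

#' Reduce a model by eliminating nodes
#'
#' Eliminates the listed nodes one at a time, in order.  To eliminate a node
#' r, the target-level function of every target of r is recomposed with r's
#' own target-level function (so the indirect effects of r's regulators are
#' absorbed), the affected nodes' interactions are re-derived from the new
#' functions, and their rules are re-synthesized exactly.  This preserves the
#' stable states (they project onto the kept nodes) and the attractors of
#' the dynamics.  A node may not be eliminated while it is self-regulated
#' (including input nodes, which implicitly maintain themselves).
#'
#' @param model a [logical_model()].
#' @param remove character vector of node ids, eliminated in order.
#' @return the reduced [logical_model()].
#' @export
reduce_model <- function(model, remove) {
  for (r in remove) model <- reduce_one(model, r)
  model
}

reduce_one <- function(model, r) {
  if (!(r %in% node_ids(model))) stop("unknown node: ", r, call. = FALSE)
  if (is_input_node(model, r)) {
    stop("cannot eliminate input node ", r, " (implicitly self-maintaining)",
         call. = FALSE)
  }
  if (r %in% regulators(model, r)) {
    stop("cannot eliminate self-regulated node ", r, call. = FALSE)
  }
  if (r %in% model$clamps$node) {
    stop("cannot eliminate clamped node ", r, call. = FALSE)
  }
  regs_r <- regulators(model, r)
  targets <- setdiff(unique(model$interactions$target[model$interactions$source == r]), r)
  new_parts <- list()
  for (g in targets) {
    vars <- union(setdiff(regulators(model, g), r), regs_r)
    vars <- setdiff(vars, r)
    vars <- vars[order(match(vars, node_ids(model)))]
    fun <- function(state) {
      state[[r]] <- target_level(model, state, r)
      target_level(model, state, g)
    }
    tbl <- tabulate_function(model, g, vars, fun = fun)
    new_parts[[g]] <- synthesize_node(model, g, tbl)
  }
  keep <- node_ids(model) != r
  nodes <- model$nodes[keep, , drop = FALSE]
  ia <- model$interactions
  ia <- ia[ia$source != r & ia$target != r & !(ia$target %in% targets), ,
           drop = FALSE]
  for (g in targets) ia <- rbind(ia, new_parts[[g]]$interactions)
  rules <- model$rules[setdiff(names(model$rules), c(r, targets))]
  for (g in targets) {
    if (length(new_parts[[g]]$entries)) rules[[g]] <- new_parts[[g]]$entries
  }
  out <- logical_model(nodes, ia, rules, comments = model$comments)
  out$clamps <- model$clamps
  out
}
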