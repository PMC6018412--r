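SIGNS <- c("+", "-", "±", "?")

#' Construct a multi-valued logical regulatory model
#'
#' A logical regulatory graph couples a set of discrete components (each with
#' levels \code{0..max}) with signed, threshold-indexed interactions and, for
#' every regulated component, logical rules giving the level toward which the
#' component is called in each state.  The declared node order is semantic: it
#' fixes the digit order of state codes such as \code{"0110"}.
#'
#' @param nodes data frame with columns \code{id}, \code{max} and optionally
#'   \code{input} (logical).  Row order defines the node order.
#' @param interactions data frame with columns \code{source}, \code{target},
#'   \code{threshold} and \code{sign} (one of \code{"+"}, \code{"-"},
#'   \code{"±"} for dual, \code{"?"} for unknown).
#' @param rules named list (by target node id); each element is a list of rule
#'   entries \code{list(value =, formulas = list(...))} where each formula is
#'   an AST as returned by [parse_formula()].  Several formulas for one entry
#'   are combined by OR.
#' @param comments optional list of free-text annotations (see
#'   [write_model()] for how they are serialized).
#' @param validate if \code{TRUE} (default), reject invalid models with an
#'   error listing the violations found by [validate_model()].
#' @return an object of class \code{logical_model}.
#' @export
logical_model <- function(nodes, interactions = NULL, rules = list(),
                          comments = list(), validate = TRUE) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  if (is.null(nodes$input)) nodes$input <- FALSE
  nodes$id <- as.character(nodes$id)
  nodes$max <- as.integer(nodes$max)
  nodes <- nodes[, c("id", "max", "input")]
  if (is.null(interactions) || nrow(as.data.frame(interactions)) == 0L) {
    interactions <- data.frame(source = character(0), target = character(0),
                               threshold = integer(0), sign = character(0),
                               stringsAsFactors = FALSE)
  } else {
    interactions <- as.data.frame(interactions, stringsAsFactors = FALSE)
    interactions$source <- as.character(interactions$source)
    interactions$target <- as.character(interactions$target)
    interactions$threshold <- as.integer(interactions$threshold)
    interactions$sign <- as.character(interactions$sign)
    interactions <- interactions[, c("source", "target", "threshold", "sign")]
  }
  m <- structure(list(nodes = nodes, interactions = interactions,
                      rules = rules,
                      clamps = empty_clamps(),
                      comments = comments),
                 class = "logical_model")
  if (validate) {
    rep <- validate_model(m)
    if (!is_valid(rep)) {
      stop("invalid model:\n", paste(format_violations(rep), collapse = "\n"),
           call. = FALSE)
    }
  }
  m
}

empty_clamps <- function() {
  data.frame(node = character(0), low = integer(0), high = integer(0),
             stringsAsFactors = FALSE)
}

node_ids <- function(model) model$nodes$id

node_max <- function(model, id) {
  i <- match(id, model$nodes$id)
  if (is.na(i)) stop("unknown node: ", id, call. = FALSE)
  model$nodes$max[i]
}

is_input_node <- function(model, id) {
  i <- match(id, model$nodes$id)
  isTRUE(model$nodes$input[i])
}

#' Regulators of a node
#'
#' The set of nodes with at least one declared interaction toward
#' \code{target}, in declared node order.
#'
#' @param model a [logical_model()].
#' @param target node id.
#' @return character vector of node ids.
#' @export
regulators <- function(model, target) {
  src <- unique(model$interactions$source[model$interactions$target == target])
  src[order(match(src, node_ids(model)))]
}

arc_thresholds <- function(model, source, target) {
  sel <- model$interactions$source == source & model$interactions$target == target
  sort(model$interactions$threshold[sel])
}

# Activity window of the interaction source->target at threshold th:
# [th, next declared threshold - 1], or [th, max(source)] if none higher.
literal_window <- function(model, source, target, th) {
  ths <- arc_thresholds(model, source, target)
  if (!(th %in% ths)) {
    stop("no interaction ", source, " -> ", target, " at threshold ", th,
         call. = FALSE)
  }
  higher <- ths[ths > th]
  hi <- if (length(higher)) min(higher) - 1L else node_max(model, source)
  c(th, hi)
}

#' States of a model
#'
#' A state assigns to every node a level in \code{0..max}.  States are
#' rendered as digit strings in declared node order (so the four-node p53
#' model state with p53 = 0, Mdm2cyt = 1, Mdm2nuc = 1, DNAdam = 0 prints as
#' \code{"0110"}); maximal levels above 9 are rejected to keep this code
#' unambiguous.
#'
#' @param model a [logical_model()].
#' @param levels integer vector of levels in node order, or a digit string.
#' @return named integer vector of class-free levels.
#' @export
model_state <- function(model, levels) {
  if (is.character(levels) && length(levels) == 1L) {
    levels <- as.integer(strsplit(levels, "")[[1]])
  }
  levels <- as.integer(levels)
  if (length(levels) != nrow(model$nodes)) {
    stop("state length ", length(levels), " != node count ",
         nrow(model$nodes), call. = FALSE)
  }
  bad <- levels < 0L | levels > model$nodes$max
  if (any(bad | is.na(levels))) {
    stop("state levels out of bounds for: ",
         paste(model$nodes$id[bad | is.na(levels)], collapse = ", "),
         call. = FALSE)
  }
  stats::setNames(levels, model$nodes$id)
}

#' Digit-string code of a state
#' @param state named integer vector as returned by [model_state()].
#' @return character scalar such as \code{"0110"}.
#' @export
state_code <- function(state) paste(state, collapse = "")

#' Enumerate the full state space of a model
#'
#' @param model a [logical_model()].
#' @return integer matrix, one row per state in lexicographic code order,
#'   columns named by node ids.
#' @export
state_space <- function(model) {
  n <- nrow(model$nodes)
  domains <- lapply(model$nodes$max, function(m) 0L:m)
  # vary last node fastest so rows sort by digit code
  grid <- expand.grid(rev(domains), KEEP.OUT.ATTRS = FALSE)
  mat <- as.matrix(grid[, rev(seq_len(n)), drop = FALSE])
  dimnames(mat) <- list(NULL, model$nodes$id)
  storage.mode(mat) <- "integer"
  mat
}

#' Validate a logical model
#'
#' Checks node-id syntax and uniqueness, maximal levels, threshold bounds and
#' per-arc threshold uniqueness, literal resolvability in every rule formula,
#' input-node constraints (no incoming interactions, no rules), rule-entry
#' value bounds, and pairwise mutual exclusion of the rule entries of each
#' node (by exhaustive evaluation over the level combinations of its
#' regulators).  Overlapping entries would make the target level ambiguous,
#' so they are reported as violations together with a witness assignment.
#'
#' @param model a [logical_model()] (possibly built with
#'   \code{validate = FALSE}).
#' @return object of class \code{mvlogic_validation}: a data frame of
#'   violations with columns \code{code}, \code{element}, \code{message}.
#' @export
validate_model <- function(model) {
  v <- list()
  add <- function(code, element, message) {
    v[[length(v) + 1L]] <<- data.frame(code = code, element = element,
                                       message = message,
                                       stringsAsFactors = FALSE)
  }
  nodes <- model$nodes
  if (nrow(nodes) == 0L) add("empty_model", "", "model declares no node")
  bad_id <- !grepl("^[A-Za-z_][A-Za-z0-9_]*$", nodes$id)
  for (id in nodes$id[bad_id]) add("node_id", id, "invalid node identifier")
  dup <- nodes$id[duplicated(nodes$id)]
  for (id in unique(dup)) add("dup_node", id, "duplicate node id")
  for (i in seq_len(nrow(nodes))) {
    if (is.na(nodes$max[i]) || nodes$max[i] < 1L) {
      add("max_level", nodes$id[i], "maximal level must be >= 1")
    } else if (nodes$max[i] > 9L) {
      add("max_level", nodes$id[i], "maximal level above 9 unsupported (digit state codes)")
    }
  }
  ia <- model$interactions
  for (i in seq_len(nrow(ia))) {
    el <- paste0(ia$source[i], "->", ia$target[i], ":", ia$threshold[i])
    if (!(ia$source[i] %in% nodes$id)) add("unknown_node", el, "unknown source node")
    if (!(ia$target[i] %in% nodes$id)) add("unknown_node", el, "unknown target node")
    if (!(ia$sign[i] %in% SIGNS)) add("sign", el, "sign must be one of + - ± ?")
    if (ia$source[i] %in% nodes$id) {
      mx <- node_max(model, ia$source[i])
      if (is.na(ia$threshold[i]) || ia$threshold[i] < 1L || ia$threshold[i] > mx) {
        add("threshold", el,
            sprintf("threshold must lie in [1, %d] (source maximal level)", mx))
      }
    }
  }
  key <- paste(ia$source, ia$target, ia$threshold)
  for (k in unique(key[duplicated(key)])) add("dup_interaction", k, "duplicate (source, target, threshold)")
  # input nodes: no incoming interactions, no rules
  for (id in nodes$id[nodes$input]) {
    if (any(ia$target == id)) add("input_regulated", id, "input node has incoming interactions")
    if (length(model$rules[[id]])) add("input_rule", id, "input node has rules")
  }
  # rules
  for (g in names(model$rules)) {
    entries <- model$rules[[g]]
    if (!length(entries)) next
    if (!(g %in% nodes$id)) {
      add("unknown_node", g, "rule for undeclared node")
      next
    }
    vals <- vapply(entries, function(e) as.integer(e$value), integer(1))
    for (val in vals[vals < 1L | vals > node_max(model, g)]) {
      add("rule_value", g, sprintf("target value %d out of [1, %d]", val, node_max(model, g)))
    }
    for (val in unique(vals[duplicated(vals)])) {
      add("dup_rule", g, sprintf("several rule entries for target value %d", val))
    }
    ok <- TRUE
    for (e in entries) {
      for (f in e$formulas) {
        err <- check_formula_literals(model, g, f)
        if (!is.null(err)) { add("literal", g, err); ok <- FALSE }
      }
    }
    # mutual exclusion over the regulator subspace, only on resolvable rules
    if (ok && length(entries) > 1L && !anyNA(vals) &&
        all(vals >= 1L & vals <= node_max(model, g))) {
      w <- rule_overlap_witness(model, g, entries)
      if (!is.null(w)) {
        add("rule_conflict", g,
            sprintf("rule entries for values %d and %d both satisfied at %s",
                    w$values[1], w$values[2], w$witness))
      }
    }
  }
  structure(do.call(rbind, c(v, list(data.frame(code = character(0),
                                                element = character(0),
                                                message = character(0),
                                                stringsAsFactors = FALSE)))),
            class = c("mvlogic_validation", "data.frame"))
}

#' @rdname validate_model
#' @param report a validation report.
#' @export
is_valid <- function(report) nrow(report) == 0L

format_violations <- function(report) {
  if (!nrow(report)) return(character(0))
  sprintf("  [%s] %s: %s", report$code, report$element, report$message)
}

#' @export
print.mvlogic_validation <- function(x, ...) {
  if (!nrow(x)) {
    cat("model is valid (no violations)\n")
  } else {
    cat(nrow(x), "violation(s):\n")
    cat(format_violations(x), sep = "\n")
  }
  invisible(x)
}

# Search the regulator subspace of g for an assignment satisfying two rule
# entries at once; NULL if the entries are mutually exclusive.
rule_overlap_witness <- function(model, g, entries) {
  regs <- regulators(model, g)
  grid <- regulator_grid(model, regs)
  state0 <- stats::setNames(integer(nrow(model$nodes)), node_ids(model))
  for (r in seq_len(nrow(grid))) {
    state <- state0
    state[regs] <- unlist(grid[r, , drop = TRUE])
    sat <- vapply(entries, function(e) entry_satisfied(model, g, e, state),
                  logical(1))
    if (sum(sat) > 1L) {
      vals <- vapply(entries[sat], function(e) as.integer(e$value), integer(1))
      wit <- if (length(regs)) {
        paste(sprintf("%s=%d", regs, state[regs]), collapse = ", ")
      } else "(no regulators)"
      return(list(values = vals[1:2], witness = wit))
    }
  }
  NULL
}

regulator_grid <- function(model, regs) {
  if (!length(regs)) return(data.frame(row.names = 1L))
  domains <- lapply(regs, function(s) 0L:node_max(model, s))
  names(domains) <- regs
  grid <- expand.grid(rev(domains), KEEP.OUT.ATTRS = FALSE)
  grid[, rev(seq_along(regs)), drop = FALSE]
}

#' @export
print.logical_model <- function(x, ...) {
  cat(sprintf("Logical regulatory model: %d node(s), %d interaction(s)\n",
              nrow(x$nodes), nrow(x$interactions)))
  for (i in seq_len(nrow(x$nodes))) {
    cat(sprintf("  %s [0..%d]%s\n", x$nodes$id[i], x$nodes$max[i],
                if (x$nodes$input[i]) " (input)" else ""))
  }
  if (nrow(x$interactions)) {
    cat("interactions:\n")
    with(x$interactions,
         cat(sprintf("  %s -%s-> %s @%d\n", source, sign, target, threshold), sep = ""))
  }
  for (g in names(x$rules)) {
    for (e in x$rules[[g]]) {
      for (f in e$formulas) {
        cat(sprintf("  %s := %d <- %s\n", g, e$value, format_formula(f)))
      }
    }
  }
  if (nrow(x$clamps)) {
    with(x$clamps,
         cat(sprintf("  clamp %s in [%d, %d]\n", node, low, high), sep = ""))
  }
  invisible(x)
}
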