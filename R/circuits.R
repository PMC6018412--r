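# Regulatory circuit enumeration, signs, functionality contexts, and
# declared-sign consistency checking.

#' Enumerate regulatory circuits
#'
#' Circuits are simple closed directed paths of the regulatory graph,
#' enumerated at arc level (a multi-threshold arc counts once; threshold
#' choices are explored later, by [functionality_context()]).  Circuits are
#' reported once, starting from their smallest node in declared order.
#'
#' @param model a [logical_model()].
#' @param max_length optional maximal number of arcs.
#' @param include optional node ids each circuit must contain.
#' @param exclude optional node ids no circuit may contain.
#' @return list of circuits; each is a list with \code{nodes} (cycle order),
#'   \code{arcs} (data frame \code{source}/\code{target}/\code{sign}) and
#'   \code{sign} (\code{"positive"}, \code{"negative"} or
#'   \code{"undetermined"}).
#' @export
enumerate_circuits <- function(model, max_length = NULL, include = NULL,
                               exclude = NULL) {
  ids <- node_ids(model)
  arcs <- unique(model$interactions[, c("source", "target")])
  if (!is.null(exclude)) {
    arcs <- arcs[!(arcs$source %in% exclude | arcs$target %in% exclude), ,
                 drop = FALSE]
  }
  succ <- split(arcs$target, factor(arcs$source, levels = ids))
  idx <- stats::setNames(seq_along(ids), ids)
  out <- list()
  path <- character(0)
  visit <- function(v, start) {
    path <<- c(path, v)
    for (w in sort(idx[succ[[v]]])) {
      w_id <- ids[w]
      if (w == idx[[start]] ) {
        if (is.null(max_length) || length(path) <= max_length) {
          out[[length(out) + 1L]] <<- path
        }
      } else if (w > idx[[start]] && !(w_id %in% path)) {
        if (is.null(max_length) || length(path) < max_length) visit(w_id, start)
      }
    }
    path <<- path[-length(path)]
  }
  for (s in ids) visit(s, s)
  if (!is.null(include)) {
    out <- Filter(function(p) all(include %in% p), out)
  }
  lapply(out, function(p) make_circuit(model, p))
}

arc_sign <- function(model, source, target) {
  sel <- model$interactions$source == source & model$interactions$target == target
  s <- unique(model$interactions$sign[sel])
  if (length(s) == 1L && s %in% c("+", "-")) s else "±"
}

make_circuit <- function(model, nodes) {
  arcs <- data.frame(source = nodes, target = c(nodes[-1L], nodes[1L]),
                     stringsAsFactors = FALSE)
  arcs$sign <- mapply(arc_sign, arcs$source, arcs$target,
                      MoreArgs = list(model = model))
  structure(list(nodes = nodes, arcs = arcs, sign = sign_product(arcs$sign)),
            class = "circuit")
}

sign_product <- function(signs) {
  if (any(!(signs %in% c("+", "-")))) return("undetermined")
  if (sum(signs == "-") %% 2L == 0L) "positive" else "negative"
}

#' Sign of a circuit
#'
#' The product of the signs of the member interactions: positive with an even
#' number of inhibitions, negative otherwise.  A member arc of dual or
#' unknown sign leaves the circuit sign undetermined.
#'
#' @param circuit a circuit from [enumerate_circuits()].
#' @return \code{"positive"}, \code{"negative"} or \code{"undetermined"}.
#' @export
circuit_sign <- function(circuit) circuit$sign

#' Functionality context of a circuit
#'
#' External regulators can prevent a circuit from playing its dynamical role.
#' For each choice of one interaction threshold per circuit arc, the circuit
#' nodes are confined to the two levels around their outgoing threshold; an
#' assignment of levels to the nodes outside the circuit is admissible when
#' every circuit interaction is operational under it -- i.e. for every
#' placement of the other circuit nodes inside their windows, moving the
#' arc's source across its threshold changes the target level of the arc's
#' target.  The functionality context is the union of admissible assignments
#' over all threshold choices; the circuit is functional iff it is non-empty.
#'
#' @param model a [logical_model()].
#' @param circuit a circuit from [enumerate_circuits()].
#' @return list with \code{functional} (flag), \code{context} (data frame of
#'   admissible external level assignments; zero columns when the circuit
#'   covers every node), \code{clauses} (compact rendering such as
#'   \code{"Mdm2cyt=1 & DNAdam=0"}), and \code{thresholds} (the threshold
#'   assignments, one per circuit arc, with a non-empty context).
#' @export
functionality_context <- function(model, circuit) {
  ids <- node_ids(model)
  cn <- circuit$nodes
  ext <- setdiff(ids, cn)
  arcs <- circuit$arcs
  th_choices <- lapply(seq_len(nrow(arcs)), function(i) {
    arc_thresholds(model, arcs$source[i], arcs$target[i])
  })
  th_grid <- expand.grid(th_choices, KEEP.OUT.ATTRS = FALSE)
  ext_grid <- regulator_grid(model, ext)
  admissible <- rep(FALSE, nrow(ext_grid))
  good_th <- list()
  state0 <- stats::setNames(integer(length(ids)), ids)
  for (t in seq_len(nrow(th_grid))) {
    th <- as.integer(th_grid[t, ])
    # circuit node window: {theta - 1, theta} of its outgoing circuit arc
    win <- stats::setNames(th, arcs$source)
    ok_rows <- logical(nrow(ext_grid))
    for (r in seq_len(nrow(ext_grid))) {
      base <- state0
      if (length(ext)) base[ext] <- as.integer(ext_grid[r, ext])
      ok_rows[r] <- all(vapply(seq_len(nrow(arcs)), function(i) {
        arc_operational(model, arcs$source[i], arcs$target[i], th[i],
                        win, base)
      }, logical(1)))
    }
    if (any(ok_rows)) good_th[[length(good_th) + 1L]] <- win
    admissible <- admissible | ok_rows
  }
  ctx <- ext_grid[admissible, , drop = FALSE]
  rownames(ctx) <- NULL
  clauses <- context_clauses(model, ext, ctx)
  list(functional = any(admissible), context = ctx, clauses = clauses,
       thresholds = good_th)
}

# Is the circuit arc s -> g at threshold th operational for external context
# `base`, for *every* placement of the other circuit nodes in their windows?
arc_operational <- function(model, s, g, th, windows, base) {
  others <- setdiff(names(windows), s)
  placements <- if (length(others)) {
    grid <- expand.grid(lapply(others, function(o) {
      unique(c(max(windows[[o]] - 1L, 0L), windows[[o]]))
    }), KEEP.OUT.ATTRS = FALSE)
    names(grid) <- others
    grid
  } else data.frame(row.names = 1L)
  for (r in seq_len(nrow(placements))) {
    st <- base
    if (length(others)) st[others] <- as.integer(placements[r, others])
    st[s] <- th - 1L
    lo <- target_level(model, st, g)
    st[s] <- th
    hi <- target_level(model, st, g)
    if (lo == hi) return(FALSE)
  }
  TRUE
}

context_clauses <- function(model, ext, ctx) {
  if (!length(ext)) {
    return(if (nrow(ctx)) "(always)" else character(0))
  }
  if (!nrow(ctx)) return(character(0))
  codes <- apply(ctx[, ext, drop = FALSE], 1L, paste, collapse = "")
  sub <- logical_model(model$nodes[model$nodes$id %in% ext, , drop = FALSE],
                       validate = FALSE)
  pats <- state_patterns(sub, codes)
  vapply(pats, function(p) {
    ch <- strsplit(p, "")[[1]]
    fixed <- ch != "*"
    if (!any(fixed)) return("(always)")
    paste(sprintf("%s=%s", node_ids(sub)[fixed], ch[fixed]), collapse = " & ")
  }, character(1), USE.NAMES = FALSE)
}

#' Check declared interaction signs against the rules
#'
#' For every declared interaction, enumerates all level combinations of the
#' target's other regulators and records how the target level changes as the
#' source enters the interaction's activity window from just below its
#' threshold.  An interaction that never changes the target is reported as
#' non-functional; one whose observed effects all match the declared sign
#' (dual and unknown signs cover both directions) is consistent; anything
#' else is inconsistent.
#'
#' @param model a [logical_model()].
#' @return data frame with one row per declared interaction: \code{source},
#'   \code{target}, \code{threshold}, \code{sign}, \code{observed}
#'   (\code{"+"}, \code{"-"}, \code{"±"} or \code{"none"}) and \code{status}
#'   (\code{"consistent"}, \code{"inconsistent"} or \code{"non-functional"}).
#' @export
interaction_functionality <- function(model) {
  ia <- model$interactions
  ids <- node_ids(model)
  state0 <- stats::setNames(integer(length(ids)), ids)
  observed <- character(nrow(ia))
  status <- character(nrow(ia))
  for (i in seq_len(nrow(ia))) {
    s <- ia$source[i]; g <- ia$target[i]; th <- ia$threshold[i]
    others <- setdiff(regulators(model, g), s)
    grid <- regulator_grid(model, others)
    seen <- integer(0)
    for (r in seq_len(nrow(grid))) {
      st <- state0
      if (length(others)) st[others] <- as.integer(grid[r, others])
      st[s] <- th - 1L
      lo <- target_level(model, st, g)
      st[s] <- th
      hi <- target_level(model, st, g)
      d <- as.integer(sign(hi - lo))
      if (d != 0L) seen <- union(seen, d)
    }
    observed[i] <- if (!length(seen)) "none"
                   else if (identical(sort(seen), c(-1L, 1L))) "±"
                   else if (seen == 1L) "+" else "-"
    status[i] <- if (observed[i] == "none") "non-functional"
                 else if (ia$sign[i] %in% c("±", "?")) "consistent"
                 else if (observed[i] == ia$sign[i]) "consistent"
                 else "inconsistent"
  }
  cbind(ia, data.frame(observed = observed, status = status,
                       stringsAsFactors = FALSE))
}

#' @export
print.circuit <- function(x, ...) {
  cat(sprintf("circuit %s (%s)\n",
              paste(c(x$nodes, x$nodes[1L]), collapse = " -> "), x$sign))
  invisible(x)
}
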