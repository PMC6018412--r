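# DOT (Graphviz) and TSV exports.

dot_quote <- function(x) {
  if (!length(x)) return(character(0))
  paste0('"', gsub('"', '\\\\"', x), '"')
}

#' Export a graph to DOT (Graphviz) format
#'
#' Supported inputs: a [build_stg()] transition graph (one DOT node per
#' state, labelled by its code; stable states drawn as boxes), a
#' [build_htg()] hierarchical graph (nodes labelled \code{ct#9}-style, with
#' kind-based styling) and a [logical_model()] (the regulatory graph view;
#' arc heads reflect interaction signs).
#'
#' @param x object to export.
#' @param ... unused.
#' @return a single string of DOT source.
#' @export
export_dot <- function(x, ...) UseMethod("export_dot")

#' @export
export_dot.transition_graph <- function(x, ...) {
  stable <- stg_stable_states(x)
  nodes <- vapply(x$states, function(s) {
    sprintf("  %s [shape=%s];", dot_quote(s),
            if (s %in% stable) "box" else "ellipse")
  }, character(1))
  edges <- sprintf("  %s -> %s;", dot_quote(x$edges$from), dot_quote(x$edges$to))
  paste0(paste(c("digraph STG {", nodes, edges, "}"), collapse = "\n"), "\n")
}

#' @export
export_dot.htg <- function(x, ...) {
  style <- c(stable = "shape=box, style=filled, fillcolor=indianred1",
             cyclic_terminal = "shape=ellipse, style=filled, fillcolor=skyblue",
             cyclic_transient = "shape=ellipse, style=filled, fillcolor=lightblue",
             transient_chain = "shape=ellipse")
  nodes <- vapply(seq_along(x$members), function(i) {
    sprintf("  %s [%s];", dot_quote(x$label[i]), style[[x$kind[i]]])
  }, character(1))
  edges <- sprintf("  %s -> %s;", dot_quote(x$label[x$edges$from]),
                   dot_quote(x$label[x$edges$to]))
  paste0(paste(c("digraph HTG {", nodes, edges, "}"), collapse = "\n"), "\n")
}

#' @export
export_dot.scc_graph <- function(x, ...) {
  lab <- vapply(seq_along(x$members), function(i) {
    if (length(x$members[[i]]) == 1L) x$members[[i]] else
      sprintf("scc#%d", length(x$members[[i]]))
  }, character(1))
  dup <- duplicated(lab) | duplicated(lab, fromLast = TRUE)
  lab[dup] <- paste0(lab[dup], ".", seq_along(lab)[dup])
  nodes <- vapply(seq_along(lab), function(i) {
    sprintf("  %s [shape=%s];", dot_quote(lab[i]),
            if (x$kind[i] == "stable") "box" else "ellipse")
  }, character(1))
  edges <- sprintf("  %s -> %s;", dot_quote(lab[x$edges$from]),
                   dot_quote(lab[x$edges$to]))
  paste0(paste(c("digraph SCC {", nodes, edges, "}"), collapse = "\n"), "\n")
}

#' @export
export_dot.logical_model <- function(x, ...) {
  nodes <- vapply(seq_len(nrow(x$nodes)), function(i) {
    sprintf("  %s [shape=box, label=\"%s (0..%d)\"];", dot_quote(x$nodes$id[i]),
            x$nodes$id[i], x$nodes$max[i])
  }, character(1))
  ia <- x$interactions
  edges <- vapply(seq_len(nrow(ia)), function(i) {
    head <- switch(ia$sign[i], "+" = "normal", "-" = "tee", "±" = "diamond",
                   "?" = "odot")
    sprintf("  %s -> %s [label=\"%d\", arrowhead=%s];",
            dot_quote(ia$source[i]), dot_quote(ia$target[i]), ia$threshold[i],
            head)
  }, character(1))
  paste0(paste(c("digraph LRG {", nodes, edges, "}"), collapse = "\n"), "\n")
}

#' Export a transition graph as a TSV edge list
#'
#' @param stg a [build_stg()] result.
#' @return a string: header \code{source_code\\ttarget_code} plus one row per
#'   transition.
#' @export
export_tsv <- function(stg) {
  rows <- sprintf("%s\t%s", stg$edges$from, stg$edges$to)
  paste0(paste(c("source_code\ttarget_code", rows), collapse = "\n"), "\n")
}
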