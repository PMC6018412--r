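# STG compression: SCC quotient, attractors, hierarchical transition graph.

stg_igraph <- function(stg) {
  igraph::graph_from_data_frame(stg$edges, directed = TRUE,
                                vertices = data.frame(name = stg$states))
}

#' Quotient a transition graph by its strongly connected components
#'
#' Lumping each SCC of the STG into one node yields an acyclic graph that
#' preserves reachability between classes.
#'
#' @param stg a [build_stg()] result.
#' @return an object of class \code{scc_graph}: \code{members} (list of state
#'   code vectors), \code{kind} (\code{"stable"}, \code{"cyclic_terminal"},
#'   \code{"cyclic_transient"} or \code{"transient"}), \code{edges} (data
#'   frame of class indices \code{from}/\code{to}).
#' @export
scc_quotient <- function(stg) {
  g <- stg_igraph(stg)
  comp <- igraph::components(g, mode = "strong")
  membership <- comp$membership[stg$states]
  classes <- split(stg$states, membership)
  # deterministic class order: by smallest member code
  ord <- order(vapply(classes, min, character(1)))
  classes <- lapply(classes[ord], function(x) sort(unname(x)))
  old_id <- as.integer(names(classes))
  remap <- integer(max(membership)); remap[old_id] <- seq_along(classes)
  cls_of <- remap[membership]
  names(cls_of) <- stg$states
  ef <- cls_of[stg$edges$from]; et <- cls_of[stg$edges$to]
  qe <- unique(data.frame(from = ef, to = et)[ef != et, , drop = FALSE])
  rownames(qe) <- NULL
  sizes <- unname(lengths(classes))
  has_out <- seq_along(classes) %in% qe$from
  kind <- ifelse(sizes > 1L,
                 ifelse(has_out, "cyclic_transient", "cyclic_terminal"),
                 ifelse(has_out, "transient", "stable"))
  structure(list(members = unname(classes), kind = kind, edges = qe,
                 membership = cls_of, model = stg$model),
            class = "scc_graph")
}

#' Attractors of a transition graph
#'
#' Attractors are the terminal strongly connected components of the STG:
#' singletons are stable states, larger ones cyclic attractors.
#'
#' @param stg a [build_stg()] result.
#' @return list of \code{list(kind, states)}, kind \code{"stable"} or
#'   \code{"cyclic"}, states sorted codes.
#' @export
attractors <- function(stg) {
  q <- scc_quotient(stg)
  term <- which(!(seq_along(q$members) %in% q$edges$from))
  lapply(term, function(i) {
    list(kind = if (q$kind[i] == "stable") "stable" else "cyclic",
         states = q$members[[i]])
  })
}

#' Hierarchical transition graph
#'
#' Further compresses the SCC quotient by merging transient states (in
#' addition to cycles) into hyper-nodes.  Two transient singleton classes are
#' merged when they share the same downstream fate: the same set of reachable
#' non-trivial components (cyclic classes and stable states).  Along any
#' trajectory this fate set can only shrink, so the merged graph is acyclic,
#' chains of states funnelling toward the same components collapse into one
#' node, and attractors are preserved exactly.  Node labels follow the
#' convention: a stable state is labelled by its code, a cyclic attractor
#' with N states by \code{ca#N}, a transient cyclic component by \code{ct#N},
#' and a merged transient chain by \code{i#N}.
#'
#' @param stg a [build_stg()] result.
#' @return object of class \code{htg}: \code{members}, \code{kind}
#'   (\code{"stable"}, \code{"cyclic_terminal"}, \code{"cyclic_transient"},
#'   \code{"transient_chain"}), \code{label}, \code{edges}, plus the source
#'   model.
#' @export
build_htg <- function(stg) {
  q <- scc_quotient(stg)
  nc <- length(q$members)
  qg <- igraph::graph_from_data_frame(q$edges, directed = TRUE,
                                      vertices = data.frame(name = seq_len(nc)))
  hard <- which(q$kind != "transient")  # cyclic components and stable states
  # signature of a class: which non-trivial components it can reach
  sig <- matrix(FALSE, nc, length(hard))
  for (j in seq_along(hard)) {
    up <- as.integer(names(igraph::subcomponent(qg, as.character(hard[j]),
                                                mode = "in")))
    sig[up, j] <- TRUE
  }
  key <- apply(sig, 1L, paste, collapse = "")
  group <- integer(nc)
  group[hard] <- seq_along(hard)
  trans <- setdiff(seq_len(nc), hard)
  tkeys <- unique(key[trans])
  group[trans] <- length(hard) + match(key[trans], tkeys)
  members <- lapply(seq_len(length(hard) + length(tkeys)), function(i) {
    sort(unlist(q$members[group == i]))
  })
  kind <- c(q$kind[hard], rep("transient_chain", length(tkeys)))
  edges <- unique(data.frame(from = group[q$edges$from], to = group[q$edges$to]))
  edges <- edges[edges$from != edges$to, , drop = FALSE]
  # deterministic node order: by smallest member code
  ord <- order(vapply(members, min, character(1)))
  members <- members[ord]
  kind <- kind[ord]
  remap <- integer(length(ord)); remap[ord] <- seq_along(ord)
  edges <- unique(data.frame(from = remap[edges$from], to = remap[edges$to]))
  rownames(edges) <- NULL
  label <- character(length(members))
  for (i in seq_along(members)) {
    n <- length(members[[i]])
    label[i] <- switch(kind[i],
                       stable = members[[i]],
                       cyclic_terminal = paste0("ca#", n),
                       cyclic_transient = paste0("ct#", n),
                       transient_chain = paste0("i#", n))
  }
  # disambiguate duplicate labels deterministically
  dup <- duplicated(label) | duplicated(label, fromLast = TRUE)
  if (any(dup & kind != "stable")) {
    for (lab in unique(label[dup])) {
      at <- which(label == lab & kind != "stable")
      if (length(at) > 1L) label[at] <- paste0(lab, letters[seq_along(at)])
    }
  }
  structure(list(members = members, kind = kind, label = label, edges = edges,
                 model = stg$model),
            class = "htg")
}

#' Compact wildcard rendering of a state set
#'
#' Renders a set of states as a minimal-ish list of digit/star patterns whose
#' disjoint union is exactly the given set: positions where a group of states
#' takes every possible value collapse to \code{*}.
#'
#' @param model a [logical_model()].
#' @param codes character vector of state codes.
#' @return character vector of patterns (digits and \code{*}).
#' @export
state_patterns <- function(model, codes) {
  if (!length(codes)) return(character(0))
  n <- nrow(model$nodes)
  pat <- do.call(rbind, strsplit(sort(codes), ""))
  repeat {
    changed <- FALSE
    for (pos in seq_len(n)) {
      full <- as.character(0L:model$nodes$max[pos])
      rest <- apply(pat[, -pos, drop = FALSE], 1L, paste, collapse = "\r")
      for (grp in split(seq_len(nrow(pat)), rest)) {
        vals <- pat[grp, pos]
        if (length(grp) >= length(full) && !("*" %in% vals) &&
            setequal(vals, full) && !anyDuplicated(vals)) {
          pat[grp[1L], pos] <- "*"
          pat <- pat[-grp[-1L], , drop = FALSE]
          changed <- TRUE
          break
        }
      }
      if (changed) break
    }
    if (!changed) break
  }
  sort(apply(pat, 1L, paste, collapse = ""))
}

#' @export
print.scc_graph <- function(x, ...) {
  cat(sprintf("SCC quotient graph: %d class(es), %d edge(s)\n",
              length(x$members), nrow(x$edges)))
  for (i in seq_along(x$members)) {
    cat(sprintf("  [%d] %s (%d state(s)): %s\n", i, x$kind[i],
                length(x$members[[i]]),
                paste(utils::head(x$members[[i]], 6L), collapse = ", ")))
  }
  invisible(x)
}

#' @export
print.htg <- function(x, ...) {
  cat(sprintf("Hierarchical transition graph: %d node(s), %d edge(s)\n",
              length(x$members), nrow(x$edges)))
  for (i in seq_along(x$members)) {
    cat(sprintf("  %s [%s]: %s\n", x$label[i], x$kind[i],
                paste(state_patterns(x$model, x$members[[i]]), collapse = ", ")))
  }
  invisible(x)
}
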