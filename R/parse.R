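# Text format for logical regulatory models (.lrg) and the formula grammar.
#
# EBNF of the model format (one declaration per line, UTF-8):
#
#   document   = { line } ;
#   line       = node-decl | edge-decl | rule-decl | comment | blank ;
#   node-decl  = "node" id "max=" integer [ "input" ] ;
#   edge-decl  = "edge" id "->" id "t=" integer "sign=" sign ;
#   rule-decl  = "rule" id ":=" integer "<-" formula ;
#   comment    = "#" free-text ;
#   sign       = "+" | "-" | "±" | "+-" | "?" ;
#   formula    = or-expr ;
#   or-expr    = and-expr { "|" and-expr } ;
#   and-expr   = not-expr { "&" not-expr } ;
#   not-expr   = "!" not-expr | "(" or-expr ")" | literal ;
#   literal    = id [ ":" integer ] ;
#
# Nodes must be declared before any edge or rule that uses them, and edges
# before the rule literals that resolve to them.  Comment lines attach to the
# next declaration; trailing comments attach to the model itself.

#' Parse a logical rule formula
#'
#' Formulas combine literals with \code{!} (NOT), \code{&} (AND) and \code{|}
#' (inclusive OR) under the usual precedence (NOT binds tightest, then AND,
#' then OR); parentheses override it.  A literal is a regulator id, with an
#' optional explicit interaction threshold as in \code{Mdm2cyt:2}.
#'
#' @param text formula string.
#' @param model,target context used to resolve literals against declared
#'   interactions; pass both or neither.  Without context the AST is returned
#'   unchecked.
#' @return formula AST (nested lists with an \code{op} field).
#' @export
parse_formula <- function(text, model = NULL, target = NULL) {
  toks <- tokenize_formula(text)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  ast <- parse_or(st, text)
  if (st$pos <= length(st$toks)) {
    tk <- st$toks[[st$pos]]
    stop(sprintf("syntax error in formula '%s' at position %d: unexpected '%s'",
                 text, tk$at, tk$text), call. = FALSE)
  }
  if (!is.null(model)) {
    if (is.null(target)) stop("formula context requires a target node", call. = FALSE)
    err <- check_formula_literals(model, target, ast)
    if (!is.null(err)) stop("in formula '", text, "': ", err, call. = FALSE)
  }
  ast
}

tokenize_formula <- function(text) {
  toks <- list()
  i <- 1L
  n <- nchar(text)
  while (i <= n) {
    rest <- substr(text, i, n)
    ws <- regmatches(rest, regexpr("^\\s+", rest))
    if (length(ws)) { i <- i + nchar(ws); next }
    m <- regmatches(rest, regexpr("^([A-Za-z_][A-Za-z0-9_]*(:[0-9]+)?|[!&|()])", rest))
    if (!length(m)) {
      stop(sprintf("syntax error in formula '%s' at position %d: unexpected '%s'",
                   text, i, substr(text, i, i)), call. = FALSE)
    }
    toks[[length(toks) + 1L]] <- list(text = m, at = i)
    i <- i + nchar(m)
  }
  toks
}

peek_tok <- function(st) if (st$pos <= length(st$toks)) st$toks[[st$pos]]$text else NULL
take_tok <- function(st) { st$pos <- st$pos + 1L; st$toks[[st$pos - 1L]]$text }

parse_or <- function(st, text) {
  lhs <- parse_and(st, text)
  while (identical(peek_tok(st), "|")) {
    take_tok(st)
    lhs <- list(op = "or", lhs = lhs, rhs = parse_and(st, text))
  }
  lhs
}

parse_and <- function(st, text) {
  lhs <- parse_not(st, text)
  while (identical(peek_tok(st), "&")) {
    take_tok(st)
    lhs <- list(op = "and", lhs = lhs, rhs = parse_not(st, text))
  }
  lhs
}

parse_not <- function(st, text) {
  tk <- peek_tok(st)
  if (is.null(tk)) {
    stop(sprintf("syntax error in formula '%s': unexpected end of input", text),
         call. = FALSE)
  }
  if (tk == "!") {
    take_tok(st)
    return(list(op = "not", x = parse_not(st, text)))
  }
  if (tk == "(") {
    take_tok(st)
    inner <- parse_or(st, text)
    if (!identical(peek_tok(st), ")")) {
      stop(sprintf("syntax error in formula '%s': missing ')'", text), call. = FALSE)
    }
    take_tok(st)
    return(inner)
  }
  if (grepl("^[A-Za-z_]", tk)) {
    take_tok(st)
    parts <- strsplit(tk, ":", fixed = TRUE)[[1]]
    return(list(op = "lit", node = parts[1],
                threshold = if (length(parts) > 1L) as.integer(parts[2]) else NA_integer_))
  }
  stop(sprintf("syntax error in formula '%s': unexpected '%s'", text, tk),
       call. = FALSE)
}

#' Render a formula AST back to text
#'
#' Inverse of [parse_formula()]: emits minimal parentheses, so
#' \code{parse_formula(format_formula(ast))} reproduces \code{ast}.
#'
#' @param ast a formula AST.
#' @return character scalar.
#' @export
format_formula <- function(ast) fmt_prec(ast, 1L)

fmt_prec <- function(ast, need) {
  prec <- switch(ast$op, or = 1L, and = 2L, not = 3L, lit = 4L)
  out <- switch(ast$op,
    lit = if (is.na(ast$threshold)) ast$node else paste0(ast$node, ":", ast$threshold),
    not = paste0("!", fmt_prec(ast$x, 3L)),
    and = paste0(fmt_prec(ast$lhs, 2L), " & ", fmt_prec(ast$rhs, 3L)),
    or  = paste0(fmt_prec(ast$lhs, 1L), " | ", fmt_prec(ast$rhs, 2L)))
  if (prec < need) paste0("(", out, ")") else out
}

#' Parse a model document
#'
#' Reads the plain-text model grammar documented in this file's header and
#' returns a validated [logical_model()].  Node declaration order becomes the
#' semantic node order.  Nodes, edges and rules must appear in dependency
#' order; violations are reported with their line number.
#'
#' @param text a single string or a character vector of lines.
#' @return a validated [logical_model()].
#' @export
parse_model <- function(text) {
  lines <- if (length(text) == 1L && grepl("\n", text)) {
    strsplit(text, "\n", fixed = TRUE)[[1]]
  } else as.character(text)
  nodes <- list(); edges <- list(); rules <- list()
  comments <- list(model = character(0), elements = list())
  pending <- character(0)
  seen_nodes <- character(0)
  perr <- function(i, msg) {
    stop(sprintf("line %d: %s", i, msg), call. = FALSE)
  }
  attach_comment <- function(key) {
    if (length(pending)) {
      comments$elements[[key]] <<- c(comments$elements[[key]], pending)
      pending <<- character(0)
    }
  }
  for (i in seq_along(lines)) {
    line <- trimws(lines[i])
    if (line == "") next
    if (startsWith(line, "#")) {
      pending <- c(pending, sub("^#\\s?", "", line))
      next
    }
    if (grepl("^node\\b", line)) {
      m <- regmatches(line, regexec(
        "^node\\s+([A-Za-z_][A-Za-z0-9_]*)\\s+max=([0-9]+)(\\s+input)?\\s*$", line))[[1]]
      if (!length(m)) perr(i, paste0("malformed node declaration: ", line))
      if (m[2] %in% seen_nodes) perr(i, paste0("duplicate node: ", m[2]))
      nodes[[length(nodes) + 1L]] <- data.frame(
        id = m[2], max = as.integer(m[3]), input = nzchar(m[4]),
        stringsAsFactors = FALSE)
      seen_nodes <- c(seen_nodes, m[2])
      attach_comment(paste0("node:", m[2]))
    } else if (grepl("^edge\\b", line)) {
      m <- regmatches(line, regexec(
        "^edge\\s+([A-Za-z_][A-Za-z0-9_]*)\\s*->\\s*([A-Za-z_][A-Za-z0-9_]*)\\s+t=([0-9]+)\\s+sign=(\\+-|±|\\+|-|\\?)\\s*$",
        line))[[1]]
      if (!length(m)) perr(i, paste0("malformed edge declaration: ", line))
      if (!(m[2] %in% seen_nodes)) perr(i, paste0("edge references undeclared node: ", m[2]))
      if (!(m[3] %in% seen_nodes)) perr(i, paste0("edge references undeclared node: ", m[3]))
      sgn <- if (m[5] == "+-") "±" else m[5]
      edges[[length(edges) + 1L]] <- data.frame(
        source = m[2], target = m[3], threshold = as.integer(m[4]), sign = sgn,
        stringsAsFactors = FALSE)
      attach_comment(paste0("edge:", m[2], "->", m[3], ":", m[4]))
    } else if (grepl("^rule\\b", line)) {
      m <- regmatches(line, regexec(
        "^rule\\s+([A-Za-z_][A-Za-z0-9_]*)\\s*:=\\s*([0-9]+)\\s*<-\\s*(.*\\S)\\s*$", line))[[1]]
      if (!length(m)) perr(i, paste0("malformed rule declaration: ", line))
      if (!(m[2] %in% seen_nodes)) perr(i, paste0("rule references undeclared node: ", m[2]))
      ast <- tryCatch(parse_formula(m[4]), error = function(e) perr(i, conditionMessage(e)))
      val <- as.integer(m[3])
      rules[[m[2]]] <- c(rules[[m[2]]], list(list(value = val, formula = ast)))
      attach_comment(paste0("rule:", m[2], ":", val))
    } else {
      perr(i, paste0("unrecognized declaration: ", line))
    }
  }
  comments$model <- pending
  if (!length(nodes)) stop("empty model: no node declared", call. = FALSE)
  # group formulas of one (node, value) into a single OR-combined rule entry
  rule_entries <- lapply(rules, function(lst) {
    vals <- vapply(lst, function(x) x$value, integer(1))
    lapply(unique(vals), function(v) {
      list(value = v, formulas = lapply(lst[vals == v], `[[`, "formula"))
    })
  })
  logical_model(do.call(rbind, nodes),
                if (length(edges)) do.call(rbind, edges),
                rule_entries, comments = comments)
}

#' Serialize a model to its text format
#'
#' Canonical serialization of the model grammar; \code{parse_model(write_model(m))}
#' is structurally identical to \code{m} (comments included).
#'
#' @param model a [logical_model()].
#' @return a single string ending in a newline.
#' @export
write_model <- function(model) {
  out <- character(0)
  cm <- model$comments
  el <- if (is.list(cm)) cm$elements else NULL
  emit_comments <- function(key) {
    for (c in el[[key]]) out <<- c(out, paste0("# ", c))
  }
  for (i in seq_len(nrow(model$nodes))) {
    id <- model$nodes$id[i]
    emit_comments(paste0("node:", id))
    out <- c(out, sprintf("node %s max=%d%s", id, model$nodes$max[i],
                          if (model$nodes$input[i]) " input" else ""))
  }
  ia <- model$interactions
  for (i in seq_len(nrow(ia))) {
    key <- paste0("edge:", ia$source[i], "->", ia$target[i], ":", ia$threshold[i])
    emit_comments(key)
    out <- c(out, sprintf("edge %s -> %s t=%d sign=%s",
                          ia$source[i], ia$target[i], ia$threshold[i], ia$sign[i]))
  }
  for (g in node_ids(model)) {
    for (e in model$rules[[g]]) {
      emit_comments(paste0("rule:", g, ":", e$value))
      for (f in e$formulas) {
        out <- c(out, sprintf("rule %s := %d <- %s", g, e$value, format_formula(f)))
      }
    }
  }
  for (c in if (is.list(cm)) cm$model else character(0)) {
    out <- c(out, paste0("# ", c))
  }
  paste0(paste(out, collapse = "\n"), "\n")
}

#' @rdname parse_model
#' @param path file path (UTF-8 text).
#' @export
read_lrg <- function(path) parse_model(readLines(path, encoding = "UTF-8", warn = FALSE))

#' @rdname write_model
#' @param path file path to write.
#' @export
write_lrg <- function(model, path) {
  writeLines(sub("\n$", "", write_model(model)), path, useBytes = FALSE)
  invisible(path)
}
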