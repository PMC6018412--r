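# Packaged reference model and the random-model generator.

#' The four-node p53-Mdm2 model
#'
#' The multi-valued logical model of the mammalian p53-Mdm2 network: p53
#' (levels 0..2), cytoplasmic Mdm2 (0..2), nuclear Mdm2 (0..1) and DNA damage
#' (0..1), in that node order, with the signed threshold interactions and
#' logical rules of the published four-node model.  Nuclear Mdm2 degrades
#' p53; p53 activates cytoplasmic Mdm2 but blocks its nuclear translocation;
#' DNA damage accelerates nuclear Mdm2 degradation and is repaired under high
#' p53.  Its asynchronous dynamics has 36 states and a unique stable state
#' \code{"0110"} (the resting state).
#'
#' @return a validated [logical_model()].
#' @export
p53_mdm2_model <- function() {
  path <- system.file("extdata", "p53_mdm2.lrg", package = "mvlogic",
                      mustWork = TRUE)
  read_lrg(path)
}

#' Generate a random logical model
#'
#' Draws a random regulatory graph (each ordered node pair carries an arc
#' with probability \code{density}; multi-valued sources may carry several
#' thresholds) and then draws, for every regulated node, a random
#' target-level function that is piecewise constant on the activity windows
#' of its regulators.  Rules are synthesized from that function, so the rule
#' entries of a node are mutually exclusive by construction, every literal
#' resolves, and declared interaction thresholds and signs agree with the
#' rules.  Unregulated nodes are occasionally marked as inputs.  The same
#' seed always yields the same model; the caller's RNG state is left
#' untouched.
#'
#' @param n_nodes number of nodes (>= 1).
#' @param max_level_cap maximal level any node may have (>= 1).
#' @param density arc probability in (0, 1].
#' @param seed integer seed.
#' @return a validated [logical_model()].
#' @export
random_model <- function(n_nodes, max_level_cap = 2L, density = 0.3, seed) {
  stopifnot(n_nodes >= 1L, max_level_cap >= 1L, density > 0, density <= 1)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  ids <- sprintf("g%d", seq_len(n_nodes))
  maxes <- sample.int(max_level_cap, n_nodes, replace = TRUE)
  nodes <- data.frame(id = ids, max = maxes, input = FALSE,
                      stringsAsFactors = FALSE)
  # candidate arcs with random threshold sets
  cand <- list()
  for (s in seq_len(n_nodes)) {
    for (g in seq_len(n_nodes)) {
      if (stats::runif(1) > density) next
      k <- sample.int(maxes[s], 1L)
      cand[[length(cand) + 1L]] <- data.frame(
        source = ids[s], target = ids[g],
        threshold = sort(sample.int(maxes[s], k)),
        stringsAsFactors = FALSE)
    }
  }
  cand <- do.call(rbind, c(cand, list(data.frame(source = character(0),
                                                 target = character(0),
                                                 threshold = integer(0)))))
  proto <- logical_model(nodes, cbind(cand, sign = rep("?", nrow(cand))),
                         validate = FALSE)
  interactions <- list(); rules <- list()
  for (g in ids) {
    regs <- regulators(proto, g)
    if (!length(regs)) next
    # random value on each window box of the candidate regulators
    windows <- lapply(regs, function(s) {
      t <- arc_thresholds(proto, s, g)
      c(0L, t)  # lower bounds of windows [0,t1-1], [t1,t2-1], ..., [tk,max]
    })
    names(windows) <- regs
    grid <- regulator_grid(proto, regs)
    box_of <- do.call(paste, lapply(regs, function(s) {
      findInterval(grid[[s]], windows[[s]])
    }))
    vals <- stats::setNames(
      sample.int(node_max(proto, g) + 1L, length(unique(box_of)), replace = TRUE) - 1L,
      unique(box_of))
    # a constant non-zero function has no literal-only formula; use the null
    # function instead (the node then simply relaxes to 0)
    if (length(unique(vals)) == 1L && vals[1] != 0L) vals[] <- 0L
    tbl <- cbind(grid, value = as.integer(vals[box_of]))
    part <- synthesize_node(proto, g, tbl)
    if (!is.null(part$interactions)) {
      interactions[[g]] <- part$interactions
      if (length(part$entries)) rules[[g]] <- part$entries
    }
  }
  interactions <- do.call(rbind, c(unname(interactions),
                                   list(data.frame(source = character(0),
                                                   target = character(0),
                                                   threshold = integer(0),
                                                   sign = character(0)))))
  regulated <- unique(interactions$target)
  for (i in seq_len(n_nodes)) {
    if (!(ids[i] %in% regulated) && stats::runif(1) < 0.3) nodes$input[i] <- TRUE
  }
  logical_model(nodes, interactions, rules)
}
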