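# Updating schemes, successors, STG construction, perturbations.

test_that("worked transitions of the reference model", {
  m <- fixture_model()
  succ <- function(code, scheme) {
    sort(vapply(successors(m, model_state(m, code), scheme),
                state_code, character(1)))
  }
  expect_identical(succ("0200", "asynchronous"), c("0100", "0210", "1200"))
  expect_identical(succ("0010", "synchronous"), "0100")
  for (sch in c("asynchronous", "synchronous", "complete", "sequential")) {
    expect_length(successors(m, model_state(m, "0110"), sch), 0L)
  }
  # complete updating: every non-empty subset of the three calls at 0200
  expect_length(succ("0200", "complete"), 7L)
  # sequential sweep uses the progressively updated state
  expect_identical(succ("0200", "sequential"), "1100")
})

test_that("full asynchronous STG has 36 states and a unique stable state 0110", {
  stg <- build_stg(fixture_model(), "asynchronous")
  expect_length(stg$states, 36L)
  expect_identical(stg_stable_states(stg), "0110")
})

test_that("synchronous dynamics is deterministic", {
  stg <- build_stg(fixture_model(), "synchronous")
  expect_length(stg$states, 36L)
  expect_true(all(table(stg$edges$from) <= 1L))
})

test_that("initial patterns restrict the STG to the reachable subgraph", {
  m <- fixture_model()
  full <- build_stg(m, "asynchronous")
  part <- build_stg(m, "asynchronous", initial = "0111")
  expect_true("0111" %in% part$states)
  expect_true(all(part$states %in% full$states))
  expect_true(all(edge_set(part) %in% edge_set(full)))
  expect_lt(length(part$states), length(full$states))
  # every state reachable from 0111 in the full STG is present
  g <- igraph::graph_from_data_frame(full$edges,
                                     vertices = data.frame(name = full$states))
  reach <- names(igraph::subcomponent(g, "0111", mode = "out"))
  expect_setequal(part$states, reach)
  # wildcard pattern expansion
  expect_identical(nrow(expand_pattern(m, "0*1*")), 6L)
  expect_error(expand_pattern(m, "031*"), "out of bounds")
})

test_that("asynchronous transitions are unit steps; synchronous steps all calls", {
  for (m in model_pool(seeds = 1:8)) {
    as <- build_stg(m, "asynchronous")
    for (i in seq_len(nrow(as$edges))) {
      a <- model_state(m, as$edges$from[i])
      b <- model_state(m, as$edges$to[i])
      expect_identical(sum(abs(a - b)), 1L)
    }
    sy <- build_stg(m, "synchronous")
    for (i in seq_len(nrow(sy$edges))) {
      a <- model_state(m, sy$edges$from[i])
      b <- model_state(m, sy$edges$to[i])
      calls <- called_nodes(m, a)
      expect_identical(sum(abs(a - b)), nrow(calls))
      expect_true(all(abs(a - b) <= 1L))
    }
  }
})

test_that("asynchronous and synchronous relations are subsets of the complete relation", {
  for (m in model_pool(seeds = 3:8)) {
    co <- edge_set(build_stg(m, "complete"))
    expect_true(all(edge_set(build_stg(m, "asynchronous")) %in% co))
    expect_true(all(edge_set(build_stg(m, "synchronous")) %in% co))
  }
})

test_that("stable states are identical across updating schemes", {
  schemes <- list("asynchronous", "synchronous", "complete", "sequential")
  for (m in model_pool(seeds = 1:10)) {
    ref <- as.character(compute_stable(m))
    for (sch in schemes) {
      expect_identical(sort(stg_stable_states(build_stg(m, sch))), ref)
    }
  }
})

test_that("a single all-node priority class reproduces the plain schemes", {
  m <- fixture_model()
  for (inner in c("asynchronous", "synchronous")) {
    pr <- updating_scheme("priority",
                          classes = list(list(nodes = m$nodes$id, rank = 1L,
                                              mode = inner)))
    expect_identical(sorted_edges(build_stg(m, pr)),
                     sorted_edges(build_stg(m, inner)))
  }
})

test_that("priority classes gate updates by rank", {
  m <- fixture_model()
  # DNA damage and p53 outrank the Mdm2 forms: at 0200 only p53 may move
  pr <- updating_scheme("priority", classes = list(
    list(nodes = c("p53", "DNAdam"), rank = 1L, mode = "asynchronous"),
    list(nodes = c("Mdm2cyt", "Mdm2nuc"), rank = 2L, mode = "synchronous")))
  s <- vapply(successors(m, model_state(m, "0200"), pr), state_code, character(1))
  expect_identical(s, "1200")
  # with no higher-ranked call, the lower class fires under its inner mode
  s2 <- vapply(successors(m, model_state(m, "2200"), pr), state_code, character(1))
  expect_identical(s2, "2210")
  # classes must partition the node set
  bad <- updating_scheme("priority", classes = list(
    list(nodes = "p53", rank = 1L, mode = "asynchronous")))
  expect_error(successors(m, model_state(m, "0200"), bad), "partition")
})

test_that("perturbations clamp target levels", {
  m <- fixture_model()
  p <- perturbation(DNAdam = 1)
  mp <- apply_perturbation(m, p)
  calls <- called_nodes(mp, model_state(mp, "0110"))
  expect_true("DNAdam" %in% calls$node)
  expect_identical(calls$dir[calls$node == "DNAdam"], 1L)
  # brute force: the ectopic-damage model has no stable state at all
  expect_length(brute_stable(mp), 0L)
  # the identity clamp changes nothing
  mid <- apply_perturbation(m, perturbation(p53 = c(0, 2)))
  expect_identical(sorted_edges(build_stg(mid, "asynchronous")),
                   sorted_edges(build_stg(m, "asynchronous")))
  expect_error(apply_perturbation(m, perturbation(nosuch = 1)), "unknown node")
  expect_error(perturbation(p53 = c(2, 1)), "low <= high")
})

test_that("attractors of a clamped model sit at the clamped level", {
  for (s in 1:6) {
    m <- model_pool(seeds = s, n_nodes = 3L)[[1]]
    g <- m$nodes$id[1L + (s %% nrow(m$nodes))]
    v <- s %% (mvlogic:::node_max(m, g) + 1L)
    p <- do.call(perturbation, stats::setNames(list(v), g))
    stg <- build_stg(m, "asynchronous", perturbation = p)
    for (a in attractors(stg)) {
      lv <- vapply(a$states, function(code) model_state(m, code)[[g]], integer(1))
      expect_true(all(lv == v))
    }
  }
})

test_that("the state cap guards full enumeration", {
  m <- fixture_model()
  expect_error(build_stg(m, "asynchronous", max_states = 10),
               class = "mvlogic_cap_error")
  expect_error(build_stg(m, "asynchronous", initial = "2211", max_states = 3),
               class = "mvlogic_cap_error")
})
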