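# SCC quotient, attractors, hierarchical transition graph.

test_that("the asynchronous STG has two non-trivial SCCs of sizes 9 and 6", {
  stg <- build_stg(fixture_model(), "asynchronous")
  q <- scc_quotient(stg)
  sizes <- sort(lengths(q$members)[lengths(q$members) > 1L])
  expect_identical(sizes, c(6L, 9L))
  # the quotient is acyclic and partitions the state set
  qg <- igraph::graph_from_data_frame(q$edges, vertices =
          data.frame(name = seq_along(q$members)))
  expect_true(igraph::is_dag(qg))
  expect_setequal(unlist(q$members), stg$states)
  expect_identical(anyDuplicated(unlist(q$members)), 0L)
})

test_that("a directed cycle collapses to one SCC; deterministic STGs have only cyclic attractors", {
  # 1-node oscillator: level flips between 0 and 1 forever
  osc <- logical_model(data.frame(id = "x", max = 1L),
                       data.frame(source = "x", target = "x",
                                  threshold = 1L, sign = "-"),
                       rules = list(x = list(list(value = 1L,
                         formulas = list(parse_formula("!x"))))))
  q <- scc_quotient(build_stg(osc, "asynchronous"))
  expect_length(q$members, 1L)
  expect_identical(q$kind, "cyclic_terminal")
  # synchronous determinism: non-trivial SCCs are exactly the cyclic attractors
  sy <- build_stg(fixture_model(), "synchronous")
  qs <- scc_quotient(sy)
  nt <- which(lengths(qs$members) > 1L)
  expect_identical(sort(qs$kind[nt]), rep("cyclic_terminal", 2L))
})

test_that("attractors are the terminal SCCs", {
  m <- fixture_model()
  a_async <- attractors(build_stg(m, "asynchronous"))
  expect_length(a_async, 1L)
  expect_identical(a_async[[1]]$kind, "stable")
  expect_identical(a_async[[1]]$states, "0110")
  a_sync <- attractors(build_stg(m, "synchronous"))
  expect_length(a_sync, 3L)
  kinds <- sort(vapply(a_sync, `[[`, character(1), "kind"))
  expect_identical(kinds, c("cyclic", "cyclic", "stable"))
  expect_identical(sort(lengths(lapply(a_sync, `[[`, "states"))), c(1L, 2L, 2L))
  # ectopic DNA damage: the unique attractor is cyclic
  a_pert <- attractors(build_stg(m, "asynchronous",
                                 perturbation = perturbation(DNAdam = 1)))
  expect_length(a_pert, 1L)
  expect_identical(a_pert[[1]]$kind, "cyclic")
})

test_that("the hierarchical transition graph matches the published compression", {
  stg <- build_stg(fixture_model(), "asynchronous")
  h <- build_htg(stg)
  expect_length(h$members, 6L)
  ct <- which(h$kind == "cyclic_transient")
  expect_identical(sort(lengths(h$members[ct])), c(6L, 9L))
  expect_setequal(h$label[ct], c("ct#9", "ct#6"))
  big <- h$members[[ct[which.max(lengths(h$members[ct]))]]]
  small <- h$members[[ct[which.min(lengths(h$members[ct]))]]]
  # large oscillations run under DNA damage, small ones after repair
  expect_true(all(substr(big, 4, 4) == "1"))
  expect_true(all(substr(small, 4, 4) == "0"))
  expect_true("0110" %in% h$label[h$kind == "stable"])
  # acyclic; members partition the states; terminal nodes are the attractors
  hg <- igraph::graph_from_data_frame(h$edges, vertices =
          data.frame(name = seq_along(h$members)))
  expect_true(igraph::is_dag(hg))
  expect_setequal(unlist(h$members), stg$states)
  terminal <- setdiff(seq_along(h$members), h$edges$from)
  att <- attractors(stg)
  expect_setequal(lapply(h$members[terminal], sort),
                  lapply(att, function(a) sort(a$states)))
})

test_that("a linear path of states compresses to chain plus stable state", {
  # one rule-free 4-level node decays 3 -> 2 -> 1 -> 0
  chain <- logical_model(data.frame(id = "x", max = 3L))
  h <- build_htg(build_stg(chain, "asynchronous"))
  expect_length(h$members, 2L)
  expect_setequal(h$kind, c("transient_chain", "stable"))
  expect_identical(sort(h$members[[which(h$kind == "transient_chain")]]),
                   c("1", "2", "3"))
})

test_that("the reduced model keeps both transient oscillatory components", {
  r <- reduce_model(fixture_model(), "Mdm2cyt")
  h <- build_htg(build_stg(r, "asynchronous"))
  expect_identical(sum(h$kind == "cyclic_transient"), 2L)
  dam <- vapply(which(h$kind == "cyclic_transient"), function(i) {
    unique(substr(h$members[[i]], 3, 3))
  }, character(1))
  expect_setequal(dam, c("0", "1"))
})

test_that("wildcard patterns cover member sets exactly", {
  m <- fixture_model()
  h <- build_htg(build_stg(m, "asynchronous"))
  for (i in seq_along(h$members)) {
    pats <- state_patterns(m, h$members[[i]])
    covered <- unlist(lapply(pats, function(p) {
      apply(expand_pattern(m, p), 1L, paste, collapse = "")
    }))
    expect_identical(sort(covered), h$members[[i]])
  }
  # grouped-by-star rendering concentrates free nodes, e.g. 9 states in 5 rows
  nine <- h$members[[which(h$label == "ct#9")]]
  expect_lt(length(state_patterns(m, nine)), length(nine))
})

test_that("HTG invariants hold on randomized models", {
  for (m in model_pool(seeds = 11:16)) {
    stg <- build_stg(m, "asynchronous")
    h <- build_htg(stg)
    expect_setequal(unlist(h$members), stg$states)
    expect_identical(anyDuplicated(unlist(h$members)), 0L)
    hg <- igraph::graph_from_data_frame(h$edges, vertices =
            data.frame(name = seq_along(h$members)))
    expect_true(igraph::is_dag(hg))
    terminal <- setdiff(seq_along(h$members), h$edges$from)
    expect_setequal(lapply(h$members[terminal], sort),
                    lapply(attractors(stg), function(a) sort(a$states)))
  }
})
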