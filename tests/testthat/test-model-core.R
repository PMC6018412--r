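# Core semantics: literals, target levels, update calls, validation.

test_that("literal truth follows interaction activity windows", {
  m <- fixture_model()
  # Mdm2cyt carries thresholds 1 and 2 toward Mdm2nuc: the window of the
  # threshold-1 interaction is exactly [1, 1]
  st <- model_state(m, c(0, 2, 0, 0))
  expect_false(eval_literal(m, "Mdm2nuc", "Mdm2cyt", st, threshold = 1))
  expect_true(eval_literal(m, "Mdm2nuc", "Mdm2cyt", st, threshold = 2))
  st1 <- model_state(m, c(0, 1, 0, 0))
  expect_true(eval_literal(m, "Mdm2nuc", "Mdm2cyt", st1, threshold = 1))
  # bare self-loop literal, level below threshold
  expect_false(eval_literal(m, "DNAdam", "DNAdam", model_state(m, "0000")))
  # the bare p53 literal in DNAdam's rule resolves to threshold 2 (window [2,2])
  for (lv in 0:2) {
    st <- model_state(m, c(lv, 0, 0, 0))
    expect_identical(eval_literal(m, "DNAdam", "p53", st), lv == 2L)
  }
  # a bare literal on a multi-threshold arc is ambiguous
  expect_error(eval_literal(m, "Mdm2nuc", "Mdm2cyt", st1), "ambiguous")
  # a literal must name a declared regulator
  expect_error(eval_literal(m, "p53", "DNAdam", st1), "regulator")
})

test_that("activity windows of one arc tile [min threshold, max]; level 0 activates nothing", {
  m <- fixture_model()
  arcs <- unique(m$interactions[, c("source", "target")])
  for (i in seq_len(nrow(arcs))) {
    s <- arcs$source[i]; g <- arcs$target[i]
    ths <- mvlogic:::arc_thresholds(m, s, g)
    covered <- unlist(lapply(ths, function(th) {
      w <- mvlogic:::literal_window(m, s, g, th)
      w[1]:w[2]
    }))
    # disjoint, contiguous, from the lowest threshold up to the source max
    expect_identical(sort(covered), min(ths):mvlogic:::node_max(m, s))
    expect_false(0L %in% covered)
  }
})

test_that("target levels follow the unique satisfied rule entry, default 0", {
  m <- fixture_model()
  # second disjunct of the nuclear-Mdm2 rule fires at medium cytoplasmic Mdm2
  expect_identical(target_level(m, model_state(m, c(0, 1, 0, 0)), "Mdm2nuc"), 1L)
  # the resting state is its own target on every node
  st <- model_state(m, "0110")
  for (g in m$nodes$id) expect_identical(target_level(m, st, g), st[[g]])
  # a node devoid of rules relaxes to 0
  plain <- logical_model(data.frame(id = c("a", "b"), max = 1L),
                         data.frame(source = "a", target = "b",
                                    threshold = 1L, sign = "+"))
  for (code in c("00", "01", "10", "11")) {
    expect_identical(target_level(plain, model_state(plain, code), "a"), 0L)
    expect_identical(target_level(plain, model_state(plain, code), "b"), 0L)
  }
  # input nodes maintain their level
  inp <- logical_model(data.frame(id = c("i", "b"), max = c(2L, 1L),
                                  input = c(TRUE, FALSE)),
                       data.frame(source = "i", target = "b",
                                  threshold = 2L, sign = "+"),
                       rules = list(b = list(list(value = 1L,
                         formulas = list(parse_formula("i"))))))
  expect_identical(target_level(inp, model_state(inp, "20"), "i"), 2L)
  expect_identical(target_level(inp, model_state(inp, "20"), "b"), 1L)
})

test_that("update calls list the nodes off their target, with unit directions", {
  m <- fixture_model()
  calls <- called_nodes(m, model_state(m, "0200"))
  expect_identical(calls$node, c("p53", "Mdm2cyt", "Mdm2nuc"))
  expect_identical(calls$dir, c(1L, -1L, 1L))
  expect_identical(nrow(called_nodes(m, model_state(m, "0110"))), 0L)
  # at rest with no nuclear Mdm2, both p53 (via !Mdm2nuc) and Mdm2cyt (via
  # !p53) are called upward -- consistent with the STG arcs 0000 -> 1000, 0100
  calls0 <- called_nodes(m, model_state(m, "0000"))
  expect_identical(calls0$node, c("p53", "Mdm2cyt"))
  expect_identical(calls0$dir, c(1L, 1L))
})

test_that("a state is stable exactly when no node is called", {
  m <- fixture_model()
  mat <- state_space(m)
  n_stable <- 0L
  for (i in seq_len(nrow(mat))) {
    st <- stats::setNames(mat[i, ], colnames(mat))
    calls <- called_nodes(m, st)
    expect_identical(nrow(calls) == 0L, is_stable_state(m, st))
    for (g in m$nodes$id) {
      t <- target_level(m, st, g)
      expect_true(t >= 0L && t <= mvlogic:::node_max(m, g))
      expect_true(abs(t - st[[g]]) < 1L || g %in% calls$node)
    }
    if (nrow(calls) == 0L) n_stable <- n_stable + 1L
  }
  # brute force over all 36 states: exactly one stable state
  expect_identical(n_stable, 1L)
  expect_identical(brute_stable(m), "0110")
})

test_that("validation accepts the reference model and reports violations with witnesses", {
  expect_true(is_valid(validate_model(fixture_model())))
  # overlapping rule entries for distinct target values
  conflict <- logical_model(data.frame(id = c("A", "B"), max = c(1L, 2L)),
                            data.frame(source = "A", target = "B",
                                       threshold = 1L, sign = "+"),
                            rules = list(B = list(
                              list(value = 1L, formulas = list(parse_formula("A"))),
                              list(value = 2L, formulas = list(parse_formula("A"))))),
                            validate = FALSE)
  rep <- validate_model(conflict)
  expect_false(is_valid(rep))
  expect_true(any(rep$code == "rule_conflict" & grepl("A=1", rep$message)))
  # threshold above the source's maximal level
  bad <- logical_model(data.frame(id = c("A", "B"), max = c(2L, 1L)),
                       data.frame(source = "A", target = "B",
                                  threshold = 3L, sign = "+"),
                       validate = FALSE)
  expect_true(any(validate_model(bad)$code == "threshold"))
  # input node with an incoming interaction
  badin <- logical_model(data.frame(id = c("A", "B"), max = 1L,
                                    input = c(FALSE, TRUE)),
                         data.frame(source = "A", target = "B",
                                    threshold = 1L, sign = "+"),
                         validate = FALSE)
  expect_true(any(validate_model(badin)$code == "input_regulated"))
  # rule conflicts also surface at evaluation time, with the witness state
  expect_error(target_level(conflict, model_state(conflict, "10"), "B"),
               "rule conflict")
})
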