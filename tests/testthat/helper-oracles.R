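# Reference implementations and small builders shared by the tests.

# Brute-force stable-state oracle: enumerate the full product state space and
# keep the states where no node is called.  Normative definition of
# stability; compute_stable() must agree with it.
brute_stable <- function(model) {
  mat <- state_space(model)
  codes <- character(0)
  for (i in seq_len(nrow(mat))) {
    st <- stats::setNames(mat[i, ], colnames(mat))
    if (is_stable_state(model, st)) codes <- c(codes, state_code(st))
  }
  sort(codes)
}

# structural model comparison (ignores clamps and comments)
model_equal <- function(a, b) {
  isTRUE(all.equal(a$nodes, b$nodes)) &&
    isTRUE(all.equal(a$interactions, b$interactions, check.attributes = FALSE)) &&
    identical(a$rules, b$rules)
}

fixture_model <- function() p53_mdm2_model()

sorted_edges <- function(stg) {
  e <- stg$edges
  e <- e[order(e$from, e$to), , drop = FALSE]
  rownames(e) <- NULL
  e
}

edge_set <- function(stg) paste(stg$edges$from, stg$edges$to)

# a deterministic pool of small random models for property tests
model_pool <- function(seeds, n_nodes = NULL, cap = 2L, density = 0.45) {
  lapply(seeds, function(s) {
    n <- if (is.null(n_nodes)) 2L + (s %% 4L) else n_nodes
    random_model(n_nodes = n, max_level_cap = cap, density = density, seed = s)
  })
}
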