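# shared fixtures, built once per test run

# the default 1366-cell template
test_graph <- local({
  g <- NULL
  function() {
    if (is.null(g)) g <<- build_sam_template()
    g
  }
})

# a small 3-layer template (~48 cells) for simulation-heavy unit tests
mini_graph <- local({
  g <- NULL
  function() {
    if (is.null(g)) {
      cv <- 2 * 0.25 / sqrt(pi)
      g <<- build_sam_template(n_layers = 3,
                               layer_radii = cv * sqrt(c(12, 16, 20) + 0.5))
    }
    g
  }
})

# minimal 3-cell vertical stack (one cell per layer)
stack_graph <- local({
  g <- NULL
  function() {
    if (is.null(g)) {
      cv <- 2 * 0.25 / sqrt(pi)
      g <<- build_sam_template(n_layers = 3, layer_radii = rep(cv * sqrt(1.5), 3))
    }
    g
  }
})
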