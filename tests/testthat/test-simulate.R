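test_that("TVD-RK2 step reproduces the two-stage formula and order 2", {
  # scalar decay du/dt = -u: one step by hand gives 0.990050
  u1 <- tvd_rk2_step(1, 0.01, function(u) -u)
  expect_equal(u1, 0.99005, tolerance = 1e-10)
  # zero derivative leaves the state unchanged
  expect_equal(tvd_rk2_step(c(1, 2), 0.5, function(u) 0 * u), c(1, 2))
  expect_error(tvd_rk2_step(1, 0, function(u) -u), "positive")
  expect_error(tvd_rk2_step(1, 0.1, function(u) NaN), "NaN")
  # halving dt reduces the global error on u' = -u by about 4x
  integrate_decay <- function(dt) {
    u <- 1
    for (i in seq_len(round(1 / dt))) u <- tvd_rk2_step(u, dt, function(x) -x)
    abs(u - exp(-1))
  }
  e1 <- integrate_decay(0.02)
  e2 <- integrate_decay(0.01)
  expect_gt(e1 / e2, 3.5)
  expect_lt(e1 / e2, 4.5)
})

test_that("one C++ integrator step equals an R TVD-RK2 step on rhs()", {
  g <- mini_graph()
  p <- sam_params()
  v <- variant("DUAL", "WT")
  p2 <- in_silico_treatment(p, v)
  set.seed(7)
  st <- empty_state(g)
  st[] <- runif(length(st), 0, 3)
  r_step <- tvd_rk2_step(st, 0.01, function(s) {
    colnames(s) <- colnames(st)
    rhs(s, g, p2, v)
  })
  csr <- wusgrad:::.csr(g)
  syn <- p2$A1 * wus_synthesis_indicator(g, p2$r_w, p2$L_w, p2$L_w_min)
  cpp <- wusgrad:::cpp_integrate(
    st, csr$row_ptr, csr$col_ind, csr$cond, syn,
    as.numeric(g$cells$layer <= p2$clv3_outer_max_layer),
    as.numeric(g$cells$z > p2$ck_deep_zmin),
    unclass(p2), wusgrad:::.variant_flags(p2, v),
    0.01, 1L, clip = FALSE)
  expect_equal(unname(cpp$state), unname(r_step), tolerance = 1e-12)
})

test_that("with no production all species decay to zero", {
  g <- mini_graph()
  p <- sam_params(A1 = 0, C_p = 0, ck_prod_L = 0, ck_prod_R = 0)
  s <- run_to_steady(g, p, variant("DUAL", "WT"), t_final = 100)
  expect_lt(max(abs(s$final_state)), 1e-8)
  expect_true(s$converged)
})

test_that("gradient metrics compute ratios, domains and thresholds", {
  g <- test_graph()
  st <- empty_state(g)
  # uniform nuclear field: L3:L1 ratio 1; Wn = Wc gives N-C ratio 1
  st[, "Wn"] <- 2; st[, "Wc"] <- 2
  m <- gradient_metrics(st, g)
  expect_equal(m$l3_l1_ratio, 1)
  expect_equal(unname(m$nc_ratio), rep(1, 7))
  expect_equal(m$clv3_domain, "absent")
  # Wn 3x higher in L3 than L1
  st2 <- st
  st2[g$cells$layer == 3, "Wn"] <- 6
  expect_equal(gradient_metrics(st2, g)$l3_l1_ratio, 3)
  # CLV3 present only in L1/L2: outer; anywhere deeper: internalized
  st3 <- st
  st3[g$cells$layer <= 2, "Co"] <- 1
  expect_equal(gradient_metrics(st3, g)$clv3_domain, "outer")
  st3[g$cells$layer == 4, "Ci"] <- 1
  expect_equal(gradient_metrics(st3, g)$clv3_domain, "internalized")
  # zero layer means raise
  expect_error(gradient_metrics(empty_state(g), g), "zero")
})

test_that("simulation reports convergence against the stated tolerance", {
  g <- mini_graph()
  p <- sam_params()
  s <- run_to_steady(g, p, variant("DUAL", "WT"))
  expect_true(s$converged)
  expect_lt(s$residual, 1e-6)
  # a too-short run is flagged, not raised
  s2 <- run_to_steady(g, p, variant("DUAL", "WT"), t_final = 0.5)
  expect_false(s2$converged)
})

test_that("trajectory trace is strided and ends at the final time", {
  g <- mini_graph()
  s <- run_to_steady(g, sam_params(), variant("DUAL", "WT"), t_final = 10,
                     trace_every = 100)
  expect_false(is.null(s$trace))
  expect_equal(nrow(s$trace), 10 / 0.01 / 100 + 1)
  expect_equal(s$trace[2, 1] - s$trace[1, 1], 1)
})
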