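test_that("Hill functions match their closed forms and bounds", {
  expect_equal(hill_down(0, 1, 2), 1)
  expect_equal(hill_down(1, 1, 3), 0.5)
  expect_equal(hill_down(2, 1, 2), 0.2)   # 1 / (1 + 4)
  expect_error(hill_down(1, 0, 2), "positive")
  x <- seq(0, 10, length.out = 50)
  h <- hill_down(x, 2.5, 3)
  expect_true(all(h >= 0 & h <= 1))
  expect_true(all(diff(h) < 0))
  expect_equal(hill_up(x, 2.5, 3), 1 - h)
})

test_that("hat-shaped CLV3 production vanishes at the extremes and is unimodal", {
  p <- sam_params()
  expect_equal(clv3_production(0, p), 0)
  expect_lt(clv3_production(1e6, p), 1e-10)
  wn <- exp(seq(log(0.01), log(100), length.out = 300))
  f <- clv3_production(wn, p)
  # unimodal: increases to a single peak then decreases
  i <- which.max(f)
  expect_true(all(diff(f[1:i]) > 0))
  expect_true(all(diff(f[i:length(f)]) < 0))
  # peak location agrees with a brute-force grid maximisation oracle
  grid <- seq(0.01, 20, by = 0.001)
  oracle <- grid[which.max(clv3_production(grid, p))]
  expect_equal(clv3_hat_peak(p), oracle, tolerance = 1e-3)
})

test_that("nuclear degradation rate is self-stabilising and bounded", {
  p <- sam_params()
  expect_equal(nuclear_degradation_rate(0, p), p$d_wn * p$d_max)
  expect_equal(nuclear_degradation_rate(p$k_ww, p),
               p$d_wn * (p$d_min + p$d_max) / 2)
  expect_equal(nuclear_degradation_rate(1e9, p), p$d_wn * p$d_min,
               tolerance = 1e-6)
  wn <- seq(0, 50, length.out = 100)
  r <- nuclear_degradation_rate(wn, p)
  expect_true(all(diff(r) <= 0))
  expect_true(all(r >= p$d_wn * p$d_min & r <= p$d_wn * p$d_max))
  p2 <- sam_params(self_stab_on = FALSE)
  expect_equal(nuclear_degradation_rate(wn, p2), rep(p2$d_wn, 100))
})

test_that("graph diffusion matches the flux formula and conserves mass", {
  g <- stack_graph()
  # two connected cells: direct evaluation of the flux sum
  field <- c(2, 0, 0)
  r <- diffusion_rates(field, g, 1)
  gcond <- g$edges$area[1] / g$edges$distance[1]
  expect_equal(r[1], -2 * gcond)
  expect_lt(abs(sum(r)), 1e-12)
  # uniform field: zero everywhere
  expect_equal(diffusion_rates(rep(3, 3), g, 1), rep(0, 3))
  # random fields on the full template: total amount conserved
  gr <- test_graph()
  set.seed(42)
  for (k in 1:5) {
    f <- runif(gr$n)
    expect_lt(abs(sum(diffusion_rates(f, gr, 2.5))), 1e-10)
  }
  expect_error(diffusion_rates(1:5, g, 1), "length")
  expect_error(diffusion_rates(field, g, -1), "non-negative")
})

test_that("rhs is zero for an empty tissue outside the synthesis domain", {
  g <- mini_graph()
  p <- sam_params(A1 = 0, ck_on = FALSE)
  d <- rhs(empty_state(g), g, p)
  expect_true(all(d == 0))
})

test_that("mRNA subsystem reaches W* = A1/d_W inside the domain", {
  g <- mini_graph()
  p <- basic_params(A1 = 12, d_W = 2)
  s <- run_to_steady(g, p, variant("DUAL", "CLV3_NULL"), t_final = 30)
  ind <- wus_synthesis_indicator(g, p$r_w, p$L_w, p$L_w_min)
  expect_equal(unname(s$final_state[ind == 1, "W"]),
               rep(12 / 2, sum(ind)), tolerance = 1e-8)
  expect_equal(unname(s$final_state[ind == 0, "W"]), rep(0, sum(ind == 0)))
})

test_that("rhs at a converged final state is numerically zero", {
  g <- mini_graph()
  p <- sam_params()
  s <- run_to_steady(g, p, variant("DUAL", "WT"))
  d <- rhs(s$final_state, g, p, variant("DUAL", "WT"))
  expect_lt(max(abs(d)), 1e-6 * max(1, max(abs(s$final_state))))
})

test_that("with feedbacks off, nuclear WUS is monotone in each screened rate", {
  g <- mini_graph()
  apex <- apex_cells(g, 3)
  base <- basic_params(A1 = 10, D_w = 4, d_wn = 1, d_wc = 1, r_ex = 1)
  wn_of <- function(p, layer) {
    s <- run_to_steady(g, p, variant("DUAL", "CLV3_NULL"), t_final = 150)
    mean(s$final_state[apex$id[apex$layer == layer], "Wn"])
  }
  up <- function(nm, layer = 2) {
    p <- base; p[[nm]] <- p[[nm]] * 2
    wn_of(p, layer)
  }
  expect_gt(up("A1"), wn_of(base, 2))
  # diffusion dilutes the source layer (quantified inside the domain)
  expect_lt(up("D_w", 3), wn_of(base, 3))
  expect_lt(up("d_wc"), wn_of(base, 2))
  expect_lt(up("d_wn"), wn_of(base, 2))
  expect_lt(up("r_ex"), wn_of(base, 2))
})

test_that("the cytokinin block is autonomous and consistent with its solver", {
  g <- mini_graph()
  p <- sam_params()
  ck <- ck_steady_state(g, p)
  # residual of the CK equations at the computed steady state
  st <- empty_state(g)
  st[, c("CkL", "CkR", "CkX")] <- ck
  d <- rhs(st, g, p, variant("DUAL", "WT"))
  expect_lt(max(abs(d[, c("CkL", "CkR", "CkX")])), 1e-8)
  # independence from the WUS/CLV3 state
  st2 <- st
  st2[, "W"] <- 5; st2[, "Wc"] <- 3; st2[, "Wn"] <- 7; st2[, "Co"] <- 2
  d2 <- rhs(st2, g, p, variant("DUAL", "WT"))
  expect_equal(d2[, c("CkL", "CkR", "CkX")], d[, c("CkL", "CkR", "CkX")])
})

test_that("variant switches act on the parameter set as documented", {
  p <- sam_params()
  expect_equal(in_silico_treatment(p, variant("DUAL", "CLV3_NULL"))$C_p, 0)
  expect_equal(in_silico_treatment(p, variant("DUAL", "WT", "LEPB"))$r_ex, 0)
  e <- in_silico_treatment(p, variant("DUAL", "WT", "EARLM"))
  expect_equal(e$r_ex, 0)
  expect_equal(e$d_wc, p$d_wc * p$earlm_dwc_factor)
  expect_equal(in_silico_treatment(p, variant("DUAL", "WT", "WBM"))$ck_s_ex, 0)
  expect_error(variant("DUAL", "WT", "MCLV3"), "dose")
})

test_that("parameter i/o round-trips and validation rejects bad values", {
  p <- sam_params()
  f <- tempfile(fileext = ".json")
  write_params(p, f)
  p2 <- read_params(f)
  expect_equal(unclass(p2), unclass(p))
  expect_error(sam_params(d_wc = -1), "negative")
  expect_error(sam_params(n1 = 0.5), "Hill")
  expect_error(sam_params(inner_potency = 0), "inner_potency")
  expect_error(sam_params(nonsense = 1), "unknown")
})
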