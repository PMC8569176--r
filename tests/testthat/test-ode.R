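test_that("without CLV3 production the steady state has its closed form", {
  p <- reduced_params(sam_params(self_stab_on = FALSE), Wp = 20)
  p$C_p <- 0
  ss <- solve_steady_state(p, "DUAL")
  expect_length(ss, 1)
  y <- ss[[1]]$y
  expect_equal(unname(y["W"]), 20 / p$d_W, tolerance = 1e-10)
  expect_equal(unname(y["C"]), 0)
  # linear chain: Wc and Wn satisfy the export/import balance exactly
  expect_equal(unname(y["Wc"]),
               unname((p$d_wn + p$r_ex) * y["Wn"] / p$r_im), tolerance = 1e-8)
  expect_false(ss[[1]]$coexisting)
  expect_true(ss[[1]]$stable)
})

test_that("returned roots satisfy all four equations to 1e-10", {
  for (reg in c("DUAL", "TRANSCRIPTIONAL_ONLY")) {
    ss <- solve_steady_state(reduced_params(calibrated_params()), reg)
    for (s in ss) expect_lt(max(s$residuals), 1e-10)
  }
})

test_that("dual and transcriptional-only rhs differ only in the export terms", {
  p <- reduced_params(calibrated_params())
  y <- c(W = 3, Wc = 2, Wn = 4, C = 1.5)
  d_dual <- reduced_rhs(y, p, "DUAL")
  d_tr <- reduced_rhs(y, p, "TRANSCRIPTIONAL_ONLY")
  expect_equal(d_dual[c("W", "C")], d_tr[c("W", "C")])
  expect_false(isTRUE(all.equal(d_dual["Wc"], d_tr["Wc"])))
  # the export flux moved between compartments: sums match
  expect_equal(d_dual["Wc"] + d_dual["Wn"], d_tr["Wc"] + d_tr["Wn"],
               tolerance = 1e-12, ignore_attr = TRUE)
  # hat production vanishes at Wn = 0 whatever C_p
  expect_equal(unname(reduced_rhs(c(0, 0, 0, 0), p, "DUAL")["C"]), 0)
})

test_that("a fully decoupled system has eigenvalues at minus the decay rates", {
  p <- reduced_params(sam_params(self_stab_on = FALSE), Wp = 0)
  p$r_c <- 0; p$r_ex <- 0; p$r_im <- 0; p$C_p <- 0
  ss <- assess_stability(list(y = c(W = 0, Wc = 0, Wn = 0, C = 0)), p, "DUAL")
  expect_equal(sort(Re(ss$eigenvalues)),
               sort(-c(p$d_W, p$d_wc, p$d_wn, p$d_c)), tolerance = 1e-6)
  expect_true(ss$stable)
})

test_that("root finding agrees with a dense-grid sign-scan oracle", {
  set.seed(101)
  n_checked <- 0
  for (i in 1:40) {
    p <- reduced_params(sam_params(self_stab_on = sample(c(TRUE, FALSE), 1)),
                        Wp = exp(runif(1, log(1), log(80))))
    for (nm in c("d_wc", "r_ex", "d_wn", "C_p", "d_c", "k_cw1", "k_cw2",
                 "k_wc1", "k_wc2"))
      p[[nm]] <- p[[nm]] * exp(runif(1, log(0.3), log(3)))
    reg <- sample(c("DUAL", "TRANSCRIPTIONAL_ONLY"), 1)
    ss <- tryCatch(solve_steady_state(p, reg), error = function(e) NULL)
    if (is.null(ss)) next
    # oracle: sign changes of the scalar balance on a 60k-point dense grid
    grid <- exp(seq(log(1e-6), log(1e4), length.out = 60000))
    gv <- wusgrad:::.ss_balance(grid, p, reg)
    flips <- which(sign(gv[-1]) * sign(gv[-60000]) < 0)
    expect_equal(length(ss), length(flips))
    roots <- vapply(ss, function(s) unname(s$y["Wn"]), numeric(1))
    oracle <- sqrt(grid[flips] * grid[flips + 1])
    expect_equal(sort(roots), sort(oracle), tolerance = 1e-3)
    n_checked <- n_checked + 1
  }
  expect_gt(n_checked, 30)
})

test_that("perturbation scan reports zero shift at factor one and monotone k_cw1", {
  p <- reduced_params(calibrated_params())
  base <- solve_steady_state(p, "DUAL")
  keep <- which(vapply(base, function(s)
    isTRUE(s$coexisting) && isTRUE(s$stable), logical(1)))
  wn0 <- base[[keep]]$y["Wn"]
  tab <- local_perturbation_scan(p, factors = c(1), params = c("Wp", "d_wc"))
  expect_equal(tab$Wn_ss, rep(unname(wn0), 2), tolerance = 1e-8)
  # weaker CLV3 repression of transcription cannot lower the mRNA level
  tab2 <- local_perturbation_scan(p, factors = c(1, 1.3), params = "k_cw1")
  w_at <- function(f) {
    q <- p; q$k_cw1 <- q$k_cw1 * f
    ss <- solve_steady_state(q, "DUAL")
    max(vapply(ss, function(s) unname(s$y["W"]), numeric(1)))
  }
  expect_gte(w_at(1.3), w_at(1) - 1e-8)
  expect_s3_class(tab2, "data.frame")
})

test_that("the calibrated set flips stability between regulation modes", {
  p <- reduced_params(calibrated_params())
  sd <- solve_steady_state(p, "DUAL")
  st <- solve_steady_state(p, "TRANSCRIPTIONAL_ONLY")
  # the number of steady states is the same in both modes
  expect_equal(length(sd), length(st))
  stable_coex <- which(vapply(sd, function(s)
    isTRUE(s$coexisting) && isTRUE(s$stable), logical(1)))
  expect_length(stable_coex, 1)
  wn_d <- sd[[stable_coex]]$y["Wn"]
  j <- which.min(abs(vapply(st, function(s) s$y["Wn"], numeric(1)) - wn_d))
  expect_false(st[[j]]$stable)
  expect_true(st[[j]]$coexisting)
})
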