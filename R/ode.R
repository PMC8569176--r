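#' Reduced single-compartment parameters
#'
#' Projects a tissue parameter set onto the spatially-ignored ODE system
#' (WUS mRNA, cytoplasmic and nuclear WUS, CLV3 in one compartment).
#'
#' `Wp` is the compartment's effective mRNA synthesis rate. In the tissue
#' only the synthesis-domain cells produce WUS mRNA while all 1366 cells
#' dilute the protein, so the lumped compartment is calibrated to the
#' apex zone where the CLV3 feedback operates: the shipped configuration
#' carries this value as `ode_Wp`, chosen so the reduced
#' steady state matches the wild-type apex nuclear-WUS level within a
#' factor of two. Parameter sets without `ode_Wp` fall back to `A1`.
#'
#' @param p `wus_params`.
#' @param Wp mRNA synthesis rate of the compartment.
#' @return list of class `reduced_params`.
#' @export
reduced_params <- function(p, Wp = NULL) {
  if (is.null(Wp)) Wp <- if (!is.null(p$ode_Wp)) p$ode_Wp else p$A1
  keep <- c("d_W", "r_c", "d_wc", "r_ex", "r_im", "d_wn", "d_min", "d_max",
            "k_ww", "n3", "k_cw1", "n1", "k_cw2", "n2", "C_p", "d_c",
            "k_wc1", "n4", "k_wc2", "n5", "self_stab_on")
  rp <- c(list(Wp = Wp), unclass(p)[keep])
  structure(rp, class = "reduced_params")
}

.ss_factor <- function(Wn, p) {
  if (!isTRUE(p$self_stab_on)) return(rep(1, length(Wn)))
  p$d_min + (p$d_max - p$d_min) / (1 + (Wn / p$k_ww)^p$n3)
}

.hat <- function(Wn, p) {
  u <- (Wn / p$k_wc2)^p$n5
  v <- (Wn / p$k_wc1)^p$n4
  p$C_p * (u / (1 + u)) / (1 + v)
}

#' Reduced ODE right-hand side
#'
#' The four-variable single-compartment system: CLV3 represses WUS
#' transcription; under dual regulation it also represses nuclear export;
#' CLV3 production is the hat-shaped function of nuclear WUS; nuclear
#' degradation carries the self-stabilisation factor.
#'
#' @param y state vector `(W, Wc, Wn, C)`.
#' @param p `reduced_params`.
#' @param regulation `"DUAL"` or `"TRANSCRIPTIONAL_ONLY"` (the CLV3 Hill
#'   factor on export replaced by 1).
#' @return derivative 4-vector.
#' @export
reduced_rhs <- function(y, p, regulation = c("DUAL", "TRANSCRIPTIONAL_ONLY")) {
  regulation <- match.arg(regulation)
  W <- unname(y[1]); Wc <- unname(y[2]); Wn <- unname(y[3]); C <- unname(y[4])
  h_ex <- if (regulation == "TRANSCRIPTIONAL_ONLY") 1
          else 1 / (1 + (C / p$k_cw2)^p$n2)
  ex <- p$r_ex * h_ex * Wn
  c(W = p$Wp / (1 + (C / p$k_cw1)^p$n1) - p$d_W * W,
    Wc = p$r_c * W - p$d_wc * Wc + ex - p$r_im * Wc,
    Wn = -p$d_wn * .ss_factor(Wn, p) * Wn - ex + p$r_im * Wc,
    C = .hat(Wn, p) - p$d_c * C)
}

# scalar steady-state balance in Wn: substitute the closed-form steady
# states of C, W and Wc and return the residual of the cytoplasmic flux
# balance
.ss_balance <- function(Wn, p, regulation) {
  C <- .hat(Wn, p) / p$d_c
  W <- (p$Wp / p$d_W) / (1 + (C / p$k_cw1)^p$n1)
  h_ex <- if (regulation == "TRANSCRIPTIONAL_ONLY") 1
          else 1 / (1 + (C / p$k_cw2)^p$n2)
  Wc <- (p$d_wn * .ss_factor(Wn, p) * Wn + p$r_ex * h_ex * Wn) / p$r_im
  p$r_c * W - p$d_wc * Wc + p$r_ex * h_ex * Wn - p$r_im * Wc
}

.ss_point <- function(Wn, p, regulation) {
  C <- .hat(Wn, p) / p$d_c
  W <- (p$Wp / p$d_W) / (1 + (C / p$k_cw1)^p$n1)
  h_ex <- if (regulation == "TRANSCRIPTIONAL_ONLY") 1
          else 1 / (1 + (C / p$k_cw2)^p$n2)
  Wc <- (p$d_wn * .ss_factor(Wn, p) * Wn + p$r_ex * h_ex * Wn) / p$r_im
  c(W = unname(W), Wc = unname(Wc), Wn = unname(Wn), C = unname(C))
}

#' Steady states of the reduced ODE system
#'
#' Substitutes the closed-form steady states of mRNA, cytoplasmic WUS and
#' CLV3 into the cytoplasmic flux balance, leaving one scalar equation in
#' nuclear WUS. Sign changes are bracketed on a log-spaced grid, refined
#' by [stats::uniroot()] and polished by Newton steps until the absolute
#' balance residual is below `res_tol`. Each root is returned with the
#' residuals of all four equations, Jacobian eigenvalues and a stability
#' flag.
#'
#' @param p `reduced_params`.
#' @param regulation `"DUAL"` or `"TRANSCRIPTIONAL_ONLY"`.
#' @param wn_range scan range for nuclear WUS.
#' @param grid_n log-grid resolution.
#' @param res_tol residual tolerance.
#' @return list of steady states; each has `y` (named 4-vector),
#'   `residuals`, `eigenvalues`, `stable` (NA when marginal),
#'   `coexisting`.
#' @export
solve_steady_state <- function(p, regulation = c("DUAL", "TRANSCRIPTIONAL_ONLY"),
                               wn_range = c(1e-6, 1e4), grid_n = 2000,
                               res_tol = 1e-10) {
  regulation <- match.arg(regulation)
  grid <- exp(seq(log(wn_range[1]), log(wn_range[2]), length.out = grid_n))
  gv <- vapply(grid, .ss_balance, numeric(1), p = p, regulation = regulation)
  sgn <- sign(gv)
  flips <- which(sgn[-1] * sgn[-grid_n] < 0)
  roots <- numeric(0)
  for (i in flips) {
    r <- stats::uniroot(.ss_balance, c(grid[i], grid[i + 1]), p = p,
                        regulation = regulation, tol = 1e-14)$root
    # Newton polish on the scalar balance
    for (k in 1:50) {
      fv <- .ss_balance(r, p, regulation)
      if (abs(fv) < res_tol) break
      h <- 1e-7 * max(abs(r), 1e-8)
      dfv <- (.ss_balance(r + h, p, regulation) -
              .ss_balance(r - h, p, regulation)) / (2 * h)
      if (!is.finite(dfv) || dfv == 0) break
      r <- r - fv / dfv
    }
    roots <- c(roots, r)
  }
  # exact zeros on the grid (rare ties)
  roots <- sort(unique(c(roots, grid[gv == 0])))
  if (length(roots) == 0)
    stop("no steady state found in the scan range")
  # "coexisting" means both species are appreciable: nuclear WUS above a
  # hard floor and CLV3 above 0.1% of its attainable maximum C_p/d_c.
  # Escaped high-WUS states retain a formally positive but negligible
  # CLV3 tail (Hill functions never reach zero), which an absolute
  # threshold would misclassify.
  c_thr <- max(1e-6, 1e-3 * p$C_p / p$d_c)
  lapply(roots, function(r) {
    y <- .ss_point(r, p, regulation)
    ss <- list(y = y, residuals = abs(reduced_rhs(y, p, regulation)),
               coexisting = unname(y["Wn"] > 1e-6 && y["C"] > c_thr))
    assess_stability(ss, p, regulation)
  })
}

#' Linear stability of a steady state
#'
#' Jacobian of [reduced_rhs()] by central finite differences (relative
#' step `1e-6`); the state is stable when all eigenvalue real parts are
#' negative. Marginal cases (`|Re| < 1e-8`) are flagged indeterminate
#' (`stable = NA`).
#'
#' @param ss steady-state list with element `y`.
#' @param p `reduced_params`.
#' @param regulation regulation mode.
#' @return `ss` with `eigenvalues` and `stable` added.
#' @export
assess_stability <- function(ss, p, regulation = c("DUAL", "TRANSCRIPTIONAL_ONLY")) {
  regulation <- match.arg(regulation)
  y <- ss$y
  J <- matrix(0, 4, 4)
  for (j in 1:4) {
    h <- 1e-6 * max(abs(y[j]), 1e-6)
    yp <- y; yp[j] <- y[j] + h
    ym <- y; ym[j] <- y[j] - h
    J[, j] <- (reduced_rhs(yp, p, regulation) -
               reduced_rhs(ym, p, regulation)) / (2 * h)
  }
  ev <- eigen(J, only.values = TRUE)$values
  re <- Re(ev)
  stable <- if (any(abs(re) < 1e-8)) NA else all(re < 0)
  ss$jacobian <- J
  ss$eigenvalues <- ev
  ss$stable <- stable
  ss
}

#' Single-parameter perturbation scan of the reduced steady state
#'
#' Multiplies one parameter at a time by each factor, re-solves the
#' steady states and records the stable coexisting root (falling back to
#' any coexisting root, then to the largest-`Wn` root). Lost-root cases
#' are recorded, not raised.
#'
#' @param p `reduced_params` with a stable coexisting baseline root.
#' @param factors multipliers to apply.
#' @param params parameter names to scan (default: all positive rates and
#'   EC50s).
#' @param regulation regulation mode.
#' @return data frame `param, factor, Wn_ss, C_ss, stable, n_roots,
#'   lost_root`.
#' @export
local_perturbation_scan <- function(p, factors = c(0.9, 1, 1.1),
                                    params = NULL,
                                    regulation = "DUAL") {
  if (is.null(params))
    params <- c("Wp", "d_W", "r_c", "d_wc", "r_ex", "r_im", "d_wn",
                "k_ww", "k_cw1", "k_cw2", "C_p", "d_c", "k_wc1", "k_wc2")
  rows <- list()
  for (nm in params) for (f in factors) {
    q <- p; q[[nm]] <- q[[nm]] * f
    res <- tryCatch(solve_steady_state(q, regulation), error = function(e) NULL)
    if (is.null(res)) {
      rows[[length(rows) + 1]] <- data.frame(
        param = nm, factor = f, Wn_ss = NA_real_, C_ss = NA_real_,
        stable = NA, n_roots = 0L, lost_root = TRUE)
      next
    }
    co <- Filter(function(s) isTRUE(s$coexisting) && isTRUE(s$stable), res)
    if (!length(co)) co <- Filter(function(s) isTRUE(s$coexisting), res)
    if (!length(co)) co <- res
    pick <- co[[which.max(vapply(co, function(s) s$y["Wn"], numeric(1)))]]
    rows[[length(rows) + 1]] <- data.frame(
      param = nm, factor = f, Wn_ss = unname(pick$y["Wn"]),
      C_ss = unname(pick$y["C"]), stable = pick$stable,
      n_roots = length(res), lost_root = length(co) == 0)
  }
  do.call(rbind, rows)
}
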