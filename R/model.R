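#' Decreasing Hill function
#'
#' `1 / (1 + (x/k)^n)`: the repression factor used throughout the model.
#' @param x concentration (>= 0).
#' @param k EC50 (> 0).
#' @param n Hill exponent (>= 1).
#' @return fraction in `[0, 1]`, strictly decreasing in `x`.
#' @export
hill_down <- function(x, k, n) {
  if (any(k <= 0)) stop("Hill EC50 k must be positive")
  1 / (1 + (x / k)^n)
}

#' Increasing (saturating) Hill function
#' @inheritParams hill_down
#' @return fraction in `[0, 1]`, increasing in `x`.
#' @export
hill_up <- function(x, k, n) {
  if (any(k <= 0)) stop("Hill EC50 k must be positive")
  xn <- (x / k)^n
  xn / (1 + xn)
}

#' Hat-shaped CLV3 production rate
#'
#' CLV3 transcription is activated by low nuclear WUS and repressed by
#' high nuclear WUS:
#' `C_p / ((1 + (Wn/k_wc1)^n4) * (1 + (Wn/k_wc2)^(-n5)))`.
#' Evaluated in the algebraically equivalent form
#' `C_p * u/(1+u) * 1/(1+v)` with `u = (Wn/k_wc2)^n5`,
#' `v = (Wn/k_wc1)^n4`, which is 0 at `Wn = 0` without special-casing.
#'
#' @param Wn nuclear WUS concentration (vectorised).
#' @param p `wus_params` (uses `C_p`, `k_wc1`, `n4`, `k_wc2`, `n5`).
#' @return production rate; 0 at `Wn = 0`, unimodal, tending to 0 as
#'   `Wn` grows.
#' @export
clv3_production <- function(Wn, p) {
  u <- (Wn / p$k_wc2)^p$n5
  v <- (Wn / p$k_wc1)^p$n4
  p$C_p * (u / (1 + u)) / (1 + v)
}

#' Location of the CLV3 activation peak
#'
#' Argmax of [clv3_production()] over a log grid, refined by
#' [stats::optimize()]. The wild-type regime places the apex-L1 nuclear
#' WUS level to the right of this peak (the repressive flank).
#' @param p `wus_params`.
#' @return nuclear WUS concentration at which CLV3 production peaks.
#' @export
clv3_hat_peak <- function(p) {
  grid <- exp(seq(log(1e-4), log(1e4), length.out = 400))
  f <- clv3_production(grid, p)
  i <- which.max(f)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  stats::optimize(function(w) clv3_production(w, p),
                  lower = lo, upper = hi, maximum = TRUE)$maximum
}

#' Self-stabilised nuclear degradation rate
#'
#' `d_wn * (d_min + (d_max - d_min) / (1 + (Wn/k_ww)^n3))`: nuclear WUS
#' protects itself from degradation, so the per-molecule rate falls from
#' `d_wn * d_max` (dilute) to `d_wn * d_min` (concentrated).
#' @param Wn nuclear WUS concentration (vectorised).
#' @param p `wus_params`.
#' @return degradation rate, bounded in `[d_wn*d_min, d_wn*d_max]`.
#' @export
nuclear_degradation_rate <- function(Wn, p) {
  if (!isTRUE(p$self_stab_on)) return(rep(p$d_wn, length(Wn)))
  p$d_wn * (p$d_min + (p$d_max - p$d_min) * hill_down(Wn, p$k_ww, p$n3))
}

#' Graph-diffusion rates
#'
#' Discrete flux sum `rate_i = sum_j D_ij (A_ij/l_ij) (u_j - u_i)` over
#' cell contacts. `D` may be a scalar coefficient or one value per
#' directed edge (row of `graph$edges`), e.g. a CLV3-regulated
#' coefficient evaluated at the mean concentration of the two cells. The
#' operator has no external edges (no-flux boundary) and conserves the
#' total amount under symmetric `D`.
#'
#' @param field per-cell values.
#' @param graph a `cell_graph`.
#' @param D scalar or per-directed-edge diffusion coefficient.
#' @return per-cell rate vector.
#' @export
diffusion_rates <- function(field, graph, D) {
  if (length(field) != graph$n) stop("field length must equal cell count")
  if (any(D < 0)) stop("diffusion coefficients must be non-negative")
  e <- graph$edges
  flux <- D * (e$area / e$distance) * (field[e$j] - field[e$i])
  out <- numeric(graph$n)
  agg <- rowsum(flux, e$i)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' Named empty tissue state
#'
#' @param graph a `cell_graph`.
#' @return `n x 8` matrix with columns `W` (WUS mRNA), `Wc`, `Wn`
#'   (cytoplasmic / nuclear WUS protein), `Co`, `Ci` (CLV3 synthesised in
#'   outer / inner layers), `CkL`, `CkR`, `CkX` (cytokinin ligand,
#'   receptor, complex), all zero.
#' @export
empty_state <- function(graph) {
  matrix(0, graph$n, 8,
         dimnames = list(NULL, c("W", "Wc", "Wn", "Co", "Ci",
                                 "CkL", "CkR", "CkX")))
}

#' Effective CLV3 concentration sensed by a cell
#'
#' Outer-source CLV3 at full potency, inner-source CLV3 weighted by
#' `inner_potency` under the dual+spatial variant (weight 1 otherwise),
#' plus any exogenous peptide dose.
#' @noRd
.c_eff <- function(state, p, v) {
  pot <- if (v$regulation == "DUAL_SPATIAL") p$inner_potency else 1
  state[, "Co"] + pot * state[, "Ci"] + v$mclv3_dose
}

#' Model right-hand side (reference implementation)
#'
#' Time derivative of the full tissue state for a given variant. This is
#' the R reference; [run_to_steady()] integrates an identical C++
#' transcription of these equations, and a unit test pins the two to each
#' other. Genotype/treatment switches are expected to have been applied
#' to `p` already (see [in_silico_treatment()]); the regulation mode and
#' the exogenous peptide dose are read from `v`.
#'
#' @param state `n x 8` state matrix (see [empty_state()]).
#' @param graph a `cell_graph`.
#' @param p `wus_params`.
#' @param v `wus_variant`.
#' @return `n x 8` matrix of time derivatives.
#' @export
rhs <- function(state, graph, p, v = variant()) {
  if (any(!is.finite(state))) stop("non-finite values in state")
  n <- graph$n
  d <- empty_state(graph)
  W <- state[, "W"]; Wc <- state[, "Wc"]; Wn <- state[, "Wn"]
  trans_only <- v$regulation == "TRANSCRIPTIONAL_ONLY"

  Ceff <- if (isTRUE(p$clv3_on) || v$mclv3_dose > 0) .c_eff(state, p, v)
          else numeric(n)
  h_tx <- if (isTRUE(p$clv3_on) || v$mclv3_dose > 0)
            hill_down(Ceff, p$k_cw1, p$n1) else 1
  h_ex <- if (trans_only || !(isTRUE(p$clv3_on) || v$mclv3_dose > 0)) 1
          else hill_down(Ceff, p$k_cw2, p$n2)

  if (isTRUE(p$ck_on)) {
    X <- state[, "CkX"]
    stab <- p$ck_s_wc * hill_up(X, p$ck_k_wc, p$ck_n)
    ret <- p$ck_s_ex * hill_up(X, p$ck_k_ex, p$ck_n)
  } else {
    stab <- 0; ret <- 0
  }

  syn <- p$A1 * wus_synthesis_indicator(graph, p$r_w, p$L_w, p$L_w_min)
  d[, "W"] <- syn * h_tx - p$d_W * W

  D_edge <- if (trans_only || !(isTRUE(p$clv3_on) || v$mclv3_dose > 0)) p$D_w
            else {
              e <- graph$edges
              p$D_w * hill_down((Ceff[e$i] + Ceff[e$j]) / 2, p$k_cw3, p$n6)
            }
  export <- p$r_ex * h_ex * (1 - ret) * Wn
  d[, "Wc"] <- diffusion_rates(Wc, graph, D_edge) + p$r_c * W -
    p$d_wc * (1 - stab) * Wc + export - p$r_im * Wc
  d[, "Wn"] <- -nuclear_degradation_rate(Wn, p) * Wn - export + p$r_im * Wc

  if (isTRUE(p$clv3_on)) {
    prod <- clv3_production(Wn, p)
    outer <- graph$cells$layer <= p$clv3_outer_max_layer
    d[, "Co"] <- prod * outer + diffusion_rates(state[, "Co"], graph, p$D_c) -
      p$d_c * state[, "Co"]
    d[, "Ci"] <- prod * (!outer) +
      diffusion_rates(state[, "Ci"], graph, p$D_c) - p$d_c * state[, "Ci"]
  }

  if (isTRUE(p$ck_on)) {
    L <- state[, "CkL"]; R <- state[, "CkR"]; X <- state[, "CkX"]
    deep <- as.numeric(graph$cells$z > p$ck_deep_zmin)
    bind <- p$ck_k_on * L * R
    d[, "CkL"] <- p$ck_prod_L * deep + diffusion_rates(L, graph, p$ck_D_L) -
      p$ck_d_L * L - bind + p$ck_k_off * X
    d[, "CkR"] <- p$ck_prod_R * deep - p$ck_d_R * R - bind + p$ck_k_off * X
    d[, "CkX"] <- bind - p$ck_k_off * X - p$ck_d_X * X
  }
  d
}
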