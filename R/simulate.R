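#' One TVD-RK2 (Heun) step
#'
#' Two-stage total-variation-diminishing Runge-Kutta step:
#' `u1 = u + dt f(u)`; `u_next = (u + u1 + dt f(u1)) / 2`.
#' Works on any state shape for which `f` returns a conformable
#' derivative.
#'
#' @param state current state (vector or matrix).
#' @param dt time step (> 0).
#' @param f derivative function of one argument.
#' @return the advanced state.
#' @export
tvd_rk2_step <- function(state, dt, f) {
  if (dt <= 0) stop("dt must be positive")
  d0 <- f(state)
  if (any(!is.finite(d0))) stop("NaN in derivative")
  u1 <- state + dt * d0
  d1 <- f(u1)
  if (any(!is.finite(d1))) stop("NaN in derivative")
  0.5 * state + 0.5 * (u1 + dt * d1)
}

# compressed sparse row arrays (0-based) of the contact graph
.csr <- function(graph) {
  e <- graph$edges  # sorted by i then j at build time
  counts <- tabulate(e$i, nbins = graph$n)
  list(row_ptr = as.integer(c(0L, cumsum(counts))),
       col_ind = as.integer(e$j - 1L),
       cond = e$area / e$distance)
}

.variant_flags <- function(p, v) {
  list(clv3_on = isTRUE(p$clv3_on),
       ck_on = isTRUE(p$ck_on),
       self_stab = isTRUE(p$self_stab_on),
       trans_only = v$regulation == "TRANSCRIPTIONAL_ONLY",
       pot = if (v$regulation == "DUAL_SPATIAL") p$inner_potency else 1,
       dose = v$mclv3_dose)
}

#' Autonomous cytokinin steady state
#'
#' The CK ligand/receptor/complex block is independent of WUS and CLV3,
#' so its steady state can be computed once per graph and used as the
#' initial condition, removing a long CK transient. Solved by alternating
#' a per-cell receptor update with a sparse linear solve for the
#' diffusing ligand.
#'
#' @param graph a `cell_graph`.
#' @param p `wus_params`.
#' @param tol fixed-point tolerance.
#' @return `n x 3` matrix with columns `CkL`, `CkR`, `CkX`.
#' @export
ck_steady_state <- function(graph, p, tol = 1e-12) {
  n <- graph$n
  deep <- as.numeric(graph$cells$z > p$ck_deep_zmin)
  gs <- Matrix::rowSums(graph$G)
  cc <- p$ck_d_X * p$ck_k_on / (p$ck_k_off + p$ck_d_X)
  L <- numeric(n)
  for (it in 1:200) {
    R <- p$ck_prod_R * deep / (p$ck_d_R + cc * L)
    M <- Matrix::Diagonal(n, p$ck_d_L + cc * R + p$ck_D_L * gs) -
      p$ck_D_L * graph$G
    L_new <- as.numeric(Matrix::solve(M, p$ck_prod_L * deep))
    if (max(abs(L_new - L)) < tol * max(1, max(L_new))) { L <- L_new; break }
    L <- L_new
  }
  R <- p$ck_prod_R * deep / (p$ck_d_R + cc * L)
  X <- p$ck_k_on * L * R / (p$ck_k_off + p$ck_d_X)
  cbind(CkL = L, CkR = R, CkX = X)
}

#' Integrate the tissue model to steady state
#'
#' Runs the full cell-based model from a zero initial state (CK species
#' start at their autonomous steady state) with the TVD-RK2 integrator at
#' fixed `dt` up to `t_final`, then reports the end residual and the
#' gradient metrics. Negative transients are clipped to zero and counted.
#'
#' @param graph a `cell_graph`.
#' @param p `wus_params` (genotype/treatment switches of `v` are applied
#'   internally via [in_silico_treatment()]).
#' @param v `wus_variant`.
#' @param dt time step.
#' @param t_final final time.
#' @param init optional full `n x 8` initial state (overrides the
#'   default).
#' @param tol convergence tolerance on the relative end residual
#'   `max|du/dt| / max(1, max|u|)`.
#' @param trace_every if > 0, record tissue-mean concentrations every
#'   this many steps.
#' @param metrics_width apex column width for the gradient metrics.
#' @return list of class `sam_sim`: `final_state`, `converged`,
#'   `residual`, `metrics` (see [gradient_metrics()]; `NULL` if not
#'   computable), `nclip`, `trace`, `params`, `variant`.
#' @export
run_to_steady <- function(graph, p, v = variant(), dt = 0.01, t_final = 300,
                          init = NULL, tol = 1e-6, trace_every = 0,
                          metrics_width = 3L) {
  stopifnot(inherits(graph, "cell_graph"))
  p <- in_silico_treatment(validate_params(p), v)
  csr <- .csr(graph)
  syn <- p$A1 * wus_synthesis_indicator(graph, p$r_w, p$L_w, p$L_w_min)
  outer <- as.numeric(graph$cells$layer <= p$clv3_outer_max_layer)
  deep <- as.numeric(graph$cells$z > p$ck_deep_zmin)
  state0 <- if (is.null(init)) empty_state(graph) else init
  if (is.null(init) && isTRUE(p$ck_on))
    state0[, c("CkL", "CkR", "CkX")] <- ck_steady_state(graph, p)
  nsteps <- as.integer(round(t_final / dt))
  res <- cpp_integrate(state0, csr$row_ptr, csr$col_ind, csr$cond,
                       syn, outer, deep, unclass(p), .variant_flags(p, v),
                       dt, nsteps, clip = TRUE, trace_every = trace_every)
  final <- res$state
  colnames(final) <- colnames(state0)
  if (res$nclip > 0)
    message("clipped ", res$nclip, " transient negative value(s) to 0")
  d <- rhs(final, graph, p, v)
  residual <- max(abs(d)) / max(1, max(abs(final)))
  metrics <- tryCatch(gradient_metrics(final, graph, width = metrics_width,
                                       p = p),
                      error = function(e) NULL)
  structure(list(final_state = final, converged = residual < tol,
                 residual = residual, metrics = metrics,
                 nclip = res$nclip, trace = res$trace,
                 params = p, variant = v),
            class = "sam_sim")
}

#' @export
print.sam_sim <- function(x, ...) {
  cat("tissue simulation (", x$variant$regulation, ", ",
      x$variant$genotype, ", ", x$variant$treatment, "): ",
      if (x$converged) "converged" else "NOT converged",
      ", residual ", format(x$residual, digits = 3), "\n", sep = "")
  if (!is.null(x$metrics))
    cat("  L3:L1 nuclear WUS =", round(x$metrics$l3_l1_ratio, 3),
        "| N-C ratios:", paste(round(x$metrics$nc_ratio, 2), collapse = ", "),
        "| CLV3 domain:", x$metrics$clv3_domain, "\n")
  invisible(x)
}

#' Gradient metrics of a tissue state
#'
#' Quantification mirrors the imaging analysis: only the `width` cells
#' nearest the tissue axis in each layer (the centre apex column) enter
#' the layer means. Reports per-layer mean nuclear WUS, cytoplasmic WUS
#' and total CLV3; the L3:L1 nuclear-WUS ratio; the per-layer
#' nuclear-to-cytoplasmic (N-C) ratio; the CLV3 expression-domain label
#' (`outer` when cells above threshold lie only in L1/L2, `internalized`
#' when any lie in L3 or deeper, `absent` when none); and the
#' shallowest/deepest layer with WUS mRNA above threshold.
#'
#' Thresholds default to 10% of the state's own apex maximum; pass fixed
#' values (e.g. from a wild-type baseline) when classifying perturbation
#' sweeps.
#'
#' @param state `n x 8` state matrix.
#' @param graph a `cell_graph`.
#' @param width apex column width (3-5).
#' @param clv3_threshold CLV3-positive threshold (absolute).
#' @param wus_threshold WUS-mRNA-positive threshold (absolute).
#' @param p optional `wus_params`; when given and thresholds are `NULL`,
#'   thresholds are `clv3_pos_threshold` / `wus_pos_threshold` fractions
#'   of the apex maxima.
#' @return list of class `gradient_metrics`: `layer_means` (data frame),
#'   `l3_l1_ratio`, `nc_ratio` (named per-layer vector), `clv3_domain`,
#'   `wus_domain_depth` (shallowest, deepest layer), and the thresholds
#'   used.
#' @export
gradient_metrics <- function(state, graph, width = 3L,
                             clv3_threshold = NULL, wus_threshold = NULL,
                             p = NULL) {
  apex <- apex_cells(graph, width)
  C_all <- state[, "Co"] + state[, "Ci"]
  lm_list <- lapply(split(apex$id, apex$layer), function(ids) {
    c(Wn = mean(state[ids, "Wn"]), Wc = mean(state[ids, "Wc"]),
      C = mean(C_all[ids]), W = mean(state[ids, "W"]))
  })
  layer_means <- do.call(rbind, lm_list)
  layer_means <- data.frame(layer = as.integer(rownames(layer_means)),
                            layer_means, row.names = NULL)

  wn1 <- layer_means$Wn[layer_means$layer == 1]
  wn3 <- layer_means$Wn[layer_means$layer == 3]
  if (wn1 == 0) stop("mean apex nuclear WUS in L1 is zero; L3:L1 undefined")
  l3_l1 <- wn3 / wn1
  if (any(layer_means$Wc == 0))
    stop("a layer mean cytoplasmic WUS is zero; N-C ratio undefined")
  nc <- stats::setNames(layer_means$Wn / layer_means$Wc,
                        paste0("L", layer_means$layer))

  cfrac <- if (!is.null(p)) p$clv3_pos_threshold else 0.1
  wfrac <- if (!is.null(p)) p$wus_pos_threshold else 0.1
  # with parameters available, CLV3-positive cells are classified on the
  # per-cell production rate (the promoter-reporter readout); otherwise
  # on the peptide concentration
  clv3_field <- if (!is.null(p)) {
    if (p$C_p > 0) clv3_production(state[, "Wn"], p) else rep(0, graph$n)
  } else C_all
  if (is.null(clv3_threshold))
    clv3_threshold <- cfrac * max(clv3_field[apex$id])
  if (is.null(wus_threshold))
    wus_threshold <- wfrac * max(state[apex$id, "W"])

  pos_layers <- unique(graph$cells$layer[clv3_field > clv3_threshold &
                                         clv3_threshold > 0])
  clv3_domain <- if (length(pos_layers) == 0) "absent"
                 else if (any(pos_layers >= 3)) "internalized"
                 else "outer"

  w_layers <- layer_means$layer[layer_means$W > wus_threshold &
                                wus_threshold > 0]
  wus_depth <- if (length(w_layers)) range(w_layers) else c(NA_integer_,
                                                            NA_integer_)

  structure(list(layer_means = layer_means, l3_l1_ratio = l3_l1,
                 nc_ratio = nc, clv3_domain = clv3_domain,
                 wus_domain_depth = wus_depth,
                 clv3_threshold = clv3_threshold,
                 wus_threshold = wus_threshold),
            class = "gradient_metrics")
}
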