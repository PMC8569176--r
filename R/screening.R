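#' Gradient selection criteria
#'
#' The printed screening bands: L3:L1 nuclear-WUS ratio between 3 and 6;
#' N-C ratio in every layer between 0.5 and 2; mean apex nuclear WUS
#' above the threshold (1) in both L1 and L2.
#'
#' @param l3_l1_range ratio band.
#' @param nc_range N-C band.
#' @param wn_threshold minimum nuclear WUS in L1 and L2.
#' @return list of class `selection_criteria`.
#' @export
selection_criteria <- function(l3_l1_range = c(3, 6), nc_range = c(0.5, 2),
                               wn_threshold = 1) {
  stopifnot(l3_l1_range[1] <= l3_l1_range[2], nc_range[1] <= nc_range[2],
            wn_threshold > 0)
  structure(list(l3_l1_range = l3_l1_range, nc_range = nc_range,
                 wn_threshold = wn_threshold), class = "selection_criteria")
}

#' Apply the selection criteria to gradient metrics
#'
#' @param metrics a [gradient_metrics()] result.
#' @param criteria a [selection_criteria()].
#' @return list of logical flags `ratio`, `nc`, `wn`, and their
#'   conjunction `pass`.
#' @export
apply_criteria <- function(metrics, criteria = selection_criteria()) {
  lm <- metrics$layer_means
  f1 <- metrics$l3_l1_ratio >= criteria$l3_l1_range[1] &&
        metrics$l3_l1_ratio <= criteria$l3_l1_range[2]
  f2 <- all(metrics$nc_ratio >= criteria$nc_range[1] &
            metrics$nc_ratio <= criteria$nc_range[2])
  f3 <- all(lm$Wn[lm$layer %in% 1:2] > criteria$wn_threshold)
  list(ratio = f1, nc = f2, wn = f3, pass = f1 && f2 && f3)
}

#' Screen parameter sets against the gradient criteria
#'
#' Simulates the basic clv3-null model (no CLV3 feedback, no cytokinin,
#' no self-stabilisation) for every design row and applies the selection
#' criteria. Non-convergent rows fail automatically with the reason
#' recorded.
#'
#' @param graph a `cell_graph`.
#' @param design matrix of parameter rows (columns `A1, D_w, d_wn, d_wc,
#'   r_ex`), e.g. [sobol_pooled_rows()] of the default design truncated
#'   to 220 rows.
#' @param criteria a [selection_criteria()].
#' @param base_params baseline `wus_params` supplying the fixed rates.
#' @return list of class `screening_result`: `table` (one row per set:
#'   parameters, metrics, flags), `pass_count`, `passing` (subset of
#'   `table`).
#' @export
screen_parameter_sets <- function(graph, design,
                                  criteria = selection_criteria(),
                                  base_params = basic_params()) {
  rows <- lapply(seq_len(nrow(design)), function(r) {
    p <- base_params
    for (nm in colnames(design)) p[[nm]] <- design[r, nm]
    p$clv3_on <- FALSE; p$ck_on <- FALSE; p$self_stab_on <- FALSE
    sim <- tryCatch(run_to_steady(graph, p, variant("DUAL", "CLV3_NULL")),
                    error = function(e) NULL)
    out <- as.data.frame(as.list(design[r, ]))
    if (is.null(sim) || !sim$converged || is.null(sim$metrics)) {
      out$l3_l1 <- NA_real_; out$nc_min <- NA_real_; out$nc_max <- NA_real_
      out$wn_L1 <- NA_real_; out$wn_L2 <- NA_real_
      out$ratio_ok <- FALSE; out$nc_ok <- FALSE; out$wn_ok <- FALSE
      out$pass <- FALSE
      out$reason <- if (is.null(sim)) "error" else "not converged"
      return(out)
    }
    m <- sim$metrics
    fl <- apply_criteria(m, criteria)
    lm <- m$layer_means
    out$l3_l1 <- m$l3_l1_ratio
    out$nc_min <- min(m$nc_ratio); out$nc_max <- max(m$nc_ratio)
    out$wn_L1 <- lm$Wn[lm$layer == 1]; out$wn_L2 <- lm$Wn[lm$layer == 2]
    out$ratio_ok <- fl$ratio; out$nc_ok <- fl$nc; out$wn_ok <- fl$wn
    out$pass <- fl$pass
    out$reason <- ""
    out
  })
  tab <- do.call(rbind, rows)
  structure(list(table = tab, pass_count = sum(tab$pass),
                 passing = tab[tab$pass, , drop = FALSE],
                 criteria = criteria),
            class = "screening_result")
}

#' @export
print.screening_result <- function(x, ...) {
  cat("parameter screening:", x$pass_count, "of", nrow(x$table),
      "sets pass all criteria\n")
  invisible(x)
}

#' Correlation structure of the selected parameter sets
#'
#' Log-log Pearson correlations among the passing sets for the pairs
#' (diffusion, cytoplasmic degradation), (nuclear export, nuclear
#' degradation) and (synthesis, cytoplasmic degradation), together with
#' the WUS decay length `sqrt(D_w / d_wc)` of each set. The first pair
#' is expected positive (fixed decay length), the second negative (N-C
#' balance), the third positive (level balance).
#'
#' @param passing data frame of passing parameter sets (columns `A1,
#'   D_w, d_wn, d_wc, r_ex`).
#' @return list: `correlations` (data frame `pair, r`), `decay_length`,
#'   `insufficient` (TRUE when fewer than 3 sets).
#' @export
selected_set_properties <- function(passing) {
  dl <- sqrt(passing$D_w / passing$d_wc)
  if (nrow(passing) < 3)
    return(list(correlations = NULL, decay_length = dl, insufficient = TRUE))
  pairs <- list(c("D_w", "d_wc"), c("r_ex", "d_wn"), c("A1", "d_wc"))
  cors <- data.frame(
    pair = vapply(pairs, paste, character(1), collapse = "~"),
    r = vapply(pairs, function(pr)
      stats::cor(log(passing[[pr[1]]]), log(passing[[pr[2]]])), numeric(1)))
  list(correlations = cors, decay_length = dl, insufficient = FALSE)
}

#' Expression-rate perturbation sweep for a model variant
#'
#' Scales the maximal WUS mRNA (`A1`) or CLV3 (`C_p`) production rate by
#' each multiplier, simulates to steady state and classifies the CLV3
#' expression domain and the WUS gradient. The CLV3-positive and
#' WUS-positive thresholds are fixed from the unperturbed dual-regulation
#' baseline so that domain labels are comparable across variants and
#' multipliers.
#'
#' @param graph a `cell_graph`.
#' @param params calibrated `wus_params` baseline.
#' @param v `wus_variant` whose regulation mode is swept.
#' @param parameter `"A1"` or `"C_p"`.
#' @param multipliers scale factors (must include 1).
#' @param thresholds optional list `clv3`, `wus` of absolute thresholds;
#'   default derives them from the dual-regulation baseline run.
#' @return list of class `sweep_result`: `table` (multiplier, domain
#'   label, WUS depth, L3:L1 ratio, converged), `robust_range` (maximal
#'   contiguous multiplier interval containing 1 with an outer CLV3
#'   domain), `variant`, `parameter`.
#' @export
variant_sweep <- function(graph, params, v = variant("DUAL"),
                          parameter = c("A1", "C_p"),
                          multipliers = c(0.25, 0.5, 0.75, 1, 1.5, 2, 4),
                          thresholds = NULL) {
  parameter <- match.arg(parameter)
  if (!any(multipliers == 1)) stop("multipliers must include 1")
  multipliers <- sort(multipliers)
  if (is.null(thresholds)) {
    base <- run_to_steady(graph, params, variant("DUAL", v$genotype))
    thresholds <- list(clv3 = base$metrics$clv3_threshold,
                       wus = base$metrics$wus_threshold)
  }
  rows <- lapply(multipliers, function(f) {
    p <- params
    p[[parameter]] <- p[[parameter]] * f
    sim <- tryCatch(run_to_steady(graph, p, v), error = function(e) NULL)
    if (is.null(sim))
      return(data.frame(multiplier = f, clv3_domain = "error",
                        wus_shallow = NA, wus_deep = NA,
                        l3_l1 = NA_real_, converged = FALSE))
    m <- gradient_metrics(sim$final_state, graph,
                          clv3_threshold = thresholds$clv3,
                          wus_threshold = thresholds$wus, p = sim$params)
    data.frame(multiplier = f, clv3_domain = m$clv3_domain,
               wus_shallow = m$wus_domain_depth[1],
               wus_deep = m$wus_domain_depth[2],
               l3_l1 = m$l3_l1_ratio, converged = sim$converged)
  })
  tab <- do.call(rbind, rows)
  ok <- tab$clv3_domain == "outer"
  i1 <- which(tab$multiplier == 1)
  lo <- i1; while (lo > 1 && ok[lo - 1]) lo <- lo - 1
  hi <- i1; while (hi < nrow(tab) && ok[hi + 1]) hi <- hi + 1
  robust <- if (ok[i1]) c(tab$multiplier[lo], tab$multiplier[hi])
            else c(NA_real_, NA_real_)
  structure(list(table = tab, robust_range = robust, variant = v,
                 parameter = parameter, thresholds = thresholds),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("sweep of", x$parameter, "under", x$variant$regulation, "\n")
  print(x$table, row.names = FALSE)
  cat("robust (outer-CLV3) range: [", x$robust_range[1], ",",
      x$robust_range[2], "] x baseline\n")
  invisible(x)
}

#' Calibrate the shipped parameter regime
#'
#' Reconstructs the full calibrated configuration from a screening
#' result, following the pipeline that produced the shipped
#' [calibrated_params()]:
#' take passing basic-model sets (closest clv3-null L3:L1 ratio to the
#' target 4 first); anchor the hat window to the clv3-null apex levels
#' (sharp activation flank just below the L1 nuclear level, moderate
#' repression flank just above it) and the self-stabilisation EC50 to
#' the L2 level; measure the realised apex CLV3 level in a trial
#' wild-type run and set the export-brake EC50 at it (so the brake is
#' partially engaged) with the transcription EC50 above it and the
#' diffusion-brake EC50 later still; then scan the transcription Hill
#' exponent and the reduced-compartment synthesis rate for a candidate
#' satisfying (a) the reduced-ODE coexistence state is stable under dual
#' and unstable under transcriptional-only regulation with equal root
#' counts, (b) the full wild-type simulation gives an apex L3:L1
#' nuclear-WUS ratio near 3, the clv3-null near 4, and per-layer N-C
#' ratios inside the screening band, and (c) CLV3 sits in the repression
#' window (wild-type apex-L1 nuclear WUS above the hat peak).
#'
#' @param graph a `cell_graph`.
#' @param screening a `screening_result` with at least one passing set.
#' @param base_params `wus_params` template providing the non-screened
#'   parameters.
#' @param wt_target,null_target target L3:L1 ratios.
#' @param ratio_tol acceptable relative deviation from the targets.
#' @param n1_grid transcription Hill-exponent candidates.
#' @param wp_grid reduced-compartment synthesis-rate candidates.
#' @param verbose print progress.
#' @return the calibrated `wus_params`, with attribute `"calibration"`
#'   recording the chosen set and the achieved ratios.
#' @export
calibrate_shipped_config <- function(graph, screening,
                                     base_params = sam_params(),
                                     wt_target = 3, null_target = 4,
                                     ratio_tol = 0.25,
                                     n1_grid = c(6, 5),
                                     wp_grid = c(90, 70, 110),
                                     verbose = TRUE) {
  passing <- screening$passing
  if (nrow(passing) < 1) stop("no passing parameter set to calibrate from")
  ord <- order(abs(passing$l3_l1 - null_target))
  apex <- apex_cells(graph, 3)
  for (idx in ord) {
    set <- passing[idx, ]
    p <- base_params
    for (nm in c("A1", "D_w", "d_wn", "d_wc", "r_ex")) p[[nm]] <- set[[nm]]
    p$clv3_on <- TRUE; p$ck_on <- TRUE; p$self_stab_on <- TRUE

    # anchor hat window, self-stabilisation and CK scales to clv3-null
    null0 <- run_to_steady(graph, sam_params_merge(p, list(clv3_on = FALSE)),
                           variant("DUAL", "CLV3_NULL"))
    wn_l1 <- null0$metrics$layer_means$Wn[1]
    p$k_ww <- null0$metrics$layer_means$Wn[2]
    p$k_wc2 <- 0.62 * wn_l1; p$n5 <- 6      # activation flank below L1
    p$k_wc1 <- 1.24 * wn_l1; p$n4 <- 4      # repression flank above L1
    ck <- ck_steady_state(graph, p)
    p$ck_k_wc <- p$ck_k_ex <-
      round(1.2 * stats::median(ck[, "CkX"][graph$cells$z > p$ck_deep_zmin]), 2)

    # trial run to place the export brake at the realised CLV3 level
    q <- p
    q$k_cw1 <- 1e3; q$k_cw2 <- 1e3; q$k_cw3 <- 1e3  # regulations off
    trial <- run_to_steady(graph, q, variant("DUAL", "WT"))
    c_ap <- mean((trial$final_state[, "Co"] +
                  trial$final_state[, "Ci"])[apex$id[apex$layer == 1]])
    if (!is.finite(c_ap) || c_ap <= 0) next
    p$k_cw2 <- 0.55 * c_ap; p$n2 <- 6       # brake partially engaged
    p$k_cw1 <- 0.7 * c_ap; p$n1 <- 6        # transcription above it
    p$k_cw3 <- 1.8 * c_ap; p$n6 <- 6        # diffusion brake last

    for (n1 in n1_grid) for (wp in wp_grid) {
      q2 <- p
      q2$n1 <- n1
      q2$ode_Wp <- wp
      cand <- .check_calibration(graph, q2, wt_target, null_target,
                                 ratio_tol)
      if (verbose)
        message(sprintf("set %d n1=%g Wp=%g: %s", idx, n1, wp, cand$status))
      if (cand$ok) {
        attr(cand$params, "calibration") <-
          list(base_set = as.list(set), wt_ratio = cand$wt_ratio,
               null_ratio = cand$null_ratio, hat_peak = cand$hat_peak)
        return(cand$params)
      }
    }
  }
  stop("no candidate satisfied the calibration conditions")
}

# merge overrides into a params list without validation ceremony
#' @noRd
sam_params_merge <- function(p, overrides) {
  p[names(overrides)] <- overrides
  validate_params(p)
}

.check_calibration <- function(graph, q, wt_target, null_target, ratio_tol) {
  out <- list(ok = FALSE, params = q, status = "", wt_ratio = NA,
              null_ratio = NA, hat_peak = NA)
  # (a) stability flip of the reduced ODE: a unique stable coexisting
  # root under dual regulation whose matched (nearest-Wn) root under
  # transcriptional-only regulation is unstable, with equal root counts
  rp <- reduced_params(q)
  ssd <- tryCatch(solve_steady_state(rp, "DUAL"), error = function(e) NULL)
  sst <- tryCatch(solve_steady_state(rp, "TRANSCRIPTIONAL_ONLY"),
                  error = function(e) NULL)
  if (is.null(ssd) || is.null(sst)) { out$status <- "ode solve failed"; return(out) }
  if (length(ssd) != length(sst)) { out$status <- "root counts differ"; return(out) }
  sc <- which(vapply(ssd, function(s) isTRUE(s$coexisting) &&
                isTRUE(s$stable), logical(1)))
  if (length(sc) != 1) { out$status <- "no unique stable coexisting dual root"; return(out) }
  wn_d <- ssd[[sc]]$y["Wn"]
  j <- which.min(abs(vapply(sst, function(s) s$y["Wn"], numeric(1)) - wn_d))
  if (!isFALSE(sst[[j]]$stable)) { out$status <- "transcriptional root stable"; return(out) }
  # (b) full-model ratios
  wt <- run_to_steady(graph, q, variant("DUAL", "WT"))
  nul <- run_to_steady(graph, q, variant("DUAL", "CLV3_NULL"))
  if (is.null(wt$metrics) || is.null(nul$metrics)) {
    out$status <- "metrics unavailable"; return(out)
  }
  out$wt_ratio <- wt$metrics$l3_l1_ratio
  out$null_ratio <- nul$metrics$l3_l1_ratio
  if (abs(out$wt_ratio - wt_target) > ratio_tol * wt_target) {
    out$status <- sprintf("wt ratio %.2f", out$wt_ratio); return(out)
  }
  if (abs(out$null_ratio - null_target) > ratio_tol * null_target) {
    out$status <- sprintf("null ratio %.2f", out$null_ratio); return(out)
  }
  if (any(wt$metrics$nc_ratio < 0.5) || any(wt$metrics$nc_ratio > 2)) {
    out$status <- "wt N-C outside band"; return(out)
  }
  # (c) repression window
  out$hat_peak <- clv3_hat_peak(q)
  wt_l1 <- wt$metrics$layer_means$Wn[1]
  if (wt_l1 <= out$hat_peak) { out$status <- "L1 below hat peak"; return(out) }
  out$ok <- TRUE
  out$status <- sprintf("ok (wt %.2f, null %.2f)", out$wt_ratio,
                        out$null_ratio)
  out
}
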