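#' Model parameters
#'
#' Returns the full parameter list of the tissue model. Defaults are the
#' shipped calibrated wild-type regime (see
#' [calibrated_params()]); any subset can be overridden by name.
#'
#' Symbols follow the model equations: `A1` is the maximal WUS mRNA
#' synthesis rate inside the synthesis domain (lateral radius `r_w`, depth
#' window `(L_w_min, L_w]`); `d_W` the mRNA turnover; `r_c` the
#' translation rate; `D_w` the cytoplasmic WUS diffusion coefficient
#' (per-edge conductance `A_ij/l_ij` multiplies it); `d_wc`, `d_wn`
#' the cytoplasmic / nuclear degradation rates, the nuclear one modulated
#' by concentration-dependent self-stabilisation
#' (`d_min`, `d_max`, `k_ww`, `n3`); `r_ex` / `r_im` nuclear export and
#' import. CLV3 represses WUS transcription (`k_cw1`, `n1`), nuclear
#' export (`k_cw2`, `n2`) and WUS diffusion (`k_cw3`, `n6`). CLV3 is
#' produced as a hat-shaped function of nuclear WUS (`C_p`, `k_wc1`,
#' `n4`, `k_wc2`, `n5`), diffuses (`D_c`) and decays (`d_c`);
#' `inner_potency` is the efficacy multiplier of CLV3 synthesised below
#' the L2 (used by the dual+spatial variant). The cytokinin block is an
#' autonomous ligand/receptor/complex system produced in deep layers
#' (`ck_*`); its complex reduces cytoplasmic degradation (stabilisation,
#' `ck_s_wc`, `ck_k_wc`) and nuclear export (retention, `ck_s_ex`,
#' `ck_k_ex`).
#'
#' `clv3_on`, `ck_on`, `self_stab_on` switch whole blocks off; the basic
#' (reduced-complexity) model used for screening and global sensitivity
#' has all three off.
#'
#' @param ... named overrides.
#' @return named list of class `wus_params`.
#' @export
sam_params <- function(...) {
  p <- calibrated_params()
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  if (length(unknown)) stop("unknown parameters: ", paste(unknown, collapse = ", "))
  p[names(dots)] <- dots
  validate_params(p)
}

#' Basic-model parameters (no CLV3, no CK, no self-stabilisation)
#'
#' The reduced-complexity regime used by the global sensitivity analysis
#' and the 220-row screening: only WUS mRNA, cytoplasmic and nuclear
#' protein dynamics are active.
#' @param ... named overrides (typically the five screened rates `A1`,
#'   `D_w`, `d_wn`, `d_wc`, `r_ex`).
#' @return `wus_params` list.
#' @export
basic_params <- function(...) {
  sam_params(clv3_on = FALSE, ck_on = FALSE, self_stab_on = FALSE, ...)
}

#' Validate a parameter list
#' @param p parameter list.
#' @return `p`, invisibly classed as `wus_params`.
#' @export
validate_params <- function(p) {
  rates <- c("A1", "d_W", "r_c", "D_w", "d_wc", "d_wn", "r_ex", "r_im",
             "C_p", "D_c", "d_c", "ck_prod_L", "ck_D_L", "ck_d_L",
             "ck_prod_R", "ck_d_R", "ck_k_on", "ck_k_off", "ck_d_X")
  bad <- rates[vapply(rates, function(s) isTRUE(p[[s]] < 0), logical(1))]
  if (length(bad)) stop("negative rate(s): ", paste(bad, collapse = ", "))
  if (p$d_min > p$d_max) stop("d_min must not exceed d_max")
  hills <- c("n1", "n2", "n3", "n4", "n5", "n6", "ck_n")
  bad <- hills[vapply(hills, function(s) isTRUE(p[[s]] < 1), logical(1))]
  if (length(bad)) stop("Hill exponent(s) below 1: ", paste(bad, collapse = ", "))
  if (p$inner_potency <= 0 || p$inner_potency > 1)
    stop("inner_potency must be in (0, 1]")
  ks <- c("k_cw1", "k_cw2", "k_cw3", "k_ww", "k_wc1", "k_wc2",
          "ck_k_wc", "ck_k_ex")
  bad <- ks[vapply(ks, function(s) isTRUE(p[[s]] <= 0), logical(1))]
  if (length(bad)) stop("non-positive EC50(s): ", paste(bad, collapse = ", "))
  structure(p, class = "wus_params")
}

#' Read / write parameter sets as JSON
#'
#' One key per parameter symbol; validated on load.
#' @param path file path.
#' @param p parameter list (for writing).
#' @return [read_params()] returns a validated `wus_params` list.
#' @export
read_params <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- calibrated_params()
  unknown <- setdiff(names(p), names(base))
  if (length(unknown)) stop("unknown parameters in file: ",
                            paste(unknown, collapse = ", "))
  base[names(p)] <- p
  validate_params(base)
}

#' @rdname read_params
#' @export
write_params <- function(p, path) {
  jsonlite::write_json(unclass(p), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' The shipped calibrated wild-type parameter set
#'
#' Reconstructed by the package's own calibration pipeline (screening of
#' 220 Sobol' rows, steady-state/stability analysis of the reduced ODE,
#' and the documented CLV3/CK parameter choices); it is a reconstruction
#' of the published regime, not a verbatim copy of an unpublished set.
#' @return `wus_params` list.
#' @export
calibrated_params <- function() {
  path <- system.file("extdata", "params_calibrated.json", package = "wusgrad")
  if (path == "") {  # during development, before installation
    path <- file.path("inst", "extdata", "params_calibrated.json")
  }
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  validate_params(p)
}

#' Model variant descriptor
#'
#' @param regulation CLV3 regulation mode: `"DUAL"` (transcriptional +
#'   post-translational), `"TRANSCRIPTIONAL_ONLY"` (the CLV3 Hill factors
#'   on nuclear export and on WUS diffusion are replaced by 1), or
#'   `"DUAL_SPATIAL"` (dual regulation plus reduced potency of CLV3
#'   synthesised in inner layers).
#' @param genotype `"WT"` or `"CLV3_NULL"` (endogenous CLV3 production
#'   forced to zero).
#' @param treatment `"NONE"`, `"MCLV3"` (uniform exogenous CLV3 peptide at
#'   full potency, dose `mclv3_dose`), `"LEPB"` (exportin inhibition,
#'   nuclear export forced to zero), `"EARLM"` (mutated nuclear export
#'   signal: export zero, cytoplasmic degradation reduced), or `"WBM"`
#'   (mutated nuclear retention signal: cytokinin retention effect
#'   disabled).
#' @param mclv3_dose exogenous peptide concentration for `"MCLV3"`.
#' @return list of class `wus_variant`.
#' @export
variant <- function(regulation = c("DUAL", "TRANSCRIPTIONAL_ONLY", "DUAL_SPATIAL"),
                    genotype = c("WT", "CLV3_NULL"),
                    treatment = c("NONE", "MCLV3", "LEPB", "EARLM", "WBM"),
                    mclv3_dose = 0) {
  v <- list(regulation = match.arg(regulation),
            genotype = match.arg(genotype),
            treatment = match.arg(treatment),
            mclv3_dose = mclv3_dose)
  if (v$treatment == "MCLV3" && mclv3_dose <= 0)
    stop("MCLV3 requires a positive mclv3_dose")
  structure(v, class = "wus_variant")
}

#' Apply a variant's parameter switches
#'
#' Returns the parameter set with the genotype and treatment switches
#' applied: CLV3-null zeroes endogenous `C_p`; LEP-B forces `r_ex = 0`;
#' the EAR-like-motif mutant forces `r_ex = 0` and scales `d_wc` by
#' `earlm_dwc_factor` (the mutant protein is also stabilised in the
#' cytoplasm); the WUS-box mutant disables the cytokinin retention effect
#' (`ck_s_ex = 0`). The exogenous-MCLV3 dose is carried by the variant and
#' applied inside the right-hand side at full potency.
#'
#' @param p `wus_params`.
#' @param v `wus_variant`.
#' @return modified `wus_params`.
#' @export
in_silico_treatment <- function(p, v) {
  stopifnot(inherits(v, "wus_variant"))
  if (v$genotype == "CLV3_NULL") p$C_p <- 0
  switch(v$treatment,
    NONE = {},
    MCLV3 = {},
    LEPB = { p$r_ex <- 0 },
    EARLM = { p$r_ex <- 0; p$d_wc <- p$d_wc * p$earlm_dwc_factor },
    WBM = { p$ck_s_ex <- 0 },
    stop("unknown treatment: ", v$treatment))
  validate_params(p)
}
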