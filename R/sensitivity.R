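# Sobol' low-discrepancy sequence (Gray-code construction, 30-bit
# resolution) for up to 13 dimensions. Direction numbers from the standard
# Joe-Kuo table (first dimensions). No installed R package provides the
# sequence, so it is implemented here and pinned in tests against an
# independently generated reference.
.sobol_dirs <- list(
  list(s = 1L, a = 0L, m = 1L),            # dim 2
  list(s = 2L, a = 1L, m = c(1L, 3L)),     # dim 3
  list(s = 3L, a = 1L, m = c(1L, 3L, 1L)), # dim 4
  list(s = 3L, a = 2L, m = c(1L, 1L, 1L)), # dim 5
  list(s = 4L, a = 1L, m = c(1L, 1L, 3L, 3L)),   # dim 6
  list(s = 4L, a = 4L, m = c(1L, 3L, 5L, 13L)),  # dim 7
  list(s = 5L, a = 2L, m = c(1L, 1L, 5L, 5L, 17L)),  # dim 8
  list(s = 5L, a = 4L, m = c(1L, 1L, 5L, 5L, 5L)),   # dim 9
  list(s = 5L, a = 7L, m = c(1L, 1L, 7L, 11L, 19L)), # dim 10
  list(s = 5L, a = 11L, m = c(1L, 1L, 5L, 1L, 1L)),  # dim 11
  list(s = 5L, a = 13L, m = c(1L, 1L, 1L, 3L, 11L)), # dim 12
  list(s = 5L, a = 14L, m = c(1L, 3L, 5L, 5L, 31L))) # dim 13

.MAXBIT <- 30L

# direction vectors (integers scaled by 2^(30-k)) for one dimension
.sobol_v <- function(dim) {
  v <- integer(.MAXBIT)
  if (dim == 1L) {
    for (k in seq_len(.MAXBIT)) v[k] <- bitwShiftL(1L, .MAXBIT - k)
    return(v)
  }
  d <- .sobol_dirs[[dim - 1L]]
  s <- d$s
  for (k in seq_len(s)) v[k] <- bitwShiftL(d$m[k], .MAXBIT - k)
  for (k in (s + 1L):.MAXBIT) {
    vk <- bitwXor(v[k - s], bitwShiftR(v[k - s], s))
    if (s > 1L) for (i in seq_len(s - 1L)) {
      if (bitwAnd(bitwShiftR(d$a, s - 1L - i), 1L) == 1L)
        vk <- bitwXor(vk, v[k - i])
    }
    v[k] <- vk
  }
  v
}

#' Sobol' quasi-random sequence
#'
#' Unscrambled Sobol' points in `[0,1)^d` (the all-zero leading point is
#' skipped by default; `skip` drops further points). An optional
#' seed applies a random digital shift (per-dimension XOR mask), which
#' preserves the low-discrepancy structure while randomising the point
#' set reproducibly.
#'
#' @param n number of points.
#' @param d dimension (<= 13).
#' @param skip additional points to drop after the implicit zero point.
#' @param seed optional integer; `NULL` leaves the sequence unscrambled.
#' @return `n x d` matrix in `[0, 1)`.
#' @export
sobol_sequence <- function(n, d, skip = 0L, seed = NULL) {
  if (d < 1 || d > 13) stop("sobol_sequence supports 1 <= d <= 13")
  total <- n + skip + 1L
  V <- vapply(seq_len(d), .sobol_v, integer(.MAXBIT))
  x <- matrix(0L, total, d)
  cur <- integer(d)
  for (i in seq_len(total - 1L)) {
    # lowest zero bit of i-1 (Gray-code step)
    c <- 1L; ii <- i - 1L
    while (bitwAnd(ii, 1L) == 1L) { ii <- bitwShiftR(ii, 1L); c <- c + 1L }
    cur <- bitwXor(cur, V[c, ])
    x[i + 1L, ] <- cur
  }
  x <- x[(skip + 2L):total, , drop = FALSE]
  if (!is.null(seed)) {
    rs <- .with_seed(seed, sample.int(2^30 - 1, d))
    for (j in seq_len(d)) x[, j] <- bitwXor(x[, j], as.integer(rs[j]))
  }
  x / 2^.MAXBIT
}

# run code under a local RNG seed without touching the global stream
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

.check_ranges <- function(ranges) {
  ranges <- as.matrix(ranges)
  if (ncol(ranges) == 2 && nrow(ranges) != 2) ranges <- t(ranges)
  if (any(ranges[1, ] >= ranges[2, ]))
    stop("each range must have low < high")
  ranges
}

#' The five printed parameter ranges of the basic model
#'
#' mRNA synthesis rate in `[0.1, 100]`; WUS diffusion, nuclear and
#' cytoplasmic degradation, and nuclear export each in `[0.01, 10]`.
#' @return 2 x 5 matrix (rows low/high) with parameter column names.
#' @export
default_sobol_ranges <- function() {
  m <- cbind(A1 = c(0.1, 100), D_w = c(0.01, 10), d_wn = c(0.01, 10),
             d_wc = c(0.01, 10), r_ex = c(0.01, 10))
  rownames(m) <- c("low", "high")
  m
}

#' Sobol' design for total-effect estimation
#'
#' Two Sobol' sample matrices `M1`, `M2` of size `n x k` scaled to the
#' ranges, plus, for each input `j`, the mixed matrix (`M1` with column
#' `j` replaced from `M2`) required by the total-effect estimator:
#' `n * (k + 2)` model evaluations in total. `M1` and `M2` are the two
#' halves of a `2k`-dimensional Sobol' point set (the standard
#' construction for two quasi-independent samples), optionally digitally
#' shifted by `seed`.
#'
#' @param ranges `2 x k` matrix of `[low, high]` per input (or `k x 2`).
#' @param n base sample size (>= 8).
#' @param seed optional digital-shift seed.
#' @return list with `M1`, `M2`, `mixed` (list of k matrices), `ranges`,
#'   `n`, `seed`.
#' @export
sobol_design <- function(ranges = default_sobol_ranges(), n = 32L,
                         seed = NULL) {
  ranges <- .check_ranges(ranges)
  k <- ncol(ranges)
  if (n < 8) stop("n must be >= 8")
  u <- sobol_sequence(n, 2L * k, seed = seed)
  scale_fn <- function(m) {
    out <- sweep(m, 2, ranges[2, ] - ranges[1, ], "*")
    out <- sweep(out, 2, ranges[1, ], "+")
    colnames(out) <- colnames(ranges)
    out
  }
  M1 <- scale_fn(u[, seq_len(k), drop = FALSE])
  M2 <- scale_fn(u[, k + seq_len(k), drop = FALSE])
  mixed <- lapply(seq_len(k), function(j) { m <- M1; m[, j] <- M2[, j]; m })
  names(mixed) <- colnames(ranges)
  list(M1 = M1, M2 = M2, mixed = mixed, ranges = ranges, n = n, seed = seed)
}

#' Pooled design rows
#'
#' Stacks `M1`, `M2` and the mixed matrices into one row pool and
#' truncates to `total` rows (the screening analysis uses 220 rows of
#' the `n = 32` design).
#' @param design a [sobol_design()].
#' @param total number of pooled rows to keep (`NULL` = all).
#' @return matrix of parameter rows.
#' @export
sobol_pooled_rows <- function(design, total = NULL) {
  rows <- do.call(rbind, c(list(design$M1, design$M2), design$mixed))
  if (!is.null(total)) {
    if (total > nrow(rows)) stop("design has only ", nrow(rows), " rows")
    rows <- rows[seq_len(total), , drop = FALSE]
  }
  rows
}

#' Sobol' total-effect indices
#'
#' The estimator
#' `S_j = 1 - (U_-j - E^2) / V` with
#' `E^2 = mean(y(M1) * y(M2))`,
#' `U_-j = sum(y(M1) * y(M1 with column j from M2)) / (n - 1)` and
#' `V = mean(y(M1)^2) - mean(y(M1))^2`.
#' Rows with missing evaluations (non-converged simulations) are excluded
#' pairwise, with a message.
#'
#' @param Y1 evaluations on `M1` (length n).
#' @param Y2 evaluations on `M2`.
#' @param Ymix `n x k` evaluations on the mixed matrices.
#' @return named total-effect index per input.
#' @export
total_effect_indices <- function(Y1, Y2, Ymix) {
  Ymix <- as.matrix(Ymix)
  n <- length(Y1)
  stopifnot(length(Y2) == n, nrow(Ymix) == n)
  ok0 <- is.finite(Y1) & is.finite(Y2)
  vapply(seq_len(ncol(Ymix)), function(j) {
    ok <- ok0 & is.finite(Ymix[, j])
    nj <- sum(ok)
    if (nj < n) message("excluding ", n - nj, " incomplete row(s) for input ", j)
    if (nj < 3) stop("too few complete rows for input ", j)
    y1 <- Y1[ok]; y2 <- Y2[ok]; ym <- Ymix[ok, j]
    E2 <- mean(y1 * y2)
    V <- mean(y1^2) - mean(y1)^2
    if (V < 1e-12 * max(1, mean(y1)^2)) stop("output variance is ~0")
    U <- sum(y1 * ym) / (nj - 1)
    1 - (U - E2) / V
  }, numeric(1)) -> s
  stats::setNames(s, colnames(Ymix))
}

# simulate the basic clv3-null model for each design row; returns a
# matrix of mean apex nuclear WUS per layer (rows) x L1..L3 (cols)
.eval_rows <- function(graph, base_params, rows, width = 3L,
                       self_stab = FALSE) {
  apex <- apex_cells(graph, width)
  out <- matrix(NA_real_, nrow(rows), 3,
                dimnames = list(NULL, c("L1", "L2", "L3")))
  failed <- 0L
  for (r in seq_len(nrow(rows))) {
    p <- base_params
    for (nm in colnames(rows)) p[[nm]] <- rows[r, nm]
    p$self_stab_on <- self_stab
    sim <- tryCatch(
      run_to_steady(graph, p, variant("DUAL", "CLV3_NULL")),
      error = function(e) NULL)
    if (is.null(sim) || !sim$converged) { failed <- failed + 1L; next }
    wn <- sim$final_state[, "Wn"]
    for (l in 1:3)
      out[r, l] <- mean(wn[apex$id[apex$layer == l]])
  }
  if (failed > 0) message(failed, " of ", nrow(rows),
                          " simulations failed or did not converge")
  out
}

#' Global (Sobol' total-effect) sensitivity of the WUS gradient
#'
#' Simulates the basic clv3-null model (no CLV3 feedback, no cytokinin,
#' no nuclear self-stabilisation) for every row of the design and
#' computes, for nuclear WUS in L1, L2 and L3, the total-effect index of
#' each of the five inputs together with the sign of the input-output
#' Spearman rank correlation (total-effect indices are signless).
#'
#' @param graph a `cell_graph`.
#' @param base_params baseline `wus_params` (the five screened inputs are
#'   overwritten row by row).
#' @param ranges `2 x 5` input ranges.
#' @param n base Sobol' sample size.
#' @param seed digital-shift seed.
#' @return list: `total_effect` (k x 3 matrix), `spearman` (k x 3 signed
#'   rank correlations on `(M1, Y)`), `design`, `Y` (all evaluations).
#' @export
run_global_sensitivity <- function(graph, base_params = basic_params(),
                                   ranges = default_sobol_ranges(),
                                   n = 32L, seed = 1L) {
  des <- sobol_design(ranges, n, seed)
  k <- ncol(des$M1)
  Y1 <- .eval_rows(graph, base_params, des$M1)
  Y2 <- .eval_rows(graph, base_params, des$M2)
  Ymix <- lapply(des$mixed, function(m) .eval_rows(graph, base_params, m))
  total <- matrix(NA_real_, k, 3,
                  dimnames = list(colnames(des$M1), colnames(Y1)))
  sp <- total
  for (out in colnames(Y1)) {
    ym <- vapply(Ymix, function(m) m[, out], numeric(des$n))
    total[, out] <- total_effect_indices(Y1[, out], Y2[, out], ym)
    sp[, out] <- apply(des$M1, 2, function(x)
      stats::cor(x, Y1[, out], method = "spearman", use = "complete.obs"))
  }
  list(total_effect = total, spearman = sp, design = des,
       Y = list(M1 = Y1, M2 = Y2, mixed = Ymix))
}

#' Latin hypercube design
#'
#' Stratified design: per parameter, each of the `n` uniform subintervals
#' of its range contains exactly one sample (via [lhs::randomLHS()]).
#'
#' @param ranges `2 x k` range matrix.
#' @param n samples (and subintervals) per parameter.
#' @param seed RNG seed.
#' @return `n x k` matrix.
#' @export
lhs_design <- function(ranges, n = 25L, seed = 1L) {
  ranges <- .check_ranges(ranges)
  if (n < 2) stop("n must be >= 2")
  u <- .with_seed(seed, lhs::randomLHS(n, ncol(ranges)))
  out <- sweep(u, 2, ranges[2, ] - ranges[1, ], "*")
  out <- sweep(out, 2, ranges[1, ], "+")
  colnames(out) <- colnames(ranges)
  out
}

#' Partial correlation coefficients
#'
#' For each input `x_i`, regresses `x_i` and `y` on the remaining inputs
#' and correlates the two residual series; the p-value uses the
#' t-transform with `n - k - 1` degrees of freedom (`k` = number of
#' controlled inputs). Inputs with zero variance are returned as `NA`
#' and flagged.
#'
#' @param X `n x k` input matrix.
#' @param y output vector.
#' @return data frame `input, pcc, p, df, degenerate`.
#' @export
partial_correlation <- function(X, y) {
  X <- as.matrix(X)
  n <- nrow(X); k <- ncol(X)
  if (n <= k + 2) stop("need n > k + 2 observations")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(k))
  res <- lapply(seq_len(k), function(i) {
    if (stats::var(X[, i]) == 0)
      return(data.frame(input = colnames(X)[i], pcc = NA_real_,
                        p = NA_real_, df = NA_integer_, degenerate = TRUE))
    Z <- X[, -i, drop = FALSE]
    # constant controls carry no information; drop them
    Z <- Z[, apply(Z, 2, stats::var) > 0, drop = FALSE]
    if (qr(cbind(1, Z))$rank < ncol(Z) + 1) stop("collinear inputs")
    rx <- stats::lm.fit(cbind(1, Z), X[, i])$residuals
    ry <- stats::lm.fit(cbind(1, Z), y)$residuals
    r <- stats::cor(rx, ry)
    df <- n - (k - 1) - 1
    tval <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
    data.frame(input = colnames(X)[i], pcc = r,
               p = 2 * stats::pt(-abs(tval), df), df = df,
               degenerate = FALSE)
  })
  do.call(rbind, res)
}

#' Local (LHS + PCC) sensitivity of the computational model
#'
#' Latin hypercube over `[0.25, 1.75]` times the baseline for the five
#' key rates, simulating the tissue model without the extrinsic CLV3 and
#' cytokinin signals (nuclear self-stabilisation stays active), and
#' partial correlation of each input against mean apex nuclear WUS in
#' L1, L2 and L3.
#'
#' @param graph a `cell_graph`.
#' @param baseline_params calibrated `wus_params`.
#' @param n LHS sample size.
#' @param seed RNG seed.
#' @param alpha significance level.
#' @return list: `pcc` (tidy data frame `input, output, pcc, p,
#'   significant`), `design`, `Y`.
#' @export
run_local_sensitivity <- function(graph, baseline_params = sam_params(),
                                  n = 25L, seed = 1L, alpha = 0.01) {
  pars <- c("A1", "D_w", "d_wn", "d_wc", "r_ex")
  base <- unlist(unclass(baseline_params)[pars])
  ranges <- rbind(low = 0.25 * base, high = 1.75 * base)
  colnames(ranges) <- pars
  X <- lhs_design(ranges, n, seed)
  bp <- baseline_params
  bp$clv3_on <- FALSE
  bp$ck_on <- FALSE
  Y <- .eval_rows(graph, bp, X, self_stab = isTRUE(baseline_params$self_stab_on))
  rows <- lapply(colnames(Y), function(out) {
    ok <- is.finite(Y[, out])
    pc <- partial_correlation(X[ok, , drop = FALSE], Y[ok, out])
    pc$output <- out
    pc
  })
  pcc <- do.call(rbind, rows)
  pcc$significant <- !is.na(pcc$p) & pcc$p <= alpha
  list(pcc = pcc[, c("input", "output", "pcc", "p", "df", "significant",
                     "degenerate")],
       design = X, Y = Y)
}
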