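#' Hill-kinetics model of a TF-activated, RBP-degraded target gene
#'
#' One transcription factor (TF) activates, and one RNA-binding protein
#' (RBP) degrades, a set of target genes (TGs). Each target gene i obeys
#'
#'   d\[TG\]_i/dt = A_i * \[TF\]^n_i / (T_i^n_i + \[TF\]^n_i)
#'                 - k_i * \[TG\]_i - j * \[RBP\] * \[TG\]_i
#'
#' with maximal expression A_i, activation coefficient T_i, Hill
#' coefficient n_i, basal decay rate k_i, RBP-mediated decay rate j and
#' initial level tg0_i. The TF level is tied to the RBP level through
#' m = \[TF\]/\[RBP\], so \[TF\] = m * \[RBP\]. With \[TF\] and \[RBP\]
#' constant the equation is linear and solves in closed form:
#' `TG(t) = SS + (tg0 - SS) * exp(-(k + j*rbp) * t)` with steady state
#' `SS = A * Hill / (k + j*rbp)`.
#'
#' `draw_gene_kinetics()` samples per-gene parameters independently and
#' uniformly over the model's parameter spaces: tg0 in (0,1), A in (1,2),
#' T in (0,4), n in (1,4), k in (0,1) - so tg0 < A for every draw.
#'
#' @param n_genes Number of target genes to draw.
#' @return `draw_gene_kinetics()`: data frame with columns `A`, `T`, `n`,
#'   `k`, `tg0`, one row per gene.
#' @export
draw_gene_kinetics <- function(n_genes) {
  stopifnot(n_genes >= 1)
  data.frame(A = stats::runif(n_genes, 1, 2),
             T = stats::runif(n_genes, 0, 4),
             n = stats::runif(n_genes, 1, 4),
             k = stats::runif(n_genes, 0, 1),
             tg0 = stats::runif(n_genes, 0, 1))
}

#' @rdname draw_gene_kinetics
#' @param g Gene kinetics: a list or one-row data frame with fields `A`,
#'   `T`, `n`, `k` (and `tg0` for [integrate_tg()]). Fields may be vectors
#'   of equal length for several genes.
#' @param rbp RBP expression level(s), > 0.
#' @param m Ratio \[TF\]/\[RBP\], so \[TF\] = m * rbp.
#' @param j RBP-mediated degradation rate.
#' @return `steady_state()`: steady-state TG level(s).
#' @export
#' @examples
#' steady_state(list(A = 1, T = 1, n = 1, k = 0.5), rbp = 1, m = 1, j = 0.5)  # 0.5
steady_state <- function(g, rbp, m, j) {
  if (any(rbp <= 0)) stop("`rbp` must be positive", call. = FALSE)
  tf <- m * rbp
  hill <- tf^g$n / (g$T^g$n + tf^g$n)
  denom <- g$k + j * rbp
  if (any(denom == 0)) stop("k + j*rbp is zero; decay vanished", call. = FALSE)
  g$A * hill / denom
}

#' Numerically integrate one target gene's trajectory
#'
#' Integrates the model ODE (see [draw_gene_kinetics()]) with constant TF
#' and RBP from `tg0` using `deSolve::ode` (lsoda, tight tolerances). The
#' trajectory is first-order linear, hence monotone between `tg0` and the
#' steady state; the integrator exists to validate the closed form and to
#' support finite-time analyses.
#'
#' @inheritParams steady_state
#' @param t_end End time (> 0).
#' @param dt Output time step (> 0).
#' @return Data frame with columns `time` and `tg`.
#' @export
integrate_tg <- function(g, rbp, m, j, t_end, dt = t_end / 200) {
  if (t_end <= 0 || dt <= 0) stop("`t_end` and `dt` must be positive", call. = FALSE)
  if (rbp <= 0) stop("`rbp` must be positive", call. = FALSE)
  tf <- m * rbp
  prod_rate <- g$A * tf^g$n / (g$T^g$n + tf^g$n)
  decay <- g$k + j * rbp
  deriv <- function(t, y, parms) list(prod_rate - decay * y)
  times <- unique(c(seq(0, t_end, by = dt), t_end))
  sol <- deSolve::ode(y = c(tg = g$tg0), times = times, func = deriv,
                      parms = NULL, rtol = 1e-10, atol = 1e-12)
  if (any(!is.finite(sol[, "tg"])))
    stop(sprintf("non-finite trajectory for draw A=%g T=%g n=%g k=%g tg0=%g",
                 g$A, g$T, g$n, g$k, g$tg0), call. = FALSE)
  data.frame(time = sol[, "time"], tg = unname(sol[, "tg"]))
}

# Closed-form TG levels for a set of genes across a vector of RBP levels:
# genes x levels matrix. t_obs = Inf gives the steady state; finite t_obs
# gives the exact snapshot of the linear ODE at that time.
tg_levels_matrix <- function(kin, rbp_levels, m, j, t_obs = Inf) {
  tf <- m * rbp_levels
  tfn <- exp(outer(kin$n, log(tf)))
  hill <- tfn / (kin$T^kin$n + tfn)
  decay <- outer(kin$k, j * rbp_levels, `+`)
  ss <- (kin$A * hill) / decay
  if (is.infinite(t_obs)) ss else ss + (kin$tg0 - ss) * exp(-decay * t_obs)
}

#' Evenly spaced RBP levels over (0, 2)
#'
#' Bin midpoints of (0, 2), excluding both endpoints.
#'
#' @param n Number of levels.
#' @return Numeric vector of length `n` in (0, 2).
#' @export
rbp_level_grid <- function(n) {
  stopifnot(n >= 1)
  (seq_len(n) - 0.5) * 2 / n
}

#' One Monte-Carlo replicate of the regulation model
#'
#' Draws one set of gene kinetics (uniform over the parameter spaces) for
#' `n_genes` target genes, holds it fixed across all RBP levels, computes
#' each gene's TG level at every RBP level (steady state, or the
#' closed-form snapshot at `t_obs`), then the across-gene mean and CD at
#' each level, and finally the correlations of the RBP level with those
#' means and CDs. Uses the current RNG state; seed upstream for
#' reproducibility.
#'
#' @param n_genes Number of target genes (>= 2).
#' @param rbp_levels Numeric vector of at least 3 RBP levels in (0, 2).
#' @param m,j System parameters (m in (0,2), j in (0,1)).
#' @param method Correlation method, `"pearson"` (default) or
#'   `"spearman"`.
#' @param t_obs Observation time; `Inf` (steady state) or a positive
#'   time. Initial conditions only matter at finite `t_obs`.
#' @return List: `rho_mean`, `rho_cd`, `degenerate`.
#' @export
simulate_rep <- function(n_genes, rbp_levels, m, j,
                         method = c("pearson", "spearman"), t_obs = Inf) {
  method <- match.arg(method)
  if (n_genes < 2) stop("`n_genes` must be >= 2", call. = FALSE)
  if (length(rbp_levels) < 3) stop("need at least 3 RBP levels", call. = FALSE)
  kin <- draw_gene_kinetics(n_genes)
  tg <- tg_levels_matrix(kin, rbp_levels, m, j, t_obs)
  mu <- colMeans(tg)
  sds <- sqrt(pmax(colSums(tg^2) - n_genes * mu^2, 0) / (n_genes - 1))
  cds <- sds / mu
  rm_ <- cor_flagged(rbp_levels, mu, method)
  rc_ <- cor_flagged(rbp_levels, cds, method)
  list(rho_mean = rm_$rho, rho_cd = rc_$rho,
       degenerate = rm_$degenerate || rc_$degenerate)
}

#' Monte-Carlo phase diagram over the (m, j) plane
#'
#' For every grid cell (m, j), runs `n_reps` independent replicates of
#' [simulate_rep()], averages the replicate correlations of the RBP level
#' with the across-gene mean and CD, and labels the cell with the sign
#' pair of the two averages - the four-region phase diagram of
#' regulator-target relationships. `pos_mean_neg_cd` (co-expression with
#' variance buffering) dominates the plane and occupies the high-m/low-j
#' corner, where transcript generation by the TF outweighs degradation by
#' the RBP.
#'
#' Each cell is seeded by mixing `seed` with the cell's grid indices, so
#' cells are independent and the grid is reproducible cell-by-cell in any
#' order. Replicates with a degenerate (constant) statistic are discarded
#' and redrawn, with the count reported.
#'
#' @param grid_m,grid_j Numeric vectors of m values in (0, 2) and j values
#'   in (0, 1).
#' @param n_genes Target genes per replicate (default 100).
#' @param n_reps Replicates per cell.
#' @param n_rbp_levels Number of RBP levels (evenly spaced over (0, 2)).
#' @param seed Master seed.
#' @param method Correlation method, `"pearson"` (default) or `"spearman"`.
#' @param t_obs Observation time per replicate; defaults to 0.5 time
#'   units, where initial conditions and regulation jointly shape
#'   abundance and all four sign classes can appear (`Inf` evaluates at
#'   steady state).
#' @return Data frame with one row per cell: `m`, `j`, `mean_rho_mean`,
#'   `mean_rho_cd`, `region`, `n_reps_used`, `n_degenerate`.
#' @export
sweep_phase_diagram <- function(grid_m, grid_j, n_genes = 100, n_reps = 200,
                                n_rbp_levels = 200, seed = 1,
                                method = c("pearson", "spearman"), t_obs = 0.5) {
  method <- match.arg(method)
  if (any(grid_m <= 0 | grid_m >= 2)) stop("`grid_m` must lie in (0, 2)", call. = FALSE)
  if (any(grid_j <= 0 | grid_j >= 1)) stop("`grid_j` must lie in (0, 1)", call. = FALSE)
  levels <- rbp_level_grid(n_rbp_levels)
  cells <- expand.grid(mi = seq_along(grid_m), ji = seq_along(grid_j))
  out <- vector("list", nrow(cells))
  for (ci in seq_len(nrow(cells))) {
    mi <- cells$mi[ci]; ji <- cells$ji[ci]
    m <- grid_m[mi]; j <- grid_j[ji]
    set.seed(mix_seed(seed, mi, ji))
    rms <- numeric(n_reps); rcs <- numeric(n_reps)
    n_degenerate <- 0L
    for (rep in seq_len(n_reps)) {
      repeat {
        r <- simulate_rep(n_genes, levels, m, j, method, t_obs)
        if (!r$degenerate) break
        n_degenerate <- n_degenerate + 1L
        if (n_degenerate > 100L * n_reps)
          stop("too many degenerate replicates at cell m=", m, ", j=", j,
               call. = FALSE)
      }
      rms[rep] <- r$rho_mean; rcs[rep] <- r$rho_cd
    }
    out[[ci]] <- data.frame(m = m, j = j,
                            mean_rho_mean = mean(rms), mean_rho_cd = mean(rcs),
                            region = classify_region(mean(rms), mean(rcs)),
                            n_reps_used = n_reps, n_degenerate = n_degenerate,
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
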