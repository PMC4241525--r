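#' Scenario for the planted co-expression fixture
#'
#' Parameters of the generator that emulates a multi-condition RNA-Seq
#' compendium with RBP regulons planted in it: per condition c, regulator
#' r has log expression `R_rc ~ Normal(mu_r, 1)` with `mu_r` drawn from
#' `rbp_mean_range`; each of its targets g has log expression
#'
#'   `base_level + base_dev_g + coactivation_strength * R_rc
#'      + scale(R_rc) * (h_g * R_rc + eps_gc)`
#'
#' where `base_dev_g ~ N(0, base_sd)` is the target's persistent offset,
#' `h_g ~ N(0, gain_sd)` its heterogeneous response gain to the shared
#' activator, `eps_gc ~ N(0, noise_sd)` condition noise, and
#' `scale(R) = 1 - damping_strength * R / max_c(R)` the RBP's damping of
#' the across-target dispersion. With damping on, target dispersion
#' shrinks as the RBP rises while the mean rises (co-expression with
#' buffering); with damping off, the heterogeneous gains spread targets
#' apart as activation rises, so both mean and CD rise.
#'
#' Background genes are independent log-normal noise. Planted targets get
#' q-values below 0.001; each regulator also receives decoy associations
#' (background genes at q >= 0.001) that the target filter must remove.
#'
#' @param n_rbps Number of regulators.
#' @param n_targets_per_rbp Targets per regulator (>= 11, so regulons
#'   survive the "more than 10 targets" filter).
#' @param n_background_genes Unregulated genes.
#' @param n_conditions Conditions/profiles (default 148, the size of a
#'   multi-condition yeast compendium).
#' @param coactivation_strength Shared-activation slope (log units per
#'   unit of regulator log expression).
#' @param damping_strength Dispersion damping in \[0, 1\].
#' @param noise_sd Condition-noise SD (log units), > 0.
#' @param base_level Mean target log expression (log2 units; 5 = RPKM 32).
#' @param base_sd SD of per-target persistent offsets.
#' @param gain_sd SD of per-target response gains.
#' @param rbp_mean_range Range of regulator mean log expression.
#' @param n_decoys_per_rbp Decoy (q >= 0.001) associations per regulator.
#' @param log_base Base on which the log-scale values are defined; the
#'   emitted expression matrix is raw-scale `log_base^x`.
#' @param seed Integer seed; the fixture is fully determined by it.
#' @return A list of class `coexpression_scenario`.
#' @export
coexpression_scenario <- function(n_rbps = 30, n_targets_per_rbp = 15,
                                  n_background_genes = 300, n_conditions = 148,
                                  coactivation_strength = 0.5,
                                  damping_strength = 0.8, noise_sd = 1,
                                  base_level = 5, base_sd = 0.5, gain_sd = 0.5,
                                  rbp_mean_range = c(1.5, 2.5),
                                  n_decoys_per_rbp = 5, log_base = 2, seed = 1) {
  if (n_targets_per_rbp < 11)
    stop("`n_targets_per_rbp` must be >= 11 so regulons survive the target filter",
         call. = FALSE)
  if (damping_strength < 0 || damping_strength > 1)
    stop("`damping_strength` must lie in [0, 1]", call. = FALSE)
  if (noise_sd <= 0) stop("`noise_sd` must be > 0", call. = FALSE)
  if (coactivation_strength < 0) stop("`coactivation_strength` must be >= 0", call. = FALSE)
  structure(list(n_rbps = n_rbps, n_targets_per_rbp = n_targets_per_rbp,
                 n_background_genes = n_background_genes,
                 n_conditions = n_conditions,
                 coactivation_strength = coactivation_strength,
                 damping_strength = damping_strength, noise_sd = noise_sd,
                 base_level = base_level, base_sd = base_sd, gain_sd = gain_sd,
                 rbp_mean_range = rbp_mean_range,
                 n_decoys_per_rbp = n_decoys_per_rbp,
                 log_base = log_base, seed = as.integer(seed)),
            class = "coexpression_scenario")
}

#' Generate a planted co-expression fixture
#'
#' Draws an expression matrix (raw scale), a target map with q-values, and
#' a truth table recording each regulator's planted regulatory class:
#' `pos_mean_neg_cd` when `damping_strength > 0`, else
#' `pos_mean_pos_cd`. See [coexpression_scenario()] for the generative
#' model.
#'
#' @param s A `coexpression_scenario`.
#' @return List with elements `expression` (`expr_matrix`, raw scale),
#'   `targets` (`target_map`), `truth` (data frame: `rbp_id`, `mu`,
#'   `region`), and `scenario`.
#' @export
planted_coexpression_fixture <- function(s) {
  stopifnot(inherits(s, "coexpression_scenario"))
  set.seed(s$seed)
  C <- s$n_conditions
  conds <- sprintf("cond%03d", seq_len(C))
  rbp_ids <- sprintf("RBP%02d", seq_len(s$n_rbps))
  bg_ids <- sprintf("BG%04d", seq_len(s$n_background_genes))
  planted_region <- if (s$damping_strength > 0) "pos_mean_neg_cd" else "pos_mean_pos_cd"

  rows <- list(); map <- list(); mus <- numeric(s$n_rbps)
  for (r in seq_len(s$n_rbps)) {
    mu <- stats::runif(1, s$rbp_mean_range[1], s$rbp_mean_range[2])
    mus[r] <- mu
    R <- stats::rnorm(C, mu, 1)
    scl <- 1 - s$damping_strength * R / max(R)
    if (any(scl < 0))
      stop("negative noise scale in condition draw; damping too strong for this draw",
           call. = FALSE)
    G <- s$n_targets_per_rbp
    tg_ids <- sprintf("%s_T%02d", rbp_ids[r], seq_len(G))
    base_dev <- stats::rnorm(G, 0, s$base_sd)
    gain <- stats::rnorm(G, 0, s$gain_sd)
    eps <- matrix(stats::rnorm(G * C, 0, s$noise_sd), G, C)
    x <- s$base_level + base_dev +
      matrix(s$coactivation_strength * R, G, C, byrow = TRUE) +
      sweep(gain %o% R + eps, 2, scl, `*`)
    block <- rbind(R, x)
    rownames(block) <- c(rbp_ids[r], tg_ids)
    rows[[r]] <- block
    map[[r]] <- data.frame(rbp_id = rbp_ids[r],
                           target_id = tg_ids,
                           q_value = stats::runif(G, 0, 0.0009),
                           stringsAsFactors = FALSE)
  }
  bg <- matrix(stats::rnorm(s$n_background_genes * C, s$base_level, 1),
               s$n_background_genes, C, dimnames = list(bg_ids, NULL))
  vals <- rbind(do.call(rbind, rows), bg)
  colnames(vals) <- conds

  decoys <- do.call(rbind, lapply(seq_len(s$n_rbps), function(r) {
    if (s$n_decoys_per_rbp == 0) return(NULL)
    data.frame(rbp_id = rbp_ids[r],
               target_id = sample(bg_ids, s$n_decoys_per_rbp),
               q_value = stats::runif(s$n_decoys_per_rbp, 0.001, 0.5),
               stringsAsFactors = FALSE)
  }))
  tm <- do.call(rbind, c(map, list(decoys)))

  list(expression = expression_matrix(s$log_base^vals, scale = "raw"),
       targets = target_map(tm$rbp_id, tm$target_id, tm$q_value),
       truth = data.frame(rbp_id = rbp_ids, mu = mus, region = planted_region,
                          stringsAsFactors = FALSE),
       scenario = s)
}

#' Scenario for the planted knockout fixture
#'
#' Parameters of the generator that emulates a paired wild-type /
#' RBP-deletion RNA-Seq experiment. Deletion-strain (KO) target
#' expression is log-normal; each target's degradation efficiency is
#'
#'   `e_g = min(base_efficiency + dependence_strength * u_g + noise, 0.95)`
#'
#' where `u_g` is the target's centred normalized expression rank in
#' (-0.5, 0.5), so efficiency rises with expression - the biased decay
#' that compresses wild-type dispersion. With `damping = FALSE` the
#' computed efficiencies are randomly shuffled across targets, preserving
#' their distribution but severing the expression dependence. Wild-type
#' expression is `KO * (1 - e_g)`; the 0.95 cap keeps it positive.
#'
#' @param n_targets Number of target genes.
#' @param dependence_strength Efficiency-expression coupling in \[0, 1\].
#' @param damping If `FALSE`, efficiencies are shuffled across targets.
#' @param noise_sd SD of efficiency noise.
#' @param base_efficiency Mean degradation efficiency.
#' @param ko_meanlog2,ko_sdlog2 Mean and SD of KO log2 expression.
#' @param n_background Unregulated genes carried in both profiles.
#' @param rbp_id Id given to the deleted regulator.
#' @param seed Integer seed.
#' @return A list of class `knockout_scenario`.
#' @export
knockout_scenario <- function(n_targets = 200, dependence_strength = 0.8,
                              damping = TRUE, noise_sd = 0.05,
                              base_efficiency = 0.5,
                              ko_meanlog2 = 5, ko_sdlog2 = 1.5,
                              n_background = 100, rbp_id = "RBP1", seed = 1) {
  if (dependence_strength < 0 || dependence_strength > 1)
    stop("`dependence_strength` must lie in [0, 1]", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  structure(list(n_targets = n_targets,
                 dependence_strength = dependence_strength,
                 damping = isTRUE(damping), noise_sd = noise_sd,
                 base_efficiency = base_efficiency,
                 ko_meanlog2 = ko_meanlog2, ko_sdlog2 = ko_sdlog2,
                 n_background = n_background, rbp_id = rbp_id,
                 seed = as.integer(seed)),
            class = "knockout_scenario")
}

#' Generate a planted knockout fixture
#'
#' Draws a [knockout_pair()] plus a truth table of the planted per-target
#' degradation efficiencies; [degradation_efficiency()] with pseudocount 0
#' recovers them exactly, since `WT = KO * (1 - e)` implies
#' `(KO - WT)/KO = e`.
#'
#' @param s A `knockout_scenario`.
#' @return List with elements `pair` (`knockout_pair`), `truth` (data
#'   frame: `gene_id`, `efficiency`), and `scenario`.
#' @export
planted_knockout_fixture <- function(s) {
  stopifnot(inherits(s, "knockout_scenario"))
  set.seed(s$seed)
  n <- s$n_targets
  tg_ids <- sprintf("TG%04d", seq_len(n))
  ko_t <- 2^stats::rnorm(n, s$ko_meanlog2, s$ko_sdlog2)
  u <- (rank(ko_t) - 0.5) / n - 0.5
  e <- pmin(s$base_efficiency + s$dependence_strength * u +
              stats::rnorm(n, 0, s$noise_sd), 0.95)
  # damping off: same efficiency distribution, shuffled off the expression ranks
  if (!s$damping) e <- sample(e)
  wt_t <- ko_t * (1 - e)
  bg_ids <- sprintf("BG%04d", seq_len(s$n_background))
  ko_b <- 2^stats::rnorm(s$n_background, s$ko_meanlog2, s$ko_sdlog2)
  wt_b <- ko_b * 2^stats::rnorm(s$n_background, 0, 0.1)
  pair <- knockout_pair(gene_ids = c(tg_ids, bg_ids),
                        wt_expr = c(wt_t, wt_b), ko_expr = c(ko_t, ko_b),
                        rbp_id = s$rbp_id, target_ids = tg_ids)
  list(pair = pair,
       truth = data.frame(gene_id = tg_ids, efficiency = e,
                          stringsAsFactors = FALSE),
       scenario = s)
}

#' Hand-checkable steady-state oracle draws
#'
#' Emits a small set of kinetics draws within the model's parameter
#' spaces together with steady states computed through an independent
#' arithmetic path (`Hill = 1/(1 + (T/TF)^n)` instead of
#' `TF^n/(T^n + TF^n)`), for regression tests of [steady_state()]. The
#' first row is the canonical hand-checked case A=1, T=1, n=1, k=0.5,
#' j=0.5, m=1, rbp=1 with steady state exactly 0.5.
#'
#' @param seed Integer seed.
#' @param n_draws Number of random draws after the canonical row (<= 9).
#' @return Data frame with the draw columns plus `ss_oracle`.
#' @export
model_oracle_fixture <- function(seed = 1, n_draws = 7) {
  stopifnot(n_draws >= 1, n_draws <= 9)
  set.seed(seed)
  draws <- data.frame(A = stats::runif(n_draws, 1, 2),
                      T = stats::runif(n_draws, 0, 4),
                      n = stats::runif(n_draws, 1, 4),
                      k = stats::runif(n_draws, 0, 1),
                      rbp = stats::runif(n_draws, 0, 2),
                      m = stats::runif(n_draws, 0, 2),
                      j = stats::runif(n_draws, 0, 1))
  # one draw exercises the j = 0 limit where TG_ss = A * Hill / k
  draws$j[n_draws] <- 0
  draws <- rbind(data.frame(A = 1, T = 1, n = 1, k = 0.5, rbp = 1, m = 1, j = 0.5),
                 draws)
  tf <- draws$m * draws$rbp
  hill <- 1 / (1 + (draws$T / tf)^draws$n)
  draws$ss_oracle <- draws$A * hill / (draws$k + draws$j * draws$rbp)
  stopifnot(all(is.finite(draws$ss_oracle)), all(draws$ss_oracle > 0),
            abs(draws$ss_oracle[1] - 0.5) < 1e-15)
  draws
}
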