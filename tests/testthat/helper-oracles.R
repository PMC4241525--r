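# Independent oracles used across tests. These deliberately avoid the code
# paths (and the base helpers) the package itself uses.

# Average ranks computed by sorting, without base::rank().
oracle_rank <- function(x) {
  o <- order(x)
  r <- numeric(length(x))
  r[o] <- seq_along(x)
  for (v in unique(x)) {
    idx <- which(x == v)
    r[idx] <- mean(r[idx])
  }
  r
}

# Closed-form Pearson correlation from sums.
oracle_pearson <- function(x, y) {
  n <- length(x)
  sx <- x - sum(x) / n
  sy <- y - sum(y) / n
  sum(sx * sy) / sqrt(sum(sx^2) * sum(sy^2))
}

# Spearman's rho as rank-then-Pearson.
oracle_spearman <- function(x, y) oracle_pearson(oracle_rank(x), oracle_rank(y))

# Two-sided p of the variance-ratio test, straight from the F CDF.
oracle_f_p <- function(f, d1, d2) {
  lower <- pf(f, d1, d2)
  min(2 * min(lower, 1 - lower), 1)
}

# Exact solution of the linear decay ODE with constant production.
oracle_tg_at <- function(g, rbp, m, j, t) {
  tf <- m * rbp
  hill <- tf^g$n / (g$T^g$n + tf^g$n)
  r <- g$k + j * rbp
  ss <- g$A * hill / r
  ss + (g$tg0 - ss) * exp(-r * t)
}

# Small log-scale expression matrix with named genes/conditions.
log_matrix <- function(values, genes, conds, base = 2) {
  expression_matrix(matrix(values, length(genes), length(conds),
                           dimnames = list(genes, conds)),
                    scale = "log", log_base = base)
}

# Hand-built summary rows for correlate_rbp().
summary_rows <- function(rbp_expr, stat, statistic = "mean", rbp = "R1") {
  df <- data.frame(rbp_id = rbp,
                   condition_id = sprintf("c%d", seq_along(rbp_expr)),
                   rbp_expr = rbp_expr, n_targets = 5L,
                   target_mean = 0, target_sd = 0, target_cd = 0,
                   cd_defined = TRUE, stringsAsFactors = FALSE)
  col <- switch(statistic, mean = "target_mean", sd = "target_sd", cd = "target_cd")
  df[[col]] <- stat
  df
}
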