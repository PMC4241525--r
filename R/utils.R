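# Internal helpers shared across modules.

# Coefficient of deviation: sd / mean (sample sd, n - 1 denominator).
coef_deviation <- function(x) stats::sd(x) / mean(x)

# Deterministic, order-insensitive seed mixing: folds integer parts into a
# 31-bit seed with a multiplicative congruential step. All products stay
# below 2^53 so the arithmetic is exact in doubles.
mix_seed <- function(...) {
  s <- 1
  for (p in c(...)) {
    s <- (s * 48271 + (as.numeric(p) %% 2147483647)) %% 2147483647
  }
  as.integer(s)
}

# Two-sided correlation with degenerate-input flagging. Returns list(rho,
# p_value, degenerate). Spearman uses average ranks for ties; for n <= 10
# the exact null distribution of the rank statistic is requested from
# cor.test (falling back to the asymptotic approximation when ties make the
# exact distribution unavailable).
cor_flagged <- function(x, y, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  n <- length(x)
  if (n != length(y)) stop("vectors must have equal length", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p_value = NA_real_, degenerate = TRUE, n = n))
  ct <- if (method == "spearman") {
    suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                     exact = n <= 10, alternative = "two.sided"))
  } else {
    stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  }
  list(rho = unname(ct$estimate), p_value = ct$p.value, degenerate = FALSE, n = n)
}

# Four-way region label from the signs of the mean- and CD-correlations.
# Zero rho (a measure-zero event with continuous data) falls on the
# negative side of its axis; callers flag such results as degenerate.
classify_region <- function(rho_mean, rho_cd) {
  ifelse(rho_mean > 0,
         ifelse(rho_cd > 0, "pos_mean_pos_cd", "pos_mean_neg_cd"),
         ifelse(rho_cd > 0, "neg_mean_pos_cd", "neg_mean_neg_cd"))
}

REGION_LEVELS <- c("pos_mean_pos_cd", "pos_mean_neg_cd",
                   "neg_mean_pos_cd", "neg_mean_neg_cd")
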