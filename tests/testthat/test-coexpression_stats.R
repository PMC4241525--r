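test_that("regulon summaries use the n-1 SD and CD = sd/mean", {
  m <- log_matrix(c(0.5, 1, 2, 3, 1, 2, 2, 2), genes = c("R1", "t1", "t2", "t3"),
                  conds = c("c1", "c2"))
  tm <- target_map("R1", c("t1", "t2", "t3"), 0)
  s <- summarize_targets(m, tm)
  expect_equal(nrow(s), 2)
  expect_equal(s$target_mean[1], 2)
  expect_equal(s$target_sd[1], 1)
  expect_equal(s$target_cd[1], 0.5)
  expect_equal(s$rbp_expr, c(0.5, 1))
  # constant targets: sd = 0, cd = 0
  expect_equal(s$target_sd[2], 0)
  expect_equal(s$target_cd[2], 0)
})

test_that("CD is invariant to scaling but not to shifts of the log values", {
  set.seed(5)
  x <- rnorm(20, 5, 1)
  cd <- sd(x) / mean(x)
  expect_equal(sd(3 * x) / mean(3 * x), cd)
  expect_false(isTRUE(all.equal(sd(x + 2) / mean(x + 2), cd)))
})

test_that("summaries guard degenerate regulons and near-zero means", {
  m <- log_matrix(c(1, 1e-12, -1e-12, 2, 3, 4), genes = c("R1", "t1", "t2"),
                  conds = c("c1", "c2"))
  tm <- target_map("R1", c("t1", "t2", "t_gone"), 0)
  expect_warning(s <- summarize_targets(m, tm), "absent")
  expect_false(s$cd_defined[1])      # |mean| below the guard
  expect_true(is.na(s$target_cd[1]))
  expect_true(s$cd_defined[2])

  tm1 <- target_map("R1", "t1", 0)
  expect_warning(expect_equal(nrow(summarize_targets(m, tm1)), 0), "< 2 usable")

  tm_missing <- target_map("Rmissing", c("t1", "t2"), 0)
  expect_error(summarize_targets(m, tm_missing), "Rmissing")
})

test_that("spearman rho matches hand-computed small cases", {
  r <- correlate_rbp(summary_rows(c(1, 2, 3), c(3, 1, 2)), "mean", "spearman")
  expect_equal(r$rho, -0.5)
  expect_false(r$degenerate)

  r2 <- correlate_rbp(summary_rows(c(4, 7, 9, 12), c(4, 7, 9, 12)), "mean", "spearman")
  expect_equal(r2$rho, 1)
})

test_that("spearman rho equals the rank-then-Pearson oracle, ties included", {
  set.seed(11)
  for (n in 3:8) {
    for (case in 1:20) {
      x <- sample(1:4, n, replace = TRUE) + runif(n, 0, 0.01) * rbinom(n, 1, 0.5)
      y <- sample(1:3, n, replace = TRUE) + runif(n, 0, 0.01) * rbinom(n, 1, 0.5)
      if (sd(x) == 0 || sd(y) == 0) next
      got <- correlate_rbp(summary_rows(x, y), "mean", "spearman")$rho
      expect_equal(got, oracle_spearman(x, y), tolerance = 1e-12)
    }
  }
})

test_that("spearman rho is invariant under strictly monotone transforms", {
  set.seed(23)
  x <- rnorm(30); y <- rnorm(30)
  base <- correlate_rbp(summary_rows(x, y), "mean", "spearman")$rho
  expect_equal(correlate_rbp(summary_rows(exp(x), y^3 + 5 * y), "mean", "spearman")$rho,
               base)
})

test_that("constant vectors yield a flagged result, not NaN", {
  r <- correlate_rbp(summary_rows(c(1, 2, 3, 4), rep(2, 4)), "mean", "spearman")
  expect_true(r$degenerate)
  expect_true(is.na(r$rho))
  expect_true(is.na(r$p_value))
  expect_error(correlate_rbp(summary_rows(c(1, 2), c(1, 2)), "mean"), "3 conditions")
})

test_that("classification follows the sign pair and reports the buffering fraction", {
  mk <- function(id, stat, rho) data.frame(rbp_id = id, statistic = stat,
                                           method = "spearman", rho = rho,
                                           p_value = 0.01, n_conditions = 100,
                                           degenerate = FALSE)
  cors <- rbind(mk("A", "mean", 0.6), mk("A", "cd", -0.4),
                mk("B", "mean", -0.2), mk("B", "cd", -0.2),
                mk("C", "mean", 0.3), mk("C", "cd", 0.7),
                mk("D", "mean", -0.5), mk("D", "cd", 0.1))
  cls <- classify_rbps(cors)
  got <- setNames(cls$classifications$region, cls$classifications$rbp_id)
  expect_identical(got[["A"]], "pos_mean_neg_cd")
  expect_identical(got[["B"]], "neg_mean_neg_cd")
  expect_identical(got[["C"]], "pos_mean_pos_cd")
  expect_identical(got[["D"]], "neg_mean_pos_cd")
  expect_equal(cls$fraction_buffering, 0.25)

  nine <- do.call(rbind, lapply(1:10, function(i)
    rbind(mk(paste0("R", i), "mean", if (i <= 9) 0.5 else -0.5),
          mk(paste0("R", i), "cd", -0.5))))
  expect_equal(classify_rbps(nine)$fraction_buffering, 0.9)

  expect_error(classify_rbps(mk("A", "mean", 0.6)), "both")
})

test_that("zero rho lands on the negative side and is flagged degenerate", {
  mk <- function(stat, rho) data.frame(rbp_id = "Z", statistic = stat,
                                       method = "spearman", rho = rho,
                                       p_value = 1, n_conditions = 10,
                                       degenerate = FALSE)
  cls <- classify_rbps(rbind(mk("mean", 0), mk("cd", 0.3)))
  expect_identical(cls$classifications$region, "neg_mean_pos_cd")
  expect_true(cls$classifications$degenerate)
})

test_that("BH adjustment is optional and leaves raw p-values in place", {
  set.seed(31)
  m <- log_matrix(rnorm(6 * 20, 5), genes = c("R1", "R2", paste0("t", 1:4)),
                  conds = sprintf("c%02d", 1:20))
  tm <- target_map(rep(c("R1", "R2"), each = 2), rep(paste0("t", 1:4)), 0)
  # regulons of size 2 are allowed through summarize directly
  s <- summarize_targets(m, tm)
  plain <- correlate_all_rbps(s, method = "spearman")
  adj <- correlate_all_rbps(s, method = "spearman", adjust = TRUE)
  expect_false("p_adjusted" %in% names(plain))
  expect_equal(adj$p_value, plain$p_value)
  expect_true(all(adj$p_adjusted >= adj$p_value - 1e-12, na.rm = TRUE))
})
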