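small_coexpr <- function(seed = 1, ...) {
  coexpression_scenario(n_rbps = 4, n_targets_per_rbp = 12,
                        n_background_genes = 40, n_conditions = 40,
                        seed = seed, ...)
}

test_that("fixtures are fully determined by their seed", {
  a <- planted_coexpression_fixture(small_coexpr(seed = 42))
  b <- planted_coexpression_fixture(small_coexpr(seed = 42))
  expect_identical(a$expression$values, b$expression$values)
  expect_identical(a$targets, b$targets)
  expect_identical(a$truth, b$truth)
  c_ <- planted_coexpression_fixture(small_coexpr(seed = 43))
  expect_false(identical(a$expression$values, c_$expression$values))

  k1 <- planted_knockout_fixture(knockout_scenario(n_targets = 50, seed = 7))
  k2 <- planted_knockout_fixture(knockout_scenario(n_targets = 50, seed = 7))
  expect_identical(k1$pair$wt_expr, k2$pair$wt_expr)
  expect_identical(k1$truth, k2$truth)
})

test_that("coexpression fixture satisfies the structural invariants", {
  fx <- planted_coexpression_fixture(small_coexpr(seed = 3))
  expect_identical(fx$expression$scale, "raw")
  expect_true(all(fx$expression$values > 0))

  planted <- fx$targets[grepl("_T", fx$targets$target_id), ]
  decoys <- fx$targets[!grepl("_T", fx$targets$target_id), ]
  expect_true(all(planted$q_value < 0.001))
  expect_true(all(decoys$q_value >= 0.001))
  expect_true(all(table(planted$rbp_id) >= 11))

  # every planted target and every regulator has an expression row
  expect_true(all(fx$targets$target_id %in% gene_ids(fx$expression)))
  expect_true(all(fx$truth$rbp_id %in% gene_ids(fx$expression)))
  expect_equal(unique(fx$truth$region), "pos_mean_neg_cd")
  fx0 <- planted_coexpression_fixture(small_coexpr(seed = 3, damping_strength = 0))
  expect_equal(unique(fx0$truth$region), "pos_mean_pos_cd")

  expect_error(coexpression_scenario(n_targets_per_rbp = 10), ">= 11")
  expect_error(coexpression_scenario(noise_sd = 0), "> 0")
})

test_that("degradation_efficiency inverts the knockout generator exactly", {
  fx <- planted_knockout_fixture(knockout_scenario(n_targets = 80, seed = 11))
  rec <- degradation_efficiency(fx$pair, pseudocount = 0)
  expect_equal(setNames(rec$efficiency, rec$gene_id),
               setNames(fx$truth$efficiency, fx$truth$gene_id),
               tolerance = 1e-12)
  expect_true(all(fx$truth$efficiency <= 0.95))
  expect_true(all(fx$pair$wt_expr > 0))
})

test_that("the damping flag controls expression-dependence, not the efficiency distribution", {
  on <- planted_knockout_fixture(knockout_scenario(n_targets = 150, damping = TRUE,
                                                   seed = 5))
  off <- planted_knockout_fixture(knockout_scenario(n_targets = 150, damping = FALSE,
                                                    seed = 5))
  rho_on <- efficiency_vs_expression(degradation_efficiency(on$pair, 0))$rho
  rho_off <- efficiency_vs_expression(degradation_efficiency(off$pair, 0))$rho
  expect_gt(rho_on, 0.5)
  expect_lt(abs(rho_off), 0.3)
  expect_equal(sort(on$truth$efficiency), sort(off$truth$efficiency))
})

test_that("planted-class recovery does not degrade as conditions accumulate", {
  acc_at <- function(nc) {
    hits <- 0L; total <- 0L
    for (s in 1:20) {
      fx <- planted_coexpression_fixture(
        coexpression_scenario(n_rbps = 5, n_targets_per_rbp = 12,
                              n_background_genes = 30, n_conditions = nc,
                              seed = s))
      res <- run_pipeline_in_memory(fx)
      got <- res$region[match(fx$truth$rbp_id, res$rbp_id)]
      hits <- hits + sum(got == fx$truth$region, na.rm = TRUE)
      total <- total + nrow(fx$truth)
    }
    hits / total
  }
  run_pipeline_in_memory <- function(fx) {
    m <- log_transform(fx$expression, base = 10, pseudocount = 0)
    tm <- filter_targets(fx$targets, 0.001, 11, universe = gene_ids(m))
    classify_rbps(correlate_all_rbps(summarize_targets(m, tm),
                                     statistics = c("mean", "cd")))$classifications
  }
  acc <- vapply(c(30, 80, 148), acc_at, numeric(1))
  expect_true(acc[1] <= acc[2] + 0.05 && acc[2] <= acc[3] + 0.05)
  expect_gt(acc[3], 0.9)
})

test_that("the steady-state oracle fixture is finite, positive and hand-checkable", {
  fx <- model_oracle_fixture(seed = 2)
  expect_lte(nrow(fx), 10)
  expect_true(all(is.finite(fx$ss_oracle)) && all(fx$ss_oracle > 0))
  expect_equal(fx$ss_oracle[1], 0.5)
  expect_equal(fx$j[nrow(fx)], 0)
  # the j = 0 row reduces to A * Hill / k
  last <- fx[nrow(fx), ]
  tf <- last$m * last$rbp
  expect_equal(last$ss_oracle,
               last$A * (tf^last$n / (last$T^last$n + tf^last$n)) / last$k,
               tolerance = 1e-12)
})
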