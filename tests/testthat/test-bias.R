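test_that("replication records are deterministic and carry the scenario factors", {
  cfg <- scenario_config(n_items = 4, group_size = 50, true_diff = 0.1,
                         dif_kind = "uniform", dif_size = 0.5,
                         dif_proportion = 0.5)
  r1 <- run_scenario(cfg, 2, master_seed = 3, cell = 5)
  r2 <- run_scenario(cfg, 2, master_seed = 3, cell = 5)
  expect_identical(r1, r2)
  expect_equal(nrow(r1), 2)
  expect_equal(r1$delta, r1$gamma_hat - 0.1)
  expect_false(identical(r1$seed,
                         run_scenario(cfg, 2, master_seed = 4, cell = 5)$seed))
  expect_error(run_scenario(cfg, 0), "at least 1")
})

test_that("measurement bias is the mean delta with its Monte-Carlo error", {
  rec <- fake_records("0.25", 0.25, "Unif", delta = c(0.1, -0.1))
  b <- measurement_bias(rec)
  expect_equal(b$bias, 0)
  expect_equal(b$n_converged, 2)

  rec2 <- fake_records("0.25", 0.25, "Unif", delta = rep(0.3, 5))
  b2 <- measurement_bias(rec2)
  expect_equal(b2$bias, 0.3)
  expect_equal(b2$mc_se, 0)

  rec$converged <- FALSE
  expect_error(measurement_bias(rec), "no converged")
})

test_that("non-converged replications are excluded and counted", {
  rec <- fake_records("0.25", 0.25, "Unif", delta = c(0.2, 0.4, 99))
  rec$converged[3] <- FALSE
  rec$delta[3] <- NA
  b <- measurement_bias(rec)
  expect_equal(b$bias, 0.3)
  expect_equal(b$n_converged, 2)
  expect_equal(b$n_total, 3)
})

test_that("the bias ANOVA recovers an exactly constructed decomposition", {
  # deterministic cell means: intercept 0.05, size and proportion effects,
  # and one genuine interaction
  grid <- expand.grid(size_label = c("0.25", "0.5", "1"),
                      prop = c(0.25, 0.5, 0.75),
                      pos = c("Unif", "High"), stringsAsFactors = FALSE)
  delta <- with(grid, 0.05 + 0.06 * (size_label == "0.5") +
                  0.15 * (size_label == "1") + 0.07 * (prop == 0.5) +
                  0.13 * (prop == 0.75) - 0.02 * (pos == "High") +
                  0.3 * (size_label == "1" & prop == 0.75))
  rec <- do.call(rbind, lapply(1:3, function(i)
    fake_records(grid$size_label, grid$prop, grid$pos, delta)))
  a <- suppressWarnings(anova_bias(rec, interactions = "always"))
  expect_s3_class(a, "bias_anova")
  expect_equal(anova_coef(a, "constant")$estimate, 0.05, tolerance = 1e-10)
  expect_equal(anova_coef(a, "effect_size", "0.5")$estimate, 0.06,
               tolerance = 1e-10)
  expect_equal(anova_coef(a, "effect_size", "1")$estimate, 0.15,
               tolerance = 1e-10)
  expect_equal(anova_coef(a, "proportion", "75%")$estimate, 0.13,
               tolerance = 1e-10)
  expect_equal(anova_coef(a, "position", "High")$estimate, -0.02,
               tolerance = 1e-10)
  expect_equal(anova_coef(a, "interaction", "1*75%")$estimate, 0.3,
               tolerance = 1e-10)
  expect_equal(anova_coef(a, "interaction", "0.5*50%")$estimate, 0,
               tolerance = 1e-10)
  expect_error(anova_coef(a, "effect_size", "7"), "no unique")
})

test_that("all-zero deltas give an all-zero coefficient table", {
  grid <- expand.grid(size_label = c("0.25", "1"), prop = c(0.25, 0.75),
                      stringsAsFactors = FALSE)
  rec <- do.call(rbind, lapply(1:2, function(i)
    fake_records(grid$size_label, grid$prop, "Unif", 0)))
  a <- suppressWarnings(anova_bias(rec, interactions = "never"))
  expect_true(all(abs(a$estimate) < 1e-12))
  expect_true(all(a$classification == "negligible"))
})

test_that("interaction auto-pruning follows the significant-and-large rule", {
  grid <- expand.grid(size_label = c("0.25", "1"), prop = c(0.25, 0.75),
                      stringsAsFactors = FALSE)
  # additive truth + tiny noise: interaction must be pruned
  set.seed(5)
  rec <- do.call(rbind, lapply(1:30, function(i)
    fake_records(grid$size_label, grid$prop, "Unif",
                 with(grid, 0.02 * (size_label == "1") + 0.01 * (prop == 0.75)) +
                   rnorm(4, 0, 0.01))))
  a <- anova_bias(rec, interactions = "auto")
  expect_false(any(a$factor == "interaction"))
  # strong interaction is retained
  rec2 <- do.call(rbind, lapply(1:30, function(i)
    fake_records(grid$size_label, grid$prop, "Unif",
                 with(grid, 0.4 * (size_label == "1" & prop == 0.75)) +
                   rnorm(4, 0, 0.01))))
  a2 <- anova_bias(rec2, interactions = "auto")
  expect_true(any(a2$factor == "interaction"))
})

test_that("varying non-DIF factors enter as reference-coded covariates", {
  rec <- rbind(fake_records("0.25", 0.25, "Unif", 0.10, true_diff = 0),
               fake_records("0.25", 0.25, "Unif", 0.08, true_diff = 0.5),
               fake_records("1",    0.25, "Unif", 0.30, true_diff = 0),
               fake_records("1",    0.25, "Unif", 0.28, true_diff = 0.5))
  a <- suppressWarnings(anova_bias(rec, interactions = "never"))
  expect_equal(anova_coef(a, "true_diff", "0.5")$estimate, -0.02,
               tolerance = 1e-10)
})

test_that("effect classification applies the negligible and major thresholds", {
  expect_equal(classify_effect(c(0, 0.015, -0.0151, 0.1, -0.101, 0.366)),
               c("negligible", "negligible", "small", "small", "major",
                 "major"))
})

test_that("cell-mean bias grows with effect size and proportion under uniform DIF", {
  cells <- expand.grid(dif_size = c(0.25, 1), dif_proportion = c(0.25, 0.75))
  out <- lapply(seq_len(nrow(cells)), function(i) {
    cfg <- scenario_config(n_items = 8, group_size = 200, true_diff = 0.1,
                           dif_kind = "uniform", dif_size = cells$dif_size[i],
                           dif_proportion = cells$dif_proportion[i])
    measurement_bias(run_scenario(cfg, 6, master_seed = 77, cell = i))
  })
  bias <- vapply(out, `[[`, numeric(1), "bias")
  slack <- 2 * vapply(out, `[[`, numeric(1), "mc_se")
  # within each proportion, bias rises with size; within each size, with prop
  expect_gt(bias[2], bias[1] - slack[2])  # size 1 vs 0.25 at 25%
  expect_gt(bias[4], bias[3] - slack[4])  # size 1 vs 0.25 at 75%
  expect_gt(bias[3], bias[1] - slack[3])  # 75% vs 25% at size 0.25
  expect_gt(bias[4], bias[2] - slack[4])  # 75% vs 25% at size 1
  expect_gt(bias[4], 0.4)                 # large-DIF cell clearly biased
})

test_that("the benchmark helper summarises the 12 no-DIF cells", {
  out <- random_error_benchmark(n_reps = 2, master_seed = 1)
  expect_equal(nrow(out$cells), 12)
  expect_true(is.finite(out$benchmark))
  expect_equal(out$benchmark, max(abs(out$cells$bias)))
  expect_setequal(unique(out$cells$n_items), c(4L, 8L))
})
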