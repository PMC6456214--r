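make_small <- function(seed, n = 25, dif_kind = "none", ...) {
  cfg <- scenario_config(n_items = 4, group_size = n, true_diff = 0.2,
                         dif_kind = dif_kind, ...)
  simulate_dataset(cfg, seed = seed)
}

test_that("quadrature marginal likelihood matches dense integration", {
  for (seed in 1:3) {
    d <- make_small(seed)
    gamma <- c(0.3, -0.2, 0)[seed]
    sigma <- c(1, 0.8, 1.3)[seed]
    ll <- marginal_loglik(gamma, sigma, d$bank, d$responses, d$group)
    oracle <- trap_marginal_loglik(gamma, sigma, d$bank, d$responses, d$group)
    expect_lt(max(abs(attr(ll, "by_person") - oracle)), 1e-4)
    expect_equal(as.numeric(ll), sum(oracle), tolerance = 1e-6)
  }
})

test_that("marginal likelihood is additive over persons and skips missing cells", {
  d <- make_small(4)
  ll1 <- marginal_loglik(0.1, 1, d$bank, d$responses, d$group)
  ll2 <- marginal_loglik(0.1, 1, d$bank, rbind(d$responses, d$responses),
                         c(d$group, d$group))
  expect_equal(2 * as.numeric(ll1), as.numeric(ll2), tolerance = 1e-10)

  resp_na <- d$responses
  resp_na[3, 2] <- NA
  ll_na <- marginal_loglik(0.1, 1, d$bank, resp_na, d$group)
  oracle <- trap_marginal_loglik(0.1, 1, d$bank, resp_na, d$group)
  expect_lt(max(abs(attr(ll_na, "by_person") - oracle)), 1e-4)
  # dropping an observed term can only raise that person's log-likelihood
  expect_gt(attr(ll_na, "by_person")[3], attr(ll1, "by_person")[3])
})

test_that("the marginal likelihood validates its inputs", {
  d <- make_small(5)
  expect_error(marginal_loglik(NA, 1, d$bank, d$responses, d$group), "finite")
  expect_error(marginal_loglik(0, -1, d$bank, d$responses, d$group), "positive")
  expect_error(marginal_loglik(0, 1, d$bank, d$responses, d$group,
                               quadrature = 3), "at least 5")
  bad <- d$responses; bad[1, 1] <- 9L
  expect_error(marginal_loglik(0, 1, d$bank, bad, d$group), "0..4")
})

test_that("refining the quadrature leaves the likelihood unchanged", {
  cfg <- scenario_config(n_items = 8, group_size = 100, true_diff = 0.1,
                         dif_kind = "uniform", dif_size = 1,
                         dif_proportion = 0.5)
  d <- simulate_dataset(cfg, seed = 11)
  fit <- fit_latent_regression_pcm(d, se = FALSE)
  ll61 <- marginal_loglik(fit$gamma, fit$sigma, fit$items, d$responses,
                          d$group)                       # default, 61 nodes
  ll101 <- marginal_loglik(fit$gamma, fit$sigma, fit$items, d$responses,
                           d$group, quadrature = 101)
  expect_lt(abs(ll61 - ll101) / nrow(d$responses), 1e-5)
})

test_that("byte-identical groups give a zero group difference", {
  d <- make_small(6, n = 60)
  half <- d$responses[d$group == "reference", ]
  resp <- rbind(half, half)
  grp <- rep(c("reference", "focal"), each = nrow(half))
  fit <- fit_latent_regression_pcm(resp, grp, se = FALSE)
  expect_true(fit$convergence$converged)
  expect_lt(abs(fit$gamma), 0.02)
})

test_that("fits expose estimates, standard errors and convergence info", {
  cfg <- scenario_config(n_items = 4, group_size = 150, true_diff = 0.3)
  d <- simulate_dataset(cfg, seed = 21)
  fit <- fit_latent_regression_pcm(d)
  expect_s3_class(fit, "pcm_fit")
  expect_true(fit$convergence$converged)
  expect_gt(fit$sigma, 0)
  expect_true(is.finite(fit$loglik))
  expect_equal(nrow(fit$items), 4)
  expect_true(is.finite(fit$se["gamma"]) && fit$se["gamma"] > 0)
  # gamma SE should be near sqrt(2/n) inflated by measurement error
  expect_lt(fit$se["gamma"], 0.35)
  expect_gt(fit$se["gamma"], 0.05)
})

test_that("estimates are invariant to a common shift of the generating scale", {
  # shifting all true locations and both trait means leaves responses, and
  # hence the fitted group difference, unchanged (reference mean is fixed at 0)
  cfg <- scenario_config(n_items = 4, group_size = 80, true_diff = 0.2)
  d <- simulate_dataset(cfg, seed = 13)
  shifted_bank <- item_bank(as.matrix(d$bank[paste0("delta_", 1:4)]) + 0.7,
                            item_id = d$bank$item_id)
  set.seed(13)
  n <- cfg$group_size
  theta <- c(rnorm(n, 0, 1), rnorm(n, -0.2, 1)) + 0.7
  m <- as.matrix(shifted_bank[paste0("delta_", 1:4)])
  resp <- sapply(1:4, function(j) difbias:::sample_pcm(theta, m[j, ]))
  expect_identical(unname(d$responses), unname(resp))
})

test_that("degenerate and sparse items are screened with warnings", {
  d <- make_small(8, n = 40)
  resp <- d$responses
  resp[, 2] <- 2L                       # constant item
  expect_warning(fit <- fit_latent_regression_pcm(resp, d$group, se = FALSE),
                 "fewer than two observed categories")
  expect_equal(fit$n_items, 3)

  resp2 <- d$responses
  resp2[, 3][resp2[, 3] == 2L] <- 3L    # middle category never observed
  expect_warning(fit2 <- fit_latent_regression_pcm(resp2, d$group, se = FALSE),
                 "collapsing unobserved categories")
  expect_equal(fit2$kvec[3], 3L)

  allsame <- matrix(1L, 20, 3)
  expect_error(
    suppressWarnings(fit_latent_regression_pcm(allsame, rep(0:1, 10))),
    "degenerate")
  expect_error(fit_latent_regression_pcm(d$responses[1:3, ],
                                         c(0, 0, 1)), "2 persons per group")
})

test_that("per-item DIF estimation flags the affected item and recovers its kind", {
  cfg <- scenario_config(n_items = 4, group_size = 400, true_diff = 0.1,
                         dif_kind = "uniform", dif_size = 1,
                         dif_proportion = 0.25, dif_position = "High")
  d <- simulate_dataset(cfg, seed = 42)
  dif_id <- colnames(d$responses)[d$dif_items]
  t_dif <- estimate_item_dif(d, item_id = dif_id)
  expect_lt(t_dif$tests$p_value[1], 1e-4)       # uniform shift detected
  expect_gt(t_dif$tests$p_value[2], 0.01)       # no extra non-uniform signal
  expect_identical(t_dif$classification$kind, "uniform")
  expect_lt(abs(t_dif$shared_shift - 1), 0.3)
  expect_true(is.finite(t_dif$shared_se) && t_dif$shared_se > 0)
  # likelihoods are nested
  expect_true(all(diff(t_dif$loglik) >= -1e-6))

  clean_id <- colnames(d$responses)[setdiff(1:4, d$dif_items)][1]
  t_clean <- estimate_item_dif(d, item_id = clean_id)
  expect_lt(abs(t_clean$shared_shift), 0.25)
  expect_error(estimate_item_dif(d, item_id = "nope"), "not present")
})

test_that("dif_summary collects one classified row per item", {
  cfg <- scenario_config(n_items = 4, group_size = 200, true_diff = 0,
                         dif_kind = "uniform", dif_size = 1,
                         dif_proportion = 0.25, dif_position = "Low")
  d <- simulate_dataset(cfg, seed = 2)
  s <- dif_summary(d)
  expect_equal(nrow(s), 4)
  expect_true(all(c("item_id", "kind", "effect", "p_value") %in% names(s)))
  expect_lt(s$p_value[d$dif_items], 0.01)
})
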