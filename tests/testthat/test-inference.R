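test_that("tied-model fit recovers generating parameters from noiseless data", {
  d <- noiseless_data()
  fit <- fit_repair(d, n_starts = 25, seed = 3)
  expect_lt(abs(fit$rates$k_s - 0.21) / 0.21, 1e-3)
  expect_lt(abs(fit$rates$k_d - 0.74) / 0.74, 1e-3)
  expect_lt(fit$ssr, 1e-10)
  expect_equal(unclass(fit$init), unclass(ref_init()), tolerance = 1e-4)

  # reported parameters achieve the minimum objective among starts
  expect_equal(fit$ssr, min(fit$starts$objective))

  # ssr equals an independent recomputation of the residuals
  resid <- vapply(seq_len(nrow(d)), function(i) {
    scn <- scenario(d$condition[i],
                    s_inh = if (d$condition[i] == "NU7441") 0 else 1)
    tr <- solve_repair(fit$rates, scn, fit$init, times = d$time_h[i])
    obs <- observe(tr)
    d$value[i] - obs[[d$observable[i]]]
  }, 0)
  expect_equal(fit$ssr, sum(resid^2), tolerance = 1e-12)
})

test_that("fit recovery holds across random generating rates", {
  set.seed(19)
  for (i in 1:5) {
    k <- stats::runif(2, 0.05, 2)
    cfg <- reference_config(rates = rate_constants(k_s = k[1], k_d = k[2]),
                            noise_sd = 0, n_replicates = 1)
    fit <- fit_repair(generate_dataset(cfg), n_starts = 60, seed = i)
    expect_lt(abs(fit$rates$k_s - k[1]) / k[1], 1e-3)
    expect_lt(abs(fit$rates$k_d - k[2]) / k[2], 1e-3)
  }
})

test_that("fits are deterministic under a fixed seed", {
  d <- generate_dataset(reference_config(seed = 5))
  f1 <- fit_repair(d, n_starts = 10, seed = 42)
  f2 <- fit_repair(d, n_starts = 10, seed = 42)
  expect_identical(f1$theta, f2$theta)
  expect_identical(f1$ssr, f2$ssr)
  c1 <- bootstrap_ci(f1, d, n_boot = 60, seed = 9)
  c2 <- bootstrap_ci(f2, d, n_boot = 60, seed = 9)
  expect_identical(c1$ci, c2$ci)
})

test_that("fit validation rejects degenerate designs", {
  d <- noiseless_data()
  expect_error(fit_repair(d[d$time_h == 0, ]), "underdetermined")
  bad <- d; bad$condition <- "mystery-drug"
  expect_error(fit_repair(bad), "mystery-drug")
  expect_error(fit_repair(data.frame()), "empty|lacks")
  expect_error(validate_measurements(transform(d, value = value + 2)),
               "outside")
  expect_error(
    validate_measurements(transform(d, observable = "nicked")),
    "unknown observable")
})

test_that("data without dynamics flag the rates as unconstrained", {
  d <- expand.grid(condition = "control", time_h = c(0, 1, 2),
                   replicate = 1:2, observable = "supercoiled",
                   stringsAsFactors = FALSE)
  d$value <- 1
  fit <- fit_repair(d, n_starts = 30, seed = 2)
  expect_true(any(grepl("unidentifiable", fit$flags)))
})

test_that("bootstrap intervals behave on noiseless and noisy data", {
  # zero residual noise -> degenerate interval at the estimate
  d0 <- noiseless_data()
  f0 <- fit_repair(d0, n_starts = 10, seed = 1)
  f0 <- bootstrap_ci(f0, d0, n_boot = 60, seed = 1)
  expect_equal(f0$ci$lower, f0$ci$estimate, tolerance = 1e-6)
  expect_equal(f0$ci$upper, f0$ci$estimate, tolerance = 1e-6)

  # noisy data: interval contains the generating value and the estimate
  d <- generate_dataset(reference_config(seed = 11))
  f <- fit_repair(d, n_starts = 10, seed = 1)
  f <- bootstrap_ci(f, d, n_boot = 200, seed = 2)
  ks <- f$ci[f$ci$parameter == "k_s", ]
  expect_lte(ks$lower, 0.21)
  expect_gte(ks$upper, 0.21)
  expect_true(all(f$ci$lower <= f$ci$estimate & f$ci$estimate <= f$ci$upper))

  # stability warning for very small bootstrap
  fs <- bootstrap_ci(f, d, n_boot = 20, seed = 2)
  expect_true(any(grepl("ci-unstable", fs$flags)))
})

test_that("multistart scan separates tied from untied identifiability", {
  d <- generate_dataset(reference_config())  # canonical noisy dataset
  free <- identifiability_scan(d, tie_rates = FALSE, n_starts = 60, seed = 3)
  tied <- identifiability_scan(d, tie_rates = TRUE, n_starts = 60, seed = 3)
  expect_true(free$non_identifiable)
  expect_false(tied$non_identifiable)
  expect_gt(free$n_near_optimal, 1)
  expect_error(identifiability_scan(d[0, ]), "empty|lacks")
})

test_that("endpoint comparison is the classical pooled-variance t-test", {
  a <- toy_table(c(0.5, 0.6, 0.7))
  b <- toy_table(c(0.1, 0.2, 0.3))
  res <- compare_endpoint(a, b, "supercoiled", 2)
  expect_equal(res$difference, 0.4)
  # oracle: pooled t by hand -> sp = 0.1, se = 0.1*sqrt(2/3), df = 4
  t_hand <- 0.4 / (0.1 * sqrt(2 / 3))
  expect_equal(res$statistic, t_hand, tolerance = 1e-12)
  expect_equal(res$df, 4)
  expect_equal(res$p_value, 2 * stats::pt(-t_hand, 4), tolerance = 1e-12)
  expect_equal(round(res$p_value, 5), 0.00805)

  # identical groups -> zero difference, p = 1
  res0 <- compare_endpoint(a, a, "supercoiled", 2)
  expect_equal(res0$difference, 0)
  expect_equal(res0$p_value, 1)

  expect_error(compare_endpoint(a, toy_table(0.5), "supercoiled", 2),
               "fewer than 2 replicates")
  expect_error(compare_endpoint(a, b, "supercoiled", 1), "no rows")
})
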