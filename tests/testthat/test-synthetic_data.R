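test_that("cohort generation is deterministic and respects its contracts", {
  co1 <- generate_cohort(n_per_group = c(50, 50), seed = 123)
  co2 <- generate_cohort(n_per_group = c(50, 50), seed = 123)
  expect_identical(co1, co2)
  expect_equal(length(unique(co1$subject_id)), 100)
  expect_true(all(table(co1$subject_id) %in% 1:4))
  # scan ages bounded by baseline range + visits x gap (with jitter slack)
  expect_true(all(co1$age >= 5 & co1$age <= 30 + 4 * 3))
  # ages non-decreasing within subject
  expect_true(all(unlist(tapply(co1$age, co1$subject_id, diff)) > 0))
  # purely cross-sectional table when visits are forced to 1
  cs <- generate_cohort(n_per_group = c(10, 10), visits_distribution = 1,
                        seed = 5)
  expect_equal(nrow(cs), 20)
  expect_true(all(cs$visit == 1))
  # subscales assessed only in the case group
  expect_true(all(is.na(co1$score_positive[co1$group == "control"])))
  expect_true(all(!is.na(co1$score_positive[co1$group == "case"])))
  expect_error(generate_cohort(n_per_group = 10), "two group sizes")
  expect_error(generate_cohort(age_range = c(30, 5)), "age_range")
})

test_that("case/control confound shifts match the generator's configuration", {
  # Monte-Carlo check of the statistical contract at generous tolerance
  co <- generate_cohort(n_per_group = c(300, 300), seed = 9)
  agg <- tapply(co$mean_fd, co$group, mean)
  expect_gt(agg[["case"]], agg[["control"]])   # motion shifted upward
  iq <- tapply(co$fsiq, co$group, mean)
  expect_lt(iq[["case"]], iq[["control"]])
  expect_equal(unname(iq[["case"]]), 72, tolerance = 0.05)
  expect_equal(unname(iq[["control"]]), 110.7, tolerance = 0.05)
})

test_that("feature generation plants recoverable latent structure", {
  co <- generate_cohort(n_per_group = c(20, 20), seed = 31)
  v <- matrix(rnorm(200), 200, 1)
  # noise-free single component: PLS-C recovers the pattern exactly
  tr0 <- ground_truth(v, c(group = 4), noise_sd = 0)
  X0 <- generate_feature_data(co, tr0, seed = 32)
  dm <- build_design_matrix(co, "group", positive_level = "case")
  fit <- plsc(X0, dm)
  expect_gt(abs(sum(fit$V[, 1] * tr0$planted_V[, 1])), 1 - 1e-8)
  # planted effect size is the covariance between design column and score
  score <- X0 %*% tr0$planted_V[, 1]
  expect_equal(sum(dm$Y[, "group"] * score) / nrow(X0), 4,
               tolerance = 1e-10)
  # determinism under seed
  expect_identical(X0, generate_feature_data(co, tr0, seed = 32))
  # unknown or degenerate planted columns error out
  expect_error(generate_feature_data(co, ground_truth(v, c(banana = 1))),
               "unknown design column")
  cs <- generate_cohort(n_per_group = c(5, 5), visits_distribution = 1,
                        seed = 2)
  expect_error(
    generate_feature_data(cs, ground_truth(v, c(age_long = 1))),
    "zero-variance")
})

test_that("toy time series carry the planted inter-region correlations", {
  C <- matrix(c(1, 1, 1, 1), 2, 2)        # perfectly coupled regions
  toy <- generate_toy_timeseries(n_regions = 2, planted_correlation = C,
                                 T = 50, grid = c(8, 4, 4), noise_sd = 0,
                                 seed = 61)
  seedc <- extract_roi_mean_timecourse(toy$ts, toy$regions[[2]])
  cm <- seed_connectivity_map(toy$ts, seedc)
  expect_equal(unname(cm$values[which(toy$regions[[1]])]),
               rep(1, sum(toy$regions[[1]])))

  # independent regions: empirical |r| within Fisher sampling error
  toy0 <- generate_toy_timeseries(n_regions = 2,
                                  planted_correlation = diag(2),
                                  T = 2000, grid = c(8, 4, 4),
                                  noise_sd = 0, seed = 62)
  r <- cor(toy0$signals[, 1], toy0$signals[, 2])
  expect_lt(abs(r), 3.5 / sqrt(2000 - 3))

  expect_error(generate_toy_timeseries(2, matrix(c(1, 2, 2, 1), 2, 2)),
               "positive semidefinite")
  expect_error(generate_toy_timeseries(2, diag(3)), "2 x 2")
})

test_that("injected motion spikes are censored exactly", {
  toy <- generate_toy_timeseries(n_regions = 2, T = 60, grid = c(6, 4, 4),
                                 spike_frames = c(10, 25, 26), seed = 63)
  fd <- compute_fd_power(toy$motion)
  res <- censor_frames(toy$ts, fd, cutoff = 0.5, min_frames = 10)
  expect_equal(res$kept, setdiff(1:60, c(10, 25, 26)))
})

test_that("atlas probabilities peak inside the true regions", {
  toy <- generate_toy_timeseries(n_regions = 3, T = 10, grid = c(12, 4, 4),
                                 seed = 64)
  ms <- build_exclusive_masks(toy$atlas, 0.5)
  for (r in 1:3)
    expect_identical(ms$masks[[paste0("R", r)]], toy$regions[[r]])
})
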