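test_that("permutation p-values follow the add-one counting rule", {
  co <- toy_cohort_mixed(seed = 4)
  dm <- build_design_matrix(co, "group", positive_level = "case")
  # strong noise-free effect planted on a subject-unique column, tested
  # against a single-column design: only the (rare) identity draw can tie
  # the observed S1, all other nulls fall strictly below
  set.seed(40)
  v <- rnorm(60); v <- v / sqrt(sum(v^2))
  X <- tcrossprod(dm$Y[, "age_cs"], v) * 50
  Ycs <- dm$Y[, "age_cs", drop = FALSE]
  pm <- permutation_test(X, Ycs, subjects = dm$subject_id, n_perm = 199,
                         seed = 41)
  n_ties <- sum(abs(pm$null_S[, 1] - pm$observed_S[1]) < 1e-8)
  expect_equal(pm$p[1], (1 + n_ties) / 200)
  expect_lt(pm$p[1], 0.05)
  expect_true(all(pm$p >= 1 / 200 & pm$p <= 1))
  # p restates the add-one counting definition of the exposed null draws
  expect_equal(pm$p, sapply(seq_along(pm$p), function(k)
    (1 + sum(pm$null_S[, k] >= pm$observed_S[k])) / 200))

  # all-zero brain block: every null equals the observed zero -> p = 1
  pm0 <- permutation_test(matrix(0, nrow(co), 10), dm, n_perm = 50,
                          seed = 42)
  expect_equal(pm0$p, rep(1, ncol(dm$Y)))
})

test_that("permutation p-values are invariant to voxel order and reproducible", {
  co <- toy_cohort_mixed(seed = 5)
  dm <- build_design_matrix(co, "group", positive_level = "case")
  set.seed(50)
  X <- matrix(rnorm(nrow(co) * 40), nrow(co), 40)
  pm1 <- permutation_test(X, dm, n_perm = 60, seed = 7)
  pm2 <- permutation_test(X[, sample(40)], dm, n_perm = 60, seed = 7)
  expect_identical(pm1$p, pm2$p)
  pm3 <- permutation_test(X, dm, n_perm = 60, seed = 7)
  expect_identical(pm1$null_S, pm3$null_S)
})

test_that("subject blocks stay intact under stratified permutation", {
  co <- toy_cohort_mixed(seed = 6)
  dm <- build_design_matrix(co, "group", positive_level = "case")
  blocks <- split(seq_len(nrow(co)), co$subject_id)
  sizes <- lengths(blocks)
  X <- matrix(rnorm(nrow(co) * 10), nrow(co), 10)
  pm <- permutation_test(X, dm, n_perm = 40, seed = 9,
                         return_perms = TRUE)
  block_list <- unname(blocks)
  is_block <- function(x)
    any(vapply(block_list, function(b) identical(b, x), logical(1)))
  for (perm in pm$perms) {
    for (b in block_list) {
      donor <- perm[b]                    # design rows given to this subject
      expect_true(is_block(donor))        # a complete subject block, in order
      expect_equal(length(donor), length(b))  # same-size stratum
    }
    # every design row used exactly once
    expect_setequal(perm, seq_len(nrow(co)))
  }
})

test_that("bootstrap resampling keeps whole subjects and aligns signs", {
  co <- toy_cohort_mixed(seed = 7)
  dm <- build_design_matrix(co, "group", positive_level = "case")
  set.seed(70)
  X <- matrix(rnorm(nrow(co) * 30), nrow(co), 30)
  bt <- bootstrap_saliences(X, dm, n_boot = 30, seed = 71,
                            return_rows = TRUE)
  blocks <- unname(split(seq_len(nrow(co)), co$subject_id))
  n_subj <- length(blocks)
  firsts <- vapply(blocks, `[`, integer(1), 1L)
  for (rows in bt$rows) {
    # replicate decomposes into a sequence of complete subject blocks
    i <- 1
    n_blocks <- 0
    ok <- TRUE
    while (i <= length(rows)) {
      b <- blocks[[match(rows[i], firsts)]]   # block starting here
      if (i + length(b) - 1 > length(rows) ||
          !identical(rows[i:(i + length(b) - 1)], b)) {
        ok <- FALSE
        break
      }
      i <- i + length(b)
      n_blocks <- n_blocks + 1
    }
    expect_true(ok)                     # no scan separated from its subject
    expect_equal(n_blocks, n_subj)      # as many draws as subjects
  }
  # reproducible given the seed
  bt2 <- bootstrap_saliences(X, dm, n_boot = 30, seed = 71)
  expect_identical(bt$bsr, bt2$bsr)
})

test_that("noise-free planted data gives degenerate, stable bootstrap voxels", {
  co <- toy_cohort_mixed(seed = 8)
  dm <- build_design_matrix(co, "group", positive_level = "case")
  v <- c(rep(0.5, 4), rep(0, 6))
  X <- tcrossprod(dm$Y[, "group"], v) * 10
  bt <- bootstrap_saliences(X, dm, n_boot = 20, seed = 80)
  # every replicate SVD returns the same rank-1 salience -> SD 0
  expect_true(all(bt$degenerate[, 1]))
  expect_true(all(is.na(bt$bsr[, 1])))
  thr <- threshold_bsr(bt, 3)
  # degenerate voxels with nonzero mean are reported stable, signed
  expect_true(all(thr$retained[1:4, 1]))
  expect_false(any(thr$retained[5:10, 1]))
  expect_true(all(is.infinite(thr$map[1:4, 1])))
})

test_that("BSR thresholding is strict, signed and monotone in the cutoff", {
  fake <- structure(list(
    bsr = matrix(c(2.9, 3.0, 3.1, -3.2), 4, 1),
    v_mean = matrix(c(0.1, 0.1, 0.1, -0.1), 4, 1),
    v_sd = matrix(0.03, 4, 1),
    degenerate = matrix(FALSE, 4, 1)), class = "bootstrap_result")
  thr <- threshold_bsr(fake, 3)
  expect_equal(thr$retained[, 1], c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(thr$map[, 1], c(0, 0, 3.1, -3.2))
  # cutoff 0 retains all non-degenerate voxels
  expect_true(all(threshold_bsr(fake, 0)$retained))
  # raising the cutoff never adds voxels
  for (cut in c(1, 2, 3, 4)) {
    lo <- threshold_bsr(fake, cut - 1)$retained
    hi <- threshold_bsr(fake, cut)$retained
    expect_true(all(lo[hi]))
  }
})

test_that("degenerate bootstrap replicates are redrawn up to the cap", {
  # one giant subject dominates: resamples drawing only the singleton
  # subjects can zero out the group column, forcing redraws
  co <- data.frame(subject_id = c(rep("big", 4), "s1", "s2"),
                   scan_id = paste0("x", 1:6),
                   age = c(10, 11, 12, 13, 20, 21),
                   group = c(rep("case", 4), "control", "control"))
  suppressWarnings(dm <- build_design_matrix(co, "group",
                                             positive_level = "case"))
  set.seed(90)
  X <- matrix(rnorm(6 * 8), 6, 8)
  bt <- bootstrap_saliences(X, dm, n_boot = 40, seed = 91,
                            max_redraw = 5000)
  expect_gt(bt$n_redraws, 0)
  expect_false(any(is.na(bt$v_mean)))
  expect_error(bootstrap_saliences(X, dm, n_boot = 200, seed = 91,
                                   max_redraw = 0),
               "max_redraw")
})
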