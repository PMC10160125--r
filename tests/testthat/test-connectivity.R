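test_that("framewise displacement matches the closed-form Power sum", {
  n_t <- 10
  zero <- matrix(0, n_t, 6)
  expect_equal(compute_fd_power(zero), rep(0, n_t))

  # +1 mm step in one translation at frame 4 -> FD 1 mm at frame 4 only
  m <- zero
  m[4:n_t, 2] <- 1
  expect_equal(compute_fd_power(m), c(rep(0, 3), 1, rep(0, n_t - 4)))

  # 0.02 rad rotation step on a 50 mm sphere -> 50 * 0.02 = 1 mm
  m2 <- zero
  m2[7:n_t, 5] <- 0.02
  expect_equal(compute_fd_power(m2, head_radius = 50),
               c(rep(0, 6), 1, rep(0, n_t - 7)))

  # all six parameters change together: contributions add
  m3 <- zero
  m3[3:n_t, ] <- rep(c(0.1, 0.2, 0.3, 0.01, 0.02, 0.03), each = n_t - 2)
  expect_equal(compute_fd_power(m3)[3], 0.6 + 50 * 0.06)
  expect_error(compute_fd_power(zero[, 1:5]), "6 columns")
})

test_that("motion traces read from whitespace and comma text identically", {
  m <- matrix(round(rnorm(5 * 6), 4), 5, 6)
  f1 <- tempfile(fileext = ".txt")
  f2 <- tempfile(fileext = ".csv")
  write.table(m, f1, row.names = FALSE, col.names = FALSE)
  write.table(m, f2, row.names = FALSE, col.names = FALSE, sep = ",")
  expect_equal(read_motion_trace(f1), m)
  expect_equal(read_motion_trace(f2), m)
})

test_that("frame censoring keeps exactly the frames at or below cutoff", {
  dat <- array(rnorm(2 * 2 * 1 * 4), c(2, 2, 1, 4))
  ts <- timeseries_image(dat, tr = 2.4)
  fd <- c(0, 0.6, 0.1, 0.3)
  res <- censor_frames(ts, fd, cutoff = 0.5, min_frames = 3)
  expect_equal(res$kept, c(1L, 3L, 4L))
  expect_false(res$excluded)
  expect_equal(res$ts$data, dat[, , , c(1, 3, 4), drop = FALSE])
  expect_equal(res$mean_fd, mean(fd[c(1, 3, 4)]))

  # all frames below cutoff -> identity
  all_ok <- censor_frames(ts, c(0.1, 0.2, 0.3, 0.4), cutoff = 0.5,
                          min_frames = 3)
  expect_equal(all_ok$kept, 1:4)
  expect_equal(all_ok$ts$data, dat)

  # all frames above cutoff -> exclusion signal, not an error
  none <- censor_frames(ts, c(1, 1, 1, 1), cutoff = 0.5, min_frames = 1)
  expect_true(none$excluded)
  expect_null(none$ts)
  expect_error(censor_frames(ts, c(0, 0), 0.5), "frames")
})

test_that("seed connectivity maps are exact Pearson correlations", {
  n_t <- 40
  seedc <- sin(seq(0, 6 * pi, length.out = n_t))
  dat <- array(0, c(4, 1, 1, n_t))
  dat[1, 1, 1, ] <- seedc                       # identical -> r = 1
  dat[2, 1, 1, ] <- -seedc                      # negated -> r = -1
  dat[3, 1, 1, ] <- 3 + 2 * seedc               # affine -> r = 1
  dat[4, 1, 1, ] <- 5                           # zero variance -> NA
  ts <- timeseries_image(dat, tr = 2.4)
  cm <- seed_connectivity_map(ts, seedc)
  expect_equal(cm$values[c(1, 2, 3)], c(1, -1, 1))
  expect_true(is.na(cm$values[4]))

  # quadrature sinusoids over whole periods are uncorrelated
  tt <- seq(0, 2 * pi, length.out = 201)[-201]
  dat2 <- array(rep(sin(tt), each = 1), c(1, 1, 1, 200))
  ts2 <- timeseries_image(dat2, tr = 2.4)
  cm2 <- seed_connectivity_map(ts2, cos(tt))
  expect_lt(abs(cm2$values[1]), 1e-6)

  expect_error(seed_connectivity_map(ts, rep(1, n_t)), "zero-variance seed")
  expect_error(seed_connectivity_map(ts, seedc[1:5]), "length")
})

test_that("censoring then correlating equals correlating the kept sub-series", {
  set.seed(5)
  n_t <- 60
  dat <- array(rnorm(8 * n_t), c(2, 2, 2, n_t))
  ts <- timeseries_image(dat, tr = 2)
  fd <- runif(n_t, 0, 1)
  res <- censor_frames(ts, fd, cutoff = 0.5, min_frames = 5)
  seedc <- rnorm(n_t)
  full <- seed_connectivity_map(res$ts, seedc[res$kept])
  manual <- apply(matrix(dat, 8, n_t)[, res$kept], 1,
                  function(v) cor(v, seedc[res$kept]))
  expect_equal(as.vector(full$values), manual)
})

test_that("stacking maps drops voxels missing in any scan and keeps a sidecar", {
  set.seed(6)
  n_t <- 30
  mk <- function(const_vox) {
    dat <- array(rnorm(6 * n_t), c(3, 2, 1, n_t))
    if (!is.na(const_vox)) {
      flat <- matrix(dat, 6, n_t)
      flat[const_vox, ] <- 7
      dat <- array(flat, dim(dat))
    }
    dat
  }
  seedc <- rnorm(n_t)
  maps <- list(
    seed_connectivity_map(timeseries_image(mk(2), 2), seedc, scan_id = "a"),
    seed_connectivity_map(timeseries_image(mk(NA), 2), seedc, scan_id = "b"))
  st <- stack_connectivity_maps(maps)
  expect_equal(nrow(st$X), 2)
  expect_equal(ncol(st$X), 5)          # voxel 2 dropped everywhere
  expect_false(2L %in% st$voxel_index)
  expect_equal(rownames(st$X), c("a", "b"))
  vol <- unflatten_voxels(st$X[1, ], st$voxel_index, st$grid_dim)
  expect_true(is.na(vol[2]))
  expect_equal(vol[st$voxel_index], unname(st$X[1, ]))
})
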