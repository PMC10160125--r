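# Synthetic-data module: cohorts, feature matrices and toy 4D volumes
# with known ground truth, so every pipeline stage is testable without
# any external data.

#' Ground truth for synthetic brain-feature data
#'
#' @param planted_V Matrix (voxels x components) of planted brain
#'   salience patterns; each column is normalized to unit norm.
#' @param planted_effect Named numeric vector mapping design-column names
#'   (`"group"`, `"age_cs"`, `"age_long"`, `"group_x_age_cs"`,
#'   `"group_x_age_long"`) to effect sizes, parameterized as the
#'   covariance between the (z-scored) design column and the latent brain
#'   score along the corresponding planted pattern.
#' @param noise_sd Per-voxel Gaussian noise SD added on top of the
#'   planted structure.
#' @param smooth Half-width (in voxel-index units) of an optional
#'   moving-average kernel applied to the noise, mimicking the spatial
#'   correlation of real maps; 0 disables smoothing.
#' @return Object of class `ground_truth`.
#' @export
ground_truth <- function(planted_V, planted_effect, noise_sd = 1,
                         smooth = 0) {
  planted_V <- as.matrix(planted_V)
  if (ncol(planted_V) != length(planted_effect))
    stop2("one effect size per planted component is required")
  if (is.null(names(planted_effect)))
    stop2("`planted_effect` must be named by design column")
  if (!all(is.finite(planted_effect))) stop2("effect sizes must be finite")
  nrms <- sqrt(colSums(planted_V^2))
  if (any(nrms == 0)) stop2("planted patterns must be nonzero")
  planted_V <- sweep(planted_V, 2L, nrms, "/")
  if (noise_sd < 0) stop2("noise_sd must be non-negative")
  structure(list(planted_V = planted_V, planted_effect = planted_effect,
                 noise_sd = noise_sd, smooth = smooth),
            class = "ground_truth")
}

#' Generate a mixed cross-sectional/longitudinal synthetic cohort
#'
#' Emulates a developmental cohort with repeated visits: per-subject
#' baseline age uniform over `age_range`, 1-4 visits drawn from
#' `visits_distribution`, inter-visit gaps of about 1.5 years with
#' jitter, and per-scan confounds (sex, full-scale IQ, mean framewise
#' displacement) drawn from group-specific distributions; motion is
#' shifted upward in the case group, as is typical of clinical
#' developmental samples. Clinical subscale scores (integer 0-6) are
#' generated for the case group only, with a target prevalence of
#' subjects ever reaching a score of 3.
#'
#' @param n_per_group Integer vector of length 2: subjects in the case
#'   and control groups.
#' @param visits_distribution Probabilities of 1, 2, ... visits.
#' @param age_range Baseline age range in years.
#' @param seed RNG seed; `NULL` leaves the RNG state untouched.
#' @param group_labels Labels for the two groups (case first).
#' @param visit_gap Mean inter-visit gap in years.
#' @param iq_mean,iq_sd Per-group full-scale IQ distribution (case,
#'   control).
#' @param fd_mean,fd_sd Per-group mean-FD distribution in mm (case,
#'   control), truncated below at 0.01 mm.
#' @param subscale_prevalence Named numeric vector: for each subscale
#'   column to generate, the probability that a case subject ever scores
#'   >= 3.
#' @return Scan-level cohort data frame with columns `subject_id`,
#'   `scan_id`, `visit`, `age`, `sex`, `fsiq`, `mean_fd`, `group` and one
#'   column per subscale.
#' @export
generate_cohort <- function(n_per_group = c(105, 120),
                            visits_distribution = c(0.61, 0.22, 0.12, 0.05),
                            age_range = c(5, 30),
                            seed = NULL,
                            group_labels = c("case", "control"),
                            visit_gap = 1.5,
                            iq_mean = c(72, 110.7), iq_sd = c(13.3, 12.9),
                            fd_mean = c(0.18, 0.14), fd_sd = c(0.06, 0.06),
                            subscale_prevalence = c(score_positive = 0.65,
                                                    score_stress = 0.37)) {
  if (length(n_per_group) != 2L || any(n_per_group < 2))
    stop2("`n_per_group` must give two group sizes, each >= 2")
  if (any(visits_distribution < 0) || sum(visits_distribution) <= 0)
    stop2("`visits_distribution` must be non-negative with positive sum")
  if (length(age_range) != 2L || age_range[1] <= 0 ||
      age_range[2] <= age_range[1])
    stop2("`age_range` must be an increasing positive pair of ages")
  if (!is.null(seed)) set.seed(seed)
  visits_distribution <- visits_distribution / sum(visits_distribution)

  n_subj <- sum(n_per_group)
  group <- rep(group_labels, times = n_per_group)
  subj <- sprintf("S%03d", seq_len(n_subj))
  n_visits <- sample(seq_along(visits_distribution), n_subj, replace = TRUE,
                     prob = visits_distribution)
  base_age <- stats::runif(n_subj, age_range[1], age_range[2])
  sex <- sample(c("F", "M"), n_subj, replace = TRUE)
  gi <- ifelse(group == group_labels[1], 1L, 2L)
  fsiq <- round(stats::rnorm(n_subj, iq_mean[gi], iq_sd[gi]))

  rows <- lapply(seq_len(n_subj), function(i) {
    gaps <- pmax(stats::rnorm(n_visits[i] - 1L, visit_gap, 0.5), 0.25)
    ages <- base_age[i] + cumsum(c(0, gaps))
    data.frame(subject_id = subj[i],
               scan_id = sprintf("%s_v%d", subj[i], seq_len(n_visits[i])),
               visit = seq_len(n_visits[i]),
               age = ages,
               sex = sex[i],
               fsiq = fsiq[i],
               mean_fd = pmax(stats::rnorm(n_visits[i], fd_mean[gi[i]],
                                           fd_sd[gi[i]]), 0.01),
               group = group[i],
               stringsAsFactors = FALSE)
  })
  cohort <- do.call(rbind, rows)

  for (sub_nm in names(subscale_prevalence)) {
    prev <- subscale_prevalence[[sub_nm]]
    score <- rep(NA_integer_, nrow(cohort))
    for (i in which(group == group_labels[1])) {
      idx <- which(cohort$subject_id == subj[i])
      nv <- length(idx)
      if (stats::runif(1) < prev) {
        s <- sample(0:6, nv, replace = TRUE)
        if (max(s) < 3) s[sample.int(nv, 1)] <- sample(3:6, 1)
      } else {
        s <- sample(0:2, nv, replace = TRUE)
      }
      score[idx] <- s
    }
    cohort[[sub_nm]] <- score
  }
  rownames(cohort) <- NULL
  cohort
}

# Unstandardized design columns used to plant effects; mirrors the
# encoding of build_design_matrix() before z-scoring.
raw_design_columns <- function(cohort, positive_level = NULL) {
  lev <- sort(unique(as.character(cohort$group)))
  if (length(lev) != 2L) stop2("cohort must have exactly two groups")
  positive_level <- positive_level %||% lev[1]
  grp <- ifelse(as.character(cohort$group) == positive_level, 1, -1)
  ages <- decompose_age(cohort)
  cbind(group = grp, age_cs = ages$age_cs, age_long = ages$age_long,
        group_x_age_cs = grp * ages$age_cs,
        group_x_age_long = grp * ages$age_long)
}

#' Generate a scans x voxels feature matrix with planted latent effects
#'
#' Builds `X = sum_k effect_k * z(y_k) %*% t(V_k) + noise`, where `y_k`
#' is the named design column derived from the cohort, `z()` is the
#' population z-score, and `V_k` the planted unit-norm voxel pattern.
#' With zero noise and a single planted component, PLS-C recovers the
#' pattern exactly (up to sign).
#'
#' @param cohort Cohort table from [generate_cohort()].
#' @param truth A [ground_truth()]; `rownames` of its `planted_V` are
#'   ignored, its `planted_effect` names select the design columns.
#' @param seed RNG seed for the noise; `NULL` leaves the RNG state
#'   untouched.
#' @param positive_level Group level coded +1 (defaults to the first
#'   sorted level, matching [build_design_matrix()]).
#' @return Matrix scans x voxels with rownames `scan_id`.
#' @export
generate_feature_data <- function(cohort, truth, seed = NULL,
                                  positive_level = NULL) {
  stopifnot(inherits(truth, "ground_truth"))
  if (!is.null(seed)) set.seed(seed)
  raw <- raw_design_columns(cohort, positive_level)
  sds <- col_sd_pop(raw)
  eff_names <- names(truth$planted_effect)
  unknown <- setdiff(eff_names, colnames(raw))
  if (length(unknown))
    stop2("unknown design column(s) in planted_effect: ",
          paste(unknown, collapse = ", "))
  degen <- eff_names[sds[eff_names] < 1e-12]
  if (length(degen))
    stop2("planted effect on zero-variance (dropped) design column(s): ",
          paste(degen, collapse = ", "))
  n <- nrow(cohort)
  p <- nrow(truth$planted_V)
  X <- matrix(0, n, p)
  for (j in seq_along(eff_names)) {
    z <- (raw[, eff_names[j]] - mean(raw[, eff_names[j]])) / sds[eff_names[j]]
    X <- X + truth$planted_effect[j] * tcrossprod(z, truth$planted_V[, j])
  }
  if (truth$noise_sd > 0) {
    noise <- matrix(stats::rnorm(n * p, sd = truth$noise_sd), n, p)
    if (truth$smooth > 0) {
      w <- 2L * as.integer(truth$smooth) + 1L
      kern <- rep(1 / w, w)
      noise <- t(apply(noise, 1L, function(row)
        stats::filter(c(rev(row[seq_len(truth$smooth)]), row,
                        rev(row[p - seq_len(truth$smooth) + 1L])),
                      kern)[truth$smooth + seq_len(p)]))
      noise <- noise * sqrt(w)   # restore per-voxel variance
    }
    X <- X + noise
  }
  rownames(X) <- cohort$scan_id
  X
}

#' Generate toy 4D volumes with planted inter-region correlations
#'
#' Builds a small 4D time-series image whose voxel courses within each of
#' `n_regions` axial slabs share a latent region signal; the latent
#' signals have the requested correlation matrix in expectation. Also
#' returns a probabilistic atlas whose probabilities peak inside the true
#' regions, and a rigid-body motion trace with translation spikes at the
#' requested frames (useful for exercising censoring).
#'
#' @param n_regions Number of regions (slabs along the x axis).
#' @param planted_correlation Valid correlation matrix (unit diagonal,
#'   positive semidefinite) of the latent region signals.
#' @param T Number of frames.
#' @param grid Integer vector of length 3, the volume dimensions.
#' @param tr Repetition time (seconds).
#' @param noise_sd SD of voxelwise noise added to the region signal
#'   inside regions. Out-of-region voxels always carry unit-SD noise.
#' @param spike_frames Frames at which a 1 mm translation increment is
#'   injected (framewise displacement spikes exactly at these frames).
#' @param seed RNG seed; `NULL` leaves the RNG state untouched.
#' @return List with `ts` ([timeseries_image()]), `atlas`
#'   ([probabilistic_atlas()] with labels `"R1"`, ...), `motion`
#'   (frames x 6 matrix), `regions` (list of true logical masks) and
#'   `signals` (frames x regions latent courses).
#' @export
generate_toy_timeseries <- function(n_regions = 3,
                                    planted_correlation = diag(n_regions),
                                    T = 200, grid = c(12, 12, 12),
                                    tr = 2.4, noise_sd = 0,
                                    spike_frames = integer(0),
                                    seed = NULL) {
  planted_correlation <- as.matrix(planted_correlation)
  if (nrow(planted_correlation) != n_regions ||
      ncol(planted_correlation) != n_regions)
    stop2("`planted_correlation` must be ", n_regions, " x ", n_regions)
  if (any(abs(diag(planted_correlation) - 1) > 1e-12))
    stop2("`planted_correlation` must have unit diagonal")
  ev <- eigen(planted_correlation, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10)
    stop2("`planted_correlation` is not positive semidefinite")
  if (!is.null(seed)) set.seed(seed)

  # latent signals with the planted correlation (in expectation)
  ev <- eigen(planted_correlation, symmetric = TRUE)
  rt <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), n_regions) %*%
    t(ev$vectors)
  signals <- matrix(stats::rnorm(T * n_regions), T, n_regions) %*% rt

  # regions: disjoint slabs along x, with a one-voxel unassigned gap
  bounds <- round(seq(0, grid[1], length.out = n_regions + 1L))
  regions <- lapply(seq_len(n_regions), function(r) {
    m <- array(FALSE, dim = grid)
    lo <- bounds[r] + 1L
    hi <- max(lo, bounds[r + 1L] - 1L)   # gap keeps slabs separated
    m[lo:hi, , ] <- TRUE
    m
  })

  data <- array(stats::rnorm(prod(grid) * T), dim = c(grid, T))
  for (r in seq_len(n_regions)) {
    idx <- which(regions[[r]])
    flat <- matrix(data, nrow = prod(grid), ncol = T)
    course <- matrix(rep(signals[, r], each = length(idx)),
                     nrow = length(idx))
    if (noise_sd > 0)
      course <- course + matrix(stats::rnorm(length(idx) * T,
                                             sd = noise_sd),
                                nrow = length(idx))
    flat[idx, ] <- course
    data <- array(flat, dim = c(grid, T))
  }

  prob <- array(0.02, dim = c(grid, n_regions))
  for (r in seq_len(n_regions)) {
    slab <- array(0.02, dim = grid)
    slab[regions[[r]]] <- 0.9
    prob[, , , r] <- slab
  }
  atlas <- probabilistic_atlas(prob, labels = sprintf("R%d", seq_len(n_regions)))

  motion <- matrix(stats::rnorm(T * 6, sd = 0.005), T, 6)
  motion[, 4:6] <- motion[, 4:6] / 50     # keep rotational FD tiny
  if (length(spike_frames)) {
    if (any(spike_frames < 2L | spike_frames > T))
      stop2("spike frames must lie in 2..T")
    incr <- rep(0, T)
    incr[spike_frames] <- 1               # 1 mm jump entering each spike
    motion[, 1] <- motion[, 1] + cumsum(incr)
  }

  list(ts = timeseries_image(data, tr = tr),
       atlas = atlas, motion = motion, regions = regions,
       signals = signals)
}
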