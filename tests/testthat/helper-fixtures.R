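# Small fixtures built in code, shared across test files.

# 4-scan toy cohort: 2 subjects per group, 2 visits each, hand-checkable.
toy_cohort_4scan <- function() {
  data.frame(
    subject_id = rep(c("A1", "B1"), each = 2),
    scan_id = c("A1_v1", "A1_v2", "B1_v1", "B1_v2"),
    visit = c(1, 2, 1, 2),
    age = c(10, 12, 20, 22),
    sex = c("F", "F", "M", "M"),
    fsiq = c(100, 100, 90, 90),
    mean_fd = c(0.1, 0.2, 0.15, 0.25),
    group = rep(c("case", "control"), each = 2),
    stringsAsFactors = FALSE)
}

# Mixed-visit toy cohort for block-resampling tests: visit counts 1..3.
toy_cohort_mixed <- function(seed = 1) {
  set.seed(seed)
  n_visits <- c(1, 2, 3, 1, 2, 3, 2, 1)
  subj <- sprintf("S%02d", seq_along(n_visits))
  do.call(rbind, lapply(seq_along(subj), function(i) {
    ages <- 8 + i + seq_len(n_visits[i]) * 1.5
    data.frame(subject_id = subj[i],
               scan_id = sprintf("%s_v%d", subj[i], seq_len(n_visits[i])),
               visit = seq_len(n_visits[i]),
               age = ages,
               sex = c("F", "M")[1 + i %% 2],
               fsiq = 90 + 3 * i,
               mean_fd = 0.1 + 0.01 * i,
               group = if (i %% 2 == 0) "case" else "control",
               stringsAsFactors = FALSE)
  }))
}

# Random probabilistic atlas on a tiny grid; prob values drawn from a
# coarse lattice so exact ties at the maximum occur regularly.
random_tie_atlas <- function(grid = c(5, 4, 3), n_labels = 3, seed = 1) {
  set.seed(seed)
  vals <- seq(0, 1, by = 0.1)
  prob <- array(sample(vals, prod(grid) * n_labels, replace = TRUE),
                dim = c(grid, n_labels))
  probabilistic_atlas(prob, labels = sample(LETTERS[seq_len(n_labels)]))
}

# Brute-force oracle for exclusive mask construction: explicit per-voxel
# loop over labels, argmax with lexicographic tie-break, strict threshold.
oracle_exclusive_masks <- function(atlas, threshold) {
  d <- dim(atlas$prob)[1:3]
  labs <- atlas$labels
  out <- lapply(labs, function(l) array(FALSE, dim = d))
  names(out) <- labs
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    pv <- atlas$prob[i, j, k, ]
    mx <- max(pv)
    if (mx > threshold) {
      winners <- labs[pv == mx]
      win <- sort(winners)[1]
      out[[win]][i, j, k] <- TRUE
    }
  }
  out
}

# Population z-score used by independent hand computations in tests.
zpop <- function(x) (x - mean(x)) / sqrt(mean((x - mean(x))^2))
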