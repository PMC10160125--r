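# Subject-block bookkeeping --------------------------------------------

# Rows of each subject, in original row order. Returns a named list of
# integer index vectors; order of subjects follows first appearance.
subject_blocks <- function(subject_id) {
  subject_id <- as.character(subject_id)
  split(seq_along(subject_id), factor(subject_id, levels = unique(subject_id)))
}

# One subject-level permutation of the block-to-design correspondence,
# stratified by scans-per-subject so every subject receives a design block
# of exactly its own length. Returns a row permutation `perm` such that
# Y[perm, ] is the permuted design; strata with a single subject are fixed
# points.
permute_blocks_stratified <- function(blocks) {
  sizes <- lengths(blocks)
  target <- seq_along(blocks)
  for (s in unique(sizes)) {
    members <- which(sizes == s)
    if (length(members) > 1L)
      target[members] <- sample(members)
  }
  # subject i's rows take the design rows of subject target[i], in order
  perm <- integer(sum(sizes))
  for (i in seq_along(blocks))
    perm[blocks[[i]]] <- blocks[[target[i]]]
  perm
}

resolve_blocks <- function(Y, subjects) {
  if (is.null(subjects) && inherits(Y, "design_matrix"))
    subjects <- Y$subject_id
  if (is.null(subjects))
    stop2("per-row subject identifiers are required (pass `subjects` or a design_matrix)")
  subjects
}

#' Permutation test of PLS-C latent components
#'
#' Builds a null distribution for the singular values by permuting the
#' correspondence between brain data and design variables, and computes a
#' per-component p-value with the add-one estimator
#' `p_k = (1 + #\{null S_k >= observed S_k\}) / (1 + n_perm)`.
#'
#' The default scheme respects the longitudinal structure: entire subject
#' blocks (all scans of one subject, in order) are exchanged among
#' subjects with the same number of scans, so no scan is ever separated
#' from its subject and every permuted design block has the right length.
#' A naive scan-level permutation is available for comparison but ignores
#' within-subject dependence.
#'
#' @param X Brain matrix (scans x voxels) or `brain_data_matrix`.
#' @param Y Design matrix (scans x columns) or `design_matrix`.
#' @param subjects Per-row subject identifiers (taken from `Y` when it is
#'   a `design_matrix`).
#' @param n_perm Number of permutations (the conventional choice is 1000).
#' @param seed RNG seed for reproducibility; `NULL` leaves the RNG state
#'   untouched.
#' @param scheme `"subject"` (block exchange, default) or `"scan"`.
#' @param return_perms Keep the row permutation used by every replicate
#'   (diagnostics; allows auditing that subject blocks stay intact).
#' @return Object of class `permutation_result`: `null_S` (n_perm x
#'   components), `p`, `observed_S`, `n_perm`, `seed`, `scheme`,
#'   `fixed_subjects` (subjects in singleton strata that can never move),
#'   and `perms` (list of row permutations) when requested.
#' @export
permutation_test <- function(X, Y, subjects = NULL, n_perm = 1000,
                             seed = NULL, scheme = c("subject", "scan"),
                             return_perms = FALSE) {
  scheme <- match.arg(scheme)
  subjects <- resolve_blocks(Y, subjects)
  if (inherits(Y, "design_matrix")) Y <- Y$Y
  if (inherits(X, "brain_data_matrix")) X <- X$X
  if (nrow(Y) != nrow(X) || length(subjects) != nrow(X))
    stop2("X, Y and subjects must have matching rows")
  if (n_perm < 1) stop2("n_perm must be >= 1")
  if (!is.null(seed)) set.seed(seed)

  blocks <- subject_blocks(subjects)
  sizes <- lengths(blocks)
  singleton_strata <- names(blocks)[sizes %in%
                                      names(which(table(sizes) == 1L))]
  obs <- svd(crossprod(Y, X), nu = 0, nv = 0)$d
  k <- length(obs)
  null_S <- matrix(NA_real_, nrow = n_perm, ncol = k)
  perms <- if (return_perms) vector("list", n_perm) else NULL
  for (b in seq_len(n_perm)) {
    perm <- if (scheme == "subject") permute_blocks_stratified(blocks)
            else sample(nrow(Y))
    if (return_perms) perms[[b]] <- perm
    null_S[b, ] <- svd(crossprod(Y[perm, , drop = FALSE], X),
                       nu = 0, nv = 0)$d
  }
  p <- vapply(seq_len(k), function(j)
    (1 + sum(null_S[, j] >= obs[j])) / (1 + n_perm), numeric(1))
  structure(list(null_S = null_S, p = p, observed_S = obs,
                 n_perm = n_perm, seed = seed, scheme = scheme,
                 fixed_subjects = singleton_strata, perms = perms),
            class = "permutation_result")
}

#' Bootstrap stability of PLS-C saliences (bootstrap ratios)
#'
#' Resamples *subjects* (not scans) with replacement: each replicate
#' draws subjects until the original subject count is reached, takes all
#' scans of every drawn subject (subjects may enter more than once),
#' recomputes the SVD of the resampled cross-covariance, and aligns each
#' replicate component's sign to the original solution (flip if the dot
#' product of the replicate brain salience with the original is
#' negative). The bootstrap ratio of a voxel on component k is the mean
#' of its salience over replicates divided by the population SD over
#' replicates; |BSR| > 3 corresponds approximately to a 99% confidence
#' interval excluding zero.
#'
#' Replicates in which a design column collapses to zero variance are
#' redrawn (up to `max_redraw` attempts in total). Voxels whose replicate
#' SD is numerically zero are flagged degenerate rather than divided.
#'
#' @param X Brain matrix (scans x voxels) or `brain_data_matrix`.
#' @param Y Design matrix or `design_matrix`.
#' @param subjects Per-row subject identifiers (taken from `Y` when it is
#'   a `design_matrix`).
#' @param n_boot Number of bootstrap replicates (the conventional choice
#'   is 500).
#' @param seed RNG seed; `NULL` leaves the RNG state untouched.
#' @param max_redraw Cap on total redraws of degenerate replicates.
#' @param return_rows Keep the resampled row indices of every replicate
#'   (diagnostics; allows auditing that subject blocks stay intact).
#' @return Object of class `bootstrap_result`: `bsr` (voxels x
#'   components, `NA` where degenerate), `v_mean`, `v_sd`, `u_mean`,
#'   `u_sd` (design-salience SDs), `degenerate` (logical voxels x
#'   components), `n_boot`, `seed`, `n_redraws`, and `rows` (list of row
#'   index vectors) when requested.
#' @export
bootstrap_saliences <- function(X, Y, subjects = NULL, n_boot = 500,
                                seed = NULL, max_redraw = 100,
                                return_rows = FALSE) {
  subjects <- resolve_blocks(Y, subjects)
  if (inherits(Y, "design_matrix")) Y <- Y$Y
  if (inherits(X, "brain_data_matrix")) X <- X$X
  if (nrow(Y) != nrow(X) || length(subjects) != nrow(X))
    stop2("X, Y and subjects must have matching rows")
  if (n_boot < 2) stop2("n_boot must be >= 2")
  if (!is.null(seed)) set.seed(seed)

  blocks <- subject_blocks(subjects)
  n_subj <- length(blocks)
  orig <- svd_decompose(crossprod(Y, X))
  k <- length(orig$S)
  p <- ncol(X)

  v_sum <- matrix(0, p, k)
  v_sumsq <- matrix(0, p, k)
  u_sum <- matrix(0, ncol(Y), k)
  u_sumsq <- matrix(0, ncol(Y), k)
  redraws <- 0L
  b <- 0L
  kept_rows <- if (return_rows) vector("list", n_boot) else NULL
  while (b < n_boot) {
    rows <- unlist(blocks[sample.int(n_subj, n_subj, replace = TRUE)],
                   use.names = FALSE)
    Yb <- Y[rows, , drop = FALSE]
    if (any(col_sd_pop(Yb) < 1e-12)) {
      redraws <- redraws + 1L
      if (redraws > max_redraw)
        stop2("exceeded max_redraw (", max_redraw,
              ") replicates with a zero-variance design column")
      next
    }
    dec <- svd(crossprod(Yb, X[rows, , drop = FALSE]), nu = k, nv = k)
    flip <- ifelse(colSums(dec$v * orig$V) < 0, -1, 1)
    Vb <- sweep(dec$v, 2L, flip, "*")
    Ub <- sweep(dec$u, 2L, flip, "*")
    v_sum <- v_sum + Vb
    v_sumsq <- v_sumsq + Vb^2
    u_sum <- u_sum + Ub
    u_sumsq <- u_sumsq + Ub^2
    b <- b + 1L
    if (return_rows) kept_rows[[b]] <- rows
  }
  v_mean <- v_sum / n_boot
  v_sd <- sqrt(pmax(v_sumsq / n_boot - v_mean^2, 0))
  u_mean <- u_sum / n_boot
  u_sd <- sqrt(pmax(u_sumsq / n_boot - u_mean^2, 0))
  degenerate <- v_sd < 1e-12
  bsr <- v_mean / ifelse(degenerate, NA_real_, v_sd)
  dimnames(bsr) <- list(colnames(X), NULL)
  dimnames(u_mean) <- dimnames(u_sd) <- list(colnames(Y), NULL)
  structure(list(bsr = bsr, v_mean = v_mean, v_sd = v_sd,
                 u_mean = u_mean, u_sd = u_sd, degenerate = degenerate,
                 n_boot = n_boot, seed = seed, n_redraws = redraws,
                 rows = kept_rows),
            class = "bootstrap_result")
}

#' Threshold bootstrap-ratio maps
#'
#' Retains, per component, the voxels whose bootstrap ratio strictly
#' exceeds `cutoff` in absolute value — with cutoff 3 this approximates a
#' 99% confidence interval not crossing zero — plus any degenerate voxels
#' (replicate SD zero) whose mean salience is nonzero, which are
#' perfectly stable by construction. The signed value is preserved so
#' positive and negative saliences remain distinguishable.
#'
#' @param boot A `bootstrap_result`.
#' @param cutoff Positive BSR threshold (default 3).
#' @return List with `retained` (logical, voxels x components) and
#'   `map` (numeric, the signed BSR where retained, 0 elsewhere;
#'   degenerate retained voxels carry `Inf` times the sign of their mean
#'   salience) and `cutoff`.
#' @export
threshold_bsr <- function(boot, cutoff = 3) {
  stopifnot(inherits(boot, "bootstrap_result"))
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff < 0)
    stop2("`cutoff` must be a non-negative scalar")
  stable_degen <- boot$degenerate & boot$v_mean != 0
  retained <- (!is.na(boot$bsr) & abs(boot$bsr) > cutoff) | stable_degen
  map <- ifelse(retained, boot$bsr, 0)
  map[stable_degen] <- Inf * sign(boot$v_mean[stable_degen])
  list(retained = retained, map = map, cutoff = cutoff)
}
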