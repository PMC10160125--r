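#' Framewise displacement (Power formula)
#'
#' Summarizes head motion per frame as the sum of absolute backward
#' differences of the three translations (mm) plus the three rotations
#' (radians) converted to arc length on a sphere of radius `head_radius`:
#' \deqn{FD_t = |\Delta d_x| + |\Delta d_y| + |\Delta d_z| +
#'   r (|\Delta \alpha| + |\Delta \beta| + |\Delta \gamma|)}
#' The first frame has no predecessor and is assigned FD = 0.
#'
#' @param motion Numeric matrix with one row per frame and 6 columns:
#'   three translations in mm, then three rotations in radians.
#' @param head_radius Sphere radius in mm used to convert rotations to
#'   displacements; 50 mm is the standard convention.
#' @return Numeric vector of per-frame displacements in mm.
#' @export
compute_fd_power <- function(motion, head_radius = 50) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6L)
    stop2("`motion` must have 6 columns (3 translations mm, 3 rotations rad)")
  if (!is.numeric(head_radius) || length(head_radius) != 1L ||
      head_radius <= 0)
    stop2("`head_radius` must be a positive scalar (mm)")
  d <- abs(diff(motion))
  fd <- c(0, rowSums(d[, 1:3, drop = FALSE]) +
            head_radius * rowSums(d[, 4:6, drop = FALSE]))
  fd
}

#' Read a 6-column rigid-body motion trace
#'
#' Accepts whitespace- or comma-delimited text with one row per frame and
#' six columns (translations in mm, rotations in radians).
#'
#' @param file Path to the motion parameter file.
#' @return Numeric matrix, frames x 6.
#' @export
read_motion_trace <- function(file) {
  first <- readLines(file, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  m <- as.matrix(utils::read.table(file, sep = sep, header = FALSE))
  if (ncol(m) != 6L) stop2("motion trace must have 6 columns")
  dimnames(m) <- NULL
  m
}

#' Censor high-motion frames
#'
#' Removes (scrubs) frames whose framewise displacement exceeds `cutoff`,
#' preserving the order of the surviving frames. If fewer than
#' `min_frames` frames survive, the scan is flagged for exclusion rather
#' than returned truncated.
#'
#' @param ts A [timeseries_image()].
#' @param fd Per-frame displacement in mm, length matching the series.
#' @param cutoff Censoring threshold in mm; frames with FD <= cutoff are
#'   kept.
#' @param min_frames Minimum number of surviving frames below which the
#'   scan is marked excluded.
#' @return A list with `ts` (the censored [timeseries_image()], or `NULL`
#'   when excluded), `kept` (indices of retained frames), `excluded`
#'   (logical scan-exclusion signal) and `mean_fd` (mean FD over the
#'   retained frames — the motion covariate used downstream).
#' @export
censor_frames <- function(ts, fd, cutoff = 0.5, min_frames = 100) {
  stopifnot(inherits(ts, "timeseries_image"))
  n_t <- dim(ts$data)[4]
  if (length(fd) != n_t)
    stop2("length of `fd` does not match the number of frames")
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0)
    stop2("`cutoff` must be a positive scalar (mm)")
  kept <- which(fd <= cutoff)
  if (length(kept) < min_frames) {
    return(list(ts = NULL, kept = kept, excluded = TRUE,
                mean_fd = if (length(kept)) mean(fd[kept]) else NA_real_))
  }
  out <- timeseries_image(ts$data[, , , kept, drop = FALSE], tr = ts$tr,
                          reference = ts$reference)
  list(ts = out, kept = kept, excluded = FALSE, mean_fd = mean(fd[kept]))
}

#' Seed-based whole-brain connectivity map
#'
#' Correlates every in-mask voxel's time course with a seed time course
#' (Pearson's r). Voxels with zero temporal variance cannot be correlated
#' and are flagged missing (`NA`); they should be dropped from the brain
#' mask before any group analysis.
#'
#' @param ts A [timeseries_image()].
#' @param seed_course Numeric vector of length `T`, typically from
#'   [extract_roi_mean_timecourse()]. Must have nonzero variance.
#' @param brain_mask Logical 3D array selecting the voxels to correlate;
#'   `NULL` means all voxels.
#' @param fisher_z If `TRUE`, apply the Fisher z-transform `atanh(r)` to
#'   the map. Off by default: maps are stored as raw correlations.
#' @param scan_id Optional identifier carried in the result.
#' @return An object of class `connectivity_map`: list with `values`
#'   (3D array, `NA` outside the mask and at zero-variance voxels),
#'   `mask`, `scan_id`, `fisher_z`.
#' @export
seed_connectivity_map <- function(ts, seed_course, brain_mask = NULL,
                                  fisher_z = FALSE, scan_id = NULL) {
  stopifnot(inherits(ts, "timeseries_image"))
  d <- dim(ts$data)
  n_t <- d[4]
  if (length(seed_course) != n_t)
    stop2("seed course length does not match the number of frames")
  if (n_t < 3L) stop2("need at least 3 frames to correlate")
  sc <- seed_course - mean(seed_course)
  s_ss <- sum(sc^2)
  if (s_ss == 0) stop2("zero-variance seed course")
  if (is.null(brain_mask)) brain_mask <- array(TRUE, dim = d[1:3])
  if (!identical(as.integer(dim(brain_mask)), as.integer(d[1:3])))
    stop2("grid error: brain mask dimensions do not match the time series")
  idx <- which(as.logical(brain_mask))
  m <- matrix(ts$data, nrow = prod(d[1:3]), ncol = n_t)[idx, , drop = FALSE]
  mc <- m - rowMeans(m)
  v_ss <- rowSums(mc^2)
  r <- as.numeric(mc %*% sc) / sqrt(v_ss * s_ss)
  r[v_ss == 0] <- NA_real_
  # numeric guard: |r| can exceed 1 by rounding
  r <- pmin(pmax(r, -1), 1)
  if (fisher_z) r <- atanh(r)
  vals <- array(NA_real_, dim = d[1:3])
  vals[idx] <- r
  structure(list(values = vals, mask = array(as.logical(brain_mask),
                                             dim = d[1:3]),
                 scan_id = scan_id, fisher_z = fisher_z),
            class = "connectivity_map")
}

#' Stack connectivity maps into a scans x voxels matrix
#'
#' Builds the brain-data matrix consumed by the design/PLS-C stages: one
#' row per scan, one column per voxel of the common brain mask. Voxels
#' that are missing (zero temporal variance) in any scan are removed from
#' the mask for all scans, and the surviving voxel linear indices are
#' returned as a sidecar so saliences can be mapped back into volumes.
#'
#' @param maps List of `connectivity_map` objects on a common grid.
#' @param scan_ids Row names; defaults to the maps' `scan_id`s.
#' @return List with `X` (scans x voxels matrix), `voxel_index` (linear
#'   indices into the 3D grid) and `grid_dim`.
#' @export
stack_connectivity_maps <- function(maps, scan_ids = NULL) {
  stopifnot(length(maps) >= 1L)
  d <- dim(maps[[1]]$values)
  for (m in maps)
    if (!identical(dim(m$values), d))
      stop2("grid error: connectivity maps have mismatched dimensions")
  base_idx <- which(maps[[1]]$mask)
  mat <- t(vapply(maps, function(m) m$values[base_idx],
                  numeric(length(base_idx))))
  ok <- colSums(is.na(mat)) == 0L
  mat <- mat[, ok, drop = FALSE]
  if (is.null(scan_ids))
    scan_ids <- vapply(seq_along(maps), function(i)
      maps[[i]]$scan_id %||% paste0("scan", i), character(1))
  rownames(mat) <- scan_ids
  list(X = mat, voxel_index = base_idx[ok], grid_dim = d)
}

#' Map a per-voxel vector back into a 3D volume
#'
#' Inverse of the flattening done by [stack_connectivity_maps()]: places
#' `values` at `voxel_index` in a volume of `grid_dim`, `NA` elsewhere.
#'
#' @param values Numeric vector, one value per retained voxel.
#' @param voxel_index Linear indices of the retained voxels.
#' @param grid_dim Integer vector of length 3.
#' @return 3D numeric array.
#' @export
unflatten_voxels <- function(values, voxel_index, grid_dim) {
  if (length(values) != length(voxel_index))
    stop2("`values` and `voxel_index` lengths differ")
  vol <- array(NA_real_, dim = grid_dim)
  vol[voxel_index] <- values
  vol
}
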