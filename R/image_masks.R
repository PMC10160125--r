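#' Probabilistic multi-label atlas
#'
#' Container for a probabilistic region-of-interest atlas: one probability
#' volume per label, all sharing a single voxel grid. Probabilities are
#' unitless values in \[0, 1\] giving, per voxel, the probability of
#' belonging to each labelled region (e.g. cytoarchitectonically defined
#' amygdala subdivisions).
#'
#' @param prob Either a 4D array (x, y, z, label) or a named list of 3D
#'   arrays, one per label, all with identical dimensions.
#' @param labels Character vector of region names, one per label volume.
#'   Defaults to the names of `prob` when it is a named list.
#' @param reference Optional reference image (e.g. an `RNifti` image the
#'   probabilities were read from) used to carry grid/affine metadata when
#'   masks are written back to NIfTI.
#' @return An object of class `probabilistic_atlas` with elements `prob`
#'   (4D array), `labels`, and `reference`.
#' @seealso [build_exclusive_masks()], [read_probabilistic_atlas()]
#' @export
probabilistic_atlas <- function(prob, labels = NULL, reference = NULL) {
  if (is.list(prob)) {
    labels <- labels %||% names(prob)
    dims <- lapply(prob, dim)
    if (length(unique(lapply(dims, as.integer))) != 1L)
      stop2("grid error: label volumes have mismatched dimensions")
    prob <- array(unlist(prob, use.names = FALSE),
                  dim = c(dims[[1]], length(prob)))
  }
  if (length(dim(prob)) != 4L)
    stop2("`prob` must be a 4D array or a list of 3D arrays")
  if (is.null(labels)) labels <- paste0("roi", seq_len(dim(prob)[4]))
  if (length(labels) != dim(prob)[4])
    stop2("number of labels must match the 4th dimension of `prob`")
  if (anyDuplicated(labels)) stop2("labels must be unique")
  if (anyNA(prob) || min(prob) < 0 || max(prob) > 1)
    stop2("probabilities must lie in [0, 1] with no missing values")
  structure(list(prob = prob, labels = as.character(labels),
                 reference = reference),
            class = "probabilistic_atlas")
}

#' Read a probabilistic atlas from NIfTI files
#'
#' @param files Character vector of NIfTI paths. Either one 4D file (one
#'   volume per label) or one 3D file per label.
#' @param labels Region names; defaults to the names of `files`, else to
#'   file basenames.
#' @return A [probabilistic_atlas()].
#' @export
read_probabilistic_atlas <- function(files, labels = NULL) {
  imgs <- lapply(files, RNifti::readNifti)
  if (length(imgs) == 1L && length(dim(imgs[[1]])) == 4L) {
    prob <- unclass(imgs[[1]])[, , , , drop = FALSE]
    labels <- labels %||% paste0("roi", seq_len(dim(prob)[4]))
  } else {
    labels <- labels %||% names(files) %||%
      sub("\\.nii(\\.gz)?$", "", basename(files))
    prob <- lapply(imgs, function(x) array(as.numeric(x), dim = dim(x)))
    names(prob) <- labels
  }
  probabilistic_atlas(prob, labels = labels, reference = imgs[[1]])
}

#' Build mutually exclusive ROI masks from a probabilistic atlas
#'
#' Each voxel is assigned to the label with the highest probability at that
#' voxel, provided that probability strictly exceeds `threshold`; all other
#' voxels remain unassigned. Assignments are therefore mutually exclusive
#' by construction. Exact ties at the maximum are resolved
#' deterministically in favour of the lexicographically first label name.
#'
#' @param atlas A [probabilistic_atlas()].
#' @param threshold Probability cutoff in \[0, 1); a voxel enters a mask
#'   only if its winning probability is strictly greater than this. The
#'   conventional cutoff for maximum-probability maps is 0.5.
#' @return An object of class `roi_mask_set`: a named list `masks` of
#'   logical 3D arrays (pairwise disjoint), plus `threshold`, `labels` and
#'   `reference`.
#' @examples
#' p <- array(0, c(2, 1, 1, 2))
#' p[1, 1, 1, ] <- c(0.7, 0.6)  # contested voxel -> label A
#' p[2, 1, 1, ] <- c(0.4, 0.2)  # below cutoff -> unassigned
#' ms <- build_exclusive_masks(probabilistic_atlas(p, c("A", "B")), 0.5)
#' which(ms$masks$A)
#' @export
build_exclusive_masks <- function(atlas, threshold = 0.5) {
  stopifnot(inherits(atlas, "probabilistic_atlas"))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold < 0 || threshold >= 1)
    stop2("`threshold` must be a single probability in [0, 1)")
  d <- dim(atlas$prob)
  nvox <- prod(d[1:3])
  ord <- order(atlas$labels)                # lexicographic tie-break
  pm <- matrix(atlas$prob, nrow = nvox)[, ord, drop = FALSE]
  win <- max.col(pm, ties.method = "first") # first = alphabetically first
  pmax_v <- pm[cbind(seq_len(nvox), win)]
  assigned <- pmax_v > threshold
  masks <- lapply(seq_along(ord), function(j) {
    array(assigned & win == j, dim = d[1:3])
  })
  names(masks) <- atlas$labels[ord]
  masks <- masks[atlas$labels]              # restore user label order
  empty <- vapply(masks, function(m) !any(m), logical(1))
  if (any(empty))
    warning("empty mask(s) for label(s): ",
            paste(names(masks)[empty], collapse = ", "), call. = FALSE)
  structure(list(masks = masks, threshold = threshold,
                 labels = atlas$labels, reference = atlas$reference),
            class = "roi_mask_set")
}

#' Write an ROI mask set to NIfTI files
#'
#' Masks are written as 0/1 integer volumes, one file per label, so a
#' write/read round-trip reproduces the mask set exactly.
#'
#' @param mask_set An `roi_mask_set` from [build_exclusive_masks()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_mask_set <- function(mask_set, dir) {
  stopifnot(inherits(mask_set, "roi_mask_set"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(names(mask_set$masks), function(lab) {
    vol <- array(as.integer(mask_set$masks[[lab]]),
                 dim = dim(mask_set$masks[[lab]]))
    img <- if (!is.null(mask_set$reference))
      RNifti::asNifti(vol, reference = mask_set$reference) else vol
    path <- file.path(dir, paste0(lab, ".nii.gz"))
    RNifti::writeNifti(img, path, datatype = "uint8")
    path
  }, character(1))
  invisible(paths)
}

#' Read an ROI mask set from NIfTI files
#'
#' @param files Named character vector of 0/1 NIfTI mask paths; names are
#'   the labels (defaults to file basenames).
#' @param threshold Probability cutoff recorded alongside the masks (for
#'   provenance only; the files already encode the assignment).
#' @return An `roi_mask_set`.
#' @export
read_mask_set <- function(files, threshold = NA_real_) {
  labels <- names(files) %||% sub("\\.nii(\\.gz)?$", "", basename(files))
  imgs <- lapply(files, RNifti::readNifti)
  masks <- lapply(imgs, function(x) array(as.numeric(x) != 0, dim = dim(x)))
  names(masks) <- labels
  structure(list(masks = masks, threshold = threshold, labels = labels,
                 reference = imgs[[1]]),
            class = "roi_mask_set")
}

#' 4D time-series image
#'
#' @param data 4D numeric array (x, y, z, time) of signal values; at least
#'   3 frames, all values finite.
#' @param tr Repetition time in seconds (time between frames).
#' @param reference Optional reference NIfTI image for grid metadata.
#' @return An object of class `timeseries_image`.
#' @export
timeseries_image <- function(data, tr, reference = NULL) {
  if (length(dim(data)) != 4L) stop2("`data` must be a 4D array")
  if (dim(data)[4] < 3L) stop2("time series must have at least 3 frames")
  if (!all(is.finite(data))) stop2("time series contains non-finite values")
  if (!is.numeric(tr) || length(tr) != 1L || tr <= 0)
    stop2("`tr` must be a positive scalar (seconds)")
  structure(list(data = data, tr = tr, reference = reference),
            class = "timeseries_image")
}

#' Read a 4D NIfTI time series
#'
#' @param file Path to a 4D NIfTI file.
#' @param tr Repetition time in seconds; if `NULL`, taken from the NIfTI
#'   header (`pixdim[4]`).
#' @return A [timeseries_image()].
#' @export
read_timeseries_image <- function(file, tr = NULL) {
  img <- RNifti::readNifti(file)
  if (is.null(tr)) tr <- RNifti::pixdim(img)[4]
  timeseries_image(array(as.numeric(img), dim = dim(img)), tr = tr,
                   reference = img)
}

#' Mean time course within an ROI mask
#'
#' Returns, for each frame, the arithmetic mean of the signal over the
#' voxels of `mask` — the seed time course used for seed-based
#' connectivity.
#'
#' @param ts A [timeseries_image()].
#' @param mask Logical 3D array on the same grid as `ts`.
#' @return Numeric vector of length `T` (frames).
#' @export
extract_roi_mean_timecourse <- function(ts, mask) {
  stopifnot(inherits(ts, "timeseries_image"))
  d <- dim(ts$data)
  if (!identical(as.integer(dim(mask)), as.integer(d[1:3])))
    stop2("grid error: mask dimensions do not match the time series")
  idx <- which(as.logical(mask))
  if (length(idx) == 0L) stop2("empty mask")
  m <- matrix(ts$data, nrow = prod(d[1:3]), ncol = d[4])
  colMeans(m[idx, , drop = FALSE])
}
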