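#' Validate a scan-level cohort table
#'
#' The cohort table has one row per scan and ties repeated scans to
#' subjects. Required columns: `subject_id`, `scan_id`, `age` (years).
#' Typical additional columns are `sex`, `fsiq`, `mean_fd` (mm), a group
#' column, and integer clinical subscale scores per visit.
#'
#' @param cohort Data frame, one row per scan.
#' @return The cohort, invisibly, with rows ordered by subject then age.
#' @export
validate_cohort <- function(cohort) {
  req <- c("subject_id", "scan_id", "age")
  miss <- setdiff(req, names(cohort))
  if (length(miss))
    stop2("cohort table is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(cohort$scan_id)) stop2("duplicated scan_id values")
  if (any(!is.finite(cohort$age)) || any(cohort$age <= 0))
    stop2("ages must be strictly positive and finite")
  invisible(cohort[order(cohort$subject_id, cohort$age), , drop = FALSE])
}

#' Assign subjects to a clinical subgroup from repeated subscale scores
#'
#' A subject is labelled positive if their subscale score reaches `cutoff`
#' at *any* visit ("ever" aggregation): the label is constant across all
#' of the subject's scans and invariant to visit order. Subjects with no
#' non-missing score at any visit are flagged unassessed and should be
#' excluded from the contrast.
#'
#' @param cohort Scan-level cohort table (see [validate_cohort()]).
#' @param subscale Name of the integer score column to aggregate.
#' @param cutoff Score threshold; positive means `max score >= cutoff`.
#' @return Data frame with one row per subject: `subject_id`, `positive`
#'   (logical, `NA` when unassessed) and `assessed`.
#' @export
assign_subgroup <- function(cohort, subscale, cutoff = 3) {
  if (!subscale %in% names(cohort))
    stop2("subscale column '", subscale, "' not found in cohort")
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff < 0 ||
      cutoff != round(cutoff))
    stop2("`cutoff` must be a single non-negative integer")
  sc <- split(cohort[[subscale]], cohort$subject_id)
  assessed <- vapply(sc, function(x) any(!is.na(x)), logical(1))
  pos <- vapply(sc, function(x) {
    if (all(is.na(x))) NA else max(x, na.rm = TRUE) >= cutoff
  }, logical(1))
  data.frame(subject_id = names(sc), positive = pos, assessed = assessed,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Decompose age into cross-sectional and longitudinal components
#'
#' Standard between/within decomposition for repeated-measures cohorts:
#' the cross-sectional (between-subject) component of a scan's age is the
#' mean age of that subject across their visits; the longitudinal
#' (within-subject) component is the deviation from that mean. The two
#' components sum back to age exactly, and the longitudinal component
#' sums to zero within every subject.
#'
#' @param cohort Scan-level cohort table.
#' @return Data frame aligned with `cohort` rows: `scan_id`, `age_cs`,
#'   `age_long` (both in years).
#' @export
decompose_age <- function(cohort) {
  mu <- stats::ave(cohort$age, cohort$subject_id, FUN = mean)
  data.frame(scan_id = cohort$scan_id, age_cs = mu,
             age_long = cohort$age - mu,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Build the longitudinal design matrix Y
#'
#' Encodes, per scan: group membership (+1/-1), cross-sectional age,
#' longitudinal age, and the two group x age interactions. Interaction
#' columns are formed from the *unstandardized* components; when
#' `standardize = TRUE` every column is then z-scored with the population
#' (divide-by-n) convention, so each column has mean 0 and unit variance.
#' Columns with zero variance (e.g. the longitudinal age of a purely
#' cross-sectional cohort) are dropped with a warning.
#'
#' @param cohort Scan-level cohort table.
#' @param group Name of a two-level column of `cohort`, or a per-scan
#'   vector of two-level labels aligned with its rows.
#' @param positive_level The level coded +1; the other level is coded -1.
#'   Defaults to the first level in sorted order.
#' @param standardize Z-score all columns after forming interactions.
#' @param age_strategy Age-encoding strategy; `"subject_mean"` (the
#'   between/within decomposition of [decompose_age()]) is the default
#'   and currently only built-in. Alternatively a function
#'   `f(cohort) -> data.frame(scan_id, age_cs, age_long)` may be supplied.
#' @return Object of class `design_matrix`: list with `Y` (scans x
#'   columns, rownames = scan_id), `dropped` (names of zero-variance
#'   columns removed), `standardized`, `group_levels` (named +1/-1
#'   coding) and `subject_id` (per-row subject, for block resampling).
#' @export
build_design_matrix <- function(cohort, group, positive_level = NULL,
                                standardize = TRUE,
                                age_strategy = "subject_mean") {
  cohort <- as.data.frame(cohort)
  g <- if (is.character(group) && length(group) == 1L) {
    if (!group %in% names(cohort))
      stop2("group column '", group, "' not found in cohort")
    cohort[[group]]
  } else group
  g <- as.character(g)
  if (length(g) != nrow(cohort))
    stop2("group labels must align with cohort rows")
  lev <- sort(unique(g))
  if (length(lev) != 2L)
    stop2("grouping must have exactly two levels, got: ",
          paste(lev, collapse = ", "))
  positive_level <- positive_level %||% lev[1]
  if (!positive_level %in% lev)
    stop2("positive_level '", positive_level, "' is not a group level")
  if (!all(table(g) > 0L)) stop2("both groups must be nonempty")
  grp <- ifelse(g == positive_level, 1, -1)

  ages <- if (is.function(age_strategy)) age_strategy(cohort)
          else switch(age_strategy,
                      subject_mean = decompose_age(cohort),
                      stop2("unknown age strategy: ", age_strategy))
  Y <- cbind(group = grp,
             age_cs = ages$age_cs,
             age_long = ages$age_long,
             group_x_age_cs = grp * ages$age_cs,
             group_x_age_long = grp * ages$age_long)
  rownames(Y) <- cohort$scan_id

  sds <- col_sd_pop(Y)
  dropped <- colnames(Y)[sds < 1e-12]
  if (length(dropped)) {
    warning("dropping zero-variance design column(s): ",
            paste(dropped, collapse = ", "), call. = FALSE)
    Y <- Y[, sds >= 1e-12, drop = FALSE]
  }
  if (standardize) {
    nm <- dimnames(Y)
    Y <- zscore_pop(Y)
    attr(Y, "degenerate") <- NULL
    dimnames(Y) <- nm
  }
  coding <- c(1, -1)
  names(coding) <- c(positive_level, setdiff(lev, positive_level))
  structure(list(Y = Y, dropped = dropped, standardized = standardize,
                 group_levels = coding,
                 subject_id = as.character(cohort$subject_id)),
            class = "design_matrix")
}

#' Residualize confounds out of the brain matrix, voxelwise
#'
#' Fits, for every voxel (column of `X`), an ordinary least squares model
#' with intercept on the confound columns, and returns the residuals,
#' column-standardized with the population convention. Residuals are
#' orthogonal to every confound column and have zero mean by
#' construction. Two-level factor confounds (e.g. sex) are coded +1/-1;
#' numeric confounds are used as given (rescaling a confound does not
#' change OLS residuals).
#'
#' @param X Raw scans x voxels matrix (e.g. from
#'   [stack_connectivity_maps()]).
#' @param confounds Data frame or matrix of per-scan confounds (e.g. sex,
#'   full-scale IQ, mean framewise displacement), rows aligned with `X`.
#'   Missing values are an error: scans with missing confounds must be
#'   excluded upstream.
#' @param tol Residual population-SD below which a voxel is declared
#'   degenerate (its signal was entirely explained by the confounds);
#'   degenerate voxels are dropped from the returned matrix.
#' @return Object of class `brain_data_matrix`: list with `X` (residual,
#'   standardized), `kept` (column indices of `X` input retained),
#'   `dropped` (degenerate column indices), `confounds` (the numeric
#'   design actually used).
#' @export
regress_confounds <- function(X, confounds, tol = 1e-10) {
  X <- as.matrix(X)
  cf <- as.data.frame(confounds)
  if (nrow(cf) != nrow(X))
    stop2("confound rows must align with brain-matrix rows")
  if (anyNA(cf))
    stop2("missing confound values; exclude those scans upstream")
  num <- lapply(names(cf), function(nm) {
    v <- cf[[nm]]
    if (is.numeric(v)) return(as.numeric(v))
    lv <- sort(unique(as.character(v)))
    if (length(lv) != 2L)
      stop2("confound '", nm, "' is non-numeric with ", length(lv),
            " levels; only two-level factors are coded automatically")
    ifelse(as.character(v) == lv[1], 1, -1)
  })
  C <- cbind(intercept = 1, do.call(cbind, num))
  colnames(C) <- c("intercept", names(cf))
  qrC <- qr(C)
  if (qrC$rank < ncol(C)) {
    bad <- colnames(C)[qrC$pivot[(qrC$rank + 1L):ncol(C)]]
    stop2("confound matrix is rank deficient; collinear column(s): ",
          paste(bad, collapse = ", "))
  }
  resid <- X - C %*% qr.coef(qrC, X)
  sds <- col_sd_pop(resid)
  keep <- sds >= tol
  if (!all(keep))
    message(sum(!keep), " voxel(s) fully explained by confounds; dropped")
  Z <- zscore_pop(resid[, keep, drop = FALSE])
  attr(Z, "degenerate") <- NULL
  rownames(Z) <- rownames(X)
  colnames(Z) <- colnames(X)[keep]
  structure(list(X = Z, kept = which(keep), dropped = which(!keep),
                 confounds = C),
            class = "brain_data_matrix")
}
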