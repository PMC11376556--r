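#' Baseline-anchored log2 response curves
#'
#' Averages replicates per (feature, group, time) on the raw scale, then
#' expresses each time point as a log2 ratio against the group's baseline
#' (earliest) time point, so every complete curve starts at exactly 0.
#' For the count layer a pseudocount is added before the ratio; for the
#' intensity layer the convention is pseudocount 0, and features whose
#' baseline mean is 0 (or whose curve contains a non-finite value) are
#' marked incomplete and excluded from downstream scoring rather than
#' imputed.
#'
#' @param matrix A `tc_matrix` (may hold one group or both).
#' @param pseudocount Non-negative value added before the ratio. Default 1
#'   for `layer == "rna"`, 0 for `"protein"`.
#' @param aggregate Replicate aggregation on the raw scale: `"mean"`
#'   (default) or `"median"`.
#' @return An object of class `"normalized_profiles"`: list with `time`
#'   (the shared grid), `groups` (named list of feature-x-time log2-ratio
#'   matrices), `complete` (named list of logical vectors), `layer`, and
#'   `excluded` (data.frame reporting incomplete features and the reason).
#' @export
normalize_to_baseline <- function(matrix,
                                  pseudocount = if (matrix$layer == "rna") 1 else 0,
                                  aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  if (pseudocount < 0) stop("pseudocount must be non-negative")
  agg <- if (aggregate == "mean") rowMeans else
    function(m, na.rm) apply(m, 1L, stats::median, na.rm = na.rm)
  sh <- matrix$samples
  groups <- unique(sh$group)
  times <- sort(unique(sh$time))
  curves <- list(); complete <- list(); excl <- list()
  for (g in groups) {
    gsh <- sh[sh$group == g, , drop = FALSE]
    gtimes <- sort(unique(gsh$time))
    if (!identical(gtimes, times))
      stop("group '", g, "' is not sampled on the shared time grid")
    if (sum(gsh$time == times[1]) == 0L)
      stop("group '", g, "' has no baseline samples")
    means <- sapply(times, function(t) {
      cols <- gsh$sample_id[gsh$time == t]
      agg(matrix$values[, cols, drop = FALSE], na.rm = TRUE)
    })
    if (is.null(dim(means))) means <- matrix(means, nrow = 1,
                                             dimnames = list(rownames(matrix$values)))
    colnames(means) <- times
    base <- means[, 1L] + pseudocount
    r <- log2(sweep(means + pseudocount, 1L, base, "/"))
    ok <- apply(is.finite(r), 1L, all) & is.finite(base) & base > 0
    reason <- ifelse(!is.finite(base) | rowSums(!is.finite(means)) > 0,
                     "missing values", "zero baseline")
    if (any(!ok))
      excl[[g]] <- data.frame(feature_id = rownames(r)[!ok], group = g,
                              reason = reason[!ok], stringsAsFactors = FALSE)
    curves[[g]] <- r
    complete[[g]] <- stats::setNames(ok, rownames(r))
  }
  structure(list(time = times, groups = curves, complete = complete,
                 layer = matrix$layer,
                 excluded = if (length(excl)) do.call(rbind, c(excl, list(make.row.names = FALSE)))
                            else data.frame(feature_id = character(),
                                            group = character(),
                                            reason = character())),
            class = "normalized_profiles")
}

#' @export
print.normalized_profiles <- function(x, ...) {
  cat(sprintf("<normalized_profiles> layer=%s: %s; grid %s h\n", x$layer,
              paste(sprintf("%s (%d/%d complete)", names(x$groups),
                            vapply(x$complete, sum, integer(1)),
                            vapply(x$complete, length, integer(1))),
                    collapse = ", "),
              paste(x$time, collapse = ",")))
  invisible(x)
}

# Curves of the complete features for one group; `group = NULL` works when
# the object holds a single group.
profile_curves <- function(profiles, group = NULL, complete_only = TRUE) {
  if (is.null(group)) {
    if (length(profiles$groups) != 1L)
      stop("profiles hold several groups; name one")
    group <- names(profiles$groups)
  }
  if (!group %in% names(profiles$groups))
    stop("no group '", group, "' in profiles")
  m <- profiles$groups[[group]]
  if (complete_only) m[profiles$complete[[group]], , drop = FALSE] else m
}

#' Replicate reproducibility QC
#'
#' Pearson correlation between every pair of replicate samples harvested at
#' the same (group, time), computed across features on
#' `log2(value + pseudocount)` (set `log = FALSE` for the raw scale). A
#' sample with zero variance across features yields `NA` for its pairs.
#'
#' @param matrix A `tc_matrix`.
#' @param pseudocount Added before the log; default 1.
#' @param log Correlate on the log2 scale (default) or raw values.
#' @return A list with `pairs` (data.frame: group, time, sample_1, sample_2,
#'   r) and `summary` (per-(group, time) minimum r).
#' @export
replicate_correlation_qc <- function(matrix, pseudocount = 1, log = TRUE) {
  sh <- matrix$samples
  vals <- matrix$values
  if (log) vals <- log2(vals + pseudocount)
  out <- list()
  for (g in unique(sh$group)) for (t in sort(unique(sh$time[sh$group == g]))) {
    cols <- sh$sample_id[sh$group == g & sh$time == t]
    if (length(cols) < 2L) next
    cmb <- utils::combn(cols, 2L)
    r <- apply(cmb, 2L, function(p) {
      x <- vals[, p[1]]; y <- vals[, p[2]]
      keep <- is.finite(x) & is.finite(y)
      if (sum(keep) < 2L || stats::sd(x[keep]) == 0 || stats::sd(y[keep]) == 0)
        return(NA_real_)
      stats::cor(x[keep], y[keep])
    })
    out[[length(out) + 1L]] <- data.frame(
      group = g, time = t, sample_1 = cmb[1, ], sample_2 = cmb[2, ], r = r,
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) stop("no (group, time) with >= 2 replicates")
  pairs <- do.call(rbind, out)
  summary <- stats::aggregate(r ~ group + time, data = pairs,
                              FUN = function(v) suppressWarnings(min(v, na.rm = FALSE)),
                              na.action = stats::na.pass)
  names(summary)[names(summary) == "r"] <- "min_r"
  list(pairs = pairs, summary = summary[order(summary$group, summary$time), ])
}

#' Per-timepoint RNA–protein correlation
#'
#' For each non-baseline time point, the Pearson correlation across features
#' between the RNA and protein log2-ratio curves of one group (features
#' joined by id within the group's namespace). Times with fewer than 3
#' jointly complete features get `NA` with a warning.
#'
#' @param rna,protein `normalized_profiles` for the same group/namespace.
#' @param group Group to correlate; may be omitted when both objects hold a
#'   single group.
#' @return Data frame with `time`, `n_features`, `r`.
#' @export
rna_protein_correlation <- function(rna, protein, group = NULL) {
  cr <- profile_curves(rna, group)
  cp <- profile_curves(protein, group)
  if (!identical(rna$time, protein$time))
    stop("RNA and protein profiles are on different time grids")
  joint <- intersect(rownames(cr), rownames(cp))
  res <- lapply(seq_along(rna$time)[-1L], function(i) {
    if (length(joint) < 3L) {
      warning("fewer than 3 jointly complete features at t = ", rna$time[i])
      return(data.frame(time = rna$time[i], n_features = length(joint),
                        r = NA_real_))
    }
    data.frame(time = rna$time[i], n_features = length(joint),
               r = stats::cor(cr[joint, i], cp[joint, i]))
  })
  do.call(rbind, res)
}
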