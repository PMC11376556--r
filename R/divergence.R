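#' Shape term A: Pearson correlation between two response curves
#'
#' `A` compares the *shape* of the two groups' baseline-anchored log2
#' curves over the shared time grid (baseline point included). If either
#' curve has zero variance — a flat curve — Pearson is undefined; the
#' convention here is `A := 0`, so a flat curve against a responsive one
#' keeps the full area term in the score instead of being dropped.
#'
#' @param curve_a,curve_b Numeric vectors on the same grid of >= 3 points.
#' @return Pearson r in `[-1, 1]`, or 0 under the zero-variance convention.
#' @export
pearson_shape <- function(curve_a, curve_b) {
  if (length(curve_a) != length(curve_b))
    stop("curves are on different grids")
  if (length(curve_a) < 3L) stop("need at least 3 time points")
  if (stats::sd(curve_a) == 0 || stats::sd(curve_b) == 0) return(0)
  stats::cor(curve_a, curve_b)
}

#' Area term B: absolute area between two piecewise-linear curves
#'
#' Treats each curve as the piecewise-linear interpolant of its values over
#' the time grid and returns the exact geometric area between them, in
#' log2-ratio x hours. Where the difference changes sign inside a segment
#' the segment is split at the crossing, so e.g. curves `(-1, 1)` vs
#' `(0, 0)` over one hour give 0.5 (two triangles), not the 1.0 an
#' endpoint-|difference| trapezoid would report. That cruder convention is
#' available as `method = "endpoint"`.
#'
#' @param curve_a,curve_b Numeric vectors on the same grid.
#' @param times Strictly increasing time grid, hours.
#' @param method `"crossing"` (exact, default) or `"endpoint"`
#'   (trapezoid of absolute endpoint differences).
#' @return `B >= 0`; 0 iff the curves agree at every grid point.
#' @export
integrated_difference <- function(curve_a, curve_b, times,
                                  method = c("crossing", "endpoint")) {
  method <- match.arg(method)
  n <- length(times)
  if (length(curve_a) != n || length(curve_b) != n)
    stop("curves and times have different lengths")
  if (n < 2L) stop("need at least 2 time points")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  d <- curve_a - curve_b
  if (method == "endpoint")
    return(sum(diff(times) * (abs(d[-n]) + abs(d[-1L])) / 2))
  area <- 0
  for (i in seq_len(n - 1L)) {
    d0 <- d[i]; d1 <- d[i + 1L]; h <- times[i + 1L] - times[i]
    if (d0 * d1 >= 0) {
      area <- area + h * (abs(d0) + abs(d1)) / 2
    } else {
      # linear difference crosses zero at fraction f of the segment
      f <- d0 / (d0 - d1)
      area <- area + f * h * abs(d0) / 2 + (1 - f) * h * abs(d1) / 2
    }
  }
  area
}

#' Divergence score
#'
#' `score = (1 - |A|) * B`: large only when the two groups' curves are both
#' dissimilar in shape (|A| far from 1) and far apart in area (B large).
#' Perfectly correlated or anti-correlated shapes score 0 regardless of B.
#'
#' @param A Pearson shape term in `[-1, 1]`.
#' @param B Area term `>= 0`.
#' @return The score, `>= 0`.
#' @export
divergence_score <- function(A, B) {
  if (any(abs(A) > 1 + 1e-12)) stop("A must lie in [-1, 1]")
  if (any(B < 0)) stop("B must be non-negative")
  (1 - abs(A)) * B
}

#' Score every ortholog pair and flag the top percentile
#'
#' Computes `A`, `B` and the divergence score for each mapped pair whose
#' curves are complete in both groups, ranks pairs by descending score
#' (dense ranks, ties broken in output order by the group-A id), and flags
#' pairs whose score lies strictly above the q-th percentile of all finite
#' scores (linear-interpolation percentile definition).
#'
#' @param profiles_a,profiles_b `normalized_profiles` for the two groups
#'   (each may hold one group, or name one via `group_a`/`group_b`).
#' @param map A validated `ortholog_map`.
#' @param q Flagging percentile in (0, 100]; default 75.
#' @param group_a,group_b Optional group names inside the profile objects.
#' @param method Area convention, see [integrated_difference()].
#' @param include_baseline Include the (always 0) baseline point in the
#'   Pearson term A. Default `TRUE` — the literal reading of scoring whole
#'   anchored response curves; `FALSE` drops t0 from A only.
#' @return Data frame of class `"divergence_table"`, one row per scored
#'   pair, ordered by rank: `feature_a`, `feature_b`, `A`, `B`, `score`,
#'   `rank`, `cutoff`, `flagged`. Attribute `n_skipped` counts mapped pairs
#'   dropped as incomplete.
#' @export
score_all <- function(profiles_a, profiles_b, map, q = 75,
                      group_a = NULL, group_b = NULL,
                      method = c("crossing", "endpoint"),
                      include_baseline = TRUE) {
  method <- match.arg(method)
  if (q <= 0 || q > 100) stop("q must lie in (0, 100]")
  if (!identical(profiles_a$time, profiles_b$time))
    stop("the two profile sets are on different time grids")
  ca <- profile_curves(profiles_a, group_a)
  cb <- profile_curves(profiles_b, group_b)
  keep <- map$feature_a %in% rownames(ca) & map$feature_b %in% rownames(cb)
  n_skipped <- sum(!keep)
  pairs <- map[keep, , drop = FALSE]
  if (nrow(pairs) == 0L)
    stop("no mapped pair has complete curves in both groups")
  times <- profiles_a$time
  idx <- if (include_baseline) seq_along(times) else seq_along(times)[-1L]
  A <- numeric(nrow(pairs)); B <- numeric(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    xa <- ca[pairs$feature_a[i], ]
    xb <- cb[pairs$feature_b[i], ]
    A[i] <- pearson_shape(xa[idx], xb[idx])
    B[i] <- integrated_difference(xa, xb, times, method = method)
  }
  score <- divergence_score(A, B)
  cutoff <- unname(stats::quantile(score, q / 100, type = 7))
  res <- data.frame(feature_a = pairs$feature_a,
                    feature_b = pairs$feature_b,
                    A = A, B = B, score = score,
                    rank = match(score, sort(unique(score), decreasing = TRUE)),
                    cutoff = cutoff, flagged = score > cutoff,
                    stringsAsFactors = FALSE)
  res <- res[order(res$rank, res$feature_a), , drop = FALSE]
  rownames(res) <- NULL
  structure(res, n_skipped = n_skipped,
            class = c("divergence_table", "data.frame"))
}
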