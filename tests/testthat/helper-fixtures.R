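# Small in-code fixtures shared across test files.

# Two-group sample sheet on a regular grid.
make_sheet <- function(groups = c("A", "B"), times = c(0, 1, 2),
                       n_reps = 2L) {
  grid <- expand.grid(replicate = seq_len(n_reps), time = times,
                      group = groups, stringsAsFactors = FALSE)
  sample_sheet(sprintf("%s_t%g_r%d", grid$group, grid$time, grid$replicate),
               grid$group, grid$time, grid$replicate)
}

# tc_matrix for one group whose replicate values are exactly
# base * 2^curve (no noise): normalisation recovers `curves` exactly.
# `curves` is a feature x time matrix of log2 ratios with first column 0.
matrix_from_curves <- function(curves, group = "A", times = NULL,
                               n_reps = 1L, layer = "protein", base = 100) {
  if (is.null(times)) times <- as.numeric(seq_len(ncol(curves)) - 1)
  sheet <- make_sheet(groups = c("A", "B"), times = times, n_reps = n_reps)
  gsh <- sheet[sheet$group == group, , drop = FALSE]
  vals <- matrix(NA_real_, nrow(curves), nrow(gsh),
                 dimnames = list(rownames(curves), gsh$sample_id))
  for (j in seq_len(nrow(gsh)))
    vals[, j] <- base * 2^curves[, match(gsh$time[j], times)]
  tc_matrix(vals, sheet, layer)
}

# normalized_profiles for one group, built through the public path.
profiles_from_curves <- function(curves, group = "A", times = NULL, ...) {
  normalize_to_baseline(
    matrix_from_curves(curves, group = group, times = times, ...),
    pseudocount = 0)
}

# Brute-force Benjamini-Hochberg step-up: q_i = min_{j: p_j >= p_i}
# of p_(j) * m / j, computed straight from the definition.
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q_sorted <- numeric(m)
  for (i in seq_len(m))
    q_sorted[i] <- min(1, min((m / (i:m)) * ps[i:m]))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Riemann-sum oracle for the area between two piecewise-linear curves.
riemann_area <- function(curve_a, curve_b, times, n_steps = 1e4) {
  grid <- seq(min(times), max(times), length.out = n_steps + 1L)
  mids <- (grid[-1L] + grid[-length(grid)]) / 2
  d <- stats::approx(times, curve_a - curve_b, xout = mids)$y
  sum(abs(d)) * diff(range(times)) / n_steps
}

# Exhaustive hypergeometric upper tail P(X >= k).
hyper_tail_brute <- function(k, K, N, n) {
  xs <- k:min(K, n)
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}

write_tsv_lines <- function(lines, ext = ".tsv") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
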