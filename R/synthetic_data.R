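#' Describe a block of planted temporal archetypes
#'
#' An archetype fixes the relationship between the two groups' latent log2
#' response curves for a block of simulated features:
#' \describe{
#'   \item{shared}{identical curves in both groups.}
#'   \item{scaled}{group-B curve is `c` times the group-A curve, `c` drawn
#'     uniformly in `[1.5, 3]` per feature (Pearson-invariant, so it must
#'     score 0 on noiseless data).}
#'   \item{anticorrelated}{group-B curve is the negation of group-A's.}
#'   \item{divergent}{the two curves are drawn independently (zero expected
#'     correlation) — the only archetype that should earn a high score.}
#'   \item{flat}{both curves identically zero.}
#' }
#'
#' @param name One of `"shared"`, `"divergent"`, `"scaled"`,
#'   `"anticorrelated"`, `"flat"`.
#' @param n_features Number of features in the block (positive).
#' @param amplitude Latent-curve amplitude in log2 units; non-baseline knots
#'   are drawn uniformly in `[-amplitude, amplitude]`.
#' @param noise_sd Replicate noise standard deviation in log2 units.
#' @return A list of class `"archetype_spec"`.
#' @export
archetype_spec <- function(name = c("shared", "divergent", "scaled",
                                    "anticorrelated", "flat"),
                           n_features, amplitude = 2, noise_sd = 0.25) {
  name <- match.arg(name)
  if (n_features < 1) stop("n_features must be positive")
  if (!is.finite(amplitude)) stop("amplitude must be finite")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (name %in% c("divergent", "anticorrelated") && amplitude <= 0)
    stop("archetype '", name, "' needs amplitude > 0 to be detectable")
  structure(list(name = name, n_features = as.integer(n_features),
                 amplitude = amplitude, noise_sd = noise_sd),
            class = "archetype_spec")
}

#' Archetype specs matching an analysis configuration
#'
#' Expands the configured archetype fractions into concrete
#' [archetype_spec()] blocks (rounded to whole features, remainder going to
#' the first named archetype).
#'
#' @param config An [analysis_config()].
#' @return A list of `archetype_spec`s.
#' @export
default_archetypes <- function(config = analysis_config()) {
  fr <- config$archetype_fractions
  fr <- fr[fr > 0]
  n <- floor(fr * config$n_features)
  n[1] <- n[1] + config$n_features - sum(n)
  lapply(names(n), function(nm)
    archetype_spec(nm, n[[nm]], amplitude = config$amplitude,
                   noise_sd = config$noise_sd))
}

#' Simulate a paired two-group, two-layer time course
#'
#' Emulates the comparative design the pipeline targets: two groups, a
#' shared time grid (default 0–4 h), replicate harvests at every point, and
#' two layers per group — RNA counts and protein intensities. Each feature's
#' latent log2 curve per group is piecewise-linear over the design time
#' points with the baseline knot forced to 0, so baseline-anchored
#' normalisation is exact on noiseless data. Replicate protein intensities
#' are `base_intensity * 2^(curve + N(0, noise_sd))`; RNA counts are
#' negative-binomial with mean `base_mean * 2^(curve + N(0, noise_sd))` and
#' fixed dispersion. The ortholog map is the identity pairing with
#' group-prefixed ids. Identical seeds give identical output.
#'
#' @param specs List of [archetype_spec()]s (total features >= 1).
#' @param times Strictly increasing time grid, hours.
#' @param n_replicates Replicates per (group, time).
#' @param seed Integer seed.
#' @param dispersion Negative-binomial dispersion (`size = 1/dispersion`).
#' @param groups Length-2 character vector of group labels.
#' @return A list of class `"tc_simulation"` with elements `rna` and
#'   `protein` (each a named list of two `tc_matrix` objects, one per
#'   group), `map` (identity `ortholog_map`), `truth` (data.frame
#'   `feature_id`, `archetype` in the group-A namespace), `latent` (list of
#'   two feature-x-time matrices of noiseless curves), `sheets` (per-group
#'   sample sheets) and `times`.
#' @export
simulate_timecourse <- function(specs, times = c(0, 1, 2, 3, 4),
                                n_replicates = 3L, seed = 1L,
                                dispersion = 0.1,
                                groups = c("A", "B")) {
  if (inherits(specs, "archetype_spec")) specs <- list(specs)
  n_total <- sum(vapply(specs, function(s) s$n_features, integer(1)))
  if (n_total < 1) stop("total features must be at least 1")
  if (length(times) < 2L || any(diff(times) <= 0))
    stop("times must be strictly increasing with at least 2 points")
  nt <- length(times)
  set.seed(as.integer(seed))

  ids <- sprintf("gene%05d", seq_len(n_total))
  archetype <- rep(vapply(specs, function(s) s$name, character(1)),
                   vapply(specs, function(s) s$n_features, integer(1)))
  noise_sd <- rep(vapply(specs, function(s) s$noise_sd, numeric(1)),
                  vapply(specs, function(s) s$n_features, integer(1)))

  latent_a <- matrix(0, n_total, nt, dimnames = list(ids, times))
  latent_b <- latent_a
  for (i in seq_len(n_total)) {
    amp <- 0
    for (s in specs) if (archetype[i] == s$name) amp <- s$amplitude
    if (archetype[i] == "flat") next
    knots_a <- c(0, stats::runif(nt - 1L, -amp, amp))
    knots_b <- switch(archetype[i],
      shared = knots_a,
      scaled = stats::runif(1L, 1.5, 3) * knots_a,
      anticorrelated = -knots_a,
      divergent = c(0, stats::runif(nt - 1L, -amp, amp)))
    latent_a[i, ] <- knots_a
    latent_b[i, ] <- knots_b
  }

  base_mean <- stats::rlnorm(n_total, meanlog = log(200), sdlog = 1)
  base_intensity <- stats::rlnorm(n_total, meanlog = log(1e6), sdlog = 1)

  grid <- expand.grid(replicate = seq_len(n_replicates), time = times,
                      group = groups, stringsAsFactors = FALSE)
  full_sheet <- sample_sheet(
    sample_id = sprintf("%s_t%g_r%d", grid$group, grid$time, grid$replicate),
    group = grid$group, time = grid$time, replicate = grid$replicate)
  sheets <- lapply(groups, function(g) {
    sh <- full_sheet[full_sheet$group == g, , drop = FALSE]
    rownames(sh) <- NULL
    sh
  })
  names(sheets) <- groups

  make_layer <- function(latent, g, layer, base) {
    sh <- full_sheet[full_sheet$group == g, , drop = FALSE]
    vals <- matrix(NA_real_, n_total, nrow(sh),
                   dimnames = list(paste0(g, "_", ids), sh$sample_id))
    for (j in seq_len(nrow(sh))) {
      ti <- match(sh$time[j], times)
      mu_log2 <- latent[, ti] + stats::rnorm(n_total, 0, noise_sd)
      mu <- base * 2^mu_log2
      vals[, j] <- if (layer == "rna") {
        stats::rnbinom(n_total, mu = mu, size = 1 / dispersion)
      } else mu
    }
    tc_matrix(vals, full_sheet, layer)
  }

  rna <- list(make_layer(latent_a, groups[1], "rna", base_mean),
              make_layer(latent_b, groups[2], "rna", base_mean))
  protein <- list(make_layer(latent_a, groups[1], "protein", base_intensity),
                  make_layer(latent_b, groups[2], "protein", base_intensity))
  names(rna) <- names(protein) <- groups

  map <- ortholog_map(paste0(groups[1], "_", ids), paste0(groups[2], "_", ids))
  truth <- data.frame(feature_id = paste0(groups[1], "_", ids),
                      archetype = archetype, stringsAsFactors = FALSE)
  rownames(latent_a) <- paste0(groups[1], "_", ids)
  rownames(latent_b) <- paste0(groups[2], "_", ids)

  structure(list(rna = rna, protein = protein, map = map, truth = truth,
                 latent = list(latent_a, latent_b), sheets = sheets,
                 times = times, groups = groups),
            class = "tc_simulation")
}

#' Probability that a positive outranks a negative (AUROC)
#'
#' Rank-based AUROC of a score against planted truth labels: the probability
#' that a randomly chosen positive-archetype feature scores above a randomly
#' chosen negative, ties counted one half (Mann–Whitney convention).
#'
#' @param scores Named numeric vector of per-feature scores (names in the
#'   group-A feature namespace).
#' @param truth Data frame with `feature_id` and `archetype` columns (as
#'   returned in `simulate_timecourse()$truth`).
#' @param positive Archetype name counted as positive.
#' @return AUROC in `[0, 1]`.
#' @export
truth_auroc <- function(scores, truth, positive = "divergent") {
  lab <- truth$archetype[match(names(scores), truth$feature_id)]
  if (anyNA(lab)) stop("scores contain features missing from the truth labels")
  pos <- lab == positive
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L)
    stop("need at least one positive and one negative feature")
  r <- rank(scores)  # average ranks handle ties as 1/2 wins
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}
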