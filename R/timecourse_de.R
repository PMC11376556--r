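#' Benjamini–Hochberg adjusted values
#'
#' Step-up FDR adjustment (wrapping [stats::p.adjust()]), with input
#' validation: raw p-values must lie in (0, 1].
#'
#' @param p Numeric vector of raw p-values.
#' @return Adjusted q-values, same order as `p`, capped at 1, monotone in p.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p) | p <= 0 | p > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Per-timepoint differential calls versus baseline
#'
#' For each feature, each non-baseline time is compared with the group's
#' baseline by a Welch two-sample t test on `log2(value + pseudocount)`
#' replicate values, and p-values are BH-adjusted across features within
#' each (group, time) stratum; calls are `q < fdr_alpha`. This is a
#' deliberately simple self-contained test whose calls feed the same
#' downstream set algebra as moderated-model pipelines.
#'
#' Degenerate features with zero variance in both samples get statistic 0
#' and p = 1 when the means agree; otherwise the variances are floored at
#' `var_floor` (log2 scale) so a clean shift still registers. Features with
#' fewer than 2 usable replicates in either sample get `NA` statistics
#' rather than failing the run.
#'
#' @param matrix A `tc_matrix`.
#' @param fdr_alpha FDR threshold for `called`; default 0.05.
#' @param pseudocount Added before log2; default 1 for RNA, 0 for protein.
#' @param var_floor Variance floor on the log2 scale; default 1e-8.
#' @return Data frame of class `"de_table"`: `feature_id`, `group`, `time`,
#'   `effect` (mean log2 difference vs baseline), `statistic`, `df`, `p`,
#'   `q`, `called`.
#' @export
per_timepoint_de <- function(matrix, fdr_alpha = 0.05,
                             pseudocount = if (matrix$layer == "rna") 1 else 0,
                             var_floor = 1e-8) {
  if (fdr_alpha <= 0 || fdr_alpha >= 1) stop("fdr_alpha must lie in (0, 1)")
  sh <- matrix$samples
  lv <- log2(matrix$values + pseudocount)
  out <- list()
  for (g in unique(sh$group)) {
    gt <- sort(unique(sh$time[sh$group == g]))
    base_cols <- sh$sample_id[sh$group == g & sh$time == gt[1]]
    if (length(base_cols) < 2L)
      stop("group '", g, "' has fewer than 2 baseline replicates")
    x0 <- lv[, base_cols, drop = FALSE]
    for (t in gt[-1L]) {
      cols <- sh$sample_id[sh$group == g & sh$time == t]
      xt <- lv[, cols, drop = FALSE]
      res <- welch_rows(x0, xt, var_floor)
      p_ok <- !is.na(res$p)
      q <- rep(NA_real_, length(res$p))
      if (any(p_ok)) q[p_ok] <- bh_adjust(res$p[p_ok])
      out[[length(out) + 1L]] <- data.frame(
        feature_id = rownames(lv), group = g, time = t,
        effect = res$effect, statistic = res$statistic, df = res$df,
        p = res$p, q = q, called = !is.na(q) & q < fdr_alpha,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  structure(res, class = c("de_table", "data.frame"))
}

# Vectorised Welch t of each row of x1 (tested time) against x0 (baseline).
welch_rows <- function(x0, x1, var_floor) {
  n0 <- rowSums(is.finite(x0)); n1 <- rowSums(is.finite(x1))
  m0 <- rowMeans(x0, na.rm = TRUE); m1 <- rowMeans(x1, na.rm = TRUE)
  v0 <- apply(x0, 1L, stats::var, na.rm = TRUE)
  v1 <- apply(x1, 1L, stats::var, na.rm = TRUE)
  effect <- m1 - m0
  statistic <- df <- p <- rep(NA_real_, length(effect))
  usable <- n0 >= 2L & n1 >= 2L & is.finite(effect)
  zerovar <- usable & v0 <= 0 & v1 <= 0
  flat <- zerovar & effect == 0
  statistic[flat] <- 0; p[flat] <- 1; df[flat] <- n0[flat] + n1[flat] - 2
  floored <- zerovar & effect != 0
  v0[floored] <- var_floor; v1[floored] <- var_floor
  calc <- usable & !flat
  se2_0 <- v0[calc] / n0[calc]; se2_1 <- v1[calc] / n1[calc]
  se <- sqrt(se2_0 + se2_1)
  tt <- effect[calc] / se
  dfc <- (se2_0 + se2_1)^2 /
    (se2_0^2 / (n0[calc] - 1) + se2_1^2 / (n1[calc] - 1))
  statistic[calc] <- tt
  df[calc] <- dfc
  p[calc] <- 2 * stats::pt(-abs(tt), dfc)
  list(effect = effect, statistic = statistic, df = df, p = p)
}

#' Cluster temporal profiles across the two groups
#'
#' Each mapped, complete pair contributes the concatenated vector
#' `[curve_A || curve_B]`, z-scored per feature across its 2T entries
#' (constant vectors map to all zeros). Pairs are clustered by Euclidean
#' distance with Ward linkage and the tree is cut at `k` groups; labels are
#' roman numerals I..k assigned by decreasing cluster size, ties broken by
#' the lexicographically smallest member id, so output is deterministic.
#'
#' @param profiles_a,profiles_b `normalized_profiles` for the two groups.
#' @param map A validated `ortholog_map`.
#' @param k Number of clusters.
#' @param group_a,group_b Optional group names inside the profile objects.
#' @param linkage Linkage method for [stats::hclust()]; default `"ward.D2"`
#'   (Ward on Euclidean distances).
#' @return A list of class `"cluster_assignment"` with `labels` (named
#'   character vector, group-A ids -> "I".."k"), `k`, and `centroids`
#'   (per-cluster mean concatenated profile, on the z-scored scale).
#' @export
cluster_profiles <- function(profiles_a, profiles_b, map, k,
                             group_a = NULL, group_b = NULL,
                             linkage = "ward.D2") {
  ca <- profile_curves(profiles_a, group_a)
  cb <- profile_curves(profiles_b, group_b)
  keep <- map$feature_a %in% rownames(ca) & map$feature_b %in% rownames(cb)
  pairs <- map[keep, , drop = FALSE]
  if (k < 1) stop("k must be positive")
  if (nrow(pairs) < k)
    stop("k = ", k, " exceeds the ", nrow(pairs), " complete mapped features")
  x <- cbind(ca[pairs$feature_a, , drop = FALSE],
             cb[pairs$feature_b, , drop = FALSE])
  rownames(x) <- pairs$feature_a
  mu <- rowMeans(x)
  sd <- apply(x, 1L, stats::sd)
  z <- (x - mu) / ifelse(sd > 0, sd, 1)
  z[sd == 0, ] <- 0
  raw <- if (k == 1L) {
    stats::setNames(rep(1L, nrow(z)), rownames(z))
  } else {
    stats::cutree(stats::hclust(stats::dist(z), method = linkage), k = k)
  }
  # renumber I..k by decreasing size; ties by smallest member id
  info <- data.frame(cluster = seq_len(k))
  info$size <- as.integer(table(factor(raw, levels = info$cluster)))
  info$first <- vapply(info$cluster, function(cl) {
    ids <- names(raw)[raw == cl]
    if (length(ids) == 0L) "" else min(ids)
  }, character(1))
  ord <- order(-info$size, info$first)
  relabel <- integer(k); relabel[info$cluster[ord]] <- seq_len(k)
  labels <- stats::setNames(as.character(utils::as.roman(relabel[raw])),
                            names(raw))
  centroids <- do.call(rbind, lapply(seq_len(k), function(i) {
    colMeans(z[labels == as.character(utils::as.roman(i)), , drop = FALSE])
  }))
  rownames(centroids) <- as.character(utils::as.roman(seq_len(k)))
  structure(list(labels = labels, k = as.integer(k), centroids = centroids),
            class = "cluster_assignment")
}

#' Overlap of differential calls across layers through the ortholog map
#'
#' Maps both layers' called features at one (group, time) into the group-A
#' namespace and intersects them — the RNA/protein agreement the study
#' design quantifies per time point.
#'
#' @param rna_de,prot_de `de_table`s for the two layers (same group
#'   namespaces; both are translated through `map` where their ids match
#'   the map's B side).
#' @param map A validated `ortholog_map` (used to translate any called id
#'   found on its B side into the A namespace; A-side ids pass through).
#' @param group Group whose calls are intersected.
#' @param time Time point, hours.
#' @return A list of class `"overlap_result"`: `group`, `time`,
#'   `n_rna`, `n_protein`, `n_overlap`, and `pairs` (character vector of
#'   overlapping ids, group-A namespace, sorted).
#' @export
cross_layer_overlap <- function(rna_de, prot_de, map, group, time) {
  called_at <- function(de) {
    sel <- de$group == group & de$time == time
    if (!any(sel)) stop("time ", time, " absent from a DE table for group '",
                        group, "'")
    ids <- de$feature_id[sel & de$called]
    hit <- match(ids, map$feature_b)
    ids[!is.na(hit)] <- map$feature_a[hit[!is.na(hit)]]
    unique(ids)
  }
  rna_ids <- called_at(rna_de)
  prot_ids <- called_at(prot_de)
  ov <- sort(intersect(rna_ids, prot_ids))
  structure(list(group = group, time = time,
                 n_rna = length(rna_ids), n_protein = length(prot_ids),
                 n_overlap = length(ov), pairs = ov),
            class = "overlap_result")
}
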