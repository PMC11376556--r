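#' Fisher's exact over-representation of a selection against gene sets
#'
#' For each gene set (intersected with the universe first), tests whether
#' the selection contains more set members than expected by chance:
#' one-sided hypergeometric upper tail `P(X >= k)` with universe size `N`,
#' set size `K`, selection size `n` and hits `k` — the one-sided Fisher's
#' exact test. Rows are BH-adjusted and sorted by p, ties by set name.
#'
#' @param selection Character vector of selected feature ids (must be a
#'   subset of `universe`).
#' @param sets A `gene_sets` collection (or named list of id vectors).
#' @param universe Character vector: background of all testable features
#'   (typically everything scored in the run, not the GMT union).
#' @param alternative `"greater"` (over-representation, default) or
#'   `"two.sided"` (via [stats::fisher.test()]).
#' @return Data frame of class `"enrichment_table"`, one row per set with
#'   `K > 0` after intersection: `set_name`, `k`, `K`, `n`, `N`,
#'   `odds_ratio` (sample odds ratio; `Inf` when a complement cell is
#'   empty), `fold_enrichment`, `p`, `q`.
#' @export
fisher_enrichment <- function(selection, sets, universe,
                              alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  selection <- unique(as.character(selection))
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) stop("universe is empty")
  bad <- setdiff(selection, universe)
  if (length(bad) > 0)
    stop("selection not a subset of the universe: ",
         paste(utils::head(bad, 5), collapse = ", "),
         if (length(bad) > 5) " ..." else "")
  N <- length(universe)
  n <- length(selection)
  rows <- lapply(names(sets), function(nm) {
    members <- intersect(sets[[nm]], universe)
    K <- length(members)
    if (K == 0L) return(NULL)
    k <- length(intersect(selection, members))
    p <- if (alternative == "greater") {
      stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    } else {
      stats::fisher.test(matrix(c(k, K - k, n - k, N - K - n + k), 2L),
                         alternative = "two.sided")$p.value
    }
    or <- (k * (N - K - n + k)) / ((K - k) * (n - k))
    data.frame(set_name = nm, k = k, K = K, n = n, N = N,
               odds_ratio = or,
               fold_enrichment = if (K > 0 && n > 0) (k / n) / (K / N) else NA_real_,
               p = p, stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows))
    stop("no gene set overlaps the universe")
  rows$q <- bh_adjust(rows$p)
  rows <- rows[order(rows$p, rows$set_name), , drop = FALSE]
  rownames(rows) <- NULL
  structure(rows, class = c("enrichment_table", "data.frame"))
}
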