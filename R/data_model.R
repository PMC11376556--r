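#' Read and validate a sample sheet
#'
#' The sample sheet describes the experimental design: one row per sample
#' with its group (exactly two levels, e.g. the two species' cell lines),
#' harvest time in hours, and replicate index.
#'
#' @param path Path to a TSV with columns `sample_id`, `group`, `time`,
#'   `replicate`.
#' @return A `data.frame` of class `"tc_sample_sheet"`.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  required <- c("sample_id", "group", "time", "replicate")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stop("sample sheet is missing column(s): ", paste(missing, collapse = ", "))
  df$time <- as.numeric(df$time)
  df$replicate <- as.integer(df$replicate)
  validate_sample_sheet(df[required])
}

#' Construct a sample sheet from vectors
#'
#' @param sample_id Character vector of unique sample identifiers.
#' @param group Character vector; exactly two distinct values overall.
#' @param time Numeric vector of harvest times in hours (non-negative).
#' @param replicate Integer vector of replicate indices (positive).
#' @return A validated sample sheet.
#' @export
sample_sheet <- function(sample_id, group, time, replicate) {
  validate_sample_sheet(data.frame(
    sample_id = as.character(sample_id), group = as.character(group),
    time = as.numeric(time), replicate = as.integer(replicate),
    stringsAsFactors = FALSE))
}

validate_sample_sheet <- function(df) {
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id(s): ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  groups <- unique(df$group)
  if (length(groups) != 2L)
    stop("sample sheet must contain exactly two groups, found: ",
         paste(groups, collapse = ", "))
  if (any(!is.finite(df$time)) || any(df$time < 0))
    stop("time must be non-negative and finite (hours)")
  if (any(is.na(df$replicate)) || any(df$replicate < 1L))
    stop("replicate must be a positive integer")
  for (g in groups) {
    gt <- df$time[df$group == g]
    if (min(gt) != min(df$time))
      stop("group '", g, "' lacks samples at the baseline time point (t = ",
           min(df$time), ")")
  }
  rownames(df) <- NULL
  class(df) <- c("tc_sample_sheet", "data.frame")
  df
}

#' Read a feature-by-sample abundance matrix
#'
#' Parses a TSV whose header row holds sample ids and whose first column
#' holds feature ids, validates it against the sample sheet, and returns a
#' `tc_matrix`. Columns are reordered to sample-sheet order; sheet samples
#' absent from the file are simply not included. Values must be non-negative;
#' the literal `NA` marks a missing measurement and is tracked per feature
#' rather than imputed.
#'
#' @param path Path to the TSV.
#' @param sheet A sample sheet covering (at least) the file's columns.
#' @param layer `"rna"` or `"protein"`.
#' @return An object of class `"tc_matrix"`: list with `layer`, `values`
#'   (numeric matrix, features x samples), and `samples` (the sheet restricted
#'   to the matrix columns, in column order).
#' @export
read_matrix <- function(path, sheet, layer = c("rna", "protein")) {
  layer <- match.arg(layer)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2L) stop("matrix TSV needs a feature_id column plus samples")
  feature_id <- as.character(df[[1L]])
  vals <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- feature_id
  tc_matrix(vals, sheet, layer)
}

#' Construct a validated time-course matrix
#'
#' @param values Numeric matrix, features x samples, with feature ids as
#'   rownames and sample ids as colnames.
#' @param sheet Sample sheet covering the columns.
#' @param layer `"rna"` or `"protein"`.
#' @return A `tc_matrix`.
#' @export
tc_matrix <- function(values, sheet, layer = c("rna", "protein")) {
  layer <- match.arg(layer)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must carry feature ids as rownames and sample ids as colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate feature_id(s): ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  unknown <- setdiff(colnames(values), sheet$sample_id)
  if (length(unknown) > 0)
    stop("column(s) not in the sample sheet: ", paste(unknown, collapse = ", "))
  neg <- which(!is.na(values) & values < 0, arr.ind = TRUE)
  if (nrow(neg) > 0)
    stop("negative value at (feature '", rownames(values)[neg[1, 1]],
         "', sample '", colnames(values)[neg[1, 2]], "')")
  keep <- sheet$sample_id[sheet$sample_id %in% colnames(values)]
  values <- values[, keep, drop = FALSE]
  samples <- sheet[match(keep, sheet$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  class(samples) <- c("tc_sample_sheet", "data.frame")
  structure(list(layer = layer, values = values, samples = samples),
            class = "tc_matrix")
}

#' @export
print.tc_matrix <- function(x, ...) {
  cat(sprintf("<tc_matrix> layer=%s: %d features x %d samples (%d group(s), %d time point(s))\n",
              x$layer, nrow(x$values), ncol(x$values),
              length(unique(x$samples$group)),
              length(unique(x$samples$time))))
  invisible(x)
}

#' Write a time-course matrix to TSV at full precision
#'
#' Numbers are written with 17 significant digits so that a write/read
#' round trip reproduces every double exactly.
#'
#' @param matrix A `tc_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(matrix, path) {
  write_numeric_tsv(matrix$values, path, id_col = "feature_id")
}

#' Write a sample sheet to TSV
#' @param sheet A sample sheet.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.table(as.data.frame(sheet), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# Full-precision numeric TSV writer shared by matrix-like outputs.
write_numeric_tsv <- function(values, path, id_col = "feature_id") {
  fmt <- function(v) {
    out <- vapply(v, function(x) {
      if (is.na(x)) "NA" else format_full(x)
    }, character(1))
    out
  }
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c(id_col, colnames(values)), collapse = "\t"), con)
  body <- apply(values, 1L, function(row) paste(fmt(row), collapse = "\t"))
  writeLines(paste(rownames(values), body, sep = "\t"), con)
  invisible(path)
}

format_full <- function(x) {
  if (!is.na(x) && is.finite(x) && x == round(x) && abs(x) < 2^53) {
    sprintf("%.0f", x)
  } else {
    sprintf("%.17g", x)
  }
}

#' Read a two-column ortholog map, enforcing one-to-one pairing
#'
#' Feature identifiers in the two groups live in different namespaces (for
#' example, two species' gene ids); every cross-group comparison goes through
#' this map. Rows participating in many-to-many relations are dropped and
#' counted: after validation each id appears at most once on its side.
#'
#' @param path Path to a 2-column TSV (header optional columns
#'   `feature_a`, `feature_b`; any header is accepted).
#' @return A `data.frame` of class `"ortholog_map"` with columns `feature_a`
#'   and `feature_b`, and attribute `n_dropped` (rows removed by the
#'   one-to-one rule).
#' @export
read_ortholog_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) != 2L) stop("ortholog map must have exactly 2 columns")
  names(df) <- c("feature_a", "feature_b")
  ortholog_map(df$feature_a, df$feature_b)
}

#' Construct a one-to-one ortholog map from id vectors
#'
#' @param feature_a,feature_b Equal-length character vectors of paired ids.
#' @return An `ortholog_map`; see [read_ortholog_map()].
#' @export
ortholog_map <- function(feature_a, feature_b) {
  df <- data.frame(feature_a = as.character(feature_a),
                   feature_b = as.character(feature_b),
                   stringsAsFactors = FALSE)
  n0 <- nrow(df)
  if (n0 == 0L) stop("ortholog map contains no rows")
  keep <- !(df$feature_a %in% df$feature_a[duplicated(df$feature_a)]) &
          !(df$feature_b %in% df$feature_b[duplicated(df$feature_b)])
  df <- df[keep, , drop = FALSE]
  rownames(df) <- NULL
  structure(df, n_dropped = n0 - nrow(df),
            class = c("ortholog_map", "data.frame"))
}

#' Write an ortholog map to TSV
#' @param map An `ortholog_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ortholog_map <- function(map, path) {
  utils::write.table(as.data.frame(map), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' Standard GMT dialect: one set per line, `set_name TAB description TAB
#' member1 TAB member2 ...`. Duplicate members within a set are removed;
#' duplicate set names are an error.
#'
#' @param path Path to the GMT file.
#' @return A named list of character vectors (class `"gene_sets"`), with a
#'   `descriptions` attribute (named character vector).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short) > 0)
    stop("GMT line ", short[1], " has fewer than 3 fields")
  nm <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(nm))
    stop("duplicate gene set name(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  desc <- vapply(fields, `[[`, character(1), 2L)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- nm
  names(desc) <- nm
  empty <- lengths(sets) == 0L
  if (any(empty))
    stop("gene set(s) with no members: ", paste(nm[empty], collapse = ", "))
  structure(sets, descriptions = desc, class = c("gene_sets", "list"))
}

#' Write gene sets in GMT format
#' @param sets A named list of character vectors (or `gene_sets`).
#' @param path Output path.
#' @param descriptions Optional named character vector of set descriptions.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- attr(sets, "descriptions")
  lines <- vapply(names(sets), function(nm) {
    d <- if (!is.null(descriptions) && nm %in% names(descriptions))
      descriptions[[nm]] else ""
    paste(c(nm, d, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Default analysis configuration
#'
#' Bundles every tunable threshold of the pipeline, with the defaults used
#' throughout: flagging at the 75th percentile of divergence scores, FDR
#' alpha 0.05, 4 temporal-profile clusters, RNA pseudocount of 1 count.
#' Generator settings (feature count, archetype mix, amplitude, noise) ride
#' along so a single config fully determines a synthetic run.
#'
#' @param percentile_q Flagging percentile, in (0, 100]. Default 75.
#' @param fdr_alpha FDR threshold for differential calls, in (0, 1).
#' @param n_clusters Number of temporal-profile clusters (k).
#' @param pseudocount_rna Pseudocount added to RNA counts before log2.
#' @param seed Integer seed for the generator.
#' @param n_features Total simulated features.
#' @param archetype_fractions Named fractions over
#'   `c(divergent, shared, scaled, anticorrelated, flat)`; must sum to 1.
#' @param amplitude Latent-curve amplitude in log2 units.
#' @param noise_sd Replicate noise standard deviation, log2 units.
#' @param dispersion Negative-binomial dispersion for the count layer.
#' @param times Time grid in hours.
#' @param n_replicates Replicates per (group, time).
#' @param linkage Hierarchical-clustering linkage passed to [stats::hclust()].
#' @return A validated list of class `"analysis_config"`.
#' @export
analysis_config <- function(percentile_q = 75, fdr_alpha = 0.05,
                            n_clusters = 4L, pseudocount_rna = 1,
                            seed = 1L, n_features = 2000L,
                            archetype_fractions = c(divergent = 0.10,
                                                    shared = 0.70,
                                                    scaled = 0.10,
                                                    anticorrelated = 0.10,
                                                    flat = 0.00),
                            amplitude = 2, noise_sd = 0.25,
                            dispersion = 0.1, times = c(0, 1, 2, 3, 4),
                            n_replicates = 3L, linkage = "ward.D2") {
  cfg <- list(percentile_q = percentile_q, fdr_alpha = fdr_alpha,
              n_clusters = as.integer(n_clusters),
              pseudocount_rna = pseudocount_rna, seed = as.integer(seed),
              n_features = as.integer(n_features),
              archetype_fractions = archetype_fractions,
              amplitude = amplitude, noise_sd = noise_sd,
              dispersion = dispersion, times = times,
              n_replicates = as.integer(n_replicates), linkage = linkage)
  validate_config(cfg)
}

validate_config <- function(cfg) {
  stopifnot(is.list(cfg))
  if (!is.numeric(cfg$percentile_q) || cfg$percentile_q <= 0 ||
      cfg$percentile_q > 100)
    stop("percentile_q must lie in (0, 100]")
  if (!is.numeric(cfg$fdr_alpha) || cfg$fdr_alpha <= 0 || cfg$fdr_alpha >= 1)
    stop("fdr_alpha must lie in (0, 1)")
  if (!is.numeric(cfg$n_clusters) || cfg$n_clusters < 1)
    stop("n_clusters must be a positive integer")
  if (!is.numeric(cfg$pseudocount_rna) || cfg$pseudocount_rna <= 0)
    stop("pseudocount_rna must be positive")
  if (!is.numeric(cfg$seed)) stop("seed must be an integer")
  if (cfg$n_features < 1) stop("n_features must be at least 1")
  fr <- cfg$archetype_fractions
  if (is.null(names(fr)) || any(fr < 0) || abs(sum(fr) - 1) > 1e-8)
    stop("archetype_fractions must be named, non-negative and sum to 1")
  if (cfg$noise_sd < 0) stop("noise_sd must be non-negative")
  if (cfg$dispersion <= 0) stop("dispersion must be positive")
  if (any(diff(cfg$times) <= 0)) stop("times must be strictly increasing")
  if (cfg$n_replicates < 1) stop("n_replicates must be positive")
  class(cfg) <- "analysis_config"
  cfg
}

#' Write an analysis configuration to YAML
#'
#' Inverse of [read_config()]: named vectors are written as YAML maps so the
#' round trip preserves archetype names.
#'
#' @param config An `analysis_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  x$archetype_fractions <- as.list(x$archetype_fractions)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Read an analysis configuration from YAML
#'
#' Fields absent from the file take the [analysis_config()] defaults; all
#' bounds are enforced at load time.
#'
#' @param path Path to a YAML file.
#' @return A validated `analysis_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  for (nm in c("archetype_fractions", "times"))
    if (!is.null(raw[[nm]])) raw[[nm]] <- unlist(raw[[nm]])
  defaults <- analysis_config()
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown) > 0)
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  for (nm in names(raw)) defaults[[nm]] <- raw[[nm]]
  validate_config(unclass(defaults))
}
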