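#' Run the full divergence pipeline on synthetic data
#'
#' One-command orchestration of every stage on a seeded synthetic dataset
#' drawn from the configured study design: simulate -> normalize -> qc ->
#' score -> de -> cluster -> overlap -> enrich. All thresholds come from the
#' config; no stage has hidden constants. Every output is a TSV under
#' `outdir`, plus a YAML manifest recording the config echo, seed, per-stage
#' files and row counts. Identical config and seed give byte-identical
#' outputs.
#'
#' The enrichment stage tests the flagged high-divergence protein set
#' against gene sets built from the planted archetype labels (one set per
#' archetype), with the scored features as universe — a self-contained
#' check that flagging enriches for the divergent archetype.
#'
#' @param config An [analysis_config()] (or path handled by
#'   [read_config()] upstream).
#' @param outdir Output directory; created if needed.
#' @param quiet Suppress progress messages (written to standard error).
#' @return The manifest, invisibly (list mirroring `manifest.yaml`).
#' @export
run_pipeline <- function(config = analysis_config(), outdir, quiet = FALSE) {
  config <- validate_config(unclass(config))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  say <- function(stage, ...) {
    if (!quiet) message(format(Sys.time(), "%H:%M:%S"), " [", stage, "] ", ...)
  }
  files <- list(); counts <- list()
  register <- function(name, path, n) {
    files[[name]] <<- path; counts[[name]] <<- n
  }
  out <- function(f) file.path(outdir, f)
  write_df <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }

  say("simulate", config$n_features, " features, seed ", config$seed)
  sim <- simulate_timecourse(default_archetypes(config),
                             times = config$times,
                             n_replicates = config$n_replicates,
                             seed = config$seed,
                             dispersion = config$dispersion)
  g <- sim$groups
  for (layer in c("rna", "protein")) for (gr in g) {
    f <- out(sprintf("%s_%s.tsv", layer, gr))
    write_matrix(sim[[layer]][[gr]], f)
    register(sprintf("%s_%s", layer, gr), f, nrow(sim[[layer]][[gr]]$values))
  }
  full_sheet <- do.call(rbind, lapply(sim$sheets, as.data.frame))
  write_df(full_sheet, out("sample_sheet.tsv"))
  register("sample_sheet", out("sample_sheet.tsv"), nrow(full_sheet))
  write_ortholog_map(sim$map, out("ortholog_map.tsv"))
  register("ortholog_map", out("ortholog_map.tsv"), nrow(sim$map))
  write_df(sim$truth, out("truth_labels.tsv"))
  register("truth_labels", out("truth_labels.tsv"), nrow(sim$truth))
  archetype_sets <- split(sim$truth$feature_id, sim$truth$archetype)
  write_gmt(archetype_sets, out("archetype_sets.gmt"),
            descriptions = stats::setNames(
              paste("planted archetype:", names(archetype_sets)),
              names(archetype_sets)))
  register("archetype_sets", out("archetype_sets.gmt"),
           length(archetype_sets))

  say("normalize", "baseline-anchored log2 ratios")
  prof <- list()
  for (layer in c("rna", "protein")) for (gr in g) {
    pc <- if (layer == "rna") config$pseudocount_rna else 0
    np <- normalize_to_baseline(sim[[layer]][[gr]], pseudocount = pc)
    prof[[layer]][[gr]] <- np
    f <- out(sprintf("profiles_%s_%s.tsv", layer, gr))
    write_numeric_tsv(profile_curves(np, gr), f)
    register(sprintf("profiles_%s_%s", layer, gr), f,
             sum(np$complete[[gr]]))
    if (nrow(np$excluded) > 0) {
      fe <- out(sprintf("excluded_%s_%s.tsv", layer, gr))
      write_df(np$excluded, fe)
      register(sprintf("excluded_%s_%s", layer, gr), fe, nrow(np$excluded))
    }
  }

  say("qc", "replicate and cross-layer correlations")
  for (layer in c("rna", "protein")) {
    qcs <- lapply(g, function(gr) {
      pc <- if (layer == "rna") config$pseudocount_rna else 1
      replicate_correlation_qc(sim[[layer]][[gr]], pseudocount = pc)$pairs
    })
    f <- out(sprintf("qc_replicates_%s.tsv", layer))
    qcs <- do.call(rbind, qcs)
    write_df(qcs, f)
    register(sprintf("qc_replicates_%s", layer), f, nrow(qcs))
  }
  xl <- do.call(rbind, lapply(g, function(gr) {
    cbind(group = gr,
          rna_protein_correlation(prof$rna[[gr]], prof$protein[[gr]], gr))
  }))
  write_df(xl, out("qc_rna_protein.tsv"))
  register("qc_rna_protein", out("qc_rna_protein.tsv"), nrow(xl))

  say("score", "divergence score per ortholog pair, q = ", config$percentile_q)
  scores <- list()
  for (layer in c("rna", "protein")) {
    st <- score_all(prof[[layer]][[g[1]]], prof[[layer]][[g[2]]], sim$map,
                    q = config$percentile_q, group_a = g[1], group_b = g[2])
    scores[[layer]] <- st
    f <- out(sprintf("score_%s.tsv", layer))
    write_df(as.data.frame(st), f)
    register(sprintf("score_%s", layer), f, nrow(st))
  }

  say("de", "per-timepoint Welch calls, alpha = ", config$fdr_alpha)
  de <- list()
  for (layer in c("rna", "protein")) {
    det <- do.call(rbind, lapply(g, function(gr) {
      pc <- if (layer == "rna") config$pseudocount_rna else 0
      per_timepoint_de(sim[[layer]][[gr]], fdr_alpha = config$fdr_alpha,
                       pseudocount = pc)
    }))
    de[[layer]] <- det
    f <- out(sprintf("de_%s.tsv", layer))
    write_df(as.data.frame(det), f)
    register(sprintf("de_%s", layer), f, nrow(det))
  }

  say("cluster", "k = ", config$n_clusters, " temporal profiles (protein)")
  cl <- cluster_profiles(prof$protein[[g[1]]], prof$protein[[g[2]]], sim$map,
                         k = config$n_clusters, group_a = g[1],
                         group_b = g[2], linkage = config$linkage)
  cl_df <- data.frame(feature_id = names(cl$labels), cluster = cl$labels,
                      stringsAsFactors = FALSE)
  write_df(cl_df, out("clusters_protein.tsv"))
  register("clusters_protein", out("clusters_protein.tsv"), nrow(cl_df))
  write_numeric_tsv(cl$centroids, out("cluster_centroids_protein.tsv"),
                    id_col = "cluster")
  register("cluster_centroids_protein", out("cluster_centroids_protein.tsv"),
           nrow(cl$centroids))

  say("overlap", "RNA/protein called-set overlap per (group, time)")
  ovl <- do.call(rbind, lapply(g, function(gr) {
    do.call(rbind, lapply(config$times[-1L], function(t) {
      o <- cross_layer_overlap(de$rna, de$protein, sim$map, gr, t)
      data.frame(group = gr, time = t, n_rna = o$n_rna,
                 n_protein = o$n_protein, n_overlap = o$n_overlap)
    }))
  }))
  write_df(ovl, out("overlap.tsv"))
  register("overlap", out("overlap.tsv"), nrow(ovl))

  say("enrich", "flagged protein set vs planted archetype sets")
  flagged <- scores$protein$feature_a[scores$protein$flagged]
  universe <- scores$protein$feature_a
  enr <- fisher_enrichment(flagged, archetype_sets, universe)
  write_df(as.data.frame(enr), out("enrichment_protein.tsv"))
  register("enrichment_protein", out("enrichment_protein.tsv"), nrow(enr))

  manifest <- list(
    tool = paste0("tcdiverge ",
                  as.character(utils::packageVersion("tcdiverge"))),
    seed = config$seed,
    config = unclass(config),
    outputs = lapply(names(files), function(nm)
      list(name = nm, path = files[[nm]], rows = counts[[nm]])))
  yaml::write_yaml(manifest, out("manifest.yaml"))
  say("done", "manifest written to ", out("manifest.yaml"))
  invisible(manifest)
}
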