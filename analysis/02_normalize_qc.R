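#!/usr/bin/env Rscript
# Stage 2 — baseline-anchored log2 response curves and QC: replicate
# reproducibility within (group, time), and RNA-protein correlation per
# time point. Reads the stage-1 TSVs through the package's validating
# readers.

library(tcdiverge)

ind <- "results/01_sim"
out <- "results/02_qc"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- read_config(file.path(ind, "config.yaml"))
sheet <- read_sample_sheet(file.path(ind, "sample_sheet.tsv"))

for (layer in c("rna", "protein")) {
  pc_norm <- if (layer == "rna") cfg$pseudocount_rna else 0
  for (g in c("A", "B")) {
    m <- read_matrix(file.path(ind, sprintf("%s_%s.tsv", layer, g)),
                     sheet, layer)
    np <- normalize_to_baseline(m, pseudocount = pc_norm)
    curves <- np$groups[[g]][np$complete[[g]], , drop = FALSE]
    tcdiverge:::write_numeric_tsv(curves,
      file.path(out, sprintf("profiles_%s_%s.tsv", layer, g)))
    qc <- replicate_correlation_qc(m, pseudocount = max(pc_norm, 1))
    write.table(qc$pairs,
                file.path(out, sprintf("qc_replicates_%s_%s.tsv", layer, g)),
                sep = "\t", quote = FALSE, row.names = FALSE)
    cat(sprintf("%s/%s: %d/%d features complete; replicate r range [%.3f, %.3f]\n",
                layer, g, nrow(curves), nrow(m$values),
                min(qc$pairs$r), max(qc$pairs$r)))
  }
}

# cross-layer agreement of anchored curves, per group
for (g in c("A", "B")) {
  rna <- normalize_to_baseline(
    read_matrix(file.path(ind, sprintf("rna_%s.tsv", g)), sheet, "rna"),
    pseudocount = cfg$pseudocount_rna)
  prot <- normalize_to_baseline(
    read_matrix(file.path(ind, sprintf("protein_%s.tsv", g)), sheet, "protein"),
    pseudocount = 0)
  xr <- rna_protein_correlation(rna, prot, g)
  write.table(xr, file.path(out, sprintf("qc_rna_protein_%s.tsv", g)),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("group %s mRNA-protein curve correlation: %s\n", g,
              paste(sprintf("t=%gh r=%.3f", xr$time, xr$r), collapse = ", ")))
}
cat("Outputs in", out, "\n")
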