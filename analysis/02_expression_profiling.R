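#!/usr/bin/env Rscript

# Stage 2: expression profiling.
#
# Detection filtering, quantile normalization, two-way ANOVA differential
# expression (cell type x organ, BH FDR < 5%), pattern clustering of the
# selected features, the overall sample dendrogram, strict marker calling
# on the intensity platform, cross-platform marker validation, and the
# HC-elevated gene set from the count platform.

suppressMessages(library(hcmotif))

ind <- "results/inputs"
outd <- "results/expression"
dir.create(outd, recursive = TRUE, showWarnings = FALSE)

ma <- read_expression_table(file.path(ind, "microarray.tsv"),
                            file.path(ind, "microarray.design.tsv"),
                            file.path(ind, "microarray.tsv.detection"))
ma_n <- quantile_normalize(detection_filter(ma))
cat(nrow(ma_n$values), "of", nrow(ma$values),
    "probes detected (p < 0.01 in >= 2 samples)\n")
write_expression_table(ma_n, file.path(outd, "microarray_normalized.tsv"))

de <- anova_de(ma_n)
cat(sum(de$selected), "features differentially expressed",
    "(cell type, organ or interaction; FDR < 5%)\n")
write.table(de, file.path(outd, "de_table.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

sel <- de$feature_id[de$selected]
clus <- cluster_patterns(standardize_rows(ma_n$values[sel, ]), k = 12L,
                         seed = 1L)
cat("Expression patterns (cluster sizes):",
    paste(sort(clus$sizes, decreasing = TRUE), collapse = ", "), "\n")
write.table(data.frame(feature_id = names(clus$cluster),
                       cluster = unname(clus$cluster)),
            file.path(outd, "clusters.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

dend <- sample_dendrogram(ma_n)
top_split <- stats::cutree(dend, k = 2)
cat("Top dendrogram split groups samples by:",
    if (length(unique(tapply(ma_n$design$cell_type, top_split, paste,
                             collapse = ","))) > 1) "cell type-related groups"
    else "another factor", "\n")

mk <- call_markers(ma_n)
cat(nrow(mk), "strict markers called (",
    sum(mk$cell_type == "HC"), "HC /", sum(mk$cell_type == "ENHC"), "ENHC /",
    sum(mk$cell_type == "NEC"), "NEC )\n")
write.table(mk, file.path(outd, "markers.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

rs <- read_expression_table(file.path(ind, "rnaseq.tsv"),
                            file.path(ind, "rnaseq.design.tsv"))
rs_n <- normalize_counts(rs)
write_expression_table(rs_n, file.path(outd, "rnaseq_normalized.tsv"))

mv <- validate_markers(mk, rs_n)
cat(sprintf("Marker validation on the count platform: %.0f%% confirmed at >= 2-fold, mean fold %.1f (%d not assessable)\n",
            100 * mv$fraction_confirmed, mv$mean_fold, mv$n_excluded))

rs_expressed <- rownames(rs$values)[rowSums(rs$values) >= 20]
hc_set <- intersect(hc_enriched_set(rs_n, fold = 3), rs_expressed)
cat(length(hc_set), "genes elevated >= 3-fold in HCs vs ENHCs",
    "in at least one organ\n")
write_gene_list(hc_set, file.path(outd, "hc_enriched.txt"))
write_gene_list(rs_expressed, file.path(outd, "expressed_genes.txt"))
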