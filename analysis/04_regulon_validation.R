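#!/usr/bin/env Rscript

# Stage 4: regulon validation.
#
# Intersects the putative targets with the two ChIP-derived target lists,
# re-tests the motif on the second species through the ortholog map, tests
# whether ChIP-target expression is shifted toward hair cells, and runs the
# curated-panel enrichment.

suppressMessages(library(hcmotif))

ind <- "results/inputs"
expd <- "results/expression"
motd <- "results/motif"
outd <- "results/validation"
dir.create(outd, recursive = TRUE, showWarnings = FALSE)

putative <- read_gene_list(file.path(motd, "putative_targets.txt"))
background <- read_gene_list(file.path(expd, "expressed_genes.txt"))
hc_set <- read_gene_list(file.path(expd, "hc_enriched.txt"))
ma_n <- read_expression_table(file.path(expd, "microarray_normalized.tsv"),
                              paste0(file.path(expd, "microarray_normalized.tsv"),
                                     ".design"))

chip1 <- read_gene_list(file.path(ind, "chip_targets_1.txt"))
chip2 <- read_gene_list(file.path(ind, "chip_targets_2.txt"))
universe <- read_tss_table(file.path(ind, "tss_a.bed"))$gene
ci <- chip_intersection(putative, intersect(chip1, universe),
                        intersect(chip2, universe), universe)
cat(sprintf("ChIP: %d of %d putative targets bound by at least one factor (p = %.3g); %d bound by both\n",
            ci$n_bound_any, ci$n_candidates, ci$any_test$p, ci$n_bound_both))
write_record_json(lapply(ci, function(x) if (inherits(x, "enrichment_result"))
  unclass(x) else x), file.path(outd, "chip_intersection.json"))

orth <- read_ortholog_map(file.path(ind, "orthologs.tsv"))
tss_b <- read_tss_table(file.path(ind, "tss_b.bed"))
prom_b <- extract_promoters(file.path(ind, "genome_b.fa"), tss_b, 1000L, 500L)
pwm <- read_pwm_meme(file.path(ind, "motif.meme"))
cs <- cross_species_test(intersect(hc_set, background), orth,
                         unname(orth[background]), promoters_b = prom_b,
                         pwm = pwm)
cat(sprintf("Second species: EF = %.2f, p = %.3g (%d targets unmapped)\n",
            cs$enrichment_factor, cs$p, cs$n_unmapped))
write_record_json(unclass(cs), file.path(outd, "cross_species.json"))

scores <- hc_enrichment_scores(ma_n)
write.table(scores, file.path(outd, "hc_enrichment_scores.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
in_chip <- scores$gene %in% chip1
st <- shift_test(scores$log2_ratio[in_chip], scores$log2_ratio[!in_chip])
cat(sprintf("ChIP targets' HC-enrichment is shifted right: median log2 difference %.2f, one-sided Wilcoxon p = %.3g\n",
            st$median_difference, st$p))
write_record_json(st, file.path(outd, "shift_test.json"))

panel <- read_gene_list(file.path(ind, "panel.txt"))
de <- read.table(file.path(expd, "de_table.tsv"), header = TRUE, sep = "\t")
pe <- geneset_enrichment(intersect(panel, rownames(ma_n$values)),
                         de$feature_id[de$selected], rownames(ma_n$values))
cat(sprintf("Curated panel: %d of %d panel genes differentially expressed (p = %.3g)\n",
            pe$k, pe$n, pe$p))
write_record_json(unclass(pe), file.path(outd, "panel_enrichment.json"))
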