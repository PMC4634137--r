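#!/usr/bin/env Rscript

# Stage 3: promoter motif analysis.
#
# Extracts promoters (-1000..+500 nt around the TSS), scans them with the
# X-box PWM at 80% of the maximum log-odds on both strands, tests the
# HC-elevated set for over-representation against the expressed-gene
# background, localizes the hits around the TSS, re-tests on the narrowed
# -200..+100 window, and runs de-novo 8-mer discovery.

suppressMessages(library(hcmotif))

ind <- "results/inputs"
expd <- "results/expression"
outd <- "results/motif"
dir.create(outd, recursive = TRUE, showWarnings = FALSE)

pwm <- read_pwm_meme(file.path(ind, "motif.meme"))
tss <- read_tss_table(file.path(ind, "tss_a.bed"))
hc_set <- read_gene_list(file.path(expd, "hc_enriched.txt"))
background <- read_gene_list(file.path(expd, "expressed_genes.txt"))

prom <- extract_promoters(file.path(ind, "genome_a.fa"), tss, 1000L, 500L)
hits <- scan_promoters(pwm, prom[intersect(background, names(prom))])
write.table(hits, file.path(outd, "motif_hits.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

enr <- motif_enrichment_test(intersect(hc_set, background), background,
                             hits = hits)
cat(sprintf("Full window: motif in %d of %d HC-elevated promoters (background %d/%d), EF = %.2f, p = %.3g\n",
            enr$k, enr$n, enr$K, enr$N, enr$enrichment_factor, enr$p))
write_record_json(unclass(enr), file.path(outd, "enrichment_full.json"))

hist <- positional_distribution(hits[hits$gene %in% hc_set, ], 1000L, 500L)
nw <- detect_tss_peak_and_narrow(hist)
cat(sprintf("Best-hit positions peak in [%d, %d) nt around the TSS\n",
            nw$mode_start, nw$mode_end))
write.table(data.frame(bin_start = hist$breaks, count = hist$counts),
            file.path(outd, "position_histogram.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

prom_n <- extract_promoters(file.path(ind, "genome_a.fa"), tss,
                            nw$upstream, nw$downstream)
hits_n <- scan_promoters(pwm, prom_n[intersect(background, names(prom_n))])
enr_n <- motif_enrichment_test(intersect(hc_set, background), background,
                               hits = hits_n)
cat(sprintf("Narrowed window (-%d..+%d): EF = %.2f, p = %.3g\n",
            nw$upstream, nw$downstream, enr_n$enrichment_factor, enr_n$p))
write_record_json(unclass(enr_n), file.path(outd, "enrichment_narrowed.json"))

putative <- sort(intersect(unique(hits_n$gene), hc_set))
cat(length(putative), "putative direct targets",
    "(HC-elevated, motif in the proximal promoter)\n")
write_gene_list(putative, file.path(outd, "putative_targets.txt"))

km <- kmer_discovery(prom, intersect(hc_set, background), background, k = 8L)
cat(sprintf("De-novo discovery: top 8-mer class %s (p = %.3g, Bonferroni-adjusted %.3g), derived consensus %s\n",
            km$top_kmer, km$table$p[1], km$table$p_adjusted[1],
            pwm_consensus(km$pwm)))
write.table(km$table, file.path(outd, "kmer_table.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
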