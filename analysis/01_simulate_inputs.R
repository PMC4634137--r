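#!/usr/bin/env Rscript

# Stage 1: build the synthetic inner-ear study.
#
# Generates the full ground-truthed input bundle at the default study
# conditions: 5000 genes; two organs (cochlea, vestibule) x three sorted
# cell types (HC, ENHC, NEC) x three replicates on the intensity platform;
# an HC/ENHC count platform; a 200-gene hair-cell regulon whose promoters
# carry an X-box-like motif concentrated ~50 nt upstream of the TSS; 30
# strict markers per cell type; two ChIP target lists; and a second species
# with 80% regulon conservation.

suppressMessages(library(hcmotif))

seed <- 1L
params <- sim_params(seed = seed)
out <- "results/inputs"

truth <- simulate_inputs(params, out)

cat("Simulated study written to", out, "\n")
cat("  genes:            ", params$n_genes, "\n")
cat("  regulon:          ", length(truth$regulon), "genes, motif planted in",
    length(truth$genome_a$motif_positions), "promoters overall\n")
cat("  markers per type: ", params$n_markers_per_type, "\n")
cat("  ChIP lists:       ", length(truth$chip_targets$chip1), "and",
    length(truth$chip_targets$chip2), "genes\n")
cat("  conserved regulon:", length(truth$orthologs$conserved), "genes\n")
cat("Ground truth is under", file.path(out, "truth"), "\n")
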