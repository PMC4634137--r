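#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis with the defaults used
#' throughout: detection p < 0.01 in >= 2 samples, count floor 20, 3-fold
#' HC/ENHC threshold, marker thresholds 250/120, FDR 5%, 12 expression
#' patterns, scan threshold 0.8 of the maximum log-odds, promoter window
#' -1000..+500 narrowed to -200..+100.
#'
#' @param input_dir Directory holding the input bundle (the layout written
#'   by \code{\link{simulate_inputs}}).
#' @param out_dir Output directory.
#' @param detection_p,min_detected Detection filter settings.
#' @param floor_value Count floor after quantile normalization.
#' @param fold HC/ENHC fold threshold.
#' @param marker_high,marker_low Marker-calling thresholds.
#' @param fdr_level ANOVA FDR threshold.
#' @param k_clusters Number of expression patterns.
#' @param theta PWM scan threshold (fraction of maximum score).
#' @param upstream,downstream Full promoter window.
#' @param narrowed_upstream,narrowed_downstream Narrowed window.
#' @param kmer_size K-mer length for de-novo discovery.
#' @param run_kmer Whether to run k-mer discovery (the slowest stage).
#' @param seed Seed for the clustering stage.
#' @return List of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(input_dir, out_dir,
                            detection_p = 0.01, min_detected = 2L,
                            floor_value = 20, fold = 3,
                            marker_high = 250, marker_low = 120,
                            fdr_level = 0.05, k_clusters = 12L,
                            theta = 0.8,
                            upstream = 1000L, downstream = 500L,
                            narrowed_upstream = 200L, narrowed_downstream = 100L,
                            kmer_size = 8L, run_kmer = TRUE, seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes, in order: detection filtering and quantile normalization of the
#' intensity platform; two-way ANOVA differential expression with BH
#' selection; row standardization and pattern clustering; the sample
#' dendrogram; strict marker calling with cross-platform validation; count
#' normalization and the HC-elevated set; promoter extraction and PWM
#' enrichment on the full window; TSS positional analysis and the
#' narrowed-window re-test; k-mer discovery; ChIP-target intersection;
#' cross-species enrichment through the ortholog map; and the HC-enrichment
#' shift test for ChIP targets. Every stage's outputs are written under
#' \code{out_dir} and a run manifest (key numbers at 6 significant digits,
#' configuration, seed) is written and hashed for regression comparison.
#'
#' @param config A \code{\link{pipeline_config}}.
#' @return Invisibly, the report: a named list of all stage results plus
#'   \code{manifest} and \code{manifest_hash}.
#' @export
run_pipeline <- function(config) {
  ind <- config$input_dir
  outd <- config$out_dir
  dir.create(outd, recursive = TRUE, showWarnings = FALSE)
  rep <- list()

  ma <- stage("read_expression", read_expression_table(
    file.path(ind, "microarray.tsv"), file.path(ind, "microarray.design.tsv"),
    file.path(ind, "microarray.tsv.detection")))
  rs <- stage("read_rnaseq", read_expression_table(
    file.path(ind, "rnaseq.tsv"), file.path(ind, "rnaseq.design.tsv")))
  pwm_path <- file.path(ind, "motif.meme")
  if (!file.exists(pwm_path)) stop("pipeline stage 'motif_scan' needs ",
                                   pwm_path, " (PWM in MEME format)")
  pwm <- stage("read_pwm", read_pwm_meme(pwm_path))
  tss_a <- stage("read_tss", read_tss_table(file.path(ind, "tss_a.bed")))
  genome_a <- file.path(ind, "genome_a.fa")

  ma_f <- stage("detection_filter",
                detection_filter(ma, config$detection_p, config$min_detected))
  ma_n <- stage("quantile_normalize", quantile_normalize(ma_f))
  rep$n_probes_input <- nrow(ma$values)
  rep$n_probes_expressed <- nrow(ma_n$values)

  de <- stage("anova_de", anova_de(ma_n, fdr_level = config$fdr_level))
  rep$de <- de
  rep$n_de_selected <- sum(de$selected)
  utils::write.table(de, file.path(outd, "de_table.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  sel <- de$feature_id[de$selected]
  std <- stage("standardize", standardize_rows(ma_n$values[sel, , drop = FALSE]))
  k_use <- min(config$k_clusters, length(sel))
  clus <- stage("cluster_patterns",
                cluster_patterns(std, k = k_use, seed = config$seed))
  rep$clusters <- clus
  utils::write.table(
    data.frame(feature_id = names(clus$cluster), cluster = unname(clus$cluster)),
    file.path(outd, "clusters.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)

  rep$dendrogram <- stage("sample_dendrogram", sample_dendrogram(ma_n))

  markers <- stage("call_markers",
                   call_markers(ma_n, config$marker_high, config$marker_low))
  rep$markers <- markers
  rep$n_markers_hc <- sum(markers$cell_type == "HC")
  utils::write.table(markers, file.path(outd, "markers.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  rs_n <- stage("normalize_counts", normalize_counts(rs, config$floor_value))
  rs_expressed <- rownames(rs$values)[rowSums(rs$values) >= config$floor_value]
  rep$n_rnaseq_expressed <- length(rs_expressed)
  rep$marker_validation <- stage("validate_markers",
                                 validate_markers(markers, rs_n))

  hc_set <- stage("hc_enriched_set",
                  intersect(hc_enriched_set(rs_n, config$fold), rs_expressed))
  rep$hc_enriched <- hc_set
  rep$n_hc_enriched <- length(hc_set)
  write_gene_list(hc_set, file.path(outd, "hc_enriched.txt"))

  background <- rs_expressed
  promoters <- stage("extract_promoters",
                     extract_promoters(genome_a, tss_a,
                                       config$upstream, config$downstream))
  hits <- stage("motif_scan",
                scan_promoters(pwm, promoters[intersect(background,
                                                        names(promoters))],
                               theta = config$theta))
  utils::write.table(hits, file.path(outd, "motif_hits.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  enr_full <- stage("motif_enrichment", motif_enrichment_test(
    intersect(hc_set, background), background, hits = hits))
  rep$motif_enrichment_full <- enr_full
  write_record_json(unclass(enr_full), file.path(outd, "motif_enrichment_full.json"))

  target_hits <- hits[hits$gene %in% hc_set, , drop = FALSE]
  hist <- stage("positional_distribution",
                positional_distribution(target_hits, config$upstream,
                                        config$downstream))
  utils::write.table(data.frame(bin_start = hist$breaks, count = hist$counts),
                     file.path(outd, "position_histogram.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  narrow <- stage("detect_tss_peak", detect_tss_peak_and_narrow(
    hist, config$narrowed_upstream, config$narrowed_downstream))
  rep$positional <- list(histogram = hist, narrow = narrow)

  prom_narrow <- stage("extract_promoters_narrow",
                       extract_promoters(genome_a, tss_a,
                                         narrow$upstream, narrow$downstream))
  hits_narrow <- stage("motif_scan_narrow",
                       scan_promoters(pwm, prom_narrow[intersect(background,
                                                                 names(prom_narrow))],
                                      theta = config$theta))
  enr_narrow <- stage("motif_enrichment_narrow", motif_enrichment_test(
    intersect(hc_set, background), background, hits = hits_narrow))
  rep$motif_enrichment_narrowed <- enr_narrow
  write_record_json(unclass(enr_narrow),
                    file.path(outd, "motif_enrichment_narrowed.json"))

  putative <- sort(intersect(unique(hits_narrow$gene), hc_set))
  rep$putative_targets <- putative
  rep$n_putative_targets <- length(putative)
  write_gene_list(putative, file.path(outd, "putative_targets.txt"))

  if (isTRUE(config$run_kmer)) {
    km <- stage("kmer_discovery", kmer_discovery(
      promoters, intersect(hc_set, background), background,
      k = config$kmer_size))
    rep$kmer <- km
    utils::write.table(km$table, file.path(outd, "kmer_table.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  chip1 <- stage("read_chip", read_gene_list(file.path(ind, "chip_targets_1.txt")))
  chip2 <- stage("read_chip", read_gene_list(file.path(ind, "chip_targets_2.txt")))
  universe <- rownames(ma$values)
  rep$chip <- stage("chip_intersection", chip_intersection(
    putative, intersect(chip1, universe), intersect(chip2, universe), universe))

  orth <- stage("read_orthologs", read_ortholog_map(file.path(ind, "orthologs.tsv")))
  tss_b <- stage("read_tss_b", read_tss_table(file.path(ind, "tss_b.bed")))
  prom_b <- stage("extract_promoters_b",
                  extract_promoters(file.path(ind, "genome_b.fa"), tss_b,
                                    config$upstream, config$downstream))
  background_b <- unname(orth[background])
  rep$cross_species <- stage("cross_species", cross_species_test(
    intersect(hc_set, background), orth, background_b,
    promoters_b = prom_b, pwm = pwm, theta = config$theta))
  write_record_json(unclass(rep$cross_species),
                    file.path(outd, "cross_species.json"))

  scores <- stage("hc_enrichment_scores", hc_enrichment_scores(ma_n))
  utils::write.table(scores, file.path(outd, "hc_enrichment_scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  in_chip <- scores$gene %in% chip1
  rep$shift_test <- stage("shift_test", shift_test(
    scores$log2_ratio[in_chip], scores$log2_ratio[!in_chip]))

  panel_path <- file.path(ind, "panel.txt")
  if (file.exists(panel_path)) {
    panel <- read_gene_list(panel_path)
    rep$panel_enrichment <- stage("panel_enrichment", geneset_enrichment(
      intersect(panel, rownames(ma_n$values)), sel, rownames(ma_n$values)))
  }

  rep$manifest <- pipeline_manifest(rep, config)
  write_record_json(rep$manifest, file.path(outd, "manifest.json"))
  rep$manifest_hash <- unname(tools::md5sum(file.path(outd, "manifest.json")))
  rep
}

# key numbers of a run, rounded to 6 significant digits for stable hashing
pipeline_manifest <- function(rep, config) {
  s6 <- function(v) signif(v, 6L)
  m <- list(
    seed = config$seed,
    n_probes_expressed = rep$n_probes_expressed,
    n_de_selected = rep$n_de_selected,
    cluster_sizes = sort(rep$clusters$sizes),
    n_markers_hc = rep$n_markers_hc,
    marker_fraction_confirmed = s6(rep$marker_validation$fraction_confirmed),
    marker_mean_fold = s6(rep$marker_validation$mean_fold),
    n_hc_enriched = rep$n_hc_enriched,
    motif_full = lapply(rep$motif_enrichment_full[c("N", "K", "n", "k")], identity),
    motif_full_p = s6(rep$motif_enrichment_full$p),
    motif_full_ef = s6(rep$motif_enrichment_full$enrichment_factor),
    motif_narrowed_p = s6(rep$motif_enrichment_narrowed$p),
    motif_narrowed_ef = s6(rep$motif_enrichment_narrowed$enrichment_factor),
    position_mode_start = rep$positional$narrow$mode_start,
    n_putative_targets = rep$n_putative_targets,
    chip_bound_any = rep$chip$n_bound_any,
    chip_bound_both = rep$chip$n_bound_both,
    cross_species_p = s6(rep$cross_species$p),
    cross_species_ef = s6(rep$cross_species$enrichment_factor),
    shift_p = s6(rep$shift_test$p),
    shift_median_difference = s6(rep$shift_test$median_difference))
  if (!is.null(rep$kmer)) {
    m$top_kmer <- rep$kmer$top_kmer
    m$top_kmer_p_adjusted <- s6(rep$kmer$table$p_adjusted[1L])
  }
  if (!is.null(rep$panel_enrichment)) {
    m$panel_p <- s6(rep$panel_enrichment$p)
    m$panel_k <- rep$panel_enrichment$k
  }
  m
}
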