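small_params <- function(...) {
  defaults <- list(n_genes = 120L, n_regulon = 20L, n_markers_per_type = 5L,
                   upstream = 120L, downstream = 60L, flank = 10L)
  do.call(sim_params, utils::modifyList(defaults, list(...)))
}

test_that("truth generation is reproducible, disjoint, and validated", {
  p <- small_params(seed = 5L)
  t1 <- generate_truth(p)
  t2 <- generate_truth(p)
  expect_identical(t1, t2)
  t3 <- generate_truth(small_params(seed = 6L))
  expect_false(identical(t1$regulon, t3$regulon))

  expect_length(t1$regulon, 20L)
  expect_true(all(t1$regulon %in% t1$genes))
  all_markers <- unlist(t1$markers, use.names = FALSE)
  expect_identical(anyDuplicated(c(t1$regulon, all_markers)), 0L)

  expect_error(sim_params(n_genes = 10L, n_regulon = 20L), "exceeds")
  expect_error(sim_params(motif_insert_rate_target = 1.5), "probabilities")
  expect_error(sim_params(n_replicates = 1L), "replicates")
})

test_that("expression model plants the designed effects exactly at zero noise", {
  p <- small_params(seed = 2L, noise_sd = 0, celltype_effect = 2.0)
  tr <- generate_truth(p)
  ma <- generate_expression_matrix(p, tr, "microarray")
  hc <- ma$design$cell_type == "HC"
  en <- ma$design$cell_type == "ENHC"
  ratio <- rowMeans(ma$values[tr$regulon, hc]) / rowMeans(ma$values[tr$regulon, en])
  expect_equal(unname(ratio), rep(2^2.0, length(tr$regulon)))
  # markers sit at marker_on in their own type, marker_off elsewhere
  m_hc <- tr$markers[["HC"]]
  expect_equal(unname(ma$values[m_hc, hc][, 1]), rep(p$marker_on, length(m_hc)))
  expect_equal(unname(ma$values[m_hc, !hc][, 1]), rep(p$marker_off, length(m_hc)))

  # no effects and no noise -> identical columns per gene
  p0 <- small_params(seed = 2L, noise_sd = 0, celltype_effect = 0,
                     organ_effect = 0, n_regulon = 0L,
                     n_markers_per_type = 0L, organ_frac = 0)
  tr0 <- generate_truth(p0)
  ma0 <- generate_expression_matrix(p0, tr0, "microarray")
  expect_true(all(ma0$values == ma0$values[, 1L]))
})

test_that("detection p-values separate cleanly at the detection threshold", {
  p <- small_params(seed = 3L)
  tr <- generate_truth(p)
  ma <- generate_expression_matrix(p, tr, "microarray")
  expect_true(all(ma$detection_p[ma$values > p$detect_threshold] < 0.01))
  expect_true(all(ma$detection_p[ma$values <= p$detect_threshold] > 0.05))
})

test_that("genome generation is byte-deterministic and plants verifiable instances", {
  p <- small_params(seed = 4L, motif_insert_rate_target = 1,
                    motif_insert_rate_background = 0)
  tr <- generate_truth(p)
  g1 <- generate_genome_and_promoters(p, tr)
  g2 <- generate_genome_and_promoters(p, tr)
  expect_identical(as.character(g1$genome), as.character(g2$genome))

  # with rates (1, 0): all regulon genes planted, no background gene
  expect_setequal(names(g1$motif_positions), tr$regulon)

  # the recorded instance is recoverable from the extracted promoter at the
  # recorded position, on both strands
  prom <- extract_promoters(g1$genome, g1$tss, p$upstream, p$downstream)
  for (g in names(g1$motif_positions)) {
    pos <- g1$motif_positions[[g]]
    idx <- pos + p$upstream + 1L
    w <- nchar(g1$motif_instances[[g]])
    expect_identical(substr(as.character(prom[[g]]), idx, idx + w - 1L),
                     g1$motif_instances[[g]])
  }

  # positions obey the clamped window
  w <- ncol(tr$pwm_used$probs)
  expect_true(all(g1$motif_positions >= -p$upstream))
  expect_true(all(g1$motif_positions <= p$downstream - w))

  # zero positional spread -> all instances exactly at the mean
  p0 <- small_params(seed = 4L, motif_insert_rate_target = 1,
                     motif_insert_rate_background = 0, motif_position_sd = 0)
  tr0 <- generate_truth(p0)
  g0 <- generate_genome_and_promoters(p0, tr0)
  expect_true(all(g0$motif_positions == p0$motif_position_mean))

  expect_error(generate_genome_and_promoters(
    small_params(seed = 1L, upstream = 5L, downstream = 5L),
    tr), "wider")
})

test_that("ChIP lists hit the regulon at the designed sensitivity", {
  p1 <- small_params(seed = 9L, chip_sensitivity = 1, chip_extra = 0L)
  tr <- generate_truth(p1)
  expect_setequal(generate_chip_targets(p1, tr), tr$regulon)

  p0 <- small_params(seed = 9L, chip_sensitivity = 0, chip_extra = 5L)
  chip0 <- generate_chip_targets(p0, generate_truth(p0))
  expect_length(chip0, 5L)
  expect_length(intersect(chip0, generate_truth(p0)$regulon), 0L)

  # binomial expectation of |chip n regulon| over 100 seeds
  sens <- 0.65
  overlaps <- vapply(1:100, function(s) {
    ps <- small_params(seed = s, chip_sensitivity = sens, chip_extra = 10L)
    ts <- generate_truth(ps)
    length(intersect(generate_chip_targets(ps, ts), ts$regulon))
  }, numeric(1))
  n_trials <- 100 * 20  # seeds x regulon size
  ci <- stats::qbinom(c(0.0005, 0.9995), n_trials, sens) / n_trials
  expect_gt(mean(overlaps) / 20, ci[1])
  expect_lt(mean(overlaps) / 20, ci[2])
})

test_that("ortholog maps are one-to-one with the designed conservation", {
  p <- small_params(seed = 12L, ortholog_conservation = 0.5)
  tr <- generate_truth(p)
  orth <- generate_ortholog_map(p, tr)
  expect_identical(anyDuplicated(orth$map), 0L)
  expect_identical(anyDuplicated(names(orth$map)), 0L)
  expect_length(orth$map, p$n_genes)
  expect_length(orth$conserved, round(0.5 * p$n_regulon))
  expect_true(all(orth$conserved %in% tr$regulon))
  # conserved genes' B promoters carry the motif at the target rate,
  # everything else at the background rate
  p1 <- small_params(seed = 13L, ortholog_conservation = 1,
                     motif_insert_rate_target = 1,
                     motif_insert_rate_background = 0)
  tr1 <- generate_truth(p1)
  orth1 <- generate_ortholog_map(p1, tr1)
  expect_setequal(names(orth1$motif_positions),
                  unname(orth1$map[tr1$regulon]))
})

test_that("simulate_inputs writes a complete, reloadable bundle", {
  dir <- withr::local_tempdir()
  p <- small_params(seed = 21L)
  truth <- simulate_inputs(p, dir)
  expected <- c("microarray.tsv", "microarray.design.tsv", "rnaseq.tsv",
                "rnaseq.design.tsv", "genome_a.fa", "tss_a.bed",
                "genome_b.fa", "tss_b.bed", "motif.meme", "chip_targets_1.txt",
                "chip_targets_2.txt", "orthologs.tsv", "panel.txt")
  expect_true(all(file.exists(file.path(dir, expected))))
  expect_length(readLines(file.path(dir, "truth", "regulon.txt")),
                p$n_regulon)
  ma <- read_expression_table(file.path(dir, "microarray.tsv"),
                              file.path(dir, "microarray.design.tsv"))
  expect_equal(ma$values, truth$microarray$values)
  tss <- read_tss_table(file.path(dir, "tss_a.bed"))
  expect_identical(nrow(tss), p$n_genes)
})
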