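test_that("log-odds scoring treats consensus, uniform PWMs and Ns as defined", {
  pwm <- consensus_pwm("ACG")
  expect_equal(pwm_log_odds(pwm, "ACG"), pwm_max_score(pwm))
  uni <- new_pwm(matrix(0.25, 4, 3), name = "uniform")
  expect_equal(pwm_log_odds(uni, "ACG"), 0)
  expect_equal(pwm_log_odds(uni, "TTT"), 0)
  expect_equal(pwm_log_odds(pwm, "NNN"), 0)
  expect_error(pwm_log_odds(pwm, "ACGT"), "width")
})

test_that("scanning reports all matches in promoter coordinates on both strands", {
  pwm <- consensus_pwm("ACG")
  seqs <- c(gene1 = "TACGACGT")
  fwd <- scan_promoters(pwm, as_promoters(seqs), theta = 1, both_strands = FALSE)
  expect_identical(nrow(fwd), 2L)
  expect_identical(fwd$position, c(1L, 4L))
  expect_true(all(fwd$strand == "+"))

  both <- scan_promoters(pwm, as_promoters(seqs), theta = 1)
  # adds the CGT at index 6 (reverse-strand ACG)
  expect_identical(nrow(both), 3L)
  expect_identical(both$position[both$strand == "-"], 5L)

  # rel_start anchors the coordinates
  shifted <- scan_promoters(pwm, as_promoters(seqs, rel_start = -4L), theta = 1,
                            both_strands = FALSE)
  expect_identical(shifted$position, c(-3L, 0L))
})

test_that("scanning is strand-symmetric and monotone in the threshold", {
  set.seed(17)
  pwm <- xbox_pwm()
  seqs <- vapply(1:40, function(i)
    paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = ""), "")
  names(seqs) <- sprintf("g%02d", 1:40)
  prom <- as_promoters(seqs)
  prom_rc <- as_promoters(stats::setNames(
    as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs))),
    names(seqs)))
  h1 <- scan_promoters(pwm, prom, theta = 0.6)
  h2 <- scan_promoters(pwm, prom_rc, theta = 0.6)
  expect_identical(sort(unique(h1$gene)), sort(unique(h2$gene)))
  expect_identical(nrow(h1), nrow(h2))

  hits_hi <- scan_promoters(pwm, prom, theta = 0.8)
  expect_true(all(hits_hi$gene %in% h1$gene))
  expect_lte(nrow(hits_hi), nrow(h1))

  # cross-check against the reference scanner on the forward strand
  lo2 <- log2(pwm$probs / pwm$background)
  ref_counts <- vapply(seqs, function(s) length(Biostrings::matchPWM(
    lo2, s, min.score = 0.8 * pwm_max_score(pwm))), numeric(1))
  got <- table(factor(hits_hi$gene[hits_hi$strand == "+"], levels = names(seqs)))
  expect_equal(unname(as.numeric(got)), unname(ref_counts))
})

test_that("hypergeometric tail matches enumeration and rejects bad counts", {
  expect_equal(hypergeom_tail(10, 4, 5, 3), 66 / 252, tolerance = 1e-12)
  expect_equal(hypergeom_tail(6, 3, 3, 3), 1 / 20, tolerance = 1e-12)
  expect_equal(hypergeom_tail(100, 10, 10, 0), 1)
  expect_error(hypergeom_tail(10, 4, 5, 6), "inconsistent")
  expect_error(hypergeom_tail(10, 12, 5, 3), "inconsistent")
  for (N in c(7, 9)) for (K in c(2, 5)) for (n in c(3, 6)) {
    for (k in 0:min(K, n))
      if (n - k <= N - K)
        expect_equal(hypergeom_tail(N, K, n, k), hyper_enum_oracle(N, K, n, k),
                     tolerance = 1e-12)
  }
})

test_that("motif enrichment counts presence per gene and computes EF", {
  genes <- sprintf("g%04d", 1:10000)
  presence <- stats::setNames(rep(FALSE, 10000), genes)
  presence[1:1000] <- TRUE  # K = 1000
  targets <- c(genes[1:30], genes[5001:5070])  # k = 30, n = 100
  res <- motif_enrichment_test(targets, genes, hits = presence)
  expect_equal(res$enrichment_factor, 3.0)
  expect_identical(c(res$N, res$K, res$n, res$k), c(10000L, 1000L, 100L, 30L))
  expect_equal(res$p, hypergeom_tail(10000, 1000, 100, 30))

  expect_error(motif_enrichment_test(c("nope"), genes, hits = presence),
               "subset")
  none <- stats::setNames(logical(0), character(0))
  expect_error(motif_enrichment_test(genes[1], genes, hits = none),
               "no target gene")
})

test_that("positional distribution bins best hits and narrowing finds the mode", {
  hits <- data.frame(gene = c("a", "a", "b"), position = c(-50L, -400L, -45L),
                     strand = "+", score = c(10, 5, 8))
  h <- positional_distribution(hits, upstream = 1000L, downstream = 500L)
  nonzero <- h$breaks[h$counts > 0]
  expect_identical(nonzero, -50L)  # both best hits inside [-50, -25)
  expect_identical(sum(h$counts), 2L)
  expect_identical(unname(h$best_positions["a"]), -50L)

  nw <- detect_tss_peak_and_narrow(h)
  expect_identical(nw$upstream, 200L)
  expect_identical(nw$downstream, 100L)
  expect_identical(nw$mode_start, -50L)
  expect_false(nw$tie)

  empty <- positional_distribution(hits[0, ], 100L, 50L)
  expect_true(all(empty$counts == 0L))
  expect_error(detect_tss_peak_and_narrow(empty), "empty")

  flat <- list(breaks = c(-50, -25), counts = c(2L, 2L))
  expect_true(detect_tss_peak_and_narrow(flat)$tie)
})

test_that("k-mer discovery pinpoints a planted word with the exact p-value", {
  set.seed(23)
  bg <- vapply(1:10, function(i)
    paste(sample(c("A", "C"), 60, TRUE), collapse = ""), "")
  tg <- vapply(1:10, function(i) {
    s <- paste(sample(c("A", "C"), 60, TRUE), collapse = "")
    substr(s, 20, 27) <- "GTTGCCAT"
    s
  }, "")
  seqs <- c(tg, bg)
  names(seqs) <- sprintf("g%02d", 1:20)
  prom <- as_promoters(seqs)
  res <- kmer_discovery(prom, names(seqs)[1:10], names(seqs), k = 8L)
  planted_class <- hcmotif:::kmer_string_to_class("GTTGCCAT")
  expect_identical(res$top_class, planted_class)
  expect_equal(res$table$p[1], 1 / choose(20, 10), tolerance = 1e-12)
  # derived PWM consensus is the canonical form of the planted word
  expect_identical(pwm_consensus(res$pwm),
                   hcmotif:::kmer_code_to_string(planted_class, 8L))
  expect_error(kmer_discovery(prom, "g99", names(seqs)), "subset")
})

test_that("k-mer classes collapse reverse complements and honor palindromes", {
  expect_identical(hcmotif:::kmer_string_to_class("GTTGCCAT"),
                   hcmotif:::kmer_string_to_class("ATGGCAAC"))
  # palindrome is its own class
  expect_identical(hcmotif:::kmer_string_to_class("GCCATGGC"),
                   hcmotif:::kmer_string_to_class("GCCATGGC"))
  s <- c(one = "AAGCCATGGCAA")
  res <- kmer_discovery(as_promoters(s), "one", "one", k = 8L)
  expect_true(hcmotif:::kmer_string_to_class("GCCATGGC") %in% res$table$class)
})

test_that("cross-species test with an identity map reproduces the direct test", {
  set.seed(29)
  genes <- sprintf("g%03d", 1:200)
  seqs <- stats::setNames(vapply(seq_along(genes), function(i)
    paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = ""), ""), genes)
  prom <- as_promoters(seqs)
  pwm <- xbox_pwm()
  targets <- genes[1:40]
  direct <- motif_enrichment_test(targets, genes, promoters = prom, pwm = pwm,
                                  theta = 0.55)
  idmap <- stats::setNames(genes, genes)
  crossed <- cross_species_test(targets, idmap, genes, promoters_b = prom,
                                pwm = pwm, theta = 0.55)
  expect_identical(crossed[c("N", "K", "n", "k")], direct[c("N", "K", "n", "k")])
  expect_equal(crossed$p, direct$p)
  expect_identical(crossed$n_unmapped, 0L)
  expect_error(cross_species_test(targets, stats::setNames("zz", "absent"),
                                  genes, promoters_b = prom, pwm = pwm),
               "no target gene maps")
})
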