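test_that("detection filter keeps features detected in enough samples", {
  design <- tiny_design(r = 3L, organs = "cochlea", cell_types = "HC")
  vals <- matrix(100, nrow = 3, ncol = 3,
                 dimnames = list(c("two", "one", "none"), design$sample_id))
  detp <- rbind(two = c(0.001, 0.005, 0.9),
                one = c(0.001, 0.5, 0.9),
                none = c(0.5, 0.5, 0.9))
  colnames(detp) <- design$sample_id
  x <- xpr(vals, design, detection_p = detp)
  f <- detection_filter(x)
  expect_identical(rownames(f$values), "two")
  # all detected everywhere -> identity
  x2 <- xpr(vals, design, detection_p = detp * 0 + 0.001)
  expect_identical(rownames(detection_filter(x2)$values), rownames(vals))
  x3 <- xpr(vals, design)
  expect_error(detection_filter(x3), "value-threshold")
})

test_that("quantile normalization equalizes column distributions and keeps ranks", {
  m <- cbind(s1 = c(1, 3, 5), s2 = c(2, 4, 8))
  out <- quantile_normalize(m)
  expect_equal(unname(out), cbind(c(1.5, 3.5, 6.5), c(1.5, 3.5, 6.5)))

  set.seed(42)
  for (i in 1:5) {
    r <- matrix(stats::rexp(60, 1 / 50), nrow = 10)
    qn <- quantile_normalize(r)
    ref <- sort(qn[, 1])
    for (j in 2:ncol(qn)) expect_equal(sort(qn[, j]), ref)
    for (j in seq_len(ncol(qn)))
      expect_identical(order(qn[, j]), order(r[, j]))
    expect_equal(quantile_normalize(qn), qn)  # idempotent
  }
  # identical columns are left unchanged
  same <- cbind(c(2, 7, 1), c(2, 7, 1))
  expect_equal(unname(quantile_normalize(same)), same)
  expect_warning(quantile_normalize(matrix(1:3, ncol = 1)), "single sample")
})

test_that("count normalization floors after quantile normalization", {
  m <- cbind(a = c(5, 20, 100), b = c(5, 20, 100))
  out <- normalize_counts(m, floor_value = 20)
  expect_equal(unname(out[, 1]), c(20, 20, 100))
  expect_true(min(normalize_counts(matrix(stats::rpois(40, 30), ncol = 4),
                                   floor_value = 20)) >= 20)
  # floor 0 leaves pure quantile normalization
  r <- matrix(stats::rpois(40, 30), ncol = 4)
  expect_equal(normalize_counts(r, floor_value = 0), quantile_normalize(r))
})

test_that("BH adjustment matches hand-computed step-up values", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(c(0.005, 0.5)), c(0.01, 0.5))
  expect_equal(bh_fdr(0.03), 0.03)
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
  # monotone in raw-p rank
  set.seed(1)
  p <- stats::runif(50)
  q <- bh_fdr(p)
  expect_true(all(diff(q[order(p)]) >= -1e-12))
})

test_that("two-way ANOVA handles degenerate features as designed", {
  design <- tiny_design(r = 3L)
  # constant feature: F = 0, p = 1, never selected
  vals <- matrix(50, nrow = 1, ncol = 18, dimnames = list("const", NULL))
  de <- anova_de(tiny_xpr(vals))
  expect_equal(de$F_cell_type, 0)
  expect_equal(de$p_organ, 1)
  expect_false(de$selected)

  # noiseless purely additive structure: zero interaction SS
  mu <- log2(50) + 2 * (design$cell_type == "HC") + 1 * (design$organ == "cochlea")
  vals2 <- matrix(2^mu - 1, nrow = 1, dimnames = list("additive", NULL))
  de2 <- anova_de(tiny_xpr(vals2))
  expect_lt(de2$p_cell_type, 1e-15)  # perfect fit
  expect_equal(de2$p_interaction, 1) # no interaction signal
})

test_that("two-way ANOVA agrees with classical per-feature type-II fits", {
  skip_if_not_installed("car")
  design <- tiny_design(r = 3L)
  set.seed(31)
  for (i in 1:10) {
    vals <- matrix(2^stats::rnorm(18, 6, 1), nrow = 1,
                   dimnames = list("g", NULL))
    de <- anova_de(tiny_xpr(vals))
    y <- log2(vals[1, ] + 1)
    fit <- stats::lm(y ~ factor(design$cell_type) * factor(design$organ))
    a <- car::Anova(fit, type = 2)
    expect_equal(de$F_cell_type, a$`F value`[1], tolerance = 1e-10)
    expect_equal(de$F_organ, a$`F value`[2], tolerance = 1e-10)
    expect_equal(de$F_interaction, a$`F value`[3], tolerance = 1e-10)
    expect_equal(de$p_cell_type, a$`Pr(>F)`[1], tolerance = 1e-10)
  }
})

test_that("row standardization hits mean 0, sd 1 and flags constants", {
  m <- rbind(a = c(1, 2, 3), b = c(5, 5, 5))
  s <- standardize_rows(m)
  expect_equal(unname(s["a", ]), c(-1, 0, 1))
  expect_equal(unname(s["b", ]), c(0, 0, 0))
  expect_identical(unname(attr(s, "constant")), c(FALSE, TRUE))
  s2 <- standardize_rows(s[1, , drop = FALSE])
  expect_equal(unname(s2[1, ]), unname(s[1, ]))  # idempotent
})

test_that("pattern clustering recovers well-separated profiles deterministically", {
  set.seed(8)
  up <- matrix(rep(c(1, 1, -1, -1), each = 10), nrow = 10) +
    stats::rnorm(40, 0, 0.05)
  down <- -up
  m <- rbind(up, down)
  rownames(m) <- sprintf("f%02d", 1:20)
  cl <- cluster_patterns(m, k = 2L, seed = 3L)
  expect_identical(length(unique(cl$cluster[1:10])), 1L)
  expect_identical(length(unique(cl$cluster[11:20])), 1L)
  expect_false(cl$cluster[1] == cl$cluster[11])
  cl2 <- cluster_patterns(m, k = 2L, seed = 3L)
  expect_identical(cl$cluster, cl2$cluster)
  one <- cluster_patterns(m, k = 1L, seed = 3L)
  expect_equal(unname(one$centers[1, ]), unname(colMeans(m)))
  expect_error(cluster_patterns(m, k = 50L), "exceeds")
})

test_that("sample dendrogram is average linkage on correlation distance", {
  set.seed(91)
  m <- matrix(stats::rnorm(300), nrow = 50)
  colnames(m) <- paste0("s", 1:6)
  hc <- sample_dendrogram(m)
  # oracle: manual average-linkage on the same distance matrix
  d <- as.matrix(1 - stats::cor(m))
  oracle <- stats::hclust(stats::as.dist(d), method = "average")
  expect_equal(hc$height, oracle$height)
  expect_true(all(diff(hc$height) >= -1e-12))

  # duplicated samples merge first at height 0
  m2 <- cbind(m, s7 = m[, 1])
  hc2 <- sample_dendrogram(m2)
  expect_equal(hc2$height[1], 0, tolerance = 1e-12)
  first <- sort(abs(hc2$merge[1, ]))
  expect_identical(colnames(m2)[first], c("s1", "s7"))

  m3 <- cbind(m, flat = rep(1, 50))
  expect_error(sample_dendrogram(m3), "flat")
})

test_that("HC-elevated set applies the fold rule per organ with OR logic", {
  design <- tiny_design(r = 2L, cell_types = c("HC", "ENHC"))
  # genes: clear pass, exact boundary, vestibule-only pass, clear fail
  build <- function(hc_c, en_c, hc_v, en_v)
    c(hc_c, hc_c, en_c, en_c, hc_v, hc_v, en_v, en_v)
  vals <- rbind(pass = build(60, 20, 30, 30),
                boundary = build(60, 20.0000001, 30, 30),
                vest_only = build(30, 30, 90, 25),
                fail = build(40, 20, 40, 25))
  vals["boundary", ] <- build(60, 20, 30, 30)  # ratio exactly 3
  x <- tiny_xpr(vals, design)
  got <- hc_enriched_set(x, fold = 3)
  expect_setequal(got, c("pass", "boundary", "vest_only"))
  bad <- tiny_xpr(vals, design)
  bad$design$cell_type <- "NEC"
  expect_error(hc_enriched_set(bad), "HC and ENHC")
})

test_that("marker calling applies the strict high/low rule per scope", {
  design <- tiny_design(r = 3L)
  base <- matrix(100, nrow = 4, ncol = 18,
                 dimnames = list(c("marker", "leaky", "weak", "cochlear"), NULL))
  hc <- design$cell_type == "HC"
  hc_c <- hc & design$organ == "cochlea"
  base["marker", ] <- 110; base["marker", hc] <- c(300, 320, 310, 300, 320, 310)
  base["leaky", ] <- 110;  base["leaky", hc] <- c(300, 320, 310, 300, 320, 310)
  base["leaky", which(!hc)[1]] <- 130          # one non-target sample too high
  base["weak", ] <- 110;   base["weak", hc] <- 240  # target mean too low
  base["cochlear", ] <- 50; base["cochlear", hc_c] <- c(400, 410, 390)
  x <- tiny_xpr(base, design)
  mk <- call_markers(x)
  expect_setequal(mk$gene, c("marker", "cochlear"))
  expect_identical(mk$organ_scope[mk$gene == "marker"], "both")
  expect_identical(mk$organ_scope[mk$gene == "cochlear"], "cochlea_only")
  expect_identical(mk$cell_type, c("HC", "HC"))

  # invariant to column order
  perm <- sample(ncol(base))
  xp <- xpr(base[, perm], design[perm, ])
  mkp <- call_markers(xp)
  expect_identical(mkp[order(mkp$gene), c("gene", "cell_type", "organ_scope")],
                   mk[order(mk$gene), c("gene", "cell_type", "organ_scope")])
})

test_that("marker validation computes cross-platform folds and exclusions", {
  markers <- data.frame(gene = c("m1", "m2", "absent"), cell_type = "HC",
                        organ_scope = "both", target_mean = 300,
                        max_other = 100)
  design2 <- tiny_design(r = 2L, cell_types = c("HC", "ENHC"))
  vals <- rbind(m1 = c(200, 200, 20, 20, 200, 200, 20, 20),
                m2 = c(30, 30, 20, 20, 30, 30, 20, 20))
  y <- tiny_xpr(vals, design2)
  v <- validate_markers(markers, y, fold_threshold = 2)
  expect_equal(v$per_marker$fold[v$per_marker$gene == "m1"], 10)
  expect_equal(v$per_marker$fold[v$per_marker$gene == "m2"], 1.5)
  expect_identical(v$n_excluded, 1L)
  expect_equal(v$fraction_confirmed, 0.5)
  expect_equal(v$mean_fold, mean(c(10, 1.5)))
})
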