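#' Filter features by detection p-values
#'
#' Keeps features detected (detection p below \code{p_threshold}) in at
#' least \code{min_samples} samples, preserving feature order. This is the
#' standard "expressed at all" filter applied before normalization of
#' bead-array data.
#'
#' @param x An \code{\link{xpr}} with a detection p-value matrix.
#' @param p_threshold Detection p-value below which a measurement counts as
#'   detected (default 0.01).
#' @param min_samples Minimum number of detected samples (default 2).
#' @return The filtered \code{xpr}.
#' @export
detection_filter <- function(x, p_threshold = 0.01, min_samples = 2L) {
  if (is.null(x$detection_p))
    stop("no detection p-values present; apply a value-threshold filter instead")
  keep <- rowSums(x$detection_p < p_threshold) >= min_samples
  xpr(x$values[keep, , drop = FALSE], x$design,
      detection_p = x$detection_p[keep, , drop = FALSE],
      feature_to_gene = x$feature_to_gene[keep])
}

#' Quantile-normalize a matrix of expression values
#'
#' Forces every column to share one empirical distribution (the per-rank
#' means of the column-sorted input) while preserving within-column ranks;
#' tied values receive the mean of their rank range's reference values.
#' Backed by \code{limma::normalizeQuantiles}.
#'
#' @param m Numeric matrix (features x samples) or an \code{\link{xpr}}.
#' @return Object of the same kind with normalized values.
#' @export
quantile_normalize <- function(m) {
  if (inherits(m, "xpr")) {
    m$values <- quantile_normalize(m$values)
    return(m)
  }
  if (ncol(m) < 2L) {
    warning("single sample: quantile normalization is the identity")
    return(m)
  }
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  out
}

#' Quantile-normalize counts and apply a floor
#'
#' Count-platform normalization: quantile normalization followed by an
#' elementwise floor, which guards fold-change estimates against division by
#' near-zero counts.
#'
#' @param m Numeric matrix or \code{\link{xpr}} of non-negative counts.
#' @param floor_value Floor applied after normalization (default 20).
#' @return Normalized, floored object of the same kind.
#' @export
normalize_counts <- function(m, floor_value = 20) {
  if (inherits(m, "xpr")) {
    m$values <- normalize_counts(m$values, floor_value)
    return(m)
  }
  if (any(m < 0)) stop("counts must be non-negative")
  out <- if (ncol(m) >= 2L) quantile_normalize(m) else m
  pmax(out, floor_value)
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up BH adjustment: monotone in raw-p rank and capped at 1.
#'
#' @param p Vector of p-values in \code{[0, 1]}.
#' @return Adjusted q-values, same length and order.
#' @export
bh_fdr <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

# residual sum of squares per feature for a given model matrix,
# via one QR shared across all features
rss_fit <- function(X, Y) {
  qrX <- qr(X)
  Q <- qr.Q(qrX)[, seq_len(qrX$rank), drop = FALSE]
  pmax(colSums(Y^2) - colSums((crossprod(Q, Y))^2), 0)
}

#' Two-way ANOVA differential expression across features
#'
#' Fits, per feature, a fixed-effects two-way ANOVA of
#' \code{log2(value + log_offset)} on cell type, organ and their
#' interaction, using type-II sums of squares (each main effect adjusted for
#' the other; interaction adjusted for both). P-values are BH-adjusted
#' across features separately per effect, and a feature is selected when any
#' of its three adjusted q-values falls below \code{fdr_level}.
#'
#' The least-squares projections are computed once per model on the shared
#' design and applied to all features simultaneously, so the fit is exact
#' classical ANOVA at matrix scale.
#'
#' @param x An \code{\link{xpr}} with at least one observation per design cell.
#' @param fdr_level FDR threshold for the selected flag (default 0.05).
#' @param log_offset Offset inside the log2 transform (default 1).
#' @return Data frame per feature: F, p and q for \code{cell_type},
#'   \code{organ} and \code{interaction}, plus \code{selected}.
#' @export
anova_de <- function(x, fdr_level = 0.05, log_offset = 1) {
  design <- x$design
  cells <- table(design$cell_type, design$organ)
  if (any(cells < 1L)) stop("every cell_type x organ cell needs >= 1 observation")
  ct <- factor(design$cell_type)
  org <- factor(design$organ)
  Y <- t(log2(x$values + log_offset))  # samples x features
  X_int   <- stats::model.matrix(~1, data = design)
  X_ct    <- stats::model.matrix(~ct)
  X_org   <- stats::model.matrix(~org)
  X_main  <- stats::model.matrix(~ct + org)
  X_full  <- stats::model.matrix(~ct * org)
  rss_ct   <- rss_fit(X_ct, Y)
  rss_org  <- rss_fit(X_org, Y)
  rss_main <- rss_fit(X_main, Y)
  rss_full <- rss_fit(X_full, Y)
  df_ct  <- nlevels(ct) - 1L
  df_org <- nlevels(org) - 1L
  df_int <- df_ct * df_org
  df_res <- nrow(design) - qr(X_full)$rank
  ss_ct  <- pmax(rss_org - rss_main, 0)   # SS(cell_type | organ)
  ss_org <- pmax(rss_ct - rss_main, 0)    # SS(organ | cell_type)
  ss_int <- pmax(rss_main - rss_full, 0)
  tot <- colSums(scale(Y, scale = FALSE)^2)
  eps <- pmax(tot, 1) * 1e-12
  fp <- function(ss, df) {
    ms_res <- rss_full / df_res
    f <- ifelse(ss <= eps & rss_full <= eps, 0, (ss / df) / ms_res)
    f[is.nan(f)] <- 0
    p <- ifelse(is.infinite(f), 0, stats::pf(f, df, df_res, lower.tail = FALSE))
    p[f == 0 & rss_full <= eps] <- 1
    list(f = f, p = p)
  }
  a_ct <- fp(ss_ct, df_ct); a_org <- fp(ss_org, df_org); a_int <- fp(ss_int, df_int)
  res <- data.frame(
    feature_id = rownames(x$values),
    F_cell_type = a_ct$f, p_cell_type = a_ct$p, q_cell_type = bh_fdr(a_ct$p),
    F_organ = a_org$f, p_organ = a_org$p, q_organ = bh_fdr(a_org$p),
    F_interaction = a_int$f, p_interaction = a_int$p,
    q_interaction = bh_fdr(a_int$p),
    stringsAsFactors = FALSE)
  res$selected <- pmin(res$q_cell_type, res$q_organ, res$q_interaction) < fdr_level
  rownames(res) <- NULL
  res
}

#' Standardize matrix rows to mean 0, s.d. 1
#'
#' Uses the sample standard deviation (n - 1 denominator). Constant rows are
#' mapped to all zeros and flagged in the \code{"constant"} attribute.
#'
#' @param m Numeric matrix.
#' @return Standardized matrix with a logical \code{"constant"} attribute.
#' @export
standardize_rows <- function(m) {
  mu <- rowMeans(m)
  sd <- apply(m, 1L, stats::sd)
  const <- sd == 0 | !is.finite(sd)
  sd[const] <- 1
  out <- (m - mu) / sd
  out[const, ] <- 0
  attr(out, "constant") <- const
  out
}

#' Cluster standardized expression patterns with seeded k-means
#'
#' Partitions feature profiles into \code{k} expression patterns by k-means
#' (Euclidean distance, many restarts, fixed seed so the assignment is
#' deterministic) and summarizes each cluster by its mean profile and
#' per-sample s.d.
#'
#' @param m Standardized matrix (features x samples).
#' @param k Number of patterns (default 12).
#' @param seed RNG seed.
#' @param nstart Number of k-means restarts (default 50).
#' @return List: \code{cluster} (named assignment), \code{centers},
#'   \code{profile_sd}, \code{sizes}.
#' @export
cluster_patterns <- function(m, k = 12L, seed = 1L, nstart = 50L) {
  if (k > nrow(m)) stop("k exceeds the number of features")
  set.seed(seed)
  if (k == 1L) {
    cl <- stats::setNames(rep(1L, nrow(m)), rownames(m))
    centers <- matrix(colMeans(m), nrow = 1L)
  } else {
    km <- stats::kmeans(m, centers = k, nstart = nstart, iter.max = 100L)
    cl <- stats::setNames(km$cluster, rownames(m))
    centers <- km$centers
  }
  sds <- t(vapply(seq_len(k), function(j) {
    rows <- m[cl == j, , drop = FALSE]
    apply(rows, 2L, stats::sd)
  }, numeric(ncol(m))))
  list(cluster = cl, centers = centers, profile_sd = sds,
       sizes = as.integer(table(factor(cl, levels = seq_len(k)))))
}

#' Average-linkage dendrogram of samples
#'
#' Agglomerative average-linkage clustering of sample columns on the
#' distance \code{1 - Pearson correlation}, the standard overall-similarity
#' view of a multi-condition expression study.
#'
#' @param m Numeric matrix (features x samples) or an \code{\link{xpr}}.
#' @return An \code{hclust} object.
#' @export
sample_dendrogram <- function(m) {
  if (inherits(m, "xpr")) m <- m$values
  sds <- apply(m, 2L, stats::sd)
  if (any(sds == 0))
    stop("constant sample column (correlation undefined): ",
         colnames(m)[which(sds == 0)[1L]])
  d <- stats::as.dist(1 - stats::cor(m))
  stats::hclust(d, method = "average")
}

#' Genes with HC-elevated expression
#'
#' A gene qualifies when its replicate-mean HC expression is at least
#' \code{fold} times its replicate-mean ENHC expression in at least one
#' organ (inclusive at the boundary). Intended for floored, normalized
#' count data.
#'
#' @param x An \code{\link{xpr}} with HC and ENHC columns per organ.
#' @param fold Fold threshold (default 3).
#' @return Character vector of qualifying gene ids.
#' @export
hc_enriched_set <- function(x, fold = 3) {
  design <- x$design
  if (!all(c("HC", "ENHC") %in% design$cell_type))
    stop("HC and ENHC columns are required")
  hit <- rep(FALSE, nrow(x$values))
  for (org in unique(design$organ)) {
    hc <- design$cell_type == "HC" & design$organ == org
    en <- design$cell_type == "ENHC" & design$organ == org
    if (!any(hc) || !any(en)) next
    ratio <- rowMeans(x$values[, hc, drop = FALSE]) /
      rowMeans(x$values[, en, drop = FALSE])
    hit <- hit | (ratio >= fold)
  }
  rownames(x$values)[hit]
}

#' Call strict cell-type marker genes
#'
#' A gene is a marker of cell type \code{c} when its mean over the target
#' replicates exceeds \code{high} while every single sample outside the
#' target group stays below \code{low}. The target group is either the cell
#' type pooled over both organs (scope \code{"both"}) or one organ's cell
#' type with all remaining samples -- including the other organ's same cell
#' type -- below \code{low} (scope \code{"cochlea_only"} /
#' \code{"vestibule_only"}). Both thresholds are strict inequalities. The
#' call is invariant to sample column order and a gene can be a marker of at
#' most one cell type.
#'
#' @param x An \code{\link{xpr}} on the intensity-like scale.
#' @param high Threshold the target mean must exceed (default 250).
#' @param low Threshold every other sample must stay below (default 120).
#' @return Data frame: \code{gene}, \code{cell_type}, \code{organ_scope},
#'   \code{target_mean}, \code{max_other}.
#' @export
call_markers <- function(x, high = 250, low = 120) {
  design <- x$design
  vals <- x$values
  organs <- unique(design$organ)
  out <- list()
  for (ct in unique(design$cell_type)) {
    scopes <- list(both = design$cell_type == ct)
    if (length(organs) > 1L)
      for (org in organs)
        scopes[[paste0(org, "_only")]] <-
          design$cell_type == ct & design$organ == org
    claimed <- rep(FALSE, nrow(vals))
    for (sc in names(scopes)) {
      tgt <- scopes[[sc]]
      if (!any(tgt)) next
      t_mean <- rowMeans(vals[, tgt, drop = FALSE])
      o_max <- apply(vals[, !tgt, drop = FALSE], 1L, max)
      is_m <- t_mean > high & o_max < low & !claimed
      if (any(is_m)) {
        claimed <- claimed | is_m
        out[[length(out) + 1L]] <- data.frame(
          gene = rownames(vals)[is_m], cell_type = ct, organ_scope = sc,
          target_mean = t_mean[is_m], max_other = o_max[is_m],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(gene = character(), cell_type = character(),
                      organ_scope = character(), target_mean = numeric(),
                      max_other = numeric(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$gene), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Validate marker calls on a second expression platform
#'
#' For each marker, computes the fold change between its cell type and the
#' complementary cell type on an independent platform (replicate means on
#' floored values, pooled over organs), and summarizes the fraction reaching
#' \code{fold_threshold} and the mean fold. Markers whose gene or cell type
#' is absent from the second platform are excluded and counted.
#'
#' @param markers Data frame from \code{\link{call_markers}}.
#' @param second An \code{\link{xpr}} for the confirmatory platform.
#' @param fold_threshold Fold considered confirmatory (default 2).
#' @return List: \code{per_marker} data frame (gene, cell_type, fold),
#'   \code{n_excluded}, \code{fraction_confirmed}, \code{mean_fold}.
#' @export
validate_markers <- function(markers, second, fold_threshold = 2) {
  design <- second$design
  folds <- data.frame(gene = character(), cell_type = character(),
                      fold = numeric(), stringsAsFactors = FALSE)
  excluded <- 0L
  for (i in seq_len(nrow(markers))) {
    g <- markers$gene[i]; ct <- markers$cell_type[i]
    tgt <- design$cell_type == ct
    if (!g %in% rownames(second$values) || !any(tgt) || all(tgt)) {
      excluded <- excluded + 1L
      next
    }
    f <- mean(second$values[g, tgt]) / mean(second$values[g, !tgt])
    folds <- rbind(folds, data.frame(gene = g, cell_type = ct, fold = f,
                                     stringsAsFactors = FALSE))
  }
  list(per_marker = folds, n_excluded = excluded,
       fraction_confirmed = if (nrow(folds)) mean(folds$fold >= fold_threshold) else NA_real_,
       mean_fold = if (nrow(folds)) mean(folds$fold) else NA_real_)
}
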