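#' Per-gene hair-cell enrichment scores
#'
#' For each gene, the ratio between its replicate-mean expression in HCs and
#' its average expression over the three probed cell types (HC, ENHC, NEC).
#' By default replicates are pooled across organs; \code{per_organ} computes
#' the score within one organ only.
#'
#' @param x An \code{\link{xpr}} with HC, ENHC and NEC columns; values must
#'   be positive (floored).
#' @param per_organ Optional organ name to restrict the score to.
#' @return Data frame: \code{gene}, \code{ratio}, \code{log2_ratio}.
#' @export
hc_enrichment_scores <- function(x, per_organ = NULL) {
  design <- x$design
  vals <- x$values
  if (!is.null(per_organ)) {
    keep <- design$organ == per_organ
    design <- design[keep, , drop = FALSE]
    vals <- vals[, keep, drop = FALSE]
  }
  types <- c("HC", "ENHC", "NEC")
  if (!all(types %in% design$cell_type))
    stop("HC, ENHC and NEC columns are all required")
  means <- vapply(types, function(ct)
    rowMeans(vals[, design$cell_type == ct, drop = FALSE]), numeric(nrow(vals)))
  r <- means[, "HC"] / rowMeans(means)
  data.frame(gene = rownames(vals), ratio = r, log2_ratio = log2(r),
             stringsAsFactors = FALSE)
}

#' Rank-based distribution-shift test
#'
#' One-sided Wilcoxon rank-sum (Mann-Whitney) test that the values of a gene
#' set are stochastically larger than the rest. Uses exact enumeration when
#' the smaller group has at most 10 values and there are no ties, otherwise
#' the normal approximation with midranks, tie-corrected variance and
#' continuity correction. Backed by \code{stats::wilcox.test}.
#'
#' @param scores_set Values for the set of interest.
#' @param scores_rest Values for the remaining genes.
#' @param alternative \code{"greater"} (default; set shifted right),
#'   \code{"less"}, or \code{"two.sided"}.
#' @param method \code{"auto"} (exact when small and tie-free),
#'   \code{"exact"}, or \code{"approx"}.
#' @return List: \code{n_set}, \code{n_rest}, \code{W} (Mann-Whitney U of
#'   set vs rest), \code{p}, \code{median_difference}, \code{method}.
#' @export
shift_test <- function(scores_set, scores_rest, alternative = "greater",
                       method = c("auto", "exact", "approx")) {
  method <- match.arg(method)
  if (length(scores_set) == 0L || length(scores_rest) == 0L)
    stop("both groups must be non-empty")
  ties <- anyDuplicated(c(scores_set, scores_rest)) > 0L
  exact <- switch(method,
                  auto = min(length(scores_set), length(scores_rest)) <= 10L && !ties,
                  exact = TRUE,
                  approx = FALSE)
  if (exact && ties) stop("exact method is not available with ties")
  wt <- suppressWarnings(
    stats::wilcox.test(scores_set, scores_rest, alternative = alternative,
                       exact = exact, correct = TRUE))
  list(n_set = length(scores_set), n_rest = length(scores_rest),
       W = unname(wt$statistic), p = wt$p.value,
       median_difference = stats::median(scores_set) - stats::median(scores_rest),
       method = if (exact) "exact" else "approx")
}

#' Intersect candidate targets with ChIP-derived target lists
#'
#' Counts how many candidate genes are bound by at least one of two ChIP
#' experiments and by both, with an upper-tail hypergeometric p-value for
#' each overlap against the gene universe, plus the overlap between the two
#' ChIP lists themselves.
#'
#' @param candidates Candidate target genes.
#' @param chip_a,chip_b ChIP-derived target gene sets.
#' @param universe The gene universe all sets live in.
#' @return List of overlap counts and \code{enrichment_result} records:
#'   \code{n_bound_any} / \code{any_test}, \code{n_bound_both} /
#'   \code{both_test}, \code{n_chip_overlap} / \code{chip_overlap_test}.
#' @export
chip_intersection <- function(candidates, chip_a, chip_b, universe) {
  for (nm in c("candidates", "chip_a", "chip_b")) {
    s <- get(nm)
    if (!all(s %in% universe))
      stop(nm, " is not contained in the universe")
  }
  any_set <- union(chip_a, chip_b)
  both_set <- intersect(chip_a, chip_b)
  k_any <- length(intersect(candidates, any_set))
  k_both <- length(intersect(candidates, both_set))
  k_chip <- length(both_set)
  N <- length(universe)
  list(
    n_candidates = length(candidates),
    n_chip_a = length(chip_a), n_chip_b = length(chip_b),
    n_bound_any = k_any,
    any_test = enrichment_record(N, length(any_set), length(candidates), k_any),
    n_bound_both = k_both,
    both_test = enrichment_record(N, length(both_set), length(candidates), k_both),
    n_chip_overlap = k_chip,
    chip_overlap_test = enrichment_record(N, length(chip_a), length(chip_b), k_chip))
}

#' Gene-panel enrichment in a selected set
#'
#' Generic hypergeometric set test (the deafness-panel style analysis): is a
#' curated panel over-represented among selected genes, relative to the
#' universe? Shares the hypergeometric implementation used by the motif
#' enrichment test.
#'
#' @param panel Curated gene panel.
#' @param selected Selected genes (e.g. differentially expressed).
#' @param universe Gene universe.
#' @return An \code{enrichment_result} with \code{N = |universe|},
#'   \code{K = |selected|}, \code{n = |panel} in universe\code{|},
#'   \code{k = |panel} in selected\code{|}.
#' @export
geneset_enrichment <- function(panel, selected, universe) {
  if (!all(selected %in% universe)) stop("selected is not contained in the universe")
  panel_in <- intersect(panel, universe)
  if (length(panel_in) == 0L) stop("panel does not intersect the universe")
  enrichment_record(N = length(universe), K = length(unique(selected)),
                    n = length(panel_in),
                    k = length(intersect(panel_in, selected)))
}

#' Per-gene fold changes between two cell types for a gene set
#'
#' Fold = replicate-mean expression in the numerator cell type divided by
#' the denominator cell type, on floored values so folds stay finite.
#' Genes absent from the matrix are reported, not silently dropped.
#'
#' @param genes Gene set to summarize.
#' @param x An \code{\link{xpr}}.
#' @param numerator,denominator Cell-type labels in the design.
#' @return List: \code{per_gene} (gene, fold), \code{n_absent},
#'   \code{min_fold}, \code{mean_fold}, \code{max_fold}.
#' @export
fold_summary <- function(genes, x, numerator = "HC", denominator = "ENHC") {
  design <- x$design
  present <- intersect(genes, rownames(x$values))
  if (length(present) == 0L) stop("none of the genes are present in the matrix")
  num <- design$cell_type == numerator
  den <- design$cell_type == denominator
  if (!any(num) || !any(den)) stop("numerator/denominator cell type absent")
  f <- rowMeans(x$values[present, num, drop = FALSE]) /
    rowMeans(x$values[present, den, drop = FALSE])
  list(per_gene = data.frame(gene = present, fold = unname(f),
                             stringsAsFactors = FALSE),
       n_absent = length(genes) - length(present),
       min_fold = min(f), mean_fold = mean(f), max_fold = max(f))
}
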