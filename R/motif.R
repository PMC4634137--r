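# base codes: A=1 C=2 G=3 T=4, anything else (N, IUPAC ambiguity) = 5
dna_code_lookup <- local({
  lk <- rep(5L, 256L)
  lk[utf8ToInt("A")] <- 1L; lk[utf8ToInt("C")] <- 2L
  lk[utf8ToInt("G")] <- 3L; lk[utf8ToInt("T")] <- 4L
  lk[utf8ToInt("a")] <- 1L; lk[utf8ToInt("c")] <- 2L
  lk[utf8ToInt("g")] <- 3L; lk[utf8ToInt("t")] <- 4L
  lk
})

encode_dna_matrix <- function(strings) {
  n <- length(strings)
  L <- unique(nchar(strings))
  stopifnot(length(L) == 1L)
  codes <- dna_code_lookup[utf8ToInt(paste(strings, collapse = ""))]
  matrix(codes, nrow = n, ncol = L, byrow = TRUE)
}

# 5-row log2-odds matrix; row 5 (N) scores 0 at every position
pwm_log_odds_matrix <- function(pwm) {
  lo <- log2(pwm$probs / pwm$background)
  rbind(lo, N = 0)
}

#' Maximum achievable log-odds score of a PWM
#' @param pwm A \code{pwm} object.
#' @export
pwm_max_score <- function(pwm) {
  sum(apply(log2(pwm$probs / pwm$background), 2L, max))
}

#' Log-odds score of one window under a PWM
#'
#' Sum over positions of \code{log2(prob / background)} for the observed
#' base; N bases contribute 0.
#'
#' @param pwm A \code{pwm} object.
#' @param window Character sequence of length equal to the PWM width.
#' @return Numeric score.
#' @export
pwm_log_odds <- function(pwm, window) {
  w <- ncol(pwm$probs)
  if (nchar(window) != w)
    stop("window length ", nchar(window), " != PWM width ", w)
  lo <- pwm_log_odds_matrix(pwm)
  codes <- dna_code_lookup[utf8ToInt(toupper(window))]
  sum(lo[cbind(codes, seq_len(w))])
}

# scan equal-length encoded sequences on one strand given a 5-row log-odds
# matrix, returning hits at or above thr (compiled kernel)
scan_hits_one_strand <- function(B, lo, thr) {
  if (ncol(B) < ncol(lo))
    return(list(seq = integer(0), start = integer(0), score = numeric(0)))
  .scan_hits_cpp(B, lo, thr)
}

#' Scan promoter sequences for PWM matches
#'
#' Reports every window whose log-odds score reaches \code{theta} times the
#' maximum achievable score, on the forward strand and (optionally) the
#' reverse complement. Positions are reported in promoter coordinates
#' (TSS = 0, transcription direction), taken from the \code{rel_start}
#' metadata of \code{\link{extract_promoters}} output. Overlapping hits are
#' all reported.
#'
#' @param pwm A \code{pwm} object.
#' @param promoters A named \code{DNAStringSet} (or named character vector);
#'   if a \code{rel_start} metadata column is present it anchors the
#'   coordinates, otherwise the first base is position 0.
#' @param theta Fraction of the maximum score required for a hit
#'   (default 0.8).
#' @param both_strands Also scan the reverse complement (default TRUE).
#' @return Data frame: \code{gene}, \code{position} (match start),
#'   \code{strand} (relative to the promoter), \code{score}.
#' @export
scan_promoters <- function(pwm, promoters, theta = 0.8, both_strands = TRUE) {
  if (theta <= 0 || theta > 1) stop("theta must lie in (0, 1]")
  if (methods::is(promoters, "DNAStringSet")) {
    rel <- S4Vectors::mcols(promoters)$rel_start
    seqs <- as.character(promoters)
  } else {
    rel <- attr(promoters, "rel_start")
    seqs <- as.character(promoters)
    names(seqs) <- names(promoters)
  }
  if (is.null(rel)) rel <- rep(0L, length(seqs))
  genes <- names(seqs)
  if (is.null(genes)) stop("promoters must be named by gene")
  lo <- pwm_log_odds_matrix(pwm)
  w <- ncol(pwm$probs)
  # reverse-strand scan: score of the reverse complement of each forward
  # window, computed by scanning with the reverse-complemented log-odds
  lo_rc <- lo[c(4L, 3L, 2L, 1L, 5L), rev(seq_len(w)), drop = FALSE]
  thr <- theta * pwm_max_score(pwm) - 1e-9
  out <- vector("list", 0L)
  for (L in unique(nchar(seqs))) {
    idx <- which(nchar(seqs) == L)
    if (L < w) next
    B <- encode_dna_matrix(seqs[idx])
    strands <- if (both_strands) c("+", "-") else "+"
    for (st in strands) {
      h <- scan_hits_one_strand(B, if (st == "+") lo else lo_rc, thr)
      if (length(h$seq) > 0L)
        out[[length(out) + 1L]] <- data.frame(
          gene = genes[idx][h$seq],
          position = rel[idx][h$seq] + h$start - 1L,
          strand = st,
          score = h$score,
          stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(gene = character(), position = integer(),
                      strand = character(), score = numeric(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$gene, res$position, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Scan a single sequence for PWM matches
#'
#' Convenience wrapper around \code{\link{scan_promoters}} for one sequence.
#'
#' @param pwm A \code{pwm} object.
#' @param seq Character sequence.
#' @param theta,both_strands See \code{\link{scan_promoters}}.
#' @param rel_start Promoter coordinate of the first base (default 0).
#' @export
scan_sequence <- function(pwm, seq, theta = 0.8, both_strands = TRUE,
                          rel_start = 0L) {
  s <- stats::setNames(as.character(seq), "seq")
  attr(s, "rel_start") <- as.integer(rel_start)
  scan_promoters(pwm, s, theta = theta, both_strands = both_strands)
}

#' Upper-tail hypergeometric probability
#'
#' \code{P(X >= k)} for \code{X ~ Hypergeometric(N, K, n)}: drawing \code{n}
#' genes from a universe of \code{N} containing \code{K} successes. The
#' shared set-test primitive behind motif enrichment, ChIP overlap and
#' gene-panel enrichment; computed in log space by \code{phyper}.
#'
#' @param N Universe size.
#' @param K Successes in the universe.
#' @param n Draw (target set) size.
#' @param k Observed successes in the draw.
#' @return Upper-tail probability in (0, 1].
#' @export
hypergeom_tail <- function(N, K, n, k) {
  if (any(c(N, K, n, k) < 0) || k > n || n > N || K > N || k > K + 0 ||
      n - k > N - K)
    stop("inconsistent hypergeometric counts (N=", N, ", K=", K,
         ", n=", n, ", k=", k, ")")
  if (k == 0) return(1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

enrichment_record <- function(N, K, n, k, extra = list()) {
  ef <- if (K > 0 && n > 0) (k / n) / (K / N) else NA_real_
  structure(c(list(N = N, K = K, n = n, k = k,
                   p = hypergeom_tail(N, K, n, k),
                   enrichment_factor = ef), extra),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("Set enrichment: k=%d of n=%d targets vs K=%d of N=%d background\n",
              x$k, x$n, x$K, x$N))
  cat(sprintf("  enrichment factor = %.3g, hypergeometric p = %.3g\n",
              x$enrichment_factor, x$p))
  invisible(x)
}

# per-gene presence/absence from a scan-hit table
hit_presence <- function(hits, genes) {
  stats::setNames(genes %in% unique(hits$gene), genes)
}

#' Promoter-motif over-representation test
#'
#' Tests whether target-gene promoters carry at least one PWM hit more often
#' than the background (the expressed-gene universe). Presence/absence per
#' gene feeds an upper-tail hypergeometric test; the enrichment factor is
#' the ratio of hit proportions, \code{(k/n) / (K/N)}. Background genes
#' without an available promoter are dropped and counted.
#'
#' @param targets Character vector of target genes (subset of background).
#' @param background Character vector: the gene universe.
#' @param promoters \code{DNAStringSet} of promoters (named by gene);
#'   ignored when \code{hits} is given.
#' @param pwm A \code{pwm} object; ignored when \code{hits} is given.
#' @param theta,both_strands Scan parameters, see \code{\link{scan_promoters}}.
#' @param hits Optional precomputed scan-hit table (from
#'   \code{\link{scan_promoters}}) or named logical presence vector, so the
#'   scan can be shared across many tests.
#' @return An \code{enrichment_result}: \code{N}, \code{K}, \code{n},
#'   \code{k}, \code{p}, \code{enrichment_factor},
#'   \code{n_missing_promoters}.
#' @export
motif_enrichment_test <- function(targets, background, promoters = NULL,
                                  pwm = NULL, theta = 0.8,
                                  both_strands = TRUE, hits = NULL) {
  if (!all(targets %in% background))
    stop("targets must be a subset of the background universe")
  if (is.null(hits)) {
    if (is.null(promoters) || is.null(pwm))
      stop("either hits or (promoters, pwm) must be supplied")
    avail <- intersect(background, names(promoters))
    hits <- scan_promoters(pwm, promoters[avail], theta = theta,
                           both_strands = both_strands)
    presence <- hit_presence(hits, avail)
  } else if (is.data.frame(hits)) {
    avail <- background
    presence <- hit_presence(hits, avail)
  } else {
    avail <- intersect(background, names(hits))
    presence <- hits[avail]
  }
  n_missing <- length(background) - length(avail)
  targets_in <- intersect(targets, avail)
  if (length(targets_in) == 0L)
    stop("no target gene has an available promoter")
  enrichment_record(N = length(avail), K = sum(presence),
                    n = length(targets_in), k = sum(presence[targets_in]),
                    extra = list(n_missing_promoters = n_missing))
}

#' Positional distribution of best motif hits around the TSS
#'
#' Takes the best-scoring hit per gene (ties broken by the most upstream
#' position) and bins its start position into fixed-width bins covering
#' \code{[-upstream, downstream)}.
#'
#' @param hits Hit table from \code{\link{scan_promoters}}.
#' @param upstream,downstream Promoter window extent in nt.
#' @param binwidth Bin width in nt (default 25).
#' @return List: \code{breaks} (bin starts), \code{counts},
#'   \code{best_positions} (named per gene).
#' @export
positional_distribution <- function(hits, upstream = 1000L, downstream = 500L,
                                    binwidth = 25L) {
  breaks <- seq(-upstream, downstream, by = binwidth)
  starts <- breaks[-length(breaks)]
  if (nrow(hits) == 0L)
    return(list(breaks = starts, counts = rep(0L, length(starts)),
                best_positions = stats::setNames(integer(0), character(0))))
  ord <- order(hits$gene, -hits$score, hits$position)
  best <- hits[ord, ][!duplicated(hits$gene[ord]), , drop = FALSE]
  bin <- findInterval(best$position, breaks, rightmost.closed = FALSE)
  bin <- bin[bin >= 1L & bin <= length(starts)]
  counts <- tabulate(bin, nbins = length(starts))
  list(breaks = starts, counts = counts,
       best_positions = stats::setNames(best$position, best$gene))
}

#' Locate the TSS-proximal peak and narrow the promoter window
#'
#' Identifies the modal bin of a positional distribution (first maximal bin
#' on ties, flagged) and returns the narrowed promoter window in which the
#' enrichment test is to be re-run. The narrowed extent defaults to 200 nt
#' upstream to 100 nt downstream of the TSS.
#'
#' @param hist Output of \code{\link{positional_distribution}}.
#' @param narrowed_upstream,narrowed_downstream Narrowed window extent.
#' @return List: \code{upstream}, \code{downstream}, \code{mode_start},
#'   \code{mode_end} (modal bin interval), \code{tie} flag.
#' @export
detect_tss_peak_and_narrow <- function(hist, narrowed_upstream = 200L,
                                       narrowed_downstream = 100L) {
  if (sum(hist$counts) == 0L) stop("positional histogram is empty")
  m <- which(hist$counts == max(hist$counts))
  binwidth <- if (length(hist$breaks) > 1L) diff(hist$breaks[1:2]) else 25L
  list(upstream = as.integer(narrowed_upstream),
       downstream = as.integer(narrowed_downstream),
       mode_start = hist$breaks[m[1L]],
       mode_end = hist$breaks[m[1L]] + binwidth,
       tie = length(m) > 1L)
}

kmer_code_to_string <- function(code, k) {
  bases <- c("A", "C", "G", "T")
  vapply(code, function(cd) {
    out <- character(k)
    for (j in k:1) { out[j] <- bases[cd %% 4 + 1]; cd <- cd %/% 4 }
    paste(out, collapse = "")
  }, "")
}

kmer_string_to_class <- function(s) {
  codes <- dna_code_lookup[utf8ToInt(toupper(s))] - 1L
  k <- length(codes)
  code <- sum(codes * 4^((k - 1L):0L))
  rc <- sum((3L - codes) * 4^(0L:(k - 1L)))
  as.integer(min(code, rc))
}

#' Simplified de-novo motif discovery by k-mer enumeration
#'
#' Scores every k-mer (collapsed with its reverse complement; palindromes
#' are their own class) by a presence/absence hypergeometric test of target
#' promoters against the background universe, Bonferroni-corrected over all
#' distinct k-mer classes. The top class's occurrences in target promoters
#' are stacked into a count-matrix PWM (pseudocount 1). This is the
#' seed-enumeration phase of de-novo discovery; no EM refinement is applied.
#'
#' @param promoters \code{DNAStringSet} named by gene.
#' @param targets,background Gene sets (targets within background).
#' @param k K-mer length (default 8).
#' @param top_n Number of rows to keep in the ranked table (default 50).
#' @return List: \code{table} (ranked data frame with kmer, k, K, n, N, p,
#'   p_adjusted), \code{top_kmer}, \code{top_class} (canonical code),
#'   \code{pwm}, \code{n_classes_tested}.
#' @export
kmer_discovery <- function(promoters, targets, background, k = 8L,
                           top_n = 50L) {
  if (!all(targets %in% background))
    stop("targets must be a subset of the background universe")
  avail <- intersect(background, names(promoters))
  seqs <- as.character(promoters[avail])
  if (min(nchar(seqs)) < k) stop("k exceeds the shortest promoter")
  is_target <- avail %in% targets
  occ <- vector("list", 0L)
  for (L in unique(nchar(seqs))) {
    idx <- which(nchar(seqs) == L)
    oc <- .kmer_counts_cpp(encode_dna_matrix(seqs[idx]), k)
    occ[[length(occ) + 1L]] <- data.table::data.table(
      gene = idx[oc$gene], class = oc$class, count = oc$count)
  }
  occ <- data.table::rbindlist(occ)
  occ[, target := is_target[gene]]
  tab <- occ[, .(K = .N, k_hit = sum(target)), by = class]
  N <- length(avail); n <- sum(is_target)
  tab[, p := stats::phyper(k_hit - 1, K, N - K, n, lower.tail = FALSE)]
  tab[k_hit == 0, p := 1]
  m_classes <- (4^k + if (k %% 2 == 0) 4^(k / 2) else 0) / 2
  tab[, p_adjusted := pmin(p * m_classes, 1)]
  data.table::setorder(tab, p, -k_hit)
  top <- tab$class[1L]
  top_kmer <- kmer_code_to_string(top, k)
  n_occ <- occ[class == top & target == TRUE, sum(count)]
  counts <- matrix(1, nrow = 4L, ncol = k,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  codes <- dna_code_lookup[utf8ToInt(top_kmer)]
  counts[cbind(codes, seq_len(k))] <- counts[cbind(codes, seq_len(k))] + n_occ
  probs <- sweep(counts, 2L, colSums(counts), "/")
  res_tab <- utils::head(as.data.frame(tab), top_n)
  res_tab$kmer <- kmer_code_to_string(res_tab$class, k)
  res_tab <- res_tab[, c("kmer", "class", "k_hit", "K", "p", "p_adjusted")]
  names(res_tab)[3L] <- "k"
  res_tab$n <- n; res_tab$N <- N
  list(table = res_tab, top_kmer = top_kmer, top_class = top,
       pwm = new_pwm(probs, name = paste0("kmer_", top_kmer)),
       n_classes_tested = m_classes)
}

#' Cross-species motif enrichment of an ortholog-mapped target set
#'
#' Maps a species-A target set through a one-to-one ortholog map, drops
#' unmapped genes (counted), and runs the promoter-motif enrichment test
#' against the species-B background.
#'
#' @param targets_a Species-A target genes.
#' @param map Named character vector (A gene -> B gene).
#' @param background_b Species-B gene universe.
#' @param promoters_b Species-B promoters (DNAStringSet named by gene).
#' @param pwm A \code{pwm} object.
#' @param theta,both_strands,hits See \code{\link{motif_enrichment_test}}.
#' @return An \code{enrichment_result} with an extra \code{n_unmapped} count.
#' @export
cross_species_test <- function(targets_a, map, background_b, promoters_b = NULL,
                               pwm = NULL, theta = 0.8, both_strands = TRUE,
                               hits = NULL) {
  mapped <- map[intersect(targets_a, names(map))]
  mapped <- unname(mapped[!is.na(mapped)])
  mapped <- intersect(mapped, background_b)
  n_unmapped <- length(targets_a) - length(mapped)
  if (length(mapped) == 0L) stop("no target gene maps to the second species")
  res <- motif_enrichment_test(mapped, background_b, promoters = promoters_b,
                               pwm = pwm, theta = theta,
                               both_strands = both_strands, hits = hits)
  res$n_unmapped <- n_unmapped
  res
}
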