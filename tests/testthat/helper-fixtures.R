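# shared fixtures, all built in code

# minimal balanced 2-organ x 3-cell-type x r-replicate design
tiny_design <- function(r = 3L, organs = c("cochlea", "vestibule"),
                        cell_types = c("HC", "ENHC", "NEC")) {
  d <- expand.grid(replicate = seq_len(r), cell_type = cell_types,
                   organ = organs, stringsAsFactors = FALSE)
  d$sample_id <- sprintf("%s_%s_r%d", substr(d$organ, 1, 1), d$cell_type,
                         d$replicate)
  d[, c("sample_id", "organ", "cell_type", "replicate")]
}

tiny_xpr <- function(values, design = tiny_design(), detection_p = NULL) {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("g%03d", seq_len(nrow(values)))
  colnames(values) <- design$sample_id
  xpr(values, design, detection_p = detection_p)
}

# a sharp PWM whose consensus is the given string (dominant prob ~1)
consensus_pwm <- function(consensus, dominant = 0.997) {
  bases <- c("A", "C", "G", "T")
  w <- nchar(consensus)
  probs <- matrix((1 - dominant) / 3, nrow = 4, ncol = w,
                  dimnames = list(bases, NULL))
  for (j in seq_len(w))
    probs[substr(consensus, j, j), j] <- dominant
  new_pwm(probs, name = paste0("consensus_", consensus))
}

# named character promoters -> DNAStringSet with rel_start metadata
as_promoters <- function(seqs, rel_start = 0L) {
  ps <- Biostrings::DNAStringSet(seqs)
  S4Vectors::mcols(ps) <- S4Vectors::DataFrame(
    gene = names(seqs), strand = "+",
    rel_start = rep(as.integer(rel_start), length.out = length(seqs)),
    clipped = FALSE)
  ps
}

# exhaustive-enumeration oracle for the upper-tail hypergeometric:
# draw n of N labelled balls (K successes), count draws with >= k successes
hyper_enum_oracle <- function(N, K, n, k) {
  if (k == 0) return(1)
  draws <- utils::combn(N, n)
  mean(colSums(draws <= K) >= k)
}

# exact one-sided Mann-Whitney oracle by enumerating all rank assignments
wilcox_enum_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  u_obs <- sum(outer(x, y, ">"))
  r <- seq_len(nx + ny)
  sets <- utils::combn(nx + ny, nx)
  u_all <- colSums(sets) - nx * (nx + 1) / 2
  mean(u_all >= u_obs)
}
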