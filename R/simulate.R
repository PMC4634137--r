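#' Simulation parameters for the synthetic inner-ear study
#'
#' Defines the generative conditions the synthetic data emulate: a two-organ
#' (cochlea, vestibule) by three-cell-type (HC, ENHC, NEC) design with
#' replicated sorted populations, a planted hair-cell regulon whose promoters
#' carry an X-box-like motif concentrated near the TSS, strict cell-type
#' marker genes, organ-biased genes, ChIP target lists overlapping the true
#' regulon, and a partially conserved second species.
#'
#' Expression is log-normal: \code{log2 x = base + effects + N(0, noise_sd)}.
#' Baselines are chosen so that roughly half the genes fall below the
#' detection threshold in every sample, as bead arrays behave; regulon genes
#' sit on a higher baseline so their non-HC expression stays clearly
#' detectable, and marker genes are near the floor outside their own type.
#'
#' @param n_genes Number of genes in the universe.
#' @param n_regulon Size of the planted hair-cell regulon.
#' @param n_markers_per_type Planted strict markers per cell type.
#' @param organs,cell_types,n_replicates Design labels and replication.
#' @param base_mean,base_sd Log2 baseline location/scale for ordinary genes.
#' @param regulon_base_mean,regulon_base_sd Log2 baseline for regulon genes.
#' @param celltype_effect Log2 fold added to regulon genes in HC columns.
#' @param organ_effect Log2 fold added to organ-biased genes in their organ.
#' @param organ_frac Fraction of ordinary genes that are organ-biased.
#' @param marker_on,marker_off Marker-gene expression (a.u.) in its own cell
#'   type and everywhere else.
#' @param noise_sd Log2-scale measurement noise s.d.
#' @param detect_threshold Expression (a.u.) above which a measurement is
#'   flagged detected (low detection p-value).
#' @param upstream,downstream Promoter window in nt around the TSS.
#' @param flank Extra contig sequence beyond the promoter window, per side.
#' @param motif_insert_rate_target Probability a regulon promoter receives a
#'   planted motif instance.
#' @param motif_insert_rate_background Same for non-regulon promoters
#'   (planted uniformly in the window).
#' @param motif_position_mean,motif_position_sd Planted position (motif start,
#'   nt relative to the TSS) for regulon promoters.
#' @param gc_content GC fraction of background sequence.
#' @param chip_sensitivity Probability a regulon gene enters a ChIP target list.
#' @param chip_extra Number of non-regulon genes added to each ChIP list.
#' @param ortholog_conservation Fraction of the regulon whose second-species
#'   promoters keep the motif at the target insertion rate.
#' @param seed Integer seed; fixed seed gives byte-identical outputs.
#' @return A validated list of class \code{"sim_params"}.
#' @export
sim_params <- function(n_genes = 5000L, n_regulon = 200L,
                       n_markers_per_type = 30L,
                       organs = c("cochlea", "vestibule"),
                       cell_types = c("HC", "ENHC", "NEC"),
                       n_replicates = 3L,
                       base_mean = 6, base_sd = 1.5,
                       regulon_base_mean = 7.8, regulon_base_sd = 0.2,
                       celltype_effect = 2.0, organ_effect = 1.0,
                       organ_frac = 0.2,
                       marker_on = 512, marker_off = 40,
                       noise_sd = 0.25, detect_threshold = 120,
                       upstream = 1000L, downstream = 500L, flank = 50L,
                       motif_insert_rate_target = 0.8,
                       motif_insert_rate_background = 0.05,
                       motif_position_mean = -50, motif_position_sd = 30,
                       gc_content = 0.42,
                       chip_sensitivity = 0.65, chip_extra = 300L,
                       ortholog_conservation = 0.8,
                       seed = 1L) {
  p <- as.list(environment())
  probs <- c(motif_insert_rate_target, motif_insert_rate_background,
             chip_sensitivity, ortholog_conservation, gc_content, organ_frac)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (n_regulon > n_genes) stop("n_regulon exceeds n_genes")
  if (n_regulon + n_markers_per_type * length(cell_types) > n_genes)
    stop("regulon plus markers exceed the gene universe")
  if (n_replicates < 2L) stop("need >= 2 replicates per condition")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (upstream + downstream < 1L) stop("empty promoter window")
  p$seed <- as.integer(seed)
  class(p) <- "sim_params"
  p
}

#' Built-in X-box-like PWM used by the simulator
#'
#' A width-14 matrix shaped like an RFX binding site: a sharp 8-bp core
#' (consensus \code{GTTGCCAT}, dominant-base probability 0.92) flanked on
#' both sides by three uninformative (uniform) positions, mimicking the
#' degenerate edges of the palindromic X-box. The uniform flanks contribute
#' nothing to the log-odds score, so scanning sensitivity is governed by the
#' core, and sampled instances routinely miss the score maximum -- which is
#' what exercises threshold handling realistically.
#'
#' @param core_prob Probability of the consensus base at core positions.
#' @return A \code{\link{new_pwm}} object.
#' @export
xbox_pwm <- function(core_prob = 0.92) {
  core <- c("G", "T", "T", "G", "C", "C", "A", "T")
  w <- 14L
  probs <- matrix(0.25, nrow = 4L, ncol = w,
                  dimnames = list(c("A", "C", "G", "T"), NULL))
  off <- (1 - core_prob) / 3
  for (j in seq_along(core)) {
    col <- rep(off, 4L)
    names(col) <- c("A", "C", "G", "T")
    col[core[j]] <- core_prob
    probs[, 3L + j] <- col
  }
  new_pwm(probs, name = "xbox_synthetic")
}

sim_gene_ids <- function(n) sprintf("g%05d", seq_len(n))

#' Generate the ground-truth record for a simulation
#'
#' Samples disjoint regulon, marker, and organ-biased gene sets and per-gene
#' log2 baselines. Motif positions, ChIP lists and the ortholog map are
#' filled in by the later generators and attached to this record.
#'
#' @param params A \code{\link{sim_params}} object.
#' @return List of class \code{"sim_truth"}: \code{genes}, \code{regulon},
#'   \code{markers} (list per cell type), \code{organ_up} (list per organ),
#'   \code{base_log2}, \code{pwm_used}.
#' @export
generate_truth <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  genes <- sim_gene_ids(params$n_genes)
  pool <- genes
  regulon <- sort(sample(pool, params$n_regulon))
  pool <- setdiff(pool, regulon)
  markers <- list()
  for (ct in params$cell_types) {
    markers[[ct]] <- sort(sample(pool, params$n_markers_per_type))
    pool <- setdiff(pool, markers[[ct]])
  }
  n_organ <- round(params$organ_frac * length(pool))
  organ_genes <- sample(pool, n_organ)
  half <- floor(n_organ / 2)
  organ_up <- stats::setNames(
    list(sort(organ_genes[seq_len(half)]),
         sort(organ_genes[setdiff(seq_len(n_organ), seq_len(half))])),
    params$organs)
  base <- stats::rnorm(length(genes), params$base_mean, params$base_sd)
  names(base) <- genes
  base[regulon] <- stats::rnorm(length(regulon), params$regulon_base_mean,
                                params$regulon_base_sd)
  for (ct in params$cell_types) base[markers[[ct]]] <- log2(params$marker_off)
  structure(list(genes = genes, regulon = regulon, markers = markers,
                 organ_up = organ_up, base_log2 = base,
                 pwm_used = xbox_pwm()),
            class = "sim_truth")
}

sim_design <- function(params, cell_types = params$cell_types) {
  d <- expand.grid(replicate = seq_len(params$n_replicates),
                   cell_type = cell_types, organ = params$organs,
                   stringsAsFactors = FALSE)
  d <- d[, c("organ", "cell_type", "replicate")]
  d$sample_id <- sprintf("%s_%s_r%d", substr(d$organ, 1L, 1L), d$cell_type,
                         d$replicate)
  d[, c("sample_id", "organ", "cell_type", "replicate")]
}

sim_mu_matrix <- function(params, truth, design) {
  mu <- matrix(truth$base_log2, nrow = length(truth$genes),
               ncol = nrow(design),
               dimnames = list(truth$genes, design$sample_id))
  hc_cols <- design$cell_type == "HC"
  mu[truth$regulon, hc_cols] <- mu[truth$regulon, hc_cols] + params$celltype_effect
  for (ct in intersect(names(truth$markers), unique(design$cell_type))) {
    own <- design$cell_type == ct
    mu[truth$markers[[ct]], own] <- log2(params$marker_on)
  }
  for (org in names(truth$organ_up)) {
    cols <- design$organ == org
    mu[truth$organ_up[[org]], cols] <-
      mu[truth$organ_up[[org]], cols] + params$organ_effect
  }
  mu
}

#' Generate an expression matrix from planted truth
#'
#' \code{platform = "microarray"} produces intensity-like values for the full
#' three-cell-type design together with detection p-values (low where the
#' value exceeds the detection threshold, high otherwise).
#' \code{platform = "rnaseq"} produces integer count-like values for an
#' HC/ENHC design, with independent noise, emulating the confirmatory
#' platform.
#'
#' @param params A \code{\link{sim_params}} object.
#' @param truth A \code{\link{generate_truth}} record.
#' @param platform \code{"microarray"} or \code{"rnaseq"}.
#' @return An \code{\link{xpr}} object.
#' @export
generate_expression_matrix <- function(params, truth,
                                       platform = c("microarray", "rnaseq")) {
  platform <- match.arg(platform)
  set.seed(params$seed + if (platform == "microarray") 1L else 2L)
  design <- if (platform == "microarray") sim_design(params)
            else sim_design(params, cell_types = c("HC", "ENHC"))
  mu <- sim_mu_matrix(params, truth, design)
  noise <- matrix(stats::rnorm(length(mu), 0, params$noise_sd), nrow = nrow(mu))
  vals <- 2^(mu + noise)
  if (platform == "rnaseq") {
    vals <- round(vals)
    return(xpr(vals, design))
  }
  detp <- ifelse(vals > params$detect_threshold, 0.001, 0.5)
  xpr(vals, design, detection_p = detp)
}

revcomp_chr <- function(s) {
  chartr("ACGTN", "TGCAN", vapply(strsplit(s, NULL),
                                  function(x) paste(rev(x), collapse = ""), ""))
}

sample_pwm_instance <- function(pwm, n = 1L) {
  w <- ncol(pwm$probs)
  draws <- vapply(seq_len(w), function(j)
    sample(rownames(pwm$probs), n, replace = TRUE, prob = pwm$probs[, j]),
    character(n))
  if (n == 1L) paste(draws, collapse = "") else apply(draws, 1L, paste, collapse = "")
}

# Build one contig per gene; plant motif instances in the promoter window.
# Returns genome (DNAStringSet), tss data frame and named vector of planted
# motif start positions (promoter coordinates, TSS = 0).
sim_make_genome <- function(params, genes, target_genes, pwm) {
  u <- params$upstream; d <- params$downstream; fl <- params$flank
  w <- ncol(pwm$probs)
  if (w > u + d) stop("motif wider than promoter window")
  contig_len <- fl + u + d + fl
  n <- length(genes)
  gc <- params$gc_content
  base_probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  draws <- sample(c("A", "C", "G", "T"), n * contig_len, replace = TRUE,
                  prob = base_probs)
  big <- paste(draws, collapse = "")
  starts <- (seq_len(n) - 1L) * contig_len + 1L
  seqs <- substring(big, starts, starts + contig_len - 1L)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  tss <- ifelse(strand == "+", fl + u, fl + d - 1L)
  is_target <- genes %in% target_genes
  rate <- ifelse(is_target, params$motif_insert_rate_target,
                 params$motif_insert_rate_background)
  planted <- stats::runif(n) < rate
  pos <- rep(NA_integer_, n)
  if (any(planted)) {
    p_target <- round(stats::rnorm(n, params$motif_position_mean,
                                   params$motif_position_sd))
    p_bg <- sample(seq(-u, d - w), n, replace = TRUE)
    p <- ifelse(is_target, p_target, p_bg)
    p <- pmin(pmax(p, -u), d - w)
    idx <- which(planted)
    inst <- sample_pwm_instance(pwm, length(idx))
    for (ii in seq_along(idx)) {
      g <- idx[ii]
      i0 <- p[g] + u                      # 0-based index within promoter
      if (strand[g] == "+") {
        gs <- fl + i0                     # 0-based genomic start
        substr(seqs[g], gs + 1L, gs + w) <- inst[ii]
      } else {
        gs <- fl + u + d - i0 - w
        substr(seqs[g], gs + 1L, gs + w) <- revcomp_chr(inst[ii])
      }
      pos[g] <- p[g]
    }
  }
  genome <- Biostrings::DNAStringSet(seqs)
  names(genome) <- genes
  tss_df <- data.frame(gene = genes, chrom = genes, tss = as.integer(tss),
                       strand = strand, stringsAsFactors = FALSE)
  list(genome = genome, tss = tss_df,
       motif_positions = stats::setNames(pos[planted], genes[planted]),
       motif_instances = if (any(planted))
         stats::setNames(inst, genes[which(planted)])
       else stats::setNames(character(0), character(0)))
}

#' Generate the species-A genome with planted promoter motifs
#'
#' One synthetic contig per gene; regulon promoters receive a PWM-sampled
#' motif instance with probability \code{motif_insert_rate_target} at a
#' TSS-proximal position, background promoters with probability
#' \code{motif_insert_rate_background} at uniform positions. Planted
#' positions (motif start, promoter coordinates) are returned.
#'
#' @param params A \code{\link{sim_params}} object.
#' @param truth A \code{\link{generate_truth}} record.
#' @return List: \code{genome} (DNAStringSet), \code{tss} (data frame),
#'   \code{motif_positions} (named integer vector).
#' @export
generate_genome_and_promoters <- function(params, truth) {
  set.seed(params$seed + 3L)
  sim_make_genome(params, truth$genes, truth$regulon, truth$pwm_used)
}

#' Generate a synthetic ChIP target list
#'
#' Includes each regulon gene independently with probability
#' \code{chip_sensitivity}, plus \code{chip_extra} uniformly drawn
#' non-regulon genes.
#'
#' @param params,truth Simulation parameters and truth record.
#' @param which_list 1 or 2 (two antibodies are emulated; each uses its own
#'   random draw).
#' @return Character vector of gene symbols.
#' @export
generate_chip_targets <- function(params, truth, which_list = 1L) {
  set.seed(params$seed + 3L + as.integer(which_list))
  hit <- stats::runif(length(truth$regulon)) < params$chip_sensitivity
  extra <- sample(setdiff(truth$genes, truth$regulon),
                  min(params$chip_extra, params$n_genes - params$n_regulon))
  sort(unique(c(truth$regulon[hit], extra)))
}

#' Generate the ortholog map and the second-species genome
#'
#' Every species-A gene gets a one-to-one species-B ortholog. A fraction
#' \code{ortholog_conservation} of the regulon is conserved: those genes'
#' B-side promoters carry the motif at the target insertion rate, all other
#' B promoters at the background rate.
#'
#' @param params,truth Simulation parameters and truth record.
#' @return List: \code{map} (named character, A -> B), \code{conserved}
#'   (A-side genes), \code{genome}, \code{tss}, \code{motif_positions}
#'   (B-side).
#' @export
generate_ortholog_map <- function(params, truth) {
  set.seed(params$seed + 6L)
  genes_b <- sub("^g", "z", truth$genes)
  map <- stats::setNames(genes_b, truth$genes)
  n_cons <- round(params$ortholog_conservation * length(truth$regulon))
  conserved <- sort(sample(truth$regulon, n_cons))
  gb <- sim_make_genome(params, genes_b, unname(map[conserved]), truth$pwm_used)
  list(map = map, conserved = conserved, genome = gb$genome, tss = gb$tss,
       motif_positions = gb$motif_positions)
}

#' Simulate a complete input bundle on disk
#'
#' Writes every file the pipeline reads -- expression and design TSVs for
#' both platforms, FASTA genomes and BED TSS tables for both species, the
#' PWM in MEME format, two ChIP target lists, the ortholog map -- plus the
#' ground truth (regulon, markers, conserved set, planted motif positions)
#' under \code{<dir>/truth/}.
#'
#' @param params A \code{\link{sim_params}} object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the truth record with all generated components attached.
#' @export
simulate_inputs <- function(params, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)
  truth <- generate_truth(params)
  ma <- generate_expression_matrix(params, truth, "microarray")
  rs <- generate_expression_matrix(params, truth, "rnaseq")
  ga <- generate_genome_and_promoters(params, truth)
  chip1 <- generate_chip_targets(params, truth, 1L)
  chip2 <- generate_chip_targets(params, truth, 2L)
  orth <- generate_ortholog_map(params, truth)
  # a curated-panel stand-in (deafness-gene style): mostly HC-biology genes,
  # some unrelated, so the panel enrichment test has signal plus noise
  set.seed(params$seed + 7L)
  hc_pool <- unique(c(truth$regulon, truth$markers[["HC"]]))
  panel <- sort(c(sample(hc_pool, min(25L, length(hc_pool))),
                  sample(setdiff(truth$genes, hc_pool), 15L)))

  write_expression_table(ma, file.path(dir, "microarray.tsv"),
                         design_path = file.path(dir, "microarray.design.tsv"))
  write_expression_table(rs, file.path(dir, "rnaseq.tsv"),
                         design_path = file.path(dir, "rnaseq.design.tsv"))
  Biostrings::writeXStringSet(ga$genome, file.path(dir, "genome_a.fa"))
  write_tss_bed(ga$tss, file.path(dir, "tss_a.bed"))
  Biostrings::writeXStringSet(orth$genome, file.path(dir, "genome_b.fa"))
  write_tss_bed(orth$tss, file.path(dir, "tss_b.bed"))
  write_pwm_meme(truth$pwm_used, file.path(dir, "motif.meme"))
  write_gene_list(chip1, file.path(dir, "chip_targets_1.txt"))
  write_gene_list(chip2, file.path(dir, "chip_targets_2.txt"))
  write_ortholog_map(orth$map, file.path(dir, "orthologs.tsv"))
  write_gene_list(panel, file.path(dir, "panel.txt"))

  write_gene_list(truth$regulon, file.path(dir, "truth", "regulon.txt"))
  for (ct in names(truth$markers))
    write_gene_list(truth$markers[[ct]],
                    file.path(dir, "truth", sprintf("markers_%s.txt", ct)))
  write_gene_list(orth$conserved, file.path(dir, "truth", "conserved_regulon.txt"))
  utils::write.table(
    data.frame(gene = names(ga$motif_positions),
               position = unname(ga$motif_positions)),
    file.path(dir, "truth", "motif_positions.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)

  truth$microarray <- ma
  truth$rnaseq <- rs
  truth$genome_a <- ga
  truth$chip_targets <- list(chip1 = chip1, chip2 = chip2)
  truth$orthologs <- orth
  invisible(truth)
}
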