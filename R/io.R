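#' Construct an expression experiment
#'
#' Bundles a features x samples value matrix with its sample design table
#' (organ, cell type, replicate) and, optionally, a detection p-value matrix
#' of the same shape, the way bead-array scanners report one.
#'
#' @param values Numeric matrix, features in rows (rownames are feature ids),
#'   samples in columns.
#' @param design Data frame with columns \code{sample_id}, \code{organ},
#'   \code{cell_type}, \code{replicate}; one row per column of \code{values}.
#' @param detection_p Optional numeric matrix in \code{[0, 1]}, same shape as
#'   \code{values}.
#' @param feature_to_gene Optional named character vector mapping feature ids
#'   to gene symbols; defaults to the identity map.
#' @return An object of class \code{"xpr"}.
#' @export
xpr <- function(values, design, detection_p = NULL, feature_to_gene = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values))) stop("values must have feature ids as rownames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate feature id: ",
         rownames(values)[duplicated(rownames(values))][1L])
  if (!all(is.finite(values))) stop("values must be finite")
  if (any(values < 0)) stop("values must be non-negative")
  design <- as.data.frame(design)
  req <- c("sample_id", "organ", "cell_type", "replicate")
  if (!all(req %in% names(design)))
    stop("design must have columns: ", paste(req, collapse = ", "))
  if (nrow(design) != ncol(values))
    stop("design has ", nrow(design), " rows but values has ",
         ncol(values), " columns")
  if (anyDuplicated(design$sample_id)) stop("duplicate sample_id in design")
  design$sample_id <- as.character(design$sample_id)
  design$organ     <- as.character(design$organ)
  design$cell_type <- as.character(design$cell_type)
  if (is.null(colnames(values))) colnames(values) <- design$sample_id
  if (!identical(colnames(values), design$sample_id))
    stop("column names of values do not match design sample_ids")
  if (!is.null(detection_p)) {
    detection_p <- as.matrix(detection_p)
    if (!identical(dim(detection_p), dim(values)))
      stop("detection_p shape differs from values")
    if (any(detection_p < 0 | detection_p > 1, na.rm = TRUE))
      stop("detection_p values must lie in [0, 1]")
    dimnames(detection_p) <- dimnames(values)
  }
  if (is.null(feature_to_gene)) {
    feature_to_gene <- stats::setNames(rownames(values), rownames(values))
  } else {
    feature_to_gene <- feature_to_gene[rownames(values)]
    if (anyNA(feature_to_gene)) stop("feature_to_gene misses some feature ids")
  }
  structure(list(values = values, design = design, detection_p = detection_p,
                 feature_to_gene = feature_to_gene), class = "xpr")
}

#' @export
print.xpr <- function(x, ...) {
  cat("Expression experiment: ", nrow(x$values), " features x ",
      ncol(x$values), " samples\n", sep = "")
  cat("  organs:     ", paste(unique(x$design$organ), collapse = ", "), "\n")
  cat("  cell types: ", paste(unique(x$design$cell_type), collapse = ", "), "\n")
  cat("  detection p:", if (is.null(x$detection_p)) "absent" else "present", "\n")
  invisible(x)
}

#' @export
dim.xpr <- function(x) dim(x$values)

#' Read an expression table with its sample design
#'
#' The expression table is TSV with feature ids in the first column and one
#' numeric column per sample; the design table is TSV with columns
#' \code{sample_id}, \code{organ}, \code{cell_type}, \code{replicate}.
#' A companion detection p-value table (same layout as the expression table)
#' is read when \code{detection_path} is supplied or when a file named
#' \code{<path>.detection} exists.
#'
#' @param path Expression TSV.
#' @param design_path Design TSV.
#' @param detection_path Optional detection-p TSV.
#' @return An \code{\link{xpr}} object.
#' @export
read_expression_table <- function(path, design_path, detection_path = NULL) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character")
  if (ncol(tab) < 2L) stop("expression table needs >= 2 columns")
  ids <- tab[[1L]]
  if (anyDuplicated(ids)) stop("duplicate feature id: ", ids[duplicated(ids)][1L])
  num <- suppressWarnings(vapply(tab[-1L], as.numeric, numeric(nrow(tab))))
  if (nrow(tab) == 1L) num <- matrix(num, nrow = 1L, dimnames = list(NULL, names(tab)[-1L]))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop("non-numeric value at row ", bad[1L], ", sample column ", bad[2L])
  }
  rownames(num) <- ids
  design <- utils::read.table(design_path, header = TRUE, sep = "\t",
                              check.names = FALSE, stringsAsFactors = FALSE)
  num <- num[, design$sample_id, drop = FALSE]
  detp <- NULL
  if (is.null(detection_path) && file.exists(paste0(path, ".detection")))
    detection_path <- paste0(path, ".detection")
  if (!is.null(detection_path)) {
    dt <- utils::read.table(detection_path, header = TRUE, sep = "\t",
                            check.names = FALSE, row.names = 1L)
    detp <- as.matrix(dt)[ids, design$sample_id, drop = FALSE]
  }
  xpr(num, design, detection_p = detp)
}

#' Write an expression experiment to TSV
#'
#' Writes the value matrix (and detection p-values, if present, to
#' \code{<path>.detection}) plus the design table, in the layout
#' \code{\link{read_expression_table}} reads back to full precision.
#'
#' @param x An \code{xpr} object.
#' @param path Output TSV for the value matrix.
#' @param design_path Output TSV for the design (default \code{<path>.design}).
#' @export
write_expression_table <- function(x, path, design_path = paste0(path, ".design")) {
  df <- data.frame(feature_id = rownames(x$values),
                   format(x$values, digits = 17, trim = TRUE, scientific = TRUE),
                   check.names = FALSE)
  ok <- try(utils::write.table(df, path, sep = "\t", quote = FALSE,
                               row.names = FALSE), silent = TRUE)
  if (inherits(ok, "try-error")) stop("cannot write to ", path)
  utils::write.table(x$design, design_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(x$detection_p)) {
    dp <- data.frame(feature_id = rownames(x$values),
                     format(x$detection_p, digits = 17, trim = TRUE,
                            scientific = TRUE), check.names = FALSE)
    utils::write.table(dp, paste0(path, ".detection"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a PWM in MEME minimal format
#'
#' Parses the first MOTIF block's letter-probability matrix (alphabet ACGT).
#' A pseudocount is added to every cell and rows are renormalized, so all
#' probabilities are strictly positive. If the file holds several motifs only
#' the first is loaded, with a warning.
#'
#' @param path MEME minimal format file.
#' @param pseudocount Small positive value added before renormalization.
#' @return A \code{pwm} object: list with \code{probs} (4 x width matrix,
#'   rows A,C,G,T, columns summing to 1), \code{background} (length-4
#'   composition), \code{name}.
#' @export
read_pwm_meme <- function(path, pseudocount = 1e-3) {
  lines <- readLines(path)
  if (!any(grepl("^ALPHABET\\s*=\\s*ACGT", lines)))
    stop("missing 'ALPHABET= ACGT' line")
  motif_at <- grep("^MOTIF\\b", lines)
  if (length(motif_at) == 0L) stop("no MOTIF block found")
  if (length(motif_at) > 1L)
    warning("file contains ", length(motif_at), " motifs; loading the first")
  name <- trimws(sub("^MOTIF", "", lines[motif_at[1L]]))
  bg <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  bg_at <- grep("^Background letter frequencies", lines)
  if (length(bg_at) > 0L) {
    toks <- strsplit(trimws(lines[bg_at[1L] + 1L]), "\\s+")[[1L]]
    vals <- as.numeric(toks[seq(2L, length(toks), by = 2L)])
    names(vals) <- toks[seq(1L, length(toks), by = 2L)]
    bg <- vals[c("A", "C", "G", "T")]
  }
  lp_at <- grep("^letter-probability matrix", lines)
  lp_at <- lp_at[lp_at > motif_at[1L]][1L]
  if (is.na(lp_at)) stop("no letter-probability matrix for first motif")
  end <- if (length(motif_at) > 1L) motif_at[2L] - 1L else length(lines)
  rows <- lines[(lp_at + 1L):end]
  rows <- rows[grepl("^\\s*[0-9.eE+-]", rows)]
  mat <- do.call(rbind, lapply(strsplit(trimws(rows), "\\s+"), as.numeric))
  if (ncol(mat) != 4L) stop("letter-probability matrix must have 4 columns")
  bad <- which(abs(rowSums(mat) - 1) > 0.01)
  if (length(bad) > 0L)
    stop("PWM row ", bad[1L], " sums to ", rowSums(mat)[bad[1L]],
         " (must be within 0.01 of 1)")
  probs <- t(mat) + pseudocount
  probs <- sweep(probs, 2L, colSums(probs), "/")
  rownames(probs) <- c("A", "C", "G", "T")
  new_pwm(probs, background = bg, name = name)
}

#' Construct a PWM object
#'
#' @param probs 4 x width matrix of per-position base probabilities
#'   (rows A, C, G, T; columns sum to 1).
#' @param background Length-4 base composition summing to 1.
#' @param name Motif name.
#' @export
new_pwm <- function(probs, background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                    name = "motif") {
  probs <- as.matrix(probs)
  if (nrow(probs) != 4L) stop("probs must have 4 rows (A, C, G, T)")
  rownames(probs) <- c("A", "C", "G", "T")
  if (any(abs(colSums(probs) - 1) > 1e-9)) stop("PWM columns must sum to 1")
  if (any(probs <= 0)) stop("PWM probabilities must be positive (add a pseudocount)")
  background <- background / sum(background)
  names(background) <- c("A", "C", "G", "T")
  structure(list(probs = probs, background = background, name = name),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("PWM '", x$name, "', width ", ncol(x$probs),
      ", consensus ", pwm_consensus(x), "\n", sep = "")
  invisible(x)
}

#' Consensus sequence of a PWM (most probable base per column)
#' @param pwm A \code{pwm} object.
#' @export
pwm_consensus <- function(pwm) {
  paste(rownames(pwm$probs)[apply(pwm$probs, 2L, which.max)], collapse = "")
}

#' Write a PWM in MEME minimal format
#' @param pwm A \code{pwm} object.
#' @param path Output file.
#' @export
write_pwm_meme <- function(pwm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               paste(sprintf("%s %.6f", names(pwm$background), pwm$background),
                     collapse = " "),
               "",
               paste("MOTIF", pwm$name),
               sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
                       ncol(pwm$probs))), con)
  writeLines(apply(pwm$probs, 2L, function(p) paste(sprintf("%.6f", p), collapse = "  ")),
             con)
  invisible(path)
}

#' Read TSS records from a BED6 file
#'
#' BED is 0-based half-open; the TSS is taken as \code{start} for plus-strand
#' records and \code{end - 1} for minus-strand records, so it always indexes
#' the first transcribed base. One record per gene name is kept: duplicates
#' keep the first occurrence, with a warning.
#'
#' @param path BED6 file (chrom, start, end, name, score, strand).
#' @return Data frame with columns \code{gene}, \code{chrom}, \code{tss}
#'   (0-based), \code{strand}.
#' @export
read_tss_table <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(!strand %in% c("+", "-")))
    stop("strand must be '+' or '-' for every TSS record")
  start0 <- GenomicRanges::start(gr) - 1L  # back to 0-based
  end0 <- GenomicRanges::end(gr)           # half-open end
  if (any(end0 <= start0)) stop("BED interval with end <= start")
  tss <- ifelse(strand == "+", start0, end0 - 1L)
  df <- data.frame(gene = as.character(gr$name),
                   chrom = as.character(GenomicRanges::seqnames(gr)),
                   tss = as.integer(tss), strand = strand,
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$gene)) {
    warning("duplicate gene names in TSS table; keeping first record per gene")
    df <- df[!duplicated(df$gene), , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

#' Write TSS records as BED6
#'
#' Inverse of \code{\link{read_tss_table}}: each TSS becomes a 1-nt interval
#' covering the TSS base on its strand.
#'
#' @param tss Data frame as returned by \code{\link{read_tss_table}}.
#' @param path Output BED file.
#' @export
write_tss_bed <- function(tss, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = tss$chrom,
    ranges = IRanges::IRanges(start = tss$tss + 1L, width = 1L),
    strand = tss$strand)
  gr$name <- tss$gene
  gr$score <- 0L
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Extract strand-aware promoter sequences around TSSs
#'
#' For a plus-strand gene the promoter is the genomic interval
#' \code{[tss - u, tss + d)}; for a minus-strand gene it is the reverse
#' complement of \code{[tss - d + 1, tss + u + 1)}. Either way the returned
#' sequence reads 5' to 3' in the direction of transcription and relative
#' position 0 is the TSS base. Windows falling off a contig edge are clipped
#' (never padded) and flagged.
#'
#' @param genome A \code{Biostrings::DNAStringSet} or path to a FASTA file.
#' @param tss TSS data frame (\code{gene}, \code{chrom}, \code{tss},
#'   \code{strand}), 0-based TSS coordinates.
#' @param upstream,downstream Window extent in nt (defaults 1000 and 500).
#' @return A \code{DNAStringSet} named by gene, with metadata columns
#'   \code{gene}, \code{strand}, \code{rel_start} (promoter coordinate of the
#'   first base, normally \code{-upstream}) and \code{clipped}.
#' @export
extract_promoters <- function(genome, tss, upstream = 1000L, downstream = 500L) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  if (upstream < 0L || downstream < 0L || upstream + downstream < 1L)
    stop("invalid promoter window")
  missing_chrom <- setdiff(unique(tss$chrom), names(genome))
  if (length(missing_chrom) > 0L)
    stop("chromosome(s) not in genome: ", paste(missing_chrom, collapse = ", "))
  if (nrow(tss) == 0L) stop("empty TSS set")
  lens <- Biostrings::width(genome)[match(tss$chrom, names(genome))]
  plus <- tss$strand == "+"
  # 0-based half-open genomic interval per gene
  g_start <- ifelse(plus, tss$tss - upstream, tss$tss - downstream + 1L)
  g_end <- ifelse(plus, tss$tss + downstream, tss$tss + upstream + 1L)
  c_start <- pmax(g_start, 0L)
  c_end <- pmin(g_end, lens)
  if (any(c_end <= c_start)) stop("promoter window entirely off contig for gene ",
                                  tss$gene[which(c_end <= c_start)[1L]])
  clipped <- (c_start != g_start) | (c_end != g_end)
  seqs <- Biostrings::subseq(genome[tss$chrom], start = c_start + 1L, end = c_end)
  seqs[!plus] <- Biostrings::reverseComplement(seqs[!plus])
  # promoter coordinate of the first returned base, in transcription direction
  rel_start <- ifelse(plus, c_start - tss$tss, tss$tss - (c_end - 1L))
  names(seqs) <- tss$gene
  S4Vectors::mcols(seqs) <- S4Vectors::DataFrame(
    gene = tss$gene, strand = tss$strand,
    rel_start = as.integer(rel_start), clipped = clipped)
  seqs
}

#' Read a gene list from a plain-text file
#'
#' One symbol per line; blank lines and \code{#} comments are ignored;
#' duplicates are removed; symbols are case-sensitive.
#'
#' @param path Text file.
#' @return Character vector of unique gene symbols.
#' @export
read_gene_list <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop("gene list is empty: ", path)
  unique(lines)
}

#' Write a gene list to a plain-text file
#' @param genes Character vector.
#' @param path Output file.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(unique(as.character(genes)), path)
  invisible(path)
}

#' Read a two-column ortholog map
#'
#' TSV with a header and two columns (species-A gene, species-B gene).
#' Many-to-many rows are resolved to a one-to-one map by keeping the first
#' occurrence of each A-side and each B-side gene, with a warning.
#'
#' @param path TSV file.
#' @return Named character vector: names are species-A genes, values their
#'   species-B orthologs.
#' @export
read_ortholog_map <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("ortholog map needs two columns")
  keep <- !duplicated(df[[1L]]) & !duplicated(df[[2L]])
  if (!all(keep)) {
    warning(sum(!keep), " many-to-many ortholog rows dropped")
    df <- df[keep, , drop = FALSE]
  }
  stats::setNames(as.character(df[[2L]]), as.character(df[[1L]]))
}

#' Write an ortholog map as TSV
#' @param map Named character vector (A gene -> B gene).
#' @param path Output file.
#' @export
write_ortholog_map <- function(map, path) {
  utils::write.table(data.frame(gene_a = names(map), gene_b = unname(map)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a pipeline record as JSON
#'
#' Serializes any list-like result (enrichment records, test records, run
#' manifests) with deterministic field ordering and full numeric precision,
#' so re-reading reproduces values exactly.
#'
#' @param record Named list.
#' @param path Output JSON file.
#' @export
write_record_json <- function(record, path) {
  ok <- try(jsonlite::write_json(record, path, auto_unbox = TRUE, digits = NA,
                                 null = "null", pretty = TRUE), silent = TRUE)
  if (inherits(ok, "try-error")) stop("cannot write to ", path)
  invisible(path)
}

#' Read a JSON record written by \code{write_record_json}
#' @param path JSON file.
#' @export
read_record_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
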