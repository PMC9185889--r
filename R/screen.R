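#' Median-of-ratios size factors
#'
#' Per-sample normalization factors computed as the median, over guides
#' detected in every sample, of the ratio of the guide's count to its
#' geometric mean across samples — the standard count-normalization used for
#' sequencing screens. Identical samples get identical factors, and a sample
#' with doubled depth gets a doubled factor.
#'
#' @param counts a `ScreenCounts` object or a guides x samples count matrix.
#' @return Named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  mat <- if (inherits(counts, "ScreenCounts")) counts$counts else as.matrix(counts)
  if (ncol(mat) < 2) stop("need at least 2 samples")
  everywhere <- rowSums(mat > 0) == ncol(mat)
  if (!any(everywhere)) stop("no guide has nonzero counts in all samples")
  logref <- rowMeans(log(mat[everywhere, , drop = FALSE]))
  apply(mat[everywhere, , drop = FALSE], 2, function(col) {
    exp(stats::median(log(col) - logref))
  })
}

#' Per-guide log2 fold-change treated vs control
#'
#' Size-factor-normalized counts are averaged within each group, a
#' pseudocount is added, and the log2 ratio taken:
#' `log2((t + pc) / (c + pc))`.
#'
#' @param counts a `ScreenCounts` object.
#' @param treated,control sample name(s); multiple names are averaged on the
#'   normalized scale before the ratio.
#' @param pseudocount added to both normalized means (default 1).
#' @param sf size factors; defaults to [size_factors()] of the full matrix.
#' @return Named numeric vector, one log2 fold-change per guide.
#' @export
guide_log2fc <- function(counts, treated, control, pseudocount = 1,
                         sf = size_factors(counts)) {
  mat <- counts$counts
  missing <- setdiff(c(treated, control), colnames(mat))
  if (length(missing)) stop("unknown sample: ", missing[1])
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  norm <- sweep(mat, 2, sf[colnames(mat)], "/")
  m_t <- rowMeans(norm[, treated, drop = FALSE])
  m_c <- rowMeans(norm[, control, drop = FALSE])
  log2((m_t + pseudocount) / (m_c + pseudocount))
}

#' Gene-level enrichment scores with permutation p-values
#'
#' The gene score is the mean log2 fold-change of its guides (positive =
#' enrichment under treatment, negative = depletion, mirroring the sign
#' convention of MLE beta scores). Significance is a two-sided permutation
#' test: for each guide-set size, a null distribution of mean fold-changes
#' is built by drawing random guide sets from all guides; the p-value is the
#' fraction of null draws at least as extreme as the observed score, floored
#' at `1/(n_perm + 1)`. FDR is Benjamini-Hochberg across genes.
#'
#' Null guide sets are drawn independently for every gene (with replacement
#' from the guide pool), which keeps the p-values independent across genes
#' and exactly uniform under the null.
#'
#' @param lfc named per-guide log2 fold-changes (from [guide_log2fc()]).
#' @param guide_map named character vector guide -> gene.
#' @param n_perm number of permutations (>= 1000).
#' @param seed RNG seed for the permutation draws.
#' @return Data frame (one row per gene, ranked by p then |score| desc):
#'   `gene`, `score`, `p_value`, `fdr`, `n_guides`.
#' @export
gene_scores <- function(lfc, guide_map, n_perm = 1000, seed = NULL) {
  if (n_perm < 1000) stop("n_perm must be >= 1000")
  if (!all(names(lfc) %in% names(guide_map))) {
    stop("every guide must be mapped to a gene")
  }
  gene_of <- guide_map[names(lfc)]
  empty <- setdiff(unique(guide_map), gene_of)
  if (length(empty)) {
    warning("excluding ", length(empty), " gene(s) with 0 guides")
  }
  score <- tapply(lfc, gene_of, mean)
  n_guides <- tapply(lfc, gene_of, length)
  sizes <- sort(unique(n_guides))
  p <- stats::setNames(numeric(length(score)), names(score))
  n_lfc <- length(lfc)
  with_seed(seed, {
    for (s in sizes) {
      sel <- which(n_guides == s)
      # per-gene independent null draws, chunked to bound memory
      chunk <- max(1L, floor(4e6 / (s * n_perm)))
      for (start in seq(1, length(sel), by = chunk)) {
        genes_i <- sel[start:min(start + chunk - 1, length(sel))]
        draws <- matrix(lfc[sample.int(n_lfc, s * n_perm * length(genes_i),
                                       replace = TRUE)],
                        nrow = s)
        null_means <- matrix(colMeans(draws), nrow = n_perm)
        exceed <- colSums(abs(null_means) >=
                            rep(abs(score[genes_i]), each = n_perm))
        p[genes_i] <- (1 + exceed) / (n_perm + 1)
      }
    }
  })
  out <- data.frame(gene = names(score), score = as.numeric(score),
                    p_value = as.numeric(p),
                    fdr = stats::p.adjust(as.numeric(p), method = "BH"),
                    n_guides = as.integer(n_guides), row.names = NULL)
  out[order(out$p_value, -abs(out$score)), , drop = FALSE]
}

#' Replicate correlation of normalized counts
#'
#' Pearson correlation of `log2(normalized count + 1)` between two samples,
#' the standard screen QC (technical replicates should reach r >= 0.98).
#'
#' @param counts a `ScreenCounts` object.
#' @param sample_a,sample_b sample names.
#' @return Pearson r.
#' @export
replicate_correlation <- function(counts, sample_a, sample_b) {
  mat <- counts$counts
  missing <- setdiff(c(sample_a, sample_b), colnames(mat))
  if (length(missing)) stop("unknown sample: ", missing[1])
  sf <- size_factors(counts)
  a <- log2(mat[, sample_a] / sf[sample_a] + 1)
  b <- log2(mat[, sample_b] / sf[sample_b] + 1)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("zero-variance sample: correlation undefined")
  }
  stats::cor(a, b)
}

#' Screen-design arithmetic: cells required per container
#'
#' Number of cells to transduce per container to maintain a target library
#' representation at a given multiplicity of infection:
#' `library_size * coverage / moi / n_containers`, reported to 3 significant
#' figures. E.g. a 76,441-guide library at 1000x coverage, MOI 0.3, split
#' over 7 flasks needs 3.64e7 cells per flask.
#'
#' @param library_size number of guides in the library.
#' @param coverage target cells per guide (representation).
#' @param moi multiplicity of infection.
#' @param n_containers number of vessels the transduction is split over.
#' @return Cells per container (3 significant figures).
#' @export
required_cells <- function(library_size, coverage, moi, n_containers) {
  vals <- c(library_size, coverage, moi, n_containers)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all inputs must be positive")
  }
  signif(library_size * coverage / moi / n_containers, 3)
}
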