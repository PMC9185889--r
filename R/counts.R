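#' sgRNA screen count container
#'
#' @param counts integer matrix, guides x samples, with guide ids as
#'   rownames and sample names as colnames.
#' @param genes named character vector mapping guide id to its single target
#'   gene.
#' @param roles optional named character vector mapping sample name to
#'   `"t0"`, `"control"` or `"treated"`.
#' @return An object of class `ScreenCounts`.
#' @export
screen_counts <- function(counts, genes, roles = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have guide rownames and sample colnames")
  }
  if (anyDuplicated(rownames(counts))) {
    stop("duplicated guide id: ", rownames(counts)[duplicated(rownames(counts))][1])
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    bad <- which(counts < 0 | counts != round(counts), arr.ind = TRUE)[1, ]
    stop("counts must be non-negative integers; offending cell: guide '",
         rownames(counts)[bad[1]], "', sample '", colnames(counts)[bad[2]], "'")
  }
  if (!setequal(names(genes), rownames(counts))) {
    stop("gene map must cover exactly the guides in the count matrix")
  }
  if (!is.null(roles)) {
    stopifnot(all(names(roles) %in% colnames(counts)),
              all(roles %in% c("t0", "control", "treated")))
  }
  structure(list(counts = counts, genes = genes[rownames(counts)], roles = roles),
            class = "ScreenCounts")
}

#' @export
print.ScreenCounts <- function(x, ...) {
  cat("ScreenCounts:", nrow(x$counts), "guides /",
      length(unique(x$genes)), "genes x", ncol(x$counts), "samples\n")
  invisible(x)
}

#' Read an sgRNA count table
#'
#' Plain TSV with header; first two columns are guide id and gene, remaining
#' columns are per-sample integer counts. No dialect sniffing.
#'
#' @param path path to the counts TSV.
#' @return A [screen_counts()] object.
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) stop("counts file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop("counts file needs guide, gene and >=1 sample column")
  guide <- as.character(df[[1]])
  gene <- as.character(df[[2]])
  if (anyDuplicated(guide)) {
    # a guide listed twice (possibly with two genes) is always an error
    stop("duplicated guide id: ", guide[duplicated(guide)][1])
  }
  mat <- df[, -(1:2), drop = FALSE]
  for (j in seq_along(mat)) {
    v <- suppressWarnings(as.numeric(mat[[j]]))
    bad <- which(is.na(v) | v < 0 | v != round(v))
    if (length(bad)) {
      stop("invalid count '", mat[[j]][bad[1]], "' at guide '", guide[bad[1]],
           "', sample '", names(mat)[j], "'")
    }
    mat[[j]] <- v
  }
  counts <- as.matrix(mat)
  rownames(counts) <- guide
  screen_counts(counts, stats::setNames(gene, guide))
}

#' Write an sgRNA count table
#'
#' @param x a `ScreenCounts` object.
#' @param path output TSV path.
#' @export
write_counts <- function(x, path) {
  df <- data.frame(guide = rownames(x$counts), gene = unname(x$genes),
                   x$counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a viability table
#'
#' TSV with columns `drug`, `concentration_nM`, `cell_line`, `replicate`,
#' `value` (percent viability or raw luminescence).
#'
#' @param path path to the viability TSV.
#' @return A data frame with those columns.
#' @export
read_viability <- function(path) {
  if (!file.exists(path)) stop("viability file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("drug", "concentration_nM", "cell_line", "replicate", "value")
  if (!all(need %in% names(df))) {
    stop("viability table must have columns: ", paste(need, collapse = ", "))
  }
  if (any(df$concentration_nM <= 0)) stop("concentrations must be positive")
  df[, need]
}
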