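# Readers/writers for the plain-text formats the pipeline exchanges:
# counts as MatrixMarket or dense TSV, cell metadata TSV, GRN edge TSV,
# BED intervals (0-based half-open on disk, converted at the boundary),
# GMT gene sets, and flat truth tables.

#' Write a count matrix
#'
#' MatrixMarket (`.mtx` plus `<stem>.genes.tsv` / `<stem>.cells.tsv`) when
#' the path ends in `.mtx`, otherwise a dense TSV with gene row names.
#'
#' @param counts gene x cell matrix.
#' @param path output path.
#' @export
write_counts <- function(counts, path) {
  if (grepl("\\.mtx$", path)) {
    Matrix::writeMM(methods::as(methods::as(Matrix::Matrix(counts,
                                                           sparse = TRUE),
                                            "CsparseMatrix"),
                    "generalMatrix"), path)
    stem <- sub("\\.mtx$", "", path)
    writeLines(rownames(counts), paste0(stem, ".genes.tsv"))
    writeLines(colnames(counts), paste0(stem, ".cells.tsv"))
  } else {
    utils::write.table(as.matrix(counts), path, sep = "\t", quote = FALSE,
                       col.names = NA)
  }
  invisible(path)
}

#' Read a count matrix written by [write_counts()]
#' @param path `.mtx` or dense TSV path.
#' @return gene x cell matrix with dimnames.
#' @export
read_counts <- function(path) {
  if (grepl("\\.mtx$", path)) {
    m <- as.matrix(Matrix::readMM(path))
    stem <- sub("\\.mtx$", "", path)
    dimnames(m) <- list(readLines(paste0(stem, ".genes.tsv")),
                        readLines(paste0(stem, ".cells.tsv")))
    m
  } else {
    as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                row.names = 1, check.names = FALSE))
  }
}

#' Write cell metadata (pseudotime, lineage, offset, covariates) as TSV
#' @param data a [trajectory_dataset()]
#' @param path output path
#' @export
write_cell_meta <- function(data, path) {
  meta <- data.frame(cell_id = colnames(data$Y),
                     lineage = as.character(data$lineage),
                     pseudotime = assigned_pseudotime(data),
                     offset = data$N, stringsAsFactors = FALSE)
  if (!is.null(data$U)) meta <- cbind(meta, data$U)
  utils::write.table(meta, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read cell metadata TSV
#' @param path TSV with columns cell_id, lineage, pseudotime, offset and
#'   optional covariates
#' @return data.frame
#' @export
read_cell_meta <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' Write genomic intervals as BED (0-based half-open)
#'
#' @param gr `GRanges`; names become the BED name column.
#' @param path output path.
#' @export
write_bed <- function(gr, path) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = if (is.null(names(gr))) "." else names(gr),
    score = 0L,
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE)
  df$strand[df$strand == "*"] <- "."
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file (0-based half-open) into `GRanges`
#' @param path BED path (3-6 columns).
#' @return `GRanges`, named when a name column is present.
#' @export
read_bed <- function(path) {
  df <- tryCatch(
    utils::read.table(path, sep = "\t", header = FALSE,
                      stringsAsFactors = FALSE),
    error = function(e) stop("malformed BED file '", path, "': ",
                             conditionMessage(e)))
  if (ncol(df) < 3L) stop("BED file needs at least 3 columns")
  strand <- if (ncol(df) >= 6L) ifelse(df[[6]] %in% c("+", "-"),
                                       df[[6]], "*") else "*"
  gr <- GenomicRanges::GRanges(
    seqnames = df[[1]],
    ranges = IRanges::IRanges(start = df[[2]] + 1L, end = df[[3]]),
    strand = strand)
  if (ncol(df) >= 4L) names(gr) <- df[[4]]
  gr
}

#' Write a GRN edge table as TSV
#' @param grn `grn_model` or edge data.frame
#' @param path output path
#' @export
write_grn <- function(grn, path) {
  edges <- if (inherits(grn, "grn_model")) grn$edges else grn
  utils::write.table(edges[, c("tf", "target", "weight")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#' @param path GMT path
#' @return named list of character vectors
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Write a flat truth (or any) table as TSV
#' @param x data.frame
#' @param path output path
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#' @param path TSV path
#' @return data.frame
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' Per-gene fit summary table
#' @param fits named list of `gene_fit` objects
#' @return data.frame with gene, loglik, aic, phi, converged, degenerate
#' @export
fit_summary <- function(fits) {
  do.call(rbind, lapply(fits, function(f) {
    data.frame(gene = f$gene, loglik = f$loglik, aic = f$aic, phi = f$phi,
               converged = f$converged, degenerate = f$degenerate,
               stringsAsFactors = FALSE)
  }))
}
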