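# Bulk RNA / ATAC integration: selection of early-response genes (silent
# before injury, upregulated after), quantification of chromatin
# accessibility in windows around the TSS, and classification of genes as
# chromatin-primed (already accessible before activation) versus de-novo
# accessible. All genomic intervals are handled 0-based half-open (BED
# convention); 1-based annotations are converted at the boundary.

#' Select early-response genes
#'
#' Genes with low-or-absent pre-injury expression that are significantly
#' upregulated after injury: `expr_pre <= baseline_max` and
#' `lfc >= lfc_min` and `fdr <= fdr_max`.
#'
#' @param expr data.frame with columns `gene`, `expr_pre`, `lfc`, `fdr`
#'   (log2 fold change and adjusted p-value from an upstream differential
#'   expression fit).
#' @param baseline_max maximum pre-injury expression (RPKM-like units;
#'   default 1).
#' @param lfc_min minimum log2 fold change (default 1).
#' @param fdr_max maximum adjusted p-value (default 0.05).
#' @return character vector of selected gene identifiers.
#' @export
select_early_response <- function(expr, baseline_max = 1, lfc_min = 1,
                                  fdr_max = 0.05) {
  need <- c("gene", "expr_pre", "lfc", "fdr")
  if (!all(need %in% names(expr))) {
    stop("expression table must have columns: ", paste(need, collapse = ", "))
  }
  with(expr, gene[expr_pre <= baseline_max & lfc >= lfc_min &
                    fdr <= fdr_max])
}

#' Symmetric windows around transcription start sites
#'
#' Converts a 1-based TSS annotation into 0-based half-open genomic windows
#' `[TSS - flank, TSS + flank)`. Windows extending below position 0 are
#' clipped at 0 (message). Strand is recorded for downstream profile
#' orientation; the genomic interval itself is strand-independent.
#'
#' @param annotation data.frame with columns `gene`, `chrom`, `tss`
#'   (1-based position of the TSS base), `strand` (`"+"` or `"-"`).
#' @param flank half-width in bp (> 0).
#' @return `GRanges` named by gene with the window per gene; metadata
#'   column `tss0` holds the 0-based TSS position.
#' @export
tss_windows <- function(annotation, flank = 2000L) {
  if (flank <= 0) stop("flank must be positive; degenerate windows rejected")
  if (!all(annotation$strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'")
  }
  tss0 <- annotation$tss - 1L                 # 0-based position of TSS base
  start0 <- pmax(0L, tss0 - as.integer(flank))
  end0 <- tss0 + as.integer(flank)
  if (any(tss0 - flank < 0)) {
    message(sum(tss0 - flank < 0), " windows clipped at position 0")
  }
  gr <- GenomicRanges::GRanges(
    seqnames = annotation$chrom,
    ranges = IRanges::IRanges(start = start0 + 1L, end = end0),
    strand = annotation$strand)
  names(gr) <- annotation$gene
  gr$tss0 <- tss0
  gr
}

#' Count fragments overlapping windows
#'
#' A fragment counts for a window iff they overlap by at least 1 bp.
#' Counts-per-million normalization uses the total number of fragments in
#' the library (all fragments supplied, not only those in windows).
#'
#' @param fragments `GRanges` of fragments (e.g. from [read_bed()]).
#' @param windows `GRanges` of windows, named by gene.
#' @param normalize return CPM in addition to raw counts (default TRUE).
#' @return data.frame: `gene`, `count`, and `cpm` when normalized (zero
#'   when the fragment library is empty).
#' @export
count_fragments <- function(fragments, windows, normalize = TRUE) {
  counts <- GenomicRanges::countOverlaps(windows, fragments,
                                         minoverlap = 1L,
                                         ignore.strand = TRUE)
  out <- data.frame(gene = names(windows), count = as.integer(counts),
                    stringsAsFactors = FALSE)
  if (normalize) {
    total <- length(fragments)
    out$cpm <- if (total > 0) out$count * 1e6 / total else 0
  }
  out
}

#' Fragment-start profile around the TSS
#'
#' Counts fragment starts in position bins relative to each TSS, over
#' `[-flank, flank)`, orientation-corrected so that for minus-strand genes
#' positive positions still point downstream of transcription.
#'
#' @param fragments `GRanges` of fragments.
#' @param annotation TSS table as in [tss_windows()].
#' @param flank half-width in bp.
#' @param bin bin width in bp; must divide `2 * flank`.
#' @return position-bin x gene matrix; row names are bin-start positions
#'   relative to the TSS.
#' @export
tss_profile <- function(fragments, annotation, flank = 2000L, bin = 100L) {
  if ((2L * flank) %% bin != 0L) stop("bin must divide 2 * flank")
  n_bins <- 2L * flank / bin
  rel_starts <- seq(-flank, flank - bin, by = bin)
  frag_start0 <- GenomicRanges::start(fragments) - 1L  # 0-based starts
  frag_chrom <- as.character(GenomicRanges::seqnames(fragments))
  prof <- matrix(0L, nrow = n_bins, ncol = nrow(annotation),
                 dimnames = list(rel_starts, annotation$gene))
  for (j in seq_len(nrow(annotation))) {
    tss0 <- annotation$tss[j] - 1L
    on_chrom <- frag_chrom == annotation$chrom[j]
    rel <- frag_start0[on_chrom] - tss0
    if (annotation$strand[j] == "-") rel <- -rel - 1L
    rel <- rel[rel >= -flank & rel < flank]
    if (length(rel)) {
      idx <- (rel + flank) %/% bin + 1L
      tab <- tabulate(idx, nbins = n_bins)
      prof[, j] <- tab
    }
  }
  prof
}

#' Classify genes as primed, de-novo accessible, constitutive or closed
#'
#' Joins expression and accessibility on gene and applies, in order:
#' `primed` if induced, accessibility fold change within
#' `[-window_threshold, window_threshold]`, and pre-injury accessibility at
#' or above the floor; `induced_accessible` if induced with accessibility
#' fold change above `window_threshold`; `constitutive` if not induced and
#' accessible pre-injury; `silent_closed` otherwise. "Induced" is the
#' [select_early_response()] predicate.
#'
#' @param expr expression table (see [select_early_response()]).
#' @param acc data.frame with columns `gene`, `acc_pre`, `acc_post` (CPM);
#'   `acc_lfc` is computed as `log2((acc_post + pseudocount) /
#'   (acc_pre + pseudocount))` unless already present.
#' @param window_threshold half-width of the unchanged-accessibility band
#'   on the log2 scale (default 0.5).
#' @param accessibility_floor minimum pre-injury CPM to call a gene
#'   accessible. Default: median + 2 MAD of `acc_pre` over `silent_genes`
#'   (a negative-control set of genes expected closed).
#' @param silent_genes character vector of negative-control genes; required
#'   when `accessibility_floor` is NULL.
#' @param pseudocount CPM pseudocount for the fold change (default 1).
#' @param baseline_max,lfc_min,fdr_max induction thresholds, passed to
#'   [select_early_response()].
#' @return data.frame (`priming_records`): `gene`, `induced`, `acc_pre`,
#'   `acc_lfc`, `class` (factor with levels primed, induced_accessible,
#'   constitutive, silent_closed). Genes present in only one table are
#'   excluded with a message.
#' @export
classify_priming <- function(expr, acc, window_threshold = 0.5,
                             accessibility_floor = NULL,
                             silent_genes = NULL, pseudocount = 1,
                             baseline_max = 1, lfc_min = 1,
                             fdr_max = 0.05) {
  common <- intersect(expr$gene, acc$gene)
  dropped <- length(union(expr$gene, acc$gene)) - length(common)
  if (dropped > 0L) {
    message(dropped, " genes present in only one table excluded")
  }
  expr <- expr[match(common, expr$gene), , drop = FALSE]
  acc <- acc[match(common, acc$gene), , drop = FALSE]
  if (is.null(acc$acc_lfc)) {
    acc$acc_lfc <- log2((acc$acc_post + pseudocount) /
                          (acc$acc_pre + pseudocount))
  }
  if (is.null(accessibility_floor)) {
    if (is.null(silent_genes)) {
      stop("supply accessibility_floor or silent_genes to derive it")
    }
    ctrl <- acc$acc_pre[acc$gene %in% silent_genes]
    if (length(ctrl) == 0L) stop("no silent control genes found in the data")
    accessibility_floor <- stats::median(ctrl) + 2 * stats::mad(ctrl)
  }
  induced <- expr$gene %in% select_early_response(expr, baseline_max,
                                                  lfc_min, fdr_max)
  open_pre <- acc$acc_pre >= accessibility_floor
  cls <- ifelse(induced & abs(acc$acc_lfc) <= window_threshold & open_pre,
                "primed",
         ifelse(induced & acc$acc_lfc > window_threshold,
                "induced_accessible",
         ifelse(!induced & open_pre, "constitutive", "silent_closed")))
  data.frame(gene = common, induced = induced, acc_pre = acc$acc_pre,
             acc_lfc = acc$acc_lfc,
             class = factor(cls, levels = c("primed", "induced_accessible",
                                            "constitutive",
                                            "silent_closed")),
             stringsAsFactors = FALSE)
}

#' Positive and negative control gene sets for accessibility profiles
#'
#' The high set is the top `high_quantile` fraction of genes by pre-injury
#' expression; the silent set is a supplied identifier list (e.g. olfactory
#' receptor symbols) restricted to genes with pre-injury expression below
#' `baseline_max`.
#'
#' @param expr expression table with `gene` and `expr_pre`.
#' @param high_quantile fraction of top-expressed genes to keep (default
#'   0.1).
#' @param silent_set character vector of candidate silent genes.
#' @param baseline_max expression ceiling for the silent set (default 1).
#' @return list with `high` and `silent` character vectors.
#' @export
control_gene_sets <- function(expr, high_quantile = 0.1, silent_set,
                              baseline_max = 1) {
  if (length(silent_set) == 0L) {
    warning("empty silent identifier set")
    silent <- character(0)
  } else {
    silent <- expr$gene[expr$gene %in% silent_set &
                          expr$expr_pre < baseline_max]
  }
  n_high <- ceiling(high_quantile * nrow(expr))
  high <- expr$gene[order(expr$expr_pre, decreasing = TRUE)][seq_len(n_high)]
  list(high = high, silent = silent)
}
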