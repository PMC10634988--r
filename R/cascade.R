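# Derivative-based cascade test: finite-difference first derivatives of the
# fitted smoothers on a pseudotime grid, a thresholded one-sided statistic
# per grid point with BH adjustment across the grid, peak localization at
# the first post-minimum zero crossing, and the downstream ordering and
# classification rules.

#' Finite-difference derivatives of a fitted smoother
#'
#' Approximates the first derivative of the lineage smoother at `J` equally
#' spaced grid points over the lineage's pseudotime range by central finite
#' differences of the basis functions,
#' \eqn{\hat\delta_{glj} = \sum_k [b_k(t + \epsilon) - b_k(t - \epsilon)] /
#' (2\epsilon) \cdot \hat\beta_{glk}}, with standard errors
#' \eqn{\sqrt{d^\top V d}} from the coefficient covariance since the
#' derivative is a linear combination of the coefficients. Grid points whose
#' \eqn{\pm\epsilon} neighbourhood leaves the knot span use a one-sided
#' difference and are flagged.
#'
#' @param fit a converged `gene_fit`.
#' @param lineage lineage name or index.
#' @param J number of grid points (default 100).
#' @param epsilon finite-difference step (default 1e-7).
#' @return A `derivative_grid` object: `grid`, `delta`, `se`, `boundary`
#'   (logical, one-sided difference used), `epsilon`, plus gene/lineage
#'   metadata. [derivative_test()] adds the test columns.
#' @export
estimate_derivatives <- function(fit, lineage, J = 100L, epsilon = 1e-7) {
  if (fit$degenerate) stop("cannot differentiate a degenerate fit")
  if (epsilon <= 0) stop("epsilon must be positive")
  l <- if (is.character(lineage)) match(lineage, fit$lineages) else
    as.integer(lineage)
  grid <- lineage_grid(fit, l, J)
  span <- knot_span(fit$spec)
  lo <- pmax(grid - epsilon, span[1])
  hi <- pmin(grid + epsilon, span[2])
  boundary <- (grid - epsilon < span[1]) | (grid + epsilon > span[2])
  D <- (build_basis(hi, fit$spec) - build_basis(lo, fit$spec)) / (hi - lo)
  delta <- drop(D %*% fit$beta[l, ])
  idx <- lineage_block(fit, l)
  Vl <- fit$V[idx, idx]
  se <- sqrt(pmax(rowSums((D %*% Vl) * D), 0))
  structure(list(
    gene = fit$gene, lineage = fit$lineages[l], grid = grid, delta = delta,
    se = se, boundary = boundary, epsilon = epsilon
  ), class = "derivative_grid")
}

#' Thresholded derivative test on the grid
#'
#' Computes, at every grid point, the thresholded statistic
#' \eqn{T_{glj} = \max(0, \hat\delta_{glj} - c) / \hat\sigma_{glj}} and the
#' one-sided p-value \eqn{1 - \Phi(T_{glj})} under a standard normal null,
#' then applies Benjamini-Hochberg step-up adjustment across the grid points
#' of this (gene, lineage). The gene is declared involved in the lineage
#' when the minimum adjusted p-value falls below `alpha`. A zero standard
#' error at a grid point yields p = 1 there (conservative).
#'
#' @param dgrid a `derivative_grid` from [estimate_derivatives()].
#' @param alpha significance cut-off on adjusted p-values (default 0.05).
#' @param c derivative threshold below which increases are ignored
#'   (default 0.1, link-scale units per pseudotime unit).
#' @return the `derivative_grid` with `stat`, `p`, `p_adj`, `c`, `alpha`,
#'   `involved` and `min_p_adj` filled in.
#' @export
derivative_test <- function(dgrid, alpha = 0.05, c = 0.1) {
  stopifnot(inherits(dgrid, "derivative_grid"))
  stat <- pmax(0, dgrid$delta - c) / dgrid$se
  p <- ifelse(dgrid$se > 0, stats::pnorm(stat, lower.tail = FALSE), 1)
  stat[dgrid$se == 0] <- 0
  p_adj <- stats::p.adjust(p, method = "BH")
  dgrid$stat <- stat
  dgrid$p <- p
  dgrid$p_adj <- p_adj
  dgrid$c <- c
  dgrid$alpha <- alpha
  dgrid$min_p_adj <- min(p_adj)
  dgrid$involved <- dgrid$min_p_adj < alpha
  dgrid
}

#' Localize the expression peak of an involved gene
#'
#' The peak is the pseudotime where the first derivative crosses zero after
#' the grid point with the lowest adjusted p-value (first index on ties),
#' localized by linear interpolation between the bracketing grid points. If
#' the derivative never changes sign after that point the peak is placed at
#' the lineage end and flagged `lineage_end`.
#'
#' @param dgrid a tested `derivative_grid` (after [derivative_test()]).
#' @return one-row data.frame: `gene`, `lineage`, `involved`, `min_p_adj`,
#'   `peak_time` (NA when not involved), `peak_rule`
#'   (`"zero_crossing"`, `"lineage_end"`, or NA).
#' @export
detect_peak <- function(dgrid) {
  stopifnot(inherits(dgrid, "derivative_grid"))
  if (is.null(dgrid$p_adj)) stop("run derivative_test() first")
  out <- data.frame(gene = dgrid$gene, lineage = dgrid$lineage,
                    involved = dgrid$involved, min_p_adj = dgrid$min_p_adj,
                    peak_time = NA_real_, peak_rule = NA_character_,
                    stringsAsFactors = FALSE)
  if (!dgrid$involved) return(out)
  j0 <- which.min(dgrid$p_adj)           # first index on ties
  d <- dgrid$delta
  t <- dgrid$grid
  J <- length(t)
  peak <- NULL
  if (j0 < J) {
    for (j in j0:(J - 1L)) {
      if (d[j] == 0) { peak <- c(t[j], "zero_crossing"); break }
      if (sign(d[j]) != sign(d[j + 1L]) && d[j + 1L] != 0 || d[j + 1L] == 0) {
        tz <- t[j] + d[j] * (t[j + 1L] - t[j]) / (d[j] - d[j + 1L])
        peak <- c(tz, "zero_crossing")
        break
      }
    }
  }
  if (is.null(peak)) peak <- c(t[J], "lineage_end")
  out$peak_time <- as.numeric(peak[1])
  out$peak_rule <- peak[2]
  out
}

#' Run the cascade test over many fits and lineages
#'
#' Applies [estimate_derivatives()], [derivative_test()] and [detect_peak()]
#' to every (converged fit, lineage) pair.
#'
#' @param fits named list of `gene_fit` objects.
#' @param lineages lineage names to test; default all lineages of the first
#'   fit.
#' @inheritParams estimate_derivatives
#' @inheritParams derivative_test
#' @return data.frame of peak records, one row per (gene, lineage);
#'   degenerate or unconverged fits yield `involved = NA` rows.
#' @export
cascade_test <- function(fits, lineages = NULL, J = 100L, epsilon = 1e-7,
                         alpha = 0.05, c = 0.1) {
  if (is.null(lineages)) lineages <- fits[[1]]$lineages
  rows <- list()
  for (g in names(fits)) {
    fit <- fits[[g]]
    for (l in lineages) {
      if (fit$degenerate || !fit$converged) {
        rows[[length(rows) + 1L]] <- data.frame(
          gene = g, lineage = l, involved = NA, min_p_adj = NA_real_,
          peak_time = NA_real_, peak_rule = NA_character_,
          stringsAsFactors = FALSE)
      } else {
        dg <- derivative_test(estimate_derivatives(fit, l, J, epsilon),
                              alpha = alpha, c = c)
        rows[[length(rows) + 1L]] <- detect_peak(dg)
      }
    }
  }
  do.call(rbind, rows)
}

#' Build the cascade heatmap matrix for one lineage
#'
#' Evaluates each involved gene's fitted response-scale expression at the
#' midpoints of `n_bins` equal-width pseudotime bins, scales each row to
#' zero mean and unit variance, and orders rows by peak pseudotime
#' (ties broken by minimum adjusted p-value, then gene identifier).
#'
#' @param fits named list of `gene_fit` objects.
#' @param peaks peak-record data.frame from [cascade_test()].
#' @param lineage lineage name.
#' @param n_bins number of pseudotime bins (default 100).
#' @return gene x bin matrix of z-scaled fitted expression, rows in cascade
#'   order; empty (0-row) matrix with a warning when no gene is involved.
#' @export
build_cascade <- function(fits, peaks, lineage, n_bins = 100L) {
  pk <- peaks[peaks$lineage == lineage & peaks$involved %in% TRUE, ,
              drop = FALSE]
  if (nrow(pk) == 0L) {
    warning("no involved genes in lineage ", lineage)
    return(matrix(numeric(0), nrow = 0, ncol = n_bins))
  }
  ord <- order(pk$peak_time, pk$min_p_adj, pk$gene)
  pk <- pk[ord, , drop = FALSE]
  fit1 <- fits[[pk$gene[1]]]
  l <- match(lineage, fit1$lineages)
  r <- fit1$lineage_ranges[[l]]
  mids <- r[1] + (seq_len(n_bins) - 0.5) / n_bins * (r[2] - r[1])
  M <- t(vapply(pk$gene, function(g) {
    predict_smoother(fits[[g]], lineage, mids, scale = "response")
  }, numeric(n_bins)))
  M <- t(apply(M, 1L, function(x) {
    s <- stats::sd(x)
    if (s < 1e-12) rep(0, length(x)) else (x - mean(x)) / s
  }))
  rownames(M) <- pk$gene
  M
}

#' Lineage-specific transcription factors
#'
#' A gene involved in a lineage is classified as specific to it when the
#' maximum of its response-scale smoother in that lineage is at least
#' `ratio` times the corresponding maximum in every other lineage.
#'
#' @param fits named list of `gene_fit` objects.
#' @param peaks peak records from [cascade_test()] (supplies involvement).
#' @param ratio fold-difference threshold (default 1.5).
#' @param n_grid grid size for the smoother maxima.
#' @return named list, one character vector of gene identifiers per lineage.
#' @export
lineage_specific_tfs <- function(fits, peaks, ratio = 1.5, n_grid = 100L) {
  lineages <- fits[[1]]$lineages
  if (length(lineages) < 2L) {
    stop("lineage specificity is undefined for a single lineage")
  }
  maxima <- t(vapply(names(fits), function(g) {
    fit <- fits[[g]]
    if (fit$degenerate || !fit$converged) return(rep(NA_real_,
                                                     length(lineages)))
    vapply(lineages, function(l) {
      max(predict_smoother(fit, l, lineage_grid(fit, l, n_grid),
                           scale = "response"))
    }, numeric(1))
  }, numeric(length(lineages))))
  colnames(maxima) <- lineages
  out <- lapply(lineages, function(l) {
    inv <- peaks$gene[peaks$lineage == l & peaks$involved %in% TRUE]
    keep <- vapply(inv, function(g) {
      m <- maxima[g, ]
      all(is.finite(m)) && all(m[l] >= ratio * m[setdiff(lineages, l)])
    }, logical(1))
    sort(inv[keep])
  })
  names(out) <- lineages
  out
}

#' Shared transcription factors across lineages
#'
#' A gene is shared when it has a localized expression peak in every lineage
#' and the largest pairwise difference between its peak pseudotimes is below
#' `delta`.
#'
#' @param peaks peak records from [cascade_test()].
#' @param delta pseudotime window (default 1).
#' @return character vector of shared gene identifiers (sorted).
#' @export
shared_tfs <- function(peaks, delta = 1.0) {
  lineages <- unique(peaks$lineage)
  keep <- vapply(unique(peaks$gene), function(g) {
    pk <- peaks[peaks$gene == g & !is.na(peaks$peak_time), , drop = FALSE]
    nrow(pk) == length(lineages) &&
      (max(pk$peak_time) - min(pk$peak_time)) < delta
  }, logical(1))
  sort(unique(peaks$gene)[keep])
}

#' Cluster cascade rows
#'
#' Agglomerative hierarchical clustering of the scaled fitted-expression
#' rows on Euclidean distance, tree cut at `k` clusters.
#'
#' @param mat cascade matrix from [build_cascade()] (rows = genes).
#' @param k number of clusters; must not exceed the number of rows.
#' @param linkage agglomeration method (default Ward).
#' @return integer cluster labels 1..k named by gene.
#' @export
cluster_cascade <- function(mat, k, linkage = "ward.D2") {
  if (k > nrow(mat)) stop("k exceeds the number of rows")
  hc <- stats::hclust(stats::dist(mat), method = linkage)
  stats::cutree(hc, k = k)
}

#' Hypergeometric gene-set enrichment of a cluster
#'
#' For each gene set, tests over-representation of the cluster's genes with
#' an exact hypergeometric tail probability \eqn{P(X \ge \mathrm{overlap})},
#' where the set is first intersected with the universe. Results are sorted
#' by p-value, BH-adjusted, and truncated to the `top_n` most enriched sets.
#'
#' @param cluster_genes character vector of genes in the cluster (must lie
#'   in `universe`).
#' @param gene_sets named list of character vectors (e.g. from
#'   [read_gmt()]).
#' @param universe character vector of all tested genes.
#' @param top_n number of rows to keep (default 10).
#' @return data.frame: `set`, `set_size`, `overlap`, `p`, `p_adj`.
#' @export
enrich_hypergeom <- function(cluster_genes, gene_sets, universe,
                             top_n = 10L) {
  if (length(universe) == 0L) stop("empty universe")
  if (!all(cluster_genes %in% universe)) {
    stop("cluster genes must be a subset of the universe")
  }
  N <- length(universe)
  k <- length(cluster_genes)
  rows <- lapply(names(gene_sets), function(s) {
    set <- intersect(gene_sets[[s]], universe)
    m <- length(set)
    ov <- length(intersect(cluster_genes, set))
    p <- if (ov == 0L) 1 else
      stats::phyper(ov - 1L, m, N - m, k, lower.tail = FALSE)
    data.frame(set = s, set_size = m, overlap = ov, p = p,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$p_adj <- stats::p.adjust(tab$p, method = "BH")
  tab <- tab[order(tab$p, tab$set), , drop = FALSE]
  utils::head(tab, top_n)
}
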