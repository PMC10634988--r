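#' Assemble a trajectory dataset
#'
#' Bundles a gene-by-cell count matrix with the per-cell trajectory
#' information needed by the negative-binomial smoother fits: lineage
#' pseudotimes, a hard one-hot lineage assignment, sequencing-depth offsets
#' and optional cell-level covariates.
#'
#' @param counts gene x cell matrix of nonnegative integer counts
#'   (dense matrix or `Matrix` sparse matrix) with gene row names.
#' @param pseudotime either a numeric vector of length `ncol(counts)` (the
#'   pseudotime of each cell along its assigned lineage, shared across
#'   lineages) or a cell x lineage matrix of per-lineage pseudotimes.
#' @param lineage factor or character vector assigning every cell to exactly
#'   one lineage.
#' @param offset positive per-cell size factors \eqn{N_i}; default all 1.
#' @param covariates optional cell x covariate numeric model matrix
#'   \eqn{U} (e.g. batch indicators). Covariate effects are estimated
#'   jointly with the smoothers and set to zero for curve predictions.
#'
#' @return An object of class `trajectory_dataset` with elements
#'   `Y`, `T` (cell x lineage pseudotime), `Z` (cell x lineage one-hot),
#'   `U`, `N`, `lineages`.
#' @export
trajectory_dataset <- function(counts, pseudotime, lineage, offset = NULL,
                               covariates = NULL) {
  if (is.null(rownames(counts))) {
    stop("'counts' must have gene row names")
  }
  n <- ncol(counts)
  lineage <- as.factor(lineage)
  if (length(lineage) != n) {
    stop("'lineage' must have one entry per cell")
  }
  lineages <- levels(lineage)
  L <- length(lineages)
  if (is.matrix(pseudotime)) {
    if (nrow(pseudotime) != n || ncol(pseudotime) != L) {
      stop("'pseudotime' matrix must be cell x lineage")
    }
    Tmat <- pseudotime
  } else {
    if (length(pseudotime) != n) {
      stop("'pseudotime' must have one entry per cell")
    }
    Tmat <- matrix(rep(as.numeric(pseudotime), L), nrow = n, ncol = L)
  }
  colnames(Tmat) <- lineages
  Z <- matrix(0L, n, L, dimnames = list(colnames(counts), lineages))
  Z[cbind(seq_len(n), as.integer(lineage))] <- 1L
  if (is.null(offset)) offset <- rep(1, n)
  if (any(!is.finite(offset)) || any(offset <= 0)) {
    stop("offsets must be positive and finite")
  }
  t_assigned <- Tmat[cbind(seq_len(n), as.integer(lineage))]
  if (any(!is.finite(t_assigned)) || any(t_assigned < 0)) {
    stop("assigned-lineage pseudotimes must be finite and nonnegative")
  }
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != n) stop("'covariates' must have one row per cell")
  }
  structure(list(
    Y = counts,
    T = Tmat,
    Z = Z,
    U = covariates,
    N = as.numeric(offset),
    lineage = lineage,
    lineages = lineages
  ), class = "trajectory_dataset")
}

#' @export
print.trajectory_dataset <- function(x, ...) {
  cat(sprintf(
    "trajectory_dataset: %d genes x %d cells, %d lineages (%s)\n",
    nrow(x$Y), ncol(x$Y), length(x$lineages),
    paste(x$lineages, collapse = ", ")
  ))
  invisible(x)
}

#' Number of lineages in a trajectory dataset
#' @param data a `trajectory_dataset`
#' @return integer count of lineages
#' @export
n_lineages <- function(data) length(data$lineages)

# pseudotime of each cell along its assigned lineage
assigned_pseudotime <- function(data) {
  data$T[cbind(seq_len(nrow(data$Z)), as.integer(data$lineage))]
}

# per-lineage pseudotime range of the assigned cells
lineage_range <- function(data, lineage) {
  l <- lineage_index(data, lineage)
  t <- data$T[data$Z[, l] == 1L, l]
  range(t)
}

lineage_index <- function(data, lineage) {
  if (is.character(lineage)) {
    l <- match(lineage, data$lineages)
    if (is.na(l)) stop("unknown lineage: ", lineage)
    l
  } else {
    l <- as.integer(lineage)
    if (l < 1L || l > length(data$lineages)) stop("lineage index out of range")
    l
  }
}
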