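# Deconvolution of gene expression into per-cell transcription-factor
# activity. Observed counts for a GRN target gene are modelled as sums of
# latent TF-attributed molecule counts,
#   X_tgi ~ Poisson(N_i beta_tg a_ti),   Y_gi = sum_t X_tgi,
# with beta supported on the GRN edges. EM alternates responsibilities
# xi_tgi = beta_tg a_ti / sum_t' beta_t'g a_t'i with blockwise closed-form
# updates of beta and a; the expected molecules assigned to a TF are its
# activity proxy.

#' Load a gene regulatory network
#'
#' Accepts a three-column edge table (`tf`, `target`, `weight`) or a path to
#' a tab-separated file with those columns. Duplicate edges are summed;
#' negative weights are an error.
#'
#' @param edges data.frame or TSV path.
#' @return A `grn_model`: `tfs`, `targets`, `edges` (aggregated data.frame),
#'   and `W`, the TF x target weight matrix carrying the support.
#' @export
load_grn <- function(edges) {
  if (is.character(edges)) {
    edges <- utils::read.table(edges, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
  }
  if (ncol(edges) < 3L) stop("edge table needs columns tf, target, weight")
  edges <- edges[, 1:3]
  names(edges) <- c("tf", "target", "weight")
  if (nrow(edges) == 0L) {
    warning("empty GRN edge table")
    return(structure(list(tfs = character(0), targets = character(0),
                          edges = edges, W = matrix(0, 0, 0)),
                     class = "grn_model"))
  }
  if (any(!is.finite(edges$weight)) || any(edges$weight < 0)) {
    stop("edge weights must be finite and nonnegative")
  }
  agg <- stats::aggregate(weight ~ tf + target, data = edges, FUN = sum)
  if (nrow(agg) < nrow(edges)) {
    message(nrow(edges) - nrow(agg), " duplicate edges summed")
  }
  tfs <- sort(unique(agg$tf))
  targets <- sort(unique(agg$target))
  W <- matrix(0, length(tfs), length(targets),
              dimnames = list(tfs, targets))
  W[cbind(match(agg$tf, tfs), match(agg$target, targets))] <- agg$weight
  structure(list(tfs = tfs, targets = targets, edges = agg, W = W),
            class = "grn_model")
}

#' @export
print.grn_model <- function(x, ...) {
  cat(sprintf("grn_model: %d TFs, %d targets, %d edges\n",
              length(x$tfs), length(x$targets), nrow(x$edges)))
  invisible(x)
}

# Poisson log-likelihood (with the lgamma term, so values are comparable
# across independent implementations)
poisson_loglik <- function(Y, Lambda) {
  sum(stats::dpois(Y, pmax(Lambda, 1e-300), log = TRUE))
}

#' Fit the TF-activity model by expectation-maximization
#'
#' The E-step computes responsibilities
#' \eqn{\xi_{tgi} = \beta_{tg} a_{ti} / \sum_{t'} \beta_{t'g} a_{t'i}};
#' the M-step updates \eqn{\beta_{tg} \leftarrow \sum_i Y_{gi}\xi_{tgi} /
#' \sum_i N_i a_{ti}} and then, with responsibilities refreshed under the
#' new rates, \eqn{a_{ti} \leftarrow \sum_g Y_{gi}\xi_{tgi} /
#' (N_i \sum_g \beta_{tg})} — one block each per iteration, which keeps the
#' log-likelihood nondecreasing. Rates are initialized proportional to the
#' GRN edge weights (uniform on the support if all weights are zero) and
#' activities from seeded positive random draws. After convergence each
#' TF's rates are rescaled to sum to one, the scale being absorbed into the
#' activities (the likelihood is invariant to this).
#'
#' @param grn a `grn_model`.
#' @param counts gene x cell count matrix; rows are restricted to GRN
#'   targets (genes without a GRN parent are excluded, with a message).
#' @param offsets positive per-cell size factors \eqn{N_i}; default all 1.
#' @param seed integer seed for the activity initialization.
#' @param tol relative log-likelihood convergence tolerance (default 1e-8).
#' @param max_iter maximum EM iterations (default 500).
#' @return An `activity_fit`: `beta` (TF x target rate matrix, zero off the
#'   GRN support), `activity` (TF x cell), `loglik_trace` (nondecreasing),
#'   `converged`, `tfs`, `targets`, `offsets`. Cells with zero total count
#'   over the retained targets get an all-zero activity column and do not
#'   enter the M-step denominators.
#' @export
em_fit <- function(grn, counts, offsets = NULL, seed = 1L, tol = 1e-8,
                   max_iter = 500L) {
  keep <- rownames(counts) %in% grn$targets
  if (sum(!keep) > 0L) {
    message(sum(!keep), " genes without a GRN parent excluded before fitting")
  }
  Y <- as.matrix(counts[keep, , drop = FALSE])
  if (nrow(Y) == 0L || all(Y == 0)) stop("no nonzero counts on GRN targets")
  targets <- rownames(Y)
  W <- as.matrix(grn$W[, targets, drop = FALSE])
  tf_keep <- rowSums(W != 0) > 0
  W <- W[tf_keep, , drop = FALSE]
  tfs <- rownames(W)
  Tn <- nrow(W)
  n <- ncol(Y)
  if (is.null(offsets)) offsets <- rep(1, n)
  if (any(offsets <= 0)) stop("offsets must be positive")

  sup <- W != 0
  beta <- W
  if (all(beta == 0)) beta[sup] <- 1
  beta[sup & beta == 0] <- min(beta[beta > 0], 1)  # keep support positive
  beta <- beta / rowSums(beta)

  set.seed(seed)
  A <- matrix(stats::rexp(Tn * n) + 0.1, Tn, n,
              dimnames = list(tfs, colnames(Y)))
  zero_cells <- colSums(Y) == 0
  A[, zero_cells] <- 0

  floor_ <- 1e-12
  ll_trace <- numeric(0)
  converged <- FALSE
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    # beta block
    M <- crossprod(beta, A)                        # G x n mixture rates
    R <- Y / pmax(M, floor_)
    R[Y == 0] <- 0
    denom <- pmax(drop(A %*% offsets), floor_)     # sum_i N_i a_ti, per TF
    beta <- beta * (A %*% t(R)) / denom
    # activity block, responsibilities refreshed under the new rates
    M <- crossprod(beta, A)
    R <- Y / pmax(M, floor_)
    R[Y == 0] <- 0
    s_t <- pmax(rowSums(beta), floor_)
    A <- A * (beta %*% R) / outer(s_t, offsets)
    A[, zero_cells] <- 0

    Lambda <- sweep(crossprod(beta, A), 2L, offsets, "*")
    ll <- poisson_loglik(Y, Lambda)
    ll_trace <- c(ll_trace, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll_old) + 1)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  # identifiability: rates sum to one per TF, scale absorbed into activity
  s_t <- rowSums(beta)
  pos <- s_t > 0
  beta[pos, ] <- beta[pos, , drop = FALSE] / s_t[pos]
  A[pos, ] <- A[pos, , drop = FALSE] * s_t[pos]

  structure(list(beta = beta, activity = A, loglik_trace = ll_trace,
                 converged = converged, tfs = tfs, targets = targets,
                 offsets = offsets),
            class = "activity_fit")
}

#' @export
print.activity_fit <- function(x, ...) {
  cat(sprintf(
    "activity_fit: %d TFs x %d targets, %d cells, %d EM iterations (%s)\n",
    length(x$tfs), length(x$targets), ncol(x$activity),
    length(x$loglik_trace),
    if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Expected molecules assigned to each TF in each cell
#'
#' Distributes every observed target-gene count over that gene's GRN
#' parents according to the fitted responsibilities and sums per TF:
#' \eqn{A_{ti} = \sum_g Y_{gi}\,\xi_{tgi}}. Molecule conservation holds to
#' machine precision: the TF totals in a cell equal the cell's total target
#' count.
#'
#' @param fit an `activity_fit`.
#' @param counts the gene x cell count matrix the model was fitted to (rows
#'   are matched to the fit's retained targets).
#' @return TF x cell matrix of expected assigned molecule counts.
#' @export
assign_molecules <- function(fit, counts) {
  Y <- as.matrix(counts[fit$targets, , drop = FALSE])
  M <- crossprod(fit$beta, fit$activity)
  R <- Y / pmax(M, 1e-300)
  R[Y == 0] <- 0
  out <- fit$activity * (fit$beta %*% R)
  dimnames(out) <- list(fit$tfs, colnames(Y))
  out
}

#' Bin TF activity over pseudotime and cluster the profiles
#'
#' Averages each TF's activity within equal-width pseudotime bins, z-scales
#' each TF's binned profile, clusters the profiles hierarchically
#' (Ward linkage on Euclidean distance) and labels the clusters by the bin
#' of their mean-profile peak; with `k = 3` the labels are
#' early / mid / late in peak order.
#'
#' @param activity TF x cell activity matrix (e.g. from
#'   [assign_molecules()]).
#' @param pseudotime per-cell pseudotime, same cell order as `activity`.
#' @param n_bins number of equal-width bins (default 100). Empty bins are
#'   imputed by linear interpolation between neighbouring bins (message).
#' @param k number of TF clusters (default 3).
#' @return list with `binned` (TF x bin z-scaled matrix), `labels` (factor
#'   per TF, levels in peak order), `cluster` (integer labels from the tree
#'   cut).
#' @export
activity_over_pseudotime <- function(activity, pseudotime, n_bins = 100L,
                                     k = 3L) {
  if (n_bins < 2L) stop("need at least 2 bins")
  breaks <- seq(min(pseudotime), max(pseudotime), length.out = n_bins + 1L)
  bin <- cut(pseudotime, breaks = breaks, include.lowest = TRUE,
             labels = FALSE)
  binned <- t(vapply(seq_len(nrow(activity)), function(t_) {
    tapply(activity[t_, ], factor(bin, levels = seq_len(n_bins)), mean)
  }, numeric(n_bins)))
  rownames(binned) <- rownames(activity)
  if (anyNA(binned)) {
    message("empty pseudotime bins imputed by linear interpolation")
    binned <- t(apply(binned, 1L, function(x) {
      stats::approx(which(!is.na(x)), x[!is.na(x)], xout = seq_along(x),
                    rule = 2)$y
    }))
  }
  scaled <- t(apply(binned, 1L, function(x) {
    s <- stats::sd(x)
    if (s < 1e-12) rep(0, length(x)) else (x - mean(x)) / s
  }))
  if (k > nrow(scaled)) stop("k exceeds the number of TFs")
  cl <- if (nrow(scaled) == 1L) 1L else
    stats::cutree(stats::hclust(stats::dist(scaled),
                                method = "ward.D2"), k = k)
  peak_bin <- vapply(seq_len(k), function(j) {
    prof <- colMeans(scaled[cl == j, , drop = FALSE])
    which.max(prof)
  }, numeric(1))
  ord <- order(peak_bin)
  lab_names <- if (k == 3L) c("early", "mid", "late") else
    paste0("group", seq_len(k))
  labels <- factor(match(cl, ord), levels = seq_len(k), labels = lab_names)
  names(labels) <- rownames(activity)
  list(binned = scaled, labels = labels, cluster = cl)
}
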