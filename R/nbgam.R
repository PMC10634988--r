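# Negative-binomial regression-spline smoothers of pseudotime, one fit per
# gene. The model for gene g in cell i is
#   Y_gi ~ NB(mu_gi, phi_g),  log mu_gi = sum_l s_gl(T_li) Z_li + U_i alpha_g
#                                         + log N_i,
# with s_gl(t) = sum_k b_k(t) beta_glk a cubic B-spline smoother per lineage.
# Fitting alternates IRLS for (beta, alpha) at fixed dispersion with a
# univariate ML update of phi.

nb_loglik <- function(y, mu, phi) {
  sum(stats::dnbinom(y, size = phi, mu = mu, log = TRUE))
}

# Full design matrix: per-lineage basis blocks masked by the one-hot
# assignment, then covariates. Cells contribute only to their own lineage's
# coefficient block.
nbgam_design <- function(data, spec) {
  t_assigned <- assigned_pseudotime(data)
  spec <- realize_knots(spec, t_assigned)
  B <- build_basis(t_assigned, spec)
  L <- n_lineages(data)
  blocks <- lapply(seq_len(L), function(l) B * data$Z[, l])
  X <- do.call(cbind, blocks)
  colnames(X) <- paste0(rep(data$lineages, each = spec$K), ".",
                        rep(colnames(B), L))
  if (!is.null(data$U)) {
    U <- data$U
    if (is.null(colnames(U))) colnames(U) <- paste0("u", seq_len(ncol(U)))
    X <- cbind(X, U)
  }
  list(X = X, spec = spec)
}

irls_nb <- function(y, X, off, phi, coef_start = NULL, tol = 1e-8,
                    max_iter = 50L) {
  if (is.null(coef_start)) {
    eta <- log(pmax(y, 0.5)) - off
    w <- rep(1, length(y))
    fit <- stats::lm.wfit(X, eta, w)
    coefs <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
  } else {
    coefs <- coef_start
  }
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% coefs) + off
    mu <- pmin(exp(eta), 1e12)
    w <- mu / (1 + mu / phi)
    z <- (eta - off) + (y - mu) / mu
    fit <- stats::lm.wfit(X, z, w)
    coefs_new <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
    mu_new <- pmin(exp(drop(X %*% coefs_new) + off), 1e12)
    ll <- nb_loglik(y, mu_new, phi)
    # step-halve if the quadratic approximation overshoots
    step <- 1
    while (!is.finite(ll) || ll < ll_old - 1e-10) {
      step <- step / 2
      if (step < 1e-10) { coefs_new <- coefs; ll <- ll_old; break }
      coefs_new <- coefs + step * (coefs_new - coefs)
      mu_new <- pmin(exp(drop(X %*% coefs_new) + off), 1e12)
      ll <- nb_loglik(y, mu_new, phi)
    }
    done <- is.finite(ll_old) && abs(ll - ll_old) <
      tol * (abs(ll_old) + 1)
    coefs <- coefs_new
    ll_old <- ll
    if (done) break
  }
  list(coefficients = coefs, loglik = ll_old)
}

update_phi <- function(y, mu, lower = 1e-8, upper = 1e8) {
  opt <- stats::optimize(function(lp) nb_loglik(y, mu, exp(lp)),
                         interval = log(c(lower, upper)), maximum = TRUE,
                         tol = 1e-10)
  min(max(exp(opt$maximum), lower), upper)
}

#' Fit the negative-binomial spline smoother for one gene
#'
#' Maximizes the NB log-likelihood over the lineage-specific spline
#' coefficients and covariate effects by iteratively reweighted least
#' squares, alternating with a univariate maximum-likelihood update of the
#' gene-wise dispersion. The coefficient covariance is the inverse observed
#' information at the optimum with the dispersion held at its estimate.
#'
#' @param data a [trajectory_dataset()].
#' @param gene gene identifier (row name of `data$Y`).
#' @param spec a [spline_spec()]; knots are realized from the assigned
#'   cells' pseudotimes on first use.
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter maximum number of outer (coefficient/dispersion)
#'   alternations.
#' @return A `gene_fit` object with elements `beta` (lineage x K coefficient
#'   matrix), `alpha` (covariate coefficients), `phi`, `V` (covariance of
#'   `(beta, alpha)`), `loglik`, `aic`, `converged`, `degenerate`, the
#'   realized `spec`, per-lineage pseudotime ranges and metadata. All-zero
#'   genes yield a degenerate fit (flagged, not an error) that downstream
#'   tests skip.
#' @export
fit_gene <- function(data, gene, spec = spline_spec(), tol = 1e-8,
                     max_iter = 200L) {
  if (!gene %in% rownames(data$Y)) stop("gene not found: ", gene)
  y <- as.numeric(data$Y[gene, ])
  L <- n_lineages(data)
  des <- nbgam_design(data, spec)
  spec <- des$spec
  ranges <- lapply(seq_len(L), function(l) lineage_range(data, l))
  names(ranges) <- data$lineages
  p_cov <- if (is.null(data$U)) 0L else ncol(data$U)
  if (all(y == 0)) {
    return(structure(list(
      gene = gene, beta = matrix(NA_real_, L, spec$K,
                                 dimnames = list(data$lineages, NULL)),
      alpha = rep(NA_real_, p_cov), phi = NA_real_, V = NULL,
      loglik = NA_real_, aic = NA_real_, converged = FALSE,
      degenerate = TRUE, spec = spec, lineages = data$lineages,
      lineage_ranges = ranges, n = length(y)
    ), class = "gene_fit"))
  }
  X <- des$X
  off <- log(data$N)

  m <- mean(y); v <- stats::var(y)
  phi <- if (is.finite(v) && v > m) max(m^2 / (v - m), 1e-3) else 100
  coefs <- NULL
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    ir <- irls_nb(y, X, off, phi, coef_start = coefs, tol = tol)
    coefs <- ir$coefficients
    mu <- pmin(exp(drop(X %*% coefs) + off), 1e12)
    phi <- update_phi(y, mu)
    ll <- nb_loglik(y, mu, phi)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll_old) + 1)) {
      converged <- TRUE
      ll_old <- ll
      break
    }
    ll_old <- ll
  }
  ll <- ll_old

  # observed information for (beta, alpha) at fixed phi:
  # -d2 loglik / deta2 = (y + phi) phi mu / (mu + phi)^2
  w_obs <- (y + phi) * phi * mu / (mu + phi)^2
  info <- crossprod(X, w_obs * X)
  V <- tryCatch(chol2inv(chol(info)), error = function(e) {
    ridge <- diag(1e-8 * max(diag(info)), ncol(info))
    solve(info + ridge)
  })
  dimnames(V) <- list(colnames(X), colnames(X))

  beta <- matrix(coefs[seq_len(L * spec$K)], nrow = L, byrow = TRUE,
                 dimnames = list(data$lineages, NULL))
  alpha <- if (p_cov > 0) coefs[L * spec$K + seq_len(p_cov)] else numeric(0)
  n_par <- length(coefs)
  structure(list(
    gene = gene, beta = beta, alpha = alpha, phi = phi, V = V,
    loglik = ll, aic = -2 * ll + 2 * n_par, converged = converged,
    degenerate = FALSE, spec = spec, lineages = data$lineages,
    lineage_ranges = ranges, n = length(y)
  ), class = "gene_fit")
}

#' @export
print.gene_fit <- function(x, ...) {
  if (x$degenerate) {
    cat(sprintf("gene_fit '%s': degenerate (all-zero counts)\n", x$gene))
  } else {
    cat(sprintf(
      "gene_fit '%s': %d lineages x K=%d, phi=%.3g, loglik=%.2f, %s\n",
      x$gene, nrow(x$beta), x$spec$K, x$phi, x$loglik,
      if (x$converged) "converged" else "NOT converged"))
  }
  invisible(x)
}

# indices of the coefficient block for one lineage inside (beta, alpha)
lineage_block <- function(fit, lineage) {
  l <- if (is.character(lineage)) match(lineage, fit$lineages) else
    as.integer(lineage)
  if (is.na(l) || l < 1L || l > nrow(fit$beta)) stop("unknown lineage")
  (l - 1L) * fit$spec$K + seq_len(fit$spec$K)
}

#' Evaluate a fitted lineage smoother on a pseudotime grid
#'
#' On the link scale this returns \eqn{s_{gl}(t) = \sum_k b_k(t)
#' \beta_{glk}}; on the response scale, \eqn{\exp(s_{gl}(t))} with offsets
#' excluded and covariates at their zero reference, so curves are
#' comparable across lineages.
#'
#' @param fit a `gene_fit`.
#' @param lineage lineage name or index.
#' @param grid pseudotimes within the knot span.
#' @param scale `"link"` or `"response"`.
#' @return numeric vector of fitted values along `grid`.
#' @export
predict_smoother <- function(fit, lineage, grid,
                             scale = c("link", "response")) {
  scale <- match.arg(scale)
  if (fit$degenerate) stop("cannot predict from a degenerate fit")
  l <- if (is.character(lineage)) match(lineage, fit$lineages) else
    as.integer(lineage)
  B <- build_basis(grid, fit$spec)
  eta <- drop(B %*% fit$beta[l, ])
  if (scale == "link") eta else exp(eta)
}

#' Grid of equally spaced pseudotimes over a lineage's range
#' @param fit a `gene_fit`
#' @param lineage lineage name or index
#' @param J number of grid points
#' @return numeric vector of length `J`
#' @export
lineage_grid <- function(fit, lineage, J = 100L) {
  l <- if (is.character(lineage)) match(lineage, fit$lineages) else
    as.integer(lineage)
  r <- fit$lineage_ranges[[l]]
  seq(r[1], r[2], length.out = J)
}

#' Wald association test along one lineage
#'
#' Tests the null hypothesis that the smoother is constant along the
#' lineage, using contrasts of the linear predictor at `n_eval` equally
#' spaced pseudotimes against their mean, referenced to a chi-square
#' distribution with degrees of freedom equal to the contrast rank. A gene
#' is additionally labelled `upregulated` when the predicted mean at the
#' lineage end exceeds the predicted mean at its start.
#'
#' @param fit a `gene_fit`.
#' @param lineage lineage name or index.
#' @param n_eval number of evaluation points for the contrast.
#' @return list with `wald_stat`, `df`, `p_value`, `upregulated`. Degenerate
#'   fits return an all-`NA` record.
#' @export
association_test <- function(fit, lineage, n_eval = 12L) {
  if (fit$degenerate || !fit$converged) {
    return(list(wald_stat = NA_real_, df = NA_integer_, p_value = NA_real_,
                upregulated = NA))
  }
  grid <- lineage_grid(fit, lineage, n_eval)
  B <- build_basis(grid, fit$spec)
  C <- sweep(B, 2, colMeans(B))          # contrasts vs the grid mean
  idx <- lineage_block(fit, lineage)
  l <- if (is.character(lineage)) match(lineage, fit$lineages) else
    as.integer(lineage)
  eta_c <- drop(C %*% fit$beta[l, ])
  S <- C %*% fit$V[idx, idx] %*% t(C)
  eg <- eigen(S, symmetric = TRUE)
  pos <- eg$values > max(eg$values) * 1e-10
  df <- sum(pos)
  if (df == 0) {
    stat <- 0
  } else {
    Sinv_half <- eg$vectors[, pos, drop = FALSE] %*%
      diag(1 / sqrt(eg$values[pos]), df)
    stat <- sum(drop(crossprod(Sinv_half, eta_c))^2)
  }
  ends <- predict_smoother(fit, lineage, range(grid), scale = "response")
  list(wald_stat = stat, df = df,
       p_value = stats::pchisq(stat, df = max(df, 1), lower.tail = FALSE),
       upregulated = unname(ends[2] > ends[1]))
}

#' Choose the number of basis functions by mean AIC
#'
#' Fits a subset of genes at each candidate `K` and returns the candidate
#' minimizing the mean AIC over the subset. Candidates infeasible for the
#' data (fewer distinct pseudotimes than K) are skipped with a warning.
#'
#' @param data a [trajectory_dataset()].
#' @param genes gene identifiers to fit.
#' @param candidates integer vector of candidate `K` values.
#' @return the chosen `K`, with the per-candidate mean-AIC table attached as
#'   attribute `"aic_table"`.
#' @export
select_knots_aic <- function(data, genes, candidates = c(4L, 6L, 8L)) {
  candidates <- sort(unique(as.integer(candidates)))
  mean_aic <- rep(NA_real_, length(candidates))
  for (j in seq_along(candidates)) {
    aics <- tryCatch({
      vapply(genes, function(g) {
        f <- fit_gene(data, g, spline_spec(K = candidates[j]))
        if (f$degenerate) NA_real_ else f$aic
      }, numeric(1))
    }, error = function(e) {
      warning("skipping K = ", candidates[j], ": ", conditionMessage(e))
      NULL
    })
    if (!is.null(aics)) mean_aic[j] <- mean(aics, na.rm = TRUE)
  }
  if (all(is.na(mean_aic))) stop("no feasible candidate K")
  tab <- data.frame(K = candidates, mean_aic = mean_aic)
  chosen <- candidates[which.min(mean_aic)]
  attr(chosen, "aic_table") <- tab
  chosen
}

#' Fit smoothers for many genes
#'
#' Convenience wrapper applying [fit_gene()] across genes.
#'
#' @inheritParams fit_gene
#' @param genes gene identifiers; default all rows of the count matrix.
#' @return named list of `gene_fit` objects.
#' @export
fit_genes <- function(data, genes = rownames(data$Y), spec = spline_spec(),
                      tol = 1e-8, max_iter = 200L) {
  fits <- lapply(genes, function(g) fit_gene(data, g, spec, tol, max_iter))
  names(fits) <- genes
  fits
}
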