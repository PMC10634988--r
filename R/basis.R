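#' Specify the spline basis for lineage smoothers
#'
#' The smoother for each gene and lineage is an unpenalized clamped cubic
#' B-spline with `K` basis functions shared across genes and lineages.
#' Interior knots are placed at quantiles of the assigned cells'
#' pseudotimes; boundary knots sit at the pseudotime minimum and maximum
#' and are repeated to full multiplicity, so the basis is a partition of
#' unity over the whole span.
#'
#' @param K number of basis functions (equivalently, regression
#'   coefficients per lineage); default 6.
#' @param degree spline degree; cubic (3) is the only supported value.
#' @param knots optional realized knot vector (length `K + degree + 1`,
#'   nondecreasing, boundary knots repeated `degree + 1` times). Usually
#'   left `NULL` and realized from data by [build_basis()] or [fit_gene()].
#' @return An object of class `spline_spec`.
#' @export
spline_spec <- function(K = 6, degree = 3, knots = NULL) {
  if (K < degree + 1) stop("K must be at least degree + 1 (>= 4 for cubic)")
  if (degree != 3) stop("only cubic splines are supported")
  if (!is.null(knots)) {
    if (length(knots) != K + degree + 1) {
      stop("realized knot vector must have length K + degree + 1")
    }
    if (is.unsorted(knots)) stop("knots must be nondecreasing")
  }
  structure(list(K = as.integer(K), degree = as.integer(degree),
                 knots = knots),
            class = "spline_spec")
}

# Place interior knots at quantiles of the pseudotimes, boundary knots at
# min/max with full multiplicity. Realizes spec$knots if not yet set.
realize_knots <- function(spec, pseudotimes) {
  if (!is.null(spec$knots)) return(spec)
  K <- spec$K
  d <- spec$degree
  if (length(unique(pseudotimes)) < K) {
    stop("need at least K distinct pseudotime values to place knots")
  }
  n_interior <- K - d - 1L
  bounds <- range(pseudotimes)
  interior <- if (n_interior > 0L) {
    probs <- seq_len(n_interior) / (n_interior + 1)
    as.numeric(stats::quantile(pseudotimes, probs = probs, names = FALSE))
  } else {
    numeric(0)
  }
  spec$knots <- c(rep(bounds[1], d + 1L), interior, rep(bounds[2], d + 1L))
  spec
}

knot_span <- function(spec) {
  if (is.null(spec$knots)) stop("spline_spec has no realized knots")
  range(spec$knots)
}

#' Evaluate the cubic B-spline basis
#'
#' Returns the n x K matrix of basis function values \eqn{b_k(t)} at the
#' given pseudotimes. If the spec carries no realized knots they are placed
#' from the input pseudotimes (quantile rule). Rows sum to one, and at the
#' left boundary knot the row is (1, 0, ..., 0) (clamped basis).
#'
#' @param pseudotimes numeric vector of evaluation points, within the knot
#'   span once knots are realized.
#' @param spec a [spline_spec()].
#' @param derivs integer derivative order for each evaluation (scalar);
#'   0 for function values.
#' @return numeric matrix with one row per pseudotime and `K` columns.
#' @export
build_basis <- function(pseudotimes, spec = spline_spec(), derivs = 0L) {
  spec <- realize_knots(spec, pseudotimes)
  span <- knot_span(spec)
  if (any(pseudotimes < span[1] | pseudotimes > span[2])) {
    stop("pseudotimes outside the knot span; extrapolation is not supported")
  }
  B <- splines::splineDesign(spec$knots, x = pseudotimes,
                             ord = spec$degree + 1L,
                             derivs = rep(as.integer(derivs),
                                          length(pseudotimes)))
  colnames(B) <- paste0("b", seq_len(spec$K))
  B
}
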