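# Derivative estimation, the thresholded grid test, peak localization and
# the downstream cascade ordering/classification rules.

test_that("finite differences are exact for constant and affine smoothers", {
  const <- make_fit(matrix(2, 1, 6))
  dg <- estimate_derivatives(const, 1, J = 50)
  # finite differencing at step 1e-7 leaves ~1e-9 cancellation noise
  expect_lt(max(abs(dg$delta)), 1e-6)
  # coefficients at the Greville abscissae reproduce the line m*t + b
  tau <- default_knots()
  grev <- vapply(1:6, function(k) mean(tau[(k + 1):(k + 3)]), numeric(1))
  m <- 0.37; b <- -1.2
  lin <- make_fit(matrix(m * grev + b, 1))
  dg <- estimate_derivatives(lin, 1, J = 50)
  interior <- !dg$boundary
  expect_equal(dg$delta[interior], rep(m, sum(interior)), tolerance = 1e-6)
  expect_true(all(dg$boundary[c(1, 50)]))
})

test_that("finite differences match the analytic B-spline derivative", {
  set.seed(7)
  tau <- default_knots()
  for (r in 1:20) {
    beta <- rnorm(6, sd = 2)
    fit <- make_fit(matrix(beta, 1))
    dg <- estimate_derivatives(fit, 1, J = 60)
    interior <- !dg$boundary
    oracle <- bspline_deriv_oracle(dg$grid[interior], tau, beta)
    rel <- max(abs(dg$delta[interior] - oracle)) / max(abs(oracle))
    expect_lt(rel, 1e-4)
  }
})

test_that("derivative standard errors propagate the coefficient covariance", {
  set.seed(8)
  Vh <- matrix(rnorm(36), 6)
  V <- crossprod(Vh)
  fit <- make_fit(matrix(rnorm(6), 1), V = V)
  dg <- estimate_derivatives(fit, 1, J = 11)
  eps <- dg$epsilon
  for (j in c(3, 6, 9)) {
    t0 <- dg$grid[j]
    d <- (splines::splineDesign(default_knots(), t0 + eps, ord = 4) -
            splines::splineDesign(default_knots(), t0 - eps, ord = 4)) /
      (2 * eps)
    expect_equal(dg$se[j], sqrt(drop(d %*% V %*% t(d))), tolerance = 1e-8)
  }
})

test_that("thresholded test defaults and null behaviour follow the rules", {
  expect_identical(formals(derivative_test)$c, 0.1)
  expect_identical(formals(estimate_derivatives)$epsilon, 1e-7)
  expect_identical(formals(estimate_derivatives)$J, 100L)
  # derivative never above c: statistic 0, p = 0.5 everywhere, not involved
  tau <- default_knots()
  grev <- vapply(1:6, function(k) mean(tau[(k + 1):(k + 3)]), numeric(1))
  slow <- make_fit(matrix(0.05 * grev, 1))        # slope 0.05 < c
  dg <- derivative_test(estimate_derivatives(slow, 1, J = 40))
  expect_equal(dg$stat, rep(0, 40))
  expect_equal(dg$p, rep(0.5, 40))
  expect_false(dg$involved)
  # zero standard error is conservative, not an involvement call
  degen <- make_fit(matrix(5 * grev, 1), V = matrix(0, 6, 6))
  dgz <- derivative_test(estimate_derivatives(degen, 1, J = 10))
  expect_equal(dgz$p, rep(1, 10))
  expect_false(dgz$involved)
})

test_that("BH adjustment matches the step-up formula and is monotone", {
  p <- c(0.01, 0.02, 0.04, 0.5)
  expect_equal(p.adjust(p, "BH"), c(0.04, 0.04, 0.16 / 3, 0.5),
               tolerance = 1e-12)
  expect_equal(p.adjust(p, "BH"), bh_oracle(p), tolerance = 1e-12)
  set.seed(9)
  for (r in 1:10) {
    p <- runif(50)
    adj <- p.adjust(p, "BH")
    expect_equal(adj, bh_oracle(p), tolerance = 1e-12)
    o <- order(p)
    expect_true(all(diff(adj[o]) > -1e-15))       # monotone in raw p
    perm <- sample(50)
    expect_equal(p.adjust(p[perm], "BH"), adj[perm], tolerance = 1e-15)
  }
})

test_that("peaks are localized at the first post-minimum zero crossing", {
  # construct a derivative grid directly: positive then negative with the
  # interpolated zero at exactly t = 5
  J <- 101
  grid <- seq(0, 10, length.out = J)
  dgrid <- structure(list(
    gene = "g", lineage = "L1", grid = grid, delta = 5 - grid,
    se = rep(0.1, J), boundary = rep(FALSE, J), epsilon = 1e-7),
    class = "derivative_grid")
  dgrid <- derivative_test(dgrid)
  expect_true(dgrid$involved)
  expect_lte(which.min(dgrid$p_adj), which.min(abs(grid - 5)))
  pk <- detect_peak(dgrid)
  expect_equal(pk$peak_time, 5, tolerance = 1e-9)
  expect_equal(pk$peak_rule, "zero_crossing")
  # always-positive derivative: peak at the lineage end, flagged
  dgrid2 <- dgrid
  dgrid2$delta <- rep(1, J)
  dgrid2 <- derivative_test(dgrid2)
  pk2 <- detect_peak(dgrid2)
  expect_equal(pk2$peak_time, 10)
  expect_equal(pk2$peak_rule, "lineage_end")
  # not involved: no peak
  dgrid3 <- dgrid
  dgrid3$delta <- rep(0, J)
  dgrid3 <- derivative_test(dgrid3)
  pk3 <- detect_peak(dgrid3)
  expect_false(pk3$involved)
  expect_true(is.na(pk3$peak_time))
})

test_that("cascade matrix is z-scaled and ordered by peak time", {
  expect_identical(formals(build_cascade)$n_bins, 100L)
  progs <- rbind(
    gene_program("early", baseline = log(2), amplitude = 1.5,
                 peak_time = 2, width = 1, n_lineages = 1L),
    gene_program("late", baseline = log(2), amplitude = 1.5,
                 peak_time = 8, width = 1, n_lineages = 1L))
  sim <- simulate_trajectory_counts(progs, cells_per_lineage = 300,
                                    seed = 41)
  fits <- fit_genes(sim$data)
  peaks <- cascade_test(fits)
  expect_true(all(peaks$involved))
  M <- build_cascade(fits, peaks, "L1")
  expect_equal(rownames(M), c("early", "late"))
  expect_equal(dim(M), c(2L, 100L))
  expect_equal(rowMeans(M), c(early = 0, late = 0), tolerance = 1e-9)
  expect_equal(apply(M, 1, var), c(early = 1, late = 1), tolerance = 1e-9)
  # one involved gene: single scaled row; none: empty matrix with warning
  M1 <- build_cascade(fits, peaks[peaks$gene == "early", ], "L1")
  expect_equal(dim(M1), c(1L, 100L))
  expect_warning(M0 <- build_cascade(fits, peaks[0, ], "L1"), "no involved")
  expect_equal(nrow(M0), 0L)
})

test_that("lineage-specific rule applies the fold threshold on smoother maxima", {
  expect_identical(formals(lineage_specific_tfs)$ratio, 1.5)
  tau <- default_knots()
  # response-scale maxima (10, 4, 4): specific to lineage 1 since 10 >= 1.5*4
  b_hi <- rep(log(10), 6); b_lo <- rep(log(4), 6)
  fit_spec <- make_fit(rbind(b_hi, b_lo, b_lo), gene = "tfA",
                       V = diag(1e-4, 18))
  fit_same <- make_fit(rbind(b_lo, b_lo, b_lo), gene = "tfB",
                       V = diag(1e-4, 18))
  fits <- list(tfA = fit_spec, tfB = fit_same)
  peaks <- data.frame(
    gene = rep(c("tfA", "tfB"), each = 3),
    lineage = rep(c("L1", "L2", "L3"), 2),
    involved = TRUE, min_p_adj = 1e-6,
    peak_time = 5, peak_rule = "zero_crossing", stringsAsFactors = FALSE)
  out <- lineage_specific_tfs(fits, peaks)
  expect_equal(out$L1, "tfA")
  expect_equal(out$L2, character(0))   # identical smoothers: specific nowhere
  expect_equal(out$L3, character(0))
  # ratio just above the observed fold excludes the gene
  out2 <- lineage_specific_tfs(fits, peaks, ratio = 2.6)
  expect_equal(out2$L1, character(0))
  single <- list(tfA = make_fit(matrix(0, 1, 6)))
  expect_error(lineage_specific_tfs(single, peaks), "single lineage")
})

test_that("shared rule is the pairwise peak-difference window", {
  expect_identical(formals(shared_tfs)$delta, 1.0)
  mk <- function(gene, pts) data.frame(
    gene = gene, lineage = c("L1", "L2", "L3"), involved = TRUE,
    min_p_adj = 1e-6, peak_time = pts, peak_rule = "zero_crossing",
    stringsAsFactors = FALSE)
  peaks <- rbind(mk("same", c(2, 2, 2)), mk("near", c(2, 2.9, 2.2)),
                 mk("far", c(2, 3.5, 2.2)))
  expect_equal(shared_tfs(peaks), c("near", "same"))
  # a gene lacking a peak in one lineage is never shared
  part <- mk("part", c(2, 2, NA))
  part$peak_time[3] <- NA
  expect_equal(shared_tfs(rbind(peaks, part)), c("near", "same"))
  # pure function of inputs: permuting rows permutes nothing in the set
  perm <- peaks[sample(nrow(peaks)), ]
  expect_equal(shared_tfs(perm), shared_tfs(peaks))
})

test_that("cascade clustering separates well-separated profile groups", {
  set.seed(51)
  g1 <- t(replicate(6, sin(seq(0, pi, length.out = 40)) + rnorm(40, 0, .05)))
  g2 <- t(replicate(6, cos(seq(0, 2 * pi, length.out = 40)) +
                      rnorm(40, 0, .05)))
  M <- rbind(g1, g2)
  rownames(M) <- paste0("tf", 1:12)
  cl <- cluster_cascade(M, k = 2)
  expect_equal(ari_oracle(cl, rep(1:2, each = 6)), 1)
  expect_equal(unname(cluster_cascade(M, k = 12)), 1:12)
  expect_error(cluster_cascade(M, k = 13), "exceeds")
})

test_that("hypergeometric enrichment matches exact tail enumeration", {
  universe <- paste0("g", 1:20)
  sets <- list(hit = paste0("g", 1:5), miss = paste0("g", 16:20),
               off = paste0("x", 1:4))
  cluster <- paste0("g", c(1:4, 11))
  tab <- enrich_hypergeom(cluster, sets, universe)
  expect_equal(tab$p[tab$set == "hit"], hyper_tail_oracle(4, 20, 5, 5),
               tolerance = 1e-12)
  expect_equal(tab$p[tab$set == "off"], 1)        # zero overlap
  expect_equal(tab$p_adj, p.adjust(tab$p, "BH"), tolerance = 1e-12)
  # cluster = universe forces every overlap: p = 1 for all sets
  tab2 <- enrich_hypergeom(universe, sets, universe)
  expect_true(all(tab2$p == 1))
  expect_error(enrich_hypergeom(cluster, sets, character(0)), "universe")
  expect_equal(nrow(enrich_hypergeom(cluster, sets, universe, top_n = 2)), 2)
})
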