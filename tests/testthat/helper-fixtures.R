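# Fixture builders shared across test files. Everything is generated in
# code; no data files.

default_knots <- function(K = 6L, lo = 0, hi = 10) {
  interior <- if (K > 4L) seq(lo, hi, length.out = K - 2L)[2:(K - 3L)]
  else numeric(0)
  c(rep(lo, 4L), interior, rep(hi, 4L))
}

# hand-assembled gene_fit, bypassing estimation: coefficients and
# covariance are specified directly so cascade operations can be tested
# against constructed ground truth
make_fit <- function(beta, gene = "g", lo = 0, hi = 10, V = NULL,
                     phi = 2, lineages = NULL) {
  beta <- rbind(beta)
  L <- nrow(beta); K <- ncol(beta)
  if (is.null(lineages)) lineages <- paste0("L", seq_len(L))
  rownames(beta) <- lineages
  if (is.null(V)) V <- diag(1e-4, L * K)
  ranges <- rep(list(c(lo, hi)), L)
  names(ranges) <- lineages
  structure(list(
    gene = gene, beta = beta, alpha = numeric(0), phi = phi, V = V,
    loglik = 0, aic = 0, converged = TRUE, degenerate = FALSE,
    spec = tfcascade::spline_spec(K = K, knots = default_knots(K, lo, hi)),
    lineages = lineages, lineage_ranges = ranges, n = 0L
  ), class = "gene_fit")
}

# bump programs with randomized parameters; widths stay at or above 1.3
# pseudotime units (the narrowest feature the 6-coefficient basis resolves
# without attenuation over a 10-unit range) and amplitudes at or above
# 1.7 natural-log units so the expected peak slope amplitude*exp(-1/2)/width
# clears the derivative threshold by several gridwise standard errors at
# 300 cells per lineage
random_bump_programs <- function(n_genes, n_lineages = 3L, seed = 1L,
                                 peak_range = c(1, 9)) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(n_genes), function(j) {
    tfcascade::gene_program(
      sprintf("g%03d", j),
      baseline = runif(n_lineages, log(0.5), log(5)),
      amplitude = runif(n_lineages, 1.7, 2.5),
      peak_time = runif(n_lineages, peak_range[1], peak_range[2]),
      width = runif(n_lineages, 1.3, 2),
      dispersion = 2, n_lineages = n_lineages)
  }))
}

flat_programs <- function(n_genes, n_lineages = 3L, baseline = log(5),
                          dispersion = 2) {
  do.call(rbind, lapply(seq_len(n_genes), function(j) {
    tfcascade::gene_program(sprintf("flat%03d", j), baseline = baseline,
                            amplitude = 0, dispersion = dispersion,
                            n_lineages = n_lineages)
  }))
}

# full priming pipeline from the generator's output to class calls
run_priming_pipeline <- function(sim, flank = 2000) {
  win <- tfcascade::tss_windows(sim$tss, flank = flank)
  acc <- data.frame(
    gene = names(win),
    acc_pre = tfcascade::count_fragments(sim$fragments_pre, win)$cpm,
    acc_post = tfcascade::count_fragments(sim$fragments_post, win)$cpm,
    stringsAsFactors = FALSE)
  expr <- merge(sim$expr, sim$de, by = "gene")
  silent <- as.character(sim$truth$gene[sim$truth$class == "silent_closed"])
  tfcascade::classify_priming(expr, acc, silent_genes = silent)
}
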