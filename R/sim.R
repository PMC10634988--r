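# Synthetic-data generators with ground truth for every pipeline stage:
# branching NB trajectory counts with known lineage-specific bump means,
# Poisson counts from a known GRN with known per-cell TF activities, and
# paired pre/post-injury expression plus accessibility fragments with known
# priming classes.

#' Gene expression programs for the trajectory generator
#'
#' Each (gene, lineage) has a log-scale Gaussian-bump mean function
#' \eqn{\log\mu(t) = \mathrm{baseline} + \mathrm{amplitude}\cdot
#' \exp(-(t - \mathrm{peak})^2 / (2\,\mathrm{width}^2))}, which guarantees a
#' unique interior peak and a one-signed derivative before it, so the true
#' peak is well defined for recovery checks. Amplitude 0 in every lineage
#' marks a null (flat) gene.
#'
#' @param gene_id gene identifier.
#' @param baseline per-lineage log-mean (natural log counts), recycled.
#' @param amplitude per-lineage bump height on the log scale (>= 0).
#' @param peak_time per-lineage bump position (pseudotime units).
#' @param width per-lineage bump width (> 0, pseudotime units).
#' @param dispersion NB size parameter (> 0), one per gene.
#' @param n_lineages number of lineages.
#' @return data.frame in long format (one row per gene x lineage) with a
#'   `dispersion` column; class `gene_program`.
#' @export
gene_program <- function(gene_id, baseline = log(2), amplitude = 0,
                         peak_time = 5, width = 1, dispersion = 2,
                         n_lineages = 3L) {
  if (any(width <= 0)) stop("width must be positive")
  if (any(dispersion <= 0)) stop("dispersion must be positive")
  if (any(amplitude < 0)) stop("amplitude must be nonnegative")
  out <- data.frame(
    gene_id = gene_id,
    lineage = paste0("L", seq_len(n_lineages)),
    baseline = rep_len(baseline, n_lineages),
    amplitude = rep_len(amplitude, n_lineages),
    peak_time = rep_len(peak_time, n_lineages),
    width = rep_len(width, n_lineages),
    dispersion = dispersion,
    stringsAsFactors = FALSE)
  class(out) <- c("gene_program", "data.frame")
  out
}

# log-scale bump mean function
bump_log_mean <- function(t, baseline, amplitude, peak_time, width) {
  baseline + amplitude * exp(-(t - peak_time)^2 / (2 * width^2))
}

# amplitude below this never pushes the derivative above the cascade
# threshold in expectation, so truth marks such (gene, lineage) uninvolved
DETECTABILITY_FLOOR <- 0.5

#' Simulate branching trajectory counts with known bump programs
#'
#' Cells are split evenly over the lineages with pseudotimes drawn
#' uniformly over a shared range (all lineages share the trajectory
#' origin); per-cell offsets are log-normal around 1 (sdlog 0.3); counts
#' are negative binomial with the program's bump mean scaled by the offset.
#'
#' @param programs `gene_program` rows for every gene (stack with `rbind`).
#' @param cells_per_lineage number of cells per lineage (>= 2).
#' @param pseudotime_range length-2 numeric, shared across lineages
#'   (default `c(0, 10)`).
#' @param seed integer seed; fixed seed gives bit-identical output.
#' @return list with `data` (a [trajectory_dataset()]) and `truth`
#'   (`trajectory_truth` data.frame: `gene`, `lineage`, `involved`
#'   (amplitude at or above the detectability floor of 0.5), `true_peak`
#'   (NA for flat genes), `amplitude`).
#' @export
simulate_trajectory_counts <- function(programs, cells_per_lineage = 300L,
                                       pseudotime_range = c(0, 10),
                                       seed = 1L) {
  stopifnot(inherits(programs, "data.frame"), nrow(programs) > 0L)
  if (cells_per_lineage < 2L) stop("need at least 2 cells per lineage")
  if (any(programs$width <= 0) || any(programs$dispersion <= 0)) {
    stop("width and dispersion must be positive")
  }
  lineages <- sort(unique(programs$lineage))
  genes <- unique(programs$gene_id)
  L <- length(lineages)
  n <- L * cells_per_lineage
  set.seed(seed)
  lineage <- factor(rep(lineages, each = cells_per_lineage),
                    levels = lineages)
  t_cell <- stats::runif(n, pseudotime_range[1], pseudotime_range[2])
  N <- stats::rlnorm(n, meanlog = 0, sdlog = 0.3)
  Y <- matrix(0L, length(genes), n,
              dimnames = list(genes, paste0("cell", seq_len(n))))
  for (g in genes) {
    pg <- programs[programs$gene_id == g, , drop = FALSE]
    pg <- pg[match(lineages, pg$lineage), , drop = FALSE]
    li <- as.integer(lineage)
    logmu <- bump_log_mean(t_cell, pg$baseline[li], pg$amplitude[li],
                           pg$peak_time[li], pg$width[li])
    Y[g, ] <- stats::rnbinom(n, size = pg$dispersion[1], mu = N * exp(logmu))
  }
  data <- trajectory_dataset(Y, pseudotime = t_cell, lineage = lineage,
                             offset = N)
  truth <- programs[, c("gene_id", "lineage", "amplitude")]
  names(truth)[1] <- "gene"
  truth$involved <- truth$amplitude >= DETECTABILITY_FLOOR
  truth$true_peak <- ifelse(truth$involved, programs$peak_time, NA_real_)
  truth <- truth[, c("gene", "lineage", "involved", "true_peak",
                     "amplitude")]
  class(truth) <- c("trajectory_truth", "data.frame")
  list(data = data, truth = truth)
}

#' Simulate Poisson counts from a known gene regulatory network
#'
#' Draws a random TF -> target network whose per-TF out-degrees have median
#' `out_degree` (log-normal spread), assigns any orphan target a random
#' parent, gives every edge a gamma-distributed rate, and generates smooth
#' nonnegative per-cell TF activities (Gaussian bumps with distinct peaks
#' along the cell ordering). Counts are Poisson with rate
#' \eqn{N_i \sum_{t \in pa(g)} \beta_{tg} a_{ti}}.
#'
#' @param n_tfs number of TFs.
#' @param n_targets number of target genes.
#' @param n_cells number of cells.
#' @param out_degree median number of targets per TF (default 27).
#' @param seed integer seed.
#' @return list with `counts` (target x cell), `grn` (edge data.frame
#'   `tf`, `target`, `weight` — the true rates), `truth`
#'   (`grn_truth`: `edges`, `activity` TF x cell, `offsets`).
#' @export
simulate_grn_dataset <- function(n_tfs = 10L, n_targets = 100L,
                                 n_cells = 500L, out_degree = 27L,
                                 seed = 1L) {
  set.seed(seed)
  tfs <- paste0("tf", seq_len(n_tfs))
  targets <- paste0("g", seq_len(n_targets))
  deg <- pmin(n_targets,
              pmax(1L, round(out_degree * exp(stats::rnorm(n_tfs, 0, 0.4)))))
  edges <- do.call(rbind, lapply(seq_len(n_tfs), function(t_) {
    data.frame(tf = tfs[t_],
               target = sample(targets, deg[t_]),
               stringsAsFactors = FALSE)
  }))
  orphans <- setdiff(targets, edges$target)
  if (length(orphans)) {
    edges <- rbind(edges, data.frame(tf = sample(tfs, length(orphans),
                                                 replace = TRUE),
                                     target = orphans,
                                     stringsAsFactors = FALSE))
  }
  edges$weight <- stats::rgamma(nrow(edges), shape = 2, rate = 2)
  B <- matrix(0, n_tfs, n_targets, dimnames = list(tfs, targets))
  B[cbind(match(edges$tf, tfs), match(edges$target, targets))] <-
    edges$weight

  s <- (seq_len(n_cells) - 0.5) / n_cells       # cell ordering on [0, 1]
  peaks <- seq(0.08, 0.92, length.out = n_tfs)[sample.int(n_tfs)]
  A <- t(vapply(seq_len(n_tfs), function(t_) {
    base <- stats::runif(1, 0.2, 0.5)
    amp <- stats::runif(1, 1.5, 3)
    base + amp * exp(-(s - peaks[t_])^2 / (2 * 0.12^2))
  }, numeric(n_cells)))
  dimnames(A) <- list(tfs, paste0("cell", seq_len(n_cells)))
  N <- stats::rlnorm(n_cells, 0, 0.3)
  Lambda <- sweep(crossprod(B, A), 2L, N, "*")
  counts <- matrix(stats::rpois(length(Lambda), Lambda),
                   nrow = n_targets,
                   dimnames = list(targets, colnames(A)))
  truth <- structure(list(edges = edges, activity = A, offsets = N),
                     class = "grn_truth")
  list(counts = counts, grn = edges, truth = truth)
}

#' Simulate paired injury-response expression and accessibility data
#'
#' Generates `n_per_class` genes in each priming class on one synthetic
#' chromosome (TSSs 10 kb apart, alternating strand), with class margins
#' strictly outside the +/-0.5 log2 accessibility-change window so the
#' ground truth is unambiguous:
#' \describe{
#'   \item{primed}{silent pre-injury expression, induced post, high and
#'     unchanged TSS accessibility (|log2FC| well below 0.5).}
#'   \item{induced_accessible}{silent pre, induced post, near-zero
#'     pre-injury accessibility gaining strongly (log2FC well above 0.5).}
#'   \item{constitutive}{expressed pre-injury, not induced, accessible
#'     throughout.}
#'   \item{silent_closed}{silent and closed throughout (also serves as the
#'     negative control set for the accessibility floor).}
#' }
#' A large constant background fragment pool far from any gene keeps the
#' pre/post library sizes comparable, as in real ATAC libraries where
#' TSS-proximal fragments are a small fraction of the total.
#'
#' @param n_per_class genes per class (>= 0; a class with 0 is absent).
#'   Default 25.
#' @param flank TSS window half-width used for rate bookkeeping (bp).
#' @param seed integer seed.
#' @return list with `expr` (gene, expr_pre, expr_post), `de` (gene, lfc,
#'   fdr), `fragments_pre`, `fragments_post` (`GRanges`), `tss` (gene,
#'   chrom, tss, strand; 1-based), and `truth` (`priming_truth`: gene,
#'   class, expr_pre, expr_post, rate_pre, rate_post).
#' @export
simulate_priming_dataset <- function(n_per_class = 25L, flank = 2000L,
                                     seed = 1L) {
  if (any(n_per_class < 0)) stop("n_per_class must be nonnegative")
  classes <- c("primed", "induced_accessible", "constitutive",
               "silent_closed")
  n_per_class <- rep_len(n_per_class, 4L)
  n_genes <- sum(n_per_class)
  if (n_genes == 0L) stop("no genes requested")
  set.seed(seed)
  class <- rep(classes, times = n_per_class)
  genes <- paste0("gene", seq_len(n_genes))
  tss <- data.frame(gene = genes, chrom = "chrSim",
                    tss = 5000L + (seq_len(n_genes) - 1L) * 10000L,
                    strand = rep_len(c("+", "-"), n_genes),
                    stringsAsFactors = FALSE)

  silent_expr <- function(m) stats::runif(m, 0, 0.3)
  # low-count pattern for closed windows; its spread keeps the adaptive
  # floor (median + 2 MAD of the silent controls) strictly above every
  # closed gene
  closed_counts <- function(idx) 1L + (idx - 1L) %% 3L
  expr_pre <- numeric(n_genes); lfc <- numeric(n_genes)
  fdr <- numeric(n_genes)
  rate_pre <- numeric(n_genes); rate_post <- numeric(n_genes)
  for (j in seq_len(n_genes)) {
    switch(class[j],
      primed = {
        expr_pre[j] <- silent_expr(1); lfc[j] <- stats::runif(1, 2, 5)
        fdr[j] <- stats::runif(1, 0, 0.01)
        rate_pre[j] <- 300; rate_post[j] <- 300 * 2^stats::runif(1, -0.2, 0.2)
      },
      induced_accessible = {
        expr_pre[j] <- silent_expr(1); lfc[j] <- stats::runif(1, 2, 5)
        fdr[j] <- stats::runif(1, 0, 0.01)
        rate_pre[j] <- closed_counts(j); rate_post[j] <- 300
      },
      constitutive = {
        expr_pre[j] <- stats::runif(1, 5, 50)
        lfc[j] <- stats::runif(1, -0.5, 0.5)
        fdr[j] <- stats::runif(1, 0.2, 1)
        rate_pre[j] <- 300; rate_post[j] <- 300 * 2^stats::runif(1, -0.2, 0.2)
      },
      silent_closed = {
        expr_pre[j] <- silent_expr(1)
        lfc[j] <- stats::runif(1, -0.5, 0.5)
        fdr[j] <- stats::runif(1, 0.2, 1)
        rate_pre[j] <- closed_counts(j); rate_post[j] <- closed_counts(j)
      })
  }
  expr_post <- expr_pre * 2^lfc

  # fragment counts are the rounded rates (positions random): sampling
  # noise on counts would let extreme draws cross the class margins, and
  # the classes are required to be recoverable without ambiguity
  frag_pool <- function(rates) {
    counts <- as.integer(round(rates))
    win_start0 <- pmax(0L, tss$tss - 1L - flank)
    starts <- unlist(lapply(seq_len(n_genes), function(j) {
      if (counts[j] == 0L) return(integer(0))
      win_start0[j] + sample.int(2L * flank - 100L, counts[j],
                                 replace = TRUE) - 1L
    }))
    bg_n <- 2e5L                     # constant background far from genes
    bg_start <- sample.int(1e6, bg_n, replace = TRUE) - 1L +
      (n_genes + 10L) * 10000L
    all_starts <- c(starts, bg_start)
    GenomicRanges::GRanges("chrSim",
                           IRanges::IRanges(start = all_starts + 1L,
                                            width = 100L))
  }
  fragments_pre <- frag_pool(rate_pre)
  fragments_post <- frag_pool(rate_post)

  truth <- data.frame(gene = genes,
                      class = factor(class, levels = classes),
                      expr_pre = expr_pre, expr_post = expr_post,
                      rate_pre = rate_pre, rate_post = rate_post,
                      stringsAsFactors = FALSE)
  class(truth) <- c("priming_truth", "data.frame")
  list(expr = data.frame(gene = genes, expr_pre = expr_pre,
                         expr_post = expr_post, stringsAsFactors = FALSE),
       de = data.frame(gene = genes, lfc = lfc, fdr = fdr,
                       stringsAsFactors = FALSE),
       fragments_pre = fragments_pre, fragments_post = fragments_post,
       tss = tss, truth = truth)
}

#' Flatten a ground-truth object to a plain table
#'
#' One row per (entity, lineage/condition) with all ground-truth fields;
#' the result round-trips through TSV.
#'
#' @param truth a truth object produced by one of the generators.
#' @return plain data.frame.
#' @export
truth_report <- function(truth) UseMethod("truth_report")

#' @export
truth_report.trajectory_truth <- function(truth) {
  as.data.frame(truth[, c("gene", "lineage", "involved", "true_peak")])
}

#' @export
truth_report.grn_truth <- function(truth) {
  as.data.frame(truth$edges)
}

#' @export
truth_report.priming_truth <- function(truth) {
  out <- as.data.frame(truth)
  out$class <- as.character(out$class)
  out
}

#' @export
truth_report.default <- function(truth) {
  stop("unknown truth type: ", paste(class(truth), collapse = "/"))
}
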