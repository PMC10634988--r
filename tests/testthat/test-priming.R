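# Early-response selection, TSS windows and coordinate conventions,
# fragment counting, profiles and the priming classification.

toy_expr <- function() {
  data.frame(
    gene = paste0("g", 1:6),
    expr_pre = c(0.1, 0.5, 3.0, 0.2, 0.9, 0.0),
    lfc      = c(2.0, 1.5, 4.0, 0.5, 1.2, 3.0),
    fdr      = c(0.01, 0.20, 0.001, 0.01, 0.04, 0.03),
    stringsAsFactors = FALSE)
}

test_that("early-response selection applies all three predicates", {
  expr <- toy_expr()
  # exhaustive predicate evaluation: g1, g5, g6 pass pre<=1, lfc>=1,
  # fdr<=0.05; g2 fails fdr, g3 fails baseline, g4 fails lfc
  expect_setequal(select_early_response(expr), c("g1", "g5", "g6"))
  # a high-baseline gene is excluded regardless of fold change
  expect_false("g3" %in% select_early_response(expr))
  expect_equal(length(select_early_response(expr[0, ])), 0L)
  expect_error(select_early_response(expr[, 1:2]), "columns")
  # tighter thresholds shrink the set monotonically
  expect_setequal(select_early_response(expr, lfc_min = 2.5), "g6")
  expect_true(all(select_early_response(expr, fdr_max = 0.02) %in%
                    select_early_response(expr)))
})

test_that("TSS windows follow the 0-based half-open convention", {
  ann <- data.frame(gene = c("a", "b"), chrom = "chr1",
                    tss = c(1000L, 50000L), strand = c("+", "-"),
                    stringsAsFactors = FALSE)
  win <- suppressMessages(tss_windows(ann, flank = 2000))
  # 1-based TSS 1000 -> 0-based 999; [999-2000, 999+2000) clips to [0, 2999)
  expect_equal(GenomicRanges::start(win)[1] - 1L, 0L)
  expect_equal(GenomicRanges::end(win)[1], 2999L)
  expect_equal(GenomicRanges::start(win)[2] - 1L, 49999L - 2000L)
  expect_equal(GenomicRanges::end(win)[2], 49999L + 2000L)
  # minus strand: same genomic interval, orientation flag flipped
  expect_equal(as.character(GenomicRanges::strand(win)), c("+", "-"))
  expect_error(tss_windows(ann, flank = 0), "positive")
  # converting the annotation to 0-based windows and back is lossless
  tss0_back <- win$tss0 + 1L
  expect_identical(tss0_back, ann$tss)
})

test_that("fragment counting uses any-overlap and library-size CPM", {
  win <- GenomicRanges::GRanges("chr1",
                                IRanges::IRanges(start = 151, end = 250))
  names(win) <- "w"
  frags <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
    start = c(101, 240, 251, 1), end = c(200, 260, 300, 100)))
  out <- count_fragments(frags, win)
  expect_equal(out$count, 2L)   # [100,200) and [239,260) overlap; others not
  expect_equal(out$cpm, 2 * 1e6 / 4)
  # empty library: zero counts and CPM defined as 0
  none <- GenomicRanges::GRanges()
  out0 <- count_fragments(none, win)
  expect_equal(out0$count, 0L)
  expect_equal(out0$cpm, 0)
  # a window covering everything counts every fragment on the chromosome
  big <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 1e6))
  names(big) <- "all"
  expect_equal(count_fragments(frags, big)$count, 4L)
})

test_that("TSS profiles are centered, mirrored and conserve counts", {
  ann <- data.frame(gene = c("p", "m"), chrom = "chr1",
                    tss = c(10000L, 10000L), strand = c("+", "-"),
                    stringsAsFactors = FALSE)
  # all fragments start exactly at the TSS base
  frags <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
    start = rep(10000L, 5), width = 100L))
  prof <- tss_profile(frags, ann, flank = 500, bin = 100)
  expect_equal(dim(prof), c(10L, 2L))
  expect_equal(prof["0", "p"], 5L)
  expect_equal(sum(prof[, "p"]), 5L)
  # minus strand sees the same start one bin to the other side of center
  expect_equal(prof["-100", "m"], 5L)
  # mirror symmetry against the plus-strand profile of shifted data
  set.seed(21)
  starts <- 10000L + sample(-400:399, 50, replace = TRUE)
  frags2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
    start = starts, width = 50L))
  prof2 <- tss_profile(frags2, ann, flank = 400, bin = 50)
  expect_equal(unname(prof2[, "m"]), rev(unname(prof2[, "p"])))
  # column sums match window fragment-start counts
  win <- tss_windows(ann[1, ], flank = 400)
  inside <- sum(starts - 10000L >= -400 & starts - 10000L < 400)
  expect_equal(sum(prof2[, "p"]), inside)
  expect_error(tss_profile(frags2, ann, flank = 400, bin = 33), "divide")
})

test_that("priming classes follow the fold-change window and floor", {
  expect_identical(formals(classify_priming)$window_threshold, 0.5)
  expr <- data.frame(gene = paste0("g", 1:5),
                     expr_pre = c(0.1, 0.1, 8, 0.1, 0.1),
                     lfc = c(3, 4, 0, 0, 3),
                     fdr = c(0.01, 0.01, 0.9, 0.9, 0.01))
  acc <- data.frame(gene = paste0("g", 1:5),
                    acc_pre = c(50, 0.5, 60, 0.4, 40),
                    acc_post = c(50, 40, 55, 0.5, 200))
  rec <- classify_priming(expr, acc, accessibility_floor = 5)
  expect_equal(as.character(rec$class),
               c("primed",               # induced, |lfc|~0, open pre
                 "induced_accessible",   # induced, de-novo accessibility
                 "constitutive",         # not induced, open
                 "silent_closed",        # not induced, closed
                 "induced_accessible"))  # induced, open but lfc > 0.5
  # idempotent and permutation-invariant join + predicate
  perm <- sample(5)
  rec2 <- classify_priming(expr[perm, ], acc[perm, ],
                           accessibility_floor = 5)
  expect_equal(rec2[order(rec2$gene), ]$class,
               rec[order(rec$gene), ]$class)
  # unmatched genes are dropped with a message
  expect_message(
    rec3 <- classify_priming(expr, acc[1:3, ], accessibility_floor = 5),
    "excluded")
  expect_equal(nrow(rec3), 3)
  expect_error(classify_priming(expr, acc), "accessibility_floor")
})

test_that("control gene sets are the expression extremes", {
  expr <- data.frame(gene = paste0("g", 1:10),
                     expr_pre = c(10, 9, 8, 7, 6, 0.5, 0.4, 0.3, 0.2, 2))
  ctrl <- control_gene_sets(expr, high_quantile = 0.2,
                            silent_set = c("g6", "g7", "g10", "zz"))
  expect_equal(ctrl$high, c("g1", "g2"))
  expect_setequal(ctrl$silent, c("g6", "g7"))    # g10 expressed above floor
  expect_setequal(control_gene_sets(expr, high_quantile = 1,
                                    silent_set = "g6")$high, expr$gene)
  expect_warning(ctrl0 <- control_gene_sets(expr, silent_set = character(0)),
                 "empty")
  expect_equal(ctrl0$silent, character(0))
})

test_that("generated priming data are classified back perfectly", {
  for (s in c(31, 32)) {
    sim <- simulate_priming_dataset(n_per_class = 20, seed = s)
    rec <- suppressMessages(run_priming_pipeline(sim))
    truth_cls <- as.character(sim$truth$class[match(rec$gene,
                                                    sim$truth$gene)])
    expect_equal(as.character(rec$class), truth_cls)
    # primed genes sit inside the unchanged-accessibility window
    expect_true(all(abs(rec$acc_lfc[rec$class == "primed"]) < 0.5))
    expect_true(all(rec$acc_lfc[rec$class == "induced_accessible"] > 0.5))
  }
})
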