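test_that("strand expression calls threshold estimated reads per strand", {
  pk <- GRanges("chrT", IRanges(1001, 2000))
  none <- toy_signal(GRanges(), numeric(0), GRanges(), numeric(0))
  expect_equal(as.character(strand_expression_call(pk, none)$call), "none")
  # 12 estimated reads on plus, 0.3 on minus, threshold 5 -> plus_only
  sig <- toy_signal(pk, 12 * 100 / width(pk), pk, 0.3 * 100 / width(pk))
  res <- strand_expression_call(pk, sig, min_reads = 5)
  expect_equal(as.character(res$call), "plus_only")
  expect_equal(res$plus_reads, 12, tolerance = 1e-9)
  expect_equal(res$minus_reads, 0.3, tolerance = 1e-9)
  both <- toy_signal(pk, 1, pk, 1)  # 10 reads per strand at read_length 100
  expect_equal(as.character(strand_expression_call(pk, both)$call), "both_strands")
})

test_that("six-class labels recover the planted truth and partition the peaks", {
  b <- default_bundle()
  rec <- classify_enhancers(b$enhancers, b$k4me1, b$rna)
  truth <- b$truth$enhancers
  expect_equal(as.character(mcols(rec)$class_label), truth$class)
  expect_equal(length(rec), sum(table(mcols(rec)$class_label)))
  # K4me1 window: overlap counts, edge gap <= 1 kb
  expect_equal(mcols(rec)$k4me1_within_window, truth$k4me1)
})

test_that("raising min_reads is monotone on class composition", {
  b <- default_bundle()
  r5 <- classify_enhancers(b$enhancers, b$k4me1, b$rna, min_reads = 5)
  r40 <- classify_enhancers(b$enhancers, b$k4me1, b$rna, min_reads = 40)
  n_none <- function(r) sum(grepl("_none$", mcols(r)$class_label))
  n_bi <- function(r) sum(grepl("bidirectional", mcols(r)$class_label))
  expect_gte(n_none(r40), n_none(r5))
  expect_lte(n_bi(r40), n_bi(r5))
})

test_that("evidence fractions count TFBS and capped calls per class", {
  pk <- GRanges("chrT", IRanges(seq(1, 991, by = 110), width = 100),
                name = sprintf("e%d", 1:10))
  mcols(pk)$class_label <- factor(rep("K4me1-_bidirectional", 10),
                                  levels = distalreg:::enhancer_classes())
  tf <- GRanges("chrT", IRanges(start(pk)[1:4] + 10, width = 5))
  empty_sig <- toy_signal(GRanges(), numeric(0), GRanges(), numeric(0))
  ev <- evidence_fractions(pk, list(tf), empty_sig)
  row <- ev$by_class[ev$by_class$class == "K4me1-_bidirectional", ]
  expect_equal(row$tfbs_fraction, 0.40)
  expect_equal(row$capped_none, 1)
  # empty classes are undefined, not zero
  expect_true(all(is.na(ev$by_class$tfbs_fraction[ev$by_class$n == 0])))
})

test_that("planted capped fractions are recovered within binomial error", {
  b <- default_bundle()
  rec <- classify_enhancers(b$enhancers, b$k4me1, b$rna)
  ev <- evidence_fractions(rec, b$tfbs, b$rampage)
  truth <- b$truth$enhancers
  for (cl in grep("bidirectional", levels(mcols(rec)$class_label), value = TRUE)) {
    got <- ev$by_class$capped_bidirectional[ev$by_class$class == cl]
    planted <- mean(truth$capped[truth$class == cl])
    n <- sum(truth$class == cl)
    expect_lt(abs(got - planted), 1e-9)  # calls match the planted flags
    expect_lt(abs(got - 0.5), 2 * sqrt(0.5 * 0.5 / n) + 1e-9)
  }
})

test_that("Welch activity comparison matches the closed form and flags planted shifts", {
  # identical distributions -> p = 1
  pos <- seq(1, 4000, by = 10)[1:40]
  pk <- GRanges("chrT", IRanges(pos, width = 1))
  mcols(pk)$class_label <- factor(rep(c("K4me1-_bidirectional", "K4me1-_none"),
                                      each = 20),
                                  levels = distalreg:::enhancer_classes())
  vals <- rep(c(2, 5), 20)  # same multiset in both classes
  lens <- stats::setNames(10000L, "chrT")
  seqlengths(pk) <- lens
  track <- coverage(pk, weight = vals)
  ac <- activity_compare(pk, track, summary = "median")
  expect_equal(ac$tests$p_value, 1, tolerance = 1e-9)
  # closed-form Welch oracle on the per-class values
  b <- default_bundle()
  rec <- classify_enhancers(b$enhancers, b$k4me1, b$rna)
  ac2 <- activity_compare(rec, b$activity, summary = "median")
  welch_oracle <- function(x, y) {
    (mean(x) - mean(y)) / sqrt(var(x) / length(x) + var(y) / length(y))
  }
  for (i in seq_len(nrow(ac2$tests))) {
    x <- ac2$by_class[[ac2$tests$class_a[i]]]
    y <- ac2$by_class[[ac2$tests$class_b[i]]]
    expect_equal(ac2$tests$statistic[i], welch_oracle(x, y), tolerance = 1e-10)
  }
  # planted ordering: bidirectional > unidirectional > none
  med <- vapply(ac2$by_class, mean, numeric(1))
  expect_gt(med[["K4me1-_bidirectional"]], med[["K4me1-_unidirectional"]])
  expect_gt(med[["K4me1-_unidirectional"]], med[["K4me1-_none"]])
  bi_none <- ac2$tests[ac2$tests$class_a == "K4me1-_bidirectional" &
                         ac2$tests$class_b == "K4me1-_none", ]
  expect_lt(bi_none$p_value, 1e-5)
})

test_that("loop linkage connects anchors to opposite-anchor genes", {
  enh <- GRanges("c", IRanges(c(100, 9000), width = 50))
  mcols(enh)$class_label <- factor(rep("K4me1-_bidirectional", 2),
                                   levels = distalreg:::enhancer_classes())
  genes <- GRanges("c", IRanges(5000, 5500), name = "gA")
  loops <- loop_set(GRanges("c", IRanges(90, 200)),
                    GRanges("c", IRanges(4900, 5600)))
  expr <- stats::setNames(rep(2, 1), "gA")
  res <- loop_link(enh, loops, genes, expr, seed = 1)
  expect_equal(mcols(res$records)$in_loop, c(TRUE, FALSE))
  expect_equal(res$linked_genes, "gA")
  expect_equal(mcols(res$records)$n_linked_genes, c(1L, 0L))
  # empty loop set short-circuits with a notice
  res0 <- loop_link(enh, loop_set(GRanges(), GRanges()), genes, expr)
  expect_false(any(mcols(res0$records)$in_loop))
  expect_match(res0$notice, "empty")
})

test_that("planted loop-linked expression shift is recovered", {
  b <- default_bundle()
  rec <- classify_enhancers(b$enhancers, b$k4me1, b$rna)
  res <- loop_link(rec, b$loops, b$genes, b$expression[, b$config$loop_tissue],
                   seed = 5)
  expect_setequal(res$linked_genes, b$truth$linked_genes)
  cmp <- res$comparison
  vs_all <- cmp[cmp$background == "random_genes", ]
  vs_loop <- cmp[cmp$background == "random_genes_in_loops", ]
  # linked genes carry the planted log2 shift relative to unlinked genes
  lg <- log2(b$expression[, b$config$loop_tissue] + 0.1)
  unlinked <- setdiff(rownames(b$expression), res$linked_genes)
  expect_equal(mean(lg[res$linked_genes]) - mean(lg[unlinked]),
               b$config$loop_expression_shift, tolerance = 0.15)
  # significantly above random genes (a draw pool that includes linked genes)
  expect_lt(vs_all$p_value, 1e-4)
  expect_gt(vs_all$linked_mean, vs_all$background_draw_median)
  # ...but only marginally different from random in-loop genes
  expect_lt(abs(vs_loop$linked_mean - vs_loop$background_draw_median), 0.3)
  expect_gt(vs_loop$p_value, 0.05)
})

test_that("conserved-element counting feeds the per-class tiers", {
  pk <- GRanges("c", IRanges(c(1000, 5000), width = 800))
  mcols(pk)$class_label <- factor(c("K4me1-_bidirectional", "K4me1-_none"),
                                  levels = distalreg:::enhancer_classes())
  elems <- GRanges("c", IRanges(1100 + (0:11) * 30, width = 10))
  res <- conservation_profile(pk, elems)
  expect_equal(mcols(res$records)$conserved_element_count, c(12L, 0L))
  row <- res$by_class[res$by_class$class == "K4me1-_bidirectional", ]
  expect_equal(row$frac_deep, 1)
  b <- default_bundle()
  rec <- classify_enhancers(b$enhancers, b$k4me1, b$rna)
  res2 <- conservation_profile(rec, b$conserved)
  truth <- b$truth$enhancers
  expect_equal(mcols(res2$records)$conserved_element_count,
               truth$conserved_elements)
})
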