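#' Call per-strand transcription within peaks
#'
#' Converts the coverage area of a stranded track inside each peak into an
#' estimated read count (coverage sum / read length) and thresholds each
#' strand at \code{min_reads} estimated reads, yielding one of the calls
#' \code{both_strands}, \code{plus_only}, \code{minus_only}, \code{none}.
#'
#' @param peaks \code{GRanges}.
#' @param signal A \code{\link{stranded_signal}}.
#' @param min_reads Estimated-read threshold per strand.
#' @return data.frame with \code{plus_reads}, \code{minus_reads},
#'   \code{call} (factor) per peak.
#' @export
strand_expression_call <- function(peaks, signal, min_reads = 5) {
  if (!inherits(signal, "stranded_signal")) stop("signal must be a stranded_signal", call. = FALSE)
  if (signal$read_length <= 0) stop("read_length must be > 0", call. = FALSE)
  sums <- strand_region_sums(signal, peaks)
  sums[is.na(sums)] <- 0
  reads <- sums / signal$read_length
  p <- reads[, "plus"] >= min_reads
  m <- reads[, "minus"] >= min_reads
  call <- ifelse(p & m, "both_strands",
                 ifelse(p, "plus_only", ifelse(m, "minus_only", "none")))
  data.frame(plus_reads = reads[, "plus"], minus_reads = reads[, "minus"],
             call = factor(call, levels = c("both_strands", "plus_only",
                                            "minus_only", "none")))
}

enhancer_classes <- function() {
  as.vector(outer(c("K4me1+", "K4me1-"),
                  c("bidirectional", "unidirectional", "none"), paste, sep = "_"))
}

collapse_call <- function(call) {
  c(both_strands = "bidirectional", plus_only = "unidirectional",
    minus_only = "unidirectional", none = "none")[as.character(call)]
}

#' Classify distal H3K27ac peaks into six enhancer classes
#'
#' Each distal peak is labelled by (i) whether an H3K4me1 peak lies within
#' \code{window_bp} (edge gap; overlap counts), separating putative
#' misannotated genes (H3K4me1 marks gene bodies) from candidate enhancers,
#' and (ii) its RNA evidence collapsed to bidirectional / unidirectional /
#' none. The cross gives six classes; raw per-strand read estimates are
#' retained on every record.
#'
#' @param distal_peaks Distal peaks (\code{GRanges}), e.g. from
#'   \code{\link{partition_local_distal}}.
#' @param k4me1_peaks H3K4me1 peak set.
#' @param rna Stranded RNA-seq signal.
#' @param window_bp Maximum H3K4me1 edge gap in bp (default 1 kb, allowing
#'   for the distance between a TSS and the marked gene body).
#' @param min_reads Per-strand estimated-read threshold.
#' @return \code{GRanges} of the input peaks with metadata columns
#'   \code{k4me1_within_window}, \code{plus_reads}, \code{minus_reads},
#'   \code{expression_call}, \code{class_label}.
#' @export
classify_enhancers <- function(distal_peaks, k4me1_peaks, rna,
                               window_bp = 1000L, min_reads = 5) {
  if (window_bp < 0L) stop("window_bp must be >= 0", call. = FALSE)
  k4 <- if (length(k4me1_peaks)) {
    nearest_distance(distal_peaks, k4me1_peaks) <= window_bp
  } else rep(FALSE, length(distal_peaks))
  expr <- strand_expression_call(distal_peaks, rna, min_reads = min_reads)
  rec <- distal_peaks
  mcols(rec)$k4me1_within_window <- k4
  mcols(rec)$plus_reads <- expr$plus_reads
  mcols(rec)$minus_reads <- expr$minus_reads
  mcols(rec)$expression_call <- expr$call
  mcols(rec)$class_label <- factor(
    paste0(ifelse(k4, "K4me1+", "K4me1-"), "_", collapse_call(expr$call)),
    levels = enhancer_classes())
  rec
}

#' Per-class TFBS and capped-RNA evidence fractions
#'
#' For every enhancer class: the fraction of records overlapping at least one
#' transcription-factor binding site (union over all TF sets), and the
#' composition of 5'-capped transcription calls derived from RAMPAGE signal.
#' Empty classes report \code{NA} (undefined), not 0.
#'
#' @param records Classified records from \code{\link{classify_enhancers}}.
#' @param tfbs_sets List of \code{GRanges}, one per transcription factor.
#' @param rampage Stranded RAMPAGE signal.
#' @param min_reads Estimated-read threshold for the capped call; the default
#'   2 reflects shallower cap-selected libraries.
#' @return List: \code{records} (input plus \code{tfbs_hit} and
#'   \code{capped_call} columns) and \code{by_class} (data.frame of per-class
#'   fractions).
#' @export
evidence_fractions <- function(records, tfbs_sets, rampage, min_reads = 2) {
  tfbs_all <- if (length(tfbs_sets)) Reduce(c, lapply(tfbs_sets, granges)) else GRanges()
  hit <- if (length(tfbs_all)) overlapsAny(records, tfbs_all, ignore.strand = TRUE) else rep(FALSE, length(records))
  capped <- strand_expression_call(records, rampage, min_reads = min_reads)
  mcols(records)$tfbs_hit <- hit
  mcols(records)$capped_call <- capped$call
  cls <- mcols(records)$class_label
  by_class <- do.call(rbind, lapply(levels(cls), function(k) {
    idx <- which(cls == k)
    if (!length(idx)) {
      return(data.frame(class = k, n = 0L, tfbs_fraction = NA_real_,
                        capped_bidirectional = NA_real_,
                        capped_unidirectional = NA_real_,
                        capped_none = NA_real_))
    }
    cc <- collapse_call(capped$call[idx])
    data.frame(class = k, n = length(idx),
               tfbs_fraction = mean(hit[idx]),
               capped_bidirectional = mean(cc == "bidirectional"),
               capped_unidirectional = mean(cc == "unidirectional"),
               capped_none = mean(cc == "none"))
  }))
  list(records = records, by_class = by_class)
}

#' Compare enhancer activity between classes (Welch t-tests)
#'
#' Summarizes an activity track (e.g. a STARR-seq reporter signal) within
#' each record by max, mean or median, then compares every pair of classes
#' with a two-sided Welch t-test. Full per-record summaries are retained.
#'
#' @param records Classified records.
#' @param activity Numeric \code{RleList} (unstranded activity track) or a
#'   \code{stranded_signal} (strands are summed).
#' @param summary One of \code{"median"}, \code{"mean"}, \code{"max"}.
#' @return List: \code{values} (per-record summary), \code{by_class} (named
#'   list of per-class value vectors), \code{tests} (data.frame of pairwise
#'   Welch statistics and p-values).
#' @export
activity_compare <- function(records, activity,
                             summary = c("median", "mean", "max")) {
  summary <- match.arg(summary)
  track <- if (inherits(activity, "stranded_signal")) activity$plus + activity$minus else activity
  vals <- region_track_summary(track, records, summary)
  cls <- droplevels(mcols(records)$class_label)
  by_class <- split(vals, cls)
  ks <- names(by_class)[lengths(by_class) >= 2L]
  pairs <- if (length(ks) >= 2L) utils::combn(ks, 2L, simplify = FALSE) else list()
  tests <- do.call(rbind, lapply(pairs, function(p) {
    x <- by_class[[p[1L]]]; y <- by_class[[p[2L]]]
    if (stats::var(x) == 0 && stats::var(y) == 0 && isTRUE(all.equal(mean(x), mean(y)))) {
      return(data.frame(class_a = p[1L], class_b = p[2L],
                        statistic = 0, p_value = 1))
    }
    tt <- stats::t.test(x, y, var.equal = FALSE)
    data.frame(class_a = p[1L], class_b = p[2L],
               statistic = unname(tt$statistic), p_value = tt$p.value)
  }))
  list(values = vals, by_class = by_class, tests = tests)
}

#' Link enhancers to genes through chromatin loops
#'
#' A record is "in a loop" when it overlaps either anchor; its linked genes
#' are the genes overlapping the opposite anchor of any such loop. Linked
#' genes' expression (log2(RPKM + 0.1)) is compared against (a) uniformly
#' random genes and (b) random genes overlapping any anchor, by two-sided
#' Welch t-tests with seeded random draws. Counts of records strictly
#' between their loop's anchors are also reported to disambiguate "present
#' in a loop" from "at an anchor".
#'
#' @param records Classified records.
#' @param loops A \code{\link{loop_set}}.
#' @param genes \code{GRanges} with a \code{name} column matching
#'   \code{expression} row names.
#' @param expression Named numeric vector of RPKM per gene (one tissue).
#' @param seed Seed for the random gene draws.
#' @param n_draws Number of repeated draws; the median of draw means is
#'   reported alongside the tests.
#' @return List: \code{records} (with \code{in_loop}, \code{n_linked_genes}),
#'   \code{linked_genes} (character), \code{between_anchors} (count),
#'   \code{comparison} (data.frame of the two Welch tests and draw medians),
#'   or a \code{notice} when the loop set is empty.
#' @export
loop_link <- function(records, loops, genes, expression, seed = 1L,
                      n_draws = 100L) {
  if (length(loops) == 0L) {
    mcols(records)$in_loop <- rep(FALSE, length(records))
    mcols(records)$n_linked_genes <- rep(0L, length(records))
    return(list(records = records, linked_genes = character(0),
                comparison = NULL, notice = "empty loop set; comparison skipped"))
  }
  a1 <- loops$anchor1; a2 <- loops$anchor2
  h1 <- findOverlaps(records, a1, ignore.strand = TRUE)
  h2 <- findOverlaps(records, a2, ignore.strand = TRUE)
  in_loop <- logical(length(records))
  in_loop[c(queryHits(h1), queryHits(h2))] <- TRUE
  # genes at the opposite anchor of each record's loops
  gene_names <- mcols(genes)$name
  linked <- vector("list", length(records))
  opp <- rbind(data.frame(rec = queryHits(h1), loop = subjectHits(h1),
                          side = rep(2L, length(h1))),
               data.frame(rec = queryHits(h2), loop = subjectHits(h2),
                          side = rep(1L, length(h2))))
  if (nrow(opp)) {
    g_in_a1 <- findOverlaps(genes, a1, ignore.strand = TRUE)
    g_in_a2 <- findOverlaps(genes, a2, ignore.strand = TRUE)
    loop_genes <- list(split(queryHits(g_in_a1), subjectHits(g_in_a1)),
                       split(queryHits(g_in_a2), subjectHits(g_in_a2)))
    for (i in seq_len(nrow(opp))) {
      gs <- loop_genes[[opp$side[i]]][[as.character(opp$loop[i])]]
      if (!is.null(gs)) linked[[opp$rec[i]]] <- union(linked[[opp$rec[i]]], gs)
    }
  }
  mcols(records)$in_loop <- in_loop
  mcols(records)$n_linked_genes <- lengths(linked)
  # strictly-between-anchors count (cis loops with a gap between anchors)
  cis <- as.character(seqnames(a1)) == as.character(seqnames(a2)) &
    end(a1) + 1L <= start(a2) - 1L
  span <- GRanges(seqnames(a1)[cis],
                  IRanges(end(a1)[cis] + 1L, start(a2)[cis] - 1L))
  between <- sum(overlapsAny(records, span, ignore.strand = TRUE) & !in_loop)
  linked_idx <- sort(unique(unlist(linked)))
  linked_names <- gene_names[linked_idx]
  lg <- log2(expression + 0.1)
  linked_vals <- lg[linked_names]
  anchor_gene_idx <- sort(unique(c(queryHits(findOverlaps(genes, a1, ignore.strand = TRUE)),
                                   queryHits(findOverlaps(genes, a2, ignore.strand = TRUE)))))
  comparison <- NULL
  if (length(linked_vals) >= 2L) {
    comparison <- with_seed(seed, {
      draw_med <- function(pool) {
        stats::median(vapply(seq_len(n_draws), function(i) {
          mean(lg[sample(pool, length(linked_vals), replace = TRUE)])
        }, numeric(1)))
      }
      all_pool <- names(expression)
      anc_pool <- gene_names[anchor_gene_idx]
      t_all <- stats::t.test(linked_vals, lg[all_pool], var.equal = FALSE)
      t_anc <- if (length(anc_pool) >= 2L) {
        stats::t.test(linked_vals, lg[anc_pool], var.equal = FALSE)
      } else NULL
      data.frame(
        background = c("random_genes", "random_genes_in_loops"),
        linked_mean = mean(linked_vals),
        background_draw_median = c(draw_med(all_pool),
                                   if (length(anc_pool)) draw_med(anc_pool) else NA_real_),
        statistic = c(unname(t_all$statistic),
                      if (is.null(t_anc)) NA_real_ else unname(t_anc$statistic)),
        p_value = c(t_all$p.value, if (is.null(t_anc)) NA_real_ else t_anc$p.value))
    })
  }
  list(records = records, linked_genes = linked_names,
       between_anchors = between, comparison = comparison)
}

#' Conserved-element content per enhancer class
#'
#' Counts conserved elements (e.g. PhastCons-derived conserved regions)
#' overlapping each record and summarizes per class the fraction of records
#' containing at least one and at least \code{deep_tier} elements.
#'
#' @param records Classified records.
#' @param conserved \code{GRanges} of conserved elements.
#' @param deep_tier Count defining the deeply-conserved tier (default 10).
#' @return List: \code{records} (with \code{conserved_element_count}) and
#'   \code{by_class} data.frame.
#' @export
conservation_profile <- function(records, conserved, deep_tier = 10L) {
  n <- countOverlaps(records, conserved, ignore.strand = TRUE)
  mcols(records)$conserved_element_count <- n
  cls <- mcols(records)$class_label
  by_class <- do.call(rbind, lapply(levels(cls), function(k) {
    idx <- which(cls == k)
    data.frame(class = k, n = length(idx),
               frac_ge1 = if (length(idx)) mean(n[idx] >= 1L) else NA_real_,
               frac_deep = if (length(idx)) mean(n[idx] >= deep_tier) else NA_real_)
  }))
  list(records = records, by_class = by_class)
}
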