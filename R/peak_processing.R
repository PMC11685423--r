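#' Pseudo-replicate reproducibility filter
#'
#' Keeps exactly the peaks of the merged-replicate sample that overlap (>= 1
#' bp) at least one peak called in each of the two pseudo-replicates, the
#' standard reproducibility rule when biological replicates are merged and
#' re-split into random halves. Names and scores of the merged peaks are
#' preserved.
#'
#' @param merged Peaks called on the merged sample (\code{GRanges}).
#' @param pseudo1,pseudo2 Peaks called on the two pseudo-replicates.
#' @return The reproducible subset of \code{merged}.
#' @export
reproducible_peaks <- function(merged, pseudo1, pseudo2) {
  check_same_genome(merged, pseudo1)
  check_same_genome(merged, pseudo2)
  if (length(merged) == 0L) return(merged)
  keep <- overlapsAny(merged, pseudo1, ignore.strand = TRUE) &
    overlapsAny(merged, pseudo2, ignore.strand = TRUE)
  merged[keep]
}

#' Partition peaks into local and distal relative to gene annotation
#'
#' A peak is distal when the edge-to-edge gap to the closest gene is at least
#' \code{threshold_bp} (2 kb by default); peaks overlapping or within the
#' threshold are local. The partition is exhaustive and disjoint.
#'
#' @param peaks \code{GRanges} of peaks.
#' @param genes Non-empty \code{GRanges} of gene bodies.
#' @param threshold_bp Distal distance threshold in bp (inclusive).
#' @return List with \code{local} and \code{distal} \code{GRanges}.
#' @export
partition_local_distal <- function(peaks, genes, threshold_bp = 2000L) {
  if (threshold_bp < 0L) stop("threshold_bp must be >= 0", call. = FALSE)
  d <- nearest_distance(peaks, genes)
  list(local = peaks[d < threshold_bp], distal = peaks[d >= threshold_bp])
}

#' Annotate intervals by overlapping genomic feature
#'
#' Assigns exactly one label per interval with priority gene > TE family >
#' near-gene intergenic > distant intergenic. When an interval overlaps
#' several TE families the most-overlapped family wins, with ties broken by
#' lexicographic family name.
#'
#' @param intervals \code{GRanges} to annotate.
#' @param genes \code{GRanges} of genes.
#' @param tes \code{GRanges} of transposable elements with a \code{family}
#'   metadata column.
#' @param near_bp Distance separating "intergenic <=2 kb from gene" from
#'   "intergenic >2 kb".
#' @return Character vector of labels: \code{"gene"}, \code{"TE:<family>"},
#'   \code{"intergenic_near_gene"} or \code{"intergenic_distal"}.
#' @export
annotate_features <- function(intervals, genes, tes, near_bp = 2000L) {
  lab <- rep("intergenic_distal", length(intervals))
  if (length(genes)) {
    d <- nearest_distance(intervals, genes)
    lab[is.finite(d) & d < near_bp] <- "intergenic_near_gene"
    lab[d == 0 & overlapsAny(intervals, genes, ignore.strand = TRUE)] <- "gene"
  }
  if (length(tes)) {
    fam <- as.character(mcols(tes)$family)
    if (is.null(mcols(tes)$family)) stop("tes needs a 'family' column", call. = FALSE)
    hits <- findOverlaps(intervals, tes, ignore.strand = TRUE)
    if (length(hits)) {
      ov <- width(pintersect(intervals[queryHits(hits)], tes[subjectHits(hits)],
                             ignore.strand = TRUE))
      df <- data.frame(q = queryHits(hits), fam = fam[subjectHits(hits)], ov = ov)
      df <- df[order(df$q, -df$ov, df$fam), ]
      best <- df[!duplicated(df$q), ]
      te_lab <- lab[best$q] != "gene"
      lab[best$q[te_lab]] <- paste0("TE:", best$fam[te_lab])
    }
  }
  lab
}

distance_bin <- function(d) {
  cut(d, breaks = c(-1, 0, 2000, 10000, 100000, Inf),
      labels = c("genic", "<2kb", "2-10kb", "10-100kb", ">100kb"))
}

#' Multi-sample peak intersection table (upset logic)
#'
#' Merges the union of all samples' peaks into regions by single-linkage
#' (>= 1 bp) overlap, computes for every region which samples contribute a
#' peak, and aggregates regions per unique membership vector together with
#' their genomic-feature composition and distance-to-gene bins.
#'
#' @param samples Named list (>= 2) of \code{GRanges} peak sets.
#' @param genes,tes Annotation sets passed to \code{\link{annotate_features}}.
#' @return List with \code{regions} (merged \code{GRanges} with membership
#'   columns) and \code{table} (one row per membership vector: \code{count},
#'   per-feature counts and per-distance-bin counts).
#' @export
intersection_matrix <- function(samples, genes, tes) {
  if (length(samples) < 2L) stop("need >= 2 samples", call. = FALSE)
  if (is.null(names(samples)) || anyDuplicated(names(samples))) {
    stop("samples must be uniquely named", call. = FALSE)
  }
  pool <- suppressWarnings(Reduce(c, lapply(samples, granges)))
  regions <- reduce(pool, min.gapwidth = 0L, ignore.strand = TRUE)
  member <- vapply(samples, function(s) {
    overlapsAny(regions, s, ignore.strand = TRUE)
  }, logical(length(regions)))
  if (length(regions) == 1L) member <- matrix(member, nrow = 1L,
                                              dimnames = list(NULL, names(samples)))
  key <- apply(member, 1L, function(v) paste(names(samples)[v], collapse = "&"))
  feat <- annotate_features(regions, genes, tes)
  feat_top <- ifelse(startsWith(feat, "TE:"), "TE", feat)
  dbin <- distance_bin(nearest_distance(regions,
                                        if (length(genes)) genes else GRanges("none", IRanges(1, 1))))
  tab <- do.call(rbind, lapply(split(seq_along(regions), key), function(idx) {
    row <- data.frame(membership = key[idx[1L]], count = length(idx))
    for (f in c("gene", "TE", "intergenic_near_gene", "intergenic_distal")) {
      row[[paste0("feat_", f)]] <- sum(feat_top[idx] == f)
    }
    for (b in levels(dbin)) {
      row[[paste0("dist_", b)]] <- sum(dbin[idx] == b, na.rm = TRUE)
    }
    row
  }))
  rownames(tab) <- NULL
  mcols(regions)$membership <- key
  mcols(regions)$feature <- feat
  list(regions = regions, table = tab[order(-tab$count), ])
}
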