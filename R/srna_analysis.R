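#' Small-RNA size distribution in counts per million
#'
#' @param reads Collapsed read data.frame with columns \code{chrom},
#'   \code{start}, \code{end}, \code{strand}, \code{length}, \code{count}.
#' @param library_size Total mapped reads (> 0) used for CPM normalization.
#' @param lengths Read lengths (nt) to report.
#' @return Named numeric vector: CPM per length.
#' @export
size_distribution <- function(reads, library_size, lengths = 18:28) {
  if (library_size <= 0) stop("library_size must be > 0", call. = FALSE)
  cpm <- vapply(lengths, function(L) {
    1e6 * sum(reads$count[reads$length == L]) / library_size
  }, numeric(1))
  names(cpm) <- lengths
  cpm
}

#' Strand bias and hairpin-like flags for small-RNA clusters
#'
#' Kilobase-scale loci producing strongly one-strand-biased, 22nt-dominated
#' siRNAs behave like fold-back (hairpin / proto-miRNA) precursors. For each
#' cluster this computes, over its 20-24nt reads: the strand bias
#' max(plus,minus)/(plus+minus), the dominant read length, the 22nt
#' fraction, and the heuristic flag span >= \code{min_len_bp} AND bias >=
#' \code{min_bias} AND 22nt fraction >= \code{min_22nt_frac}. Clusters with
#' no 20-24nt reads get NA flags.
#'
#' @param clusters \code{GRanges} of sRNA clusters.
#' @param reads Collapsed read data.frame (see
#'   \code{\link{size_distribution}}).
#' @param min_len_bp,min_bias,min_22nt_frac Flag thresholds.
#' @return data.frame, one row per cluster: \code{span}, \code{strand_bias},
#'   \code{dominant_length}, \code{frac_22nt}, \code{hairpin_like}.
#' @export
hairpin_flags <- function(clusters, reads, min_len_bp = 1000L,
                          min_bias = 0.8, min_22nt_frac = 0.5) {
  rgr <- GRanges(reads$chrom, IRanges(reads$start + 1L, reads$end))
  hits <- findOverlaps(clusters, rgr, ignore.strand = TRUE)
  out <- data.frame(span = width(clusters),
                    strand_bias = NA_real_, dominant_length = NA_integer_,
                    frac_22nt = NA_real_, hairpin_like = NA)
  for (i in seq_len(length(clusters))) {
    rd <- reads[subjectHits(hits)[queryHits(hits) == i], , drop = FALSE]
    if (nrow(rd)) {
      tot <- tapply(rd$count, rd$length, sum)
      out$dominant_length[i] <- as.integer(names(tot)[which.max(tot)])
    }
    sir <- rd[rd$length >= 20L & rd$length <= 24L, , drop = FALSE]
    if (!nrow(sir)) next
    plus <- sum(sir$count[sir$strand == "+"])
    minus <- sum(sir$count[sir$strand == "-"])
    out$strand_bias[i] <- max(plus, minus) / (plus + minus)
    out$frac_22nt[i] <- sum(sir$count[sir$length == 22L]) / sum(sir$count)
    out$hairpin_like[i] <- out$span[i] >= min_len_bp &&
      out$strand_bias[i] >= min_bias && out$frac_22nt[i] >= min_22nt_frac
  }
  out
}

#' Count telomere repeats at chromosome ends
#'
#' Counts non-overlapping exact occurrences of the telomere motif within the
#' first \code{window_bp} bases of each chromosome, and of its reverse
#' complement within the last \code{window_bp} bases. Windows larger than a
#' chromosome are truncated (with a message). Assembly-based counts like
#' these underestimate true telomere length.
#'
#' @param genome \code{DNAStringSet}.
#' @param motif Repeat unit (default the plant telomere repeat
#'   \code{"CCCTAAA"}).
#' @param window_bp Window size per end.
#' @return List: \code{per_end} data.frame (\code{chrom}, \code{end5},
#'   \code{end3}) and \code{total}.
#' @export
telomere_repeat_count <- function(genome, motif = "CCCTAAA",
                                  window_bp = 10000L) {
  if (!grepl("^[ACGT]+$", motif)) stop("motif must be over ACGT", call. = FALSE)
  if (window_bp < nchar(motif)) stop("window_bp smaller than motif", call. = FALSE)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(motif)))
  count_nonoverlap <- function(seq, pat) {
    m <- Biostrings::matchPattern(pat, seq)
    if (!length(m)) return(0L)
    n <- 0L; last_end <- 0L
    for (j in seq_along(m)) {
      if (start(m)[j] > last_end) {
        n <- n + 1L
        last_end <- end(m)[j]
      }
    }
    n
  }
  per_end <- do.call(rbind, lapply(seq_along(genome), function(i) {
    s <- genome[[i]]
    w <- window_bp
    if (w > length(s)) {
      message("window truncated to chromosome ", names(genome)[i])
      w <- length(s)
    }
    data.frame(chrom = names(genome)[i],
               end5 = count_nonoverlap(Biostrings::subseq(s, 1L, w), motif),
               end3 = count_nonoverlap(Biostrings::subseq(s, length(s) - w + 1L,
                                                          length(s)), rc))
  }))
  list(per_end = per_end, total = sum(per_end$end5) + sum(per_end$end3))
}
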