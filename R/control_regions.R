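#' Mappability mask from exact k-mer uniqueness
#'
#' Tiles the genome into non-overlapping k-bp bins (a short final remainder
#' per chromosome is dropped) and marks a bin mappable when its sequence
#' occurs exactly once across the whole genome considering both strands and
#' contains no N, the single-end unique-mapping criterion evaluated by exact
#' string matching. Adjacent mappable bins are merged into runs.
#'
#' @param genome A \code{\link[Biostrings]{DNAStringSet}} (one entry per
#'   chromosome).
#' @param k Bin size in bp (>= 20; 150 matches a typical single-end read).
#' @return List of class \code{mappability_mask}: \code{mappable} (merged
#'   \code{GRanges} runs), \code{bins} (per-bin \code{GRanges} with a
#'   \code{mappable} flag), \code{k}.
#' @export
mappability_mask <- function(genome, k = 150L) {
  if (k < 20L) stop("k must be >= 20", call. = FALSE)
  lens <- Biostrings::width(genome)
  if (all(lens < k)) stop("k is larger than every chromosome", call. = FALSE)
  bin_list <- list()
  seq_list <- list()
  for (i in seq_along(genome)) {
    nb <- lens[i] %/% k
    if (nb == 0L) next
    at <- IRanges(start = seq_len(nb) * k - k + 1L, width = k)
    bin_list[[length(bin_list) + 1L]] <- GRanges(names(genome)[i], at)
    seq_list[[length(seq_list) + 1L]] <- Biostrings::extractAt(genome[[i]], at)
  }
  bins <- Reduce(c, bin_list)
  seqs <- Reduce(c, seq_list)
  has_n <- Biostrings::vcountPattern("N", seqs) > 0L
  counts <- integer(length(bins))
  clean <- which(!has_n)
  if (length(clean)) {
    pd <- Biostrings::PDict(seqs[clean])
    for (i in seq_along(genome)) {
      counts[clean] <- counts[clean] +
        Biostrings::countPDict(pd, genome[[i]]) +
        Biostrings::countPDict(pd, Biostrings::reverseComplement(genome[[i]]))
    }
  }
  mappable <- !has_n & counts == 1L
  mcols(bins)$mappable <- mappable
  runs <- reduce(bins[mappable], min.gapwidth = 1L)
  structure(list(mappable = runs, bins = bins, k = as.integer(k)),
            class = "mappability_mask")
}

#' @export
print.mappability_mask <- function(x, ...) {
  cat("mappability_mask: k =", x$k, "bp;",
      sum(mcols(x$bins)$mappable), "of", length(x$bins), "bins mappable in",
      length(x$mappable), "runs\n")
  invisible(x)
}

#' Build a mask directly from known mappable intervals
#'
#' @param mappable \code{GRanges} of mappable space (merged internally).
#' @param k Nominal bin size recorded on the mask.
#' @return A \code{mappability_mask}.
#' @export
mask_from_intervals <- function(mappable, k = 150L) {
  structure(list(mappable = reduce(mappable, ignore.strand = TRUE),
                 bins = GRanges(), k = as.integer(k)),
            class = "mappability_mask")
}

#' Size-preserving random controls within mappable space
#'
#' Places one control per input interval, of identical length, uniformly at
#' random over every start position at which the whole control fits inside a
#' single mappable run (the behaviour of shuffling within an include mask).
#' The output conserves the count and length multiset exactly and is
#' deterministic for a given seed.
#'
#' @param intervals \code{GRanges} to shuffle.
#' @param mask A \code{\link{mappability_mask}} (or object with a
#'   \code{mappable} \code{GRanges}).
#' @param seed Integer seed for placement.
#' @param allow_overlap May controls overlap one another (default TRUE)?
#' @param max_attempts Rejection-sampling cap per interval when
#'   \code{allow_overlap = FALSE}.
#' @param exclude Optional \code{GRanges} subtracted from the mappable space
#'   before placement.
#' @return \code{GRanges} of control regions (names/scores copied from input).
#' @export
shuffle_controls <- function(intervals, mask, seed, allow_overlap = TRUE,
                             max_attempts = 1000L, exclude = NULL) {
  runs <- if (inherits(mask, "mappability_mask")) mask$mappable else reduce(mask)
  if (!is.null(exclude)) runs <- setdiff(runs, exclude, ignore.strand = TRUE)
  if (length(intervals) == 0L) return(intervals)
  lens <- width(intervals)
  if (max(lens) > max(width(runs))) {
    stop("interval of length ", max(lens),
         " exceeds the longest mappable run (", max(width(runs)), ")",
         call. = FALSE)
  }
  run_chrom <- as.character(seqnames(runs))
  run_start <- start(runs)
  run_w <- width(runs)
  with_seed(seed, {
    place_one <- function(L) {
      valid <- pmax(0L, run_w - L + 1L)
      tot <- sum(valid)
      if (tot == 0L) stop("no mappable run can hold an interval of length ", L,
                          call. = FALSE)
      u <- sample.int(tot, 1L)
      r <- findInterval(u - 1L, cumsum(valid)) + 1L
      off <- u - c(0L, cumsum(valid))[r] - 1L
      c(r, run_start[r] + off)
    }
    chrom <- character(length(lens))
    st <- integer(length(lens))
    for (i in seq_along(lens)) {
      if (allow_overlap) {
        p <- place_one(lens[i])
        chrom[i] <- run_chrom[p[1L]]; st[i] <- p[2L]
      } else {
        ok <- FALSE
        prev <- seq_len(i - 1L)
        for (a in seq_len(max_attempts)) {
          p <- place_one(lens[i])
          cand_chrom <- run_chrom[p[1L]]; cand_s <- p[2L]
          cand_e <- cand_s + lens[i] - 1L
          clash <- any(chrom[prev] == cand_chrom & st[prev] <= cand_e &
                         cand_s <= st[prev] + lens[prev] - 1L)
          if (!clash) {
            chrom[i] <- cand_chrom; st[i] <- cand_s
            ok <- TRUE
            break
          }
        }
        if (!ok) stop("could not place non-overlapping control for interval ",
                      i, " (length ", lens[i], ") within ", max_attempts,
                      " attempts", call. = FALSE)
      }
    }
    out <- GRanges(chrom, IRanges(st, width = lens))
    GenomeInfoDb::seqlevels(out) <- GenomeInfoDb::seqlevels(runs)
    GenomeInfoDb::seqinfo(out) <- GenomeInfoDb::seqinfo(runs)
    mcols(out) <- mcols(intervals)
    out
  })
}
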