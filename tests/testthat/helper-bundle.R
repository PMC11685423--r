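suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
  library(S4Vectors)
  library(Biostrings)
})

# Bundles are expensive enough to build once per session and share.
.bundle_cache <- new.env(parent = emptyenv())

default_bundle <- function() {
  if (is.null(.bundle_cache$default)) {
    .bundle_cache$default <- generate_dataset(synthetic_config(seed = 1))
  }
  .bundle_cache$default
}

# 500 bidirectional enhancers, all carrying the 3x boundary factor: the
# configuration used for the boundary-statistic checks.
boundary_bundle <- function() {
  if (is.null(.bundle_cache$boundary)) {
    .bundle_cache$boundary <- generate_dataset(synthetic_config(
      seed = 1,
      enhancers_per_class = c("K4me1+_bidirectional" = 250L,
                              "K4me1+_unidirectional" = 0L,
                              "K4me1+_none" = 0L,
                              "K4me1-_bidirectional" = 250L,
                              "K4me1-_unidirectional" = 0L,
                              "K4me1-_none" = 0L),
      n_loops = 100L, n_repro_peaks = 100L))
  }
  .bundle_cache$boundary
}

# Stranded signal with constant per-strand values over given intervals on a
# single synthetic chromosome.
toy_signal <- function(plus_gr, plus_val, minus_gr, minus_val,
                       chrom_len = 10000L, chrom = "chrT",
                       read_length = 100) {
  lens <- stats::setNames(chrom_len, chrom)
  cov <- function(gr, v) {
    if (length(gr) == 0L) {
      return(RleList(stats::setNames(list(Rle(0, chrom_len)), chrom)))
    }
    seqlengths(gr) <- lens
    coverage(gr, weight = v)
  }
  stranded_signal(cov(plus_gr, plus_val), cov(minus_gr, minus_val),
                  read_length = read_length)
}

# Brute-force O(n*m) edge-gap distance oracle (half-open gap semantics on
# 1-based closed coordinates).
brute_nearest <- function(query, reference) {
  qs <- start(query); qe <- end(query)
  rs <- start(reference); re <- end(reference)
  qc <- as.character(seqnames(query)); rc <- as.character(seqnames(reference))
  vapply(seq_along(query), function(i) {
    j <- which(rc == qc[i])
    if (!length(j)) return(Inf)
    min(vapply(j, function(k) {
      if (qs[i] <= re[k] && rs[k] <= qe[i]) return(0)
      max(rs[k] - qe[i] - 1L, qs[i] - re[k] - 1L)
    }, numeric(1)))
  }, numeric(1))
}

# Brute-force all-pairs overlap oracle.
brute_overlap_flag <- function(a, b, min_bp = 1L) {
  as_ <- start(a); ae <- end(a); bs <- start(b); be <- end(b)
  ac <- as.character(seqnames(a)); bc <- as.character(seqnames(b))
  vapply(seq_along(a), function(i) {
    any(bc == ac[i] & pmin(ae[i], be) - pmax(as_[i], bs) + 1L >= min_bp)
  }, logical(1))
}

random_granges <- function(n, chroms = c("c1", "c2"), max_pos = 10000L,
                           max_width = 300L) {
  GRanges(sample(chroms, n, replace = TRUE),
          IRanges(sample.int(max_pos, n, replace = TRUE),
                  width = sample.int(max_width, n, replace = TRUE)))
}
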