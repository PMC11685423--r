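#' Strand-resolved base-pair coverage
#'
#' Holds run-length-encoded per-base coverage for the plus and minus strands
#' of one library (e.g. stranded RNA-seq, RAMPAGE or shRNA tracks), together
#' with the library size and read length used to convert coverage area back
#' into estimated read counts.
#'
#' @param plus,minus Numeric \code{RleList}, one element per chromosome, all
#'   values >= 0. Both lists must cover the same chromosomes.
#' @param library_size Total mapped reads in the library (may be \code{NA}).
#' @param read_length Read length in bp used for the coverage-area to
#'   read-count conversion; must be > 0.
#' @return An object of class \code{stranded_signal}.
#' @export
stranded_signal <- function(plus, minus, library_size = NA_real_,
                            read_length = 100) {
  if (read_length <= 0) stop("read_length must be > 0", call. = FALSE)
  if (!setequal(names(plus), names(minus))) {
    stop("plus and minus tracks cover different chromosomes", call. = FALSE)
  }
  if (any(vapply(plus, function(r) any(S4Vectors::runValue(r) < 0), logical(1))) ||
      any(vapply(minus, function(r) any(S4Vectors::runValue(r) < 0), logical(1)))) {
    stop("coverage values must be >= 0", call. = FALSE)
  }
  structure(list(plus = plus, minus = minus[names(plus)],
                 library_size = library_size, read_length = read_length),
            class = "stranded_signal")
}

#' @export
print.stranded_signal <- function(x, ...) {
  cat("stranded_signal over", length(x$plus), "chromosomes; read_length",
      x$read_length, "bp\n")
  invisible(x)
}

#' Read a stranded signal from one bedGraph per strand
#'
#' @param plus_path,minus_path bedGraph files of non-negative coverage.
#' @param seqlengths Named chromosome lengths; coverage vectors are padded
#'   with zeros to these lengths.
#' @param library_size,read_length See \code{\link{stranded_signal}}.
#' @return A \code{stranded_signal}.
#' @export
read_stranded_bedgraph <- function(plus_path, minus_path, seqlengths,
                                   library_size = NA_real_, read_length = 100) {
  stranded_signal(bedgraph_coverage(plus_path, seqlengths),
                  bedgraph_coverage(minus_path, seqlengths),
                  library_size = library_size, read_length = read_length)
}

bedgraph_coverage <- function(path, seqlengths) {
  gr <- parse_intervals(path, "bedgraph")
  GenomeInfoDb::seqlevels(gr) <- names(seqlengths)
  GenomeInfoDb::seqlengths(gr) <- seqlengths
  coverage(gr, weight = "score")
}

# Per-interval summary over an RleList track. Intervals are clipped to the
# chromosome; chromosomes absent from the track yield NA.
region_track_summary <- function(track, gr,
                                 stat = c("sum", "mean", "max", "median")) {
  stat <- match.arg(stat)
  out <- rep(NA_real_, length(gr))
  chroms <- as.character(seqnames(gr))
  for (chrom in unique(chroms)) {
    if (!chrom %in% names(track)) next
    idx <- which(chroms == chrom)
    r <- track[[chrom]]
    s <- pmax(1L, start(gr)[idx])
    e <- pmin(length(r), end(gr)[idx])
    ok <- s <= e
    if (!any(ok)) next
    v <- Views(r, s[ok], e[ok])
    out[idx[ok]] <- switch(stat,
      sum = viewSums(v),
      mean = viewMeans(v),
      max = viewMaxs(v),
      median = vapply(seq_along(v), function(j) {
        stats::median(as.numeric(v[[j]]))
      }, numeric(1)))
  }
  out
}

#' Per-interval coverage sums on each strand
#'
#' @param signal A \code{stranded_signal}.
#' @param gr Intervals to summarize.
#' @return Two-column matrix (\code{plus}, \code{minus}) of coverage sums.
#' @export
strand_region_sums <- function(signal, gr) {
  cbind(plus = region_track_summary(signal$plus, gr, "sum"),
        minus = region_track_summary(signal$minus, gr, "sum"))
}
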