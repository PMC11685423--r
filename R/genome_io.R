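#' Parse genomic intervals from standard text formats
#'
#' Reads BED (3-6 columns), narrowPeak, GFF3 or bedGraph into a
#' \link[GenomicRanges]{GRanges}. BED-family coordinates (0-based half-open)
#' are converted to the 1-based closed convention used throughout the
#' package; GFF3 is already 1-based closed and passes through. The
#' narrowPeak summit offset is retained as metadata column \code{peak} but
#' not used by any downstream operation.
#'
#' @param path Path to the file.
#' @param format One of \code{"bed"}, \code{"narrowpeak"}, \code{"gff3"},
#'   \code{"bedgraph"}.
#' @param genome_id Optional genome identifier attached to the result so that
#'   cross-genome operations can be caught.
#' @param seqlengths Optional named vector of chromosome lengths; when given,
#'   intervals extending past a chromosome end raise an error.
#' @return A \code{GRanges}. BED name/score/strand become \code{name},
#'   \code{score} and the strand slot; GFF3 \code{type} and attributes are
#'   kept as metadata columns; bedGraph values are in \code{score}.
#' @export
parse_intervals <- function(path,
                            format = c("bed", "narrowpeak", "gff3", "bedgraph"),
                            genome_id = NULL, seqlengths = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  gr <- switch(format,
    bed = read_bed_family(path, extra = 0L),
    narrowpeak = read_bed_family(path, extra = 4L),
    bedgraph = read_bedgraph(path),
    gff3 = read_gff3(path)
  )
  if (!is.null(seqlengths)) {
    bad <- which(end(gr) > seqlengths[as.character(seqnames(gr))])
    if (length(bad)) {
      stop("interval ", bad[1L], " extends past the end of ",
           as.character(seqnames(gr))[bad[1L]], call. = FALSE)
    }
    GenomeInfoDb::seqlevels(gr) <- names(seqlengths)
    GenomeInfoDb::seqlengths(gr) <- seqlengths
  }
  if (!is.null(genome_id)) {
    suppressWarnings(GenomeInfoDb::genome(gr) <- genome_id)
  }
  gr
}

# BED3-6 (extra = 0) and narrowPeak (extra = 4: signalValue pValue qValue peak)
read_bed_family <- function(path, extra = 0L) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (!length(lines)) return(GRanges())
  fields <- split_fields(lines)
  min_cols <- 3L + if (extra > 0L) 3L + extra else 0L
  chrom <- character(length(fields)); start0 <- integer(length(fields))
  end0 <- integer(length(fields))
  name <- rep(NA_character_, length(fields)); score <- rep(0, length(fields))
  strand <- rep("*", length(fields))
  np <- matrix(NA_real_, length(fields), 4L)
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < max(3L, min_cols)) {
      stop_at_line(path, i, sprintf("expected >= %d fields, got %d",
                                    max(3L, min_cols), length(f)))
    }
    s <- suppressWarnings(as.integer(f[2L])); e <- suppressWarnings(as.integer(f[3L]))
    if (is.na(s) || is.na(e)) stop_at_line(path, i, "non-integer coordinates")
    if (s < 0L || s >= e) stop_at_line(path, i, "requires 0 <= start < end")
    chrom[i] <- f[1L]; start0[i] <- s; end0[i] <- e
    if (length(f) >= 4L && f[4L] != ".") name[i] <- f[4L]
    if (length(f) >= 5L && f[5L] != ".") {
      sc <- suppressWarnings(as.numeric(f[5L]))
      if (is.na(sc)) stop_at_line(path, i, "non-numeric score")
      score[i] <- sc
    }
    if (length(f) >= 6L) {
      if (!f[6L] %in% c("+", "-", ".")) stop_at_line(path, i, "bad strand")
      strand[i] <- sub(".", "*", f[6L], fixed = TRUE)
    }
    if (extra > 0L) np[i, ] <- suppressWarnings(as.numeric(f[7L:10L]))
  }
  gr <- GRanges(chrom, IRanges(start0 + 1L, end0), strand = strand,
                name = name, score = score)
  if (extra > 0L) {
    mcols(gr)$signalValue <- np[, 1L]
    mcols(gr)$pValue <- np[, 2L]
    mcols(gr)$qValue <- np[, 3L]
    mcols(gr)$peak <- as.integer(np[, 4L])
  }
  gr
}

read_bedgraph <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (!length(lines)) return(GRanges(score = numeric(0)))
  fields <- split_fields(lines)
  n <- lengths(fields)
  if (any(n < 4L)) stop_at_line(path, which(n < 4L)[1L], "expected 4 fields")
  m <- matrix(unlist(fields), ncol = max(n), byrow = TRUE)
  s <- suppressWarnings(as.integer(m[, 2L])); e <- suppressWarnings(as.integer(m[, 3L]))
  v <- suppressWarnings(as.numeric(m[, 4L]))
  bad <- which(is.na(s) | is.na(e) | is.na(v) | s < 0L | s >= e)
  if (length(bad)) stop_at_line(path, bad[1L], "bad coordinates or value")
  GRanges(m[, 1L], IRanges(s + 1L, e), score = v)
}

read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  mcols(gr)$name <- if (!is.null(mcols(gr)$ID)) mcols(gr)$ID else NA_character_
  gr
}

#' Parse a BEDPE file into a loop set
#'
#' Each line gives two anchor intervals of one chromatin contact (e.g. a Hi-C
#' loop). Anchor order is normalized so the left anchor sorts first.
#'
#' @param path Path to a BEDPE file (>= 6 tab-separated columns).
#' @param genome_id Optional genome identifier.
#' @return A \code{loop_set}: list with parallel \code{GRanges} elements
#'   \code{anchor1} and \code{anchor2}.
#' @export
parse_loops <- function(path, genome_id = NULL) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track)", lines) & nzchar(lines)]
  if (!length(lines)) return(loop_set(GRanges(), GRanges()))
  fields <- split_fields(lines)
  n <- lengths(fields)
  if (any(n < 6L)) stop_at_line(path, which(n < 6L)[1L], "expected >= 6 fields")
  m <- matrix(unlist(lapply(fields, `[`, 1:6)), ncol = 6L, byrow = TRUE)
  co <- suppressWarnings(matrix(as.integer(m[, c(2, 3, 5, 6)]), ncol = 4L))
  bad <- which(apply(is.na(co), 1L, any) | co[, 1] >= co[, 2] | co[, 3] >= co[, 4])
  if (length(bad)) stop_at_line(path, bad[1L], "bad anchor coordinates")
  a1 <- GRanges(m[, 1L], IRanges(co[, 1L] + 1L, co[, 2L]))
  a2 <- GRanges(m[, 4L], IRanges(co[, 3L] + 1L, co[, 4L]))
  if (!is.null(genome_id)) {
    suppressWarnings(GenomeInfoDb::genome(a1) <- genome_id)
    suppressWarnings(GenomeInfoDb::genome(a2) <- genome_id)
  }
  loop_set(a1, a2)
}

#' Construct a loop set from two parallel anchor GRanges
#'
#' @param anchor1,anchor2 \code{GRanges} of equal length; pairs are reordered
#'   so anchor1 is never to the right of anchor2.
#' @return An object of class \code{loop_set}.
#' @export
loop_set <- function(anchor1, anchor2) {
  stopifnot(is(anchor1, "GRanges"), is(anchor2, "GRanges"),
            length(anchor1) == length(anchor2))
  if (length(anchor1)) {
    swap <- as.character(seqnames(anchor1)) > as.character(seqnames(anchor2)) |
      (as.character(seqnames(anchor1)) == as.character(seqnames(anchor2)) &
         start(anchor1) > start(anchor2))
    if (any(swap)) {
      tmp <- anchor1[swap]
      anchor1[swap] <- anchor2[swap]
      anchor2[swap] <- tmp
    }
  }
  structure(list(anchor1 = anchor1, anchor2 = anchor2), class = "loop_set")
}

#' @export
length.loop_set <- function(x) length(x$anchor1)

#' @export
print.loop_set <- function(x, ...) {
  cat("loop_set with", length(x), "anchor pairs\n")
  invisible(x)
}

#' Write intervals as BED (0-based half-open)
#'
#' @param x A \code{GRanges}; \code{name}/\code{score} metadata columns and
#'   strand are written when present.
#' @param path Output path.
#' @export
write_bed <- function(x, path) {
  name <- if (!is.null(mcols(x)$name)) ifelse(is.na(mcols(x)$name), ".", mcols(x)$name) else rep(".", length(x))
  score <- if (!is.null(mcols(x)$score)) mcols(x)$score else rep(0, length(x))
  strand <- sub("*", ".", as.character(strand(x)), fixed = TRUE)
  df <- data.frame(as.character(seqnames(x)), start(x) - 1L, end(x),
                   name, score, strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a loop set as BEDPE
#' @param x A \code{loop_set}.
#' @param path Output path.
#' @export
write_bedpe <- function(x, path) {
  a1 <- x$anchor1; a2 <- x$anchor2
  df <- data.frame(as.character(seqnames(a1)), start(a1) - 1L, end(a1),
                   as.character(seqnames(a2)), start(a2) - 1L, end(a2))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a per-chromosome coverage vector as bedGraph
#' @param cov A numeric \code{RleList} (one element per chromosome).
#' @param path Output path.
#' @export
write_bedgraph <- function(cov, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (chrom in names(cov)) {
    r <- cov[[chrom]]
    ends <- cumsum(S4Vectors::runLength(r))
    starts <- c(0L, ends[-length(ends)])
    vals <- S4Vectors::runValue(r)
    keep <- vals != 0
    if (any(keep)) {
      writeLines(sprintf("%s\t%d\t%d\t%s", chrom, starts[keep], ends[keep],
                         format(vals[keep], trim = TRUE, scientific = FALSE,
                                digits = 15)), con)
    }
  }
  invisible(path)
}

#' Edge-to-edge distance from each query interval to its nearest reference
#'
#' Distance is the gap between closest edges in bp: 0 when the query overlaps
#' (or directly abuts) any reference interval, \code{Inf} when the query's
#' chromosome carries no reference interval. This is the distance used to
#' call a peak "distal" when it is at least 2 kb from the closest gene.
#'
#' @param query,reference \code{GRanges} on the same genome; reference must
#'   be non-empty.
#' @return Numeric vector of length \code{length(query)}.
#' @export
nearest_distance <- function(query, reference) {
  if (length(reference) == 0L) stop("reference set is empty", call. = FALSE)
  check_same_genome(query, reference)
  # absent seqlevels are a supported case (distance Inf), not a warning
  hit <- suppressWarnings(distanceToNearest(query, reference,
                                            ignore.strand = TRUE))
  d <- rep(Inf, length(query))
  d[queryHits(hit)] <- mcols(hit)$distance
  d
}

#' Flag intervals overlapping another set and list the overlapping pairs
#'
#' @param a,b \code{GRanges} on the same genome.
#' @param min_bp Minimum shared bases (>= 1) for an overlap to count.
#' @return List with \code{flag} (logical per \code{a} interval) and
#'   \code{pairs} (data.frame of qualifying a/b index pairs).
#' @export
interval_overlaps <- function(a, b, min_bp = 1L) {
  if (min_bp < 1L) stop("min_bp must be >= 1", call. = FALSE)
  check_same_genome(a, b)
  hits <- suppressWarnings(findOverlaps(a, b, minoverlap = min_bp,
                                        ignore.strand = TRUE))
  flag <- logical(length(a))
  flag[queryHits(hits)] <- TRUE
  list(flag = flag,
       pairs = data.frame(a = queryHits(hits), b = subjectHits(hits)))
}
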