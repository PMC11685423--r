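#' @importFrom methods is
#' @import GenomicRanges
#' @import IRanges
#' @import S4Vectors
NULL

# Run code under a fixed RNG state without disturbing the caller's stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# Genome identity check: errors only when both sets carry distinct, known ids.
check_same_genome <- function(a, b) {
  ga <- unique(stats::na.omit(GenomeInfoDb::genome(a)))
  gb <- unique(stats::na.omit(GenomeInfoDb::genome(b)))
  if (length(ga) == 1L && length(gb) == 1L && ga != gb) {
    stop("genome mismatch: '", ga, "' vs '", gb, "'", call. = FALSE)
  }
  invisible(TRUE)
}

# Fields shared by every tabular text format we read.
split_fields <- function(lines) {
  strsplit(lines, "\t", fixed = TRUE)
}

stop_at_line <- function(path, i, msg) {
  stop(sprintf("%s: malformed line %d: %s", basename(path), i, msg), call. = FALSE)
}
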