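#' Signal metaprofile over a set of intervals
#'
#' Builds a per-interval, per-bin matrix of mean signal. In
#' \code{scale_regions} mode each interval body is rescaled to
#' \code{body_bins} bins (fractional bp weighting, so intervals shorter than
#' a bin are still handled exactly) and fixed-width flanks of
#' \code{flank_bp} are appended on both sides, binned at \code{bin_bp}. In
#' \code{reference_point} mode bins of \code{bin_bp} cover
#' \code{[-flank_bp, +flank_bp)} around the interval midpoint. Positions
#' falling outside a chromosome are missing values, excluded from column
#' means rather than zero-filled.
#'
#' @param signal Numeric \code{RleList} or a \code{\link{stranded_signal}}
#'   (strands summed).
#' @param intervals \code{GRanges}.
#' @param mode \code{"scale_regions"} or \code{"reference_point"}.
#' @param flank_bp Flank width in bp (multiple of \code{bin_bp}).
#' @param bin_bp Flank/reference bin width in bp.
#' @param body_bins Number of body bins in \code{scale_regions} mode.
#' @return Object of class \code{profile_matrix}: a numeric matrix (rows =
#'   intervals, cols = bins) with attributes \code{mode}, \code{flank_bp},
#'   \code{bin_bp}, \code{body_bins}, \code{widths}; \code{colMeans} with
#'   \code{na.rm} gives the metaplot vector.
#' @export
metaprofile <- function(signal, intervals,
                        mode = c("scale_regions", "reference_point"),
                        flank_bp = 5000L, bin_bp = 50L, body_bins = 100L) {
  mode <- match.arg(mode)
  if (bin_bp < 1L) stop("bin_bp must be >= 1", call. = FALSE)
  if (flank_bp %% bin_bp != 0L) stop("flank_bp must be a multiple of bin_bp", call. = FALSE)
  track <- if (inherits(signal, "stranded_signal")) signal$plus + signal$minus else signal
  n_flank <- flank_bp %/% bin_bp
  n_cols <- if (mode == "scale_regions") 2L * n_flank + body_bins else 2L * n_flank
  mat <- matrix(NA_real_, length(intervals), n_cols)
  chroms <- as.character(seqnames(intervals))
  for (i in seq_along(intervals)) {
    if (!chroms[i] %in% names(track)) next
    r <- track[[chroms[i]]]
    clen <- length(r)
    if (mode == "scale_regions") {
      s <- start(intervals)[i]; e <- end(intervals)[i]
      v <- row_window(r, s - flank_bp, e + flank_bp, clen)
      L <- e - s + 1L
      mat[i, seq_len(n_flank)] <- bin_fixed(v[seq_len(flank_bp)], bin_bp)
      mat[i, n_flank + seq_len(body_bins)] <-
        bin_scaled(v[flank_bp + seq_len(L)], body_bins)
      mat[i, n_flank + body_bins + seq_len(n_flank)] <-
        bin_fixed(v[flank_bp + L + seq_len(flank_bp)], bin_bp)
    } else {
      mid <- (start(intervals)[i] + end(intervals)[i]) %/% 2L
      v <- row_window(r, mid - flank_bp, mid + flank_bp - 1L, clen)
      mat[i, ] <- bin_fixed(v, bin_bp)
    }
  }
  structure(mat, class = c("profile_matrix", "matrix"),
            mode = mode, flank_bp = flank_bp, bin_bp = bin_bp,
            body_bins = if (mode == "scale_regions") body_bins else 0L,
            widths = width(intervals))
}

# Decode r over [from, to], NA outside the chromosome.
row_window <- function(r, from, to, clen) {
  v <- rep(NA_real_, to - from + 1L)
  s2 <- max(1L, from); e2 <- min(clen, to)
  if (s2 <= e2) {
    v[(s2 - from + 1L):(e2 - from + 1L)] <- as.numeric(window(r, s2, e2))
  }
  v
}

# Fixed-width bins; out-of-chromosome bp are NA and excluded from each bin's
# mean (a fully out-of-range bin stays NA/NaN).
bin_fixed <- function(v, bin_bp) {
  m <- matrix(v, nrow = bin_bp)
  out <- colMeans(m, na.rm = TRUE)
  out[colSums(!is.na(m)) == 0L] <- NA_real_
  out
}

# Body of length L rescaled to `nbins` equal fractional windows via the
# cumulative sum: exact mean under fractional-overlap bp weighting.
bin_scaled <- function(v, nbins) {
  L <- length(v)
  if (all(is.na(v))) return(rep(NA_real_, nbins))
  cs <- c(0, cumsum(ifelse(is.na(v), 0, v)))
  cn <- c(0, cumsum(!is.na(v)))
  edges <- L * (0:nbins) / nbins
  interp <- function(cum, o) {
    lo_i <- pmin(floor(o), L - 1L)
    frac <- o - lo_i
    cum[lo_i + 1L] + frac * (cum[lo_i + 2L] - cum[lo_i + 1L])
  }
  area <- diff(interp(cs, edges))
  nbp <- diff(interp(cn, edges))
  ifelse(nbp > 1e-12, area / nbp, NA_real_)
}

#' Boundary enrichment of a scaled-region profile
#'
#' Quantifies signal concentration at interval boundaries (e.g. 24nt siRNA
#' islands at enhancer borders): the mean signal within \code{edge_bp} of
#' each boundary, taken on both the inside (body bins, converted per row
#' from that row's interval width) and the outside (flank bins), divided by
#' the mean over the remaining interior body bins.
#'
#' @param mat A \code{profile_matrix} in \code{scale_regions} mode with
#'   flanks >= \code{edge_bp}.
#' @param edge_bp Boundary window in bp.
#' @return List with \code{ratio} (combined), \code{left}, \code{right},
#'   \code{edge_mean}, \code{interior_mean}. An interior mean of 0 yields
#'   \code{Inf} with a message.
#' @export
boundary_enrichment <- function(mat, edge_bp = 500L) {
  stopifnot(inherits(mat, "profile_matrix"))
  if (attr(mat, "mode") != "scale_regions") {
    stop("boundary_enrichment needs a scale_regions profile", call. = FALSE)
  }
  flank_bp <- attr(mat, "flank_bp"); bin_bp <- attr(mat, "bin_bp")
  body_bins <- attr(mat, "body_bins"); widths <- attr(mat, "widths")
  if (flank_bp < edge_bp) stop("flanks are narrower than edge_bp", call. = FALSE)
  n_flank <- flank_bp %/% bin_bp
  n_edge_flank <- edge_bp %/% bin_bp
  side <- function(row, w) {
    # per-row: body bins covering the first/last edge_bp of the interval
    n_in <- max(1L, min(body_bins %/% 2L, round(edge_bp * body_bins / w)))
    left_out <- row[(n_flank - n_edge_flank + 1L):n_flank]
    left_in <- row[n_flank + seq_len(n_in)]
    right_in <- row[n_flank + body_bins - n_in + seq_len(n_in)]
    right_out <- row[n_flank + body_bins + seq_len(n_edge_flank)]
    interior <- if (n_in + 1L <= body_bins - n_in) {
      row[n_flank + (n_in + 1L):(body_bins - n_in)]
    } else NA_real_
    c(left = mean(c(left_out, left_in), na.rm = TRUE),
      right = mean(c(right_in, right_out), na.rm = TRUE),
      interior = mean(interior, na.rm = TRUE))
  }
  per_row <- t(vapply(seq_len(nrow(mat)), function(i) side(mat[i, ], widths[i]),
                      numeric(3)))
  edge_mean <- mean(c(per_row[, "left"], per_row[, "right"]), na.rm = TRUE)
  interior_mean <- mean(per_row[, "interior"], na.rm = TRUE)
  if (interior_mean == 0) {
    message("interior mean is 0; boundary ratio is Inf")
  }
  list(ratio = edge_mean / interior_mean,
       left = mean(per_row[, "left"], na.rm = TRUE) / interior_mean,
       right = mean(per_row[, "right"], na.rm = TRUE) / interior_mean,
       edge_mean = edge_mean, interior_mean = interior_mean)
}
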