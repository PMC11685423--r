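#' Tissue-specific differential-expression gene sets
#'
#' A gene is tissue-specific (in the stated direction) when it is
#' differentially expressed that way in EVERY pairwise comparison of the
#' tissue against each other tissue, the "versus all other tissues"
#' intersection rule.
#'
#' The table needs columns \code{gene}, \code{tissue_a}, \code{tissue_b} and
#' either a pre-thresholded \code{label} (\code{up}/\code{down}/\code{ns},
#' direction relative to \code{tissue_a}) or \code{logFC} (positive = up in
#' \code{tissue_a}) plus \code{fdr}.
#'
#' @param de Long-format pairwise DE data.frame.
#' @param tissue Tissue whose specific genes are sought.
#' @param direction \code{"up"} or \code{"down"}.
#' @param fdr FDR threshold applied when no \code{label} column is present.
#' @param min_lfc Absolute log2 fold-change floor (default 0: none).
#' @return Character vector of gene ids.
#' @export
tissue_specific_sets <- function(de, tissue, direction = c("up", "down"),
                                 fdr = 0.05, min_lfc = 0) {
  direction <- match.arg(direction)
  tissues <- sort(unique(c(de$tissue_a, de$tissue_b)))
  others <- setdiff(tissues, tissue)
  if (!length(others)) stop("no other tissues in the table", call. = FALSE)
  have <- unique(paste(de$tissue_a, de$tissue_b))
  missing <- others[!(paste(tissue, others) %in% have |
                        paste(others, tissue) %in% have)]
  if (length(missing)) {
    stop("missing pairwise comparison(s): ",
         paste(tissue, "vs", missing, collapse = ", "), call. = FALSE)
  }
  rel <- de[de$tissue_a == tissue | de$tissue_b == tissue, , drop = FALSE]
  flip <- rel$tissue_b == tissue
  if (!is.null(rel$label)) {
    lab <- as.character(rel$label)
    lab[flip] <- c(up = "down", down = "up", ns = "ns")[lab[flip]]
  } else {
    lfc <- ifelse(flip, -rel$logFC, rel$logFC)
    sig <- rel$fdr < fdr & abs(lfc) >= min_lfc
    lab <- ifelse(!sig, "ns", ifelse(lfc > 0, "up", "down"))
  }
  ok <- lab == direction
  counts <- table(factor(rel$gene[ok], levels = unique(rel$gene)))
  names(counts)[counts == length(others)]
}

#' Cross-inbred conservation flow of differentially expressed genes
#'
#' For each reference DEG and each target inbred, assigns one of three
#' exclusive statuses: \code{conserved_DEG} when ANY listed homolog is a DEG
#' in that inbred, \code{homolog_not_DEG} when homologs exist but none
#' qualifies, \code{no_homolog} otherwise. Percentages are computed over all
#' reference DEGs.
#'
#' @param ref_degs Character vector of reference DEG ids.
#' @param orthology data.frame with columns \code{ref_gene}, \code{inbred},
#'   \code{homolog} (one homolog per row; one-to-many allowed).
#' @param target_degs Named list of per-inbred DEG id vectors.
#' @return List: \code{flow} (long data.frame gene x inbred x status) and
#'   \code{summary} (per-inbred percentages, summing to 100).
#' @export
homolog_flow <- function(ref_degs, orthology, target_degs) {
  statuses <- c("conserved_DEG", "homolog_not_DEG", "no_homolog")
  flow <- do.call(rbind, lapply(names(target_degs), function(inb) {
    orth <- orthology[orthology$inbred == inb, , drop = FALSE]
    homs <- split(orth$homolog, orth$ref_gene)
    deg <- target_degs[[inb]]
    status <- vapply(ref_degs, function(g) {
      h <- homs[[g]]
      if (is.null(h) || !length(h)) return("no_homolog")
      if (any(h %in% deg)) "conserved_DEG" else "homolog_not_DEG"
    }, character(1))
    data.frame(ref_gene = ref_degs, inbred = inb,
               status = factor(status, levels = statuses), row.names = NULL)
  }))
  summary <- do.call(rbind, lapply(split(flow, flow$inbred), function(d) {
    pct <- 100 * table(d$status) / nrow(d)
    data.frame(inbred = d$inbred[1L],
               pct_conserved = unname(pct["conserved_DEG"]),
               pct_homolog_not_DEG = unname(pct["homolog_not_DEG"]),
               pct_no_homolog = unname(pct["no_homolog"]))
  }))
  rownames(summary) <- NULL
  list(flow = flow, summary = summary)
}

#' Expression quintiles of expressed genes
#'
#' Genes with RPKM above \code{min_rpkm} in the chosen tissue are ranked and
#' split into five near-equal bins (1 = lowest expression); ties are broken
#' by gene id so the binning is deterministic. Non-expressed genes are left
#' out.
#'
#' @param expr Numeric matrix or data.frame of RPKM, genes as rownames,
#'   tissues as columns.
#' @param tissue Column to bin on.
#' @param min_rpkm Expression floor (strict; default 0 means RPKM > 0).
#' @return Named integer vector (1..5) over expressed genes.
#' @export
quintile_bins <- function(expr, tissue, min_rpkm = 0) {
  v <- expr[, tissue]
  names(v) <- rownames(expr)
  v <- v[v > min_rpkm]
  if (length(v) < 5L) stop("fewer than 5 expressed genes", call. = FALSE)
  ord <- order(v, names(v))
  q <- integer(length(v))
  q[ord] <- ceiling(seq_along(v) * 5 / length(v))
  names(q) <- names(v)
  q
}
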