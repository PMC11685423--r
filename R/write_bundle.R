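#' Write a GFF3 file from a GRanges
#'
#' @param x \code{GRanges} with optional \code{name}, \code{type} and
#'   \code{family} metadata columns.
#' @param path Output path.
#' @param source Value of the GFF3 source column.
#' @export
write_gff3 <- function(x, path, source = "distalreg") {
  type <- if (!is.null(mcols(x)$type)) as.character(mcols(x)$type) else rep("region", length(x))
  name <- if (!is.null(mcols(x)$name)) mcols(x)$name else sprintf("feat%d", seq_along(x))
  attrs <- sprintf("ID=%s", name)
  if (!is.null(mcols(x)$family)) {
    attrs <- paste0(attrs, ";family=", mcols(x)$family)
  }
  strand <- sub("*", ".", as.character(strand(x)), fixed = TRUE)
  lines <- sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\t%s",
                   as.character(seqnames(x)), source, type, start(x), end(x),
                   strand, attrs)
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Write a synthetic bundle to disk
#'
#' Serializes every component of a \code{\link{generate_dataset}} bundle as
#' plain-text standard formats (FASTA, GFF3, BED, bedGraph, BEDPE, TSV),
#' with the truth tables under \code{truth/}.
#'
#' @param bundle A \code{synthetic_bundle}.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)
  p <- function(...) file.path(dir, ...)
  Biostrings::writeXStringSet(bundle$genome, p("genome.fa"))
  ann <- c(bundle$genes, bundle$tes)
  mcols(ann)$type <- rep(c("gene", "transposable_element"),
                         c(length(bundle$genes), length(bundle$tes)))
  if (is.null(mcols(bundle$genes)$family)) {
    mcols(ann)$family <- c(rep(NA_character_, length(bundle$genes)),
                           as.character(mcols(bundle$tes)$family))
  }
  write_gff3(ann, p("annotation.gff3"))
  write_bed(bundle$enhancers, p("h3k27ac_distal.bed"))
  write_bed(bundle$k4me1, p("h3k4me1.bed"))
  write_bed(bundle$merged_peaks, p("peaks_merged.bed"))
  write_bed(bundle$pseudo1, p("peaks_pseudo1.bed"))
  write_bed(bundle$pseudo2, p("peaks_pseudo2.bed"))
  write_bed(bundle$conserved, p("conserved_elements.bed"))
  write_bed(bundle$srna_clusters, p("srna_clusters.bed"))
  for (i in seq_along(bundle$tfbs)) {
    write_bed(bundle$tfbs[[i]], p(sprintf("tfbs_TF%d.bed", i)))
  }
  write_bedgraph(bundle$rna$plus, p("rna_plus.bedgraph"))
  write_bedgraph(bundle$rna$minus, p("rna_minus.bedgraph"))
  write_bedgraph(bundle$rampage$plus, p("rampage_plus.bedgraph"))
  write_bedgraph(bundle$rampage$minus, p("rampage_minus.bedgraph"))
  write_bedgraph(bundle$srna24, p("srna24.bedgraph"))
  write_bedgraph(bundle$activity, p("activity.bedgraph"))
  write_bedpe(bundle$loops, p("loops.bedpe"))
  wt <- function(x, f) utils::write.table(x, f, sep = "\t", quote = FALSE,
                                          row.names = FALSE)
  wt(data.frame(gene = rownames(bundle$expression), bundle$expression,
                check.names = FALSE), p("expression_rpkm.tsv"))
  wt(bundle$de, p("de_pairwise.tsv"))
  wt(bundle$orthology, p("orthology.tsv"))
  wt(do.call(rbind, lapply(names(bundle$target_degs), function(i) {
    data.frame(inbred = i, gene = bundle$target_degs[[i]])
  })), p("target_degs.tsv"))
  wt(bundle$srna_reads, p("srna_reads.tsv"))
  for (nm in names(bundle$truth)) {
    x <- bundle$truth[[nm]]
    if (is.null(x)) next
    if (is.data.frame(x)) {
      wt(x, p("truth", paste0(nm, ".tsv")))
    } else {
      wt(data.frame(key = names(x) %||% nm, value = unname(unlist(x))),
         p("truth", paste0(nm, ".tsv")))
    }
  }
  invisible(dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a small genome with planted exact duplications
#'
#' Intended for mappability testing: a random genome in which
#' \code{n_dups} segments of \code{dup_len} bp are copied to a second
#' location, making the covered k-mer bins non-unique.
#'
#' @param seed Seed.
#' @param chrom_length Genome length (single chromosome).
#' @param n_dups Number of duplicated segments.
#' @param dup_len Length of each duplicated segment (bp).
#' @return List: \code{genome} (\code{DNAStringSet}), \code{dups}
#'   (data.frame of source/target starts).
#' @export
synthetic_repeat_genome <- function(seed = 1L, chrom_length = 50000L,
                                    n_dups = 3L, dup_len = 300L) {
  with_seed(seed, {
    s <- random_dna(chrom_length)
    slots <- floor(chrom_length / (2L * n_dups + 1L))
    src <- integer(n_dups); dst <- integer(n_dups)
    for (i in seq_len(n_dups)) {
      src[i] <- (2L * i - 2L) * slots + sample.int(slots - dup_len, 1L)
      dst[i] <- (2L * i - 1L) * slots + sample.int(slots - dup_len, 1L)
      Biostrings::subseq(s, dst[i], dst[i] + dup_len - 1L) <-
        Biostrings::subseq(s, src[i], src[i] + dup_len - 1L)
    }
    genome <- Biostrings::DNAStringSet(list(chr01 = s))
    list(genome = genome, dups = data.frame(src = src, dst = dst,
                                            len = dup_len))
  })
}
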