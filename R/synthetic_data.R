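#' Configuration for the synthetic regulatory-genomics bundle
#'
#' Defines the study conditions emulated by \code{\link{generate_dataset}}:
#' a random genome organized into fixed-pitch units each carrying a gene and
#' (optionally) one distal enhancer, telomere repeat runs at chromosome
#' ends, six planted enhancer classes with strand-resolved RNA evidence,
#' boundary-enriched 24nt siRNA signal, TFBS / capped-RNA / activity /
#' conserved-element evidence at class-specific rates, chromatin loops
#' wiring enhancers to genes with shifted expression, pairwise DE tables
#' with planted tissue-specific genes, an orthology map with a planted
#' conservation rate, and collapsed small-RNA reads with tissue-like
#' size/strand structure.
#'
#' Counts are realized exactly; rates/probabilities are sampled.
#'
#' @param seed Integer master seed; the whole bundle is deterministic in it.
#' @param n_chroms,units_per_chrom,unit_bp Genome layout; each chromosome is
#'   \code{units_per_chrom * unit_bp + 2 * 10000} bp (10 kb telomeric pads).
#' @param telomere_copies Telomere motif copies planted per chromosome end.
#' @param telomere_motif Telomere repeat unit.
#' @param enhancers_per_class Named counts for the six classes
#'   (\code{K4me1+/-} x bidirectional/unidirectional/none).
#' @param enhancer_lengths Pool of enhancer lengths (bp) sampled uniformly.
#' @param read_length RNA read length used to realize planted read counts as
#'   idealized uniform coverage.
#' @param expressed_read_range Planted per-strand read-count range for
#'   expressed strands (kept well above the default calling threshold of 5).
#' @param boundary_factor Named 24nt boundary enrichment factor per
#'   collapsed expression class (edge signal = factor x interior).
#' @param tfbs_rate,capped_fraction,conserved_rate Named per-class (or per
#'   collapsed class) planting probabilities.
#' @param activity_mean Named per-class mean of the planted activity value.
#' @param n_tfs Number of TF sets the TFBS are split over.
#' @param n_loops Enhancers wired by a chromatin loop to their unit's gene.
#' @param loop_expression_shift log2-units added to loop-linked genes'
#'   expression in the loop tissue.
#' @param loop_tissue Tissue whose expression carries the loop shift.
#' @param tissues Tissue names (>= 2).
#' @param specific_degs Named list per tissue of planted
#'   \code{c(up=,down=)} tissue-specific gene counts.
#' @param n_ref_degs Reference DEGs for the conservation flow.
#' @param conservation_probs Probabilities of
#'   \code{conserved_DEG}/\code{homolog_not_DEG}/\code{no_homolog}.
#' @param target_inbreds Target inbred names for the flow.
#' @param n_srna_clusters,n_hairpin Small-RNA cluster counts (hairpin-like
#'   subset planted with long span, strong strand bias and 22nt dominance).
#' @param srna_size_mix Named integer ratio of global 21/22/24nt read counts
#'   (realized exactly).
#' @param n_repro_peaks,repro_fractions Merged-peak count and exact
#'   both/one/neither pseudo-replicate fractions.
#' @return A validated list of class \code{synthetic_config}.
#' @export
synthetic_config <- function(
    seed = 1L,
    n_chroms = 10L, units_per_chrom = 60L, unit_bp = 30000L,
    telomere_copies = 40L, telomere_motif = "CCCTAAA",
    enhancers_per_class = c("K4me1+_bidirectional" = 100L,
                            "K4me1+_unidirectional" = 100L,
                            "K4me1+_none" = 100L,
                            "K4me1-_bidirectional" = 100L,
                            "K4me1-_unidirectional" = 100L,
                            "K4me1-_none" = 100L),
    enhancer_lengths = seq(1200L, 3000L, by = 100L),
    read_length = 100L,
    expressed_read_range = c(15L, 30L),
    boundary_factor = c(bidirectional = 3, unidirectional = 2, none = 1),
    tfbs_rate = c("K4me1+_bidirectional" = 0.2, "K4me1+_unidirectional" = 0.2,
                  "K4me1+_none" = 0.2, "K4me1-_bidirectional" = 0.6,
                  "K4me1-_unidirectional" = 0.4, "K4me1-_none" = 0.2),
    capped_fraction = c(bidirectional = 0.5, unidirectional = 0.3, none = 0.1),
    conserved_rate = c(bidirectional = 0.7, unidirectional = 0.5, none = 0.3),
    activity_mean = c("K4me1+_bidirectional" = 1.5, "K4me1+_unidirectional" = 1.5,
                      "K4me1+_none" = 1.5, "K4me1-_bidirectional" = 3,
                      "K4me1-_unidirectional" = 2, "K4me1-_none" = 1),
    n_tfs = 3L,
    n_loops = 300L, loop_expression_shift = 1.5, loop_tissue = "ear",
    tissues = c("pollen", "ear", "root", "endosperm", "cn"),
    specific_degs = list(pollen = c(up = 150L, down = 100L),
                         ear = c(up = 60L, down = 40L)),
    n_ref_degs = 2000L,
    conservation_probs = c(conserved_DEG = 0.6, homolog_not_DEG = 0.3,
                           no_homolog = 0.1),
    target_inbreds = c("B73", "Mo17"),
    n_srna_clusters = 50L, n_hairpin = 10L,
    srna_size_mix = c("21" = 1L, "22" = 3L, "24" = 6L),
    n_repro_peaks = 200L,
    repro_fractions = c(both = 0.6, one = 0.2, neither = 0.2)) {
  cfg <- as.list(environment())
  if (!setequal(names(cfg$enhancers_per_class), enhancer_classes())) {
    stop("enhancers_per_class must name all six classes", call. = FALSE)
  }
  probs <- c(cfg$tfbs_rate, cfg$capped_fraction, cfg$conserved_rate,
             cfg$conservation_probs, cfg$repro_fractions)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0,1]", call. = FALSE)
  counts <- c(cfg$enhancers_per_class, cfg$n_loops, cfg$n_ref_degs,
              cfg$n_srna_clusters, cfg$n_hairpin, cfg$n_repro_peaks,
              cfg$telomere_copies)
  if (any(counts < 0)) stop("counts must be >= 0", call. = FALSE)
  if (abs(sum(cfg$conservation_probs) - 1) > 1e-9) {
    stop("conservation_probs must sum to 1", call. = FALSE)
  }
  structure(cfg, class = "synthetic_config")
}

# layout offsets within a unit (1-based, relative to unit base)
.unit_layout <- list(srna_bg = c(2001L, 4000L), gene = c(5001L, 8000L),
                     repro = c(10001L, 10800L), enh_start = 15001L,
                     cluster_start = 21001L, te = c(26001L, 28000L))
.tel_pad <- 10000L

random_dna <- function(n) {
  Biostrings::DNAString(paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                               collapse = ""))
}

# Remove chance motif occurrences in [lo, hi] outside the protected starts.
scrub_motif <- function(seq, pattern, lo, hi, protect_max_start = 0L,
                        protect_min_start = .Machine$integer.max) {
  bases <- c("A", "C", "G", "T")
  repeat {
    m <- Biostrings::matchPattern(pattern, Biostrings::subseq(seq, lo, hi))
    st <- start(m) + lo - 1L
    st <- st[st > protect_max_start & st < protect_min_start]
    if (!length(st)) break
    for (s in st) {
      pos <- s + 3L
      cur <- as.character(Biostrings::subseq(seq, pos, pos))
      Biostrings::subseq(seq, pos, pos) <- Biostrings::DNAString(sample(setdiff(bases, cur), 1L))
    }
  }
  seq
}

#' Generate the full synthetic data bundle with planted truth
#'
#' Deterministic in \code{config$seed}. See \code{\link{synthetic_config}}
#' for the planted structure. When \code{dir} is given the bundle is also
#' written to disk as FASTA / GFF3 / BED / bedGraph / BEDPE / TSV files via
#' \code{\link{write_bundle}}.
#'
#' @param config A \code{\link{synthetic_config}}.
#' @param dir Optional output directory.
#' @return List of class \code{synthetic_bundle}: genome and annotation,
#'   peak sets, signals, loops, expression/DE/orthology tables, small-RNA
#'   reads and clusters, and \code{truth} (the planted labels for every
#'   generated entity).
#' @export
generate_dataset <- function(config = synthetic_config(), dir = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  n_units <- cfg$n_chroms * cfg$units_per_chrom
  n_enh <- sum(cfg$enhancers_per_class)
  need_units <- max(n_enh,
                    if (cfg$n_repro_peaks > 0L) cfg$n_repro_peaks + 40L else 0L,
                    cfg$n_srna_clusters)
  if (need_units > n_units) {
    stop("genome too small: ", n_units, " units cannot host ", need_units,
         " features", call. = FALSE)
  }
  chrom_len <- cfg$units_per_chrom * cfg$unit_bp + 2L * .tel_pad
  chroms <- sprintf("chr%02d", seq_len(cfg$n_chroms))
  seqlens <- stats::setNames(rep(chrom_len, cfg$n_chroms), chroms)
  L <- .unit_layout
  with_seed(cfg$seed, {
    ## genome with telomere runs
    motif <- cfg$telomere_motif
    rc_motif <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(motif)))
    run <- strrep(motif, cfg$telomere_copies)
    rc_run <- strrep(rc_motif, cfg$telomere_copies)
    seqs <- lapply(seq_len(cfg$n_chroms), function(i) {
      s <- random_dna(chrom_len)
      if (cfg$telomere_copies > 0L) {
        Biostrings::subseq(s, 1L, nchar(run)) <- Biostrings::DNAString(run)
        Biostrings::subseq(s, chrom_len - nchar(rc_run) + 1L, chrom_len) <- Biostrings::DNAString(rc_run)
      }
      s <- scrub_motif(s, motif, 1L, .tel_pad,
                       protect_max_start = nchar(run))
      s <- scrub_motif(s, rc_motif, chrom_len - .tel_pad + 1L, chrom_len,
                       protect_min_start = chrom_len - nchar(rc_run) + 1L)
      s
    })
    genome <- Biostrings::DNAStringSet(seqs)
    names(genome) <- chroms

    unit_chrom <- chroms[(seq_len(n_units) - 1L) %/% cfg$units_per_chrom + 1L]
    unit_base <- .tel_pad + ((seq_len(n_units) - 1L) %% cfg$units_per_chrom) * cfg$unit_bp

    si <- GenomeInfoDb::Seqinfo(chroms, seqlens, genome = "synthetic")
    mkgr <- function(chrom, start, end, ...) {
      GRanges(chrom, IRanges(start, end), seqinfo = si, ...)
    }

    ## annotation: one gene per unit, a TE in every third unit
    genes <- mkgr(unit_chrom, unit_base + L$gene[1L], unit_base + L$gene[2L],
                  strand = "+", name = sprintf("gene%04d", seq_len(n_units)))
    te_units <- which(seq_len(n_units) %% 3L == 0L)
    families <- c("LTR", "TIR", "LINE", "Helitron")
    tes <- mkgr(unit_chrom[te_units], unit_base[te_units] + L$te[1L],
                unit_base[te_units] + L$te[2L],
                name = sprintf("te%04d", seq_along(te_units)),
                family = families[(seq_along(te_units) - 1L) %% length(families) + 1L])

    ## enhancers: class assignment over randomly chosen units
    class_vec <- rep(names(cfg$enhancers_per_class), cfg$enhancers_per_class)
    enh_units <- sample(n_units, n_enh)
    enh_len <- sample(cfg$enhancer_lengths, n_enh, replace = TRUE)
    enh_start <- unit_base[enh_units] + L$enh_start
    enhancers <- mkgr(unit_chrom[enh_units], enh_start, enh_start + enh_len - 1L,
                      name = sprintf("enh%04d", seq_len(n_enh)))
    collapsed <- sub("^K4me1[+-]_", "", class_vec)
    k4_flag <- startsWith(class_vec, "K4me1+")

    ## H3K4me1 peaks within 1 kb of K4me1+ enhancers
    k4_gap <- sample(100:800, n_enh, replace = TRUE)
    k4_start <- end(enhancers) + k4_gap + 1L
    k4me1 <- mkgr(unit_chrom[enh_units][k4_flag], k4_start[k4_flag],
                  k4_start[k4_flag] + 499L,
                  name = sprintf("k4me1_%04d", seq_len(sum(k4_flag))))

    ## stranded RNA coverage realizing planted per-strand read counts
    draw_reads <- function(n) {
      if (n == 0L) integer(0) else
        sample(cfg$expressed_read_range[1L]:cfg$expressed_read_range[2L], n,
               replace = TRUE)
    }
    plus_count <- integer(n_enh); minus_count <- integer(n_enh)
    bi <- collapsed == "bidirectional"
    uni <- collapsed == "unidirectional"
    plus_count[bi] <- draw_reads(sum(bi)); minus_count[bi] <- draw_reads(sum(bi))
    uni_plus <- uni & (stats::runif(n_enh) < 0.5)
    plus_count[uni & uni_plus] <- draw_reads(sum(uni & uni_plus))
    minus_count[uni & !uni_plus] <- draw_reads(sum(uni & !uni_plus))
    cov_tracks <- function(grs, values) {
      values <- as.numeric(values)
      keep <- values > 0
      coverage(grs[keep], weight = values[keep])
    }
    rna_plus_segs <- c(granges(enhancers), granges(genes))
    rna_plus_vals <- c(plus_count * cfg$read_length / width(enhancers),
                       rep(2, length(genes)))
    rna <- stranded_signal(
      cov_tracks(rna_plus_segs, rna_plus_vals),
      cov_tracks(granges(enhancers), minus_count * cfg$read_length / width(enhancers)),
      library_size = 1e6, read_length = cfg$read_length)

    ## RAMPAGE: capped enhancers get bidirectional 5' signal; genes get a TSS
    capped <- stats::runif(n_enh) < cfg$capped_fraction[collapsed]
    tss <- resize(granges(genes), 200L, fix = "start")
    ram_val <- 8 * cfg$read_length / width(enhancers)
    rampage <- stranded_signal(
      cov_tracks(c(granges(enhancers), tss), c(ifelse(capped, ram_val, 0), rep(4, length(tss)))),
      cov_tracks(granges(enhancers), ifelse(capped, ram_val, 0)),
      library_size = 2e5, read_length = cfg$read_length)

    ## 24nt siRNA: background 0.2, interior 1.0, 1 kb boundary zones at the
    ## class boundary factor (the RdDM-island pattern)
    edge <- 500L
    factor_vec <- cfg$boundary_factor[collapsed]
    seg_left <- mkgr(unit_chrom[enh_units], start(enhancers) - edge,
                     start(enhancers) + edge - 1L)
    seg_right <- mkgr(unit_chrom[enh_units], end(enhancers) - edge + 1L,
                      end(enhancers) + edge)
    seg_mid <- mkgr(unit_chrom[enh_units], start(enhancers) + edge,
                    end(enhancers) - edge)
    srna24 <- cov_tracks(c(seg_left, seg_right, seg_mid),
                         c(factor_vec - 0.2, factor_vec - 0.2,
                           rep(1 - 0.2, n_enh))) + 0.2

    ## activity track (reporter-assay-like): constant per enhancer
    act_val <- round(pmax(stats::rnorm(n_enh, cfg$activity_mean[class_vec], 1),
                          0.05), 3)
    activity <- cov_tracks(granges(enhancers), act_val)

    ## TFBS split across TF sets
    tf_hit <- stats::runif(n_enh) < cfg$tfbs_rate[class_vec]
    tf_of <- sample.int(cfg$n_tfs, n_enh, replace = TRUE)
    tfbs_sets <- lapply(seq_len(cfg$n_tfs), function(f) {
      idx <- which(tf_hit & tf_of == f)
      mkgr(unit_chrom[enh_units][idx], start(enhancers)[idx] + 100L,
           start(enhancers)[idx] + 109L,
           name = sprintf("TF%d_site%03d", f, seq_along(idx)))
    })

    ## conserved elements
    cons_hit <- stats::runif(n_enh) < cfg$conserved_rate[collapsed]
    cons_deep <- cons_hit & stats::runif(n_enh) < 0.3
    n_elem <- ifelse(cons_deep, 12L, ifelse(cons_hit, 2L, 0L))
    cons_list <- lapply(which(n_elem > 0L), function(i) {
      st <- start(enhancers)[i] + 200L + (seq_len(n_elem[i]) - 1L) * 60L
      mkgr(unit_chrom[enh_units][i], st, st + 19L)
    })
    conserved <- if (length(cons_list)) Reduce(c, cons_list) else mkgr(character(0), integer(0), integer(0))

    ## chromatin loops: enhancer anchor <-> same-unit gene anchor
    loop_idx <- sort(sample(n_enh, min(cfg$n_loops, n_enh)))
    loops <- loop_set(granges(genes)[enh_units[loop_idx]],
                      granges(enhancers)[loop_idx])
    linked_genes <- sprintf("gene%04d", enh_units[loop_idx])

    ## expression matrix with loop-linked shift
    gene_names <- mcols(genes)$name
    expression <- matrix(stats::rlnorm(n_units * length(cfg$tissues),
                                       meanlog = 1, sdlog = 0.8),
                         nrow = n_units,
                         dimnames = list(gene_names, cfg$tissues))
    expression[linked_genes, cfg$loop_tissue] <-
      expression[linked_genes, cfg$loop_tissue] * 2^cfg$loop_expression_shift

    ## pairwise DE tables with planted tissue-specific genes
    de_parts <- plant_de_tables(gene_names, cfg$tissues, cfg$specific_degs)

    ## conservation flow inputs
    cons_flow <- plant_conservation(cfg)

    ## small RNA reads and clusters
    srna <- plant_srna(cfg, n_units, unit_chrom, unit_base, L)

    ## pseudo-replicate reproducibility design
    repro <- plant_repro(cfg, n_units, unit_chrom, unit_base, L, si)

    truth <- list(
      enhancers = data.frame(
        name = mcols(enhancers)$name, chrom = unit_chrom[enh_units],
        start = start(enhancers), end = end(enhancers),
        class = class_vec, k4me1 = k4_flag,
        plus_count = plus_count, minus_count = minus_count,
        boundary_factor = unname(factor_vec), tfbs = tf_hit, capped = capped,
        activity = act_val, conserved_elements = n_elem,
        in_loop = seq_len(n_enh) %in% loop_idx,
        linked_gene = ifelse(seq_len(n_enh) %in% loop_idx,
                             sprintf("gene%04d", enh_units), NA_character_)),
      degs = de_parts$truth,
      conservation = cons_flow$truth,
      srna_clusters = srna$truth,
      srna_size_mix = cfg$srna_size_mix,
      reproducibility = repro$truth,
      telomere_copies = cfg$telomere_copies,
      linked_genes = linked_genes)

    bundle <- structure(list(
      config = cfg, genome = genome, seqlengths = seqlens,
      genes = genes, tes = tes,
      enhancers = enhancers, k4me1 = k4me1,
      merged_peaks = repro$merged, pseudo1 = repro$pseudo1,
      pseudo2 = repro$pseudo2,
      rna = rna, rampage = rampage, srna24 = srna24, activity = activity,
      tfbs = tfbs_sets, conserved = conserved, loops = loops,
      expression = expression, de = de_parts$de,
      ref_degs = cons_flow$ref_degs, orthology = cons_flow$orthology,
      target_degs = cons_flow$target_degs,
      srna_reads = srna$reads, srna_clusters = srna$clusters,
      srna_library_size = srna$library_size,
      truth = truth), class = "synthetic_bundle")
    if (!is.null(dir)) write_bundle(bundle, dir)
    bundle
  })
}

#' @export
print.synthetic_bundle <- function(x, ...) {
  cat("synthetic_bundle:", length(x$genome), "chromosomes,",
      length(x$genes), "genes,", length(x$enhancers), "enhancers,",
      length(x$loops), "loops\n")
  invisible(x)
}

# Pairwise DE labels: planted sets are exactly tissue-specific; noise genes
# get at most 3 non-ns pairings so they can never be specific by chance.
plant_de_tables <- function(gene_names, tissues, specific_degs) {
  pairs <- utils::combn(sort(tissues), 2L)
  pair_key <- paste(pairs[1L, ], pairs[2L, ], sep = "|")
  lab <- matrix("ns", nrow = length(gene_names), ncol = ncol(pairs),
                dimnames = list(gene_names, pair_key))
  pool <- sample(gene_names)
  truth <- NULL
  for (tis in names(specific_degs)) {
    for (dirn in c("up", "down")) {
      sd <- specific_degs[[tis]]
      n <- if (dirn %in% names(sd)) sd[[dirn]] else 0L
      if (n == 0L) next
      take <- pool[seq_len(n)]; pool <- pool[-seq_len(n)]
      for (j in seq_len(ncol(pairs))) {
        if (pairs[1L, j] == tis) lab[take, j] <- dirn
        if (pairs[2L, j] == tis) lab[take, j] <- c(up = "down", down = "up")[dirn]
      }
      truth <- rbind(truth, data.frame(gene = take, tissue = tis,
                                       direction = dirn))
    }
  }
  for (g in pool) {
    k <- sample(0:3, 1L)
    if (k > 0L) {
      lab[g, sample(ncol(pairs), k)] <- sample(c("up", "down"), k, replace = TRUE)
    }
  }
  de <- data.frame(gene = rep(gene_names, ncol(pairs)),
                   tissue_a = rep(pairs[1L, ], each = length(gene_names)),
                   tissue_b = rep(pairs[2L, ], each = length(gene_names)),
                   label = as.vector(lab))
  list(de = de, truth = truth)
}

# Conservation flow: per reference DEG and inbred, a 3-way multinomial
# status realized through the orthology map and target DEG sets.
plant_conservation <- function(cfg) {
  ref_degs <- sprintf("ref_gene%05d", seq_len(cfg$n_ref_degs))
  statuses <- names(cfg$conservation_probs)
  orth <- NULL; tdeg <- list(); truth <- NULL
  for (inb in cfg$target_inbreds) {
    st <- sample(statuses, cfg$n_ref_degs, replace = TRUE,
                 prob = cfg$conservation_probs)
    hom1 <- sprintf("%s_hom%05d", inb, seq_len(cfg$n_ref_degs))
    hom2 <- sprintf("%s_par%05d", inb, seq_len(cfg$n_ref_degs))
    has_hom <- st != "no_homolog"
    two <- has_hom & stats::runif(cfg$n_ref_degs) < 0.4
    orth <- rbind(orth,
                  data.frame(ref_gene = ref_degs[has_hom],
                             inbred = rep(inb, sum(has_hom)),
                             homolog = hom1[has_hom]),
                  data.frame(ref_gene = ref_degs[two],
                             inbred = rep(inb, sum(two)),
                             homolog = hom2[two]))
    decoys <- sprintf("%s_dec%03d", inb, 1:200)
    tdeg[[inb]] <- c(hom1[st == "conserved_DEG"], decoys)
    truth <- rbind(truth, data.frame(ref_gene = ref_degs,
                                     inbred = rep(inb, length(ref_degs)),
                                     status = st))
  }
  list(ref_degs = ref_degs, orthology = orth, target_degs = tdeg,
       truth = truth)
}

# Small RNA clusters (hairpin-like and not) plus background reads topping up
# the global 21/22/24 mixture to the exact configured ratio.
plant_srna <- function(cfg, n_units, unit_chrom, unit_base, L) {
  n_cl <- cfg$n_srna_clusters
  if (n_cl == 0L) {
    return(list(clusters = GRanges(), reads = data.frame(),
                truth = NULL, library_size = 0))
  }
  cl_units <- sample(n_units, n_cl)
  hairpin <- seq_len(n_cl) <= cfg$n_hairpin
  long_bias <- !hairpin & seq_len(n_cl) <= cfg$n_hairpin + 20L
  span <- ifelse(hairpin, 3000L, ifelse(long_bias, 1500L, 600L))
  cl_start <- unit_base[cl_units] + L$cluster_start
  clusters <- GRanges(unit_chrom[cl_units], IRanges(cl_start, cl_start + span - 1L),
                      name = sprintf("cluster%03d", seq_len(n_cl)))
  reads <- NULL
  for (i in seq_len(n_cl)) {
    n_rec <- 80L
    if (hairpin[i]) {
      len <- sample(c(22L, 21L, 24L), n_rec, replace = TRUE,
                    prob = c(0.7, 0.15, 0.15))
      strand <- sample(c("+", "-"), n_rec, replace = TRUE, prob = c(0.95, 0.05))
    } else {
      len <- sample(c(24L, 21L, 22L), n_rec, replace = TRUE,
                    prob = c(0.8, 0.1, 0.1))
      strand <- sample(c("+", "-"), n_rec, replace = TRUE)
    }
    pos0 <- cl_start[i] - 1L + sample.int(span[i] - 24L, n_rec, replace = TRUE)
    reads <- rbind(reads, data.frame(
      chrom = unit_chrom[cl_units[i]], start = pos0, end = pos0 + len,
      strand = strand, length = len,
      count = sample(1:10, n_rec, replace = TRUE)))
  }
  ## background reads in a zone guaranteed outside every cluster
  mix <- cfg$srna_size_mix / sum(cfg$srna_size_mix)
  have <- vapply(names(mix), function(l) {
    sum(reads$count[reads$length == as.integer(l)])
  }, numeric(1))
  total <- max(ceiling(have / mix / 10)) * 10
  bg_counts <- round(mix * total) - have
  bg <- NULL
  for (l in names(bg_counts)) {
    n_bg <- as.integer(bg_counts[[l]])
    if (n_bg <= 0L) next
    n_rec <- min(500L, n_bg)
    counts <- rep(n_bg %/% n_rec, n_rec)
    counts[seq_len(n_bg %% n_rec)] <- counts[seq_len(n_bg %% n_rec)] + 1L
    u <- sample(n_units, n_rec, replace = TRUE)
    pos0 <- unit_base[u] + L$srna_bg[1L] - 1L +
      sample.int(diff(L$srna_bg) - 30L, n_rec, replace = TRUE)
    bg <- rbind(bg, data.frame(chrom = unit_chrom[u], start = pos0,
                               end = pos0 + as.integer(l), strand = sample(c("+", "-"), n_rec, replace = TRUE),
                               length = as.integer(l), count = counts))
  }
  reads <- rbind(reads, bg)
  list(clusters = clusters, reads = reads,
       truth = data.frame(name = mcols(clusters)$name, hairpin = hairpin,
                          span = span),
       library_size = sum(reads$count))
}

# Merged peaks and two pseudo-replicates with exact both/one/neither counts.
plant_repro <- function(cfg, n_units, unit_chrom, unit_base, L, si) {
  n <- cfg$n_repro_peaks
  if (n == 0L) {
    empty <- GRanges(seqinfo = si)
    return(list(merged = empty, pseudo1 = empty, pseudo2 = empty, truth = NULL))
  }
  n_both <- round(n * cfg$repro_fractions[["both"]])
  n_one <- round(n * cfg$repro_fractions[["one"]])
  n_neither <- n - n_both - n_one
  units <- sample(n_units, n + 40L)
  mu <- units[seq_len(n)]
  merged <- GRanges(unit_chrom[mu],
                    IRanges(unit_base[mu] + L$repro[1L], unit_base[mu] + L$repro[2L]),
                    seqinfo = si, name = sprintf("peak%04d", seq_len(n)),
                    score = round(stats::runif(n, 5, 100), 1))
  cat_vec <- rep(c("both", "one_p1", "one_p2", "neither"),
                 c(n_both, ceiling(n_one / 2), floor(n_one / 2), n_neither))
  cat_vec <- sample(cat_vec)
  jitter <- function(gr) shift(granges(gr), 50L)
  noise1 <- units[n + 1:20]; noise2 <- units[n + 21:40]
  mk_noise <- function(u) {
    GRanges(unit_chrom[u], IRanges(unit_base[u] + L$repro[1L],
                                   unit_base[u] + L$repro[2L]), seqinfo = si)
  }
  pseudo1 <- c(jitter(merged[cat_vec %in% c("both", "one_p1")]), mk_noise(noise1))
  pseudo2 <- c(jitter(merged[cat_vec %in% c("both", "one_p2")]), mk_noise(noise2))
  list(merged = merged, pseudo1 = pseudo1, pseudo2 = pseudo2,
       truth = data.frame(name = mcols(merged)$name, category = cat_vec))
}
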