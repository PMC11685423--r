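test_that("config validation rejects bad probabilities, counts and class names", {
  expect_error(synthetic_config(conservation_probs = c(conserved_DEG = 0.9,
                                                       homolog_not_DEG = 0.3,
                                                       no_homolog = 0.1)),
               "sum to 1")
  expect_error(synthetic_config(tfbs_rate = c("K4me1+_bidirectional" = 1.4,
                                              "K4me1+_unidirectional" = 0.2,
                                              "K4me1+_none" = 0.2,
                                              "K4me1-_bidirectional" = 0.6,
                                              "K4me1-_unidirectional" = 0.4,
                                              "K4me1-_none" = 0.2)),
               "\\[0,1\\]")
  expect_error(synthetic_config(enhancers_per_class = c(foo = 5L)),
               "six classes")
  expect_error(generate_dataset(synthetic_config(n_chroms = 1L,
                                                 units_per_chrom = 5L)),
               "too small")
})

test_that("generation is deterministic in the seed", {
  cfg <- synthetic_config(seed = 99, n_chroms = 2L, units_per_chrom = 30L,
                          enhancers_per_class = c(
                            "K4me1+_bidirectional" = 8L,
                            "K4me1+_unidirectional" = 8L, "K4me1+_none" = 8L,
                            "K4me1-_bidirectional" = 8L,
                            "K4me1-_unidirectional" = 8L, "K4me1-_none" = 8L),
                          n_loops = 20L, n_ref_degs = 100L,
                          n_srna_clusters = 12L, n_hairpin = 3L,
                          n_repro_peaks = 15L,
                          specific_degs = list(pollen = c(up = 5L, down = 5L)))
  b1 <- generate_dataset(cfg)
  b2 <- generate_dataset(cfg)
  expect_equal(as.character(b1$genome), as.character(b2$genome))
  expect_identical(granges(b1$enhancers), granges(b2$enhancers))
  expect_identical(b1$truth, b2$truth)
  expect_identical(b1$de, b2$de)
  expect_identical(as.numeric(b1$srna24[[1]]), as.numeric(b2$srna24[[1]]))
  b3 <- generate_dataset(synthetic_config(seed = 100, n_chroms = 2L,
                                          units_per_chrom = 30L,
                                          enhancers_per_class = cfg$enhancers_per_class,
                                          n_loops = 20L, n_ref_degs = 100L,
                                          n_srna_clusters = 12L, n_hairpin = 3L,
                                          n_repro_peaks = 15L,
                                          specific_degs = cfg$specific_degs))
  expect_false(identical(as.character(b3$genome[[1]]),
                         as.character(b1$genome[[1]])))
  expect_identical(names(b3$truth), names(b1$truth))
})

test_that("an all-zero configuration still yields a valid genome bundle", {
  cfg <- synthetic_config(seed = 3, n_chroms = 1L, units_per_chrom = 10L,
                          enhancers_per_class = c(
                            "K4me1+_bidirectional" = 0L,
                            "K4me1+_unidirectional" = 0L, "K4me1+_none" = 0L,
                            "K4me1-_bidirectional" = 0L,
                            "K4me1-_unidirectional" = 0L, "K4me1-_none" = 0L),
                          n_loops = 0L, n_ref_degs = 0L,
                          n_srna_clusters = 0L, n_hairpin = 0L,
                          n_repro_peaks = 0L, specific_degs = list())
  b <- generate_dataset(cfg)
  expect_length(b$enhancers, 0L)
  expect_length(b$loops, 0L)
  expect_equal(nrow(b$truth$enhancers), 0L)
  expect_equal(sum(Biostrings::width(b$genome)),
               10L * cfg$unit_bp + 2L * 10000L)
})

test_that("planted structure is internally consistent", {
  b <- default_bundle()
  truth <- b$truth$enhancers
  # enhancers are distal by construction
  expect_true(all(nearest_distance(b$enhancers, b$genes) >= 2000))
  # every K4me1+ enhancer has a K4me1 peak within 1 kb, no K4me1- one does
  d <- nearest_distance(b$enhancers, b$k4me1)
  expect_true(all(d[truth$k4me1] <= 1000))
  expect_true(all(d[!truth$k4me1] > 1000))
  # coverage realizes the planted per-strand read counts
  sums <- strand_region_sums(b$rna, b$enhancers) / b$rna$read_length
  expect_equal(unname(sums[, "plus"]), truth$plus_count, tolerance = 1e-6)
  expect_equal(unname(sums[, "minus"]), truth$minus_count, tolerance = 1e-6)
  # class counts are exact
  expect_equal(as.integer(table(truth$class)[names(b$config$enhancers_per_class)]),
               as.integer(b$config$enhancers_per_class))
})

test_that("a written bundle round-trips through the standard-format parsers", {
  cfg <- synthetic_config(seed = 7, n_chroms = 2L, units_per_chrom = 30L,
                          enhancers_per_class = c(
                            "K4me1+_bidirectional" = 5L,
                            "K4me1+_unidirectional" = 5L, "K4me1+_none" = 5L,
                            "K4me1-_bidirectional" = 5L,
                            "K4me1-_unidirectional" = 5L, "K4me1-_none" = 5L),
                          n_loops = 10L, n_ref_degs = 50L,
                          n_srna_clusters = 8L, n_hairpin = 2L,
                          n_repro_peaks = 10L,
                          specific_degs = list(pollen = c(up = 4L)))
  dir <- withr::local_tempdir()
  b <- generate_dataset(cfg, dir = dir)
  # BED round trip
  enh <- parse_intervals(file.path(dir, "h3k27ac_distal.bed"), "bed")
  expect_equal(start(enh), start(b$enhancers))
  expect_equal(end(enh), end(b$enhancers))
  expect_equal(mcols(enh)$name, mcols(b$enhancers)$name)
  # GFF3 keeps 1-based coordinates
  ann <- parse_intervals(file.path(dir, "annotation.gff3"), "gff3")
  genes <- ann[mcols(ann)$type == "gene"]
  expect_equal(start(genes), start(b$genes))
  expect_equal(end(genes), end(b$genes))
  # BEDPE round trip
  loops <- parse_loops(file.path(dir, "loops.bedpe"))
  expect_equal(ranges(loops$anchor1), ranges(b$loops$anchor1),
               ignore_attr = TRUE)
  # bedGraph coverage round trip
  sig <- read_stranded_bedgraph(file.path(dir, "rna_plus.bedgraph"),
                                file.path(dir, "rna_minus.bedgraph"),
                                b$seqlengths, read_length = cfg$read_length)
  expect_equal(as.numeric(sig$plus[[1]]), as.numeric(b$rna$plus[[1]]),
               tolerance = 1e-9)
  # FASTA round trip
  g <- Biostrings::readDNAStringSet(file.path(dir, "genome.fa"))
  expect_equal(as.character(g[[1]]), as.character(b$genome[[1]]))
  # truth tables serialized
  expect_true(file.exists(file.path(dir, "truth", "enhancers.tsv")))
})
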