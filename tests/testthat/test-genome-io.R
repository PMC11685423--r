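test_that("BED lines parse with 0-based to 1-based conversion", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t100\t200\tp1\t5\t+", f)
  gr <- parse_intervals(f, "bed")
  expect_equal(start(gr), 101L)
  expect_equal(end(gr), 200L)
  expect_equal(width(gr), 100L)
  expect_equal(as.character(strand(gr)), "+")
  expect_equal(mcols(gr)$name, "p1")
  expect_equal(mcols(gr)$score, 5)
})

test_that("GFF3 1-based closed coordinates describe the same interval as BED", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tgene\t101\t200\t.\t+\t.\tID=g1"), f)
  gff <- parse_intervals(f, "gff3")
  b <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t100\t200", b)
  bed <- parse_intervals(b, "bed")
  expect_equal(ranges(gff), ranges(bed), ignore_attr = TRUE)
  expect_equal(width(gff), 100L)
})

test_that("malformed lines are reported with their line number", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t10\t20", "chr1\t50\t40", "chr1\t5\t9"), f)
  expect_error(parse_intervals(f, "bed"), "line 2")
  writeLines(c("chr1\t10\t20\tx\tNaNish\t+"), f)
  expect_error(parse_intervals(f, "bed"), "line 1")
})

test_that("a large random BED round-trips bit-exactly", {
  set.seed(42)
  gr <- random_granges(1000)
  mcols(gr)$name <- sprintf("p%04d", seq_along(gr))
  mcols(gr)$score <- round(runif(1000, 0, 1000), 2)
  strand(gr) <- sample(c("+", "-", "*"), 1000, replace = TRUE)
  f <- withr::local_tempfile(fileext = ".bed")
  write_bed(gr, f)
  back <- parse_intervals(f, "bed")
  expect_equal(as.character(seqnames(back)), as.character(seqnames(gr)))
  expect_equal(start(back), start(gr))
  expect_equal(end(back), end(gr))
  expect_equal(mcols(back)$name, mcols(gr)$name)
  expect_equal(mcols(back)$score, mcols(gr)$score)
  expect_equal(as.character(strand(back)), as.character(strand(gr)))
})

test_that("bedGraph coverage round-trips through write and parse", {
  cov <- RleList(cA = Rle(c(0, 1.5, 0, 2, 0), c(100, 50, 30, 20, 300)))
  f <- withr::local_tempfile(fileext = ".bedgraph")
  write_bedgraph(cov, f)
  gr <- parse_intervals(f, "bedgraph")
  lens <- c(cA = 500L)
  seqlevels(gr) <- names(lens); seqlengths(gr) <- lens
  back <- coverage(gr, weight = "score")
  expect_identical(as.numeric(back$cA), as.numeric(cov$cA))
})

test_that("BEDPE parses to a loop set with normalized anchor order", {
  f <- withr::local_tempfile(fileext = ".bedpe")
  writeLines(c("chr1\t5000\t6000\tchr1\t100\t200",
               "chr2\t10\t20\tchr2\t500\t600"), f)
  ls <- parse_loops(f)
  expect_s3_class(ls, "loop_set")
  expect_length(ls, 2L)
  expect_true(all(start(ls$anchor1) <= start(ls$anchor2)))
  f2 <- withr::local_tempfile(fileext = ".bedpe")
  write_bedpe(ls, f2)
  ls2 <- parse_loops(f2)
  expect_equal(ranges(ls2$anchor1), ranges(ls$anchor1), ignore_attr = TRUE)
  expect_equal(ranges(ls2$anchor2), ranges(ls$anchor2), ignore_attr = TRUE)
})

test_that("nearest_distance matches edge-gap semantics and the brute-force oracle", {
  q <- GRanges("chr1", IRanges(101, 200))
  expect_equal(nearest_distance(q, GRanges("chr1", IRanges(151, 300))), 0)
  expect_equal(nearest_distance(q, GRanges("chr1", IRanges(2201, 2400))), 2000)
  expect_equal(nearest_distance(q, GRanges("chr9", IRanges(1, 10))), Inf)
  expect_error(nearest_distance(q, GRanges()), "empty")
  set.seed(7)
  qq <- random_granges(500)
  rr <- random_granges(50)
  expect_equal(nearest_distance(qq, rr), brute_nearest(qq, rr))
})

test_that("interval overlap is half-open-consistent and matches brute force", {
  a <- GRanges("c", IRanges(1, 10))      # BED (0,10)
  expect_true(interval_overlaps(a, GRanges("c", IRanges(10, 20)))$flag)
  expect_false(interval_overlaps(a, GRanges("c", IRanges(11, 20)))$flag)
  expect_error(interval_overlaps(a, a, min_bp = 0), "min_bp")
  set.seed(8)
  x <- random_granges(300); y <- random_granges(120)
  for (mb in c(1L, 5L, 50L)) {
    expect_equal(interval_overlaps(x, y, mb)$flag, brute_overlap_flag(x, y, mb))
  }
  # invariance under shuffling and consistent chromosome renaming
  perm <- sample(length(x))
  expect_equal(sum(interval_overlaps(x[perm], y, 1L)$flag),
               sum(interval_overlaps(x, y, 1L)$flag))
  ren <- function(g) renameSeqlevels(g, c(c1 = "K9", c2 = "K2"))
  expect_equal(sum(interval_overlaps(ren(x), ren(y), 1L)$flag),
               sum(interval_overlaps(x, y, 1L)$flag))
})

test_that("zero distance coincides with 1-bp overlap away from book-ended pairs", {
  set.seed(9)
  x <- random_granges(200); y <- random_granges(80)
  d <- nearest_distance(x, y)
  ov <- interval_overlaps(x, y, 1L)$flag
  booked <- vapply(seq_along(x), function(i) {
    any(as.character(seqnames(y)) == as.character(seqnames(x))[i] &
          (end(y) + 1L == start(x)[i] | end(x)[i] + 1L == start(y)))
  }, logical(1))
  expect_equal((d == 0)[!booked], ov[!booked])
})

test_that("genome mismatch between interval sets is an error", {
  a <- GRanges("c1", IRanges(1, 10)); genome(a) <- "g1"
  b <- GRanges("c1", IRanges(5, 20)); genome(b) <- "g2"
  expect_error(nearest_distance(a, b), "genome mismatch")
  expect_error(interval_overlaps(a, b), "genome mismatch")
})

test_that("stranded signals reject negative values and bad read lengths", {
  good <- RleList(c1 = Rle(1, 100))
  bad <- RleList(c1 = Rle(-1, 100))
  expect_error(stranded_signal(good, bad), ">= 0")
  expect_error(stranded_signal(good, good, read_length = 0), "read_length")
})
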