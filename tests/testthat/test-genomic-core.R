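gm <- genome_model(c("chr1", "chr2"), c(10000L, 10000L))

test_that("genome model enforces its invariants", {
  expect_error(genome_model(c("chr1", "chr1"), c(10, 10)), "unique")
  expect_error(genome_model("chr1", 0), "> 0")
  expect_error(peak_set("chr9", 0, 10, genome = gm), "unknown chromosome")
  expect_error(peak_set("chr1", 9999, 10005, genome = gm), "bounds")
  expect_error(peak_set("chr1", 100, 100), "end must be > start")
})

test_that("read_bed parses BED3-BED6, skips comments, reports bad lines", {
  p <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("# a comment", "track name=x", "chr1\t100\t200"), p)
  ps <- read_bed(p, genome = gm)
  expect_length(ps, 1L)
  expect_identical(GenomicRanges::start(ps), 101L) # internal 1-based
  expect_identical(GenomicRanges::end(ps), 200L)
  expect_equal(as.character(GenomicRanges::strand(ps)), "*")

  writeLines(character(0), p)
  expect_length(read_bed(p), 0L)

  writeLines("chr1\t300\t200", p)
  expect_error(read_bed(p), "start >= end")
  writeLines(c("chr1\t1\t2", "chr1\tx"), p)
  expect_error(read_bed(p), "line 2")
})

test_that("BED6 write/read round-trips and output is sorted and deterministic", {
  set.seed(7)
  ps <- random_peaks(1000, chrom_len = 10000, chroms = c("chr1", "chr2"))
  ps$name <- sprintf("pk%04d", seq_along(ps))
  ps$score <- round(runif(1000, 0, 100), 3)
  GenomicRanges::strand(ps) <- sample(c("+", "-", "*"), 1000, replace = TRUE)
  p1 <- withr::local_tempfile(fileext = ".bed")
  p2 <- withr::local_tempfile(fileext = ".bed")
  write_bed(ps, p1)
  back <- read_bed(p1, genome = gm)
  # sorted by (chrom, start)
  expect_false(is.unsorted(order(as.character(GenomicRanges::seqnames(back)),
                                 GenomicRanges::start(back))))
  # lossless up to sorting
  key <- function(x) {
    o <- order(as.character(GenomicRanges::seqnames(x)),
               GenomicRanges::start(x), GenomicRanges::end(x), x$name)
    paste(as.character(GenomicRanges::seqnames(x))[o],
          GenomicRanges::start(x)[o], GenomicRanges::end(x)[o], x$name[o],
          x$score[o], as.character(GenomicRanges::strand(x))[o])
  }
  expect_identical(key(back), key(ps))
  write_bed(back, p2)
  write_bed(back, p1)
  expect_identical(readLines(p1), readLines(p2)) # byte-identical reruns
})

test_that("read_bedgraph fills per-base values, sums overlaps, validates", {
  p <- withr::local_tempfile(fileext = ".bg")
  gm1 <- genome_model("chr1", 100L)
  writeLines("chr1\t0\t10\t2.0", p)
  tr <- read_bedgraph(p, gm1)
  expect_equal(mean(as.numeric(tr$cov$chr1)), 0.2) # hand sum: 10*2/100
  expect_equal(tr$library_scale, 20)

  writeLines(character(0), p)
  tr0 <- read_bedgraph(p, gm1)
  expect_true(all(as.numeric(tr0$cov$chr1) == 0))

  writeLines(c("chr1\t0\t20\t1", "chr1\t10\t30\t2"), p)
  tr2 <- read_bedgraph(p, gm1)
  v <- as.numeric(tr2$cov$chr1)
  expect_equal(v[11:20], rep(3, 10)) # additive on the overlap
  expect_equal(v[1:10], rep(1, 10))
  expect_equal(v[21:30], rep(2, 10))

  writeLines("chr1\t0\t10\t-1", p)
  expect_error(read_bedgraph(p, gm1), "negative")
  writeLines("chrX\t0\t10\t1", p)
  expect_error(read_bedgraph(p, gm1), "unknown chromosome")
})

test_that("merge_intervals matches the per-base oracle and is idempotent", {
  a <- peak_set(c("chr1", "chr1"), c(100, 150), c(200, 250))
  m <- merge_intervals(a)
  expect_equal(GenomicRanges::start(m) - 1L, 100L)
  expect_equal(GenomicRanges::end(m), 250L)
  b <- peak_set(c("chr1", "chr1"), c(100, 300), c(200, 400))
  expect_length(merge_intervals(b), 2L)

  set.seed(42)
  ps <- random_peaks(500, chrom_len = 10000, chroms = c("chr1", "chr2"))
  m <- merge_intervals(ps)
  oracle <- brute_merge(ps, 10000L)
  expect_equal(GenomicRanges::start(m) - 1L, oracle$start)
  expect_equal(GenomicRanges::end(m), oracle$end)
  expect_identical(merge_intervals(m), m) # idempotent

  # min_gap: no two output regions within min_gap of each other
  g <- merge_intervals(ps, min_gap = 50)
  for (chr in c("chr1", "chr2")) {
    gc <- g[GenomicRanges::seqnames(g) == chr]
    if (length(gc) > 1) {
      gaps <- GenomicRanges::start(gc)[-1] - GenomicRanges::end(gc)[-length(gc)] - 1L
      expect_true(all(gaps > 50))
    }
  }
})

test_that("intersect_peaks is half-open, honors min_overlap, matches O(n^2) oracle", {
  a <- peak_set("chr1", 0, 100)
  b <- peak_set("chr1", 99, 200)
  expect_equal(nrow(intersect_peaks(a, b)), 1L) # 1-bp overlap
  b2 <- peak_set("chr1", 100, 200)
  expect_equal(nrow(intersect_peaks(a, b2)), 0L) # adjacency, half-open

  set.seed(5)
  x <- random_peaks(120, chrom_len = 5000, chroms = c("chr1", "chr2"))
  y <- random_peaks(150, chrom_len = 5000, chroms = c("chr1", "chr2"))
  for (mo in c(1L, 25L, 80L)) {
    expect_equal(nrow(intersect_peaks(x, y, mo)), brute_intersect(x, y, mo))
  }
  expect_equal(nrow(intersect_peaks(x, y)), nrow(intersect_peaks(y, x)))
})

test_that("nearest_tss signs distances, breaks ties lexicographically, flags gene-free chroms", {
  genes <- read_gene_table(local({
    p <- tempfile(fileext = ".bed")
    writeLines(c("chr1\t1000\t2000\tgA\t0\t+",
                 "chr1\t3000\t4000\tgC\t0\t+",
                 "chr1\t5000\t6000\tgB\t0\t-"), p)
    p
  }))
  # site centered at gA's TSS
  s <- peak_set("chr1", 950, 1050)
  nt <- nearest_tss(s, genes)
  expect_equal(nt$distance, 0L)
  expect_equal(nt$gene_id, "gA")
  # 5 kb right of gB's TSS (minus strand: TSS = end-1 = 5999)
  s2 <- peak_set("chr1", 10949, 11049)
  nt2 <- nearest_tss(s2, genes)
  expect_equal(nt2$distance, 5000L)
  expect_equal(nt2$gene_id, "gB")
  # equidistant between gA (TSS 1000) and gC (TSS 3000) -> smaller gene_id
  s3 <- peak_set("chr1", 1950, 2050) # center 2000
  nt3 <- nearest_tss(s3, genes)
  expect_equal(abs(nt3$distance), 1000L)
  expect_equal(nt3$gene_id, "gA")
  # gene-free chromosome is unassigned
  s4 <- peak_set("chr2", 0, 100)
  nt4 <- nearest_tss(s4, genes)
  expect_true(is.na(nt4$gene_id) && is.na(nt4$distance))

  # 200 random sites vs 50 genes: exhaustive oracle
  set.seed(9)
  sites <- random_peaks(200, chrom_len = 50000, chroms = c("chr1", "chr2"))
  gdt <- data.frame(chrom = sample(c("chr1", "chr2"), 50, replace = TRUE),
                    start = sample.int(49000, 50) - 1L)
  gp <- tempfile(fileext = ".bed")
  writeLines(sprintf("%s\t%d\t%d\tg%02d\t0\t%s", gdt$chrom, gdt$start,
                     gdt$start + 500L, seq_len(50),
                     sample(c("+", "-"), 50, replace = TRUE)), gp)
  genes2 <- read_gene_table(gp)
  expect_equal(nearest_tss(sites, genes2), brute_nearest(sites, genes2))
})
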