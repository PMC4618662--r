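gm <- genome_model("chr1", 200000L)

flat_track <- function(value, genome = gm) {
  lens <- GenomeInfoDb::seqlengths(genome)
  cov <- IRanges::RleList(lapply(lens, function(l) S4Vectors::Rle(value, l)),
                          compress = FALSE)
  coverage_track(cov, genome)
}

test_that("estimate_background recovers flat and Poisson backgrounds", {
  expect_equal(estimate_background(flat_track(0.5)), 0.5)
  expect_equal(estimate_background(flat_track(0)), 1e-6) # epsilon floor
  # Poisson(0.02/bp) background, 1-kb run-length bins
  set.seed(2)
  big <- genome_model("chr1", 2e6)
  v <- rep(rpois(2000, 20) / 1000, each = 1000)
  cov <- IRanges::RleList(chr1 = S4Vectors::Rle(v), compress = FALSE)
  tr <- coverage_track(cov, big)
  bg <- estimate_background(tr, n_windows = 5000)
  expect_lt(abs(bg - 0.02) / 0.02, 0.20)
})

test_that("call_mark_state computes fold enrichment against background", {
  st <- call_mark_state(100000L, "chr1", flat_track(0.1), background = 0.1)
  expect_equal(st$fold, 1.0)
  expect_false(st$marked)
  st0 <- call_mark_state(100000L, "chr1", flat_track(0), background = 0.1)
  expect_equal(st0$fold, 0)
  expect_false(st0$marked)

  # planted Gaussian peak (height 1, sd 100) over background 0.02:
  # window mean ~ height * sd * sqrt(2*pi) / (2 * half_window) + bg
  center <- 100000L
  x <- seq_len(200000L) - 1L
  v <- 0.02 + exp(-(x - center)^2 / (2 * 100^2))
  cov <- IRanges::RleList(chr1 = S4Vectors::Rle(v), compress = FALSE)
  tr <- coverage_track(cov, gm)
  st2 <- call_mark_state(center, "chr1", tr, half_window = 1000L,
                         background = 0.02)
  expected_fold <- (100 * sqrt(2 * pi) / 2000 + 0.02) / 0.02
  expect_lt(abs(st2$fold - expected_fold) / expected_fold, 0.05)
  expect_true(st2$marked)
})

test_that("mark-class rule partitions all 16 mark combinations", {
  combos <- expand.grid(k4me1 = c(FALSE, TRUE), k27ac = c(FALSE, TRUE),
                        p300 = c(FALSE, TRUE), k27me3 = c(FALSE, TRUE))
  got <- classify_by_marks(combos$k4me1, combos$k27ac, combos$p300,
                           combos$k27me3)
  oracle <- with(combos, ifelse(k4me1 & k27ac & !k27me3, "pre_existing",
                         ifelse(!k4me1 & !k27ac & !p300, "de_novo",
                                "ambiguous")))
  expect_equal(as.character(got), oracle)
  expect_false(anyNA(got)) # total function, exhaustive partition
  # headline patterns
  expect_equal(as.character(classify_by_marks(TRUE, TRUE, TRUE, FALSE)),
               "pre_existing")
  expect_equal(as.character(classify_by_marks(FALSE, FALSE, FALSE, TRUE)),
               "de_novo")
  expect_equal(as.character(classify_by_marks(FALSE, TRUE, FALSE, FALSE)),
               "ambiguous")
  # optional P300 requirement tightens the pre-existing call
  expect_equal(as.character(classify_by_marks(TRUE, TRUE, FALSE, FALSE,
                                              require_p300 = TRUE)),
               "ambiguous")
})

test_that("promoter state follows the K4me3/K27me3 rule", {
  hi <- flat_track(0.5); lo <- flat_track(0.01)
  bg <- 0.05
  args <- function(k4, k27) {
    classify_promoter(100000L, "chr1", k4, k27, background_k4me3 = bg,
                      background_k27me3 = bg)
  }
  expect_equal(as.character(args(hi, lo)), "active")
  expect_equal(as.character(args(hi, hi)), "bivalent")
  expect_equal(as.character(args(lo, lo)), "inactive")
  expect_equal(as.character(args(lo, hi)), "inactive")
})

test_that("select_distal removes TSS-proximal sites", {
  gp <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t50000\t52000\tgA\t0\t+"), gp)
  genes <- read_gene_table(gp, genome = gm)
  sites <- peak_set("chr1", c(49950, 100000, 53000), c(50050, 100200, 53200),
                    genome = gm)
  kept <- select_distal(sites, genes)
  expect_equal(GenomicRanges::start(kept) - 1L, c(100000L, 53000L))
  expect_equal(kept$nearest_gene, c("gA", "gA"))
  # brute-force filter equivalence on a random mix
  set.seed(10)
  mix <- random_peaks(100, chrom_len = 190000)
  nt <- brute_nearest(mix, genes)
  expect_equal(length(select_distal(mix, genes)),
               sum(abs(nt$distance) > 2000))
})

test_that("final-class refinement enumerates all 9 combinations", {
  grid <- expand.grid(mark_class = c("pre_existing", "de_novo", "ambiguous"),
                      promoter_state = c("active", "bivalent", "inactive"),
                      stringsAsFactors = FALSE)
  out <- finalize_classes(grid)
  oracle <- with(grid, ifelse(mark_class == "pre_existing" &
                                promoter_state == "active", "pre_existing",
                       ifelse(mark_class == "de_novo" &
                                promoter_state == "inactive", "de_novo",
                              "excluded")))
  expect_equal(as.character(out$final_class), oracle)
})

test_that("overlap_with_factor reports per-class bound fractions", {
  rec <- data.frame(chrom = "chr1", start = c(0, 1000, 2000, 3000),
                    end = c(200, 1200, 2200, 3200),
                    final_class = factor(c("pre_existing", "pre_existing",
                                           "de_novo", "de_novo"),
                                         levels = c("pre_existing", "de_novo",
                                                    "excluded")))
  all_peaks <- peak_set("chr1", 0, 4000, genome = gm)
  expect_equal(unname(overlap_with_factor(rec, all_peaks)), c(1, 1))
  none <- peak_set("chr1", 100000, 100100, genome = gm)
  expect_equal(unname(overlap_with_factor(rec, none)), c(0, 0))
  one_pre <- peak_set("chr1", 1100, 1150, genome = gm)
  expect_equal(unname(overlap_with_factor(rec, one_pre)), c(0.5, 0))
})

test_that("Ebf1-like factor planted at pre-existing sites stays off de novo enhancers", {
  sc <- demo_scenario()
  rep <- demo_report()
  rec <- attr(rep, "records")
  ebf1 <- read_bed(sc$files$ebf1_preB, genome = sc$genome)
  fr <- overlap_with_factor(rec, ebf1)
  expect_gt(fr["pre_existing"], 0.2)
  expect_lt(fr["de_novo"], 0.01)
})

test_that("raising the mark threshold shrinks pre-existing and grows de novo", {
  sc <- demo_scenario()
  rep <- demo_report()
  rec <- attr(rep, "records")
  # the rising threshold governs decoration (active-mark) calls; the
  # H3K27Me3 depletion call keeps its own default cutoff, so shrinkage of
  # the pre-existing set is guaranteed by construction
  counts <- lapply(c(1.5, 2, 3), function(th) {
    cls <- classify_by_marks(rec$fold_k4me1 >= th, rec$fold_k27ac >= th,
                             rec$fold_p300 >= th, rec$fold_k27me3 >= 2)
    table(cls)
  })
  pre <- vapply(counts, function(x) x[["pre_existing"]], numeric(1))
  de <- vapply(counts, function(x) x[["de_novo"]], numeric(1))
  expect_true(all(diff(pre) <= 0))
  expect_true(all(diff(de) >= 0))
})
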