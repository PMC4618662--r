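gm <- genome_model("chr1", 100000L)

test_that("build_presence marks region x time overlaps correctly", {
  one <- peak_set("chr1", 100, 300, genome = gm)
  p <- build_presence(list("0" = one), times = 0)
  expect_equal(dim(p$presence), c(1L, 1L))
  expect_true(p$presence[1, 1])

  same3 <- list("0" = one, "3" = one, "12" = one)
  p3 <- build_presence(same3)
  expect_equal(dim(p3$presence), c(1L, 3L))
  expect_true(all(p3$presence))
})

test_that("build_presence equals a per-base brute-force overlap oracle", {
  set.seed(31)
  sets <- lapply(1:3, function(i) random_peaks(60, chrom_len = 20000))
  names(sets) <- c("3", "12", "24")
  p <- build_presence(sets)
  # oracle: per-base coverage marking per region and time
  for (j in 1:3) {
    covered <- logical(20000)
    s <- sets[[j]]
    for (i in seq_along(s)) {
      covered[GenomicRanges::start(s)[i]:GenomicRanges::end(s)[i]] <- TRUE
    }
    for (r in seq_along(p$regions)) {
      span <- GenomicRanges::start(p$regions)[r]:GenomicRanges::end(p$regions)[r]
      expect_identical(unname(p$presence[r, j]), any(covered[span]))
    }
  }
})

test_that("stability rule: gap-free from first detection through terminal", {
  # enumerate all 16 presence patterns over post-induction times 3/12/24/48
  times <- c(0, 3, 12, 24, 48)
  regions <- peak_set("chr1", (0:15) * 1000, (0:15) * 1000 + 200, genome = gm)
  pat <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), 4)))
  presence <- cbind(rep(FALSE, 16), pat) # never present at baseline
  colnames(presence) <- as.character(times)
  p <- structure(list(regions = regions, times = times,
                      time_labels = colnames(presence), presence = presence,
                      factor_label = "x", time_unit = "hpi"),
                 class = "tc_presence")
  got <- classify_stability(p, terminal_time = 48)
  # oracle: present at 48 and contiguous TRUE run reaching 48
  oracle <- apply(pat, 1, function(row) {
    first <- which(row)[1]
    if (is.na(first) || !row[4]) return("transient")
    if (all(row[first:4])) "stable" else "transient"
  })
  expect_equal(as.character(got), oracle)
  # spec-level cases
  expect_equal(as.character(got[16]), "stable")      # present at all times
  expect_equal(as.character(got[2]), "transient")    # only at 3 hpi
  gap <- which(pat[, 1] & !pat[, 2] & !pat[, 3] & pat[, 4])
  expect_equal(as.character(got[gap]), "transient")  # 3 & 48, absent between

  # terminal mode only requires terminal presence
  got_t <- classify_stability(p, 48, mode = "terminal")
  expect_equal(as.character(got_t), ifelse(pat[, 4], "stable", "transient"))

  # baseline presence is ignored for stability
  presence2 <- presence
  presence2[, 1] <- TRUE
  p2 <- p; p2$presence <- presence2
  expect_equal(classify_stability(p2, 48), got)
})

test_that("first_detection matches a linear scan", {
  times <- c(10, 30, 60)
  regions <- peak_set("chr1", (0:9) * 1000, (0:9) * 1000 + 100, genome = gm)
  set.seed(4)
  m <- matrix(sample(c(TRUE, FALSE), 30, replace = TRUE), nrow = 10)
  colnames(m) <- as.character(times)
  p <- structure(list(regions = regions, times = times, time_labels = colnames(m),
                      presence = m, factor_label = "x", time_unit = "min"),
                 class = "tc_presence")
  expect_equal(first_detection(p),
               apply(m, 1, function(r) if (any(r)) times[which(r)[1]] else NA_real_))
  expect_equal(first_detection(p, 2), {
    r <- m[2, ]; if (any(r)) times[which(r)[1]] else NA_real_
  })
})

test_that("binding order is exhaustive over all first-detection patterns and antisymmetric", {
  times <- c(10, 30, 60)
  opts <- c(10, 30, 60, NA)
  grid <- expand.grid(fa = opts, fb = opts)
  n <- nrow(grid) # 16
  regions <- peak_set("chr1", (seq_len(n) - 1) * 1000,
                      (seq_len(n) - 1) * 1000 + 100, genome = gm)
  mk <- function(firsts) {
    m <- sapply(times, function(t) !is.na(firsts) & firsts <= t)
    colnames(m) <- as.character(times)
    structure(list(regions = regions, times = times,
                   time_labels = colnames(m), presence = m,
                   factor_label = "x", time_unit = "min"),
              class = "tc_presence")
  }
  pa <- mk(grid$fa); pb <- mk(grid$fb)
  calls <- classify_binding_order(pa, pb)
  oracle <- with(grid, ifelse(is.na(fa) & is.na(fb), "unclassified",
                       ifelse(is.na(fb), "a_first",
                       ifelse(is.na(fa), "b_first",
                       ifelse(fa < fb, "a_first",
                       ifelse(fb < fa, "b_first", "simultaneous"))))))
  expect_equal(as.character(calls$order), oracle)
  # antisymmetry: swapping factors swaps a_first/b_first
  swapped <- classify_binding_order(pb, pa)
  map <- c(a_first = "b_first", b_first = "a_first",
           simultaneous = "simultaneous", unclassified = "unclassified")
  expect_equal(as.character(swapped$order), unname(map[as.character(calls$order)]))
})

test_that("prebound_fraction counts overlap fractions and rejects empty input", {
  sites <- peak_set("chr1", c(0, 1000, 2000), c(200, 1200, 2200), genome = gm)
  expect_equal(prebound_fraction(sites, sites), 1.0)
  far <- peak_set("chr1", 50000, 50100, genome = gm)
  expect_equal(prebound_fraction(sites, far), 0.0)
  expect_error(prebound_fraction(sites[0], far), "empty")
})
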