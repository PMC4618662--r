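test_that("default scenario config plants the headline quantities", {
  cfg <- default_scenario_config()
  expect_equal(cfg$frac_cebpa_first_de_novo, 0.74)
  expect_equal(cfg$promoter_state_mix_pre_existing,
               c(active = 0.73, inactive = 0.07, bivalent = 0.20))
  expect_equal(cfg$promoter_state_mix_de_novo,
               c(active = 0.36, inactive = 0.44, bivalent = 0.20))
  expect_equal(cfg$frac_prebound_pu1, 0.40)
  expect_equal(cfg$frac_upregulated_within_100kb, 0.70)
  expect_equal(cfg$fold_change_pre_existing, 4)
  expect_equal(cfg$fold_change_de_novo, 9)
  la <- cfg$lineage_activity
  expect_equal(la$pre_existing[la$cell_type == "LT_HSC"], 0.58)
  oc <- cfg$occupancy
  expect_equal(oc$pre_existing[oc$cell_type == "GMP"], 0.80)
  expect_lt(oc$pre_existing[oc$cell_type == "LSK"], 0.10)
  # invariant: every fraction in [0, 1] (validated on construction)
  expect_silent(validate_scenario_config(cfg))
})

test_that("config validation rejects broken invariants", {
  cfg <- default_scenario_config()
  bad <- cfg; bad$frac_prebound_pu1 <- 1.2
  expect_error(validate_scenario_config(bad), "\\[0, 1\\]")
  bad <- cfg; bad$promoter_state_mix_de_novo <- c(active = 0.5, inactive = 0.4,
                                                  bivalent = 0.2)
  expect_error(validate_scenario_config(bad), "sum to 1")
  bad <- cfg; bad$time_points_hpi <- c(0, 12, 3)
  expect_error(validate_scenario_config(bad), "increasing")
})

test_that("scenario config round-trips through YAML", {
  cfg <- mini_config()
  p <- withr::local_tempfile(fileext = ".yaml")
  write_scenario_config(cfg, p)
  back <- read_scenario_config(p)
  expect_equal(back$promoter_state_mix_pre_existing,
               cfg$promoter_state_mix_pre_existing)
  expect_equal(back$lineage_activity, cfg$lineage_activity)
  expect_equal(back$n_pre_existing, cfg$n_pre_existing)
})

test_that("generation is byte-identical under a fixed seed", {
  d1 <- file.path(tempdir(), "ek_det1")
  d2 <- file.path(tempdir(), "ek_det2")
  unlink(c(d1, d2), recursive = TRUE)
  generate_scenario(mini_config(seed = 5L), d1)
  generate_scenario(mini_config(seed = 5L), d2)
  f1 <- sort(list.files(d1)); f2 <- sort(list.files(d2))
  expect_identical(f1, f2)
  h1 <- tools::md5sum(file.path(d1, f1))
  h2 <- tools::md5sum(file.path(d2, f2))
  expect_identical(unname(h1), unname(h2))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("every generated file parses with the core readers", {
  sc <- mini_scenario()
  genome <- sc$genome
  for (key in names(sc$files)) {
    path <- sc$files[[key]]
    if (grepl("\\.bed$", path)) {
      expect_no_error(read_bed(path, genome = genome))
    } else if (grepl("\\.bedgraph$", path)) {
      expect_no_error(read_bedgraph(path, genome))
    }
  }
  expect_no_error(read_gene_table(sc$files$genes, genome = genome))
  expect_no_error(read_expression(sc$files$expression))
})

test_that("planted fractions are realized by exact counts", {
  sc <- mini_scenario()
  tr <- sc$truth$enhancers
  cfg <- sc$config
  n <- nrow(tr)
  expect_equal(n, cfg$n_pre_existing + cfg$n_de_novo)
  expect_equal(sum(tr$class == "pre_existing"), cfg$n_pre_existing)
  expect_equal(sum(tr$prebound_pu1), round(cfg$frac_prebound_pu1 * n))
  de <- tr[tr$class == "de_novo", ]
  expect_equal(sum(de$binding_order == "cebpa_first"),
               round(cfg$frac_cebpa_first_de_novo * nrow(de)), tolerance = 2)
  # promoter mixes within binomial-free exact-count tolerance (rounding only)
  pre <- tr[tr$class == "pre_existing", ]
  mix <- table(pre$promoter_state) / nrow(pre)
  expect_equal(unname(mix["active"]),
               unname(cfg$promoter_state_mix_pre_existing["active"]),
               tolerance = 0.02)
  # per-gene truth covers every generated gene exactly once
  g <- sc$truth$genes
  expr <- read_expression(sc$files$expression)
  expect_setequal(g$gene_id, rownames(expr))
  expect_false(anyDuplicated(g$gene_id) > 0)
})

test_that("enhancer midpoints keep the minimum distance from every TSS", {
  sc <- mini_scenario()
  genes <- read_gene_table(sc$files$genes, genome = sc$genome)
  tr <- sc$truth$enhancers
  for (i in seq_len(nrow(tr))) {
    gi <- which(as.character(GenomicRanges::seqnames(genes)) == tr$chrom[i])
    expect_gte(min(abs(tr$center[i] - genes$tss[gi])), sc$config$min_tss_gap)
  }
  # and the designated gene is the nearest one
  sites <- peak_set(tr$chrom, tr$start, tr$end, genome = sc$genome)
  nt <- nearest_tss(sites, genes)
  expect_equal(nt$gene_id, tr$gene_id)
})

test_that("a scenario without de novo enhancers has no H3K27Me3-marked distal truth", {
  cfg <- mini_config(seed = 3L)
  cfg$n_de_novo <- 0L
  cfg$n_genes <- 200L
  d <- file.path(tempdir(), "ek_nodenovo")
  unlink(d, recursive = TRUE)
  sc <- generate_scenario(cfg, d)
  expect_equal(sum(sc$truth$enhancers$class == "de_novo"), 0L)
  # the baseline K27me3 track is unmarked at every enhancer midpoint
  tr <- read_bedgraph(sc$files$k27me3_t0hpi, sc$genome)
  bg <- estimate_background(tr)
  st <- call_mark_state(sc$truth$enhancers$center, sc$truth$enhancers$chrom,
                        tr, background = bg)
  expect_false(any(st$marked))
  unlink(d, recursive = TRUE)
})

test_that("an oversubscribed genome is rejected", {
  cfg <- mini_config()
  cfg$chrom_length <- 2e6
  expect_error(generate_scenario(cfg, tempfile()), "genome too small")
})
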