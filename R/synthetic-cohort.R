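#' Default synthetic-scenario configuration
#'
#' Returns the configuration of the study-default synthetic cohort: every
#' planted quantity equals the corresponding headline value of the
#' transdifferentiation system the package models (fractions of upregulated
#' genes near stable sites, promoter-state mixes of the two enhancer classes,
#' pioneer-first binding-order fraction, PU.1 pre-binding, per-class
#' expression folds, lineage activity and occupancy), at desk scale
#' (4 chromosomes x 10 Mb, 800 pre-existing + 600 de novo enhancers,
#' 3,000 genes).
#'
#' @param seed integer RNG seed (default 1).
#' @return A `scenario_config` list; see the field list in the source and the
#'   methods vignette for semantics.
#' @export
default_scenario_config <- function(seed = 1L) {
  cfg <- list(
    # genome
    n_chroms = 4L, chrom_length = 1e7,
    # cohort sizes
    n_pre_existing = 800L, n_de_novo = 600L, n_genes = 3000L,
    # time axes
    time_points_hpi = c(0, 3, 12, 24, 48),
    early_time_points_min = c(10, 30, 60),
    # planted headline quantities
    frac_cebpa_first_de_novo = 0.74,
    frac_prebound_pu1 = 0.40,
    promoter_state_mix_pre_existing = c(active = 0.73, inactive = 0.07,
                                        bivalent = 0.20),
    promoter_state_mix_de_novo = c(active = 0.36, inactive = 0.44,
                                   bivalent = 0.20),
    frac_upregulated_within_100kb = 0.70,
    fold_change_pre_existing = 4, fold_change_de_novo = 9,
    baseline_expression_pre_existing = 20, baseline_expression_de_novo = 2,
    # lineage tree activity: fraction of each final class carrying active
    # enhancer marks per cell type
    lineage_activity = data.frame(
      cell_type = c("LT_HSC", "ST_HSC", "MPP", "CMP", "CLP", "GMP", "MEP",
                    "Gn", "Mphi", "Ery", "B", "T"),
      pre_existing = c(0.58, 0.58, 0.60, 0.62, 0.60, 0.64, 0.30,
                       0.66, 0.74, 0.30, 0.60, 0.30),
      de_novo = c(0.07, 0.07, 0.14, 0.25, 0.02, 0.28, 0.02,
                  0.40, 0.40, 0.02, 0.02, 0.02),
      stringsAsFactors = FALSE),
    # C/EBPa occupancy per cell type (LSK progenitors, GMPs, macrophages)
    occupancy = data.frame(
      cell_type = c("LSK", "GMP", "Mphi"),
      pre_existing = c(0.08, 0.80, 0.80),
      de_novo = c(0.08, 0.80, 0.80),
      stringsAsFactors = FALSE),
    # noise / shape parameters
    background_rate = 0.02,  # Poisson background, signal per bp
    peak_height = 1.0,       # mark peak amplitude (50x background)
    peak_width = 400,        # mark peak width; Gaussian sd = width / 4
    expression_sigma = 0.2,  # log-normal noise sd (log scale)
    # structure parameters
    transient_ratio = 4L,    # transient : stable C/EBPa regions
    min_tss_gap = 10000L,    # min distance enhancer midpoint <-> any TSS
    frac_ebf1_pre_existing = 0.30,
    frac_leaky_t0 = 0.05,    # leaky baseline C/EBPa binding
    frac_down_other = 0.30,  # of non-enhancer, non-far-up genes
    background_bin = 1000L,  # run-length granularity of emitted background
    tf_peak_width = 200L,
    seed = as.integer(seed)
  )
  class(cfg) <- "scenario_config"
  validate_scenario_config(cfg)
  cfg
}

#' Validate a scenario configuration
#'
#' @param cfg a `scenario_config`.
#' @return `cfg`, invisibly; errors on violated invariants.
#' @export
validate_scenario_config <- function(cfg) {
  fr <- c(cfg$frac_cebpa_first_de_novo, cfg$frac_prebound_pu1,
          cfg$frac_upregulated_within_100kb, cfg$frac_ebf1_pre_existing,
          cfg$frac_leaky_t0, cfg$frac_down_other,
          cfg$promoter_state_mix_pre_existing, cfg$promoter_state_mix_de_novo,
          cfg$lineage_activity$pre_existing, cfg$lineage_activity$de_novo,
          cfg$occupancy$pre_existing, cfg$occupancy$de_novo)
  if (any(fr < 0 | fr > 1)) stop("all fractions must be in [0, 1]")
  for (mix in list(cfg$promoter_state_mix_pre_existing,
                   cfg$promoter_state_mix_de_novo)) {
    if (abs(sum(mix) - 1) > 1e-9) stop("promoter-state mixes must sum to 1")
    if (!identical(names(mix), c("active", "inactive", "bivalent"))) {
      stop("promoter-state mixes must be named (active, inactive, bivalent)")
    }
  }
  if (is.unsorted(cfg$time_points_hpi, strictly = TRUE) ||
      is.unsorted(cfg$early_time_points_min, strictly = TRUE)) {
    stop("time points must be strictly increasing")
  }
  if (cfg$n_pre_existing < 0 || cfg$n_de_novo < 0) stop("negative class size")
  if (cfg$background_rate <= 0 || cfg$peak_height <= 0) {
    stop("background_rate and peak_height must be > 0")
  }
  invisible(cfg)
}

# Exact-count label assignment (largest-remainder rounding), permuted with
# the current RNG stream. Planted fractions are realized by counts, not
# Bernoulli draws, so recovery targets are sharp.
#' @noRd
.exact_labels <- function(n, props) {
  if (n == 0L) return(character(0))
  cnt <- floor(props * n)
  rem <- n - sum(cnt)
  if (rem > 0) {
    extra <- order(-(props * n - cnt))[seq_len(rem)]
    cnt[extra] <- cnt[extra] + 1L
  }
  sample(rep(names(props), times = cnt))
}

# Exact-count logical assignment: round(f * n) TRUEs, permuted.
#' @noRd
.exact_flags <- function(n, f) {
  k <- round(f * n)
  sample(c(rep(TRUE, k), rep(FALSE, n - k)))
}

#' @noRd
.write_bed_dt <- function(chrom, start0, end, name, path, score = 0,
                          strand = ".") {
  dt <- data.table::data.table(chrom = chrom, start = as.integer(start0),
                               end = as.integer(end), name = name,
                               score = score, strand = strand)
  data.table::setorder(dt, chrom, start, end)
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE, quote = FALSE)
  path
}

# Gaussian mark peaks as 25-bp bedGraph steps over +/- 3 sd.
#' @noRd
.gaussian_records <- function(chrom, centers, heights, sd) {
  step <- 25L
  span <- ceiling(3 * sd / step) * step
  offs <- seq(-span, span - step, by = step)
  shape <- exp(-(offs + step / 2)^2 / (2 * sd^2))
  n <- length(centers)
  data.table::data.table(
    chrom = rep(chrom, each = length(offs)),
    start = rep(as.integer(centers), each = length(offs)) + rep(offs, n),
    end = rep(as.integer(centers), each = length(offs)) + rep(offs, n) + step,
    value = rep(heights, each = length(offs)) * rep(shape, n))
}

# Poisson background at `bin` granularity for every chromosome.
#' @noRd
.background_records <- function(chrom_names, chrom_length, rate, bin) {
  nb <- as.integer(chrom_length %/% bin)
  out <- lapply(chrom_names, function(chr) {
    v <- stats::rpois(nb, rate * bin) / bin
    data.table::data.table(chrom = chr,
                           start = (seq_len(nb) - 1L) * bin,
                           end = seq_len(nb) * bin, value = v)[v > 0]
  })
  data.table::rbindlist(out)
}

#' @noRd
.write_bedgraph_dt <- function(dt, path) {
  data.table::setorder(dt, chrom, start, end)
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE, quote = FALSE)
  path
}

#' Generate a complete synthetic scenario
#'
#' Writes a full synthetic input dataset to `out_dir` — gene table,
#' per-time-point TF peak BEDs (hour-scale and minute-scale series),
#' per-time-point histone-mark/P300 bedGraph tracks, an expression
#' time-course TSV, per-cell-type lineage peak BEDs, MNase fragment BEDs and
#' the planted truth tables — fully deterministic given `cfg$seed`.
#'
#' Structure planted (see the methods vignette for the full account):
#' enhancers are laid out in non-overlapping cassettes with their designated
#' nearest gene 10.0-10.4 kb away; pre-existing enhancers carry active marks
#' (H3K4Me1/H3K27Ac/P300) at baseline while de novo enhancers carry only
#' H3K27Me3, which decays as active marks rise after pioneer binding;
#' transient binding regions (config ratio, default 4x the stable count)
#' appear in contiguous runs that end before the terminal time point;
#' minute-scale peak appearance encodes the planted binding order; expression
#' folds, promoter states, lineage activity and factor occupancy are planted
#' by exact counts within class/promoter strata.
#'
#' @param cfg a `scenario_config` (see [default_scenario_config()]).
#' @param out_dir output directory (created if needed).
#' @return A `synthetic_scenario` list: `dir`, `genome` (`Seqinfo`), `files`
#'   (named paths), `truth` (list of `enhancers` and `genes` data.frames)
#'   and `config`.
#' @export
generate_scenario <- function(cfg, out_dir) {
  validate_scenario_config(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(cfg$seed)

  chrom_names <- paste0("chr", seq_len(cfg$n_chroms))
  genome <- genome_model(chrom_names, rep(cfg$chrom_length, cfg$n_chroms))

  ## ---- layout ------------------------------------------------------------
  n_enh <- cfg$n_pre_existing + cfg$n_de_novo
  spacing <- 22000L
  terr_start <- 100000L
  per_chrom <- diff(floor(seq(0, n_enh, length.out = cfg$n_chroms + 1)))
  n_cass_max <- max(per_chrom)
  terr_end <- terr_start + n_cass_max * spacing
  desert_start <- terr_end + 550000L
  desert_end <- cfg$chrom_length - 50000L

  n_far_up <- round(n_enh * (1 - cfg$frac_upregulated_within_100kb) /
                      cfg$frac_upregulated_within_100kb)
  n_other <- cfg$n_genes - n_enh - n_far_up
  if (n_other < 0) stop("n_genes too small for the requested enhancer count")
  n_desert <- n_far_up + n_other
  desert_per_chrom <- diff(floor(seq(0, n_desert, length.out = cfg$n_chroms + 1)))
  gene_spacing <- if (max(desert_per_chrom) > 0) {
    floor((desert_end - desert_start) / max(desert_per_chrom))
  } else 4000L
  if (desert_start >= desert_end || gene_spacing < 3000L) {
    stop("genome too small for requested scenario")
  }

  # enhancer cassettes, chromosome-major
  enh_chrom <- rep(chrom_names, times = per_chrom)
  cass_idx <- unlist(lapply(per_chrom, seq_len)) - 1L
  e_center <- terr_start + cass_idx * spacing + spacing %/% 2L +
    as.integer(floor(stats::runif(n_enh, -250, 251)))
  # designated gene always to the right of its enhancer so that promoter
  # windows of neighboring cassettes stay disjoint; strand is still random
  # (gene body extends left of the TSS for minus-strand genes)
  gene_dir <- sample(c(-1L, 1L), n_enh, replace = TRUE)
  gene_dist <- as.integer(round(stats::runif(n_enh, 10000, 10400)))
  gene_tss_pos <- e_center + gene_dist

  ## ---- planted labels (exact counts, stratified) ---------------------------
  class <- sample(rep(c("pre_existing", "de_novo"),
                      times = c(cfg$n_pre_existing, cfg$n_de_novo)))
  promoter_state <- character(n_enh)
  ip <- which(class == "pre_existing"); id <- which(class == "de_novo")
  promoter_state[ip] <- .exact_labels(length(ip),
                                      cfg$promoter_state_mix_pre_existing)
  promoter_state[id] <- .exact_labels(length(id),
                                      cfg$promoter_state_mix_de_novo)

  # binding order: de novo only, exact counts within each promoter stratum
  binding_order <- rep(NA_character_, n_enh)
  p_rest <- (1 - cfg$frac_cebpa_first_de_novo) / 2
  for (st in c("active", "inactive", "bivalent")) {
    i <- which(class == "de_novo" & promoter_state == st)
    binding_order[i] <- .exact_labels(length(i), c(
      cebpa_first = cfg$frac_cebpa_first_de_novo,
      simultaneous = p_rest, pu1_first = p_rest))
  }

  # PU.1 pre-binding: planted entirely within the pre-existing class (its
  # hallmark), sized to the whole stable universe
  n_prebound <- round(cfg$frac_prebound_pu1 * n_enh)
  if (n_prebound > length(ip)) {
    stop("frac_prebound_pu1 too large for the pre-existing class size")
  }
  prebound <- rep(FALSE, n_enh)
  prebound[sample(ip, n_prebound)] <- TRUE

  ebf1 <- rep(FALSE, n_enh)
  ebf1[ip] <- .exact_flags(length(ip), cfg$frac_ebf1_pre_existing)
  leaky <- .exact_flags(n_enh, cfg$frac_leaky_t0)

  # lineage activity / occupancy: exact counts within class x promoter strata
  plant_by_stratum <- function(rate_pre, rate_de) {
    flag <- rep(FALSE, n_enh)
    for (cl in c("pre_existing", "de_novo")) {
      rate <- if (cl == "pre_existing") rate_pre else rate_de
      for (st in c("active", "inactive", "bivalent")) {
        i <- which(class == cl & promoter_state == st)
        flag[i] <- .exact_flags(length(i), rate)
      }
    }
    flag
  }
  activity <- lapply(seq_len(nrow(cfg$lineage_activity)), function(k) {
    plant_by_stratum(cfg$lineage_activity$pre_existing[k],
                     cfg$lineage_activity$de_novo[k])
  })
  names(activity) <- cfg$lineage_activity$cell_type
  occup <- lapply(seq_len(nrow(cfg$occupancy)), function(k) {
    plant_by_stratum(cfg$occupancy$pre_existing[k], cfg$occupancy$de_novo[k])
  })
  names(occup) <- cfg$occupancy$cell_type

  ## ---- genes ---------------------------------------------------------------
  gene_len <- 2000L
  enh_gene_id <- sprintf("gene_enh_%04d", seq_len(n_enh))
  d_idx <- seq_len(n_desert)
  desert_chrom <- rep(chrom_names, times = desert_per_chrom)
  d_local <- unlist(lapply(desert_per_chrom, seq_len)) - 1L
  desert_tss <- desert_start + d_local * gene_spacing +
    as.integer(floor(stats::runif(n_desert, 0, 500)))
  desert_dir <- sample(c(-1L, 1L), n_desert, replace = TRUE)
  desert_group <- sample(rep(c("far_up", "down", "unchanged"),
                             times = c(n_far_up,
                                       round(cfg$frac_down_other * n_other),
                                       n_other - round(cfg$frac_down_other *
                                                         n_other))))
  desert_gene_id <- sprintf("gene_des_%04d", d_idx)

  gene_bed <- function(chrom, tss, dir, id) {
    plus <- dir == 1L
    data.table::data.table(
      chrom = chrom,
      start = ifelse(plus, tss, tss - gene_len + 1L),
      end = ifelse(plus, tss + gene_len, tss + 1L),
      name = id, score = 0, strand = ifelse(plus, "+", "-"))
  }
  genes_dt <- rbind(gene_bed(enh_chrom, gene_tss_pos, gene_dir, enh_gene_id),
                    gene_bed(desert_chrom, desert_tss, desert_dir,
                             desert_gene_id))
  files <- list()
  files$genes <- file.path(out_dir, "genes.bed")
  .write_bed_dt(genes_dt$chrom, genes_dt$start, genes_dt$end, genes_dt$name,
                files$genes, strand = genes_dt$strand)

  ## ---- TF peak BEDs --------------------------------------------------------
  tf_half <- cfg$tf_peak_width %/% 2L
  peak_dt <- function(i, label) {
    jit <- as.integer(floor(stats::runif(length(i), -20, 21)))
    data.table::data.table(chrom = enh_chrom[i],
                           start = e_center[i] - tf_half + jit,
                           end = e_center[i] + tf_half + jit,
                           name = label)
  }
  # transient C/EBPa regions: contiguous runs ending before terminal time
  post_times <- setdiff(cfg$time_points_hpi, c(0, max(cfg$time_points_hpi)))
  runs <- list()
  for (a in seq_along(post_times)) for (b in a:length(post_times)) {
    runs[[length(runs) + 1L]] <- post_times[a:b]
  }
  trans_offsets <- c(-6500L, -3500L, 3500L, 6500L)
  n_per_enh <- min(length(trans_offsets), cfg$transient_ratio)
  n_trans <- if (length(runs)) n_per_enh * n_enh else 0L
  trans_anchor <- rep(seq_len(n_enh), each = n_per_enh)[seq_len(n_trans)]
  trans_off <- rep(trans_offsets[seq_len(n_per_enh)],
                   times = n_enh)[seq_len(n_trans)]
  trans_center <- e_center[trans_anchor] + trans_off
  trans_chrom <- enh_chrom[trans_anchor]
  trans_run <- if (n_trans) sample(seq_along(runs), n_trans, replace = TRUE) else integer(0)

  term <- max(cfg$time_points_hpi)
  for (t in cfg$time_points_hpi) {
    lab <- paste0("t", t, "hpi")
    stable_i <- if (t == 0) which(leaky) else seq_len(n_enh)
    dt <- peak_dt(stable_i, paste0("cebpa_", lab))
    if (t > 0 && t < term) {
      ti <- which(vapply(trans_run, function(r) t %in% runs[[r]], logical(1)))
      if (length(ti)) {
        jit <- as.integer(floor(stats::runif(length(ti), -20, 21)))
        dt <- rbind(dt, data.table::data.table(
          chrom = trans_chrom[ti],
          start = trans_center[ti] - tf_half + jit,
          end = trans_center[ti] + tf_half + jit,
          name = paste0("cebpa_trans_", lab)))
      }
    }
    files[[paste0("cebpa_", lab)]] <- file.path(out_dir,
                                                paste0("cebpa_", lab, ".bed"))
    .write_bed_dt(dt$chrom, dt$start, dt$end, dt$name,
                  files[[paste0("cebpa_", lab)]])
    # PU.1: pre-bound subset at baseline (plus decoy pre-B sites), the whole
    # pre-existing class from 3 hpi, everything from 12 hpi
    pu_i <- if (t == 0) which(prebound) else if (t <= 3) {
      union(which(prebound), ip)
    } else seq_len(n_enh)
    pdt <- peak_dt(pu_i, paste0("pu1_", lab))
    if (t == 0) {
      dz0 <- terr_end + 100000L
      n_decoy <- 200L
      dstep <- max((desert_start - 200000L - dz0) %/% n_decoy, 300L)
      decoy_pos <- as.integer(dz0 + (seq_len(n_decoy) - 1L) * dstep +
                                floor(stats::runif(n_decoy, 0, 200)))
      pdt <- rbind(pdt, data.table::data.table(
        chrom = rep(chrom_names, each = n_decoy),
        start = rep(decoy_pos, cfg$n_chroms) - tf_half,
        end = rep(decoy_pos, cfg$n_chroms) + tf_half,
        name = "pu1_decoy"))
    }
    files[[paste0("pu1_", lab)]] <- file.path(out_dir,
                                              paste0("pu1_", lab, ".bed"))
    .write_bed_dt(pdt$chrom, pdt$start, pdt$end, pdt$name,
                  files[[paste0("pu1_", lab)]])
    # C/EBPb follows C/EBPa from 3 hpi
    cb_i <- if (t == 0) integer(0) else seq_len(n_enh)
    cdt <- peak_dt(cb_i, paste0("cebpb_", lab))
    files[[paste0("cebpb_", lab)]] <- file.path(out_dir,
                                                paste0("cebpb_", lab, ".bed"))
    .write_bed_dt(cdt$chrom, cdt$start, cdt$end, cdt$name,
                  files[[paste0("cebpb_", lab)]])
  }

  # minute-scale series: appearance encodes planted binding order
  et <- cfg$early_time_points_min
  first_cebpa <- rep(NA_real_, n_enh)
  first_pu1 <- rep(NA_real_, n_enh)
  first_cebpa[ip] <- et[1]
  first_pu1[which(prebound)] <- et[1]
  first_pu1[setdiff(ip, which(prebound))] <- et[length(et)]
  io_ <- function(lbl) which(binding_order == lbl)
  first_cebpa[io_("cebpa_first")] <- et[1]
  first_pu1[io_("cebpa_first")] <- et[length(et)]
  first_cebpa[io_("pu1_first")] <- et[length(et)]
  first_pu1[io_("pu1_first")] <- et[1]
  mid_t <- et[max(1L, (length(et) + 1L) %/% 2L)]
  first_cebpa[io_("simultaneous")] <- mid_t
  first_pu1[io_("simultaneous")] <- mid_t
  for (t in et) {
    for (fac in c("cebpa", "pu1")) {
      first <- if (fac == "cebpa") first_cebpa else first_pu1
      i <- which(!is.na(first) & first <= t)
      dt <- peak_dt(i, paste0(fac, "_", t, "min"))
      key <- paste0(fac, "_early_", t, "min")
      files[[key]] <- file.path(out_dir, paste0(key, ".bed"))
      .write_bed_dt(dt$chrom, dt$start, dt$end, dt$name, files[[key]])
    }
  }

  ## ---- mark bedGraph tracks ------------------------------------------------
  sd <- cfg$peak_width / 4
  h <- cfg$peak_height
  nt <- length(cfg$time_points_hpi)
  ramp_up <- stats::approx(x = c(0, 3, 24, 48), y = c(0, 0.3, 1, 1),
                           xout = cfg$time_points_hpi, rule = 2)$y
  decay <- stats::approx(x = c(0, 3, 12, 24, 48), y = c(1, 0.7, 0.4, 0.2, 0.1),
                         xout = cfg$time_points_hpi, rule = 2)$y
  # promoter mark carriers
  biv <- which(promoter_state == "bivalent")
  inact <- which(promoter_state == "inactive")
  inact_k27 <- inact[.exact_flags(length(inact), 0.5)] # K27Me3 or no marks
  act <- which(promoter_state %in% c("active", "bivalent"))
  desert_active <- which(.exact_flags(n_desert, 0.6))
  for (k in seq_len(nt)) {
    t <- cfg$time_points_hpi[k]
    lab <- paste0("t", t, "hpi")
    tracks <- list(
      k4me1 = rbind(
        .gaussian_records(enh_chrom[ip], e_center[ip], rep(h, length(ip)), sd),
        .gaussian_records(enh_chrom[id], e_center[id],
                          rep(h * ramp_up[k], length(id)), sd)),
      k27ac = rbind(
        .gaussian_records(enh_chrom[ip], e_center[ip],
                          rep(h * (1 + 0.5 * ramp_up[k]), length(ip)), sd),
        .gaussian_records(enh_chrom[id], e_center[id],
                          rep(h * ramp_up[k], length(id)), sd)),
      p300 = rbind(
        .gaussian_records(enh_chrom[ip], e_center[ip], rep(h, length(ip)), sd),
        .gaussian_records(enh_chrom[id], e_center[id],
                          rep(h * ramp_up[k], length(id)), sd)),
      k27me3 = rbind(
        .gaussian_records(enh_chrom[id], e_center[id],
                          rep(h * decay[k], length(id)), sd),
        .gaussian_records(enh_chrom[c(biv, inact_k27)],
                          gene_tss_pos[c(biv, inact_k27)],
                          rep(h, length(biv) + length(inact_k27)), sd)),
      k4me3 = rbind(
        .gaussian_records(enh_chrom[act], gene_tss_pos[act],
                          rep(1.2 * h, length(act)), sd),
        .gaussian_records(desert_chrom[desert_active],
                          desert_tss[desert_active],
                          rep(1.2 * h, length(desert_active)), sd))
    )
    for (mk in names(tracks)) {
      dt <- tracks[[mk]][value > 0]
      bg <- .background_records(chrom_names, cfg$chrom_length,
                                cfg$background_rate, cfg$background_bin)
      dt <- rbind(dt, bg)
      key <- paste0(mk, "_", lab)
      files[[key]] <- file.path(out_dir, paste0(key, ".bedgraph"))
      .write_bedgraph_dt(dt, files[[key]])
    }
  }

  ## ---- expression time course ---------------------------------------------
  n_genes_all <- n_enh + n_desert
  gene_ids <- c(enh_gene_id, desert_gene_id)
  baseline <- c(ifelse(class == "pre_existing",
                       cfg$baseline_expression_pre_existing,
                       cfg$baseline_expression_de_novo),
                ifelse(desert_group == "far_up", 10,
                       ifelse(desert_group == "down", 40, 10)))
  far_fold <- stats::runif(n_desert, 3, 6)
  fold <- c(ifelse(class == "pre_existing", cfg$fold_change_pre_existing,
                   cfg$fold_change_de_novo),
            ifelse(desert_group == "far_up", far_fold,
                   ifelse(desert_group == "down", 0.25, 1)))
  # activation ramps: pre-existing (and generic) genes rise gradually,
  # de novo targets lag behind pioneer binding; terminal exponent is 1
  ramp_generic <- stats::approx(c(0, 3, 12, 24, 48), c(0, 0.25, 0.5, 0.8, 1),
                                xout = cfg$time_points_hpi, rule = 2)$y
  ramp_lagged <- stats::approx(c(0, 3, 12, 24, 48), c(0, 0.1, 0.4, 0.8, 1),
                               xout = cfg$time_points_hpi, rule = 2)$y
  lagged <- c(class == "de_novo", rep(FALSE, n_desert))
  expr <- matrix(0, nrow = n_genes_all, ncol = nt,
                 dimnames = list(gene_ids, as.character(cfg$time_points_hpi)))
  noise <- matrix(stats::rlnorm(n_genes_all * nt, 0, cfg$expression_sigma),
                  nrow = n_genes_all)
  for (k in seq_len(nt)) {
    r <- ifelse(lagged, ramp_lagged[k], ramp_generic[k])
    expr[, k] <- baseline * fold^r * noise[, k]
  }
  files$expression <- file.path(out_dir, "expression_timecourse.tsv")
  write_expression(expr, files$expression)

  ## ---- lineage peak sets ---------------------------------------------------
  enh_half <- 150L
  for (ct in names(activity)) {
    i <- which(activity[[ct]])
    for (mk in c("k27ac", "k4me1")) {
      key <- paste0(mk, "_", ct)
      files[[key]] <- file.path(out_dir, paste0(mk, "_", ct, ".bed"))
      .write_bed_dt(enh_chrom[i], e_center[i] - enh_half,
                    e_center[i] + enh_half, paste0(mk, "_", ct),
                    files[[key]])
    }
  }
  for (ct in names(occup)) {
    i <- which(occup[[ct]])
    key <- paste0("cebpa_", ct)
    files[[key]] <- file.path(out_dir, paste0("cebpa_", ct, ".bed"))
    .write_bed_dt(enh_chrom[i], e_center[i] - enh_half,
                  e_center[i] + enh_half, paste0("cebpa_", ct), files[[key]])
  }
  # Ebf1 in the starting pre-B state: pre-existing enhancers only
  i <- which(ebf1)
  files$ebf1_preB <- file.path(out_dir, "ebf1_preB.bed")
  .write_bed_dt(enh_chrom[i], e_center[i] - enh_half, e_center[i] + enh_half,
                "ebf1_preB", files$ebf1_preB)

  ## ---- MNase fragments -----------------------------------------------------
  frag <- function(chrom, mid) {
    mid <- as.integer(round(mid))
    data.table::data.table(chrom = chrom, start = mid - 73L, end = mid + 74L,
                           name = "frag")
  }
  phased <- function(i, n_per_cluster, n_bg) {
    mids <- c(
      rep(e_center[i], each = n_per_cluster) - 150 +
        stats::rnorm(length(i) * n_per_cluster, 0, 30),
      rep(e_center[i], each = n_per_cluster) + 150 +
        stats::rnorm(length(i) * n_per_cluster, 0, 30),
      rep(e_center[i], each = n_bg) +
        stats::runif(length(i) * n_bg, -3000, 3000))
    chr <- c(rep(enh_chrom[i], each = n_per_cluster),
             rep(enh_chrom[i], each = n_per_cluster),
             rep(enh_chrom[i], each = n_bg))
    frag(chr, mids)
  }
  dense <- function(i, n_core, n_bg) {
    mids <- c(rep(e_center[i], each = n_core) +
                stats::runif(length(i) * n_core, -1000, 1000),
              rep(e_center[i], each = n_bg) +
                stats::runif(length(i) * n_bg, -3000, 3000))
    chr <- c(rep(enh_chrom[i], each = n_core), rep(enh_chrom[i], each = n_bg))
    frag(chr, mids)
  }
  # iMphi: pre-existing sites show a nucleosome-depleted valley flanked by
  # two positioned nucleosomes; pre-B: de novo sites sit in dense chromatin
  imphi <- rbind(phased(ip, 30L, 20L), dense(id, 10L, 10L))
  preb <- rbind(phased(ip, 20L, 15L), dense(id, 80L, 20L))
  files$mnase_iMphi <- file.path(out_dir, "mnase_iMphi.bed")
  files$mnase_preB <- file.path(out_dir, "mnase_preB.bed")
  .write_bed_dt(imphi$chrom, imphi$start, imphi$end, imphi$name,
                files$mnase_iMphi)
  .write_bed_dt(preb$chrom, preb$start, preb$end, preb$name, files$mnase_preB)

  ## ---- truth tables --------------------------------------------------------
  enh_id <- sprintf("enh_%04d", seq_len(n_enh))
  truth_enh <- data.frame(
    enh_id = enh_id, chrom = enh_chrom,
    start = e_center - tf_half, end = e_center + tf_half,
    center = e_center, class = class, promoter_state = promoter_state,
    binding_order = binding_order, gene_id = enh_gene_id,
    prebound_pu1 = prebound, ebf1 = ebf1, leaky_t0 = leaky,
    stringsAsFactors = FALSE)
  for (ct in names(activity)) truth_enh[[paste0("active_", ct)]] <- activity[[ct]]
  for (ct in names(occup)) truth_enh[[paste0("occupied_", ct)]] <- occup[[ct]]
  truth_genes <- data.frame(
    gene_id = gene_ids,
    chrom = c(enh_chrom, desert_chrom),
    tss = c(gene_tss_pos, desert_tss),
    group = c(paste0("enhancer_target_", class), desert_group),
    baseline = baseline, fold = fold,
    upregulated = fold > 2,
    within_100kb = c(rep(TRUE, n_enh),
                     rep(FALSE, n_desert)) & fold > 2,
    stringsAsFactors = FALSE)
  files$truth_enhancers <- file.path(out_dir, "truth_enhancers.tsv")
  files$truth_genes <- file.path(out_dir, "truth_genes.tsv")
  data.table::fwrite(truth_enh, files$truth_enhancers, sep = "\t", quote = FALSE)
  data.table::fwrite(truth_genes, files$truth_genes, sep = "\t", quote = FALSE)

  files$config <- file.path(out_dir, "scenario_config.yaml")
  write_scenario_config(cfg, files$config)
  files$genome <- file.path(out_dir, "genome.tsv")
  data.table::fwrite(data.table::data.table(chrom = chrom_names,
                                            length = cfg$chrom_length),
                     files$genome, sep = "\t", quote = FALSE)

  structure(list(dir = out_dir, genome = genome, files = files,
                 truth = list(enhancers = truth_enh, genes = truth_genes),
                 config = cfg),
            class = "synthetic_scenario")
}

#' Write a scenario config as YAML-compatible key:value text
#' @param cfg `scenario_config`.
#' @param path output path.
#' @export
write_scenario_config <- function(cfg, path) {
  x <- unclass(cfg)
  x$lineage_activity <- as.list(x$lineage_activity)
  x$occupancy <- as.list(x$occupancy)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Read a scenario config written by [write_scenario_config()]
#' @param path YAML file.
#' @return A validated `scenario_config`.
#' @export
read_scenario_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$lineage_activity <- as.data.frame(x$lineage_activity,
                                      stringsAsFactors = FALSE)
  x$occupancy <- as.data.frame(x$occupancy, stringsAsFactors = FALSE)
  for (f in c("promoter_state_mix_pre_existing", "promoter_state_mix_de_novo")) {
    x[[f]] <- unlist(x[[f]])
    names(x[[f]]) <- c("active", "inactive", "bivalent")
  }
  class(x) <- "scenario_config"
  validate_scenario_config(x)
  x
}
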