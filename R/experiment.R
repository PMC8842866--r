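#' Configuration for a power-evaluation experiment
#'
#' Defaults reproduce the standard full-scale study design: a 5-chromosome,
#' 3509-marker, 485 cM map; 10 ancestral groups of 10 tetraploid founders
#' drifted for 50 generations at size 100; NAM populations of 460
#' individuals (1 central + 9 peripheral parents, 50 offspring per cross);
#' 11 replicate populations at each diversity level 1, 3, 7, 10; three
#' marker systems; 100-permutation thresholds at alpha 0.05; linking
#' distances 0..10 cM in 0.5 steps; 3 major QTLs plus 50 polygenic loci,
#' heritability ~0.6.
#'
#' `scale` shrinks the design for desk runs: it multiplies the chromosome
#' count (and with it the marker and polygenic-locus counts, keeping
#' density), the replicate count and the permutation count. Major QTLs on
#' dropped chromosomes are themselves dropped.
#'
#' @param scale design shrink factor in (0, 1].
#' @param ... overrides for any configuration field.
#' @return A `pq_config` list.
#' @export
experiment_config <- function(scale = 1, ...) {
  cfg <- list(
    n_chrom = 5, chrom_lengths = c(115, 96, 88, 106, 80), n_markers = 3509,
    n_ag = 10, n_founders = 10, generations = 50, ag_size = 100, ploidy = 4,
    diversity_levels = c(1, 3, 7, 10), n_replicates = 11,
    n_peripheral = 9, offspring_per_cross = 50,
    models = c("snp", "ibd", "hap"),
    l_grid = seq(0, 10, by = 0.5), alpha = 0.05, n_perm = 100,
    window = 6, overlap = 4, truth_window = 5,
    qtl_major = data.frame(chromosome = c("1", "2", "4"),
                           position_cM = c(67.88, 61.2, 100.49),
                           stringsAsFactors = FALSE),
    n_polygenic = 50, sigma_ag = 1, sigma_within = 0.5,
    polygenic_fraction = 0.3, h2 = 0.6, seed = 1)
  if (scale < 1) cfg <- .shrink_config(cfg, scale)
  over <- list(...)
  cfg[names(over)] <- over
  structure(cfg, class = "pq_config")
}

# shrink a configuration for desk runs, preserving marker density
.shrink_config <- function(cfg, scale) {
  nch <- max(2L, ceiling(cfg$n_chrom * scale))
  cfg$n_markers <- round(cfg$n_markers * nch / cfg$n_chrom)
  cfg$n_polygenic <- round(cfg$n_polygenic * nch / cfg$n_chrom)
  cfg$n_chrom <- nch
  cfg$n_replicates <- max(3L, round(cfg$n_replicates * scale))
  cfg$n_perm <- max(20L, round(cfg$n_perm * scale))
  cfg$qtl_major <- cfg$qtl_major[
    as.integer(cfg$qtl_major$chromosome) <= nch, , drop = FALSE]
  cfg
}

#' Desk-scale preset
#'
#' The reduced design used for quick end-to-end reproduction: 2 chromosomes
#' (~1400 markers, 194 cM), 5 replicates per diversity level,
#' 50-permutation thresholds; 2 major QTLs (chr 1 at 67.88, chr 2 at
#' 61.2 cM) and 20 polygenic loci.
#'
#' @param seed base seed.
#' @param ... further overrides.
#' @return A `pq_config`.
#' @export
desk_config <- function(seed = 1, ...) {
  experiment_config(scale = 0.4, n_chrom = 2, n_markers = 1404,
                    n_polygenic = 20, n_replicates = 5, n_perm = 50,
                    seed = seed, ...)
}

# marker systems for one population; only the requested models are built
.encode_models <- function(nam, models, window, overlap) {
  enc <- list()
  if ("snp" %in% models) {
    dos <- snp_dosages(nam)
    enc$snp <- list(design = scan_design(dos, nam$map, model = "snp"),
                    K = kinship_for(dos, nam$map))
  }
  if ("ibd" %in% models) {
    ma <- ibd_loci(nam)
    enc$ibd <- list(design = scan_design(ma, model = "ibd"),
                    K = kinship_for(ma))
  }
  if ("hap" %in% models) {
    ma <- build_haploblocks(nam, window, overlap)
    enc$hap <- list(design = scan_design(ma, model = "hap"),
                    K = kinship_for(ma))
  }
  enc
}

#' Run the full power-evaluation experiment
#'
#' Simulates the ancestral-group pool once, then for every (diversity
#' level, replicate) builds a NAM population with additive phenotypes, runs
#' the EMMAX scan under each marker system with its matched kinship, uses a
#' permutation threshold computed on the first replicate of each
#' (diversity, model) pair (thresholds change little between populations),
#' sweeps the linking distance and scores every power metric against the
#' simulated truth. Deterministic given `cfg$seed`.
#'
#' @param cfg a [experiment_config()] / [desk_config()].
#' @param progress print per-population progress lines.
#' @return A `power_experiment` list: `results` (one row per population x
#'   model x l), `thresholds`, `truth`, `config`.
#' @export
run_experiment <- function(cfg, progress = FALSE) {
  stopifnot(inherits(cfg, "pq_config"))
  set.seed(cfg$seed)
  map <- synthetic_map(cfg$n_markers, cfg$chrom_lengths[seq_len(cfg$n_chrom)])
  ags <- simulate_ag_pool(cfg$n_ag, map, cfg$n_founders, cfg$generations,
                          cfg$ag_size, cfg$ploidy)
  qtls <- qtl_spec(cfg$qtl_major, n_polygenic = cfg$n_polygenic, map = map)
  # effects sit at the nearest map marker; score against realized positions
  truth <- qtl_positions(qtls, map)

  thresholds <- list()
  rows <- list()
  for (di in seq_along(cfg$diversity_levels)) {
    dv <- cfg$diversity_levels[di]
    for (rep_i in seq_len(cfg$n_replicates)) {
      set.seed(cfg$seed + 1000L * di + rep_i)
      nam <- build_nam(ags, dv, cfg$n_peripheral, cfg$offspring_per_cross)
      eff <- assign_effects(nam, qtls, cfg$sigma_ag, cfg$sigma_within,
                            cfg$polygenic_fraction, cfg$h2)
      y <- phenotype(nam, eff)
      enc <- .encode_models(nam, cfg$models, cfg$window, cfg$overlap)
      for (mod in cfg$models) {
        e <- enc[[mod]]
        vc <- reml_null(y, e$K)
        key <- paste(dv, mod, sep = ":")
        if (is.null(thresholds[[key]])) {
          th <- permutation_threshold(e$design, y, e$K,
                                      n_perm = cfg$n_perm, alpha = cfg$alpha)
          thresholds[[key]] <- data.frame(diversity = dv, model = mod,
                                          alpha = cfg$alpha,
                                          n_perm = cfg$n_perm,
                                          threshold = th$threshold)
        }
        thr <- thresholds[[key]]$threshold
        scan <- scan_qtl(e$design, y, e$K, vc = vc)
        for (l in cfg$l_grid) {
          pr <- power_report(scan, thr, truth, l, cfg$truth_window)
          rows[[length(rows) + 1L]] <-
            cbind(data.frame(diversity = dv, replicate = rep_i), pr)
        }
      }
      if (progress)
        message(sprintf("diversity %d replicate %d done", dv, rep_i))
    }
  }
  structure(list(results = do.call(rbind, rows),
                 thresholds = do.call(rbind, thresholds),
                 truth = truth, config = cfg),
            class = "power_experiment")
}

#' Aggregate an experiment over replicates
#'
#' Unweighted mean of each metric over replicate populations, per
#' (diversity, model, l); undefined (`NA`) cells are dropped from their
#' mean rather than counted as zero.
#'
#' @param exp_ a `power_experiment`.
#' @return data.frame of per-(diversity, model, l) means.
#' @export
summarize_experiment <- function(exp_) {
  res <- exp_$results
  agg <- stats::aggregate(
    res[c("detection_power", "false_positive_rate", "qtl_precision",
          "marker_precision", "peak_accuracy_cM")],
    by = res[c("diversity", "model", "l")],
    FUN = function(x) mean(x, na.rm = TRUE))
  agg[order(agg$model, agg$diversity, agg$l), ]
}
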