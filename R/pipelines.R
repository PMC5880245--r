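# Canned whole-pipeline experiments. Each function wires the simulator to
# the analysis stages under one fixed set of study conditions, so that the
# same computation backs both the test suite and reproduction scripts.

#' Null calibration of the strain-sharing cutoff
#'
#' Simulates a cohort with no inter-family transmission (unrelated
#' individuals share only population-level variation), computes symmetric
#' rmSNV similarity for a large set of unrelated sample pairs across all
#' species, and reports how often the strain-sharing cutoff is exceeded --
#' the empirical false-discovery rate of the call.
#'
#' @param n_background background individuals.
#' @param n_families two-parent families (one vaginally born neonate each).
#' @param pairs_per_species unrelated sample pairs evaluated per species.
#' @param cutoff strain-sharing cutoff.
#' @param seed RNG seed (drives both simulation and pair sampling).
#' @return list with `sharing` (the pair table), `n_defined`,
#'   `exceedance_pct` (percentage of defined similarities above `cutoff`),
#'   `mean_similarity_pct` and `calibration` (a [calibrate_cutoff()] table).
#' @export
null_calibration_experiment <- function(n_background = 100, n_families = 20,
                                        pairs_per_species = 250,
                                        cutoff = 0.2, seed = 1) {
  cfg <- cohort_config(n_background = n_background, n_families = n_families,
                       child_sample_ages = c(4), seed = seed)
  sim <- simulate_cohort(cfg)
  set.seed(seed + 1L)
  pairs <- sample_pairs(sim$metadata, "unrelated",
                        max_pairs = pairs_per_species)
  sh <- sharing_table(sim$snv, sim$metadata, pairs, coverage = sim$coverage,
                      cutoff = cutoff)
  def <- sh$sim_sym[!is.na(sh$sim_sym)]
  list(sharing = sh,
       n_defined = length(def),
       exceedance_pct = 100 * mean(def > cutoff),
       mean_similarity_pct = 100 * mean(def),
       calibration = calibrate_cutoff(sh$sim_sym,
                                      cutoffs = c(0.1, cutoff, 0.3)))
}

#' Maternal-seeding detection under copy-at-birth transmission
#'
#' Simulates vaginally delivering families whose transmissible-class
#' (Actinobacteria, Bacteroidia) maternal strains are copied to the neonate
#' at birth with probability 1, under the default observation noise, then
#' classifies every neonate's strain populations from the first neonatal
#' sample and summarizes detection per class.
#'
#' @param n_families vaginal mother-father-neonate families.
#' @param n_background background individuals forming the reference
#'   population.
#' @param seed RNG seed.
#' @return list with `labels` (classification table), `sharing`
#'   (mother-neonate comparisons), `fractions` (per class: fraction of
#'   neonates with tracked species labeled maternal) and
#'   `median_similarity_pct` (cohort median mother-neonate rmSNV similarity
#'   over transmissible classes, in %).
#' @export
maternal_seeding_experiment <- function(n_families = 50, n_background = 100,
                                        seed = 1) {
  cfg <- cohort_config(n_background = n_background, n_families = n_families,
                       child_sample_ages = c(4), seed = seed)
  sim <- simulate_cohort(cfg)
  m <- as.data.frame(sim$metadata)
  kids <- unique(m$individual_id[m$role == "child"])
  pairs <- do.call(rbind, lapply(kids, function(k) {
    fam <- m$family_id[m$individual_id == k][1]
    data.frame(sample_a = m$sample_id[m$individual_id == k][1],
               sample_b = m$sample_id[m$family_id == fam &
                                        m$role == "mother"][1])
  }))
  sh <- sharing_table(sim$snv, sim$metadata, pairs, coverage = sim$coverage)
  labels <- classify_maternal_cohort(sh, sim$metadata)
  cls <- sim$truth$species_class
  fractions <- sapply(c("Actinobacteria", "Bacteroidia", "Clostridia"),
                      function(cl) class_maternal_fraction(
                        labels, cls, cl, sim$metadata)$fraction)
  transmissible <- cls[sh$species] %in% c("Actinobacteria", "Bacteroidia")
  med <- median(sh$sim_sym[transmissible], na.rm = TRUE)
  list(labels = labels, sharing = sh, fractions = fractions,
       median_similarity_pct = 100 * med, truth = sim$truth)
}

#' Annual strain-replacement recovery on longitudinal adults
#'
#' Simulates adults sampled three times at gaps of 0.5 to 3 years with the
#' default annual replacement rate, computes intra-individual symmetric
#' rmSNV similarity between consecutive time points (non-overlapping
#' intervals, so each record is an independent replacement opportunity),
#' and estimates the annual change with [annual_change()].
#'
#' @param n_individuals longitudinal adults per replicate cohort.
#' @param n_species how many of the default species to simulate.
#' @param annual_drift simulated annual replacement rate.
#' @param n_boot bootstrap replicates for the confidence interval.
#' @param n_replicates independent replicate cohorts whose records are
#'   pooled before estimation (individuals are independent across cohorts,
#'   so pooling only adds precision while keeping each simulated SNV matrix
#'   small).
#' @param seed RNG seed.
#' @return the [annual_change()] result, plus `records` and
#'   `simulated_rate_pct`.
#' @export
drift_recovery_experiment <- function(n_individuals = 250, n_species = 3,
                                      annual_drift = 0.13, n_boot = 500,
                                      n_replicates = 1, seed = 1) {
  records <- list()
  for (r in seq_len(n_replicates)) {
    cfg <- cohort_config(
      n_background = n_individuals, n_families = 0,
      background_timepoints = 3, background_gap_range = c(0.5, 3),
      species_spec = default_species_spec()[seq_len(n_species), ],
      annual_drift = annual_drift, seed = seed + (r - 1L) * 1009L)
    sim <- simulate_cohort(cfg)
    m <- as.data.frame(sim$metadata)
    pairs <- do.call(rbind, lapply(split(m, m$individual_id), function(d) {
      d <- d[order(d$age_days), ]
      data.frame(sample_a = d$sample_id[-nrow(d)], sample_b = d$sample_id[-1])
    }))
    sh <- sharing_table(sim$snv, sim$metadata, pairs, coverage = sim$coverage)
    pc <- persistence_curve(sh, sim$metadata)
    rec <- pc$records
    rec$individual_id <- paste0("rep", r, "_", rec$individual_id)
    records[[r]] <- rec
  }
  records <- do.call(rbind, records)
  set.seed(seed + 2L)
  ac <- annual_change(records, n_boot = n_boot)
  c(ac, list(records = records,
             simulated_rate_pct = 100 * annual_drift))
}
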