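# Brute-force oracles and tiny fixture builders. The oracles re-derive every
# quantity by exhaustive looping over sites and samples, independently of the
# package's vectorized/indexed implementations.

# metadata for a hand-built cohort: one row per sample
make_meta <- function(sample_id, individual_id, family_id,
                      age_days = seq_along(sample_id) * 100,
                      role = "mother", delivery_mode = "not_applicable",
                      collection_day = NULL) {
  d <- data.frame(sample_id = sample_id, individual_id = individual_id,
                  family_id = family_id, age_days = age_days,
                  delivery_mode = delivery_mode, role = role)
  if (!is.null(collection_day)) d$collection_day <- collection_day
  cohort_metadata(d)
}

# random small SNV matrix with missingness
random_snv <- function(n_pos, samples, p_missing = 0.2, species = "spX") {
  v <- matrix(round(runif(n_pos * length(samples)), 3),
              n_pos, length(samples))
  v[runif(length(v)) < p_missing] <- NA
  rownames(v) <- sprintf("c1:%d:A>G", seq_len(n_pos))
  colnames(v) <- samples
  snv_matrix(v, species)
}

oracle_present <- function(x, min_freq = 0.05) !is.na(x) && x >= min_freq

# exhaustive marker identification: triple loop over sites, reference
# samples, and (for emsnv) family samples
oracle_markers <- function(snv, focal, other, metadata, variant = "rmsnv",
                           min_freq = 0.05) {
  v <- unclass(snv)
  m <- as.data.frame(metadata)
  ind_of <- setNames(m$individual_id, m$sample_id)
  fam_of <- setNames(m$family_id, m$sample_id)
  pair_ind <- c(ind_of[[focal]], ind_of[[other]])
  pair_fam <- unique(c(fam_of[[focal]], fam_of[[other]]))
  ref_samples <- m$sample_id[!(m$family_id %in% pair_fam)]
  fam_samples <- m$sample_id[m$family_id %in% pair_fam &
                               !(m$individual_id %in% pair_ind)]
  out <- character(0)
  for (pos in rownames(v)) {
    if (!oracle_present(v[pos, focal], min_freq)) next
    in_ref <- FALSE
    for (s in ref_samples)
      if (s %in% colnames(v) && oracle_present(v[pos, s], min_freq)) {
        in_ref <- TRUE; break
      }
    if (in_ref) next
    if (variant == "emsnv") {
      in_fam <- FALSE
      for (s in fam_samples)
        if (s %in% colnames(v) && oracle_present(v[pos, s], min_freq)) {
          in_fam <- TRUE; break
        }
      if (in_fam) next
    }
    out <- c(out, pos)
  }
  out
}

# exhaustive directional similarity from a marker list
oracle_similarity <- function(snv, markers, other, min_freq = 0.05,
                              min_markers = 100) {
  v <- unclass(snv)
  den <- num <- 0
  for (pos in markers) {
    if (is.na(v[pos, other])) next
    den <- den + 1
    if (oracle_present(v[pos, other], min_freq)) num <- num + 1
  }
  list(n = den, sim = if (den > min_markers) num / den else NA_real_)
}

oracle_symmetric <- function(d1, d2) {
  s <- c(d1$sim, d2$sim); w <- c(d1$n, d2$n)
  def <- !is.na(s)
  if (!any(def)) NA_real_ else sum(s[def] * w[def]) / sum(w[def])
}

# exhaustive novel-SNV scan
oracle_novel <- function(snv, now, earlier, min_freq = 0.05) {
  v <- unclass(snv)
  out <- character(0)
  for (pos in rownames(v)) {
    if (!oracle_present(v[pos, now], min_freq)) next
    covered <- FALSE; seen <- FALSE
    for (s in earlier) {
      if (!is.na(v[pos, s])) covered <- TRUE
      if (oracle_present(v[pos, s], min_freq)) seen <- TRUE
    }
    if (covered && !seen) out <- c(out, pos)
  }
  out
}

# a small simulated cohort reused by several test files (lazy, cached)
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- cohort_config(n_background = 12, n_families = 3,
                           children_per_family = 2,
                           species_spec = default_species_spec(n_sites = 60)[c(1, 3, 5), ],
                           private_variant_rate = 0.2,
                           child_sample_ages = c(4, 365), seed = 421)
      cache <<- simulate_cohort(cfg)
    }
    cache
  }
})
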