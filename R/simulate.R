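# Synthetic family-cohort simulator with ground truth.
#
# The generative model, per species:
#   1. population alternative-allele frequencies for the common sites are
#      drawn from a Beta distribution (skewed minor-allele spectrum);
#   2. every founding strain samples each common site independently at the
#      population frequency and additionally receives a block of private
#      alleles drawn from a disjoint monomorphic site pool, so private
#      alleles are structurally exclusive to their strain;
#   3. vaginally born children copy the mother's strain haplotypes at birth
#      for species whose class passes a Bernoulli(p_vertical) draw and
#      otherwise receive a fresh environmental strain; Caesarean-born
#      children start with environmental strains and may acquire the
#      maternal strain postnatally (as a two-strain mixture);
#   4. between consecutive samples, a strain population is wholly replaced
#      with probability 1 - (1 - delta)^dt (delta = annual drift), by an
#      environmental strain or, optionally, a family member's current one;
#   5. observation: per sample, vertical coverage follows a Gamma around the
#      abundance-scaled mean depth; horizontal coverage is 1 - exp(-vc);
#      each site is covered with that probability and covered sites report
#      the carried-strain mixture fraction under binomial read sampling at
#      a Poisson site depth, floored to 0 below the detection threshold;
#      uncovered sites are MISSING.
# Every transmission, replacement and private-allele set is recorded in the
# returned ground truth.

#' Default species specification
#'
#' Five species spanning the three dominant gut classes; class-level
#' abundance weights differ between infants (< 2 yr) and older individuals,
#' mirroring the Actinobacteria/Bacteroidia-dominated infant gut versus the
#' Clostridia/Bacteroidia-dominated adult gut.
#'
#' @param n_sites number of common (polymorphic) sites per species.
#' @return data frame with columns `species_id`, `class`, `n_sites`.
#' @export
default_species_spec <- function(n_sites = 800) {
  data.frame(
    species_id = c("Bifidobacterium_sim", "Collinsella_sim",
                   "Bacteroides_sim1", "Bacteroides_sim2", "Clostridium_sim"),
    class = c("Actinobacteria", "Actinobacteria", "Bacteroidia",
              "Bacteroidia", "Clostridia"),
    n_sites = n_sites)
}

# class-level abundance weights (infant = < 2 yr at sampling)
.CLASS_ABUNDANCE <- cbind(
  infant = c(Actinobacteria = 0.35, Bacteroidia = 0.30, Clostridia = 0.08,
             other = 0.05),
  adult = c(Actinobacteria = 0.04, Bacteroidia = 0.50, Clostridia = 0.34,
            other = 0.05))

#' Simulation configuration
#'
#' Collects every tunable of [simulate_cohort()] with the package defaults.
#' Probabilities are in \eqn{[0, 1]}; `annual_drift` is the expected
#' fraction of a strain population replaced per year; the number of private
#' alleles per founding strain is `round(private_variant_rate * n_sites)`
#' and must comfortably exceed the >100 marker-position filter for sharing
#' to be assessable.
#'
#' @param n_background unrelated single-adult background individuals.
#' @param n_families number of families (father, mother, children).
#' @param children_per_family children per family (recycled).
#' @param delivery_mode `"vaginal"` or `"caesarean"` per family (recycled).
#' @param twins logical per family: children are co-twins (recycled).
#' @param species_spec see [default_species_spec()].
#' @param allele_freq_params shape1/shape2 of the Beta population
#'   minor-allele-frequency distribution.
#' @param private_variant_rate fraction of common sites privately mutated
#'   per founding strain.
#' @param p_vertical named per-class probability that a species' maternal
#'   strain population is copied to a vaginally born neonate at birth.
#' @param annual_drift expected fraction of strain-defining alleles
#'   replaced per year (whole-strain replacement model).
#' @param csection_acquisition_rate per-month probability that a
#'   Caesarean-born infant acquires the maternal strain of a transmissible
#'   species postnatally.
#' @param family_replacement_prob probability that a replacement strain is
#'   copied from a family member rather than the environment.
#' @param donor_role_weights relative donor weights by role when a family
#'   member sources a replacement.
#' @param depth_mean mean vertical coverage (x) at average abundance.
#' @param depth_shape Gamma shape of the depth noise.
#' @param detect_threshold minimum observed frequency treated as nonzero.
#' @param noise_free TRUE replaces the observation layer by exact reporting
#'   (full coverage, exact mixture fractions); used for analytic checks.
#' @param child_sample_ages child sampling ages in days.
#' @param background_timepoints samples per background individual.
#' @param background_gap_range uniform range (years) between consecutive
#'   background samples.
#' @param background_age_range age (days) at first background sample.
#' @param parent_age_range parent age (days) at the first child's birth.
#' @param sibling_spacing_days birth spacing of non-twin siblings.
#' @param seed integer RNG seed used by [simulate_cohort()].
#' @return a list of class `cohort_config`.
#' @export
cohort_config <- function(n_background = 100,
                          n_families = 20,
                          children_per_family = 1,
                          delivery_mode = "vaginal",
                          twins = FALSE,
                          species_spec = default_species_spec(),
                          allele_freq_params = c(0.5, 5),
                          private_variant_rate = 0.1875,
                          p_vertical = c(Actinobacteria = 1, Bacteroidia = 1,
                                         Clostridia = 0, other = 0.5),
                          annual_drift = 0.13,
                          csection_acquisition_rate = 0.08,
                          family_replacement_prob = 0,
                          donor_role_weights = c(mother = 1, father = 1,
                                                 child = 1),
                          depth_mean = 20,
                          depth_shape = 10,
                          detect_threshold = 0.05,
                          noise_free = FALSE,
                          child_sample_ages = c(4, 120, 365),
                          background_timepoints = 1,
                          background_gap_range = c(0.5, 3),
                          background_age_range = c(25, 55) * 365,
                          parent_age_range = c(25, 40) * 365,
                          sibling_spacing_days = 730,
                          seed = 1) {
  cfg <- as.list(environment())
  probs <- c(cfg$p_vertical, cfg$annual_drift, cfg$csection_acquisition_rate,
             cfg$family_replacement_prob, cfg$private_variant_rate)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (cfg$n_families > 0 && cfg$children_per_family < 1)
    stop("families must have at least one child (a child needs a mother)")
  k <- round(cfg$private_variant_rate * cfg$species_spec$n_sites)
  if (any(k < 1)) stop("private_variant_rate too small: no private alleles")
  class(cfg) <- "cohort_config"
  cfg
}

.build_cohort_frame <- function(cfg) {
  rows <- list()
  add <- function(ind, fam, role, mode, twin, day, age) {
    k <- length(rows) + 1
    rows[[k]] <<- data.frame(
      sample_id = sprintf("%s_t%d", ind, seq_along(day)),
      individual_id = ind, family_id = fam, age_days = age,
      delivery_mode = mode, role = role, twin_group = twin,
      collection_day = day, birth_event = c(NA_real_))
  }
  if (cfg$n_background > 0) {
    roles <- rep(c("mother", "father"), length.out = cfg$n_background)
    for (i in seq_len(cfg$n_background)) {
      ind <- sprintf("bg%03d", i)
      age0 <- runif(1, cfg$background_age_range[1], cfg$background_age_range[2])
      gaps <- if (cfg$background_timepoints > 1)
        runif(cfg$background_timepoints - 1,
              cfg$background_gap_range[1], cfg$background_gap_range[2]) * 365.25
      else numeric(0)
      days <- cumsum(c(0, gaps))
      add(ind, paste0("bgfam", i), roles[i], "not_applicable",
          NA_character_, days, age0 + days)
    }
  }
  modes <- rep(cfg$delivery_mode, length.out = max(cfg$n_families, 1))
  twins <- rep(cfg$twins, length.out = max(cfg$n_families, 1))
  births <- list()
  for (f in seq_len(cfg$n_families)) {
    fam <- sprintf("fam%03d", f)
    for (p in c("father", "mother")) {
      ind <- paste0(fam, "_", substr(p, 1, 3))
      age0 <- runif(1, cfg$parent_age_range[1], cfg$parent_age_range[2])
      add(ind, fam, p, "not_applicable", NA_character_, 3, age0 + 3)
    }
    for (ch in seq_len(cfg$children_per_family)) {
      ind <- sprintf("%s_ch%d", fam, ch)
      birth <- if (twins[f]) 0 else (ch - 1) * cfg$sibling_spacing_days
      tw <- if (twins[f] && cfg$children_per_family > 1)
        paste0(fam, "_tw") else NA_character_
      add(ind, fam, "child", modes[f], tw,
          birth + cfg$child_sample_ages, cfg$child_sample_ages)
      births[[ind]] <- birth
    }
  }
  frame <- do.call(rbind, rows)
  frame$birth_event <- NULL
  list(frame = frame, births = births)
}

.simulate_species <- function(sp, cls, n_common, cfg, meta, births) {
  p_pop <- rbeta(n_common, cfg$allele_freq_params[1], cfg$allele_freq_params[2])
  k_priv <- round(cfg$private_variant_rate * n_common)
  env <- new.env(parent = emptyenv())
  env$cursor <- 0L
  env$strains <- list()
  new_strain <- function(owner, origin) {
    uid <- sprintf("%s.s%d", sp, length(env$strains) + 1L)
    priv <- env$cursor + seq_len(k_priv)
    env$cursor <- env$cursor + k_priv
    env$strains[[uid]] <- list(uid = uid, owner = owner, origin = origin,
                               common = runif(n_common) < p_pop, private = priv)
    uid
  }
  states <- list()   # individual -> list of list(day, uids, weights)
  events <- list()
  log_event <- function(ind, day, origin, donor, uids) {
    events[[length(events) + 1]] <<- data.frame(
      individual_id = ind, species_id = sp, day = day, origin = origin,
      donor = donor %||% NA_character_,
      strain_uid = paste(uids, collapse = ","))
  }
  set_state <- function(ind, day, uids, weights)
    states[[ind]][[length(states[[ind]]) + 1L]] <<-
      list(day = day, uids = uids, weights = weights)
  state_at <- function(ind, day) {
    st <- states[[ind]]
    if (is.null(st)) return(NULL)
    days <- vapply(st, `[[`, 0, "day")
    ok <- which(days <= day)
    if (!length(ok)) NULL else st[[max(ok)]]
  }
  p_vert <- function() {
    pv <- cfg$p_vertical
    if (cls %in% names(pv)) unname(pv[[cls]]) else unname(pv[["other"]] %||% 0)
  }
  replace_maybe <- function(ind, fam_members, day_prev, day_now) {
    dt <- (day_now - day_prev) / 365.25
    if (dt <= 0 || runif(1) >= 1 - (1 - cfg$annual_drift)^dt) return(FALSE)
    donor <- NULL
    if (length(fam_members) && runif(1) < cfg$family_replacement_prob) {
      w <- cfg$donor_role_weights[fam_members$role]
      w[is.na(w)] <- 0
      if (sum(w) > 0) {
        pick <- sample(seq_len(nrow(fam_members)), 1, prob = w)
        donor <- fam_members$individual_id[pick]
      }
    }
    if (!is.null(donor)) {
      ds <- state_at(donor, day_now)
      if (!is.null(ds)) {
        set_state(ind, day_now, ds$uids, ds$weights)
        log_event(ind, day_now, "family_replacement", donor, ds$uids)
        return(TRUE)
      }
    }
    uid <- new_strain(ind, "environmental")
    set_state(ind, day_now, uid, 1)
    log_event(ind, day_now, "environmental_replacement", NULL, uid)
    TRUE
  }

  m <- meta
  inds <- unique(m$individual_id)
  # fixed processing order: background, then per family father, mother,
  # children by birth day (so donors are resolvable when copying states)
  fam_of <- .individual_families(m)
  role_of <- setNames(m$role[!duplicated(m$individual_id)],
                      m$individual_id[!duplicated(m$individual_id)])
  ord <- order(match(fam_of[inds], unique(fam_of[inds])),
               match(role_of[inds], c("father", "mother", "child")))
  for (ind in inds[ord]) {
    own <- m[m$individual_id == ind, ]
    own <- own[order(own$collection_day), ]
    fam_members <- m[m$family_id == own$family_id[1] &
                       m$individual_id != ind, ]
    fam_members <- fam_members[!duplicated(fam_members$individual_id),
                               c("individual_id", "role")]
    if (role_of[[ind]] != "child") {
      uid <- new_strain(ind, "founding")
      set_state(ind, own$collection_day[1], uid, 1)
      log_event(ind, own$collection_day[1], "founding", NULL, uid)
      prev <- own$collection_day[1]
      for (k in seq_len(nrow(own))[-1]) {
        replace_maybe(ind, fam_members, prev, own$collection_day[k])
        prev <- own$collection_day[k]
      }
    } else {
      birth <- births[[ind]]
      mom <- fam_members$individual_id[fam_members$role == "mother"]
      mode <- own$delivery_mode[1]
      maternal <- FALSE
      if (mode == "vaginal" && length(mom) && runif(1) < p_vert()) {
        ms <- state_at(mom[1], birth)
        if (is.null(ms)) ms <- state_at(mom[1], Inf)  # mother founded at her sample
        set_state(ind, birth, ms$uids, ms$weights)
        log_event(ind, birth, "maternal_birth", mom[1], ms$uids)
        maternal <- TRUE
      } else {
        uid <- new_strain(ind, "environmental")
        set_state(ind, birth, uid, 1)
        log_event(ind, birth, "environmental_birth", NULL, uid)
      }
      prev <- birth
      for (day in own$collection_day) {
        if (day > prev) {
          replaced <- replace_maybe(ind, fam_members, prev, day)
          if (replaced) maternal <- FALSE
          if (!maternal && mode == "caesarean" && length(mom) && p_vert() > 0) {
            months <- (day - prev) / 30.44
            if (runif(1) < 1 - (1 - cfg$csection_acquisition_rate)^months) {
              ms <- state_at(mom[1], day)
              if (!is.null(ms)) {
                cur <- state_at(ind, day)
                wm <- rbeta(1, 2, 2)
                set_state(ind, day, c(cur$uids, ms$uids),
                          c(cur$weights * (1 - wm), ms$weights * wm))
                log_event(ind, day, "maternal_postnatal", mom[1], ms$uids)
                maternal <- TRUE
              }
            }
          }
        }
        prev <- day
      }
    }
  }

  # --- observation layer ---
  n_total <- n_common + env$cursor
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_total, replace = TRUE)
  alt <- bases[(match(ref, bases) - 1 + sample(1:3, n_total, TRUE)) %% 4 + 1]
  pos_ids <- sprintf("%s_c1:%d:%s>%s", sp, seq_len(n_total), ref, alt)
  samples <- m$sample_id[order(m$collection_day, m$sample_id)]
  vals <- matrix(NA_real_, n_total, length(samples),
                 dimnames = list(pos_ids, samples))
  cov_rows <- vector("list", length(samples))
  carried <- list()
  mean_ab <- list()
  for (period in colnames(.CLASS_ABUNDANCE)) {
    cw <- .CLASS_ABUNDANCE[, period]
    spw <- cw[cfg$species_spec$class]
    spw[is.na(spw)] <- cw[["other"]]
    spw <- spw / table(cfg$species_spec$class)[cfg$species_spec$class]
    mean_ab[[period]] <- mean(spw)
  }
  cls_w <- function(period) {
    cw <- .CLASS_ABUNDANCE[, period]
    w <- if (cls %in% names(cw)) cw[[cls]] else cw[["other"]]
    w / sum(cfg$species_spec$class == cls)
  }
  for (j in seq_along(samples)) {
    row <- m[m$sample_id == samples[j], ]
    period <- if (row$age_days < 730) "infant" else "adult"
    target <- cfg$depth_mean * cls_w(period) / mean_ab[[period]]
    if (cfg$noise_free) {
      vc <- target; h <- 1
    } else {
      vc <- rgamma(1, shape = cfg$depth_shape,
                   scale = target / cfg$depth_shape)
      h <- 1 - exp(-vc)
    }
    st <- state_at(row$individual_id, row$collection_day)
    w <- numeric(n_total)
    for (i in seq_along(st$uids)) {
      s <- env$strains[[st$uids[i]]]
      w[seq_len(n_common)] <- w[seq_len(n_common)] + st$weights[i] * s$common
      w[n_common + s$private] <- w[n_common + s$private] + st$weights[i]
    }
    carried[[samples[j]]] <- st
    if (cfg$noise_free) {
      f <- w
      f[f < cfg$detect_threshold] <- 0
      vals[, j] <- f
    } else {
      covered <- runif(n_total) < h
      col <- rep(NA_real_, n_total)
      col[covered] <- 0
      hot <- which(covered & w > 0)
      if (length(hot)) {
        d <- pmax(rpois(length(hot), vc), 1L)
        f <- rbinom(length(hot), d, w[hot]) / d
        f[f < cfg$detect_threshold] <- 0
        col[hot] <- f
      }
      vals[, j] <- col
    }
    cov_rows[[j]] <- data.frame(species_id = sp, sample_id = samples[j],
                                vertical_coverage = vc,
                                horizontal_coverage = if (vc > 0) h else 0)
  }
  list(snv = snv_matrix(vals, sp),
       coverage = do.call(rbind, cov_rows),
       events = if (length(events)) do.call(rbind, events) else NULL,
       strains = env$strains, carried = carried,
       n_common = n_common, position_ids = pos_ids)
}

#' Simulate a synthetic family cohort
#'
#' Runs the generative model described in the package overview and returns
#' the three analysis inputs (per-species SNV matrices, coverage table,
#' metadata) together with the full ground truth.
#'
#' @param config a [cohort_config()].
#' @return list with elements `snv` (named list of [snv_matrix()]),
#'   `coverage`, `metadata` (a [cohort_metadata()] with `collection_day`),
#'   `truth` (list: `events`, `strains`, `carried`, `species_class`) and
#'   `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  built <- .build_cohort_frame(config)
  meta <- built$frame
  snv <- list()
  coverage <- list()
  events <- list()
  strains <- list()
  carried <- list()
  for (r in seq_len(nrow(config$species_spec))) {
    sp <- config$species_spec$species_id[r]
    res <- .simulate_species(sp, config$species_spec$class[r],
                             config$species_spec$n_sites[r], config,
                             meta, built$births)
    snv[[sp]] <- res$snv
    coverage[[sp]] <- res$coverage
    events[[sp]] <- res$events
    strains[[sp]] <- res$strains
    carried[[sp]] <- res$carried
  }
  list(snv = snv,
       coverage = validate_coverage_table(do.call(rbind, coverage)),
       metadata = cohort_metadata(meta),
       truth = list(events = do.call(rbind, events),
                    strains = strains, carried = carried,
                    species_class = setNames(config$species_spec$class,
                                             config$species_spec$species_id)),
       config = config)
}

#' Summarize simulated ground truth
#'
#' One row per (individual, species, strain interval): the origin of the
#' strain population, when it was established, and when (if ever) it was
#' replaced.
#'
#' @param truth the `truth` element of a [simulate_cohort()] result.
#' @return data frame with columns `individual_id`, `species_id`,
#'   `start_day`, `end_day` (NA while still carried), `origin`, `donor`,
#'   `replaced`; origin counts are attached as attribute `totals`.
#' @export
summarize_ground_truth <- function(truth) {
  ev <- truth$events
  out <- lapply(split(ev, paste(ev$individual_id, ev$species_id, sep = "\r")),
                function(d) {
    d <- d[order(d$day), ]
    n <- nrow(d)
    data.frame(individual_id = d$individual_id, species_id = d$species_id,
               start_day = d$day,
               end_day = c(if (n > 1) d$day[-1], NA_real_),
               origin = d$origin, donor = d$donor,
               replaced = c(if (n > 1) rep(TRUE, n - 1), FALSE))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  structure(out, totals = table(out$origin))
}

#' Ground-truth private alleles of an individual
#'
#' Position ids of private alleles carried by strains owned by the
#' individual, per species.
#'
#' @param truth `truth` element of [simulate_cohort()].
#' @param sim the full [simulate_cohort()] result (for position ids).
#' @param individual individual id.
#' @param species species id.
#' @return character vector of position ids.
#' @export
private_positions <- function(truth, sim, individual, species) {
  st <- truth$strains[[species]]
  own <- Filter(function(s) s$owner == individual, st)
  idx <- unlist(lapply(own, `[[`, "private"), use.names = FALSE)
  nc <- sim$config$species_spec$n_sites[
    sim$config$species_spec$species_id == species]
  rownames(sim$snv[[species]])[nc + idx]
}

#' Write a simulated cohort to TSV files
#'
#' Emits one SNV table per species plus `coverage.tsv`, `metadata.tsv` and
#' `ground_truth.tsv` into a directory.
#'
#' @param sim a [simulate_cohort()] result.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (sp in names(sim$snv))
    write_snv_table(sim$snv[[sp]], file.path(dir, paste0("snv_", sp, ".tsv")))
  write_coverage_table(sim$coverage, file.path(dir, "coverage.tsv"))
  write_cohort_metadata(sim$metadata, file.path(dir, "metadata.tsv"))
  write.table(sim$truth$events, file.path(dir, "ground_truth.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
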