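# Maternal-strain classification, persistence and drift, and novel-SNV
# based transmission directionality within families.

#' Classify a child's strain populations as maternal or not
#'
#' Per species, the child's strain population is classified from the FIRST
#' available child sample: *maternal* when the symmetric rmSNV similarity to
#' the mother exceeds the strain-sharing cutoff, *nonmaternal* when it is
#' defined and at or below the cutoff, *untracked* when undefined. The label
#' is assigned once and kept through all later time points, even if
#' similarity to the mother later rises.
#'
#' The mother's comparison sample is her sample nearest in time to the
#' child's first sample when `collection_day` is present in the metadata,
#' otherwise her earliest sample (cohorts typically sample mothers once,
#' near birth).
#'
#' @param child,mother individual ids.
#' @param sharing a [sharing_table()] result containing the child-mother
#'   sample comparisons (symmetric similarities in `sim_sym`).
#' @param metadata [cohort_metadata()].
#' @param cutoff strain-sharing cutoff, default 0.2.
#' @return data frame with one row per species: `child`, `species`, `label`
#'   (`maternal` / `nonmaternal` / `untracked`), `similarity`, `assigned_at`
#'   (the child sample id used).
#' @export
classify_maternal <- function(child, mother, sharing, metadata, cutoff = 0.2) {
  m <- as.data.frame(metadata)
  cs <- m[m$individual_id == child, ]
  ms <- if (is.na(mother)) m[0, ] else m[m$individual_id == mother, ]
  if (!nrow(cs)) stop("no samples for child '", child, "'")
  if (!nrow(ms)) {
    sp <- unique(sharing$species)
    return(data.frame(child = child, species = sp, label = "untracked",
                      similarity = NA_real_, assigned_at = NA_character_,
                      reason = "no mother sample"))
  }
  first_child <- as.character(cs$sample_id[which.min(cs$age_days)])
  if ("collection_day" %in% names(m) && !anyNA(m$collection_day)) {
    day0 <- cs$collection_day[which.min(cs$age_days)]
    mom_sample <- as.character(ms$sample_id[which.min(abs(ms$collection_day - day0))])
  } else {
    mom_sample <- as.character(ms$sample_id[which.min(ms$age_days)])
  }
  hit <- (sharing$sample_a == first_child & sharing$sample_b == mom_sample) |
         (sharing$sample_b == first_child & sharing$sample_a == mom_sample)
  rec <- sharing[hit, ]
  if (!nrow(rec))
    stop("sharing table lacks the comparison of '", first_child,
         "' with '", mom_sample, "'")
  lab <- ifelse(is.na(rec$sim_sym), "untracked",
                ifelse(rec$sim_sym > cutoff, "maternal", "nonmaternal"))
  data.frame(child = child, species = rec$species, label = lab,
             similarity = rec$sim_sym, assigned_at = first_child,
             reason = NA_character_)
}

#' Classify all children of a cohort
#'
#' Applies [classify_maternal()] to every child with a mother in the same
#' family.
#'
#' @inheritParams classify_maternal
#' @return row-bound classification table.
#' @export
classify_maternal_cohort <- function(sharing, metadata, cutoff = 0.2) {
  m <- as.data.frame(metadata)
  u <- m[!duplicated(m$individual_id), ]
  out <- list()
  for (ch in u$individual_id[u$role == "child"]) {
    fam <- u$family_id[u$individual_id == ch]
    mom <- u$individual_id[u$family_id == fam & u$role == "mother"]
    out[[ch]] <- classify_maternal(ch, if (length(mom)) mom[1] else NA_character_,
                                   sharing, metadata, cutoff)
  }
  do.call(rbind, out)
}

#' Intra-individual persistence of strain populations
#'
#' For each later sample of an individual, the symmetric rmSNV similarity to
#' each earlier sample, summarized as the per-individual median within each
#' grouping (e.g. age group of the later sample, taxonomic class, maternal
#' label).
#'
#' @param sharing a [sharing_table()] computed over within-individual sample
#'   pairs (both samples of each pair from the same individual).
#' @param metadata [cohort_metadata()].
#' @param species_class optional named character vector mapping species id
#'   to taxonomic class; adds a `class` grouping column.
#' @param labels optional [classify_maternal_cohort()] table; adds the
#'   frozen maternal label as a grouping column.
#' @return list with `records` (one row per sample pair x species, with
#'   `individual_id`, `gap_years`, `similarity` and grouping columns) and
#'   `medians` (per-individual medians within each grouping).
#' @export
persistence_curve <- function(sharing, metadata, species_class = NULL,
                              labels = NULL) {
  m <- as.data.frame(metadata)
  ia <- match(sharing$sample_a, m$sample_id)
  ib <- match(sharing$sample_b, m$sample_id)
  if (anyNA(ia) || anyNA(ib)) stop("sharing table contains unknown samples")
  if (any(m$individual_id[ia] != m$individual_id[ib]))
    stop("persistence_curve expects within-individual sample pairs")
  rec <- data.frame(
    individual_id = as.character(m$individual_id[ia]),
    species = sharing$species,
    gap_years = abs(m$age_days[ib] - m$age_days[ia]) / 365.25,
    age_group = assign_age_group(pmax(m$age_days[ia], m$age_days[ib])),
    similarity = sharing$sim_sym)
  if (!is.null(species_class))
    rec$class <- unname(species_class[rec$species])
  if (!is.null(labels)) {
    key <- paste(labels$child, labels$species)
    rec$label <- labels$label[match(paste(rec$individual_id, rec$species), key)]
  }
  grp_cols <- intersect(c("age_group", "class", "label"), names(rec))
  rec_def <- rec[!is.na(rec$similarity), ]
  med <- aggregate(rec_def["similarity"],
                   by = rec_def[c("individual_id", grp_cols)],
                   FUN = median)
  names(med)[names(med) == "similarity"] <- "median_similarity"
  list(records = rec, medians = med)
}

#' Annual strain-replacement rate
#'
#' Estimates the average fraction of an individual's strain-defining
#' markers replaced per year, as the slope of a through-origin linear fit
#' of (1 - similarity) against the time gap in years, reported in percent
#' per year with a bootstrap confidence interval over individuals.
#'
#' @param records data frame with columns `individual_id`, `gap_years` and
#'   `similarity` (e.g. `persistence_curve()$records`); NA similarities are
#'   dropped.
#' @param n_boot bootstrap replicates (resampling individuals).
#' @param conf confidence level.
#' @return list with `estimate` (percent per year), `ci`, `n_records`,
#'   `n_individuals` and `low_leverage` (TRUE when all gaps coincide).
#' @export
annual_change <- function(records, n_boot = 500, conf = 0.95) {
  r <- records[!is.na(records$similarity) & records$gap_years > 0, ]
  if (nrow(r) < 2) stop("need at least 2 records with defined similarity")
  slope <- function(d) 100 * sum(d$gap_years * (1 - d$similarity)) /
    sum(d$gap_years^2)
  inds <- unique(r$individual_id)
  by_ind <- split(r, r$individual_id)
  boot <- vapply(seq_len(n_boot), function(i) {
    pick <- sample(inds, length(inds), replace = TRUE)
    slope(do.call(rbind, by_ind[pick]))
  }, 0)
  a <- (1 - conf) / 2
  list(estimate = slope(r),
       ci = unname(quantile(boot, c(a, 1 - a))),
       n_records = nrow(r), n_individuals = length(inds),
       low_leverage = length(unique(r$gap_years)) < 2)
}

#' Detect novel SNVs of an individual at a time point
#'
#' Novel alleles are present now (per [allele_present()]) at positions that
#' were covered in at least one earlier sample of the same individual and
#' absent in *every* earlier covered observation. Positions never
#' previously covered are excluded: absence of observation is not absence.
#' All SNVs are used (not only markers), to maximize the number of events.
#'
#' @param snv an [snv_matrix()].
#' @param sample the current sample id.
#' @param earlier_samples character vector of the individual's strictly
#'   earlier sample ids.
#' @param min_freq presence threshold.
#' @return character vector of novel position ids.
#' @export
detect_novel_snvs <- function(snv, sample, earlier_samples, min_freq = 0.05) {
  stopifnot(inherits(snv, "snv_matrix"))
  if (!length(earlier_samples)) stop("need at least one earlier sample")
  v <- unclass(snv)
  bad <- setdiff(c(sample, earlier_samples), colnames(v))
  if (length(bad)) stop("samples not in SNV matrix: ", paste(bad, collapse = ", "))
  now <- allele_present(v[, sample], min_freq)
  E <- v[, earlier_samples, drop = FALSE]
  seen_before <- rowSums(allele_present(E, min_freq)) > 0
  covered_before <- rowSums(!is.na(E)) > 0
  rownames(v)[now & covered_before & !seen_before]
}

#' Attribute a novel-SNV event to family-member donors
#'
#' For each family member, support is the number of the event's novel
#' alleles present in any of that member's strictly earlier samples. A
#' member is attributed as donor when support reaches `min_support`
#' (default: a strict majority of the novel alleles). Several members may
#' be attributed for the same event.
#'
#' @param novel character vector of novel position ids
#'   (from [detect_novel_snvs()]).
#' @param snv the [snv_matrix()].
#' @param member_samples named list: family member individual id ->
#'   character vector of their strictly earlier sample ids.
#' @param min_support absolute support threshold; default
#'   `floor(length(novel)/2) + 1` (majority).
#' @param min_freq presence threshold.
#' @return data frame with one row per member: `member`, `support`,
#'   `n_novel`, `attributed`.
#' @export
attribute_transmission <- function(novel, snv, member_samples,
                                   min_support = NULL, min_freq = 0.05) {
  stopifnot(inherits(snv, "snv_matrix"))
  v <- unclass(snv)
  if (is.null(min_support)) min_support <- floor(length(novel) / 2) + 1
  support <- vapply(member_samples, function(ss) {
    ss <- intersect(ss, colnames(v))
    if (!length(ss) || !length(novel)) return(0L)
    sum(rowSums(allele_present(v[novel, ss, drop = FALSE], min_freq)) > 0)
  }, 0L)
  data.frame(member = names(member_samples), support = unname(support),
             n_novel = length(novel),
             attributed = unname(support) >= min_support & length(novel) > 0)
}

#' Scan a cohort for novel-SNV transmission events
#'
#' Runs [detect_novel_snvs()] for every individual sample with at least one
#' earlier sample and [attribute_transmission()] against family members with
#' strictly earlier samples, and tallies donor role -> recipient role
#' proportions (attributed events / total comparisons per ordered role
#' pair).
#'
#' @param snv an [snv_matrix()] or list of them.
#' @param metadata [cohort_metadata()]; requires `collection_day` or
#'   comparable sampling on the `age_days` axis within each family (samples
#'   are ordered by `collection_day` when present, else by `age_days`).
#' @param min_freq presence threshold.
#' @param min_support see [attribute_transmission()]; NULL = majority rule.
#' @param min_novel minimum number of novel alleles for an event to be
#'   evaluated (tiny events carry no directional signal).
#' @return list with `events` (one row per member comparison) and `tallies`
#'   (per donor role -> recipient role: events, comparisons, proportion).
#' @export
detect_family_transmissions <- function(snv, metadata, min_freq = 0.05,
                                        min_support = NULL, min_novel = 5) {
  if (inherits(snv, "snv_matrix")) snv <- list(snv)
  m <- as.data.frame(metadata)
  tcol <- if ("collection_day" %in% names(m)) "collection_day" else "age_days"
  rows <- list()
  for (sp in snv) {
    v <- unclass(sp)
    ms <- m[m$sample_id %in% colnames(v), ]
    for (ind in unique(ms$individual_id)) {
      own <- ms[ms$individual_id == ind, ]
      own <- own[order(own[[tcol]]), ]
      if (nrow(own) < 2) next
      fam <- ms[ms$family_id == own$family_id[1] & ms$individual_id != ind, ]
      for (k in 2:nrow(own)) {
        t_now <- own[[tcol]][k]
        novel <- detect_novel_snvs(sp, own$sample_id[k],
                                   own$sample_id[seq_len(k - 1)], min_freq)
        if (length(novel) < min_novel) next
        earlier <- fam[fam[[tcol]] < t_now, ]
        if (!nrow(earlier)) next
        member_samples <- split(as.character(earlier$sample_id),
                                as.character(earlier$individual_id))
        att <- attribute_transmission(novel, sp, member_samples,
                                      min_support, min_freq)
        roles <- ms$role[match(att$member, ms$individual_id)]
        rows[[length(rows) + 1]] <- data.frame(
          recipient = ind,
          recipient_role = own$role[1],
          recipient_sample = own$sample_id[k],
          species = species_id(sp),
          donor = att$member, donor_role = roles,
          support = att$support, n_novel = att$n_novel,
          attributed = att$attributed)
      }
    }
  }
  events <- if (length(rows)) do.call(rbind, rows) else
    data.frame(recipient = character(), recipient_role = character(),
               recipient_sample = character(), species = character(),
               donor = character(), donor_role = character(),
               support = integer(), n_novel = integer(),
               attributed = logical())
  tallies <- if (nrow(events)) {
    ag <- aggregate(cbind(events = attributed, comparisons = 1) ~
                      donor_role + recipient_role, data = events, FUN = sum)
    ag$proportion <- ag$events / ag$comparisons
    ag
  } else data.frame(donor_role = character(), recipient_role = character(),
                    events = numeric(), comparisons = numeric(),
                    proportion = numeric())
  list(events = events, tallies = tallies)
}

#' Birth-mode contrast of maternal-strain carriage
#'
#' Per child, the indicator is whether any tracked species was labeled
#' maternal; children are cross-tabulated by birth mode and the 2x2 table
#' tested by chi-squared (reported both without and with continuity
#' correction).
#'
#' @param labels a [classify_maternal_cohort()] table, or directly a 2x2
#'   matrix (rows = birth mode, columns = maternal yes/no).
#' @param metadata [cohort_metadata()] (ignored when `labels` is a matrix).
#' @return list with `table`, `chisq` (uncorrected), `chisq_corrected`,
#'   and `proportions` (per birth mode).
#' @export
birthmode_contrast <- function(labels, metadata = NULL) {
  if (is.matrix(labels)) {
    tab <- labels
  } else {
    m <- as.data.frame(metadata)
    u <- m[!duplicated(m$individual_id), ]
    lab <- labels[labels$label != "untracked", ]
    kids <- unique(lab$child)
    if (!length(kids)) stop("no children with tracked species")
    has_mat <- vapply(kids, function(k)
      any(lab$label[lab$child == k] == "maternal"), TRUE)
    mode <- u$delivery_mode[match(kids, u$individual_id)]
    tab <- table(factor(mode, levels = c("vaginal", "caesarean")),
                 factor(has_mat, levels = c(TRUE, FALSE)))
    tab <- unclass(tab)
    if (any(rowSums(tab) == 0)) {
      warning("empty birth-mode stratum; test skipped")
      return(list(table = tab, chisq = NULL, chisq_corrected = NULL,
                  proportions = tab[, 1] / pmax(rowSums(tab), 1)))
    }
  }
  list(table = tab,
       chisq = suppressWarnings(chisq.test(tab, correct = FALSE)),
       chisq_corrected = suppressWarnings(chisq.test(tab, correct = TRUE)),
       proportions = tab[, 1] / rowSums(tab))
}

#' Per-class maternal fraction among vaginally born neonates
#'
#' Fraction of children with at least one tracked species of the class that
#' have at least one species of the class labeled maternal.
#'
#' @param labels [classify_maternal_cohort()] table.
#' @param species_class named character vector: species id -> class.
#' @param class taxonomic class name.
#' @param metadata optional [cohort_metadata()] to restrict to a delivery
#'   mode.
#' @param delivery_mode restriction applied when `metadata` is given.
#' @return list with `fraction`, `n_children` (tracked), `n_maternal`.
#' @export
class_maternal_fraction <- function(labels, species_class, class,
                                    metadata = NULL,
                                    delivery_mode = "vaginal") {
  lab <- labels[unname(species_class[labels$species]) == class &
                  labels$label != "untracked", ]
  if (!is.null(metadata)) {
    u <- as.data.frame(metadata)
    u <- u[!duplicated(u$individual_id), ]
    keep_kids <- u$individual_id[u$delivery_mode == delivery_mode]
    lab <- lab[lab$child %in% keep_kids, ]
  }
  kids <- unique(lab$child)
  if (!length(kids))
    return(list(fraction = NA_real_, n_children = 0L, n_maternal = 0L))
  mat <- vapply(kids, function(k)
    any(lab$label[lab$child == k] == "maternal"), TRUE)
  list(fraction = mean(mat), n_children = length(kids),
       n_maternal = sum(mat))
}
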