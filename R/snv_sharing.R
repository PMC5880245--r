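# Rare-marker-SNV algebra.
#
# For each compared pair of samples (A, B) a *reference population* is
# formed from all samples of individuals unrelated to both donors (plus any
# unrelated background cohort). Markers of A are the alleles present in A
# but in no reference sample:
#   rmSNV / FmSNV : absent from all reference samples (family members of
#                   either donor are allowed to carry them);
#   EmSNV         : additionally absent from every sample of every *other*
#                   member of both families (exclusive to the pair).
# Similarity A->B is the fraction of A's marker positions covered in B at
# which B carries the marker allele; it is only assessed when more than
# `min_markers` (default 100) marker positions are covered in B.

#' Allele presence call
#'
#' An allele is present when its observed frequency is not MISSING and is at
#' least `min_freq`. The small floor guards against read noise; `0` (covered,
#' reference-only) and `NA` (not covered) are both absent.
#'
#' @param freq numeric vector of observed frequencies (`NA` = MISSING).
#' @param min_freq detection threshold, default 0.05.
#' @return logical vector.
#' @export
allele_present <- function(freq, min_freq = 0.05) {
  !is.na(freq) & freq >= min_freq
}

#' Build the pair-specific reference population
#'
#' The reference population for a compared pair excludes every sample from
#' the two individuals and from all their family members -- even when the
#' two individuals are unrelated, both families are excluded.
#'
#' @param individual_a,individual_b the two compared individuals.
#' @param metadata a [cohort_metadata()] table covering all cohort samples.
#' @param background optional character vector of additional sample ids from
#'   unrelated background individuals not listed in `metadata`.
#' @return an object of class `reference_population`: a list with `pair`,
#'   `excluded_individuals`, `reference_samples` and `family_samples` (sample
#'   -> individual map for the two excluded families, used for EmSNVs).
#' @export
build_reference_population <- function(individual_a, individual_b, metadata,
                                       background = NULL) {
  fam <- .individual_families(metadata)
  for (i in c(individual_a, individual_b))
    if (!i %in% names(fam)) stop("unknown individual: '", i, "'")
  fams <- unique(c(fam[[individual_a]], fam[[individual_b]]))
  excluded <- names(fam)[fam %in% fams]
  in_excl <- metadata$individual_id %in% excluded
  ref <- c(as.character(metadata$sample_id[!in_excl]), as.character(background))
  if (!length(ref))
    stop("empty reference population: marker rarity is undefinable")
  structure(list(
    pair = c(individual_a, individual_b),
    excluded_individuals = excluded,
    reference_samples = ref,
    family_samples = data.frame(
      sample_id = as.character(metadata$sample_id[in_excl]),
      individual_id = as.character(metadata$individual_id[in_excl]))
  ), class = "reference_population")
}

#' Identify marker SNVs of a focal sample
#'
#' Markers are alleles present in the focal sample (per [allele_present()])
#' and absent from every reference sample. For `variant = "emsnv"`, alleles
#' present in any sample of any *other* member of the two families are also
#' removed. The partner sample of the pair is never consulted for rarity.
#'
#' @param focal focal sample id (must be a column of `snv`).
#' @param other the partner sample of the comparison (excluded from the
#'   reference by construction; used only for book-keeping).
#' @param snv an [snv_matrix()] for one species.
#' @param refpop a [build_reference_population()] result valid for the pair.
#' @param variant `"rmsnv"`, `"fmsnv"` (identical marker rule) or `"emsnv"`.
#' @param min_freq presence threshold, see [allele_present()].
#' @return object of class `marker_set`: list with `markers` (position ids),
#'   `species_id`, `variant`, `focal`, `other`, `untracked` (TRUE when the
#'   species has no covered position in the focal sample).
#' @export
identify_markers <- function(focal, other, snv, refpop,
                             variant = c("rmsnv", "fmsnv", "emsnv"),
                             min_freq = 0.05) {
  variant <- match.arg(variant)
  stopifnot(inherits(snv, "snv_matrix"), inherits(refpop, "reference_population"))
  v <- unclass(snv)
  if (!focal %in% colnames(v)) stop("focal sample '", focal, "' not in SNV matrix")
  ref <- intersect(refpop$reference_samples, colnames(v))
  if (other %in% refpop$reference_samples || other %in% ref)
    stop("partner sample '", other, "' must not be part of the reference population")
  untracked <- all(is.na(v[, focal]))
  pres_focal <- allele_present(v[, focal], min_freq)
  in_ref <- if (length(ref))
    rowSums(allele_present(v[, ref, drop = FALSE], min_freq)) > 0
  else rep(FALSE, nrow(v))
  keep <- pres_focal & !in_ref
  if (variant == "emsnv") {
    fs <- refpop$family_samples
    others <- fs$sample_id[!fs$individual_id %in% refpop$pair]
    others <- intersect(others, colnames(v))
    if (length(others))
      keep <- keep &
        rowSums(allele_present(v[, others, drop = FALSE], min_freq)) == 0
  }
  structure(list(markers = rownames(v)[keep], species_id = species_id(snv),
                 variant = variant, focal = focal, other = other,
                 pair = refpop$pair, untracked = untracked),
            class = "marker_set")
}

#' Directional marker-sharing similarity
#'
#' The denominator is the number of the focal sample's marker positions that
#' are covered (not MISSING) in the partner sample; the numerator is the
#' subset at which the partner carries the marker allele. Similarity is
#' undefined (NA) unless more than `min_markers` marker positions are
#' available. When the species has zero genome coverage in either sample,
#' similarity is set to 0 (defined), which takes precedence.
#'
#' @param markers an [identify_markers()] result.
#' @param other partner sample id.
#' @param snv the [snv_matrix()] the markers were derived from.
#' @param min_markers marker-position filter, strict (`> min_markers`).
#' @param coverage optional coverage table used for the zero-coverage rule.
#' @param min_freq presence threshold.
#' @return a `sharing_record` list: `focal`, `other`, `species_id`,
#'   `variant`, `n_marker_positions`, `similarity`.
#' @export
marker_similarity <- function(markers, other, snv, min_markers = 100,
                              coverage = NULL, min_freq = 0.05) {
  stopifnot(inherits(markers, "marker_set"), inherits(snv, "snv_matrix"))
  v <- unclass(snv)
  if (!other %in% colnames(v)) stop("sample '", other, "' not in SNV matrix")
  zero_cov <- FALSE
  if (!is.null(coverage)) {
    vc <- .species_coverage(coverage, species_id(snv), c(markers$focal, other))
    zero_cov <- any(vc == 0)
  }
  if (zero_cov) {
    sim <- 0
    n <- 0L
  } else {
    f <- v[markers$markers, other]
    n <- sum(!is.na(f))
    sim <- if (n > min_markers) sum(allele_present(f, min_freq)) / n else NA_real_
  }
  structure(list(focal = markers$focal, other = other,
                 species_id = species_id(snv), variant = markers$variant,
                 n_marker_positions = n, similarity = sim,
                 zero_coverage = zero_cov),
            class = "sharing_record")
}

.species_coverage <- function(coverage, species, samples) {
  vc <- numeric(length(samples))
  for (i in seq_along(samples)) {
    hit <- coverage$species_id == species & coverage$sample_id == samples[i]
    vc[i] <- if (any(hit)) coverage$vertical_coverage[hit][1] else 0
  }
  vc
}

#' Combine the two directional records of a pair
#'
#' Pair-level similarity is the marker-count-weighted mean of the defined
#' directional similarities; it is undefined only when both directions are.
#'
#' @param rec_ab,rec_ba `sharing_record`s for the two directions of one
#'   pair/species comparison.
#' @return a `sharing_record` with the symmetric similarity and both
#'   directional values retained for audit.
#' @export
symmetrize <- function(rec_ab, rec_ba) {
  if (!identical(rec_ab$species_id, rec_ba$species_id) ||
      !identical(sort(c(rec_ab$focal, rec_ab$other)),
                 sort(c(rec_ba$focal, rec_ba$other))))
    stop("directional records do not describe the same pair and species")
  if (isTRUE(rec_ab$zero_coverage) || isTRUE(rec_ba$zero_coverage)) {
    sim <- 0
  } else {
    s <- c(rec_ab$similarity, rec_ba$similarity)
    w <- c(rec_ab$n_marker_positions, rec_ba$n_marker_positions)
    def <- !is.na(s)
    sim <- if (any(def)) sum(s[def] * w[def]) / sum(w[def]) else NA_real_
  }
  structure(list(sample_a = rec_ab$focal, sample_b = rec_ab$other,
                 species_id = rec_ab$species_id, variant = rec_ab$variant,
                 sim_ab = rec_ab$similarity, n_markers_ab = rec_ab$n_marker_positions,
                 sim_ba = rec_ba$similarity, n_markers_ba = rec_ba$n_marker_positions,
                 similarity = sim),
            class = "sharing_record")
}

#' Strain-sharing call
#'
#' Shared strains are called when similarity is strictly greater than the
#' cutoff (default 0.2, calibrated so that unrelated pairs exceed it in
#' about 0.5% of comparisons). NA (undefined) propagates.
#'
#' @param similarity numeric vector of similarities.
#' @param cutoff call threshold in (0, 1).
#' @return logical vector with NA propagated.
#' @export
call_strain_sharing <- function(similarity, cutoff = 0.2) {
  stopifnot(cutoff > 0, cutoff < 1)
  similarity > cutoff
}

#' Empirical exceedance of candidate cutoffs among unrelated pairs
#'
#' For each candidate cutoff, the fraction of defined unrelated-pair
#' similarities strictly exceeding it. The exceedance at the chosen call
#' threshold is the empirical false-discovery rate of the strain-sharing
#' call.
#'
#' @param similarities numeric vector of unrelated-pair similarities (NA =
#'   undefined, dropped).
#' @param cutoffs candidate cutoffs.
#' @param min_pairs minimum number of defined similarities required.
#' @return data frame with columns `cutoff`, `n_pairs`, `exceedance`.
#' @export
calibrate_cutoff <- function(similarities, cutoffs = seq(0.05, 0.5, by = 0.05),
                             min_pairs = 30) {
  s <- similarities[!is.na(similarities)]
  if (length(s) < min_pairs)
    stop("need at least ", min_pairs, " unrelated pairs with defined similarity")
  data.frame(cutoff = cutoffs, n_pairs = length(s),
             exceedance = vapply(cutoffs, function(k) mean(s > k), 0))
}

#' Select species trackable within families
#'
#' A species is tracked when, in at least one family, at least
#' `min_family_members` distinct members have a sample with vertical
#' coverage above `min_depth` and horizontal coverage above
#' `min_horizontal` (both conditions on the same sample).
#'
#' @param coverage coverage table.
#' @param metadata [cohort_metadata()].
#' @param min_depth vertical-coverage threshold (x), strict; default 10.
#' @param min_horizontal horizontal-coverage threshold, strict; default 0.4.
#' @param min_family_members members required per family; default 2.
#' @return character vector of species ids (possibly empty).
#' @export
select_tracked_species <- function(coverage, metadata, min_depth = 10,
                                   min_horizontal = 0.4,
                                   min_family_members = 2) {
  d <- merge(coverage, as.data.frame(metadata)[c("sample_id", "individual_id",
                                                 "family_id")],
             by = "sample_id")
  d <- d[d$vertical_coverage > min_depth & d$horizontal_coverage > min_horizontal, ]
  if (!nrow(d)) return(character(0))
  key <- paste(d$species_id, d$family_id, sep = "\r")
  n_members <- tapply(d$individual_id, key, function(x) length(unique(x)))
  ok <- names(n_members)[n_members >= min_family_members]
  sort(unique(vapply(strsplit(ok, "\r", fixed = TRUE), `[`, "", 1L)))
}

#' Marker-richness and abundance bias diagnostics
#'
#' Marker-sharing similarity should not depend on how many markers a sample
#' has, nor on how abundant the species is; a dependence indicates that
#' similarity is underestimated by insufficient sampling. Per taxonomic
#' class, similarity is correlated against marker richness and against
#' species abundance; classes with a significant association are flagged
#' for exclusion.
#'
#' @param records data frame with columns `similarity`, `marker_richness`,
#'   `abundance` and `class`.
#' @param alpha significance level for the exclusion flag.
#' @param method correlation method passed to [stats::cor.test()].
#' @param min_records minimum records per class.
#' @return data frame with one row per class: correlations, p-values and
#'   an `excluded` flag (NA when the correlation is undefined).
#' @export
bias_diagnostics <- function(records, alpha = 0.05, method = "spearman",
                             min_records = 10) {
  need <- c("similarity", "marker_richness", "abundance", "class")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records lack columns: ", paste(miss, collapse = ", "))
  res <- lapply(split(records, records$class), function(d) {
    d <- d[!is.na(d$similarity), ]
    if (nrow(d) < min_records)
      stop("fewer than ", min_records, " records for class '", d$class[1], "'")
    ct <- function(x) {
      if (sd(d$similarity) == 0 || sd(x) == 0)
        return(c(NA_real_, NA_real_))
      t <- suppressWarnings(cor.test(d$similarity, x, method = method))
      c(unname(t$estimate), t$p.value)
    }
    r1 <- ct(d$marker_richness)
    r2 <- ct(d$abundance)
    excl <- if (all(is.na(c(r1[2], r2[2])))) NA else
      isTRUE(r1[2] < alpha) || isTRUE(r2[2] < alpha)
    data.frame(class = d$class[1], n = nrow(d),
               cor_richness = r1[1], p_richness = r1[2],
               cor_abundance = r2[1], p_abundance = r2[2],
               excluded = excl)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' SNV frequency spectrum of a sample
#'
#' Within-species SNV frequencies are often bimodal, peaking below 20% or
#' above 80%: one dominant strain carries either the reference or the
#' alternative allele. This diagnostic reports the spectrum of observed
#' non-zero alternative-allele frequencies and the fraction of mass in the
#' extreme bins.
#'
#' @param snv an [snv_matrix()].
#' @param sample sample id.
#' @param breaks histogram breaks over \eqn{[0, 1]}.
#' @param min_sites minimum number of observed frequencies required.
#' @return list with `histogram` (a [graphics::hist()] object, not plotted),
#'   `extreme_fraction` (mass in \eqn{[0,0.2) \cup (0.8,1]}) and `n`.
#' @export
snv_frequency_modality <- function(snv, sample, breaks = seq(0, 1, 0.05),
                                   min_sites = 50) {
  stopifnot(inherits(snv, "snv_matrix"))
  v <- unclass(snv)
  if (!sample %in% colnames(v)) stop("unknown sample: '", sample, "'")
  f <- v[, sample]
  f <- f[!is.na(f) & f > 0]
  if (length(f) < min_sites)
    stop("need at least ", min_sites, " observed SNV frequencies, got ", length(f))
  h <- graphics::hist(f, breaks = breaks, plot = FALSE)
  list(histogram = h,
       extreme_fraction = mean(f < 0.2 | f > 0.8),
       n = length(f))
}

# ---------------------------------------------------------------------------
# Fast whole-cohort engine. Per species it precomputes presence and coverage
# masks plus per-family (and, for EmSNVs, per-individual) presence counts,
# so that each pair's reference-population scan reduces to
#   present_in_reference = total_count - count(family A) - count(family B).
# This is an exact rewrite of the per-pair definition (no caching leaks:
# every pair still gets its own reference population), verified against the
# op-level functions and a brute-force oracle in the test suite.

.sharing_index <- function(snv, metadata, min_freq = 0.05, emsnv = FALSE) {
  v <- unclass(snv)
  meta <- as.data.frame(metadata)
  idx <- match(colnames(v), meta$sample_id)
  if (anyNA(idx))
    stop("samples missing from metadata: ",
         paste(head(colnames(v)[is.na(idx)]), collapse = ", "))
  indiv <- as.character(meta$individual_id[idx])
  fam <- as.character(meta$family_id[idx])
  P <- !is.na(v) & v >= min_freq
  Cov <- !is.na(v)
  fams <- unique(fam)
  fam_count <- vapply(fams, function(f)
    rowSums(P[, fam == f, drop = FALSE]), numeric(nrow(v)))
  colnames(fam_count) <- fams
  ind_count <- NULL
  if (emsnv) {
    inds <- unique(indiv)
    ind_count <- vapply(inds, function(i)
      rowSums(P[, indiv == i, drop = FALSE]), numeric(nrow(v)))
    colnames(ind_count) <- inds
  }
  list(P = P, Cov = Cov, total = rowSums(P), fam_count = fam_count,
       ind_count = ind_count, indiv = setNames(indiv, colnames(v)),
       fam = setNames(fam, colnames(v)), species_id = species_id(snv),
       positions = rownames(v))
}

.markers_fast <- function(idx, a, b, variant = "rmsnv") {
  fa <- idx$fam[[a]]
  fb <- idx$fam[[b]]
  ref_count <- idx$total - idx$fam_count[, fa]
  if (fb != fa) ref_count <- ref_count - idx$fam_count[, fb]
  m <- idx$P[, a] & ref_count == 0
  if (variant == "emsnv") {
    ia <- idx$indiv[[a]]
    ib <- idx$indiv[[b]]
    others <- idx$fam_count[, fa] - idx$ind_count[, ia]
    if (fb != fa) others <- others + idx$fam_count[, fb]
    if (ib != ia) others <- others - idx$ind_count[, ib]
    m <- m & others == 0
  }
  m
}

.directional_fast <- function(idx, a, b, variant, min_markers) {
  m <- .markers_fast(idx, a, b, variant)
  n <- sum(m & idx$Cov[, b])
  sim <- if (n > min_markers) sum(m & idx$P[, b]) / n else NA_real_
  list(n = n, sim = sim)
}

#' Compute a sharing table for many sample pairs
#'
#' The workhorse of the package: for each requested pair of samples it
#' builds the pair-specific reference population, identifies the focal
#' markers in both directions, and reports directional and symmetric
#' marker-sharing similarity plus the strain-sharing call. Results are
#' exactly equal to composing [build_reference_population()],
#' [identify_markers()], [marker_similarity()] and [symmetrize()] pair by
#' pair (tested), but use a shared presence index for speed.
#'
#' @param snv an [snv_matrix()] (one species) or a list of them.
#' @param metadata [cohort_metadata()] covering every SNV-matrix sample.
#'   Background individuals are ordinary rows (their own single-member
#'   families).
#' @param pairs data frame with columns `sample_a`, `sample_b`; each row is
#'   evaluated against every supplied species.
#' @param coverage optional coverage table enabling the zero-coverage rule
#'   (similarity 0 when the species has zero vertical coverage in either
#'   sample).
#' @param variant marker flavour: `"rmsnv"`, `"fmsnv"` or `"emsnv"`.
#' @param min_freq presence threshold.
#' @param min_markers marker-position filter (strict `>`).
#' @param cutoff strain-sharing cutoff.
#' @return data frame with columns `sample_a`, `sample_b`, `species`,
#'   `variant`, `n_markers_ab`, `sim_ab`, `n_markers_ba`, `sim_ba`,
#'   `sim_sym`, `shared_call`.
#' @export
sharing_table <- function(snv, metadata, pairs, coverage = NULL,
                          variant = c("rmsnv", "fmsnv", "emsnv"),
                          min_freq = 0.05, min_markers = 100, cutoff = 0.2) {
  variant <- match.arg(variant)
  if (inherits(snv, "snv_matrix")) snv <- list(snv)
  out <- vector("list", length(snv))
  for (k in seq_along(snv)) {
    sp <- species_id(snv[[k]])
    idx <- .sharing_index(snv[[k]], metadata, min_freq, emsnv = variant == "emsnv")
    n <- nrow(pairs)
    n_ab <- n_ba <- integer(n)
    s_ab <- s_ba <- s_sym <- numeric(n)
    cov_vc <- NULL
    if (!is.null(coverage)) {
      cc <- coverage[coverage$species_id == sp, ]
      cov_vc <- setNames(cc$vertical_coverage, cc$sample_id)
    }
    for (r in seq_len(n)) {
      a <- as.character(pairs$sample_a[r])
      b <- as.character(pairs$sample_b[r])
      if (!is.null(cov_vc)) {
        vca <- if (a %in% names(cov_vc)) cov_vc[[a]] else 0
        vcb <- if (b %in% names(cov_vc)) cov_vc[[b]] else 0
        if (vca == 0 || vcb == 0) {
          n_ab[r] <- n_ba[r] <- 0L
          s_ab[r] <- s_ba[r] <- s_sym[r] <- 0
          next
        }
      }
      d1 <- .directional_fast(idx, a, b, variant, min_markers)
      d2 <- .directional_fast(idx, b, a, variant, min_markers)
      n_ab[r] <- d1$n; s_ab[r] <- d1$sim
      n_ba[r] <- d2$n; s_ba[r] <- d2$sim
      def <- !is.na(c(d1$sim, d2$sim))
      s_sym[r] <- if (any(def))
        sum(c(d1$sim, d2$sim)[def] * c(d1$n, d2$n)[def]) / sum(c(d1$n, d2$n)[def])
      else NA_real_
    }
    out[[k]] <- data.frame(
      sample_a = as.character(pairs$sample_a),
      sample_b = as.character(pairs$sample_b),
      species = sp, variant = variant,
      n_markers_ab = n_ab, sim_ab = s_ab,
      n_markers_ba = n_ba, sim_ba = s_ba,
      sim_sym = s_sym,
      shared_call = call_strain_sharing(s_sym, cutoff))
  }
  do.call(rbind, out)
}

#' Enumerate sample pairs by relatedness
#'
#' Convenience helper returning all between-individual sample pairs that
#' are related (same family) or unrelated, optionally capped at `max_pairs`
#' randomly chosen pairs (uses the current RNG state).
#'
#' @param metadata [cohort_metadata()].
#' @param relation `"related"`, `"unrelated"` or `"all"`.
#' @param max_pairs optional cap; pairs are subsampled without replacement.
#' @return data frame with columns `sample_a`, `sample_b`.
#' @export
sample_pairs <- function(metadata, relation = c("all", "related", "unrelated"),
                         max_pairs = NULL) {
  relation <- match.arg(relation)
  m <- as.data.frame(metadata)
  cmb <- utils::combn(nrow(m), 2)
  ia <- cmb[1, ]; ib <- cmb[2, ]
  keep <- m$individual_id[ia] != m$individual_id[ib]
  same_fam <- m$family_id[ia] == m$family_id[ib]
  if (relation == "related") keep <- keep & same_fam
  if (relation == "unrelated") keep <- keep & !same_fam
  ia <- ia[keep]; ib <- ib[keep]
  if (!is.null(max_pairs) && length(ia) > max_pairs) {
    pick <- sample(length(ia), max_pairs)
    ia <- ia[pick]; ib <- ib[pick]
  }
  data.frame(sample_a = as.character(m$sample_id[ia]),
             sample_b = as.character(m$sample_id[ib]))
}
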