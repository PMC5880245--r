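# Hand-built toy cohort: 3 families (F1: i1+i2 with sibling i3; F2: i4;
# F3: i5) plus two background singletons. Small enough for exhaustive
# reasoning.
toy_cohort <- function() {
  samples <- c("i1a", "i2a", "i3a", "i4a", "i5a", "b1", "b2")
  meta <- make_meta(samples,
                    individual_id = c("i1", "i2", "i3", "i4", "i5", "b1", "b2"),
                    family_id = c("F1", "F1", "F1", "F2", "F3", "B1", "B2"),
                    age_days = rep(10000, 7))
  set.seed(33)
  snv <- random_snv(20, samples, p_missing = 0.15, species = "toy")
  list(meta = meta, snv = snv)
}

test_that("allele presence requires coverage and the frequency floor", {
  expect_false(allele_present(NA_real_))
  expect_false(allele_present(0))
  expect_false(allele_present(0.049))
  expect_true(allele_present(0.05))   # boundary is inclusive
  expect_true(allele_present(1))
})

test_that("reference populations exclude both families of the pair", {
  tc <- toy_cohort()
  # related pair: only F1 excluded
  rp <- build_reference_population("i1", "i2", tc$meta)
  expect_setequal(rp$excluded_individuals, c("i1", "i2", "i3"))
  expect_setequal(rp$reference_samples, c("i4a", "i5a", "b1", "b2"))
  # unrelated pair: both families excluded even though unrelated
  rp2 <- build_reference_population("i1", "i4", tc$meta)
  expect_setequal(rp2$excluded_individuals, c("i1", "i2", "i3", "i4"))
  expect_setequal(rp2$reference_samples, c("i5a", "b1", "b2"))
  # recount oracle
  m <- as.data.frame(tc$meta)
  expect_equal(length(rp2$reference_samples),
               sum(!(m$family_id %in% c("F1", "F2"))))
  # background samples are appended verbatim
  rp3 <- build_reference_population("i1", "i2", tc$meta,
                                    background = c("x1", "x2"))
  expect_true(all(c("x1", "x2") %in% rp3$reference_samples))
  expect_error(build_reference_population("i1", "nope", tc$meta),
               "unknown individual")
  solo <- make_meta("s1", "i1", "F1")
  expect_error(build_reference_population("i1", "i1", solo),
               "empty reference population")
})

test_that("marker identification matches the exhaustive oracle", {
  tc <- toy_cohort()
  pairs <- list(c("i1", "i2"), c("i1", "i4"), c("i4", "i5"), c("i1", "i1"))
  sample_of <- setNames(as.data.frame(tc$meta)$sample_id,
                        as.data.frame(tc$meta)$individual_id)
  for (p in pairs) {
    rp <- build_reference_population(p[1], p[2], tc$meta)
    for (variant in c("rmsnv", "emsnv")) {
      ms <- identify_markers(sample_of[[p[1]]], sample_of[[p[2]]], tc$snv,
                             rp, variant = variant)
      expect_setequal(ms$markers,
                      oracle_markers(tc$snv, sample_of[[p[1]]],
                                     sample_of[[p[2]]], tc$meta, variant))
    }
  }
})

test_that("family-shared alleles are rmSNV markers but not EmSNV markers", {
  samples <- c("A", "sib", "M", "ref1", "ref2")
  meta <- make_meta(samples, individual_id = c("iA", "iS", "iM", "r1", "r2"),
                    family_id = c("F", "F", "F", "R1", "R2"))
  v <- matrix(0, 3, 5, dimnames = list(
    sprintf("c1:%d:A>G", 1:3), samples))
  v[1, c("A", "sib")] <- 0.9          # shared with sibling only
  v[2, c("A", "ref1")] <- 0.9         # present in a reference sample
  v[3, "A"] <- 0.9                    # exclusive to A
  snv <- snv_matrix(v, "sp")
  rp <- build_reference_population("iA", "iM", meta)
  rm_ <- identify_markers("A", "M", snv, rp, "rmsnv")
  em <- identify_markers("A", "M", snv, rp, "emsnv")
  expect_setequal(rm_$markers, c("c1:1:A>G", "c1:3:A>G"))
  expect_setequal(em$markers, "c1:3:A>G")
  expect_true(all(em$markers %in% rm_$markers))  # EmSNV subset of rmSNV
})

test_that("marker rarity: no emitted marker is present in any reference sample", {
  sim <- small_sim()
  m <- as.data.frame(sim$metadata)
  set.seed(8)
  pairs <- sample_pairs(sim$metadata, "all", max_pairs = 15)
  for (r in seq_len(nrow(pairs))) {
    a <- pairs$sample_a[r]; b <- pairs$sample_b[r]
    rp <- build_reference_population(m$individual_id[m$sample_id == a],
                                     m$individual_id[m$sample_id == b],
                                     sim$metadata)
    for (sp in sim$snv) {
      ms <- identify_markers(a, b, sp, rp, "rmsnv")
      ref <- intersect(rp$reference_samples, colnames(sp))
      if (length(ms$markers))
        expect_equal(sum(allele_present(unclass(sp)[ms$markers, ref])), 0)
    }
  }
})

test_that("enlarging the reference population never enlarges a marker set", {
  tc <- toy_cohort()
  rp_full <- build_reference_population("i1", "i2", tc$meta)
  rp_small <- rp_full
  rp_small$reference_samples <- setdiff(rp_full$reference_samples, c("b1", "b2"))
  m_full <- identify_markers("i1a", "i2a", tc$snv, rp_full)$markers
  m_small <- identify_markers("i1a", "i2a", tc$snv, rp_small)$markers
  expect_true(all(m_full %in% m_small))
})

test_that("the partner sample is never consulted for marker rarity", {
  tc <- toy_cohort()
  rp <- build_reference_population("i1", "i4", tc$meta)
  v2 <- unclass(tc$snv)
  v2[, "i4a"] <- 1        # partner now carries everything
  snv2 <- snv_matrix(v2, "toy")
  expect_identical(identify_markers("i1a", "i4a", tc$snv, rp)$markers,
                   identify_markers("i1a", "i4a", snv2, rp)$markers)
  expect_error(identify_markers("i1a", "b1", tc$snv, rp),
               "must not be part of the reference")
})

test_that("directional similarity counts markers covered and present in the partner", {
  # 150 markers: 120 covered in partner, 30 of those present
  samples <- c("A", "B", "r1")
  v <- matrix(NA_real_, 150, 3, dimnames = list(
    sprintf("c1:%d:A>G", 1:150), samples))
  v[, "A"] <- 1
  v[, "r1"] <- 0
  v[1:120, "B"] <- 0
  v[1:30, "B"] <- 1
  snv <- snv_matrix(v, "sp")
  meta <- make_meta(samples, c("iA", "iB", "iR"), c("FA", "FB", "FR"))
  rp <- build_reference_population("iA", "iB", meta)
  ms <- identify_markers("A", "B", snv, rp)
  expect_length(ms$markers, 150)
  rec <- marker_similarity(ms, "B", snv)
  expect_equal(rec$n_marker_positions, 120)
  expect_equal(rec$similarity, 0.25)
  o <- oracle_similarity(snv, ms$markers, "B")
  expect_equal(rec$similarity, o$sim)

  # identity comparison: all covered, all present
  rec_self <- marker_similarity(ms, "A", snv)
  expect_equal(rec_self$similarity, 1)

  # at most 100 usable marker positions -> undefined
  v2 <- v; v2[101:150, "B"] <- NA; v2[1:100, "B"] <- 1
  snv2 <- snv_matrix(v2, "sp")
  rec2 <- marker_similarity(identify_markers("A", "B", snv2, rp), "B", snv2)
  expect_equal(rec2$n_marker_positions, 100)
  expect_true(is.na(rec2$similarity))

  # zero-coverage rule: similarity set to 0, not undefined
  cov <- data.frame(species_id = "sp", sample_id = c("A", "B"),
                    vertical_coverage = c(20, 0),
                    horizontal_coverage = c(0.9, 0))
  rec3 <- marker_similarity(ms, "B", snv, coverage = cov)
  expect_equal(rec3$similarity, 0)
})

test_that("symmetrization is the marker-weighted mean of defined directions", {
  mk <- function(f, o, n, s) structure(
    list(focal = f, other = o, species_id = "sp", variant = "rmsnv",
         n_marker_positions = n, similarity = s, zero_coverage = FALSE),
    class = "sharing_record")
  expect_equal(symmetrize(mk("A", "B", 200, 0.9), mk("B", "A", 100, 0.9))$similarity, 0.9)
  # one direction undefined (n = 100 is not > 100)
  expect_equal(symmetrize(mk("A", "B", 100, NA), mk("B", "A", 150, 0.8))$similarity, 0.8)
  set.seed(4)
  for (i in 1:10) {
    n1 <- sample(101:300, 1); n2 <- sample(101:300, 1)
    s1 <- runif(1); s2 <- runif(1)
    expect_equal(symmetrize(mk("A", "B", n1, s1), mk("B", "A", n2, s2))$similarity,
                 (s1 * n1 + s2 * n2) / (n1 + n2))
  }
  expect_error(symmetrize(mk("A", "B", 150, 0.5), mk("C", "A", 150, 0.5)),
               "same pair")
})

test_that("strain sharing requires similarity strictly above the cutoff", {
  expect_true(call_strain_sharing(0.21))
  expect_false(call_strain_sharing(0.20))
  expect_true(is.na(call_strain_sharing(NA_real_)))
  expect_identical(call_strain_sharing(c(0.5, 0.1, NA)), c(TRUE, FALSE, NA))
})

test_that("cutoff calibration reports exceedance frequencies", {
  set.seed(6)
  sims <- c(rbeta(200, 0.2, 5), rep(NA, 10))
  cal <- calibrate_cutoff(sims, cutoffs = c(0.1, 0.2, 1.01))
  def <- sims[!is.na(sims)]
  expect_equal(cal$exceedance, c(mean(def > 0.1), mean(def > 0.2), 0))
  expect_equal(cal$n_pairs, rep(200, 3))
  expect_equal(calibrate_cutoff(rep(0, 50), cutoffs = 0.01)$exceedance, 0)
  expect_error(calibrate_cutoff(rep(0.1, 5)), "at least 30")
})

test_that("species selection follows the coverage thresholds per family", {
  meta <- make_meta(c("m1", "c1", "x1"), c("mom", "kid", "solo"),
                    c("F1", "F1", "F2"))
  cov <- rbind(
    data.frame(species_id = "good", sample_id = c("m1", "c1"),
               vertical_coverage = 12, horizontal_coverage = 0.6),
    data.frame(species_id = "one_member", sample_id = "m1",
               vertical_coverage = 50, horizontal_coverage = 0.9),
    data.frame(species_id = "shallow", sample_id = c("m1", "c1"),
               vertical_coverage = 9, horizontal_coverage = 0.6),
    data.frame(species_id = "narrow", sample_id = c("m1", "c1"),
               vertical_coverage = 12, horizontal_coverage = 0.3))
  expect_identical(select_tracked_species(cov, meta), "good")

  # brute-force filter oracle on a random coverage table
  set.seed(14)
  sim <- small_sim()
  sel <- select_tracked_species(sim$coverage, sim$metadata)
  m <- as.data.frame(sim$metadata)
  d <- merge(sim$coverage, m[c("sample_id", "individual_id", "family_id")])
  oracle <- sort(unique(unlist(lapply(
    split(d, d$species_id), function(s) {
      ok <- s[s$vertical_coverage > 10 & s$horizontal_coverage > 0.4, ]
      n <- tapply(ok$individual_id, ok$family_id,
                  function(x) length(unique(x)))
      if (any(n >= 2)) s$species_id[1] else NULL
    }))))
  expect_identical(sel, oracle)
})

test_that("bias diagnostics flag similarity tied to richness or abundance", {
  set.seed(21)
  n <- 60
  null_rec <- data.frame(similarity = rbeta(n, 2, 2),
                         marker_richness = sample(100:500, n, TRUE),
                         abundance = runif(n), class = "NullClass")
  biased <- data.frame(marker_richness = sample(100:500, n, TRUE),
                       abundance = runif(n), class = "BiasClass")
  biased$similarity <- biased$marker_richness / 600
  d <- bias_diagnostics(rbind(null_rec, biased))
  expect_false(d$excluded[d$class == "NullClass"])
  expect_true(d$excluded[d$class == "BiasClass"])
  # product-moment arithmetic oracle
  dp <- bias_diagnostics(null_rec, method = "pearson")
  expect_equal(dp$cor_richness,
               cor(null_rec$similarity, null_rec$marker_richness))
  expect_error(bias_diagnostics(null_rec[1:5, ]), "fewer than")
})

test_that("frequency-spectrum diagnostic reports extreme-bin mass", {
  mk <- function(f) snv_matrix(matrix(f, ncol = 1,
    dimnames = list(sprintf("c1:%d:A>G", seq_along(f)), "s")), "sp")
  expect_equal(snv_frequency_modality(mk(rep(1, 60)), "s")$extreme_fraction, 1)
  expect_equal(snv_frequency_modality(mk(rep(0.5, 60)), "s")$extreme_fraction, 0)
  set.seed(9)
  f <- runif(200)
  r <- snv_frequency_modality(mk(f), "s")
  expect_equal(r$extreme_fraction, mean(f < 0.2 | f > 0.8))
  expect_equal(sum(r$histogram$counts), r$n)
  expect_error(snv_frequency_modality(mk(rep(0.5, 10)), "s"), "at least 50")
})

test_that("the indexed sharing engine equals the op-level composition", {
  sim <- small_sim()
  m <- as.data.frame(sim$metadata)
  set.seed(17)
  pairs <- sample_pairs(sim$metadata, "all", max_pairs = 12)
  for (variant in c("rmsnv", "fmsnv", "emsnv")) {
    tab <- sharing_table(sim$snv, sim$metadata, pairs,
                         coverage = sim$coverage, variant = variant,
                         min_markers = 5)
    for (r in seq_len(nrow(pairs))) {
      a <- pairs$sample_a[r]; b <- pairs$sample_b[r]
      rp <- build_reference_population(m$individual_id[m$sample_id == a],
                                       m$individual_id[m$sample_id == b],
                                       sim$metadata)
      for (sp in names(sim$snv)) {
        snv <- sim$snv[[sp]]
        ms_ab <- identify_markers(a, b, snv, rp, variant)
        ms_ba <- identify_markers(b, a, snv, rp, variant)
        rec <- symmetrize(
          marker_similarity(ms_ab, b, snv, min_markers = 5,
                            coverage = sim$coverage),
          marker_similarity(ms_ba, a, snv, min_markers = 5,
                            coverage = sim$coverage))
        row <- tab[tab$sample_a == a & tab$sample_b == b & tab$species == sp, ]
        expect_equal(row$sim_sym, rec$similarity, tolerance = 1e-12)
      }
    }
  }
})
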