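# Species composition: coverage-based relative abundance and
# between-sample compositional similarity.

#' Coverage-based relative species abundance
#'
#' Species abundance is estimated from mean genome coverage: within a
#' sample, the relative abundance of species *s* is its vertical coverage
#' divided by the summed vertical coverage of all species in the sample.
#'
#' @param coverage a coverage table (see [read_coverage_table()]).
#' @param sample optional single sample id; if given, a named abundance
#'   vector for that sample is returned.
#' @return a species x samples matrix of relative abundances (columns sum
#'   to 1), or a named vector for one sample.
#' @export
relative_abundance <- function(coverage, sample = NULL) {
  validate_coverage_table(coverage)
  species <- sort(unique(as.character(coverage$species_id)))
  samples <- unique(as.character(coverage$sample_id))
  if (!is.null(sample)) {
    if (!sample %in% samples) stop("unknown sample: '", sample, "'")
    samples <- sample
  }
  m <- matrix(0, length(species), length(samples),
              dimnames = list(species, samples))
  keep <- coverage$sample_id %in% samples
  m[cbind(match(coverage$species_id[keep], species),
          match(coverage$sample_id[keep], samples))] <-
    coverage$vertical_coverage[keep]
  tot <- colSums(m)
  if (any(tot == 0))
    stop("no species with nonzero coverage in sample '",
         samples[tot == 0][1], "': composition undefined")
  m <- sweep(m, 2, tot, "/")
  if (!is.null(sample)) m[, 1] else m
}

#' Compositional similarity between two samples
#'
#' Pearson correlation of log-transformed relative abundances across a
#' common species universe (the union of species named in either profile).
#' Zeros are shifted by a small pseudocount before the log transform.
#'
#' @param a,b named relative-abundance vectors (one sample each, e.g.
#'   columns of [relative_abundance()]).
#' @param pseudocount positive shift added to abundances before `log`;
#'   default `1e-6`, roughly the smallest detectable abundance.
#' @return correlation in \eqn{[-1, 1]}, or `NA` when either log-vector has
#'   zero variance (the correlation is undefined, not zero).
#' @export
composition_similarity <- function(a, b, pseudocount = 1e-6) {
  stopifnot(pseudocount > 0)
  if (is.null(names(a)) || is.null(names(b)))
    stop("abundance profiles must be named by species")
  universe <- union(names(a), names(b))
  av <- setNames(numeric(length(universe)), universe)
  bv <- av
  av[names(a)] <- a
  bv[names(b)] <- b
  la <- log(av + pseudocount)
  lb <- log(bv + pseudocount)
  if (sd(la) == 0 || sd(lb) == 0) {
    warning("zero variance in log-abundance vector; similarity undefined")
    return(NA_real_)
  }
  cor(la, lb)
}
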