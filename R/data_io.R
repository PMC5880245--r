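# Data containers and file formats.
#
# SNV tables follow the tabular dialect of metagenomic SNV callers: one row
# per biallelic position ("contig:pos:ref>alt"), one column per sample, cells
# holding the observed non-reference allele frequency in [0,1]. An empty
# cell means the position was not covered in that sample (MISSING), which is
# distinct from 0 (covered, reference-only).

AGE_GROUP_LEVELS <- c("Neonate", "6_months", "12_months", "2_10y", "10_25y", "over_25y")
# left-closed, right-open day boundaries: 1 wk, 6 mo, 2 yr, 10 yr, 25 yr
AGE_GROUP_BREAKS <- c(0, 7, 183, 730, 3652, 9131, Inf)

DELIVERY_MODES <- c("vaginal", "caesarean", "not_applicable")
ROLES <- c("mother", "father", "child")

#' Construct an SNV allele-frequency matrix
#'
#' A thin S3 wrapper around a numeric matrix of observed alternative-allele
#' frequencies: rows are biallelic genomic positions named
#' `"contig:pos:ref>alt"`, columns are samples. `NA` encodes MISSING (the
#' position was not covered in that sample) and is deliberately distinct
#' from `0` (covered, only the reference allele observed).
#'
#' @param values numeric matrix with row and column names; entries in
#'   \eqn{[0,1]} or `NA`.
#' @param species_id single string identifying the species the positions
#'   belong to.
#' @return an object of class `snv_matrix`.
#' @export
snv_matrix <- function(values, species_id) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have position rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate position ids: ", rownames(values)[duplicated(rownames(values))][1])
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids in SNV matrix")
  bad <- !is.na(values) & (values < 0 | values > 1)
  if (any(bad)) {
    i <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("allele frequency outside [0,1] at position '%s', sample '%s'",
                 rownames(values)[i[1]], colnames(values)[i[2]]))
  }
  .parse_position_ids(rownames(values))  # validates coordinates
  structure(values, species_id = as.character(species_id),
            class = c("snv_matrix", class(values)))
}

#' @export
print.snv_matrix <- function(x, ...) {
  cat(sprintf("<snv_matrix> species '%s': %d positions x %d samples (%.1f%% missing)\n",
              attr(x, "species_id"), nrow(x), ncol(x), 100 * mean(is.na(x))))
  invisible(x)
}

#' Species identifier of an SNV matrix
#' @param x an `snv_matrix`.
#' @return a string.
#' @export
species_id <- function(x) attr(x, "species_id")

.parse_position_ids <- function(ids) {
  m <- regmatches(ids, regexec("^(.+):([0-9]+):([ACGT]+)>([ACGT]+)$", ids))
  bad <- vapply(m, length, 1L) != 5L
  if (any(bad))
    stop("malformed position id (expected 'contig:pos:ref>alt'): '",
         ids[which(bad)[1]], "'")
  coord <- as.integer(vapply(m, `[`, "", 3L))
  if (any(coord < 1L))
    stop("coordinates must be 1-based positive integers")
  data.frame(contig = vapply(m, `[`, "", 2L), coordinate = coord,
             ref_allele = vapply(m, `[`, "", 4L),
             alt_allele = vapply(m, `[`, "", 5L))
}

#' Parse position ids into their components
#'
#' @param x an `snv_matrix` or a character vector of `"contig:pos:ref>alt"` ids.
#' @return data frame with columns contig, coordinate, ref_allele, alt_allele.
#' @export
snv_positions <- function(x) {
  ids <- if (inherits(x, "snv_matrix")) rownames(x) else as.character(x)
  cbind(position_id = ids, .parse_position_ids(ids))
}

#' Read an SNV allele-frequency table
#'
#' Reads the tab-separated dialect described in the package overview: first
#' column `position` (`"contig:pos:ref>alt"`), one column per sample, empty
#' cells for positions not covered in a sample.
#'
#' @param path path to a TSV file.
#' @param species_id species identifier; defaults to the file name without
#'   extension.
#' @return an [snv_matrix()].
#' @export
read_snv_table <- function(path, species_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(species_id))
    species_id <- sub("\\.[^.]*$", "", basename(path))
  d <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                  colClasses = "character", na.strings = "")
  if (ncol(d) < 2) stop("SNV table must have a position column and >=1 sample")
  ids <- d[[1]]
  if (anyDuplicated(ids))
    stop("duplicate position in '", path, "': row ",
         which(duplicated(ids))[1] + 1L, " ('", ids[duplicated(ids)][1], "')")
  vals <- as.matrix(d[, -1, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(vals), nrow = nrow(vals)))
  bad <- is.na(num) & !is.na(vals)
  if (any(bad)) {
    i <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric frequency in '%s': row %d ('%s'), sample '%s'",
                 path, i[1] + 1L, ids[i[1]], colnames(vals)[i[2]]))
  }
  out <- !is.na(num) & (num < 0 | num > 1)
  if (any(out)) {
    i <- which(out, arr.ind = TRUE)[1, ]
    stop(sprintf("frequency outside [0,1] in '%s': row %d ('%s'), sample '%s'",
                 path, i[1] + 1L, ids[i[1]], colnames(vals)[i[2]]))
  }
  dimnames(num) <- list(ids, colnames(vals))
  snv_matrix(num, species_id)
}

#' Write an SNV allele-frequency table
#'
#' Inverse of [read_snv_table()]: `NA` (MISSING) is written as an empty cell,
#' so the missingness mask round-trips exactly.
#'
#' @param x an [snv_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_snv_table <- function(x, path) {
  stopifnot(inherits(x, "snv_matrix"))
  d <- data.frame(position = rownames(x), unclass(x), check.names = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' Read / write a per-species coverage table
#'
#' TSV with columns `species_id`, `sample_id`, `vertical_coverage` (mean read
#' depth over the genome, x) and `horizontal_coverage` (fraction of genome
#' positions covered at all, in \eqn{[0,1]}).
#'
#' @param path file path.
#' @return data frame with the four columns above.
#' @export
read_coverage_table <- function(path) {
  d <- read.delim(path, sep = "\t", check.names = FALSE)
  validate_coverage_table(d)
}

#' @rdname read_coverage_table
#' @param coverage a coverage table data frame.
#' @export
write_coverage_table <- function(coverage, path) {
  validate_coverage_table(coverage)
  write.table(coverage, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_coverage_table
#' @export
validate_coverage_table <- function(coverage) {
  need <- c("species_id", "sample_id", "vertical_coverage", "horizontal_coverage")
  miss <- setdiff(need, names(coverage))
  if (length(miss)) stop("coverage table lacks columns: ", paste(miss, collapse = ", "))
  if (any(coverage$vertical_coverage < 0)) stop("negative vertical coverage")
  if (any(coverage$horizontal_coverage < 0 | coverage$horizontal_coverage > 1))
    stop("horizontal coverage outside [0,1]")
  zero <- coverage$vertical_coverage == 0 & coverage$horizontal_coverage > 0
  if (any(zero))
    stop("vertical coverage 0 with nonzero horizontal coverage for species '",
         coverage$species_id[zero][1], "', sample '", coverage$sample_id[zero][1], "'")
  if (anyDuplicated(coverage[c("species_id", "sample_id")]))
    stop("duplicated (species_id, sample_id) in coverage table")
  coverage
}

#' Validate cohort metadata
#'
#' One row per sample. Required columns: `sample_id`, `individual_id`,
#' `family_id`, `age_days`, `delivery_mode` (`vaginal`, `caesarean`,
#' `not_applicable`), `role` (`mother`, `father`, `child`). Optional:
#' `twin_group` (shared by co-twins), `timepoint_index` (computed from
#' `age_days` if absent) and `collection_day` (a shared cohort timeline used
#' to align samples of different individuals in time).
#'
#' @param metadata data frame as described above.
#' @return the validated data frame, with `timepoint_index` and an
#'   `age_group` factor added, classed `cohort_metadata`.
#' @export
cohort_metadata <- function(metadata) {
  need <- c("sample_id", "individual_id", "family_id", "age_days",
            "delivery_mode", "role")
  miss <- setdiff(need, names(metadata))
  if (length(miss)) stop("metadata lacks columns: ", paste(miss, collapse = ", "))
  m <- as.data.frame(metadata)
  if (anyDuplicated(m$sample_id))
    stop("duplicate sample_id: ", m$sample_id[duplicated(m$sample_id)][1])
  if (any(m$age_days < 0)) stop("negative age_days")
  if (!all(m$delivery_mode %in% DELIVERY_MODES))
    stop("delivery_mode must be one of: ", paste(DELIVERY_MODES, collapse = ", "))
  if (!all(m$role %in% ROLES))
    stop("role must be one of: ", paste(ROLES, collapse = ", "))
  # individual -> exactly one family and one role
  for (col in c("family_id", "role")) {
    k <- tapply(m[[col]], m$individual_id, function(v) length(unique(v)))
    if (any(k > 1))
      stop("individual '", names(k)[k > 1][1], "' has multiple values of ", col)
  }
  if (is.null(m$twin_group)) m$twin_group <- NA_character_
  if (is.null(metadata$timepoint_index)) {
    ord <- order(m$individual_id, m$age_days)
    tp <- unlist(lapply(split(seq_along(ord), m$individual_id[ord]), seq_along),
                 use.names = FALSE)
    m$timepoint_index[ord] <- tp
  } else {
    # user-supplied index must increase with age within individual
    chk <- split(m[c("timepoint_index", "age_days")], m$individual_id)
    ok <- vapply(chk, function(d) {
      d <- d[order(d$age_days), ]
      nrow(d) == 1 || all(diff(d$timepoint_index) > 0)
    }, TRUE)
    if (!all(ok))
      stop("timepoint_index not strictly increasing with age_days for individual '",
           names(chk)[!ok][1], "'")
  }
  m$age_group <- assign_age_group(m$age_days)
  class(m) <- c("cohort_metadata", "data.frame")
  m
}

#' @rdname cohort_metadata
#' @param path TSV path with the columns described above.
#' @export
read_cohort_metadata <- function(path) {
  cohort_metadata(read.delim(path, sep = "\t", check.names = FALSE,
                             na.strings = c("", "NA")))
}

#' @rdname cohort_metadata
#' @export
write_cohort_metadata <- function(metadata, path) {
  keep <- setdiff(names(metadata), "age_group")
  write.table(as.data.frame(metadata)[keep], path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "")
  invisible(path)
}

#' Assign samples to age groups
#'
#' Six groups partition age: `<1 wk` (Neonate), `1 wk - 6 mo` (6_months),
#' `6 mo - 2 yr` (12_months), `2 - 10 yr`, `10 - 25 yr`, and `>25 yr`.
#' Intervals are left-closed, right-open in days, with 1 wk = 7, 6 mo = 183,
#' 2 yr = 730, 10 yr = 3652 and 25 yr = 9131 days.
#'
#' @param age_days numeric vector of non-negative ages in days.
#' @return factor with levels `Neonate`, `6_months`, `12_months`, `2_10y`,
#'   `10_25y`, `over_25y`.
#' @export
assign_age_group <- function(age_days) {
  if (any(is.na(age_days)) || any(age_days < 0))
    stop("age_days must be non-negative and non-missing")
  cut(age_days, breaks = AGE_GROUP_BREAKS, labels = AGE_GROUP_LEVELS,
      right = FALSE, include.lowest = TRUE)
}

#' Are two individuals related?
#'
#' Related means: the same individual, or members of the same family.
#'
#' @param individual_a,individual_b individual ids.
#' @param metadata a [cohort_metadata()] table.
#' @return logical.
#' @export
related <- function(individual_a, individual_b, metadata) {
  fam <- .individual_families(metadata)
  for (i in c(individual_a, individual_b))
    if (!i %in% names(fam)) stop("unknown individual: '", i, "'")
  individual_a == individual_b ||
    fam[[individual_a]] == fam[[individual_b]]
}

.individual_families <- function(metadata) {
  u <- !duplicated(metadata$individual_id)
  setNames(as.character(metadata$family_id[u]),
           as.character(metadata$individual_id[u]))
}
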