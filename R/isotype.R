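# IGH constant-region measures: isotype usage, class-switch recombination
# index, somatic hypermutation (SHM) burden, percent mutated IgD/M, plus
# SHM on the light chains. All measures are clonotype-based: a unique VDJ
# clonotype is keyed by (cdr3_aa, v_call, j_call), so UMI counts do not
# enter.

vdj_key <- function(records) {
  paste(records$cdr3_aa, records$v_call, records$j_call, sep = "\r")
}

igh_subset <- function(records, sample) {
  rec <- records[records$chain == "IGH" & records$sample_id == sample &
                   !is.na(records$isotype), , drop = FALSE]
  rec
}

#' Per-isotype usage
#'
#' The usage of isotype X in a sample is the percentage of unique VDJ
#' clonotypes observed with isotype X, out of all (clonotype, isotype)
#' observations; a clonotype expressed as two isotypes contributes to
#' both. Percentages over observed isotypes sum to 100.
#'
#' @param records Clonotype record table.
#' @param sample Sample id.
#' @return Named numeric vector over `IGH_ISOTYPES` (percent), or all-`NA`
#'   when the sample has no isotype-resolved IGH records.
#' @export
isotype_usage <- function(records, sample) {
  rec <- igh_subset(records, sample)
  if (nrow(rec) == 0L)
    return(setNames(rep(NA_real_, length(IGH_ISOTYPES)), IGH_ISOTYPES))
  obs <- unique(data.frame(key = vdj_key(rec), isotype = rec$isotype,
                           stringsAsFactors = FALSE))
  counts <- table(factor(obs$isotype, levels = IGH_ISOTYPES))
  setNames(100 * as.numeric(counts) / sum(counts), IGH_ISOTYPES)
}

#' Class-switch recombination index
#'
#' Fraction of unique VDJ clonotypes expressed as both isotypes of a pair.
#' With the default `"union"` denominator the index is the Jaccard overlap
#' of the two isotypes' clonotype sets; `"conditional"` divides by the
#' first isotype's clonotype count only.
#'
#' @param records Clonotype record table.
#' @param sample Sample id.
#' @param pair Character vector of two distinct isotypes, e.g.
#'   `c("IgM", "IgG")`.
#' @param denominator `"union"` (default, symmetric) or `"conditional"`.
#' @return Fraction in `[0, 1]`, or `NA` when the denominator is empty.
#' @export
class_switch_index <- function(records, sample, pair,
                               denominator = c("union", "conditional")) {
  denominator <- match.arg(denominator)
  if (length(pair) != 2L || pair[1L] == pair[2L])
    stop("pair must name two distinct isotypes")
  if (!all(pair %in% IGH_ISOTYPES))
    stop("unknown isotype in pair: ", paste(pair, collapse = ", "))
  rec <- igh_subset(records, sample)
  keys_x <- unique(vdj_key(rec[rec$isotype == pair[1L], , drop = FALSE]))
  keys_y <- unique(vdj_key(rec[rec$isotype == pair[2L], , drop = FALSE]))
  shared <- length(intersect(keys_x, keys_y))
  denom <- if (denominator == "union") length(union(keys_x, keys_y))
           else length(keys_x)
  if (denom == 0L) return(NA_real_)
  shared / denom
}

#' Full pairwise class-switch matrix
#'
#' @inheritParams class_switch_index
#' @return Symmetric 5x5 matrix of switch indices (`NA` diagonal).
#' @export
class_switch_matrix <- function(records, sample,
                                denominator = c("union", "conditional")) {
  denominator <- match.arg(denominator)
  m <- base::matrix(NA_real_, 5L, 5L,
                    dimnames = list(IGH_ISOTYPES, IGH_ISOTYPES))
  for (i in 1:4) for (j in (i + 1):5) {
    v <- class_switch_index(records, sample,
                            c(IGH_ISOTYPES[i], IGH_ISOTYPES[j]),
                            denominator)
    m[i, j] <- v
    m[j, i] <- v
  }
  m
}

#' Somatic hypermutation rate
#'
#' Average number of V-region mutations per unique VDJ clonotype in a
#' stratum: an IGH isotype (e.g. `"IgG"`) or a light chain (`"IGK"`,
#' `"IGL"`). Clonotypes observed several times contribute their mean
#' mutation count once.
#'
#' @param records Clonotype record table.
#' @param stratum An isotype in `IGH_ISOTYPES` or a chain in
#'   `c("IGK", "IGL")`.
#' @param sample Optional sample id restriction.
#' @return Mean mutations per unique VDJ clonotype (`NA` with a warning
#'   when no mutation counts are available).
#' @export
shm_rate <- function(records, stratum, sample = NULL) {
  if (!is.null(sample))
    records <- records[records$sample_id == sample, , drop = FALSE]
  rec <- if (stratum %in% IGH_ISOTYPES)
    records[records$chain == "IGH" & !is.na(records$isotype) &
              records$isotype == stratum, , drop = FALSE]
  else if (stratum %in% c("IGK", "IGL"))
    records[records$chain == stratum, , drop = FALSE]
  else stop("stratum must be an IGH isotype or IGK/IGL")
  rec <- rec[!is.na(rec$v_mutation_count), , drop = FALSE]
  if (nrow(rec) == 0L) {
    warning("no mutation counts available for stratum ", stratum)
    return(NA_real_)
  }
  per_clonotype <- tapply(rec$v_mutation_count, vdj_key(rec), mean)
  mean(per_clonotype)
}

#' Percentage of mutated IgD/M clonotypes
#'
#' Fraction (percent) of unique IgD or IgM VDJ clonotypes carrying at
#' least `min_mutations` V-region mutations — a readout of antigen
#' experience in the unswitched compartment.
#'
#' @param records Clonotype record table.
#' @param sample Sample id.
#' @param min_mutations Mutation threshold defining "mutated", default 1.
#' @return Percentage in `[0, 100]`, or `NA` when the sample has no IgD/M
#'   clonotypes with mutation information.
#' @export
pct_mutated_igdm <- function(records, sample, min_mutations = 1) {
  rec <- igh_subset(records, sample)
  rec <- rec[rec$isotype %in% c("IgD", "IgM") &
               !is.na(rec$v_mutation_count), , drop = FALSE]
  if (nrow(rec) == 0L) return(NA_real_)
  per_clonotype <- tapply(rec$v_mutation_count, vdj_key(rec), mean)
  100 * mean(per_clonotype >= min_mutations)
}

#' Per-sample isotype profile
#'
#' Bundles the four isotype measures for one sample: usage percentages,
#' the pairwise class-switch matrix, per-isotype SHM means and the percent
#' of mutated IgD/M clonotypes.
#'
#' @inheritParams pct_mutated_igdm
#' @param denominator Switch-index denominator convention.
#' @return List with `usage`, `switch_matrix`, `shm`, `pct_mutated_igdm`.
#' @export
isotype_profile <- function(records, sample, min_mutations = 1,
                            denominator = "union") {
  shm <- vapply(IGH_ISOTYPES, function(iso)
    suppressWarnings(shm_rate(records, iso, sample)), numeric(1L))
  list(usage = isotype_usage(records, sample),
       switch_matrix = class_switch_matrix(records, sample, denominator),
       shm = shm,
       pct_mutated_igdm = pct_mutated_igdm(records, sample, min_mutations))
}
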