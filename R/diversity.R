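# Repertoire-level descriptors: diversity indices on clone frequency
# vectors, chain and gene-segment usage, clone-length distribution
# comparisons and publicity rarefaction.

check_freqs <- function(p, tol = 1e-9) {
  if (length(p) == 0L) stop("empty frequency vector")
  if (any(is.na(p)) || any(p < 0)) stop("frequencies must be non-negative")
  if (abs(sum(p) - 1) > tol)
    stop("frequencies must sum to 1 (got ", format(sum(p)), ")")
  p
}

#' Clone frequency vector from counts
#'
#' @param counts Non-negative clone counts, optionally named by CDR3.
#' @return Frequencies summing to one.
#' @export
clone_frequencies <- function(counts) {
  if (length(counts) == 0L || sum(counts) <= 0)
    stop("counts must contain at least one positive value")
  counts / sum(counts)
}

#' Shannon entropy of a clone frequency vector
#'
#' `-sum(p * log(p))` in natural log units (nats), with `0 * log(0) == 0`.
#' Captures both richness and evenness of the repertoire.
#'
#' @param p Clone frequencies summing to 1.
#' @return Entropy in nats.
#' @examples
#' shannon_entropy(rep(0.25, 4))  # log(4)
#' @export
shannon_entropy <- function(p) {
  p <- check_freqs(p)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Inverse Simpson index
#'
#' `1 / sum(p^2)`: the effective number of clones under proportional
#' abundance weighting. High values indicate an even repertoire, low values
#' clonal expansion.
#'
#' @inheritParams shannon_entropy
#' @export
inverse_simpson <- function(p) {
  p <- check_freqs(p)
  1 / sum(p^2)
}

#' Gini-Simpson index
#'
#' One minus Simpson's index, `1 - sum(p^2)`; low values indicate an
#' oligoclonal repertoire dominated by a few clones. With
#' `log_transform = TRUE` the natural log of the index is returned; a
#' single-clone repertoire has index 0 and the transform is then undefined,
#' returning `NA` with a warning.
#'
#' @inheritParams shannon_entropy
#' @param log_transform Return `log(1 - sum(p^2))` instead.
#' @export
gini_simpson <- function(p, log_transform = FALSE) {
  p <- check_freqs(p)
  gs <- 1 - sum(p^2)
  if (!log_transform) return(gs)
  if (gs <= 0) {
    warning("Gini-Simpson index is 0 (single clone); log transform undefined")
    return(NA_real_)
  }
  log(gs)
}

#' Number of dominant clones covering a cumulative frequency fraction
#'
#' D20 and D50 are the smallest number of top clones whose cumulative
#' frequency reaches 20% and 50% of the repertoire. Frequencies are sorted
#' in decreasing order; ties are broken by descending frequency then
#' lexicographic clone name, making the result deterministic.
#'
#' @inheritParams shannon_entropy
#' @param fraction Cumulative frequency target in (0, 1); 0.20 for D20,
#'   0.50 for D50.
#' @return Positive integer count of dominant clones.
#' @export
dxx <- function(p, fraction) {
  p <- check_freqs(p)
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  nm <- names(p) %||% sprintf("%09d", seq_along(p))
  o <- order(-p, nm)
  cum <- cumsum(p[o])
  as.integer(which(cum >= fraction - 1e-12)[1L])
}

#' Diversity profile of one (sample, chain) repertoire
#'
#' Computes the five complementary diversity measures: D20, D50,
#' Gini-Simpson (plus its log transform), Inverse-Simpson and Shannon
#' entropy, together with richness.
#'
#' @param counts Clone counts (named by CDR3 when tie-breaking matters).
#' @return One-row data frame.
#' @export
diversity_profile <- function(counts) {
  p <- clone_frequencies(counts)
  gs <- gini_simpson(p)
  data.frame(richness = length(p),
             d20 = dxx(p, 0.20),
             d50 = dxx(p, 0.50),
             gini_simpson = gs,
             log_gini_simpson = if (gs > 0) log(gs) else NA_real_,
             inverse_simpson = inverse_simpson(p),
             shannon = shannon_entropy(p))
}

#' Per-sample chain usage
#'
#' The usage of each receptor chain is the proportion of the sample's UMIs
#' assigned to that chain; all seven chains are reported (zero when
#' absent). Additionally reports the IGK share of light-chain reads,
#' `IGK / (IGK + IGL)` (`NA` when neither light chain is observed).
#'
#' @param records Clonotype record table.
#' @param sample Optional sample id; default computes all samples.
#' @return Data frame with one row per sample: seven usage columns plus
#'   `igk_share`.
#' @export
chain_usage <- function(records, sample = NULL) {
  if (!is.null(sample)) {
    records <- records[records$sample_id %in% sample, , drop = FALSE]
    if (nrow(records) == 0L) stop("no records for sample ", sample)
  }
  tot <- tapply(records$umi_count,
                list(records$sample_id,
                     factor(records$chain, levels = AIRR_CHAINS)),
                sum, default = 0)
  tot[is.na(tot)] <- 0
  usage <- tot / rowSums(tot)
  igk <- tot[, "IGK"]
  igl <- tot[, "IGL"]
  share <- ifelse(igk + igl > 0, igk / (igk + igl), NA_real_)
  out <- data.frame(sample_id = rownames(tot), usage, igk_share = share,
                    stringsAsFactors = FALSE, check.names = FALSE)
  rownames(out) <- NULL
  out
}

#' PCA of gene-segment usage
#'
#' Converts a segment-level count matrix to within-sample usage
#' proportions, removes rarely used segments, and performs a principal
#' component analysis (SVD on centered, optionally scaled usage). The
#' default filter drops segments detected in fewer than
#' `usage_filter * 100`% of samples; `filter = "mean_usage"` instead drops
#' segments whose mean usage is below `usage_filter`.
#'
#' @param matrix Segment-level `feature_matrix` (count scale).
#' @param usage_filter Filter threshold, default 0.05.
#' @param filter `"detection"` (default) or `"mean_usage"`.
#' @param scale. Scale usage columns to unit variance before PCA.
#' @return List with `scores` (samples x PC1/PC2), `loadings`,
#'   `var_explained` (all components), `n_removed`.
#' @export
segment_usage_pca <- function(matrix, usage_filter = 0.05,
                              filter = c("detection", "mean_usage"),
                              scale. = FALSE) {
  stopifnot(inherits(matrix, "feature_matrix"))
  filter <- match.arg(filter)
  if (ncol(matrix$counts) < 3L) stop("PCA needs at least 3 samples")
  usage <- t(sweep(matrix$counts, 2L, matrix$library_sizes, `/`))  # samples x segments
  keep <- if (filter == "detection") colMeans(usage > 0) >= usage_filter
          else colMeans(usage) >= usage_filter
  n_removed <- sum(!keep)
  usage <- usage[, keep, drop = FALSE]
  if (ncol(usage) < 2L)
    stop("fewer than 2 segments retained after the usage filter")
  if (scale.) {
    keep2 <- apply(usage, 2L, sd) > 0
    usage <- usage[, keep2, drop = FALSE]
  }
  pc <- prcomp(usage, center = TRUE, scale. = scale.)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x[, 1:2, drop = FALSE],
       loadings = pc$rotation[, 1:2, drop = FALSE],
       var_explained = ve,
       n_removed = n_removed)
}

#' Compare CDR3 length distributions between two groups of clones
#'
#' Multi-step comparison of clone-length distributions for one chain:
#' (i) a Wilcoxon rank-sum test for a global shift, on per-clone lengths
#' (each unique clone contributing once by default; `weighted = TRUE`
#' weights clones by their total UMI count); (ii) a per-length Fisher exact
#' test on the 2x2 table (clones of length L vs not, group A vs group B);
#' (iii) ECDF and quantile-quantile data series for plotting.
#'
#' @param records_a,records_b Record tables for the two groups.
#' @param chain Chain to analyze.
#' @param weighted Weight clone lengths by UMI counts in the shift test.
#' @return List with `wilcoxon_p`, `per_length` (length, counts, odds
#'   ratio, Fisher p), `ecdf` (long data frame), `qq` (quantile pairs).
#' @export
clone_length_analysis <- function(records_a, records_b, chain,
                                  weighted = FALSE) {
  lens <- function(rec) {
    rec <- rec[rec$chain == chain, , drop = FALSE]
    if (nrow(rec) == 0L) stop("a group has no records for chain ", chain)
    agg <- tapply(rec$umi_count, rec$cdr3_aa, sum)
    data.frame(cdr3_aa = names(agg), length = nchar(names(agg)),
               umi = as.numeric(agg), stringsAsFactors = FALSE)
  }
  a <- lens(records_a)
  b <- lens(records_b)
  la <- if (weighted) rep(a$length, a$umi) else a$length
  lb <- if (weighted) rep(b$length, b$umi) else b$length
  wp <- NA_real_
  if (length(unique(la)) < 2L || length(unique(lb)) < 2L) {
    warning("fewer than 2 distinct lengths in a group; shift test skipped")
  } else {
    wp <- suppressWarnings(wilcox.test(la, lb)$p.value)
  }
  all_len <- sort(unique(c(a$length, b$length)))
  per_length <- do.call(rbind, lapply(all_len, function(L) {
    tab <- matrix(c(sum(a$length == L), sum(a$length != L),
                    sum(b$length == L), sum(b$length != L)),
                  nrow = 2L, byrow = TRUE)
    ft <- fisher.test(tab)
    data.frame(length = L, n_a = tab[1L, 1L], n_b = tab[2L, 1L],
               odds_ratio = unname(ft$estimate), p = ft$p.value)
  }))
  probs <- seq(0.01, 0.99, by = 0.01)
  ecdf_series <- rbind(
    data.frame(group = "A", length = all_len, ecdf = ecdf(la)(all_len)),
    data.frame(group = "B", length = all_len, ecdf = ecdf(lb)(all_len)))
  qq <- data.frame(prob = probs,
                   q_a = as.numeric(quantile(la, probs, type = 1L)),
                   q_b = as.numeric(quantile(lb, probs, type = 1L)))
  list(wilcoxon_p = wp, per_length = per_length, ecdf = ecdf_series,
       qq = qq)
}

# clone x subject incidence (logical) for one chain
publicity_incidence <- function(records, subject_of, chain) {
  rec <- records[records$chain == chain, , drop = FALSE]
  subj <- subject_of[rec$sample_id]
  if (any(is.na(subj))) stop("sample(s) missing from subject mapping")
  clones <- unique(rec$cdr3_aa)
  subjects <- sort(unique(subj))
  m <- Matrix::sparseMatrix(i = match(rec$cdr3_aa, clones),
                            j = match(subj, subjects),
                            x = 1,
                            dims = c(length(clones), length(subjects)),
                            dimnames = list(clones, subjects))
  m > 0
}

#' Rarefied clone publicity spectra
#'
#' Clone publicity is the number of subjects in which a clone is detected.
#' Because sharing rises with group size, groups of unequal size are
#' compared after rarefaction: each iteration samples `subsample_size`
#' subjects per group without replacement and computes the fraction of
#' observed clones shared by at least k subjects; spectra are averaged over
#' iterations.
#'
#' @param records Clonotype record table.
#' @param metadata Sample metadata with `sample_id`, `subject_id` and the
#'   grouping column.
#' @param chain Chain to analyze.
#' @param group_col Metadata column defining the groups.
#' @param subsample_size Subjects drawn per group; must not exceed the
#'   smallest group.
#' @param n_iter Rarefaction iterations.
#' @param seed RNG seed for reproducibility.
#' @return Matrix of mean spectra, groups x k (`k = 1..subsample_size`);
#'   entry (g, k) is the mean fraction of clones shared by >= k subjects.
#' @export
publicity_rarefaction <- function(records, metadata, chain,
                                  group_col = "group", subsample_size,
                                  n_iter = 100, seed = NULL) {
  if (n_iter < 1) stop("n_iter must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  subject_of <- setNames(as.character(metadata$subject_id),
                         metadata$sample_id)
  group_of <- tapply(as.character(metadata[[group_col]]),
                     as.character(metadata$subject_id),
                     function(g) g[1L])
  inc <- publicity_incidence(records, subject_of, chain)
  groups <- sort(unique(as.character(group_of)))
  out <- matrix(0, nrow = length(groups), ncol = subsample_size,
                dimnames = list(groups, paste0("k", seq_len(subsample_size))))
  for (g in groups) {
    subs <- names(group_of)[group_of == g]
    subs <- intersect(subs, colnames(inc))
    if (length(subs) < subsample_size)
      stop("subsample_size exceeds group size for group ", g)
    acc <- numeric(subsample_size)
    for (it in seq_len(n_iter)) {
      pick <- sample(subs, subsample_size)
      pub <- Matrix::rowSums(inc[, pick, drop = FALSE])
      pub <- pub[pub > 0]
      acc <- acc + vapply(seq_len(subsample_size),
                          function(k) mean(pub >= k), numeric(1L))
    }
    out[g, ] <- acc / n_iter
  }
  out
}
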