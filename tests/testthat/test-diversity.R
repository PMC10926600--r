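test_that("diversity indices match closed forms and direct sums", {
  expect_equal(shannon_entropy(rep(0.25, 4)), log(4))
  expect_equal(shannon_entropy(1), 0)
  expect_equal(shannon_entropy(c(0.5, 0.25, 0.25)), 1.0397, tolerance = 1e-4)
  expect_equal(inverse_simpson(rep(1 / 7, 7)), 7)
  expect_equal(inverse_simpson(c(0.5, 0.5)), 2)
  expect_equal(inverse_simpson(c(0.5, 0.25, 0.25)), 1 / 0.375)
  expect_equal(gini_simpson(1), 0)
  expect_equal(gini_simpson(rep(0.1, 10)), 1 - 1 / 10)
  expect_equal(gini_simpson(c(0.5, 0.25, 0.25)), 0.625)
  expect_warning(lg <- gini_simpson(1, log_transform = TRUE), "single clone")
  expect_true(is.na(lg))
})

test_that("dxx agrees with brute-force prefix search and breaks ties", {
  expect_equal(dxx(rep(0.1, 10), 0.5), 5L)
  expect_equal(dxx(c(0.4, 0.3, 0.2, 0.1), 0.5), 2L)
  brute_dxx <- function(p, fr) {
    o <- order(-p, names(p) %||% seq_along(p))
    for (m in seq_along(p)) if (sum(p[o][1:m]) >= fr - 1e-12) return(m)
  }
  set.seed(11)
  for (i in 1:200) {
    k <- sample(2:40, 1)
    p <- rgamma(k, 1)
    p <- p / sum(p)
    names(p) <- random_cdr3(k)
    fr <- runif(1, 0.05, 0.95)
    expect_equal(dxx(p, fr), brute_dxx(p, fr))
    expect_lte(dxx(p, 0.2), dxx(p, 0.5))
  }
  expect_error(dxx(numeric(0), 0.5), "empty")
})

test_that("diversity profile invariants hold on random frequency vectors", {
  set.seed(5)
  for (i in 1:2000) {
    k <- sample(1:60, 1)
    counts <- rpois(k, 5) + 1
    names(counts) <- sprintf("c%03d", seq_len(k))
    pr <- diversity_profile(counts)
    expect_lte(pr$d20, pr$d50)
    expect_lte(pr$d50, pr$richness)
    expect_gte(pr$gini_simpson, 0)
    expect_lt(pr$gini_simpson, 1)
    expect_gte(pr$inverse_simpson, 1 - 1e-12)
    expect_lte(pr$inverse_simpson, pr$richness + 1e-9)
    expect_gte(pr$shannon, -1e-12)
    expect_lte(pr$shannon, log(pr$richness) + 1e-9)
  }
})

test_that("chain usage proportions sum to one with the IGK share", {
  rec <- rbind(make_records("A", "TRB", "CASSF", umi_count = 10),
               make_records("A", "IGK", c("CQQF", "CQRF"),
                            umi_count = c(20, 10)),
               make_records("A", "IGL", "CSSF", umi_count = 15))
  cu <- chain_usage(rec)
  expect_equal(sum(cu[1, AIRR_CHAINS]), 1)
  expect_equal(cu$igk_share, 30 / 45)
  only_trb <- chain_usage(make_records("B", "TRB", "CASSF", umi_count = 5))
  expect_equal(only_trb$TRB, 1)
  expect_true(is.na(only_trb$igk_share))
  set.seed(2)
  sim <- tiny_cohort(seed = 2, n_cases = 3, n_controls = 3,
                     chains = list(TRB = list(richness = 50, depth = 500,
                                              len_mean = 14, len_sd = 1,
                                              n_v = 10, n_j = 5),
                                   IGK = list(richness = 30, depth = 400,
                                              len_mean = 9, len_sd = 1,
                                              n_v = 8, n_j = 4)))
  cu <- chain_usage(sim$records)
  expect_equal(rowSums(cu[, AIRR_CHAINS]), rep(1, nrow(cu)),
               ignore_attr = TRUE)
})

test_that("segment usage PCA matches an independent eigendecomposition", {
  set.seed(8)
  usage_counts <- base::matrix(rpois(10 * 6, 40), 6, 10,
                               dimnames = list(paste0("V", 1:6),
                                               paste0("s", 1:10)))
  fm <- feature_matrix(usage_counts, colSums(usage_counts), "segmentV",
                       "TRB")
  pca <- segment_usage_pca(fm, usage_filter = 0)
  # oracle: eigendecomposition of the covariance of centered usage
  usage <- t(sweep(usage_counts, 2, colSums(usage_counts), `/`))
  cen <- scale(usage, center = TRUE, scale = FALSE)
  eig <- eigen(crossprod(cen) / (nrow(cen) - 1))
  ve_oracle <- eig$values / sum(eig$values)
  expect_equal(pca$var_explained[1:2], ve_oracle[1:2], tolerance = 1e-8)
  scores_oracle <- cen %*% eig$vectors[, 1:2]
  for (j in 1:2)  # eigenvectors are sign-ambiguous
    expect_equal(abs(unname(pca$scores[, j])),
                 abs(unname(scores_oracle[, j])), tolerance = 1e-8)
  # two perfectly anticorrelated usages -> PC1 carries all variance
  two <- base::matrix(c(30, 70, 40, 60, 20, 80), 2, 3,
                      dimnames = list(c("V1", "V2"), c("a", "b", "c")))
  fm2 <- feature_matrix(two, colSums(two), "segmentV", "TRB")
  p2 <- segment_usage_pca(fm2, usage_filter = 0)
  expect_equal(p2$var_explained[1], 1, tolerance = 1e-12)
  # duplicate samples score identically
  dup <- base::matrix(c(30, 70, 30, 70, 10, 90), 2, 3,
                      dimnames = list(c("V1", "V2"), c("a", "b", "c")))
  fm3 <- feature_matrix(dup, colSums(dup), "segmentV", "TRB")
  p3 <- segment_usage_pca(fm3, usage_filter = 0)
  expect_equal(p3$scores["a", ], p3$scores["b", ])
  expect_error(segment_usage_pca(fm, usage_filter = 1.01), "retained")
})

test_that("clone length analysis detects shifts and reports exact tables", {
  set.seed(9)
  a <- make_records("A", "TRB", random_cdr3(150, 10, 16))
  b_same <- a
  b_same$sample_id <- "B"
  same <- clone_length_analysis(a, b_same, "TRB")
  expect_equal(same$per_length$n_a, same$per_length$n_b)
  expect_true(all(same$per_length$p > 0.999))
  # +3 shift on every length -> strong Wilcoxon signal
  b_shift <- make_records("B", "TRB",
                          paste0(random_cdr3(150, 10, 16), "AAA"))
  shift <- clone_length_analysis(a, b_shift, "TRB")
  expect_lt(shift$wilcoxon_p, 1e-4)
  # ECDF nondecreasing, ends at 1
  for (g in c("A", "B")) {
    e <- shift$ecdf[shift$ecdf$group == g, ]
    expect_true(all(diff(e$ecdf) >= 0))
    expect_equal(max(e$ecdf), 1)
  }
  one_len <- make_records("A", "TRB", c("CAAAF", "CAATF"))
  expect_warning(clone_length_analysis(one_len, b_same, "TRB"),
                 "distinct lengths")
})

test_that("rarefied publicity matches exhaustive subset enumeration", {
  # 5 subjects, clones with known publicity
  subj <- paste0("P", 1:5)
  rec <- do.call(rbind, lapply(1:5, function(i) {
    clones <- c("CAAAAF",                      # in every subject
                paste0("CPRIV", i, "F"))       # private
    if (i <= 3) clones <- c(clones, "CSHRDF")  # in subjects 1-3
    make_records(paste0("S", i), "TRB", clones)
  }))
  meta <- data.frame(sample_id = paste0("S", 1:5), subject_id = subj,
                     group = "g", stringsAsFactors = FALSE)
  spec <- publicity_rarefaction(rec, meta, "TRB", subsample_size = 3,
                                n_iter = 4000, seed = 1)
  # exact expectation by enumerating all C(5,3) subsets
  subsets <- combn(1:5, 3, simplify = FALSE)
  spectra <- sapply(subsets, function(ss) {
    pub <- c(3,                                   # CAAAAF
             rep(1, 3),                           # private clones of ss
             if (any(ss <= 3)) sum(ss <= 3))      # CSHRDF
    vapply(1:3, function(k) mean(pub >= k), numeric(1))
  })
  expect_equal(unname(spec["g", ]), rowMeans(spectra), tolerance = 0.03)
  # monotone nonincreasing in k
  expect_true(all(diff(unname(spec["g", ])) <= 1e-12))
  expect_error(publicity_rarefaction(rec, meta, "TRB", subsample_size = 9,
                                     n_iter = 2), "exceeds")
})
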