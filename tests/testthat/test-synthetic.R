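test_that("generation is deterministic under seed and depth-exact", {
  chains <- list(TRB = list(richness = 80, depth = 1500, len_mean = 14,
                            len_sd = 1.5, n_v = 12, n_j = 6))
  cfg <- cohort_config(n_cases = 5, n_controls = 5, chains = chains,
                       seed = 9, depth_cv = 0)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  # multinomial conditioning: per-sample chain totals equal the depth
  totals <- tapply(a$records$umi_count, a$records$sample_id, sum)
  expect_true(all(totals == 1500))
  expect_true(all(a$metadata$total_umis == 1500))
  validate_records(a$records)
})

test_that("publicity model keeps the median observed clone private", {
  sim <- tiny_cohort(seed = 19, n_cases = 12, n_controls = 12)
  rec <- sim$records[sim$records$chain == "TRB", ]
  pub <- tapply(rec$sample_id, rec$cdr3_aa, function(s) length(unique(s)))
  expect_equal(unname(median(pub)), 1)
  expect_gt(max(pub), 3)  # but a public tail exists
})

test_that("power-law abundances give dominant top clones", {
  set.seed(20)
  top_vs_med <- replicate(20, {
    sim <- tiny_cohort(seed = sample.int(1e6, 1), n_cases = 1,
                       n_controls = 1,
                       chains = list(TRB = list(richness = 500,
                                                depth = 30000,
                                                len_mean = 14, len_sd = 1.5,
                                                n_v = 20, n_j = 8)))
    counts <- sim$records$umi_count[sim$records$sample_id == "S001"]
    max(counts) / median(counts)
  })
  expect_true(all(top_vs_med > 10))
})

test_that("planted differential clones carry the configured shifts", {
  chains <- list(TRB = list(richness = 150, depth = 4000, len_mean = 14,
                            len_sd = 1.5, n_v = 15, n_j = 6))
  cfg <- cohort_config(n_cases = 40, n_controls = 40, chains = chains,
                       seed = 23,
                       spike = list(chain = "TRB", n_clones = 10,
                                    detection_p0 = 0.4,
                                    detection_odds = 6, log2fc = 1))
  sim <- generate_cohort(cfg)
  truth <- sim$truth$differential_clones
  expect_equal(nrow(truth), 10)
  expect_true(all(truth$observed))
  cases <- sim$metadata$sample_id[sim$metadata$group == "case"]
  controls <- sim$metadata$sample_id[sim$metadata$group == "control"]
  rec <- sim$records[sim$records$chain == "TRB", ]
  det_case <- vapply(truth$cdr3_aa, function(cl)
    mean(cases %in% rec$sample_id[rec$cdr3_aa == cl]), numeric(1))
  det_ctrl <- vapply(truth$cdr3_aa, function(cl)
    mean(controls %in% rec$sample_id[rec$cdr3_aa == cl]), numeric(1))
  expect_gt(mean(det_case), mean(det_ctrl) + 0.15)
})

test_that("post-hoc spiking shifts cases only and validates targets", {
  sim <- tiny_cohort(seed = 29, n_cases = 10, n_controls = 10)
  rec <- sim$records[sim$records$chain == "TRB", ]
  pub <- tapply(rec$sample_id, rec$cdr3_aa, function(s) length(unique(s)))
  target <- names(sort(pub, decreasing = TRUE))[1:3]
  before <- sim$records
  set.seed(1)
  sp <- spike_differential_features(sim$records, sim$metadata, "TRB",
                                    target, detection_odds = Inf,
                                    log2fc = 2)
  controls <- sim$metadata$sample_id[sim$metadata$group == "control"]
  for (cl in target) {
    rows_new <- sp$records[sp$records$cdr3_aa == cl, ]
    rows_old <- before[before$cdr3_aa == cl & before$chain == "TRB", ]
    # control rows untouched
    expect_equal(rows_new[rows_new$sample_id %in% controls, ],
                 rows_old[rows_old$sample_id %in% controls, ],
                 ignore_attr = TRUE)
    # detection-odds Inf makes the clone present in every case sample
    cases <- sim$metadata$sample_id[sim$metadata$group == "case"]
    expect_setequal(intersect(cases, rows_new$sample_id), cases)
  }
  expect_error(spike_differential_features(sim$records, sim$metadata,
                                           "TRB", "ZZZNOPEZZZ"),
               "non-existent")
})

test_that("planted k-mer motifs enrich case repertoires", {
  chains <- list(TRB = list(richness = 120, depth = 3000, len_mean = 14,
                            len_sd = 1.5, n_v = 15, n_j = 6))
  cfg <- cohort_config(n_cases = 15, n_controls = 15, chains = chains,
                       seed = 31,
                       spike = list(chain = "TRB", n_clones = 0,
                                    kmer = list(motif = "DHRE",
                                                case_clone_fraction = 0.3)))
  sim <- generate_cohort(cfg)
  expect_equal(sim$truth$kmer$motif, "DHRE")
  km <- kmer_matrix(sim$records, chain = "TRB",
                    samples = sort(sim$metadata$sample_id))
  expect_true("DHRE" %in% rownames(km$counts))
  grp <- sim$metadata$group[match(colnames(km$counts),
                                  sim$metadata$sample_id)]
  case_mean <- mean(km$counts["DHRE", grp == "case"] > 0)
  ctrl_mean <- mean(km$counts["DHRE", grp == "control"] > 0)
  expect_gt(case_mean, ctrl_mean)
})

test_that("longitudinal generation pairs subjects and plants fold changes", {
  chains <- list(IGH = list(richness = 150, depth = 20000, len_mean = 15,
                            len_sd = 2, n_v = 15, n_j = 5),
                 TRB = list(richness = 150, depth = 20000, len_mean = 14,
                            len_sd = 1.5, n_v = 15, n_j = 6))
  cfg <- cohort_config(n_cases = 12, n_controls = 0, chains = chains,
                       seed = 37, depth_cv = 0)
  sim <- generate_longitudinal(cfg)
  # every subject has exactly 2 samples
  expect_true(all(table(sim$metadata$subject_id) == 2))
  expect_setequal(unique(sim$metadata$timepoint), c("baseline", "week12"))
  dyn <- sim$truth$dynamics
  expect_true(all(dyn$label %in% c("contracted", "expanded")))
  expect_true(all(dyn$log2fc[dyn$label == "contracted"] < 0))
  expect_true(all(dyn$log2fc[dyn$label == "expanded"] > 0))
  # contraction rate larger for the BCR chain by construction
  n_igh <- length(unique(sim$records$cdr3_aa[sim$records$chain == "IGH"]))
  n_trb <- length(unique(sim$records$cdr3_aa[sim$records$chain == "TRB"]))
  frac_igh <- sum(dyn$chain == "IGH" & dyn$label == "contracted") / n_igh
  frac_trb <- sum(dyn$chain == "TRB" & dyn$label == "contracted") / n_trb
  expect_gt(frac_igh, frac_trb)
  # a strongly contracted high-frequency clone drops as expected
  rec <- sim$records
  strong <- dyn[dyn$label == "contracted" & dyn$log2fc < -2, ]
  key_pre <- paste(rec$chain, rec$cdr3_aa)
  pre <- tapply(rec$umi_count[rec$sample_id %in%
                                sim$metadata$sample_id[
                                  sim$metadata$timepoint == "baseline"]],
                key_pre[rec$sample_id %in%
                          sim$metadata$sample_id[
                            sim$metadata$timepoint == "baseline"]], sum)
  post <- tapply(rec$umi_count[grepl("w12$", rec$sample_id)],
                 key_pre[grepl("w12$", rec$sample_id)], sum)
  skey <- paste(strong$chain, strong$cdr3_aa)
  common <- skey[skey %in% names(pre) & pre[skey] >= 50]
  post_counts <- ifelse(is.na(post[common]), 0, post[common])
  expect_lt(sum(post_counts), 0.6 * sum(pre[common]))
})

test_that("infeasible configurations are rejected", {
  expect_error(cohort_config(chains = list(
    TRB = list(richness = 1e7, depth = 100, len_mean = 6, len_sd = 0.1,
               n_v = 5, n_j = 2))), "infeasible|capacity")
  expect_error(cohort_config(isotype_mix = c(IgM = 0.7, IgD = 0.1,
                                             IgG = 0.1, IgA = 0.05,
                                             IgE = 0.5)), "sum to 1")
  expect_error(cohort_config(chains = "XXX"), "unknown chain")
})
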