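test_that("negative-binomial baseline model recovers a planted effect", {
  set.seed(101)
  est <- replicate(40, {
    n <- 200
    meta <- data.frame(sample_id = seq_len(n), age = rnorm(n, 50, 10),
                       sex = sample(c("M", "F"), n, TRUE),
                       total_umis = round(runif(n, 5e3, 2e4)))
    x <- rep(c("case", "control"), each = n / 2)
    mu <- exp(log(meta$total_umis) - 6 + 0.8 * (x == "case"))
    y <- rnbinom(n, size = 3, mu = mu)
    fit <- fit_baseline_association(y, factor(x, c("control", "case")),
                                    meta, family = "negative_binomial")
    fit$effect
  })
  expect_lt(abs(median(est) - 0.8), 0.15)
})

test_that("baseline models are calibrated under the null and reject bad input", {
  set.seed(102)
  ps <- replicate(300, {
    n <- 80
    meta <- data.frame(sample_id = seq_len(n), age = rnorm(n, 50, 10),
                       sex = sample(c("M", "F"), n, TRUE),
                       total_umis = rep(1e4, n))
    x <- sample(rep(c("case", "control"), each = n / 2))
    y <- rnorm(n)
    fit_baseline_association(y, x, meta, family = "gaussian")$p
  })
  expect_gt(mean(ps < 0.05), 0.02)
  expect_lt(mean(ps < 0.05), 0.09)
  meta <- data.frame(sample_id = 1:10, age = rep(50, 10),
                     sex = rep("F", 10), total_umis = rep(1e4, 10))
  expect_error(
    fit_baseline_association(rnorm(10), rep(c("a", "b"), 5), meta,
                             family = "gaussian"),
    "age|constant")
  expect_error(
    fit_baseline_association(rnorm(10), rep("a", 10),
                             data.frame(sample_id = 1:10,
                                        age = rnorm(10),
                                        sex = rep(c("M", "F"), 5)),
                             family = "logistic"),
    "2 outcome classes")
})

test_that("longitudinal mixed model recovers an exact within-subject shift", {
  set.seed(103)
  n <- 25
  subj <- rep(seq_len(n), each = 2)
  tp <- rep(c("baseline", "week12"), n)
  base <- rnorm(n, 10, 2)
  delta <- 1.7
  y <- base[subj] + delta * (tp == "week12") + rnorm(2 * n, 0, 1e-8)
  meta <- data.frame(sample_id = seq_len(2 * n),
                     age = rep(rnorm(n, 50, 8), each = 2),
                     sex = rep(sample(c("M", "F"), n, TRUE), each = 2))
  fit <- fit_longitudinal_mixed(y, tp, subj, meta)
  expect_equal(fit$effect, delta, tolerance = 1e-6)
  expect_error(
    fit_longitudinal_mixed(y[-1], tp[-1], subj[-1], meta[-1, ]),
    "both timepoints")
})

test_that("hurdle results carry coherent two-part structure", {
  set.seed(104)
  sim <- tiny_cohort(seed = 104, n_cases = 15, n_controls = 15)
  fm <- build_feature_matrix(sim$records, "clone", chain = "TRB",
                             samples = sort(sim$metadata$sample_id))
  lg <- cpm_log_transform(filter_low_detection(fm, 0.1))
  ph <- setNames(sim$metadata$group, sim$metadata$sample_id)
  h <- hurdle_test(lg, ph, sim$metadata)
  expect_true(all(h$p_hurdle >= 0 & h$p_hurdle <= 1, na.rm = TRUE))
  expect_true(all(h$q >= h$p_hurdle - 1e-12, na.rm = TRUE))
  # features detected everywhere fall back to the continuous part
  full_det <- h[h$flag == "all_detected", ]
  if (nrow(full_det) > 0)
    expect_equal(full_det$p_hurdle, full_det$p_cont)
  # all-zero feature is rejected
  bad <- lg
  bad$counts <- rbind(bad$counts, ZZZZ = 0)
  expect_error(hurdle_test(bad, ph, sim$metadata), "all-zero")
})

test_that("case-only detection signal loads on the discrete part", {
  set.seed(105)
  n <- 100
  meta <- data.frame(sample_id = sprintf("s%03d", 1:(2 * n)),
                     age = rnorm(2 * n, 50, 10),
                     sex = sample(c("M", "F"), 2 * n, TRUE))
  ph <- setNames(rep(c("case", "control"), each = n), meta$sample_id)
  counts <- base::matrix(rpois(40 * 2 * n, 2) + 1, 40, 2 * n,
                         dimnames = list(sprintf("f%02d", 1:40),
                                         meta$sample_id))
  # feature f01: detected in 20 cases, 0 controls, equal abundance
  counts["f01", ] <- 0
  counts["f01", sample(which(ph == "case"), 20)] <- 5
  fm <- feature_matrix(counts, setNames(rep(1000, 2 * n), meta$sample_id),
                       "clone", "TRB")
  lg <- cpm_log_transform(fm)
  h <- hurdle_test(lg, ph, meta)
  f1 <- h[h$feature == "f01", ]
  expect_lt(f1$p_disc, 1e-4)
  expect_true(is.na(f1$p_cont) || f1$p_disc < f1$p_cont)
})

test_that("BH adjustment matches brute force and propagates NA", {
  expect_equal(fdr_adjust(0.03), 0.03)
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  brute_bh <- function(p) {
    m <- length(p)
    o <- order(p)
    q <- p[o] * m / seq_len(m)
    q <- rev(cummin(rev(q)))
    out <- numeric(m)
    out[o] <- pmin(q, 1)
    out
  }
  set.seed(106)
  for (i in 1:200) {
    p <- runif(sample(1:50, 1))
    expect_equal(fdr_adjust(p), brute_bh(p))
    # order invariance
    perm <- sample(length(p))
    expect_equal(fdr_adjust(p[perm]), fdr_adjust(p)[perm])
  }
  q <- fdr_adjust(c(0.01, NA, 0.04))
  expect_true(is.na(q[2]))
  expect_equal(q[c(1, 3)], fdr_adjust(c(0.01, 0.04)))
  expect_error(fdr_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("dynamics summary reproduces exact Fisher and detects magnitude shifts", {
  set.seed(107)
  # hand-built 2x2: BCR 30 contracted of 100, TCR 10 of 100
  dyn <- data.frame(
    clone_id = sprintf("c%03d", 1:200),
    chain = rep(c("IGH", "TRB"), each = 100),
    label = c(rep("contracted", 30), rep("unchanged", 70),
              rep("contracted", 10), rep("unchanged", 90)),
    magnitude = abs(rnorm(200)), stringsAsFactors = FALSE)
  ds <- suppressWarnings(dynamics_summary(dyn))
  oracle <- fisher.test(base::matrix(c(30, 70, 10, 90), 2, byrow = TRUE))
  expect_equal(ds$fisher$p[ds$fisher$direction == "contracted"],
               oracle$p.value)
  # balanced proportions give odds ratio ~ 1
  dyn_eq <- dyn
  dyn_eq$label <- rep(c(rep("contracted", 20), rep("unchanged", 80)), 2)
  ds_eq <- suppressWarnings(dynamics_summary(dyn_eq))
  expect_equal(ds_eq$fisher$odds_ratio[1], 1, tolerance = 0.02)
  # contracted |change| stochastically larger -> Wilcoxon detects
  dyn2 <- data.frame(
    clone_id = sprintf("d%04d", 1:1000),
    chain = "IGH",
    label = rep(c("contracted", "expanded"), each = 500),
    magnitude = c(abs(rnorm(500, 3, 1)), abs(rnorm(500, 2, 1))),
    stringsAsFactors = FALSE)
  ds2 <- suppressWarnings(dynamics_summary(dyn2))
  expect_lt(ds2$wilcoxon$p[1], 1e-6)
  # magnitude formula with the documented epsilon
  dyn3 <- data.frame(clone_id = "x", chain = "IGH", label = "contracted",
                     freq_pre = 0.01, freq_post = 0.001,
                     stringsAsFactors = FALSE)
  ds3 <- suppressWarnings(dynamics_summary(dyn3, min_depth = 1e4))
  eps <- 1 / (2 * 1e4)
  expect_equal(ds3$dynamics$magnitude,
               abs(log2((0.001 + eps) / (0.01 + eps))))
})
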