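# The statistical engine: baseline GLM associations, paired longitudinal
# mixed models, the CDR-adjusted two-part hurdle model for clone-like
# features, FDR control and clone-dynamics summaries.

# ---- internal: fast logistic fitting by IRLS --------------------------------
# Small fixed designs are fit thousands of times per hurdle call, so a thin
# iteratively-reweighted-least-squares routine with an optional ridge
# penalty (the perfect-separation fallback) is used instead of glm().
irls_logistic <- function(X, y, weights = NULL, ridge = 0, maxit = 30L,
                          tol = 1e-8, vcov = FALSE) {
  n <- nrow(X)
  p <- ncol(X)
  w_obs <- weights %||% rep(1, n)
  beta <- numeric(p)
  beta[1L] <- qlogis(min(max(sum(w_obs * y) / sum(w_obs), 1e-6), 1 - 1e-6))
  dev_old <- Inf
  separated <- FALSE
  clamp <- function(mu) {
    mu[mu < 1e-12] <- 1e-12
    mu[mu > 1 - 1e-12] <- 1 - 1e-12
    mu
  }
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- clamp(plogis(eta))
    Wmu <- mu * (1 - mu)
    W <- w_obs * Wmu
    H <- crossprod(X, X * W)
    if (ridge > 0) diag(H) <- diag(H) + ridge
    rhs <- crossprod(X, W * eta + w_obs * (y - mu))
    beta_new <- tryCatch(solve(H, rhs), error = function(e) NULL)
    if (is.null(beta_new)) { separated <- TRUE; break }
    beta <- drop(beta_new)
    dev <- -2 * sum(w_obs * (y * log(mu) + (1 - y) * log(1 - mu)))
    if (abs(dev - dev_old) < tol) break
    dev_old <- dev
  }
  mu <- clamp(plogis(drop(X %*% beta)))
  dev <- -2 * sum(w_obs * (y * log(mu) + (1 - y) * log(1 - mu)))
  if (max(abs(beta)) > 15) separated <- TRUE
  vc <- NULL
  if (vcov) {
    vc <- tryCatch({
      H <- crossprod(X, X * (w_obs * mu * (1 - mu)))
      if (ridge > 0) diag(H) <- diag(H) + ridge
      solve(H)
    }, error = function(e) base::matrix(NA_real_, p, p))
  }
  list(coef = beta, deviance = dev, separated = separated, vcov = vc)
}

# Firth-penalized logistic fit: the Jeffreys-prior score adjustment keeps
# coefficients finite under separation, stabilizing null fits with very
# few events.
firth_logistic <- function(X, y, maxit = 40L, tol = 1e-6) {
  p <- ncol(X)
  beta <- numeric(p)
  beta[1L] <- qlogis(min(max(mean(y), 1e-6), 1 - 1e-6))
  for (it in seq_len(maxit)) {
    mu <- plogis(drop(X %*% beta))
    W <- mu * (1 - mu)
    XW <- X * sqrt(W)
    XtWX <- crossprod(XW)
    inv <- tryCatch(solve(XtWX), error = function(e) NULL)
    if (is.null(inv)) break
    h <- rowSums((XW %*% inv) * XW)
    U <- crossprod(X, y - mu + h * (0.5 - mu))
    if (max(abs(U)) < tol) break
    beta <- beta + drop(solve(XtWX, U))
  }
  list(coef = beta)
}

# Logistic association test of the term in column 2 of X_full against the
# covariate-only null. The chi-square is the Rao score statistic computed
# at the null fit: with the few detected samples typical of sparse clones
# the likelihood-ratio statistic is markedly anti-conservative, while the
# score statistic keeps its nominal level (and needs no full-model MLE, so
# it is immune to separation in the term of interest). When the null fit
# itself degenerates (nuisance-covariate separation with a handful of
# events), it is refit by Firth penalization before the score statistic is
# formed. The effect estimate still comes from the full ML fit,
# ridge-penalized (1e-4) and flagged when separation occurs.
logistic_lrt <- function(X_full, X_null, y, weights = NULL,
                         ridge_fallback = 1e-4, effect = TRUE) {
  w_obs <- weights %||% rep(1, length(y))
  null <- irls_logistic(X_null, y, weights)
  if (null$separated) null$coef <- firth_logistic(X_null, y)$coef
  score_chi2 <- function(null_coef) {
    mu0 <- pmin(pmax(plogis(drop(X_null %*% null_coef)), 1e-12), 1 - 1e-12)
    W <- w_obs * mu0 * (1 - mu0)
    x <- X_full[, 2L]
    U <- sum(w_obs * x * (y - mu0))
    XtWX0 <- crossprod(X_null, X_null * W)
    v <- tryCatch({
      b <- solve(XtWX0, crossprod(X_null, x * W))
      sum(x * W * x) - drop(crossprod(crossprod(X_null, x * W), b))
    }, error = function(e) NA_real_)
    if (!is.na(v) && v > 0) U^2 / v else NA_real_
  }
  chi2 <- score_chi2(null$coef)
  if (!is.finite(chi2)) chi2 <- 0
  df <- ncol(X_full) - ncol(X_null)
  eff <- NA_real_
  flagged <- FALSE
  if (effect) {
    full <- irls_logistic(X_full, y, weights)
    if (full$separated) {
      full <- irls_logistic(X_full, y, weights, ridge = ridge_fallback)
      flagged <- TRUE
    }
    eff <- full$coef[2L]
  }
  list(chi2 = chi2, df = df, p = pchisq(chi2, df, lower.tail = FALSE),
       effect = eff, flagged = flagged)
}

# Gaussian likelihood-ratio comparison of nested linear models. The raw
# 2*logLR = n*log(RSS0/RSS1) statistic is anti-conservative for the small
# detected-sample counts typical of sparse clones, so the p-value is taken
# from the exact F reference and mapped back to an equivalent chi-square
# (same tail probability, same df) for the hurdle sum combination.
gaussian_lrt <- function(X_full, X_null, y) {
  f1 <- stats::.lm.fit(X_full, y)
  f0 <- stats::.lm.fit(X_null, y)
  rss1 <- sum(f1$residuals^2)
  rss0 <- sum(f0$residuals^2)
  n <- length(y)
  df1 <- ncol(X_full) - ncol(X_null)
  df2 <- n - f1$rank
  if (df2 <= 0 || rss1 <= 1e-300) {
    chi2 <- if (rss0 > rss1) Inf else 0
    return(list(chi2 = chi2, df = df1,
                p = if (is.infinite(chi2)) 0 else 1,
                effect = f1$coefficients[2L]))
  }
  Fstat <- max(((rss0 - rss1) / df1) / (rss1 / df2), 0)
  p <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)
  chi2 <- stats::qchisq(p, df1, lower.tail = FALSE)
  list(chi2 = chi2, df = df1, p = p, effect = f1$coefficients[2L])
}

# design matrix from metadata covariates; factors/characters expand to
# treatment contrasts, constants are rejected by name
build_design <- function(metadata, covariates, check_constant = TRUE) {
  cols <- list(`(Intercept)` = rep(1, nrow(metadata)))
  for (cv in covariates) {
    if (!cv %in% names(metadata))
      stop("covariate '", cv, "' not found in metadata")
    v <- metadata[[cv]]
    if (is.character(v) || is.factor(v)) {
      v <- factor(v)
      if (nlevels(v) < 2L) {
        if (check_constant) stop("covariate '", cv, "' is constant")
        next
      }
      for (lev in levels(v)[-1L])
        cols[[paste0(cv, lev)]] <- as.numeric(v == lev)
    } else {
      if (check_constant && (all(is.na(v)) || sd(v, na.rm = TRUE) == 0))
        stop("covariate '", cv, "' is constant")
      cols[[cv]] <- as.numeric(v)
    }
  }
  do.call(cbind, cols)
}

#' Baseline association between an AIRR measure and a phenotype
#'
#' Fits the regression family matched to the distribution of the AIRR
#' variable: `"logistic"` regresses the binary phenotype on the measure
#' (reporting the measure's coefficient), `"negative_binomial"` models the
#' count-valued measure on the phenotype with a log-depth offset and
#' ML-estimated dispersion, `"gaussian"` is an ordinary linear model of the
#' measure on the phenotype. Covariates (age, sex, depth as applicable) are
#' always included.
#'
#' @param y Per-sample AIRR measure.
#' @param x Per-sample phenotype (two-level factor/character for
#'   case-control).
#' @param metadata Sample metadata holding the covariates (and
#'   `total_umis` for the depth offset).
#' @param family `"logistic"`, `"negative_binomial"` or `"gaussian"`.
#' @param covariates Covariate column names, default `c("age", "sex")`.
#' @param depth_offset Include `log(total_umis)` as offset (negative
#'   binomial only), default `TRUE`.
#' @return List with `effect`, `se`, `p` (Wald test of the coefficient of
#'   interest), `family`, `converged`.
#' @export
fit_baseline_association <- function(y, x, metadata,
                                     family = c("logistic",
                                                "negative_binomial",
                                                "gaussian"),
                                     covariates = c("age", "sex"),
                                     depth_offset = TRUE) {
  family <- match.arg(family)
  X <- build_design(metadata, covariates)
  dat <- data.frame(y = y, x = if (is.numeric(x)) x else factor(x),
                    X[, -1L, drop = FALSE], check.names = FALSE)
  covar_terms <- paste(sprintf("`%s`", colnames(X)[-1L]), collapse = " + ")
  rhs <- if (nchar(covar_terms)) paste("x", covar_terms, sep = " + ") else "x"
  if (family == "logistic") {
    if (length(unique(na.omit(x))) < 2L)
      stop("logistic family needs >= 2 outcome classes")
    fml <- as.formula(paste("factor(x) ~ y +", covar_terms))
    fit <- glm(fml, data = dat, family = binomial())
    co <- summary(fit)$coefficients
    row <- "y"
  } else if (family == "negative_binomial") {
    if (any(y < 0) || any(y != round(y)))
      stop("negative binomial family needs count-valued y")
    if (depth_offset) {
      if (!"total_umis" %in% names(metadata))
        stop("depth offset requires metadata$total_umis")
      dat$.off <- log(metadata$total_umis)
      fml <- as.formula(paste("y ~", rhs, "+ offset(.off)"))
    } else fml <- as.formula(paste("y ~", rhs))
    fit <- tryCatch(suppressWarnings(MASS::glm.nb(fml, data = dat)),
                    error = function(e) NULL)
    if (is.null(fit))
      return(list(effect = NA_real_, se = NA_real_, p = NA_real_,
                  family = family, converged = FALSE))
    co <- summary(fit)$coefficients
    row <- grep("^x", rownames(co), value = TRUE)[1L]
  } else {
    fml <- as.formula(paste("y ~", rhs))
    fit <- lm(fml, data = dat)
    co <- summary(fit)$coefficients
    row <- grep("^x", rownames(co), value = TRUE)[1L]
  }
  conv <- if (!is.null(fit$converged)) fit$converged else TRUE
  if (!conv || !row %in% rownames(co))
    return(list(effect = NA_real_, se = NA_real_, p = NA_real_,
                family = family, converged = FALSE))
  list(effect = unname(co[row, 1L]), se = unname(co[row, 2L]),
       p = unname(co[row, 4L]), family = family, converged = conv)
}

#' Longitudinal mixed-effect association
#'
#' Tests the timepoint effect on a per-sample AIRR measure in a paired
#' design using a subject random intercept, adjusted for covariates.
#' Gaussian outcomes use `lmer` fit by maximum likelihood (REML off) with
#' Satterthwaite degrees of freedom for the p-value; binary outcomes use
#' `glmer` (Laplace approximation); counts use `glmer.nb`.
#'
#' @param y Per-sample measure.
#' @param timepoint Per-sample timepoint factor (two levels, e.g. baseline
#'   / week12).
#' @param subject Per-sample subject id; every subject must appear at both
#'   timepoints.
#' @param metadata Sample metadata with the covariates.
#' @param family `"gaussian"`, `"logistic"` or `"negative_binomial"`.
#' @param covariates Covariate columns, default `c("age", "sex")`.
#' @return List with `effect` (timepoint coefficient), `se`, `p`.
#' @export
fit_longitudinal_mixed <- function(y, timepoint, subject, metadata,
                                   family = c("gaussian", "logistic",
                                              "negative_binomial"),
                                   covariates = c("age", "sex")) {
  family <- match.arg(family)
  timepoint <- factor(timepoint)
  if (nlevels(timepoint) != 2L) stop("timepoint must have exactly 2 levels")
  tab <- table(subject, timepoint)
  bad <- rownames(tab)[rowSums(tab > 0) < 2L]
  if (length(bad) > 0L)
    stop("subject(s) without both timepoints: ", paste(bad, collapse = ", "))
  X <- build_design(metadata, covariates, check_constant = FALSE)
  dat <- data.frame(y = y, tp = timepoint, subj = factor(subject),
                    X[, -1L, drop = FALSE], check.names = FALSE)
  covar_terms <- colnames(X)[-1L]
  # drop covariates constant within the model frame
  covar_terms <- covar_terms[vapply(covar_terms, function(cn)
    sd(dat[[cn]], na.rm = TRUE) > 0, logical(1L))]
  rhs <- paste(c("tp", sprintf("`%s`", covar_terms), "(1 | subj)"),
               collapse = " + ")
  fml <- as.formula(paste("y ~", rhs))
  if (family == "gaussian") {
    fit <- suppressWarnings(suppressMessages(
      lmerTest::lmer(fml, data = dat, REML = FALSE)))
    co <- coef(summary(fit))
    row <- grep("^tp", rownames(co), value = TRUE)[1L]
    list(effect = unname(co[row, "Estimate"]),
         se = unname(co[row, "Std. Error"]),
         p = unname(co[row, "Pr(>|t|)"]))
  } else if (family == "logistic") {
    fit <- suppressWarnings(suppressMessages(
      lme4::glmer(fml, data = dat, family = binomial())))
    co <- coef(summary(fit))
    row <- grep("^tp", rownames(co), value = TRUE)[1L]
    list(effect = unname(co[row, 1L]), se = unname(co[row, 2L]),
         p = unname(co[row, 4L]))
  } else {
    fit <- suppressWarnings(suppressMessages(
      lme4::glmer.nb(fml, data = dat)))
    co <- coef(summary(fit))
    row <- grep("^tp", rownames(co), value = TRUE)[1L]
    list(effect = unname(co[row, 1L]), se = unname(co[row, 2L]),
         p = unname(co[row, 4L]))
  }
}

#' CDR-adjusted two-part hurdle association test
#'
#' Tests every feature of a log-CPM matrix for association with a two-group
#' phenotype using the two-part hurdle model: a discrete part (logistic
#' regression of the detection indicator on phenotype + covariates, tested
#' by likelihood ratio against the covariate-only null) and a continuous
#' part (Gaussian regression of the positive log-CPM values on phenotype +
#' covariates over the detected samples only). The combined hurdle
#' statistic is the sum of the two likelihood-ratio chi-squares with summed
#' degrees of freedom. By default the model adjusts for the Clone
#' Detection Rate (computed on the same matrix), age and sex.
#'
#' Features detected in all samples have no discrete part (the combined
#' test reduces to the continuous part, flagged); features with fewer than
#' 3 detected samples in either group have no continuous part. Perfect
#' separation in the discrete part triggers a ridge-penalized refit
#' (penalty 1e-4), flagged in the output.
#'
#' @param matrix A log-CPM `feature_matrix`, already filtered with
#'   [filter_low_detection()].
#' @param phenotype Per-sample two-level phenotype (aligned with matrix
#'   columns or named by sample).
#' @param metadata Sample metadata providing the covariates.
#' @param covariates Covariate columns, default `c("age", "sex")`; the CDR
#'   is always added unless `cdr = FALSE`.
#' @param cdr Add the Clone Detection Rate covariate (default `TRUE`);
#'   alternatively a numeric vector of precomputed CDR values.
#' @param effects Estimate per-part effect sizes via the full model fits
#'   (default `TRUE`); `FALSE` skips them and reports `NA` effects, which
#'   roughly halves the run time of large calibration screens.
#' @return Data frame of class `hurdle_result` with columns `feature`,
#'   `chain`, `p_disc`, `p_cont`, `p_hurdle`, `effect_disc` (log-odds),
#'   `effect_cont`, `q` (Benjamini-Hochberg over `p_hurdle`), plus
#'   `n_det_a`, `n_det_b` and `flag`.
#' @export
hurdle_test <- function(matrix, phenotype, metadata = NULL,
                        covariates = c("age", "sex"), cdr = TRUE,
                        effects = TRUE) {
  stopifnot(inherits(matrix, "feature_matrix"))
  if (matrix$scale != "logcpm")
    warning("hurdle_test expects a log-CPM matrix; got scale '",
            matrix$scale, "'")
  vals <- matrix$counts
  n <- ncol(vals)
  if (!is.null(names(phenotype))) phenotype <- phenotype[colnames(vals)]
  ph <- factor(phenotype)
  if (nlevels(ph) != 2L) stop("phenotype must have exactly 2 levels")
  ph_num <- as.numeric(ph == levels(ph)[1L])  # first level = group A
  X_cov <- if (is.null(metadata) || length(covariates) == 0L)
    base::matrix(1, n, 1L, dimnames = list(NULL, "(Intercept)"))
  else build_design(metadata, covariates)
  if (isTRUE(cdr)) {
    cdr_vals <- compute_detection_rate(matrix)$cdr
    X_cov <- cbind(X_cov, CDR = cdr_vals)
  } else if (is.numeric(cdr)) {
    X_cov <- cbind(X_cov, CDR = cdr)
  }
  X_full <- cbind(X_cov[, 1L, drop = FALSE], phenotype = ph_num,
                  X_cov[, -1L, drop = FALSE])
  X_null <- X_cov
  res <- vector("list", nrow(vals))
  for (f in seq_len(nrow(vals))) {
    v <- vals[f, ]
    det <- as.numeric(v > 0)
    n_det_a <- sum(det == 1 & ph_num == 1)
    n_det_b <- sum(det == 1 & ph_num == 0)
    flag <- ""
    # discrete part
    if (all(det == 1)) {
      disc <- list(chi2 = 0, df = 0L, p = NA_real_, effect = NA_real_)
      flag <- "all_detected"
    } else if (all(det == 0)) {
      stop("all-zero feature '", rownames(vals)[f],
           "' passed to hurdle_test; filter first")
    } else {
      disc <- logistic_lrt(X_full, X_null, det, effect = effects)
      if (disc$flagged) flag <- paste0(flag, "separation")
    }
    # continuous part on detected samples only
    if (n_det_a >= 3L && n_det_b >= 3L) {
      keep <- det == 1
      cont <- gaussian_lrt(X_full[keep, , drop = FALSE],
                           X_null[keep, , drop = FALSE], v[keep])
    } else {
      cont <- list(chi2 = 0, df = 0L, p = NA_real_, effect = NA_real_)
    }
    df_tot <- disc$df + cont$df
    p_h <- if (df_tot == 0L) NA_real_
           else pchisq(disc$chi2 + cont$chi2, df_tot, lower.tail = FALSE)
    res[[f]] <- c(disc$chi2, disc$p, disc$effect, cont$chi2, cont$p,
                  cont$effect, p_h, n_det_a, n_det_b,
                  flag_code = match(flag, c("", "all_detected",
                                            "separation"), nomatch = 0L))
  }
  m <- do.call(rbind, res)
  out <- data.frame(feature = rownames(vals),
                    chain = matrix$chain %||% NA_character_,
                    p_disc = m[, 2L], p_cont = m[, 5L], p_hurdle = m[, 7L],
                    effect_disc = m[, 3L], effect_cont = m[, 6L],
                    q = fdr_adjust(m[, 7L]),
                    n_det_a = as.integer(m[, 8L]),
                    n_det_b = as.integer(m[, 9L]),
                    flag = c("", "all_detected", "separation")[
                      pmax(m[, 10L], 1L)],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("hurdle_result", "data.frame")
  out
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up BH q-values. `NA` p-values are left out of the adjustment (the
#' correction size is the number of non-missing tests) and propagate as
#' `NA` q-values.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NAs allowed).
#' @return Vector of q-values of the same length.
#' @export
fdr_adjust <- function(p) {
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must be in [0, 1]")
  q[ok] <- p.adjust(p[ok], method = "BH")
  q
}

#' Summarize clone expansion/contraction dynamics
#'
#' Given per-clone dynamics labels (`contracted`, `expanded`, `unchanged`)
#' with pre/post frequencies, compares (i) the number of significantly
#' contracted (and expanded) clones between BCR and TCR chains with
#' Fisher's exact test, and (ii) the magnitude of the frequency change
#' between contracted and expanded clones per chain with the Wilcoxon
#' test. The magnitude of clonal change is
#' `|log2((f_post + eps) / (f_pre + eps))|` with
#' `eps = 1 / (2 * min_depth)`.
#'
#' @param dynamics Data frame with columns `clone_id`, `chain`, `label`
#'   and either `magnitude` or both `freq_pre` and `freq_post`.
#' @param min_depth Smallest per-sample depth, used for the pseudo-frequency
#'   `eps`; required when magnitudes are computed from frequencies.
#' @return List with `fisher` (per direction: odds ratio and p for BCR vs
#'   TCR), `wilcoxon` (per chain: p for |change| contracted vs expanded)
#'   and the augmented `dynamics` table.
#' @export
dynamics_summary <- function(dynamics, min_depth = NULL) {
  stopifnot(all(c("clone_id", "chain", "label") %in% names(dynamics)))
  if (!all(dynamics$label %in% c("contracted", "expanded", "unchanged")))
    stop("labels must be contracted/expanded/unchanged")
  if (!"magnitude" %in% names(dynamics)) {
    if (is.null(min_depth))
      stop("min_depth is required to compute change magnitudes")
    eps <- 1 / (2 * min_depth)
    dynamics$magnitude <- abs(log2((dynamics$freq_post + eps) /
                                     (dynamics$freq_pre + eps)))
  }
  receptor <- ifelse(dynamics$chain %in% BCR_CHAINS, "BCR", "TCR")
  fisher <- do.call(rbind, lapply(c("contracted", "expanded"),
                                  function(dir) {
    tab <- table(factor(receptor, levels = c("BCR", "TCR")),
                 factor(dynamics$label == dir, levels = c(TRUE, FALSE)))
    if (any(rowSums(tab) == 0L)) {
      warning("no ", dir, " comparison possible: a receptor class is empty")
      return(data.frame(direction = dir, odds_ratio = NA_real_,
                        p = NA_real_))
    }
    ft <- fisher.test(tab)
    data.frame(direction = dir, odds_ratio = unname(ft$estimate),
               p = ft$p.value)
  }))
  chains <- sort(unique(dynamics$chain))
  wilcoxon <- do.call(rbind, lapply(chains, function(ch) {
    mc <- dynamics$magnitude[dynamics$chain == ch &
                               dynamics$label == "contracted"]
    me <- dynamics$magnitude[dynamics$chain == ch &
                               dynamics$label == "expanded"]
    if (length(mc) == 0L || length(me) == 0L) {
      warning("chain ", ch, ": empty contracted or expanded class; ",
              "Wilcoxon skipped")
      return(data.frame(chain = ch, p = NA_real_,
                        n_contracted = length(mc), n_expanded = length(me)))
    }
    data.frame(chain = ch,
               p = suppressWarnings(wilcox.test(mc, me)$p.value),
               n_contracted = length(mc), n_expanded = length(me))
  }))
  list(fisher = fisher, wilcoxon = wilcoxon, dynamics = dynamics)
}
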