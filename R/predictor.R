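# Multi-chain repertoire classifier: per-sample feature assembly,
# leave-one-out cross-validated random forests with per-tree class
# down-sampling, performance metrics and a feature-block aggregation
# search.

#' Assemble per-sample repertoire features for classification
#'
#' Builds a samples x features matrix from a record table, organized in
#' provenance blocks: per-chain diversity indices, chain usage (plus IGK
#' light-chain share), V-segment usage and IGH isotype measures.
#'
#' @param records Clonotype record table.
#' @param metadata Sample metadata with `sample_id` and the label column.
#' @param label_col Metadata column holding the class label, default
#'   `"group"`.
#' @param blocks Feature blocks to include, subset of
#'   `c("diversity", "chain_usage", "segment_usage", "isotype")`.
#' @param segment_min_detection Keep V segments detected in at least this
#'   fraction of samples (bounds the segment block's width).
#' @return Object of class `predictor_dataset`: list with `x` (numeric
#'   matrix), `y` (factor), `blocks` (per-column provenance tags).
#' @export
build_predictor_dataset <- function(records, metadata, label_col = "group",
                                    blocks = c("diversity", "chain_usage",
                                               "segment_usage", "isotype"),
                                    segment_min_detection = 0.2) {
  blocks <- match.arg(blocks, several.ok = TRUE)
  sids <- metadata$sample_id
  feats <- list()
  tags <- character(0)
  add <- function(m, tag) {
    feats[[length(feats) + 1L]] <<- m
    tags <<- c(tags, rep(tag, ncol(m)))
  }
  if ("diversity" %in% blocks) {
    for (ch in intersect(AIRR_CHAINS, unique(records$chain))) {
      rec <- records[records$chain == ch, , drop = FALSE]
      rows <- lapply(sids, function(s) {
        counts <- rec$umi_count[rec$sample_id == s]
        names(counts) <- rec$cdr3_aa[rec$sample_id == s]
        if (length(counts) == 0L)
          return(data.frame(richness = NA, d20 = NA, d50 = NA,
                            gini_simpson = NA, log_gini_simpson = NA,
                            inverse_simpson = NA, shannon = NA))
        counts <- tapply(counts, names(counts), sum)
        diversity_profile(counts)
      })
      m <- as.matrix(do.call(rbind, rows))
      colnames(m) <- paste(ch, colnames(m), sep = "_")
      add(m, "diversity")
    }
  }
  if ("chain_usage" %in% blocks) {
    cu <- chain_usage(records)
    m <- as.matrix(cu[match(sids, cu$sample_id), -1L, drop = FALSE])
    rownames(m) <- sids
    colnames(m) <- paste0("usage_", colnames(m))
    add(m, "chain_usage")
  }
  if ("segment_usage" %in% blocks) {
    for (ch in intersect(AIRR_CHAINS, unique(records$chain))) {
      fm <- tryCatch(build_feature_matrix(records, "segmentV", chain = ch,
                                          samples = sort(sids)),
                     error = function(e) NULL)
      if (is.null(fm)) next
      usage <- sweep(fm$counts, 2L, pmax(fm$library_sizes, 1), `/`)
      keep <- rowMeans(usage > 0) >= segment_min_detection
      if (!any(keep)) next
      m <- t(usage[keep, sids, drop = FALSE])
      add(m, "segment_usage")
    }
  }
  if ("isotype" %in% blocks && "IGH" %in% records$chain) {
    rows <- lapply(sids, function(s) {
      pr <- isotype_profile(records, s)
      c(pr$usage,
        switch_IgM_IgG = pr$switch_matrix["IgM", "IgG"],
        switch_IgG_IgA = pr$switch_matrix["IgG", "IgA"],
        shm_IgG = pr$shm[["IgG"]], shm_IgM = pr$shm[["IgM"]],
        pct_mutated_igdm = pr$pct_mutated_igdm)
    })
    m <- do.call(rbind, rows)
    rownames(m) <- sids
    colnames(m) <- paste0("isotype_", colnames(m))
    add(m, "isotype")
  }
  x <- do.call(cbind, feats)
  rownames(x) <- sids
  y <- factor(metadata[[label_col]])
  if (any(is.na(y))) stop("missing class labels")
  structure(list(x = x, y = y, blocks = setNames(tags, colnames(x))),
            class = "predictor_dataset")
}

# median imputation learned on training rows only
impute_median <- function(train, test) {
  med <- apply(train, 2L, function(v) median(v, na.rm = TRUE))
  med[is.na(med)] <- 0
  fix <- function(m) {
    for (j in seq_len(ncol(m))) m[is.na(m[, j]), j] <- med[j]
    m
  }
  list(train = fix(train), test = fix(test))
}

#' Leave-one-out cross-validated random forest
#'
#' For each sample, trains a random forest on all other samples and
#' predicts the held-out sample; out-of-fold predictions are aggregated
#' into a performance report. Class imbalance is handled by per-tree
#' balanced down-sampling: every tree draws from each class at most the
#' minority-class count of the training fold. NA features are
#' median-imputed within the training fold only. Variable importance
#' (permutation / mean decrease accuracy, and Gini impurity) is computed
#' on a full-data forest.
#'
#' @param x Samples x features numeric matrix (or a
#'   `predictor_dataset`).
#' @param y Class factor (ignored when `x` is a `predictor_dataset`).
#' @param n_trees Trees per forest, default 500.
#' @param downsample Balance classes by per-tree down-sampling, default
#'   `TRUE`.
#' @param seed Integer seed governing fold-level and tree-level
#'   randomness through derived streams.
#' @param positive Positive class for sensitivity/precision; defaults to
#'   `"case"` when present, else the first factor level.
#' @return Object of class `loocv_report`: list with `predictions`
#'   (per-sample truth, predicted class, positive-class score),
#'   `confusion`, `metrics`, `importance`.
#' @export
loocv_random_forest <- function(x, y = NULL, n_trees = 500,
                                downsample = TRUE, seed = 1,
                                positive = NULL) {
  if (inherits(x, "predictor_dataset")) {
    y <- x$y
    x <- x$x
  }
  y <- factor(y)
  if (nlevels(y) < 2L) stop("need at least 2 classes")
  if (any(table(y) < 2L)) stop("each class needs at least 2 samples")
  n <- nrow(x)
  positive <- positive %||% if ("case" %in% levels(y)) "case"
                            else levels(y)[1L]
  set.seed(seed)
  fold_seeds <- sample.int(.Machine$integer.max - 1L, n + 2L)
  pred_class <- character(n)
  score <- numeric(n)
  for (i in seq_len(n)) {
    ytr <- y[-i]
    if (nlevels(droplevels(ytr)) < 2L)
      stop("single-class training fold at sample ", i)
    imp <- impute_median(x[-i, , drop = FALSE], x[i, , drop = FALSE])
    cls_n <- table(ytr)
    # class-wise sample.fraction: draw the minority-class count from every
    # class on each tree (fractions are of the total training n)
    frac <- if (downsample) rep(min(cls_n) / length(ytr), nlevels(y))
            else 1
    fit <- ranger::ranger(
      x = imp$train, y = ytr, num.trees = n_trees,
      sample.fraction = frac, replace = !downsample,
      probability = TRUE, num.threads = 1L,
      seed = fold_seeds[i])
    pr <- predict(fit, data = imp$test, num.threads = 1L)$predictions
    pred_class[i] <- colnames(pr)[which.max(pr[1L, ])]
    score[i] <- pr[1L, positive]
  }
  predictions <- data.frame(sample = rownames(x) %||% seq_len(n),
                            truth = as.character(y),
                            predicted = pred_class,
                            score = score, stringsAsFactors = FALSE)
  metrics <- performance_metrics(y, factor(pred_class, levels = levels(y)),
                                 score, positive = positive)
  imp_all <- impute_median(x, x)$train
  imp_perm <- ranger::ranger(x = imp_all, y = y, num.trees = n_trees,
                             importance = "permutation", num.threads = 1L,
                             seed = fold_seeds[n + 1L])
  imp_gini <- ranger::ranger(x = imp_all, y = y, num.trees = n_trees,
                             importance = "impurity", num.threads = 1L,
                             seed = fold_seeds[n + 2L])
  importance <- data.frame(
    feature = names(imp_perm$variable.importance),
    mean_decrease_accuracy = as.numeric(imp_perm$variable.importance),
    gini = as.numeric(imp_gini$variable.importance),
    stringsAsFactors = FALSE)
  importance <- importance[order(-importance$mean_decrease_accuracy), ]
  rownames(importance) <- NULL
  structure(list(predictions = predictions,
                 confusion = metrics$confusion,
                 metrics = metrics, importance = importance,
                 positive = positive, seed = seed),
            class = "loocv_report")
}

#' @export
#' @method print loocv_report
print.loocv_report <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(
    "loocv_report: n=%d  accuracy=%.3f  sens=%.3f  spec=%.3f  auc=%.3f\n",
    nrow(x$predictions), m$accuracy, m$sensitivity, m$specificity,
    m$roc_auc))
  invisible(x)
}

#' Classification performance metrics
#'
#' Confusion-matrix metrics for a binary classifier: accuracy (correct
#' predictions out of all predictions), sensitivity, specificity,
#' precision and false-positive rate, plus ROC-AUC (trapezoid rule, via
#' pROC) and PR-AUC (step interpolation: sum over descending-score
#' thresholds of precision times the recall increment) when scores are
#' given. Ratios with zero denominators are `NA` with a warning.
#'
#' @param truth,predicted Class vectors of equal length.
#' @param scores Optional positive-class scores.
#' @param positive Positive class label.
#' @return List with `confusion` (2x2 table) and the metric values.
#' @export
performance_metrics <- function(truth, predicted, scores = NULL,
                                positive = NULL) {
  if (length(truth) != length(predicted))
    stop("truth and predicted must have equal length")
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  positive <- positive %||% if ("case" %in% truth) "case" else truth[1L]
  tp <- sum(truth == positive & predicted == positive)
  tn <- sum(truth != positive & predicted != positive)
  fp <- sum(truth != positive & predicted == positive)
  fn <- sum(truth == positive & predicted != positive)
  ratio <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (zero denominator)")
      return(NA_real_)
    }
    num / den
  }
  confusion <- base::matrix(c(tp, fn, fp, tn), 2L, 2L,
                            dimnames = list(truth = c(positive, "other"),
                                            predicted = c(positive,
                                                          "other")))
  roc_auc <- pr_auc <- NA_real_
  if (!is.null(scores)) {
    roc_auc <- tryCatch(
      as.numeric(pROC::auc(pROC::roc(
        response = factor(truth == positive, levels = c(FALSE, TRUE)),
        predictor = scores, quiet = TRUE, direction = "<"))),
      error = function(e) NA_real_)
    o <- order(scores, decreasing = TRUE)
    lab <- truth[o] == positive
    tp_c <- cumsum(lab)
    prec <- tp_c / seq_along(lab)
    rec <- tp_c / sum(lab)
    d_rec <- diff(c(0, rec))
    pr_auc <- sum(prec * d_rec)
  }
  list(confusion = confusion,
       accuracy = ratio(tp + tn, tp + tn + fp + fn, "accuracy"),
       sensitivity = ratio(tp, tp + fn, "sensitivity"),
       specificity = ratio(tn, tn + fp, "specificity"),
       precision = ratio(tp, tp + fp, "precision"),
       fpr = ratio(fp, fp + tn, "false-positive rate"),
       roc_auc = roc_auc, pr_auc = pr_auc)
}

#' Search feature-block aggregations for the best classifier
#'
#' Evaluates combinations of feature blocks with the LOOCV random forest
#' and ranks them by the selected metric (accuracy by default;
#' specificity when the minority class is the clinical target). By
#' default all non-empty block combinations are tried.
#'
#' @param dataset A `predictor_dataset` with at least 2 blocks.
#' @param combos Optional list of character vectors of block names; the
#'   default enumerates all non-empty subsets.
#' @param metric `"accuracy"` or `"specificity"`.
#' @param n_trees,seed Passed to [loocv_random_forest()].
#' @return List with `ranking` (data frame of combinations and metrics,
#'   best first) and `reports` (per-combination `loocv_report`s).
#' @export
feature_aggregation_search <- function(dataset, combos = NULL,
                                       metric = c("accuracy",
                                                  "specificity"),
                                       n_trees = 500, seed = 1) {
  stopifnot(inherits(dataset, "predictor_dataset"))
  metric <- match.arg(metric)
  blocks <- unique(dataset$blocks)
  if (length(blocks) < 2L) stop("need at least 2 feature blocks")
  if (is.null(combos)) {
    combos <- unlist(lapply(seq_along(blocks), function(k)
      utils::combn(blocks, k, simplify = FALSE)), recursive = FALSE)
  }
  reports <- list()
  rows <- list()
  for (cmb in combos) {
    cols <- dataset$blocks %in% cmb
    if (!any(cols)) {
      warning("empty block combination skipped: ",
              paste(cmb, collapse = "+"))
      next
    }
    key <- paste(sort(cmb), collapse = "+")
    rep_ <- loocv_random_forest(dataset$x[, cols, drop = FALSE],
                                dataset$y, n_trees = n_trees, seed = seed)
    reports[[key]] <- rep_
    rows[[key]] <- data.frame(combination = key,
                              n_features = sum(cols),
                              accuracy = rep_$metrics$accuracy,
                              specificity = rep_$metrics$specificity,
                              sensitivity = rep_$metrics$sensitivity,
                              roc_auc = rep_$metrics$roc_auc,
                              stringsAsFactors = FALSE)
  }
  ranking <- do.call(rbind, rows)
  ranking <- ranking[order(-ranking[[metric]], ranking$n_features), ]
  rownames(ranking) <- NULL
  list(ranking = ranking, reports = reports)
}
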