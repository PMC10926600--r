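# End-to-end orchestration: case-control and longitudinal runs driven by a
# config (list or YAML file), writing a fixed output layout with a
# manifest. Stage failures abort the run with the stage name. FDR is
# applied within each (feature level x chain) family.

#' Assemble and validate a run configuration
#'
#' A run is configured by a plain list (or a YAML file with the same
#' structure): `input` (`records` and `metadata` TSV paths) or `simulate`
#' (arguments for [cohort_config()]), plus thresholds and toggles.
#'
#' @param config A list or path to a YAML file.
#' @return Validated config list with defaults filled in.
#' @export
run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(min_sample_fraction = 0.01, fdr_alpha = 0.05,
                   n_perm = 1000, k = 4,
                   covariates = c("age", "sex"),
                   analyses = c("diversity", "usage", "clones",
                                "metaclones", "kmers", "isotype"),
                   seed = 1)
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  if (config$fdr_alpha <= 0 || config$fdr_alpha >= 1)
    stop("fdr_alpha must be in (0, 1)")
  if (is.null(config$input) && is.null(config$simulate))
    stop("config needs either `input` paths or a `simulate` block")
  if (!is.null(config$input)) {
    for (p in unlist(config$input))
      if (!file.exists(p)) stop("input path does not exist: ", p)
  }
  config
}

load_run_inputs <- function(config) {
  if (!is.null(config$input)) {
    parsed <- read_airr_tsv(config$input$records)
    meta <- read_sample_metadata(config$input$metadata,
                                 records = parsed$records)
    list(records = parsed$records, metadata = meta, truth = NULL)
  } else {
    sim_args <- config$simulate
    sim_args$seed <- config$seed
    cfg <- do.call(cohort_config, sim_args)
    if (isTRUE(config$longitudinal_design)) generate_longitudinal(cfg)
    else generate_cohort(cfg)
  }
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

write_manifest <- function(out_dir, config, stages) {
  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(config, cfg_path)
  manifest <- list(
    package = "airrstat",
    version = as.character(utils::packageVersion("airrstat")),
    seed = config$seed,
    config_hash = unname(tools::md5sum(cfg_path)),
    stages_completed = stages)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  manifest
}

hurdle_one_level <- function(fm, phenotype, metadata, covariates,
                             min_sample_fraction) {
  fm <- filter_low_detection(fm, min_sample_fraction)
  if (nrow(fm$counts) == 0L) return(NULL)
  lg <- cpm_log_transform(fm)
  hurdle_test(lg, phenotype, metadata, covariates = covariates)
}

#' Run the case-control analysis pipeline
#'
#' Executes, per chain: diversity profiling, chain usage, V/J segment
#' usage PCA, clone / meta-clone / k-mer hurdle associations (each CDR-
#' adjusted, with FDR applied within the feature level x chain family),
#' and IGH isotype summaries. Writes TSV result tables and a JSON
#' manifest (package version, seed, config hash, completed stages) to
#' `out_dir`; reruns with the same config and seed are byte-identical.
#'
#' @param config Run configuration (list, YAML path or [run_config()]
#'   output).
#' @param out_dir Output directory (created if needed).
#' @return The manifest list, invisibly.
#' @export
run_case_control <- function(config, out_dir) {
  config <- run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  inputs <- run_stage("load", load_run_inputs(config))
  records <- inputs$records
  meta <- inputs$metadata
  if (!"group" %in% names(meta))
    stop("pipeline stage 'load' failed: metadata is missing column 'group'",
         call. = FALSE)
  phenotype <- setNames(meta$group, meta$sample_id)
  chains <- intersect(AIRR_CHAINS, unique(records$chain))
  stages <- character(0)
  if ("diversity" %in% config$analyses) {
    run_stage("diversity", {
      rows <- do.call(rbind, lapply(chains, function(ch) {
        rec <- records[records$chain == ch, , drop = FALSE]
        do.call(rbind, lapply(unique(rec$sample_id), function(s) {
          counts <- tapply(rec$umi_count[rec$sample_id == s],
                           rec$cdr3_aa[rec$sample_id == s], sum)
          cbind(sample_id = s, chain = ch, diversity_profile(counts))
        }))
      }))
      write_tsv(rows, file.path(out_dir, "diversity.tsv"))
    })
    stages <- c(stages, "diversity")
  }
  if ("usage" %in% config$analyses) {
    run_stage("usage", {
      write_tsv(chain_usage(records), file.path(out_dir, "chain_usage.tsv"))
      for (ch in chains) {
        fm <- build_feature_matrix(records, "segmentVJ", chain = ch,
                                   samples = sort(meta$sample_id))
        pca <- tryCatch(segment_usage_pca(fm), error = function(e) NULL)
        if (!is.null(pca)) {
          out <- data.frame(sample_id = rownames(pca$scores), pca$scores,
                            stringsAsFactors = FALSE)
          write_tsv(out, file.path(out_dir,
                                   sprintf("segment_pca_%s.tsv", ch)))
        }
      }
    })
    stages <- c(stages, "usage")
  }
  clone_matrices <- list()
  if (any(c("clones", "metaclones") %in% config$analyses)) {
    for (ch in chains)
      clone_matrices[[ch]] <- build_feature_matrix(
        records, "clone", chain = ch, samples = sort(meta$sample_id))
  }
  if ("clones" %in% config$analyses) {
    run_stage("clones", {
      for (ch in chains) {
        res <- hurdle_one_level(clone_matrices[[ch]], phenotype, meta,
                                config$covariates,
                                config$min_sample_fraction)
        if (!is.null(res))
          write_tsv(res, file.path(out_dir,
                                   sprintf("hurdle_clones_%s.tsv", ch)))
      }
    })
    stages <- c(stages, "clones")
  }
  if ("metaclones" %in% config$analyses) {
    run_stage("metaclones", {
      for (ch in chains) {
        fm <- filter_low_detection(clone_matrices[[ch]],
                                   config$min_sample_fraction)
        if (nrow(fm$counts) < 2L) next
        net <- build_similarity_network(rownames(fm$counts))
        mc <- detect_metaclones(net)
        agg <- aggregate_metaclone_counts(mc, fm)
        res <- hurdle_one_level(agg, phenotype, meta, config$covariates,
                                config$min_sample_fraction)
        if (!is.null(res))
          write_tsv(res, file.path(out_dir,
                                   sprintf("hurdle_metaclones_%s.tsv", ch)))
        write_tsv(mc$membership,
                  file.path(out_dir, sprintf("metaclones_%s.tsv", ch)))
      }
    })
    stages <- c(stages, "metaclones")
  }
  if ("kmers" %in% config$analyses) {
    run_stage("kmers", {
      for (ch in chains) {
        km <- tryCatch(kmer_matrix(records, chain = ch, k = config$k,
                                   samples = sort(meta$sample_id)),
                       error = function(e) NULL)
        if (is.null(km)) next
        res <- hurdle_one_level(km, phenotype, meta, config$covariates,
                                config$min_sample_fraction)
        if (!is.null(res))
          write_tsv(res, file.path(out_dir,
                                   sprintf("hurdle_kmers_%s.tsv", ch)))
      }
    })
    stages <- c(stages, "kmers")
  }
  if ("isotype" %in% config$analyses && "IGH" %in% chains) {
    run_stage("isotype", {
      rows <- do.call(rbind, lapply(meta$sample_id, function(s) {
        pr <- isotype_profile(records, s)
        data.frame(sample_id = s, t(pr$usage),
                   pct_mutated_igdm = pr$pct_mutated_igdm,
                   t(setNames(pr$shm, paste0("shm_", names(pr$shm)))),
                   stringsAsFactors = FALSE)
      }))
      write_tsv(rows, file.path(out_dir, "isotype_profile.tsv"))
    })
    stages <- c(stages, "isotype")
  }
  invisible(write_manifest(out_dir, config, stages))
}

#' Run the longitudinal (paired) analysis pipeline
#'
#' For paired baseline / week-12 samples: mixed-model timepoint tests on
#' per-chain diversity and usage measures, contraction/expansion dynamics
#' summaries (given labels from the synthetic truth or an external
#' expansion caller) and biochemistry contrasts between contracted and
#' expanded clone sets.
#'
#' @inheritParams run_case_control
#' @return The manifest list, invisibly.
#' @export
run_longitudinal <- function(config, out_dir) {
  config <- run_config(config)
  config$longitudinal_design <- TRUE
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  inputs <- run_stage("load", load_run_inputs(config))
  records <- inputs$records
  meta <- inputs$metadata
  tab <- table(meta$subject_id, meta$timepoint)
  bad <- rownames(tab)[rowSums(tab > 0) < 2L]
  if (length(bad) > 0L)
    stop("pipeline stage 'load' failed: subject(s) without both ",
         "timepoints: ", paste(bad, collapse = ", "), call. = FALSE)
  chains <- intersect(AIRR_CHAINS, unique(records$chain))
  stages <- character(0)
  run_stage("mixed_diversity", {
    rows <- do.call(rbind, lapply(chains, function(ch) {
      rec <- records[records$chain == ch, , drop = FALSE]
      y <- vapply(meta$sample_id, function(s) {
        counts <- rec$umi_count[rec$sample_id == s]
        if (length(counts) == 0L) return(NA_real_)
        shannon_entropy(clone_frequencies(counts))
      }, numeric(1L))
      ok <- !is.na(y)
      subj_tab <- table(meta$subject_id[ok])
      keep <- ok & meta$subject_id %in% names(subj_tab)[subj_tab == 2L]
      if (sum(keep) < 8L) return(NULL)
      fit <- fit_longitudinal_mixed(y[keep], meta$timepoint[keep],
                                    meta$subject_id[keep],
                                    meta[keep, , drop = FALSE],
                                    family = "gaussian",
                                    covariates = config$covariates)
      data.frame(chain = ch, measure = "shannon", effect = fit$effect,
                 p = fit$p, stringsAsFactors = FALSE)
    }))
    if (!is.null(rows)) {
      rows$q <- fdr_adjust(rows$p)
      write_tsv(rows, file.path(out_dir, "mixed_diversity.tsv"))
    }
  })
  stages <- c(stages, "mixed_diversity")
  dyn <- NULL
  if (!is.null(inputs$truth) && !is.null(inputs$truth$dynamics)) {
    dyn <- inputs$truth$dynamics
  } else if (!is.null(config$input$dynamics)) {
    dyn <- read.delim(config$input$dynamics, stringsAsFactors = FALSE)
  }
  if (!is.null(dyn)) {
    run_stage("dynamics", {
      base_ids <- meta$sample_id[meta$timepoint == "baseline"]
      w12_ids <- meta$sample_id[meta$timepoint == "week12"]
      freq_of <- function(ids) {
        tot <- tapply(records$umi_count[records$sample_id %in% ids],
                      paste(records$chain, records$cdr3_aa)[
                        records$sample_id %in% ids], sum)
        tot / sum(tot)
      }
      f_pre <- freq_of(base_ids)
      f_post <- freq_of(w12_ids)
      key <- paste(dyn$chain, dyn$cdr3_aa)
      dtab <- data.frame(clone_id = dyn$cdr3_aa, chain = dyn$chain,
                         label = dyn$label,
                         freq_pre = as.numeric(f_pre[key]),
                         freq_post = as.numeric(f_post[key]),
                         stringsAsFactors = FALSE)
      dtab$freq_pre[is.na(dtab$freq_pre)] <- 0
      dtab$freq_post[is.na(dtab$freq_post)] <- 0
      ds <- suppressWarnings(
        dynamics_summary(dtab, min_depth = min(meta$total_umis)))
      write_tsv(ds$fisher, file.path(out_dir, "dynamics_fisher.tsv"))
      write_tsv(ds$wilcoxon, file.path(out_dir, "dynamics_wilcoxon.tsv"))
      # biochemistry of contracted vs expanded clones, per receptor class
      for (ch in intersect(chains, unique(dyn$chain))) {
        ca <- dyn$cdr3_aa[dyn$chain == ch & dyn$label == "contracted"]
        ex <- dyn$cdr3_aa[dyn$chain == ch & dyn$label == "expanded"]
        if (length(ca) >= 5L && length(ex) >= 5L) {
          bc <- suppressWarnings(contrast_biochemistry(ca, ex))
          write_tsv(bc, file.path(out_dir,
                                  sprintf("biochem_contrast_%s.tsv", ch)))
        }
      }
    })
    stages <- c(stages, "dynamics")
  }
  invisible(write_manifest(out_dir, config, stages))
}
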