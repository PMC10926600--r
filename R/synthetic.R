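# Seeded synthetic multi-chain cohort generator. Emulates the statistical
# structure that the association machinery assumes: per-chain clone pools
# with rank-weighted sharing (low publicity: most observed clones are
# private to one subject), discrete power-law within-sample clone
# abundances conditioned to the sample depth by multinomial sampling,
# chain-specific richness and CDR3 length distributions, isotype mixtures
# with class switching and negative-binomial somatic hypermutation, and
# planted case-control and longitudinal effects with ground-truth labels.

default_chain_params <- function() {
  list(
    TRA = list(richness = 800, depth = 20000, len_mean = 14, len_sd = 2,
               n_v = 40, n_j = 50),
    TRB = list(richness = 1000, depth = 25000, len_mean = 14.5,
               len_sd = 1.5, n_v = 45, n_j = 13),
    TRD = list(richness = 80, depth = 1500, len_mean = 14.5, len_sd = 2.5,
               n_v = 8, n_j = 4),
    TRG = list(richness = 120, depth = 2000, len_mean = 13, len_sd = 1.5,
               n_v = 10, n_j = 5),
    IGH = list(richness = 600, depth = 15000, len_mean = 15.5, len_sd = 3,
               n_v = 50, n_j = 6),
    IGK = list(richness = 350, depth = 12000, len_mean = 9, len_sd = 1,
               n_v = 35, n_j = 5),
    IGL = list(richness = 300, depth = 10000, len_mean = 11, len_sd = 1.5,
               n_v = 30, n_j = 7))
}

#' Synthetic cohort configuration
#'
#' Collects every knob of the generator in one validated object. Defaults
#' describe a small but realistic seven-chain case-control cohort:
#' chain-specific richness and depth, a power-law within-sample clone
#' abundance distribution, a rank-weighted publicity model under which the
#' median observed clone is private to a single subject, and lognormal
#' depth variation.
#'
#' @param n_cases,n_controls Number of case and control subjects.
#' @param chains Character vector of chains to simulate, or a named list of
#'   per-chain parameter lists (`richness`, `depth`, `len_mean`, `len_sd`,
#'   `n_v`, `n_j`) overriding the defaults.
#' @param power_law_exponent Exponent of the within-sample rank-frequency
#'   power law (frequency of the r-th clone proportional to `r^-a`).
#' @param publicity_exponent Exponent of the rank weights governing which
#'   pool clones a subject samples; larger values concentrate sampling on
#'   a small public tail.
#' @param pool_scale Pool size relative to `n_samples * richness`; 1 keeps
#'   median clone publicity at one subject.
#' @param depth_cv Lognormal coefficient of variation of per-sample depth
#'   around the configured chain depth (0 = exact depth).
#' @param trd_case_length_shift Additive shift (amino acids) of the TRD
#'   CDR3 length distribution in cases, implemented by exponential tilting
#'   of the sampling weights.
#' @param v_usage_case_shift Log-scale boost of case sampling weights for
#'   the first 10% of V segments (0 = no usage difference).
#' @param isotype_mix Isotype mixture over `IGH_ISOTYPES` (sums to 1).
#' @param switch_prob Probability that an IGH clonotype with at least two
#'   UMIs is additionally observed under a second isotype.
#' @param shm_mu Named negative-binomial mean mutation counts per isotype
#'   and per light chain.
#' @param shm_size Negative-binomial size (dispersion) parameter.
#' @param age_mean,age_sd Age distribution (years).
#' @param sex_prob_f Probability of female sex per group.
#' @param spike Optional planted case-control effect: a list with `chain`,
#'   `n_clones`, `detection_p0` (control detection probability),
#'   `detection_odds` (case/control detection odds ratio), `log2fc`
#'   (abundance shift in cases), `rank_quantile` (abundance tier of the
#'   planted clones as a within-sample rank quantile, default 0.25 so the
#'   configured fold change is not eroded by count dropout at the rank
#'   floor), and optionally `kmer = list(motif, case_clone_fraction)`
#'   planting a motif into case-specific clones.
#' @param longitudinal Parameters of the paired design: fractions of
#'   contracted/expanded clones per receptor class and the lognormal |log2
#'   fold change| law for each direction.
#' @param seed Integer seed; the generator is byte-deterministic given the
#'   configuration.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_cases = 30, n_controls = 30,
                          chains = AIRR_CHAINS,
                          power_law_exponent = 1.5,
                          publicity_exponent = 0.8,
                          pool_scale = 1.0,
                          depth_cv = 0.3,
                          trd_case_length_shift = 1,
                          v_usage_case_shift = 0,
                          isotype_mix = c(IgM = 0.45, IgD = 0.10,
                                          IgG = 0.30, IgA = 0.13,
                                          IgE = 0.02),
                          switch_prob = 0.10,
                          shm_mu = c(IgM = 2, IgD = 2, IgG = 12, IgA = 10,
                                     IgE = 8, IGK = 4, IGL = 4),
                          shm_size = 2,
                          age_mean = 55, age_sd = 12,
                          sex_prob_f = c(case = 0.75, control = 0.60),
                          spike = NULL,
                          longitudinal = list(frac_contracted_bcr = 0.06,
                                              frac_contracted_tcr = 0.02,
                                              frac_expanded = 0.02,
                                              lfc_mean_contracted = 3,
                                              lfc_mean_expanded = 2,
                                              lfc_sd = 0.8),
                          seed = 1) {
  if (is.character(chains)) {
    bad <- setdiff(chains, AIRR_CHAINS)
    if (length(bad) > 0L) stop("unknown chain(s): ", paste(bad, collapse = ", "))
    chains <- default_chain_params()[chains]
  }
  for (ch in names(chains)) {
    p <- chains[[ch]]
    if (p$richness <= 0 || p$depth <= 0)
      stop("richness and depth must be > 0 (chain ", ch, ")")
    min_len <- max(6L, round(p$len_mean - 3 * p$len_sd))
    if (p$richness * pool_scale * (n_cases + n_controls) >
          0.5 * 20^(min_len - 2))
      stop("infeasible config: pool for chain ", ch,
           " exceeds the sequence capacity at its CDR3 lengths")
  }
  if (abs(sum(isotype_mix) - 1) > 1e-8)
    stop("isotype_mix must sum to 1")
  stopifnot(switch_prob >= 0, switch_prob <= 1,
            all(sex_prob_f >= 0 & sex_prob_f <= 1),
            power_law_exponent > 0, pool_scale > 0, depth_cv >= 0)
  structure(list(n_cases = n_cases, n_controls = n_controls,
                 chains = chains,
                 power_law_exponent = power_law_exponent,
                 publicity_exponent = publicity_exponent,
                 pool_scale = pool_scale, depth_cv = depth_cv,
                 trd_case_length_shift = trd_case_length_shift,
                 v_usage_case_shift = v_usage_case_shift,
                 isotype_mix = isotype_mix, switch_prob = switch_prob,
                 shm_mu = shm_mu, shm_size = shm_size,
                 age_mean = age_mean, age_sd = age_sd,
                 sex_prob_f = sex_prob_f, spike = spike,
                 longitudinal = longitudinal, seed = seed),
            class = "cohort_config")
}

# n unique CDR3 sequences: canonical C...F scaffold with random interior.
# Sequences are built per length class in one matrix operation.
gen_cdr3 <- function(n, len_mean, len_sd, min_len = 6L, max_len = 35L) {
  out <- character(0)
  for (attempt in 1:50) {
    need <- n - length(out)
    if (need <= 0L) break
    lens <- pmin(max_len, pmax(min_len, round(rnorm(need, len_mean, len_sd))))
    interior <- character(need)
    for (L in unique(lens)) {
      idx <- which(lens == L)
      chars <- base::matrix(sample(AA_ALPHABET, length(idx) * (L - 2L),
                                   replace = TRUE),
                            nrow = length(idx))
      interior[idx] <- do.call(paste0, as.data.frame(chars,
                                                     stringsAsFactors = FALSE))
    }
    out <- unique(c(out, paste0("C", interior, "F")))
  }
  if (length(out) < n)
    stop("infeasible config: cannot generate ", n, " unique CDR3 sequences")
  out[seq_len(n)]
}

# insert a motif at a random interior position (start >= 3, keeping the
# final residue) by substitution
insert_motif <- function(seq, motif) {
  L <- nchar(seq)
  k <- nchar(motif)
  if (L < k + 3L) return(seq)
  start <- sample(3:(L - k), 1L)
  paste0(substr(seq, 1L, start - 1L), motif, substr(seq, start + k, L))
}

# weighted sampling without replacement (Efraimidis-Spirakis keys); a
# partial sort finds the `size` smallest keys in O(n)
ws_sample <- function(n_pool, size, w) {
  keys <- rexp(n_pool) / w
  if (size >= n_pool) return(seq_len(n_pool))
  th <- sort(keys, partial = size)[size]
  idx <- which(keys <= th)
  if (length(idx) > size) idx <- idx[order(keys[idx])][seq_len(size)]
  idx
}

# clone draw for one sample x chain; returns pool indices and counts
sample_chain_records <- function(chain, pool, cfg, is_case,
                                 spike_info = NULL) {
  pars <- cfg$chains[[chain]]
  depth <- if (cfg$depth_cv > 0)
    max(100L, round(pars$depth *
                      exp(rnorm(1L, -cfg$depth_cv^2 / 2, cfg$depth_cv))))
  else pars$depth
  w <- pool$weight
  if (is_case) {
    if (chain == "TRD" && cfg$trd_case_length_shift != 0) {
      tilt <- cfg$trd_case_length_shift / pars$len_sd^2
      w <- w * exp(tilt * (pool$len - pars$len_mean))
    }
    if (cfg$v_usage_case_shift != 0)
      w <- w * ifelse(pool$v_shifted, exp(cfg$v_usage_case_shift), 1)
  }
  n_draw <- min(pars$richness, nrow(pool$df))
  idx <- ws_sample(nrow(pool$df), n_draw, w)
  # planted differential clones enter by their own detection probability
  if (!is.null(spike_info)) {
    p <- if (is_case) spike_info$p_case else spike_info$p_control
    present <- spike_info$idx[runif(length(spike_info$idx)) < p]
    idx <- union(setdiff(idx, spike_info$idx), present)
  }
  n_tot <- length(idx)
  # power-law abundance over a random within-sample rank permutation
  ab <- sample(n_tot)^(-cfg$power_law_exponent)
  if (!is.null(spike_info)) {
    # planted clones sit at a defined abundance tier (rank quantile), so
    # the realized abundance fold change matches the configured one
    # instead of being eroded by multinomial dropout at the rank floor
    sp <- idx %in% spike_info$idx
    if (any(sp)) {
      tier_rank <- max(1, ceiling(spike_info$rank_quantile * n_tot))
      ab[sp] <- tier_rank^(-cfg$power_law_exponent)
      if (is_case && spike_info$log2fc != 0)
        ab[sp] <- ab[sp] * 2^spike_info$log2fc
    }
  }
  counts <- as.integer(rmultinom(1L, depth, ab))
  keep <- counts > 0L
  list(idx = idx[keep], counts = counts[keep])
}

# build the clone pool for one chain
build_pool <- function(chain, cfg, n_samples) {
  pars <- cfg$chains[[chain]]
  pool_size <- max(pars$richness,
                   round(cfg$pool_scale * n_samples * pars$richness))
  cdr3 <- gen_cdr3(pool_size, pars$len_mean, pars$len_sd)
  v_simplex <- sort(rexp(pars$n_v), decreasing = TRUE)
  v_simplex <- v_simplex / sum(v_simplex)
  j_simplex <- sort(rexp(pars$n_j), decreasing = TRUE)
  j_simplex <- j_simplex / sum(j_simplex)
  v_names <- sprintf("%sV%d", chain, seq_len(pars$n_v))
  j_names <- sprintf("%sJ%d", chain, seq_len(pars$n_j))
  df <- data.frame(cdr3_aa = cdr3,
                   v_call = sample(v_names, pool_size, replace = TRUE,
                                   prob = v_simplex),
                   j_call = sample(j_names, pool_size, replace = TRUE,
                                   prob = j_simplex),
                   stringsAsFactors = FALSE)
  shifted_v <- v_names[seq_len(max(1L, ceiling(pars$n_v * 0.1)))]
  list(df = df,
       weight = seq_len(pool_size)^(-cfg$publicity_exponent),
       len = nchar(cdr3),
       v_shifted = df$v_call %in% shifted_v)
}

# assign isotypes, class switching and SHM counts in place
annotate_bcr <- function(records, cfg) {
  igh <- records$chain == "IGH"
  if (any(igh)) {
    records$isotype[igh] <- sample(names(cfg$isotype_mix), sum(igh),
                                   replace = TRUE, prob = cfg$isotype_mix)
    # class switching: clonotypes with >= 2 UMIs may appear under a second
    # isotype, splitting their count
    cand <- which(igh & records$umi_count >= 2)
    switch_rows <- cand[runif(length(cand)) < cfg$switch_prob]
    if (length(switch_rows) > 0L) {
      extra <- records[switch_rows, , drop = FALSE]
      half <- floor(extra$umi_count / 2)
      records$umi_count[switch_rows] <- records$umi_count[switch_rows] - half
      extra$umi_count <- half
      extra$isotype <- vapply(extra$isotype, function(iso)
        sample(setdiff(IGH_ISOTYPES, iso), 1L), character(1L))
      records <- rbind(records, extra)
    }
    igh <- records$chain == "IGH"
    records$v_mutation_count[igh] <-
      rnbinom(sum(igh), size = cfg$shm_size,
              mu = cfg$shm_mu[records$isotype[igh]])
  }
  for (ch in intersect(c("IGK", "IGL"), unique(records$chain))) {
    sel <- records$chain == ch
    records$v_mutation_count[sel] <-
      rnbinom(sum(sel), size = cfg$shm_size, mu = cfg$shm_mu[[ch]])
  }
  records
}

#' Generate a synthetic case-control cohort
#'
#' Draws a seeded multi-chain cohort under the configured publicity,
#' clonality and covariate models, optionally planting differential clones
#' and k-mer motifs, and returns the ground truth needed for recovery
#' studies. Per-sample chain totals equal the (possibly depth-varied)
#' drawn depth exactly because abundances are multinomial-conditioned.
#'
#' @param config A [cohort_config()].
#' @return List with `records` (clonotype table), `metadata` (sample
#'   metadata with `group`, `subject_id`, `age`, `sex`, `total_umis`) and
#'   `truth` (object of class `synthetic_truth`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_cases + config$n_controls
  groups <- c(rep("case", config$n_cases), rep("control", config$n_controls))
  sids <- sprintf("S%03d", seq_len(n))
  meta <- data.frame(
    sample_id = sids,
    subject_id = sprintf("P%03d", seq_len(n)),
    group = groups,
    timepoint = "baseline",
    response = NA_character_,
    age = round(pmin(85, pmax(18, rnorm(n, config$age_mean, config$age_sd)))),
    sex = ifelse(runif(n) < config$sex_prob_f[groups], "F", "M"),
    stringsAsFactors = FALSE)
  spike <- config$spike
  truth_diff <- NULL
  kmer_truth <- NULL
  all_records <- vector("list", length(config$chains))
  names(all_records) <- names(config$chains)
  for (chain in names(config$chains)) {
    pool <- build_pool(chain, config, n)
    spike_info <- NULL
    if (!is.null(spike) && identical(spike$chain, chain) &&
        (spike$n_clones %||% 0) > 0) {
      spike_idx <- sample(nrow(pool$df), spike$n_clones)
      p0 <- spike$detection_p0 %||% 0.25
      orr <- spike$detection_odds %||% 1
      p1 <- if (is.infinite(orr)) 1 else plogis(qlogis(p0) + log(orr))
      spike_info <- list(idx = spike_idx, p_control = p0, p_case = p1,
                         log2fc = spike$log2fc %||% 0,
                         rank_quantile = spike$rank_quantile %||% 0.25)
      truth_diff <- data.frame(chain = chain,
                               cdr3_aa = pool$df$cdr3_aa[spike_idx],
                               detection_p0 = p0, detection_odds = orr,
                               log2fc = spike_info$log2fc,
                               stringsAsFactors = FALSE)
    }
    # motif-carrying clones reachable by case samples only
    motif_pool_idx <- integer(0)
    if (!is.null(spike) && identical(spike$chain, chain) &&
        !is.null(spike$kmer)) {
      frac <- spike$kmer$case_clone_fraction
      n_motif <- max(1L, round(frac * config$chains[[chain]]$richness))
      motif_pool_idx <- sample(setdiff(seq_len(nrow(pool$df)),
                                       spike_info$idx %||% integer(0)),
                               n_motif)
      pool$df$cdr3_aa[motif_pool_idx] <-
        vapply(pool$df$cdr3_aa[motif_pool_idx], insert_motif,
               character(1L), motif = spike$kmer$motif)
      kmer_truth <- list(motif = spike$kmer$motif,
                         clones = pool$df$cdr3_aa[motif_pool_idx])
    }
    chain_recs <- vector("list", n)
    for (s in seq_len(n)) {
      is_case <- groups[s] == "case"
      si <- spike_info
      if (length(motif_pool_idx) > 0L) {
        # cases sample motif clones with boosted weight; controls never do
        pool_s <- pool
        pool_s$weight[motif_pool_idx] <-
          if (is_case) stats::median(pool$weight) * 4 else 0
        chain_recs[[s]] <- sample_chain_records(chain, pool_s, config,
                                                is_case, si)
      } else {
        chain_recs[[s]] <- sample_chain_records(chain, pool, config,
                                                is_case, si)
      }
    }
    ns <- vapply(chain_recs, function(x) length(x$idx), integer(1L))
    idx_all <- unlist(lapply(chain_recs, `[[`, "idx"), use.names = FALSE)
    all_records[[chain]] <- data.frame(
      sample_id = rep.int(sids, ns),
      chain = chain,
      cdr3_aa = pool$df$cdr3_aa[idx_all],
      v_call = pool$df$v_call[idx_all],
      j_call = pool$df$j_call[idx_all],
      umi_count = unlist(lapply(chain_recs, `[[`, "counts"),
                         use.names = FALSE),
      isotype = NA_character_,
      v_mutation_count = NA_real_,
      stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, all_records)
  rownames(records) <- NULL
  records <- annotate_bcr(records, config)
  records <- records[order(records$sample_id, records$chain,
                           records$cdr3_aa), , drop = FALSE]
  rownames(records) <- NULL
  depth <- tapply(records$umi_count, records$sample_id, sum)
  meta$total_umis <- as.numeric(depth[meta$sample_id])
  if (!is.null(truth_diff)) {
    obs <- paste(records$chain, records$cdr3_aa) # mark planted clones seen
    truth_diff$observed <- paste(truth_diff$chain, truth_diff$cdr3_aa) %in% obs
  }
  truth <- structure(list(differential_clones = truth_diff,
                          kmer = kmer_truth,
                          dynamics = NULL,
                          seed = config$seed),
                     class = "synthetic_truth")
  list(records = records, metadata = meta, truth = truth)
}

#' Generate a paired longitudinal cohort
#'
#' Simulates patients sampled at baseline and after twelve weeks of
#' therapy. Baseline repertoires come from the case-control generator;
#' week-12 counts are resampled multinomially from baseline frequencies
#' multiplied by `2^lfc` for clones labeled contracted (negative lfc) or
#' expanded (positive lfc), with zero fold change for unlabeled clones.
#' Contraction is more frequent for BCR than TCR chains, and contracted
#' clones carry stochastically larger |log2 fold changes| than expanded
#' ones, matching the configured longitudinal law.
#'
#' @param config A [cohort_config()]; `n_cases` patients are simulated
#'   (controls are ignored in the paired design).
#' @return List with `records` (baseline + week12), `metadata` (two rows
#'   per subject sharing `subject_id`, differing in `timepoint`) and
#'   `truth` with a `dynamics` table (`chain`, `cdr3_aa`, `label`,
#'   `log2fc`).
#' @export
generate_longitudinal <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  base_cfg <- config
  base_cfg$n_controls <- 0
  base <- generate_cohort(base_cfg)
  lcfg <- config$longitudinal
  rec0 <- base$records
  set.seed(config$seed + 1L)
  dyn <- do.call(rbind, lapply(unique(rec0$chain), function(ch) {
    clones <- unique(rec0$cdr3_aa[rec0$chain == ch])
    frac_c <- if (ch %in% BCR_CHAINS) lcfg$frac_contracted_bcr
              else lcfg$frac_contracted_tcr
    n_c <- round(frac_c * length(clones))
    n_e <- round(lcfg$frac_expanded * length(clones))
    lab <- sample(clones, n_c + n_e)
    contracted <- lab[seq_len(n_c)]
    expanded <- setdiff(lab, contracted)
    rbind(
      if (n_c > 0) data.frame(chain = ch, cdr3_aa = contracted,
                              label = "contracted",
                              log2fc = -abs(rnorm(n_c,
                                                  lcfg$lfc_mean_contracted,
                                                  lcfg$lfc_sd))),
      if (n_e > 0) data.frame(chain = ch, cdr3_aa = expanded,
                              label = "expanded",
                              log2fc = abs(rnorm(n_e,
                                                 lcfg$lfc_mean_expanded,
                                                 lcfg$lfc_sd))))
  }))
  lfc_of <- setNames(dyn$log2fc, paste(dyn$chain, dyn$cdr3_aa))
  w12 <- do.call(rbind, lapply(split(rec0,
                                     list(rec0$sample_id, rec0$chain),
                                     drop = TRUE), function(g) {
    depth <- sum(g$umi_count)
    lfc <- lfc_of[paste(g$chain, g$cdr3_aa)]
    lfc[is.na(lfc)] <- 0
    p <- g$umi_count * 2^lfc
    counts <- as.integer(rmultinom(1L, depth, p))
    keep <- counts > 0L
    out <- g[keep, , drop = FALSE]
    out$umi_count <- counts[keep]
    out$sample_id <- paste0(out$sample_id, "w12")
    out
  }))
  rownames(w12) <- NULL
  records <- rbind(rec0, w12)
  meta12 <- base$metadata
  meta12$sample_id <- paste0(meta12$sample_id, "w12")
  meta12$timepoint <- "week12"
  meta <- rbind(base$metadata, meta12)
  depth <- tapply(records$umi_count, records$sample_id, sum)
  meta$total_umis <- as.numeric(depth[meta$sample_id])
  meta$response <- rep(ifelse(runif(nrow(base$metadata)) < 0.6,
                              "responder", "nonresponder"), 2L)
  truth <- base$truth
  truth$dynamics <- dyn
  list(records = records, metadata = meta, truth = truth)
}

#' Plant differential effects into an existing record table
#'
#' Applies abundance and/or detection shifts of a stated size to target
#' clones in case samples, leaving control samples untouched. Detection
#' shifts insert the clone into case samples that lack it with the
#' probability implied by the control detection rate and the requested
#' odds ratio (`Inf` makes the clone case-only from the detection side);
#' abundance shifts multiply case UMI counts by `2^log2fc`.
#'
#' @param records Clonotype record table.
#' @param metadata Sample metadata with `group`.
#' @param chain Chain of the target clones.
#' @param clones CDR3 sequences to spike; must exist in the records.
#' @param detection_odds Case/control detection odds ratio (1 = none).
#' @param log2fc Case abundance log2 fold change (0 = none).
#' @return List with modified `records` and a `truth` data frame.
#' @export
spike_differential_features <- function(records, metadata, chain, clones,
                                        detection_odds = 1, log2fc = 0) {
  sel_chain <- records$chain == chain
  missing <- setdiff(clones, records$cdr3_aa[sel_chain])
  if (length(missing) > 0L)
    stop("cannot spike non-existent clone(s): ",
         paste(head(missing, 3L), collapse = ", "))
  case_samples <- metadata$sample_id[metadata$group == "case"]
  control_samples <- metadata$sample_id[metadata$group == "control"]
  for (cl in clones) {
    rows <- which(records$chain == chain & records$cdr3_aa == cl)
    in_case <- rows[records$sample_id[rows] %in% case_samples]
    if (log2fc != 0 && length(in_case) > 0L)
      records$umi_count[in_case] <-
        pmax(1, round(records$umi_count[in_case] * 2^log2fc))
    if (detection_odds != 1) {
      p0 <- mean(control_samples %in% records$sample_id[rows])
      p0 <- min(max(p0, 1 / (length(control_samples) + 2)), 0.95)
      p1 <- if (is.infinite(detection_odds)) 1
            else plogis(qlogis(p0) + log(detection_odds))
      absent <- setdiff(case_samples, records$sample_id[rows])
      add_p <- max(0, (p1 - p0) / (1 - p0))
      to_add <- absent[runif(length(absent)) < add_p]
      if (length(to_add) > 0L) {
        template <- records[rows[1L], , drop = FALSE]
        umi <- max(1, round(stats::median(records$umi_count[rows])))
        new <- template[rep(1L, length(to_add)), , drop = FALSE]
        new$sample_id <- to_add
        new$umi_count <- umi
        records <- rbind(records, new)
      }
    }
  }
  rownames(records) <- NULL
  truth <- data.frame(chain = chain, cdr3_aa = clones,
                      detection_odds = detection_odds, log2fc = log2fc,
                      stringsAsFactors = FALSE)
  list(records = records, truth = truth)
}
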