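# Physicochemical characterization of CDR3 amino-acid sequences: property
# vectors, the resampling-based Biochemical Enrichment Score (BES) and
# logistic contrasts between clone sets.

# Kyte-Doolittle hydropathy scale
KD_HYDROPATHY <- c(A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8, G = -0.4,
                   H = -3.2, I = 4.5, K = -3.9, L = 3.8, M = 1.9, N = -3.5,
                   P = -1.6, Q = -3.5, R = -4.5, S = -0.8, T = -0.7,
                   V = 4.2, W = -0.9, Y = -1.3)

# EMBOSS pKa values for ionizable groups
EMBOSS_PKA <- c(Nterm = 8.6, Cterm = 3.6, C = 8.5, D = 3.9, E = 4.1,
                H = 6.5, K = 10.8, R = 12.5, Y = 10.1)

# Boman residue scale (water-to-cyclohexane transfer free energies,
# kcal/mol); the Boman protein-interaction index is minus their mean.
BOMAN_SCALE <- c(A = 1.81, C = 1.28, D = -8.72, E = -6.81, F = 2.98,
                 G = 0.94, H = -4.66, I = 4.92, K = -5.55, L = 4.92,
                 M = 2.35, N = -6.64, P = 0, Q = -5.54, R = -14.92,
                 S = -3.40, T = -2.57, V = 4.04, W = 2.33, Y = -0.14)

# average residue masses (Da); water (18.02) is added per peptide
AA_MASS <- c(A = 71.0788, C = 103.1388, D = 115.0886, E = 129.1155,
             F = 147.1766, G = 57.0519, H = 137.1411, I = 113.1594,
             K = 128.1741, L = 113.1594, M = 131.1926, N = 114.1038,
             P = 97.1167, Q = 128.1307, R = 156.1875, S = 87.0782,
             T = 101.1051, V = 99.1326, W = 186.2132, Y = 163.1760)

# residue classes: acidic, basic, and polar (uncharged polar plus charged)
ACIDIC_AA <- c("D", "E")
BASIC_AA <- c("K", "R", "H")
POLAR_AA <- c("S", "T", "N", "Q", "Y", "C", ACIDIC_AA, BASIC_AA)

aa_counts <- function(seq) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  bad <- which(!ch %in% AA_ALPHABET)
  if (length(bad) > 0L)
    stop("invalid residue '", ch[bad[1L]], "' at position ", bad[1L],
         " of '", seq, "'")
  table(factor(ch, levels = AA_ALPHABET))
}

# Henderson-Hasselbalch net charge of a peptide at a given pH
peptide_charge <- function(counts, pH = 7) {
  pos <- c(Nterm = 1, K = unname(counts["K"]), R = unname(counts["R"]),
           H = unname(counts["H"]))
  neg <- c(Cterm = 1, D = unname(counts["D"]), E = unname(counts["E"]),
           C = unname(counts["C"]), Y = unname(counts["Y"]))
  pka_pos <- EMBOSS_PKA[c("Nterm", "K", "R", "H")]
  pka_neg <- EMBOSS_PKA[c("Cterm", "D", "E", "C", "Y")]
  sum(pos / (1 + 10^(pH - pka_pos))) - sum(neg / (1 + 10^(pka_neg - pH)))
}

#' Physicochemical property vector of a CDR3 sequence
#'
#' Computes, per sequence: net charge at pH 7 (Henderson-Hasselbalch with
#' the EMBOSS pKa set), isoelectric point (bisection on the charge
#' function), GRAVY hydrophobicity (mean Kyte-Doolittle hydropathy),
#' aliphatic index (Ikai), Boman protein-protein interaction index
#' (negated mean residue transfer free energy), average molecular weight
#' (Da), polarity/acidic/basic residue fractions and length.
#'
#' @param cdr3 Character vector of amino-acid sequences.
#' @return Data frame, one row per sequence, with columns `cdr3_aa`,
#'   `net_charge`, `isoelectric_point`, `hydrophobicity`,
#'   `aliphatic_index`, `boman_index`, `molecular_weight`,
#'   `polarity_fraction`, `acidic_fraction`, `basic_fraction`, `length`.
#' @examples
#' compute_properties("IIII")$hydrophobicity  # 4.5
#' @export
compute_properties <- function(cdr3) {
  rows <- lapply(as.character(cdr3), function(s) {
    counts <- aa_counts(s)
    L <- sum(counts)
    frac <- counts / L
    charge <- peptide_charge(counts, 7)
    pi_fun <- function(pH) peptide_charge(counts, pH)
    pI <- tryCatch(uniroot(pi_fun, c(0, 14), tol = 1e-6)$root,
                   error = function(e) NA_real_)
    data.frame(
      cdr3_aa = s,
      net_charge = charge,
      isoelectric_point = pI,
      hydrophobicity = sum(frac * KD_HYDROPATHY[names(frac)]),
      aliphatic_index = 100 * (frac[["A"]] + 2.9 * frac[["V"]] +
                                 3.9 * (frac[["I"]] + frac[["L"]])),
      boman_index = -sum(frac * BOMAN_SCALE[names(frac)]),
      molecular_weight = sum(counts * AA_MASS[names(counts)]) + 18.02,
      polarity_fraction = sum(frac[POLAR_AA]),
      acidic_fraction = sum(frac[ACIDIC_AA]),
      basic_fraction = sum(frac[BASIC_AA]),
      length = L,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

BES_PROPERTIES <- c("net_charge", "isoelectric_point", "hydrophobicity",
                    "aliphatic_index", "boman_index", "molecular_weight",
                    "polarity_fraction", "acidic_fraction",
                    "basic_fraction", "length")

#' Biochemical Enrichment Score by random-repertoire resampling
#'
#' Compares the mean biochemical properties of a clone set against a null
#' of random repertoires: sets of the same size sampled uniformly without
#' replacement from the background clones of the same chain. Per property,
#' the enrichment p-value is `(1 + #{null >= observed}) / (n + 1)` and the
#' depletion p-value the mirror count; the Biochemical Enrichment Score is
#' `BES = -log10(p_enrich) + log10(p_deplete)`, positive when the set is
#' enriched for the property relative to chance.
#'
#' @param clone_set CDR3 sequences of interest (>= 2, subset of the
#'   background).
#' @param background Background CDR3 sequences (same chain).
#' @param n_resamples Number of resampled sets, default 1000.
#' @param seed RNG seed.
#' @param properties Property columns to score (default all).
#' @return Data frame with `property`, `observed`, `null_mean`,
#'   `p_enrich`, `p_deplete`, `bes`, `n_resamples`.
#' @export
bes_resampling <- function(clone_set, background, n_resamples = 1000,
                           seed = NULL, properties = BES_PROPERTIES) {
  clone_set <- unique(as.character(clone_set))
  background <- unique(as.character(background))
  if (length(clone_set) < 2L) stop("clone_set must contain >= 2 clones")
  if (!all(clone_set %in% background))
    stop("clone_set must be a subset of the background")
  if (length(background) < length(clone_set))
    stop("background smaller than clone_set")
  if (!is.null(seed)) set.seed(seed)
  props <- compute_properties(background)
  pm <- as.matrix(props[, properties, drop = FALSE])
  set_idx <- match(clone_set, background)
  m <- length(set_idx)
  observed <- colMeans(pm[set_idx, , drop = FALSE])
  null <- base::matrix(NA_real_, n_resamples, length(properties),
                       dimnames = list(NULL, properties))
  for (i in seq_len(n_resamples)) {
    null[i, ] <- colMeans(pm[sample.int(nrow(pm), m), , drop = FALSE])
  }
  p_enr <- (1 + colSums(sweep(null, 2L, observed, `>=`))) / (n_resamples + 1)
  p_dep <- (1 + colSums(sweep(null, 2L, observed, `<=`))) / (n_resamples + 1)
  data.frame(property = properties,
             observed = unname(observed),
             null_mean = unname(colMeans(null)),
             p_enrich = unname(p_enr),
             p_deplete = unname(p_dep),
             bes = unname(-log10(p_enr) + log10(p_dep)),
             n_resamples = n_resamples,
             stringsAsFactors = FALSE)
}

# weighted logistic contrast shared by the two contrast functions; weights
# are normalized to mean 1 so that constant weights reduce exactly to the
# unweighted analysis
contrast_engine <- function(set_a, set_b, weights_a, weights_b,
                            properties) {
  pa <- compute_properties(set_a)
  pb <- compute_properties(set_b)
  y <- c(rep(1, nrow(pa)), rep(0, nrow(pb)))
  w <- c(weights_a, weights_b)
  w <- w / mean(w)
  len <- c(pa$length, pb$length)
  out <- lapply(properties, function(pr) {
    v <- c(pa[[pr]], pb[[pr]])
    if (sd(pa[[pr]]) == 0 && sd(pb[[pr]]) == 0) {
      warning("property '", pr, "' is constant in both sets")
      return(data.frame(property = pr, effect = NA_real_, se = NA_real_,
                        p = NA_real_, flag = "constant"))
    }
    X <- cbind(1, v, len)
    if (pr == "length") X <- X[, 1:2, drop = FALSE]
    fit <- irls_logistic(X, y, weights = w, vcov = TRUE)
    flag <- ""
    if (fit$separated) {
      fit <- irls_logistic(X, y, weights = w, ridge = 1e-4, vcov = TRUE)
      flag <- "separation"
    }
    se <- sqrt(fit$vcov[2L, 2L])
    z <- fit$coef[2L] / se
    data.frame(property = pr, effect = fit$coef[2L], se = se,
               p = 2 * pnorm(-abs(z)), flag = flag,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Contrast the biochemical profiles of two clone sets
#'
#' Per property, fits a logistic regression of set membership (A = 1,
#' B = 0) on the property value adjusted for CDR3 length, and reports the
#' property coefficient with its Wald p-value. Complete separation
#' triggers a ridge-penalized refit, flagged in the output.
#'
#' @param set_a,set_b CDR3 sequences of the two sets (same chain).
#' @param properties Property columns, default all.
#' @return Data frame with `property`, `effect`, `se`, `p`, `flag`.
#' @export
contrast_biochemistry <- function(set_a, set_b,
                                  properties = BES_PROPERTIES) {
  if (length(set_a) == 0L || length(set_b) == 0L)
    stop("both sets must be non-empty")
  contrast_engine(set_a, set_b, rep(1, length(set_a)),
                  rep(1, length(set_b)), properties)
}

#' Magnitude-weighted global biochemical contrast
#'
#' As [contrast_biochemistry()], but each clone is weighted in the
#' likelihood by the magnitude of its frequency change (|log2 fold
#' change|), quantifying the global biochemical effect of the perturbation
#' rather than the per-clone composition. Weights are normalized to mean
#' one, so equal weights reproduce the unweighted contrast exactly.
#'
#' @param set_a,set_b CDR3 sequences.
#' @param weights_a,weights_b Non-negative finite clone weights.
#' @param properties Property columns, default all.
#' @return Data frame as in [contrast_biochemistry()].
#' @export
weighted_global_contrast <- function(set_a, weights_a, set_b, weights_b,
                                     properties = BES_PROPERTIES) {
  w <- c(weights_a, weights_b)
  if (any(!is.finite(w)) || any(w < 0))
    stop("weights must be non-negative and finite")
  if (all(w == 0)) stop("weights must not be all zero")
  if (length(weights_a) != length(set_a) ||
      length(weights_b) != length(set_b))
    stop("weights must match the clone sets in length")
  contrast_engine(set_a, set_b, weights_a, weights_b, properties)
}
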