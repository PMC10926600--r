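# Shared fixture builders. Everything is generated in code; no data files.

make_records <- function(sample_id, chain, cdr3_aa, v_call = "V1",
                         j_call = "J1", umi_count = 1, isotype = NA,
                         v_mutation_count = NA) {
  data.frame(sample_id = sample_id, chain = chain, cdr3_aa = cdr3_aa,
             v_call = v_call, j_call = j_call, umi_count = umi_count,
             isotype = as.character(isotype),
             v_mutation_count = as.numeric(v_mutation_count),
             stringsAsFactors = FALSE)
}

# random CDR3-like sequences (no uniqueness guarantee)
random_cdr3 <- function(n, len_min = 8, len_max = 18) {
  aa <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q","R",
          "S","T","V","W","Y")
  lens <- if (len_min == len_max) rep(len_min, n)
          else sample(len_min:len_max, n, replace = TRUE)
  vapply(lens, function(L)
    paste0("C", paste(sample(aa, L - 2, replace = TRUE), collapse = ""),
           "F"), character(1))
}

# brute-force Levenshtein distance by dynamic programming (test oracle,
# independent of the package implementation)
dp_levenshtein <- function(a, b) {
  sa <- strsplit(a, "")[[1]]
  sb <- strsplit(b, "")[[1]]
  la <- length(sa); lb <- length(sb)
  d <- matrix(0L, la + 1, lb + 1)
  d[, 1] <- 0:la
  d[1, ] <- 0:lb
  for (i in seq_len(la)) for (j in seq_len(lb)) {
    cost <- if (sa[i] == sb[j]) 0L else 1L
    d[i + 1, j + 1] <- min(d[i, j + 1] + 1L, d[i + 1, j] + 1L,
                           d[i, j] + cost)
  }
  d[la + 1, lb + 1]
}

# small single-chain AIRR TSV written to a temp file
write_fixture_tsv <- function(rows, path = tempfile(fileext = ".tsv")) {
  header <- paste(c("repertoire_id", "locus", "junction_aa", "v_call",
                    "j_call", "duplicate_count", "c_call",
                    "v_mutation_count"), collapse = "\t")
  writeLines(c(header, rows), path)
  path
}

# tiny deterministic cohort used across tests
tiny_cohort <- function(seed = 42, n_cases = 8, n_controls = 8,
                        chains = list(TRB = list(richness = 100,
                                                 depth = 2000,
                                                 len_mean = 14,
                                                 len_sd = 1.5,
                                                 n_v = 15, n_j = 6)),
                        ...) {
  generate_cohort(cohort_config(n_cases = n_cases,
                                n_controls = n_controls,
                                chains = chains, seed = seed, ...))
}

# pair-vectorized Levenshtein DP oracle: runs the classic (L1+1) x (L2+1)
# dynamic program with all pairs in lock-step, masking positions beyond
# each string's length
vectorized_dp_levenshtein <- function(a, b) {
  n <- length(a)
  la <- nchar(a)
  lb <- nchar(b)
  L1 <- max(la)
  L2 <- max(lb)
  am <- matrix("", n, L1)
  bm <- matrix("", n, L2)
  for (k in seq_len(n)) {
    am[k, seq_len(la[k])] <- strsplit(a[k], "")[[1]]
    bm[k, seq_len(lb[k])] <- strsplit(b[k], "")[[1]]
  }
  prev <- matrix(rep(0:L2, each = n), n, L2 + 1)
  out <- integer(n)
  done_a <- la == 0
  out[done_a] <- lb[done_a]
  for (i in seq_len(L1)) {
    cur <- matrix(0L, n, L2 + 1)
    cur[, 1] <- i
    for (j in seq_len(L2)) {
      cost <- ifelse(am[, i] == bm[, j], 0L, 1L)
      cur[, j + 1] <- pmin(prev[, j + 1] + 1L, cur[, j] + 1L,
                           prev[, j] + cost)
    }
    hit <- la == i
    if (any(hit)) out[hit] <- cur[cbind(which(hit), lb[hit] + 1L)]
    prev <- cur
  }
  as.integer(out)
}
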