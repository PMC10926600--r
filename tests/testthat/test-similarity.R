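test_that("levenshtein matches the dynamic-programming oracle", {
  expect_equal(levenshtein("CASSL", "CASSL"), 0L)
  expect_equal(levenshtein("CASS", "CASR"), 1L)
  expect_equal(levenshtein("kitten", "sitting"), 3L)
  set.seed(21)
  for (i in 1:300) {
    a <- random_cdr3(1, 4, 14)
    b <- random_cdr3(1, 4, 14)
    expect_equal(levenshtein(a, b), dp_levenshtein(a, b))
  }
  # triangle inequality on random triples
  for (i in 1:500) {
    s <- random_cdr3(3, 4, 12)
    d <- levenshtein_matrix(s)
    expect_lte(d[1, 3], d[1, 2] + d[2, 3])
  }
})

test_that("similarity network equals brute-force all-pairs construction", {
  net <- build_similarity_network(c("CASS", "CASR", "CAS", "WXYZ"))
  edges <- network_edges(net)
  key <- function(df) sort(paste(pmin(df$from, df$to),
                                 pmax(df$from, df$to)))
  expect_identical(key(edges),
                   key(data.frame(from = c("CASS", "CASS", "CASR"),
                                  to = c("CASR", "CAS", "CAS"))))
  expect_equal(igraph::degree(net$graph)[["WXYZ"]], 0)
  expect_equal(igraph::ecount(build_similarity_network("CASS")$graph), 0)
  # oracle equivalence on 500 random CDR3s (forces the hashing path)
  set.seed(31)
  clones <- unique(random_cdr3(500, 8, 14))
  net <- build_similarity_network(clones)
  d <- adist(clones)
  oracle_edges <- which(d <= 1 & upper.tri(d), arr.ind = TRUE)
  expect_equal(igraph::ecount(net$graph), nrow(oracle_edges))
  got <- key(network_edges(net))
  want <- sort(paste(pmin(clones[oracle_edges[, 1]],
                          clones[oracle_edges[, 2]]),
                     pmax(clones[oracle_edges[, 1]],
                          clones[oracle_edges[, 2]])))
  expect_identical(got, want)
  # hamming mode never links length-mismatched sequences
  neth <- build_similarity_network(c("CASS", "CAS", "CASR"),
                                   mode = "hamming")
  eh <- network_edges(neth)
  expect_identical(key(eh), sort(paste("CASR", "CASS")))
})

test_that("degree-centrality permutation test is calibrated and bounded", {
  set.seed(41)
  background <- unique(random_cdr3(300, 8, 12))
  # null-drawn sets give roughly uniform p (coarse check; full KS in the
  # acceptance suite)
  ps <- replicate(60, {
    degree_centrality_similarity_test(sample(background, 15), background,
                                      n_perm = 200)$p
  })
  expect_gt(mean(ps > 0.1), 0.5)
  expect_true(all(ps >= 1 / 201))
  # forced extreme: single-substitution variants of one sequence
  seed_seq <- "CASSLGQAYEQYF"
  variants <- unique(vapply(1:20, function(i) {
    s <- strsplit(seed_seq, "")[[1]]
    pos <- 2 + (i %% (nchar(seed_seq) - 2))
    s[pos] <- sample(setdiff(c("A", "G", "T", "S", "R", "K"), s[pos]), 1)
    paste(s, collapse = "")
  }, character(1)))
  bg2 <- unique(c(variants, background))
  res <- degree_centrality_similarity_test(variants, bg2, n_perm = 500,
                                           seed = 1)
  expect_equal(res$p, 1 / 501)
  expect_error(degree_centrality_similarity_test("CASSF", background),
               "at least 2")
  expect_error(degree_centrality_similarity_test(c("NOTINBGX", "NOTINBGY"),
                                                 background), "subset")
})

test_that("meta-clone detection recovers components and conserves counts", {
  # two disjoint triangles
  tri1 <- c("CAAAF", "CAABF", "CAACF")
  tri2 <- c("WWWWW", "WWWWA", "WWWWC")
  mc <- detect_metaclones(build_similarity_network(c(tri1, tri2)))
  expect_length(mc$communities, 2L)
  expect_setequal(mc$communities[[1]], tri1)
  expect_setequal(mc$communities[[2]], tri2)
  # path of 3 stays one community
  path3 <- detect_metaclones(build_similarity_network(
    c("CAAAF", "CAABF", "CAABG")))
  expect_length(path3$communities, 1L)
  # aggregation: sums per sample, exact conservation, identity for
  # singleton meta-clones
  sim <- tiny_cohort(seed = 13, n_cases = 4, n_controls = 4)
  fm <- build_feature_matrix(sim$records, "clone", chain = "TRB")
  net <- build_similarity_network(rownames(fm$counts))
  mc <- detect_metaclones(net)
  agg <- aggregate_metaclone_counts(mc, fm)
  expect_equal(colSums(agg$counts), colSums(fm$counts))
  singles <- names(mc$communities)[lengths(mc$communities) == 1L]
  for (s in head(singles, 3)) {
    member <- mc$communities[[s]]
    expect_equal(agg$counts[s, ], fm$counts[member, ])
  }
  expect_error(aggregate_metaclone_counts(
    list(membership = data.frame(clone = "ZZZZZ", metaclone_id = "mc1")),
    fm), "missing")
})

test_that("greedy modularity is near-optimal on exhaustive small graphs", {
  # exhaustive best-partition modularity via set partitions of <= 7 nodes
  partitions <- function(n) {
    if (n == 1) return(list(list(1L)))
    smaller <- partitions(n - 1)
    out <- list()
    for (p in smaller) {
      for (i in seq_along(p)) {
        q <- p
        q[[i]] <- c(q[[i]], n)
        out[[length(out) + 1]] <- q
      }
      out[[length(out) + 1]] <- c(p, list(n))
    }
    out
  }
  set.seed(51)
  for (rep in 1:25) {
    n <- sample(4:7, 1)
    g <- igraph::sample_gnp(n, runif(1, 0.3, 0.7))
    if (igraph::ecount(g) == 0) next
    best <- max(vapply(partitions(n), function(p) {
      memb <- integer(n)
      for (i in seq_along(p)) memb[p[[i]]] <- i
      igraph::modularity(g, memb)
    }, numeric(1)))
    igraph::V(g)$name <- paste0("v", seq_len(n))
    net <- structure(list(graph = g, clones = igraph::V(g)$name,
                          mode = "levenshtein", max_distance = 1),
                     class = "similarity_network")
    got <- detect_metaclones(net)$modularity
    expect_gte(got, 0.9 * best - 1e-9)
  }
})

test_that("k-mer extraction and counting follow the window rules", {
  expect_equal(extract_kmers("CASSL"), c("CASS", "ASSL"))
  expect_equal(extract_kmers("CAS"), character(0))
  set.seed(61)
  for (s in random_cdr3(50, 3, 20))
    expect_length(extract_kmers(s), max(0, nchar(s) - 3))
  rec <- rbind(make_records("A", "TRB", "CASS", umi_count = 7),
               make_records("A", "TRB", "AAAAA", umi_count = 2))
  km <- kmer_matrix(rec)
  expect_equal(km$counts["CASS", "A"], 7)
  expect_equal(km$counts["AAAA", "A"], 4)   # two windows, multiplicity
  kp <- kmer_matrix(rec, mode = "presence")
  expect_equal(kp$counts["AAAA", "A"], 2)
  # totals equal a brute-force scan on a random fixture
  sim <- tiny_cohort(seed = 17, n_cases = 3, n_controls = 3)
  km <- kmer_matrix(sim$records, chain = "TRB")
  rec <- sim$records[sim$records$chain == "TRB", ]
  brute <- sum(rec$umi_count * pmax(0, nchar(rec$cdr3_aa) - 3))
  expect_equal(sum(km$counts), brute)
})

test_that("k-mer dissimilarity matrix is a valid Levenshtein matrix", {
  kms <- c("CASS", "CASS", "DHRE", "DHRA")
  kd <- kmer_dissimilarity_matrix(kms)
  expect_equal(kd$d[1, 2], 0L)
  expect_true(isSymmetric(unname(kd$d)))
  expect_true(all(diag(kd$d) == 0))
  set.seed(71)
  kms <- unique(substring(random_cdr3(40, 8, 8), 2, 5))
  kd <- kmer_dissimilarity_matrix(kms)
  for (i in 1:10) {
    a <- sample(length(kms), 1); b <- sample(length(kms), 1)
    expect_equal(kd$d[a, b], dp_levenshtein(kms[a], kms[b]))
  }
  expect_error(kmer_dissimilarity_matrix("CASS"), "at least 2")
})
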