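# CDR3 similarity machinery: edit distances, similarity networks,
# degree-centrality permutation tests, meta-clone communities and k-mer
# features. Networks are always chain-stratified; cross-chain edges are
# never formed.

#' Levenshtein edit distance
#'
#' Minimum number of single-character substitutions, insertions and
#' deletions turning one string into the other (each edit costs 1). Unlike
#' the Hamming distance it is defined for strings of unequal length.
#'
#' @param a,b Character vectors (recycled to common length).
#' @return Integer vector of distances.
#' @examples
#' levenshtein("kitten", "sitting")  # 3
#' @export
levenshtein <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  as.integer(mapply(function(x, y) adist(x, y), a, b))
}

#' Pairwise Levenshtein distance matrix
#'
#' @param x Character vector.
#' @return Symmetric integer matrix with zero diagonal.
#' @export
levenshtein_matrix <- function(x) {
  d <- adist(x)
  dimnames(d) <- list(x, x)
  storage.mode(d) <- "integer"
  d
}

# All unordered pairs (i, j), i < j, of strings at Levenshtein distance <= 1
# (or Hamming <= 1: equal length, at most one substitution). Uses
# deletion-key hashing for candidate generation — two strings at edit
# distance <= 1 necessarily share a key among {string} U {single-deletion
# variants} — then verifies candidates with the exact distance, so the
# result equals brute-force all-pairs comparison.
neighbor_pairs <- function(clones, mode = c("levenshtein", "hamming")) {
  mode <- match.arg(mode)
  n <- length(clones)
  if (n < 2L) return(matrix(integer(0), ncol = 2L))
  if (n <= 400L) {
    d <- adist(clones)
    if (mode == "hamming") {
      len <- nchar(clones)
      d[outer(len, len, `!=`)] <- Inf
    }
    idx <- which(d <= 1 & upper.tri(d), arr.ind = TRUE)
    return(unname(idx[, c(1L, 2L), drop = FALSE]))
  }
  keys <- vector("list", n)
  for (i in seq_len(n)) {
    s <- clones[i]
    L <- nchar(s)
    dels <- vapply(seq_len(L), function(p)
      paste0(substr(s, 1L, p - 1L), substr(s, p + 1L, L)), character(1L))
    keys[[i]] <- unique(c(s, dels))
  }
  lens <- lengths(keys)
  idx <- rep.int(seq_len(n), lens)
  key_vec <- unlist(keys, use.names = FALSE)
  buckets <- split(idx, key_vec)
  cand <- unique(do.call(rbind, lapply(buckets[lengths(buckets) > 1L],
                                       function(v) {
    v <- sort(unique(v))
    if (length(v) < 2L) return(NULL)
    t(combn(v, 2L))
  })))
  if (is.null(cand) || nrow(cand) == 0L)
    return(matrix(integer(0), ncol = 2L))
  d <- mapply(function(i, j) adist(clones[i], clones[j]),
              cand[, 1L], cand[, 2L])
  if (mode == "hamming") {
    same_len <- nchar(clones[cand[, 1L]]) == nchar(clones[cand[, 2L]])
    ok <- d <= 1 & same_len
  } else ok <- d <= 1
  unname(cand[ok, , drop = FALSE])
}

#' CDR3 sequence similarity network
#'
#' Builds the undirected network whose nodes are unique clones of one chain
#' and whose edges connect CDR3 amino-acid sequences differing by at most
#' one amino acid. The default edge criterion is Levenshtein distance <= 1
#' (substitutions and single indels); `mode = "hamming"` restricts edges to
#' equal-length single substitutions.
#'
#' @param clones Character vector of CDR3 amino-acid sequences from one
#'   chain (duplicates are removed).
#' @param max_distance Edge threshold; 1 (the default) uses fast
#'   deletion-key candidate hashing, larger values fall back to all-pairs
#'   computation.
#' @param mode `"levenshtein"` (default) or `"hamming"`.
#' @return Object of class `similarity_network`: list with `graph` (an
#'   igraph object with vertex name = CDR3), `clones`, `mode`,
#'   `max_distance`.
#' @export
build_similarity_network <- function(clones, max_distance = 1,
                                     mode = c("levenshtein", "hamming")) {
  mode <- match.arg(mode)
  clones <- unique(as.character(clones))
  if (length(clones) == 0L) {
    g <- igraph::make_empty_graph(0, directed = FALSE)
  } else if (max_distance == 1) {
    pairs <- neighbor_pairs(clones, mode)
    g <- igraph::make_empty_graph(length(clones), directed = FALSE)
    igraph::V(g)$name <- clones
    if (nrow(pairs) > 0L)
      g <- igraph::add_edges(g, t(pairs))
  } else {
    d <- adist(clones)
    if (mode == "hamming") {
      len <- nchar(clones)
      d[outer(len, len, `!=`)] <- Inf
    }
    idx <- which(d <= max_distance & upper.tri(d), arr.ind = TRUE)
    g <- igraph::make_empty_graph(length(clones), directed = FALSE)
    igraph::V(g)$name <- clones
    if (nrow(idx) > 0L)
      g <- igraph::add_edges(g, t(idx[, c(1L, 2L), drop = FALSE]))
  }
  structure(list(graph = g, clones = clones, mode = mode,
                 max_distance = max_distance),
            class = "similarity_network")
}

#' @export
#' @method print similarity_network
print.similarity_network <- function(x, ...) {
  cat(sprintf("similarity_network: %d clones, %d edges (%s distance <= %d)\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph), x$mode,
              x$max_distance))
  invisible(x)
}

#' Edge list of a similarity network
#'
#' @param network A `similarity_network`.
#' @return Data frame with columns `from`, `to` (CDR3 sequences).
#' @export
network_edges <- function(network) {
  e <- igraph::as_edgelist(network$graph)
  data.frame(from = e[, 1L], to = e[, 2L], stringsAsFactors = FALSE)
}

#' Degree-centrality similarity permutation test
#'
#' Tests whether a set of clones is more sequence-similar than expected by
#' chance. The observed statistic is the mean node degree of the set's
#' internal similarity network; the null distribution is obtained by
#' resampling, uniformly and without replacement from the background
#' repertoire of the same chain, sets of the same size, and recomputing the
#' statistic. The empirical p-value uses the standard pseudocount,
#' `(1 + #{null >= observed}) / (n_perm + 1)`, so it can never be zero.
#'
#' @param clone_set Character vector of clones of interest (>= 2, subset of
#'   `background`).
#' @param background Character vector of background clones (same chain).
#' @param n_perm Number of permutations, default 1000.
#' @param seed RNG seed.
#' @param mode Edge criterion passed to the network construction.
#' @return List with `observed`, `null_mean`, `p`, `n_perm`.
#' @export
degree_centrality_similarity_test <- function(clone_set, background,
                                              n_perm = 1000, seed = NULL,
                                              mode = "levenshtein") {
  clone_set <- unique(as.character(clone_set))
  background <- unique(as.character(background))
  if (length(clone_set) < 2L) stop("clone_set must contain at least 2 clones")
  if (!all(clone_set %in% background))
    stop("clone_set must be a subset of the background")
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  m <- length(clone_set)
  mean_degree <- function(set) {
    pairs <- neighbor_pairs(set, mode)
    2 * nrow(pairs) / length(set)
  }
  # For moderate backgrounds, precompute the full adjacency once and reuse
  # it across permutations; otherwise recompute per draw.
  if (length(background) <= 5000L) {
    pairs <- neighbor_pairs(background, mode)
    adj <- Matrix::sparseMatrix(i = pairs[, 1L], j = pairs[, 2L], x = 1,
                                dims = rep(length(background), 2L),
                                symmetric = TRUE)
    set_idx <- match(clone_set, background)
    sub_degree <- function(idx) {
      Matrix::nnzero(adj[idx, idx]) / length(idx)
    }
    observed <- sub_degree(set_idx)
    null <- vapply(seq_len(n_perm), function(i)
      sub_degree(sample.int(length(background), m)), numeric(1L))
  } else {
    observed <- mean_degree(clone_set)
    null <- vapply(seq_len(n_perm), function(i)
      mean_degree(sample(background, m)), numeric(1L))
  }
  p <- (1 + sum(null >= observed)) / (n_perm + 1)
  list(observed = observed, null_mean = mean(null), p = p, n_perm = n_perm)
}

# Exhaustive maximum-modularity partition of a small connected subgraph
# (<= 8 nodes; Bell(8) = 4140 candidate partitions). `m_global` is the
# edge count of the full network the modularity is taken over.
exact_modularity_partition <- function(sub, m_global) {
  k <- igraph::vcount(sub)
  el <- igraph::as_edgelist(sub, names = FALSE)
  deg <- igraph::degree(sub)
  parts <- set_partitions(k)
  best_q <- -Inf
  best <- NULL
  for (p in parts) {
    q <- 0
    for (block in p) {
      e_in <- sum(el[, 1L] %in% block & el[, 2L] %in% block)
      dsum <- sum(deg[block])
      q <- q + e_in / m_global - (dsum / (2 * m_global))^2
    }
    if (q > best_q + 1e-12) {
      best_q <- q
      best <- p
    }
  }
  memb <- integer(k)
  for (i in seq_along(best)) memb[best[[i]]] <- i
  memb
}

# all set partitions of 1..n (n small), deterministic order; memoized
.partition_cache <- new.env(parent = emptyenv())
set_partitions <- function(n) {
  key <- as.character(n)
  if (!is.null(.partition_cache[[key]])) return(.partition_cache[[key]])
  if (n == 1L) return(list(list(1L)))
  smaller <- set_partitions(n - 1L)
  out <- vector("list", 0L)
  for (p in smaller) {
    for (i in seq_along(p)) {
      q <- p
      q[[i]] <- c(q[[i]], n)
      out[[length(out) + 1L]] <- q
    }
    out[[length(out) + 1L]] <- c(p, list(n))
  }
  .partition_cache[[key]] <- out
  out
}

# Deterministic local refinement of a modularity partition: alternating
# passes of single-node moves (into adjacent communities, nodes visited in
# fixed order) and pairwise community merges, accepted only when they
# increase modularity, until a fixed point. Greedy agglomeration alone can
# return visibly sub-optimal cuts on small graphs; the refinement repairs
# those while leaving good partitions untouched.
refine_modularity <- function(g, memb, m = igraph::ecount(g)) {
  n <- igraph::vcount(g)
  if (m == 0L) return(seq_len(n))
  adj <- igraph::as_adj_list(g, mode = "all")
  adj <- lapply(adj, as.integer)
  deg <- vapply(adj, length, integer(1L))
  tot <- tapply(deg, memb, sum)
  sig_tot <- numeric(max(memb))
  sig_tot[as.integer(names(tot))] <- tot
  for (outer in 1:60) {
    changed <- FALSE
    # single-node moves
    for (i in seq_len(n)) {
      cur <- memb[i]
      nb <- adj[[i]]
      if (length(nb) == 0L) next
      k_to <- tapply(rep(1L, length(nb)), memb[nb], sum)
      cand <- as.integer(names(k_to))
      k_cur <- if (as.character(cur) %in% names(k_to))
        k_to[[as.character(cur)]] else 0
      base_gain <- -(k_cur / m) + deg[i] * (sig_tot[cur] - deg[i]) /
        (2 * m^2)
      best_gain <- 0
      best_c <- cur
      for (cc in cand) {
        if (cc == cur) next
        gain <- base_gain + k_to[[as.character(cc)]] / m -
          deg[i] * sig_tot[cc] / (2 * m^2)
        if (gain > best_gain + 1e-12 ||
            (abs(gain - best_gain) <= 1e-12 && best_c != cur &&
               cc < best_c)) {
          best_gain <- gain
          best_c <- cc
        }
      }
      # allow splitting: moving i into a fresh community of its own
      if (base_gain > best_gain + 1e-12 &&
          sig_tot[cur] - deg[i] > 0) {
        best_gain <- base_gain
        best_c <- length(sig_tot) + 1L
        sig_tot <- c(sig_tot, 0)
      }
      if (best_c != cur) {
        sig_tot[cur] <- sig_tot[cur] - deg[i]
        sig_tot[best_c] <- sig_tot[best_c] + deg[i]
        memb[i] <- best_c
        changed <- TRUE
      }
    }
    # pairwise merges of edge-connected communities
    el <- igraph::as_edgelist(g, names = FALSE)
    cpair <- cbind(pmin(memb[el[, 1L]], memb[el[, 2L]]),
                   pmax(memb[el[, 1L]], memb[el[, 2L]]))
    between <- cpair[cpair[, 1L] != cpair[, 2L], , drop = FALSE]
    if (nrow(between) > 0L) {
      keys <- paste(between[, 1L], between[, 2L])
      e_ab <- table(keys)
      for (k in names(sort(e_ab, decreasing = TRUE))) {
        ab <- as.integer(strsplit(k, " ")[[1L]])
        a <- ab[1L]; b <- ab[2L]
        e_between <- sum((memb[el[, 1L]] == a & memb[el[, 2L]] == b) |
                           (memb[el[, 1L]] == b & memb[el[, 2L]] == a))
        gain <- e_between / m - sig_tot[a] * sig_tot[b] / (2 * m^2)
        if (gain > 1e-12) {
          memb[memb == b] <- a
          sig_tot[a] <- sig_tot[a] + sig_tot[b]
          sig_tot[b] <- 0
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  memb
}

#' Detect meta-clones (similarity-network communities)
#'
#' A meta-clone is a community of clones differing by at most one amino
#' acid, found in the CDR3 similarity network by directly optimizing the
#' partition modularity per connected component — exhaustively for small
#' components, and by fast-greedy agglomeration with a deterministic local
#' refinement (single-node moves and community merges accepted only when
#' modularity increases) for larger ones. Singleton network components
#' are their own communities. Community labels are assigned
#' deterministically: communities are ordered by decreasing size, ties by
#' the lexicographically smallest member CDR3.
#'
#' @param network A `similarity_network` built at `max_distance = 1`.
#' @return List with `membership` (data frame `clone`, `metaclone_id`),
#'   `communities` (named list of member vectors), `modularity` (of the
#'   partition; `NA` for an edgeless network).
#' @export
detect_metaclones <- function(network) {
  stopifnot(inherits(network, "similarity_network"))
  g <- network$graph
  n <- igraph::vcount(g)
  if (n == 0L)
    return(list(membership = data.frame(clone = character(0),
                                        metaclone_id = character(0)),
                communities = list(), modularity = NA_real_))
  if (igraph::ecount(g) == 0L) {
    memb <- seq_len(n)
    mod <- NA_real_
  } else {
    # communities never span connected components (cross-component merges
    # always lower modularity), so each component is partitioned on its
    # own: exactly for small components, greedy + refinement otherwise
    comp <- igraph::components(g)
    m_global <- igraph::ecount(g)
    memb <- integer(n)
    next_id <- 0L
    for (ci in seq_len(comp$no)) {
      vs <- which(comp$membership == ci)
      sub <- igraph::induced_subgraph(g, vs)
      k <- length(vs)
      sub_memb <- if (k == 1L) 1L
      else if (k <= 8L) exact_modularity_partition(sub, m_global)
      else {
        cl <- igraph::cluster_fast_greedy(igraph::simplify(sub))
        refine_modularity(sub, as.integer(igraph::membership(cl)),
                          m_global)
      }
      memb[vs] <- next_id + as.integer(sub_memb)
      next_id <- next_id + max(sub_memb)
    }
    mod <- igraph::modularity(g, memb)
  }
  clones <- igraph::V(g)$name
  comm <- split(clones, memb)
  ord <- order(-lengths(comm),
               vapply(comm, function(v) min(v), character(1L)))
  comm <- comm[ord]
  names(comm) <- sprintf("mc%05d", seq_along(comm))
  membership <- data.frame(
    clone = unlist(comm, use.names = FALSE),
    metaclone_id = rep.int(names(comm), lengths(comm)),
    stringsAsFactors = FALSE)
  list(membership = membership, communities = comm, modularity = mod)
}

#' Aggregate clone counts into meta-clone counts
#'
#' The expression of each meta-clone is the per-sample sum of the counts of
#' its member clones; total counts are conserved exactly. The aggregated
#' matrix then goes through the standard CPM/log transform and low-detection
#' filtering like any clone matrix.
#'
#' @param metaclones Result of [detect_metaclones()].
#' @param matrix Clone-level count `feature_matrix`.
#' @return Meta-clone level `feature_matrix`.
#' @export
aggregate_metaclone_counts <- function(metaclones, matrix) {
  stopifnot(inherits(matrix, "feature_matrix"))
  memb <- metaclones$membership
  missing <- setdiff(memb$clone, rownames(matrix$counts))
  if (length(missing) > 0L)
    stop("member clone(s) missing from the matrix: ",
         paste(head(missing, 3L), collapse = ", "))
  agg <- rowsum(matrix$counts[memb$clone, , drop = FALSE],
                group = memb$metaclone_id)
  agg <- agg[sort(rownames(agg)), , drop = FALSE]
  feature_matrix(agg, matrix$library_sizes, "metaclone", matrix$chain,
                 matrix$scale)
}

#' Break a CDR3 sequence into overlapping k-mers
#'
#' All `L - k + 1` windows of length `k` (default 4) in order; sequences
#' shorter than `k` yield an empty vector.
#'
#' @param cdr3 A single CDR3 amino-acid sequence.
#' @param k Window length, default 4.
#' @return Character vector of k-mers.
#' @examples
#' extract_kmers("CASSL")  # "CASS" "ASSL"
#' @export
extract_kmers <- function(cdr3, k = 4) {
  if (k < 1) stop("k must be >= 1")
  L <- nchar(cdr3)
  if (L < k) return(character(0))
  substring(cdr3, seq_len(L - k + 1L), seq_len(L - k + 1L) + k - 1L)
}

#' k-mer count matrix
#'
#' Builds a k-mers x samples count matrix for one chain. In the default
#' `"multiplicity"` mode each window of each clone contributes the clone's
#' UMI count (a clone "AAAAA" with count 2 adds 4 to k-mer "AAAA");
#' `"presence"` mode counts each clone once per distinct k-mer it contains,
#' weighted by the clone's UMI count.
#'
#' @param records Clonotype record table.
#' @param chain Chain to analyze (may be omitted for single-chain records).
#' @param k k-mer length, default 4.
#' @param mode `"multiplicity"` or `"presence"`.
#' @param samples Optional fixed sample set (columns).
#' @return A `feature_matrix` with `feature_level = "kmer"`; library sizes
#'   are per-sample total k-mer counts.
#' @export
kmer_matrix <- function(records, chain = NULL, k = 4,
                        mode = c("multiplicity", "presence"),
                        samples = NULL) {
  mode <- match.arg(mode)
  chains_present <- unique(records$chain)
  if (is.null(chain)) {
    if (length(chains_present) > 1L)
      stop("records contain multiple chains; supply `chain`")
    chain <- chains_present
  }
  rec <- records[records$chain == chain, , drop = FALSE]
  if (nrow(rec) == 0L) stop("no records for chain ", chain)
  # collapse to (sample, clone) with summed UMIs, then expand k-mers per
  # unique CDR3 once
  agg <- tapply(rec$umi_count, list(rec$sample_id, rec$cdr3_aa), sum)
  obs <- which(!is.na(agg), arr.ind = TRUE)
  sample_of <- rownames(agg)[obs[, 1L]]
  cdr3_of <- colnames(agg)[obs[, 2L]]
  umi_of <- agg[obs]
  uniq <- unique(cdr3_of)
  km_list <- lapply(uniq, function(s) {
    km <- extract_kmers(s, k)
    if (mode == "presence") km <- unique(km)
    km
  })
  names(km_list) <- uniq
  km_per <- km_list[cdr3_of]
  nk <- lengths(km_per)
  kmers <- unlist(km_per, use.names = FALSE)
  samp <- rep.int(sample_of, nk)
  w <- rep.int(umi_of, nk)
  sample_ids <- samples %||% sort(unique(rec$sample_id))
  if (length(kmers) == 0L)
    stop("no CDR3 sequence of length >= k for chain ", chain)
  feature_ids <- sort(unique(kmers))
  m <- Matrix::sparseMatrix(i = match(kmers, feature_ids),
                            j = match(samp, sample_ids),
                            x = w,
                            dims = c(length(feature_ids), length(sample_ids)),
                            dimnames = list(feature_ids, sample_ids))
  counts <- as.matrix(m)
  feature_matrix(counts, colSums(counts), "kmer", chain)
}

#' k-mer dissimilarity matrix with display ordering
#'
#' Pairwise Levenshtein distances between k-mers, with an average-linkage
#' hierarchical clustering order for heatmap display.
#'
#' @param kmers Character vector of at least 2 k-mers.
#' @return List with `d` (symmetric integer matrix), `order` (display
#'   permutation), `hclust`.
#' @export
kmer_dissimilarity_matrix <- function(kmers) {
  kmers <- as.character(kmers)
  if (length(kmers) < 2L) stop("need at least 2 k-mers")
  d <- levenshtein_matrix(kmers)
  hc <- hclust(as.dist(d), method = "average")
  list(d = d, order = hc$order, hclust = hc)
}
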