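# Reading, validation and matrix construction for chain-resolved clonotype
# tables. A "record" table holds one row per (sample, chain, CDR3, V, J,
# isotype) clonotype observation with a UMI count; all downstream feature
# levels (clones, segments, k-mers, meta-clones) derive from it.

RECORD_COLUMNS <- c("sample_id", "chain", "cdr3_aa", "v_call", "j_call",
                    "umi_count", "isotype", "v_mutation_count")

# Default mapping from AIRR Community Rearrangement column names to the
# internal record fields. Overridable for MiXCR-style exports.
AIRR_SCHEMA <- c(sample_id = "repertoire_id",
                 chain = "locus",
                 cdr3_aa = "junction_aa",
                 v_call = "v_call",
                 j_call = "j_call",
                 umi_count = "duplicate_count",
                 isotype = "c_call",
                 v_mutation_count = "v_mutation_count")

# constant-region gene -> isotype class
C_CALL_MAP <- c(IGHM = "IgM", IGHD = "IgD", IGHG = "IgG", IGHG1 = "IgG",
                IGHG2 = "IgG", IGHG3 = "IgG", IGHG4 = "IgG", IGHA = "IgA",
                IGHA1 = "IgA", IGHA2 = "IgA", IGHE = "IgE",
                IgM = "IgM", IgD = "IgD", IgG = "IgG", IgA = "IgA",
                IgE = "IgE")

normalize_isotype <- function(x) {
  x <- as.character(x)
  x[!nzchar(x) | is.na(x)] <- NA_character_
  mapped <- unname(C_CALL_MAP[x])
  bad <- !is.na(x) & is.na(mapped)
  mapped[is.na(x)] <- NA_character_
  list(isotype = mapped, bad = bad)
}

#' Validate a clonotype record table
#'
#' Checks the invariants every record table must satisfy: known chain
#' tokens, CDR3 sequences over the 20-letter amino-acid alphabet, UMI
#' counts of at least one molecule, and isotype present only on IGH rows.
#'
#' @param records Data frame with columns `sample_id`, `chain`, `cdr3_aa`,
#'   `v_call`, `j_call`, `umi_count`, `isotype`, `v_mutation_count`.
#' @return The validated records, invisibly.
#' @export
validate_records <- function(records) {
  missing <- setdiff(RECORD_COLUMNS, names(records))
  if (length(missing) > 0L)
    stop("record table is missing column(s): ", paste(missing, collapse = ", "))
  bad_chain <- which(!records$chain %in% AIRR_CHAINS)
  if (length(bad_chain) > 0L)
    stop("invalid chain token '", records$chain[bad_chain[1L]],
         "' in row ", bad_chain[1L])
  bad_iso <- which(!is.na(records$isotype) &
                     !records$isotype %in% IGH_ISOTYPES)
  if (length(bad_iso) > 0L)
    stop("invalid isotype token '", records$isotype[bad_iso[1L]],
         "' in row ", bad_iso[1L])
  iso_on_tcr <- which(!is.na(records$isotype) & records$chain != "IGH")
  if (length(iso_on_tcr) > 0L)
    stop("isotype must be NA for chain ", records$chain[iso_on_tcr[1L]],
         " (row ", iso_on_tcr[1L], ")")
  bad_cdr3 <- which(is.na(records$cdr3_aa) | !nzchar(records$cdr3_aa) |
                      grepl(paste0("[^", paste(AA_ALPHABET, collapse = ""), "]"),
                            records$cdr3_aa))
  if (length(bad_cdr3) > 0L)
    stop("invalid CDR3 amino-acid sequence in row ", bad_cdr3[1L])
  bad_umi <- which(is.na(records$umi_count) | records$umi_count < 1)
  if (length(bad_umi) > 0L)
    stop("umi_count must be >= 1 (row ", bad_umi[1L], ")")
  bad_mut <- which(!is.na(records$v_mutation_count) &
                     records$v_mutation_count < 0)
  if (length(bad_mut) > 0L)
    stop("v_mutation_count must be non-negative (row ", bad_mut[1L], ")")
  invisible(records)
}

# Sum duplicate (sample, chain, cdr3, v, j, isotype) rows; first non-NA
# mutation count wins within a key.
collapse_duplicate_records <- function(records) {
  key <- paste(records$sample_id, records$chain, records$cdr3_aa,
               records$v_call, records$j_call,
               ifelse(is.na(records$isotype), "<NA>", records$isotype),
               sep = "\r")
  if (!anyDuplicated(key)) return(records)
  idx <- split(seq_len(nrow(records)), factor(key, levels = unique(key)))
  first <- vapply(idx, `[`, integer(1L), 1L)
  out <- records[first, , drop = FALSE]
  out$umi_count <- vapply(idx, function(i) sum(records$umi_count[i]),
                          numeric(1L))
  out$v_mutation_count <- vapply(idx, function(i) {
    m <- records$v_mutation_count[i]
    m <- m[!is.na(m)]
    if (length(m) == 0L) NA_real_ else m[1L]
  }, numeric(1L))
  rownames(out) <- NULL
  out
}

#' Read an AIRR rearrangement TSV into a clonotype record table
#'
#' Reads a tab-separated rearrangement table following the AIRR Community
#' column naming (`repertoire_id`, `locus`, `junction_aa`, `v_call`,
#' `j_call`, `duplicate_count`, `c_call`), validates each row, collapses
#' duplicate clonotype rows by summing their UMI counts, and computes
#' per-sample sequencing depth as the sum of UMI counts.
#'
#' @param path Path to the TSV file.
#' @param schema_map Optional named character vector overriding the default
#'   column mapping; names are internal field names (`sample_id`, `chain`,
#'   `cdr3_aa`, `v_call`, `j_call`, `umi_count`, `isotype`,
#'   `v_mutation_count`), values the column names present in the file.
#' @return A list with `records` (validated clonotype table) and `samples`
#'   (data frame with `sample_id` and `total_umis`).
#' @examples
#' tsv <- tempfile(fileext = ".tsv")
#' writeLines(c("repertoire_id\tlocus\tjunction_aa\tv_call\tj_call\tduplicate_count\tc_call",
#'              "S1\tTRB\tCASSLGF\tTRBV5-1\tTRBJ2-7\t3\t",
#'              "S1\tTRB\tCASSLGF\tTRBV5-1\tTRBJ2-7\t2\t"), tsv)
#' read_airr_tsv(tsv)$records$umi_count  # 5
#' @export
read_airr_tsv <- function(path, schema_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(tab) == 0L) stop("empty input: ", path, " contains no records")
  schema <- AIRR_SCHEMA
  if (!is.null(schema_map)) schema[names(schema_map)] <- schema_map
  mandatory <- c("sample_id", "chain", "cdr3_aa", "v_call", "j_call",
                 "umi_count")
  for (field in mandatory) {
    if (!schema[[field]] %in% names(tab))
      stop("missing mandatory column '", schema[[field]], "' (", field, ")")
  }
  get_col <- function(field, default = NA) {
    if (schema[[field]] %in% names(tab)) tab[[schema[[field]]]] else default
  }
  iso <- normalize_isotype(get_col("isotype", NA_character_))
  if (any(iso$bad)) {
    i <- which(iso$bad)[1L]
    stop("invalid isotype token '", get_col("isotype")[i],
         "' in line ", i + 1L)  # +1 for the header line
  }
  records <- data.frame(
    sample_id = as.character(get_col("sample_id")),
    chain = as.character(get_col("chain")),
    cdr3_aa = toupper(as.character(get_col("cdr3_aa"))),
    v_call = as.character(get_col("v_call")),
    j_call = as.character(get_col("j_call")),
    umi_count = as.numeric(get_col("umi_count")),
    isotype = iso$isotype,
    v_mutation_count = as.numeric(get_col("v_mutation_count", NA_real_)),
    stringsAsFactors = FALSE)
  bad_chain <- which(!records$chain %in% AIRR_CHAINS)
  if (length(bad_chain) > 0L)
    stop("invalid chain token '", records$chain[bad_chain[1L]],
         "' in line ", bad_chain[1L] + 1L)
  iso_on_tcr <- which(!is.na(records$isotype) & records$chain != "IGH")
  if (length(iso_on_tcr) > 0L)
    stop("isotype given for non-IGH chain in line ", iso_on_tcr[1L] + 1L)
  records <- collapse_duplicate_records(records)
  validate_records(records)
  depth <- tapply(records$umi_count, records$sample_id, sum)
  samples <- data.frame(sample_id = names(depth),
                        total_umis = as.numeric(depth),
                        stringsAsFactors = FALSE)
  rownames(samples) <- NULL
  list(records = records, samples = samples)
}

#' Write a clonotype record table as an AIRR rearrangement TSV
#'
#' Inverse of [read_airr_tsv()]: emits AIRR Community column names so that
#' reading the file back reproduces the record multiset.
#'
#' @param records Validated clonotype record table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_airr_tsv <- function(records, path) {
  validate_records(records)
  out <- data.frame(repertoire_id = records$sample_id,
                    locus = records$chain,
                    junction_aa = records$cdr3_aa,
                    v_call = records$v_call,
                    j_call = records$j_call,
                    duplicate_count = records$umi_count,
                    c_call = ifelse(is.na(records$isotype), "",
                                    records$isotype),
                    v_mutation_count = records$v_mutation_count,
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' Read a sample metadata table
#'
#' Reads a TSV/CSV of per-sample phenotype and covariates and, when a record
#' table is supplied, attaches per-sample depth (`total_umis`) computed from
#' the records.
#'
#' @param path Path to a TSV (default) or CSV metadata table with at least a
#'   `sample_id` column.
#' @param records Optional record table used to compute `total_umis`.
#' @param sep Field separator; `"\t"` or `","`.
#' @return Data frame of metadata.
#' @export
read_sample_metadata <- function(path, records = NULL, sep = "\t") {
  meta <- read.delim(path, sep = sep, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(meta))
    stop("metadata is missing mandatory column 'sample_id'")
  if (!is.null(records)) {
    depth <- tapply(records$umi_count, records$sample_id, sum)
    meta$total_umis <- as.numeric(depth[meta$sample_id])
  }
  if ("total_umis" %in% names(meta) &&
      any(!is.na(meta$total_umis) & meta$total_umis <= 0))
    stop("total_umis must be > 0 for every sample")
  meta
}

#' Construct a feature-by-sample count matrix
#'
#' A `feature_matrix` is the package's central container: a features x
#' samples matrix of summed UMI counts together with per-sample library
#' sizes (total chain UMIs) used for normalization. Chains are always
#' analyzed separately, so a matrix is built for one chain at a time.
#'
#' @param records Clonotype record table.
#' @param feature_level One of `"clone"` (features keyed by CDR3 amino-acid
#'   sequence), `"segmentV"`, `"segmentJ"` or `"segmentVJ"` (keyed by
#'   `v_call`, `j_call` or `"v_call:j_call"`).
#' @param chain Chain to build the matrix for. May be omitted when the
#'   records contain a single chain.
#' @param samples Optional character vector of sample ids fixing the column
#'   set and order (samples absent from the records get all-zero columns
#'   and zero library size).
#' @return An object of class `feature_matrix`: a list with `counts`
#'   (numeric matrix), `library_sizes`, `feature_level`, `chain` and
#'   `scale` (`"count"` here; `"logcpm"` after [cpm_log_transform()]).
#' @export
build_feature_matrix <- function(records,
                                 feature_level = c("clone", "segmentV",
                                                   "segmentJ", "segmentVJ"),
                                 chain = NULL, samples = NULL) {
  feature_level <- match.arg(feature_level)
  if (nrow(records) == 0L) stop("records must be non-empty")
  chains_present <- unique(records$chain)
  if (is.null(chain)) {
    if (length(chains_present) > 1L)
      stop("records contain multiple chains (",
           paste(chains_present, collapse = ", "),
           "); supply `chain` explicitly")
    chain <- chains_present
  }
  rec <- records[records$chain == chain, , drop = FALSE]
  if (nrow(rec) == 0L) stop("no records for chain ", chain)
  feats <- switch(feature_level,
                  clone = rec$cdr3_aa,
                  segmentV = rec$v_call,
                  segmentJ = rec$j_call,
                  segmentVJ = paste(rec$v_call, rec$j_call, sep = ":"))
  sample_ids <- samples %||% sort(unique(rec$sample_id))
  if (!all(rec$sample_id %in% sample_ids))
    stop("records contain samples not in `samples`")
  feature_ids <- sort(unique(feats))
  m <- Matrix::sparseMatrix(
    i = match(feats, feature_ids),
    j = match(rec$sample_id, sample_ids),
    x = rec$umi_count,
    dims = c(length(feature_ids), length(sample_ids)),
    dimnames = list(feature_ids, sample_ids))
  counts <- as.matrix(m)
  libs <- setNames(numeric(length(sample_ids)), sample_ids)
  depth <- tapply(rec$umi_count, rec$sample_id, sum)
  libs[names(depth)] <- as.numeric(depth)
  feature_matrix(counts, libs, feature_level, chain)
}

#' @rdname build_feature_matrix
#' @param counts Numeric features x samples matrix with dimnames.
#' @param library_sizes Named per-sample totals.
#' @param scale `"count"` or `"logcpm"`.
#' @export
feature_matrix <- function(counts, library_sizes, feature_level, chain,
                           scale = "count") {
  if ((nrow(counts) > 0 && is.null(rownames(counts))) ||
      (ncol(counts) > 0 && is.null(colnames(counts))))
    stop("counts must carry feature and sample dimnames")
  if (is.null(rownames(counts)))
    dimnames(counts) <- list(character(0), colnames(counts))
  if (anyDuplicated(rownames(counts)))
    stop("duplicate feature_ids in counts")
  if (length(library_sizes) != ncol(counts))
    stop("library_sizes length must equal the number of samples")
  if (is.null(names(library_sizes)))
    names(library_sizes) <- colnames(counts)
  library_sizes <- library_sizes[colnames(counts)]
  if (scale == "count" && any(counts < 0))
    stop("counts must be non-negative")
  structure(list(counts = counts,
                 library_sizes = library_sizes,
                 feature_level = feature_level,
                 chain = chain,
                 scale = scale),
            class = "feature_matrix")
}

#' @export
#' @method print feature_matrix
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix: %d %s features x %d samples [%s, %s scale]\n",
              nrow(x$counts), x$feature_level, ncol(x$counts),
              x$chain %||% "all chains", x$scale))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$counts)

#' Log counts-per-million transform
#'
#' Normalizes counts for library size, scales to counts per million (CPM)
#' and moves to the log scale: `log2(1e6 * count / library_size + 1)`.
#' Zero counts map exactly to zero, preserving the detection pattern that
#' the hurdle model's discrete part relies on.
#'
#' @param matrix A count-scale `feature_matrix`.
#' @return A `feature_matrix` on the `"logcpm"` scale.
#' @export
cpm_log_transform <- function(matrix) {
  stopifnot(inherits(matrix, "feature_matrix"))
  if (matrix$scale != "count")
    stop("cpm_log_transform expects a count-scale matrix")
  zero <- matrix$library_sizes <= 0
  if (any(zero))
    stop("zero library size for sample(s): ",
         paste(names(matrix$library_sizes)[zero], collapse = ", "))
  vals <- log2(sweep(matrix$counts, 2L, matrix$library_sizes, `/`) * 1e6 + 1)
  feature_matrix(vals, matrix$library_sizes, matrix$feature_level,
                 matrix$chain, scale = "logcpm")
}

#' Remove features detected in too few samples
#'
#' Drops features whose detection proportion (fraction of samples with a
#' nonzero value) falls strictly below `min_sample_fraction`. Features at
#' exactly the threshold are retained, i.e. "detected in < 1% of samples"
#' are excluded.
#'
#' @param matrix A `feature_matrix` (count or logcpm scale).
#' @param min_sample_fraction Minimum detection proportion, default 0.01.
#' @return The filtered `feature_matrix`, with attribute `n_removed`.
#' @export
filter_low_detection <- function(matrix, min_sample_fraction = 0.01) {
  stopifnot(inherits(matrix, "feature_matrix"))
  if (min_sample_fraction <= 0 || min_sample_fraction > 1)
    stop("min_sample_fraction must be in (0, 1]")
  det <- rowMeans(matrix$counts > 0)
  keep <- det >= min_sample_fraction
  out <- feature_matrix(matrix$counts[keep, , drop = FALSE],
                        matrix$library_sizes, matrix$feature_level,
                        matrix$chain, matrix$scale)
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Clone Detection Rate (CDR)
#'
#' The CDR is the standardized per-sample fraction of matrix features that
#' are detected (nonzero). It acts as a proxy for technical and global
#' biological factors influencing clone abundances and enters the hurdle
#' model as a covariate. Standardization uses the sample (n-1) standard
#' deviation; when the raw rates are constant the standardized values are
#' all zero.
#'
#' @param matrix A `feature_matrix` with at least two samples.
#' @return Data frame with `sample_id`, `raw` (detection proportion in
#'   `[0, 1]`) and `cdr` (standardized value).
#' @export
compute_detection_rate <- function(matrix) {
  stopifnot(inherits(matrix, "feature_matrix"))
  if (ncol(matrix$counts) < 2L)
    stop("detection rate standardization needs at least 2 samples")
  raw <- colMeans(matrix$counts > 0)
  s <- sd(raw)
  std <- if (is.na(s) || s == 0) rep(0, length(raw)) else (raw - mean(raw)) / s
  data.frame(sample_id = colnames(matrix$counts), raw = as.numeric(raw),
             cdr = as.numeric(std), stringsAsFactors = FALSE)
}

#' Export a feature matrix
#'
#' Writes the counts as a TSV (features x samples, feature ids in the first
#' column) or as MatrixMarket triplets plus sidecar feature/sample name
#' files.
#'
#' @param matrix A `feature_matrix`.
#' @param path Output path (for `"mtx"`, the `.mtx` path; `<path>.features`
#'   and `<path>.samples` are written next to it).
#' @param format `"tsv"` or `"mtx"`.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(matrix, path, format = c("tsv", "mtx")) {
  stopifnot(inherits(matrix, "feature_matrix"))
  format <- match.arg(format)
  if (format == "tsv") {
    out <- data.frame(feature_id = rownames(matrix$counts),
                      matrix$counts, check.names = FALSE,
                      stringsAsFactors = FALSE)
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    Matrix::writeMM(Matrix::Matrix(matrix$counts, sparse = TRUE), path)
    writeLines(rownames(matrix$counts), paste0(path, ".features"))
    writeLines(colnames(matrix$counts), paste0(path, ".samples"))
  }
  invisible(path)
}
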