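#' Read a labeled numeric matrix from delimited text
#'
#' Reads the labeled-matrix dialect used by the public DTI benchmarks: first
#' row holds column identifiers (an optional corner label is ignored), first
#' column holds row identifiers, remaining cells are numeric. Both tabs and
#' runs of spaces are accepted as delimiters; files are always written back
#' with tabs.
#'
#' @param path Path to a delimited text file.
#' @param expect_square If `TRUE`, assert that row and column identifiers
#'   coincide and that the matrix is symmetric within `1e-8` (similarity
#'   matrices).
#' @return A list with `row_ids`, `col_ids` and the numeric `matrix`
#'   (dimnames set from the identifiers).
#' @export
read_labeled_matrix <- function(path, expect_square = FALSE) {
  lines <- readLines(path, warn = FALSE)
  while (length(lines) && !nzchar(trimws(lines[length(lines)]))) {
    lines <- lines[-length(lines)]
  }
  if (length(lines) < 2L) {
    stop("parse error in '", path, "': need a header line and at least one data row")
  }
  split_fields <- function(x) {
    f <- strsplit(sub("[ \t]+$", "", x), "[ \t]+")[[1]]
    f[nzchar(f)]
  }
  header <- split_fields(lines[1L])
  body <- lapply(lines[-1L], split_fields)
  widths <- lengths(body)
  if (length(unique(widths)) != 1L) {
    bad <- which(widths != widths[1L])[1L] + 1L
    stop("parse error in '", path, "': ragged row at line ", bad)
  }
  ncol_data <- widths[1L] - 1L
  if (ncol_data < 1L) stop("parse error in '", path, "': rows carry no data cells")
  if (length(header) == ncol_data + 1L) header <- header[-1L]
  if (length(header) != ncol_data) {
    stop("parse error in '", path, "': header names ", length(header),
         " columns but data rows have ", ncol_data)
  }
  row_ids <- vapply(body, `[[`, character(1), 1L)
  vals <- suppressWarnings(
    vapply(body, function(f) as.numeric(f[-1L]), numeric(ncol_data))
  )
  mat <- if (ncol_data == 1L) matrix(vals, ncol = 1L) else t(vals)
  if (anyNA(mat)) {
    bad <- which(is.na(mat), arr.ind = TRUE)[1L, ]
    stop("parse error in '", path, "': non-numeric cell at row '",
         row_ids[bad[1L]], "', column '", header[bad[2L]], "'")
  }
  if (anyDuplicated(row_ids)) {
    stop("duplicate row identifiers in '", path, "': ",
         paste(unique(row_ids[duplicated(row_ids)]), collapse = ", "))
  }
  if (anyDuplicated(header)) {
    stop("duplicate column identifiers in '", path, "': ",
         paste(unique(header[duplicated(header)]), collapse = ", "))
  }
  dimnames(mat) <- list(row_ids, header)
  if (expect_square) {
    if (!identical(row_ids, header)) {
      stop("expected a square labeled matrix but row and column identifiers differ")
    }
    if (max(abs(mat - t(mat))) > 1e-8) {
      stop("expected a symmetric matrix but asymmetry exceeds 1e-8")
    }
  }
  list(row_ids = row_ids, col_ids = header, matrix = mat)
}

#' Write a labeled numeric matrix as tab-delimited text
#'
#' @param mat Numeric matrix with dimnames (or supply `row_ids`/`col_ids`).
#' @param path Output path.
#' @param row_ids,col_ids Identifier vectors; default to `dimnames(mat)`.
#' @export
write_labeled_matrix <- function(mat, path, row_ids = rownames(mat),
                                 col_ids = colnames(mat)) {
  stopifnot(is.matrix(mat), length(row_ids) == nrow(mat),
            length(col_ids) == ncol(mat))
  fmt <- function(x) sprintf("%.15g", x)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("", col_ids), collapse = "\t"), con)
  for (i in seq_len(nrow(mat))) {
    writeLines(paste(c(row_ids[i], fmt(mat[i, ])), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read protein sequences from a FASTA file
#'
#' Header token up to the first whitespace is the identifier; sequences are
#' uppercased and input order preserved.
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  first <- readLines(path, n = 1L)
  if (!length(first) || !startsWith(first, ">")) {
    stop("'", path, "' does not start with a FASTA header line")
  }
  seqs <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(seqs), "[ \t]"), `[[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate sequence identifiers: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  out <- toupper(as.character(seqs))
  names(out) <- ids
  empty <- ids[nchar(out) == 0L]
  if (length(empty)) stop("empty sequence for ", paste(empty, collapse = ", "))
  out
}

#' Construct a feature matrix
#'
#' Entities x features real matrix with identifier bookkeeping; flagged
#' binary when every value is 0 or 1 (fingerprints).
#'
#' @param values Numeric matrix, rows = entities.
#' @param entity_ids,feature_names Identifier vectors (default: dimnames).
#' @return An object of class `feature_matrix`: list with `entity_ids`,
#'   `feature_names`, `values`, `binary`.
#' @export
feature_matrix <- function(values, entity_ids = rownames(values),
                           feature_names = colnames(values)) {
  stopifnot(is.matrix(values))
  if (is.null(entity_ids)) entity_ids <- paste0("e", seq_len(nrow(values)))
  if (is.null(feature_names)) feature_names <- paste0("f", seq_len(ncol(values)))
  if (anyDuplicated(entity_ids)) stop("duplicate entity identifiers")
  if (anyDuplicated(feature_names)) stop("duplicate feature names")
  if (length(entity_ids) != nrow(values) || length(feature_names) != ncol(values)) {
    stop("identifier lists inconsistent with matrix dimensions")
  }
  if (anyNA(values)) stop("feature matrix contains NA values")
  all_nan_col <- apply(values, 2, function(x) all(is.nan(x)))
  if (any(all_nan_col)) stop("all-NaN feature column(s): ",
                             paste(feature_names[all_nan_col], collapse = ", "))
  dimnames(values) <- list(entity_ids, feature_names)
  structure(
    list(entity_ids = entity_ids, feature_names = feature_names,
         values = values, binary = all(values %in% c(0, 1))),
    class = "feature_matrix"
  )
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix: %d entities x %d features (%s)\n",
              nrow(x$values), ncol(x$values),
              if (x$binary) "binary" else "real-valued"))
  invisible(x)
}

#' Read an entities x features table
#'
#' Labeled TSV: rows are entities, columns are feature names.
#'
#' @param path Input path.
#' @return A [feature_matrix()].
#' @export
read_feature_table <- function(path) {
  parsed <- read_labeled_matrix(path)
  feature_matrix(parsed$matrix)
}

#' Write a feature matrix as labeled TSV
#' @param fm A [feature_matrix()].
#' @param path Output path.
#' @export
write_feature_table <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  write_labeled_matrix(fm$values, path)
}

#' Construct and validate a DTI dataset
#'
#' Bundles the binary m x n adjacency matrix `A` (rows = drugs, columns =
#' targets; 1 = known interaction, 0 = unlabeled pair) with optional pairwise
#' similarity matrices and explicit feature matrices. Unobserved status is
#' never encoded in `A`; it lives in a separate observation mask.
#'
#' @param drug_ids,target_ids Unique identifier vectors.
#' @param A Binary matrix, `length(drug_ids)` x `length(target_ids)`.
#' @param S_d,S_t Optional symmetric similarity matrices with unit diagonal.
#' @param F_d,F_t Optional [feature_matrix()] objects (drug, target features).
#' @return An object of class `dti_dataset`.
#' @export
dti_dataset <- function(drug_ids, target_ids, A, S_d = NULL, S_t = NULL,
                        F_d = NULL, F_t = NULL) {
  drug_ids <- as.character(drug_ids)
  target_ids <- as.character(target_ids)
  if (anyDuplicated(drug_ids)) stop("duplicate drug identifiers")
  if (anyDuplicated(target_ids)) stop("duplicate target identifiers")
  stopifnot(is.matrix(A))
  if (nrow(A) != length(drug_ids) || ncol(A) != length(target_ids)) {
    stop("adjacency matrix dimensions inconsistent with identifier lists")
  }
  if (!all(A %in% c(0, 1))) stop("adjacency matrix must be binary (0/1)")
  check_sim <- function(S, k, what) {
    if (is.null(S)) return(NULL)
    stopifnot(is.matrix(S))
    if (nrow(S) != k || ncol(S) != k) stop(what, " similarity has wrong dimensions")
    if (max(abs(S - t(S))) > 1e-8) stop(what, " similarity is not symmetric within 1e-8")
    if (max(abs(diag(S) - 1)) > 1e-6) stop(what, " similarity diagonal is not 1 within 1e-6")
    S
  }
  check_feat <- function(F, k, what) {
    if (is.null(F)) return(NULL)
    stopifnot(inherits(F, "feature_matrix"))
    if (nrow(F$values) != k) stop(what, " feature matrix has wrong number of rows")
    F
  }
  m <- length(drug_ids); n <- length(target_ids)
  dimnames(A) <- list(drug_ids, target_ids)
  structure(
    list(drug_ids = drug_ids, target_ids = target_ids, A = A,
         S_d = check_sim(S_d, m, "drug"), S_t = check_sim(S_t, n, "target"),
         F_d = check_feat(F_d, m, "drug"), F_t = check_feat(F_t, n, "target")),
    class = "dti_dataset"
  )
}

#' @export
print.dti_dataset <- function(x, ...) {
  cat(sprintf("dti_dataset: %d drugs x %d targets, %d known interactions\n",
              length(x$drug_ids), length(x$target_ids), sum(x$A)))
  cat(sprintf("  similarities: drug=%s target=%s; features: drug=%s target=%s\n",
              !is.null(x$S_d), !is.null(x$S_t), !is.null(x$F_d), !is.null(x$F_t)))
  invisible(x)
}

#' Write ranked interaction predictions as TSV
#'
#' @param records Data frame with columns `rank`, `drug_id`, `target_id`,
#'   `score`, sorted by rank ascending.
#' @param path Output path.
#' @export
write_ranked_predictions <- function(records, path) {
  records <- as.data.frame(records)
  need <- c("rank", "drug_id", "target_id", "score")
  if (!all(need %in% names(records))) {
    stop("records must have columns: ", paste(need, collapse = ", "))
  }
  if (nrow(records) && is.unsorted(records$rank, strictly = TRUE)) {
    stop("records must be sorted by rank ascending")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("rank\tdrug_id\ttarget_id\tscore", con)
  if (nrow(records)) {
    writeLines(sprintf("%d\t%s\t%s\t%s", as.integer(records$rank),
                       records$drug_id, records$target_id,
                       sprintf("%.15g", records$score)), con)
  }
  invisible(path)
}

#' Read ranked predictions written by [write_ranked_predictions()]
#' @param path Input path.
#' @return Data frame with `rank`, `drug_id`, `target_id`, `score`.
#' @export
read_ranked_predictions <- function(path) {
  df <- utils::read.delim(path, colClasses = c("integer", "character",
                                               "character", "numeric"))
  names(df) <- c("rank", "drug_id", "target_id", "score")
  df
}

#' Write / read a cross-validation metric report
#'
#' Flat key/value text: scenario, fold counts, repetition count, seed, the
#' per-repetition AUPR/AUC lists and their mean/std. Round-trips exactly
#' through [read_metric_report()].
#'
#' @param report A `metric_report` from [run_cv()].
#' @param path Output path.
#' @export
write_metric_report <- function(report, path) {
  stopifnot(inherits(report, "metric_report"))
  fmt <- function(x) paste(sprintf("%.15g", x), collapse = ",")
  kv <- c(
    scenario = report$scenario,
    K = fmt(report$K),
    N = fmt(report$N),
    seed = fmt(report$seed),
    aupr_mean = fmt(report$aupr_mean), aupr_std = fmt(report$aupr_std),
    auc_mean = fmt(report$auc_mean), auc_std = fmt(report$auc_std),
    aupr_per_rep = fmt(report$aupr_per_rep),
    auc_per_rep = fmt(report$auc_per_rep)
  )
  writeLines(paste(names(kv), kv, sep = "\t"), path)
  invisible(path)
}

#' @rdname write_metric_report
#' @export
read_metric_report <- function(path) {
  lines <- readLines(path, warn = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  kv <- stats::setNames(vapply(parts, `[`, character(1), 2L),
                        vapply(parts, `[`, character(1), 1L))
  num <- function(key) as.numeric(strsplit(kv[[key]], ",", fixed = TRUE)[[1]])
  structure(
    list(scenario = kv[["scenario"]], K = num("K"), N = num("N"),
         seed = num("seed"),
         aupr_per_rep = num("aupr_per_rep"), auc_per_rep = num("auc_per_rep"),
         aupr_mean = num("aupr_mean"), aupr_std = num("aupr_std"),
         auc_mean = num("auc_mean"), auc_std = num("auc_std")),
    class = "metric_report"
  )
}
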