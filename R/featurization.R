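#' Extract latent features from a similarity matrix
#'
#' Turns a pairwise similarity matrix S into an explicit feature matrix F
#' with `F %*% t(F)` equal to the positive-semidefinite projection of the
#' symmetrized S: symmetrize, eigendecompose, clamp negative eigenvalues to
#' zero, keep components above `eig_tol`, and set `F = U_+ sqrt(L_+)`.
#' Columns are ordered by decreasing eigenvalue and each eigenvector is
#' scaled so that its largest-magnitude entry is positive, making the output
#' deterministic across platforms.
#'
#' @param S Square similarity matrix, symmetric within `1e-8`.
#' @param eig_tol Eigenvalue cutoff; components with eigenvalue `<= eig_tol`
#'   are discarded. Default `k * .Machine$double.eps * max(eigenvalue)`
#'   (the usual numerical-rank rule).
#' @return A [feature_matrix()] (k x p', p' <= k) with feature names
#'   `"sv1"`, `"sv2"`, ...
#' @export
features_from_similarity <- function(S, eig_tol = NULL) {
  stopifnot(is.matrix(S))
  if (nrow(S) != ncol(S)) stop("similarity matrix must be square")
  if (max(abs(S - t(S))) > 1e-8) stop("similarity matrix is not symmetric within 1e-8")
  k <- nrow(S)
  Ssym <- (S + t(S)) / 2
  eg <- eigen(Ssym, symmetric = TRUE)
  vals <- pmax(eg$values, 0)
  if (is.null(eig_tol)) eig_tol <- k * .Machine$double.eps * max(vals, 0)
  keep <- which(vals > eig_tol)
  if (!length(keep)) stop("no eigenvalue above the cutoff; similarity matrix is numerically zero")
  U <- eg$vectors[, keep, drop = FALSE]
  pivots <- integer(ncol(U))
  for (j in seq_len(ncol(U))) {
    piv <- which.max(abs(U[, j]))
    if (U[piv, j] < 0) U[, j] <- -U[, j]
    pivots[j] <- piv
  }
  # deterministic order: decreasing eigenvalue, pivot position breaking exact ties
  ord <- order(-vals[keep], pivots)
  U <- U[, ord, drop = FALSE]
  vals_kept <- vals[keep][ord]
  F <- U %*% diag(sqrt(vals_kept), nrow = length(vals_kept))
  rn <- rownames(S)
  if (is.null(rn)) rn <- paste0("e", seq_len(k))
  dimnames(F) <- list(rn, paste0("sv", seq_along(keep)))
  feature_matrix(F)
}

#' Overlapping k-mer frequency features for protein sequences
#'
#' One column per possible k-mer over the alphabet in lexicographic order
#' (`|alphabet|^k` columns; 8000 amino-acid trimers for k = 3). Each entry is
#' the count of the k-mer among the `L - k + 1` overlapping windows divided
#' by `L - k + 1`, so each row sums to 1.
#'
#' @param sequences Named character vector of sequences (see [read_fasta()]).
#' @param k k-mer length (default 3, trimers).
#' @param alphabet Characters allowed in sequences; default the 20 standard
#'   amino acids.
#' @return A [feature_matrix()] of frequencies.
#' @export
kmer_frequency_features <- function(sequences, k = 3,
                                    alphabet = "ACDEFGHIKLMNPQRSTVWY") {
  stopifnot(length(sequences) >= 1L, k >= 1L)
  if (is.null(names(sequences)) || anyDuplicated(names(sequences))) {
    stop("sequences must carry unique names")
  }
  letters <- sort(strsplit(alphabet, "")[[1]])
  grid <- expand.grid(rep(list(letters), k), stringsAsFactors = FALSE)
  kmer_names <- do.call(paste0, grid[rev(seq_len(k))])
  valid <- paste0("^[", paste(letters, collapse = ""), "]*$")
  out <- matrix(0, nrow = length(sequences), ncol = length(kmer_names),
                dimnames = list(names(sequences), kmer_names))
  for (i in seq_along(sequences)) {
    s <- sequences[[i]]
    L <- nchar(s)
    if (L < k) stop("sequence '", names(sequences)[i], "' is shorter than k = ", k)
    if (!grepl(valid, s)) {
      pos <- regexpr(paste0("[^", paste(letters, collapse = ""), "]"), s)
      stop("sequence '", names(sequences)[i], "' has a character outside the alphabet at position ", pos)
    }
    windows <- substring(s, 1:(L - k + 1), k:L)
    counts <- table(factor(windows, levels = kmer_names))
    out[i, ] <- as.numeric(counts) / (L - k + 1)
  }
  feature_matrix(out)
}

#' Validate a supplied fingerprint feature matrix
#'
#' Asserts binarity and (optionally) the expected bit width, e.g. 881 for
#' PubChem fingerprints. Constant columns are reported with a warning but
#' kept: multicollinearity among fingerprint bits is expected and the
#' downstream regressions are regularized against it.
#'
#' @param F A binary [feature_matrix()].
#' @param expected_width Optional required column count.
#' @return `F`, unchanged.
#' @export
validate_fingerprint_features <- function(F, expected_width = NULL) {
  stopifnot(inherits(F, "feature_matrix"))
  if (!F$binary || !all(F$values %in% c(0, 1))) {
    stop("fingerprint features must be binary (0/1)")
  }
  if (!is.null(expected_width) && ncol(F$values) != expected_width) {
    stop("fingerprint width mismatch: expected ", expected_width,
         " bits, got ", ncol(F$values))
  }
  const <- which(apply(F$values, 2, function(x) length(unique(x)) == 1L))
  if (length(const)) {
    warning("constant fingerprint column(s): ",
            paste(F$feature_names[const], collapse = ", "))
  }
  F
}
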