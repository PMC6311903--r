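#' Specification for a synthetic DTI dataset
#'
#' Defines the study conditions of the planted-structure generator: entity
#' counts, feature widths, the rank of the planted bi-projection matrix, the
#' fraction of positive cells, the label-flip noise fraction, and the
#' expected fraction of set feature bits. Defaults are the package's
#' standard simulation conditions (50 drugs x 40 targets, 12 binary features
#' per side, rank 3, 10% interaction density, 2% label noise, 30% bit
#' density).
#'
#' @param m,n Drug / target counts.
#' @param p,q Drug / target feature widths.
#' @param r Planted rank (`r <= min(p, q)`).
#' @param density Target fraction of positive cells, in (0, 1).
#' @param noise Fraction of cells whose label is flipped, in [0, 1).
#' @param feature_sparsity Expected fraction of set bits, in (0, 1).
#' @param feature_mode `"binary"` (fingerprint-like, default) or
#'   `"dirichlet"` (k-mer-frequency-like rows summing to 1).
#' @param seed Integer seed; all randomness derives from it.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(m = 50, n = 40, p = 12, q = 12, r = 3,
                           density = 0.1, noise = 0.02,
                           feature_sparsity = 0.3,
                           feature_mode = c("binary", "dirichlet"),
                           seed = 1) {
  feature_mode <- match.arg(feature_mode)
  stopifnot(m >= 2, n >= 2, p >= 1, q >= 1, r >= 1, r <= min(p, q),
            density > 0, density < 1, noise >= 0, noise < 1,
            feature_sparsity > 0, feature_sparsity < 1)
  if (density * m * n < 1) stop("density too low: fewer than one positive cell")
  structure(list(m = m, n = n, p = p, q = q, r = r, density = density,
                 noise = noise, feature_sparsity = feature_sparsity,
                 feature_mode = feature_mode, seed = as.integer(seed)),
            class = "synthetic_spec")
}

draw_binary_features <- function(k, w, sparsity, prefix) {
  F <- matrix(stats::rbinom(k * w, 1, sparsity), k, w)
  for (i in which(rowSums(F) == 0)) {
    while (sum(F[i, ]) == 0) F[i, ] <- stats::rbinom(w, 1, sparsity)
  }
  dimnames(F) <- list(sprintf("%s%03d", substr(prefix, 1, 1), seq_len(k)),
                      paste0(prefix, "f", seq_len(w)))
  F
}

#' Generate a synthetic DTI dataset with planted bilinear structure
#'
#' Draws binary feature matrices, a rank-r bi-projection matrix
#' `theta_true = G_d %*% t(G_t)` with standard-normal factors, computes
#' `Z = F_d theta_true F_t'`, thresholds at the (1 - density) quantile of Z
#' so the positive count matches `round(density * m * n)`, and flips a
#' `noise` fraction of cells chosen uniformly. Tanimoto similarity matrices
#' of the binary features are attached so the SVD featurization route is
#' exercisable. Because the labels come from an exact bilinear model,
#' parameter-recovery tests against `theta_true` are sharp.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `dataset` (a [dti_dataset()]) and `truth` (list with
#'   `theta_true`, `threshold_used`, `flipped_cells`, `A_clean`).
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  if (spec$feature_mode == "binary") {
    Fd <- draw_binary_features(spec$m, spec$p, spec$feature_sparsity, "d")
    Ft <- draw_binary_features(spec$n, spec$q, spec$feature_sparsity, "t")
  } else {
    Fd <- t(replicate(spec$m, {
      g <- stats::rgamma(spec$p, shape = 1); g / sum(g)
    }))
    Ft <- t(replicate(spec$n, {
      g <- stats::rgamma(spec$q, shape = 1); g / sum(g)
    }))
    dimnames(Fd) <- list(sprintf("d%03d", seq_len(spec$m)), paste0("df", seq_len(spec$p)))
    dimnames(Ft) <- list(sprintf("t%03d", seq_len(spec$n)), paste0("tf", seq_len(spec$q)))
  }
  G_d <- matrix(stats::rnorm(spec$p * spec$r), spec$p, spec$r)
  G_t <- matrix(stats::rnorm(spec$q * spec$r), spec$q, spec$r)
  theta_true <- tcrossprod(G_d, G_t)
  dimnames(theta_true) <- list(colnames(Fd), colnames(Ft))
  Z <- Fd %*% theta_true %*% t(Ft)
  s <- round(spec$density * spec$m * spec$n)
  zs <- sort(as.vector(Z), decreasing = TRUE)
  threshold <- zs[min(s + 1L, length(zs))]
  A_clean <- matrix(as.numeric(Z > threshold), spec$m, spec$n)
  A <- A_clean
  nflip <- round(spec$noise * spec$m * spec$n)
  flipped <- NULL
  if (nflip > 0) {
    cells <- sample.int(spec$m * spec$n, nflip)
    A[cells] <- 1 - A[cells]
    flipped <- arrayInd(cells, dim(A))
    colnames(flipped) <- c("drug", "target")
  }
  ds <- dti_dataset(
    drug_ids = rownames(Fd), target_ids = rownames(Ft), A = A,
    S_d = if (spec$feature_mode == "binary") similarity_from_binary_features(Fd) else NULL,
    S_t = if (spec$feature_mode == "binary") similarity_from_binary_features(Ft) else NULL,
    F_d = feature_matrix(Fd), F_t = feature_matrix(Ft))
  list(dataset = ds,
       truth = list(theta_true = theta_true, threshold_used = threshold,
                    flipped_cells = flipped, A_clean = A_clean))
}

#' Tanimoto similarity of binary feature rows
#'
#' Entry (i, j) is `|x_i AND x_j| / |x_i OR x_j|`; symmetric with an exactly
#' unit diagonal. Rows must carry at least one set bit.
#'
#' @param F Binary matrix or binary [feature_matrix()].
#' @return A symmetric similarity matrix with unit diagonal.
#' @export
similarity_from_binary_features <- function(F) {
  F <- as_values(F)
  if (!all(F %in% c(0, 1))) stop("Tanimoto similarity requires binary features")
  zero <- which(rowSums(F) == 0)
  if (length(zero)) stop("all-zero feature row(s): ", paste(zero, collapse = ", "))
  inter <- tcrossprod(F)
  sums <- rowSums(F)
  uni <- outer(sums, sums, `+`) - inter
  S <- inter / uni
  diag(S) <- 1
  dimnames(S) <- list(rownames(F), rownames(F))
  S
}

#' Parameter-recovery statistics against the planted truth
#'
#' Compares a fitted model with the generator's ground truth: (a) cosine
#' similarity between the vectorized fitted bi-projection `B_d %*% t(B_t)`
#' and `theta_true`; (b) the fraction of the truth's `top_k`
#' largest-magnitude feature pairs recovered among the fitted matrix's
#' `top_k`; (c) AUPR of the model's scores against the noise-free labels.
#'
#' @param model A fitted `tmf_model`.
#' @param truth The `truth` element from [generate_dataset()].
#' @param dataset The matching [dti_dataset()] (for feature matrices).
#' @param top_k Number of feature pairs compared (default 10).
#' @return List with `cosine`, `topk_overlap` (fraction), `topk_hits`,
#'   `aupr_clean`.
#' @export
recovery_report <- function(model, truth, dataset, top_k = 10) {
  theta_hat <- tcrossprod(model$B_d, model$B_t)
  if (!all(dim(theta_hat) == dim(truth$theta_true))) {
    stop("fitted bi-projection shape does not match the planted truth")
  }
  v1 <- as.vector(theta_hat); v2 <- as.vector(truth$theta_true)
  cosine <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  topset <- function(M) order(-abs(as.vector(M)), seq_along(M))[seq_len(top_k)]
  hits <- length(intersect(topset(theta_hat), topset(truth$theta_true)))
  S <- score_pairs(model, dataset$F_d, dataset$F_t)
  aupr <- average_precision_aupr(as.vector(S), as.vector(truth$A_clean))
  list(cosine = cosine, topk_overlap = hits / top_k, topk_hits = hits,
       aupr_clean = aupr)
}
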