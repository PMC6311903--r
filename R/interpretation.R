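#' Build the three interpretation matrices
#'
#' From a fitted model and the explicit feature matrices:
#' * `theta` (p x q) — the bi-projection matrix `B_d %*% t(B_t)`; the sign of
#'   entry (i, j) indicates whether the pair of the i-th drug feature and the
#'   j-th target feature tends to occur in interactions (+), non-interactions
#'   (-), or is absent from all drug-target pairs (0); the magnitude is the
#'   occurring intensity.
#' * `theta_d` (p x n) — the drug projection matrix `theta %*% t(F_t)`; column
#'   j profiles how each drug feature appears among the drugs interacting
#'   with target j.
#' * `theta_t` (q x m) — the target projection matrix `t(F_d %*% theta)`;
#'   column j profiles how each target feature appears among the targets
#'   interacting with drug j. (Stored q x m per its defining formula; use
#'   `t()` for the drugs-as-rows view.)
#'
#' @param model A fitted `tmf_model`.
#' @param F_d,F_t Feature matrices used in the fit.
#' @return An object of class `projection_set`.
#' @export
build_projections <- function(model, F_d, F_t) {
  Fd <- as_values(F_d); Ft <- as_values(F_t)
  if (ncol(Fd) != nrow(model$B_d)) stop("drug feature width mismatch")
  if (ncol(Ft) != nrow(model$B_t)) stop("target feature width mismatch")
  theta <- tcrossprod(model$B_d, model$B_t)
  dimnames(theta) <- list(colnames(Fd), colnames(Ft))
  theta_d <- tcrossprod(theta, Ft)
  dimnames(theta_d) <- list(colnames(Fd), rownames(Ft))
  theta_t <- t(Fd %*% theta)
  dimnames(theta_t) <- list(colnames(Ft), rownames(Fd))
  structure(list(theta = theta, theta_d = theta_d, theta_t = theta_t),
            class = "projection_set")
}

#' @export
print.projection_set <- function(x, ...) {
  cat(sprintf("projection_set: theta %d x %d, theta_d %d x %d, theta_t %d x %d\n",
              nrow(x$theta), ncol(x$theta), nrow(x$theta_d), ncol(x$theta_d),
              nrow(x$theta_t), ncol(x$theta_t)))
  invisible(x)
}

#' Rank drug-feature/target-feature pairs by bi-projection value
#'
#' Sorts the entries of `theta`: the strongest positive pairs (interaction
#' drivers), the strongest negative pairs (non-interaction markers), and a
#' count of exact zeros (feature pairs absent from every drug-target pair).
#' Values within `1e-12` of zero but not exactly zero are counted separately
#' as numerically zero. Ties are broken by (drug-feature index,
#' target-feature index) ascending.
#'
#' @param theta The p x q bi-projection matrix.
#' @param top_k Number of pairs to return on each end.
#' @return List with data frames `top_positive`, `bottom_negative` (columns
#'   `drug_feature`, `target_feature`, `value`), `zero_count` and
#'   `near_zero_count`.
#' @export
rank_feature_pairs <- function(theta, top_k) {
  stopifnot(is.matrix(theta), top_k >= 1)
  dn <- dimnames(theta)
  dfn <- if (is.null(dn[[1]])) paste0("df", seq_len(nrow(theta))) else dn[[1]]
  tfn <- if (is.null(dn[[2]])) paste0("tf", seq_len(ncol(theta))) else dn[[2]]
  idx <- arrayInd(seq_along(theta), dim(theta))
  v <- as.vector(theta)
  pick <- function(sel, decreasing) {
    if (!any(sel)) {
      return(data.frame(drug_feature = character(0), target_feature = character(0),
                        value = numeric(0), stringsAsFactors = FALSE))
    }
    vi <- v[sel]; ii <- idx[sel, , drop = FALSE]
    ord <- order(if (decreasing) -vi else vi, ii[, 1], ii[, 2])
    ord <- ord[seq_len(min(top_k, length(ord)))]
    data.frame(drug_feature = dfn[ii[ord, 1]], target_feature = tfn[ii[ord, 2]],
               value = vi[ord], stringsAsFactors = FALSE)
  }
  list(top_positive = pick(v > 0, decreasing = TRUE),
       bottom_negative = pick(v < 0, decreasing = FALSE),
       zero_count = sum(v == 0),
       near_zero_count = sum(v != 0 & abs(v) < 1e-12))
}

#' Interaction bookkeeping for one feature pair
#'
#' For drug feature i and target feature j (binary features): the drugs
#' carrying bit i, the targets carrying bit j, the known interactions among
#' their cross-pairs, and the interaction ratio
#' `n_known_interactions / (n_drugs * n_targets)`. The complementary
#' non-interaction ratio is `1 - interaction_ratio`.
#'
#' @param A Binary adjacency matrix.
#' @param F_d,F_t Binary feature matrices ([feature_matrix()] or plain).
#' @param drug_feature,target_feature Column index or name.
#' @return A `feature_pair_support` list; when no drug or no target carries
#'   the feature the ratio is `NA` and `undefined` is `TRUE`.
#' @export
feature_pair_support <- function(A, F_d, F_t, drug_feature, target_feature) {
  Fd <- as_values(F_d); Ft <- as_values(F_t)
  if (!all(Fd %in% c(0, 1)) || !all(Ft %in% c(0, 1))) {
    stop("feature_pair_support requires binary feature matrices")
  }
  drugs <- which(Fd[, drug_feature] == 1)
  targets <- which(Ft[, target_feature] == 1)
  nd <- length(drugs); nt <- length(targets)
  ni <- if (nd && nt) sum(A[drugs, targets, drop = FALSE]) else 0L
  structure(list(
    drug_feature = drug_feature, target_feature = target_feature,
    n_drugs_with_feature = nd, n_targets_with_feature = nt,
    n_known_interactions = as.integer(ni),
    interaction_ratio = if (nd && nt) ni / (nd * nt) else NA_real_,
    undefined = !(nd && nt)
  ), class = "feature_pair_support")
}

#' @export
print.feature_pair_support <- function(x, ...) {
  if (x$undefined) {
    cat(sprintf("feature pair (%s, %s): no carrier on one side; ratio undefined\n",
                x$drug_feature, x$target_feature))
  } else {
    cat(sprintf("feature pair (%s, %s): %d drugs x %d targets, %d interactions, ratio %.3f\n",
                x$drug_feature, x$target_feature, x$n_drugs_with_feature,
                x$n_targets_with_feature, x$n_known_interactions,
                x$interaction_ratio))
  }
  invisible(x)
}

#' Frequently occurring features with positive projection entries
#'
#' A feature qualifies when its row of the projection matrix (`theta_d` for
#' drug substructures, `t(theta_t)`-style for target k-mers) has at least one
#' strictly positive entry (`mode = "any"`), or a positive row sum under the
#' stricter `mode = "rowsum"`. Occurrence is the fraction of entities whose
#' bit is set in `F`; features at or above `occurrence_threshold` are
#' returned sorted by occurrence descending (ties by feature index).
#'
#' @param theta_proj Projection matrix with rows indexed by the features of `F`.
#' @param F Binary [feature_matrix()] over the same features.
#' @param occurrence_threshold Minimum occurrence fraction (default 0.75).
#' @param mode `"any"` (default) or `"rowsum"`.
#' @return Data frame with `feature` and `occurrence`.
#' @export
frequent_positive_features <- function(theta_proj, F, occurrence_threshold = 0.75,
                                       mode = c("any", "rowsum")) {
  mode <- match.arg(mode)
  Fv <- as_values(F)
  if (nrow(theta_proj) != ncol(Fv)) {
    stop("projection rows (", nrow(theta_proj),
         ") do not match feature columns (", ncol(Fv), ")")
  }
  if (!all(Fv %in% c(0, 1))) stop("occurrence counting requires binary features")
  qual <- if (mode == "any") {
    apply(theta_proj, 1, function(x) any(x > 0))
  } else {
    rowSums(theta_proj) > 0
  }
  occ <- colMeans(Fv)
  keep <- which(qual & occ >= occurrence_threshold)
  fn <- colnames(Fv)
  if (is.null(fn)) fn <- paste0("f", seq_len(ncol(Fv)))
  ord <- keep[order(-occ[keep], keep)]
  data.frame(feature = fn[ord], occurrence = unname(occ[ord]),
             stringsAsFactors = FALSE)
}

#' Top and bottom projection features for one entity
#'
#' Sorts column `entity` of a projection matrix: the strongest positive
#' features (shared by the entity's interaction partners) and the strongest
#' negative ones. Exact zeros are excluded from both lists (a zero means the
#' feature appears in none of the dataset's entities).
#'
#' @param theta_proj Projection matrix (features x entities).
#' @param entity Column index or name.
#' @param top_k,bottom_k List lengths (truncated, never padded).
#' @return List with data frames `top` and `bottom` (`feature`, `value`).
#' @export
entity_feature_profile <- function(theta_proj, entity, top_k, bottom_k) {
  if (is.character(entity)) {
    entity <- match(entity, colnames(theta_proj))
    if (is.na(entity)) stop("unknown entity")
  }
  if (entity < 1 || entity > ncol(theta_proj)) stop("invalid entity index")
  col <- theta_proj[, entity]
  fn <- rownames(theta_proj)
  if (is.null(fn)) fn <- paste0("f", seq_along(col))
  take <- function(sel, decreasing, k) {
    ii <- which(sel)
    ord <- ii[order(if (decreasing) -col[ii] else col[ii], ii)]
    ord <- ord[seq_len(min(k, length(ord)))]
    data.frame(feature = fn[ord], value = unname(col[ord]),
               stringsAsFactors = FALSE)
  }
  list(top = take(col > 0, TRUE, top_k),
       bottom = take(col < 0, FALSE, bottom_k))
}
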