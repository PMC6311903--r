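#' Bilinear confidence scores for arbitrary feature rows
#'
#' Computes `(F_d_rows %*% B_d) %*% t(F_t_rows %*% B_t)`, which equals
#' `F_d_rows %*% Theta %*% t(F_t_rows)` with `Theta = B_d %*% t(B_t)` but
#' never materializes the p x q bi-projection matrix. This one formula
#' covers all four screening scenarios: pass training feature rows for
#' known entities and new feature rows for cold-start entities.
#'
#' @param model A fitted `tmf_model`.
#' @param F_d_rows Drug feature rows (a x p), plain or [feature_matrix()].
#' @param F_t_rows Target feature rows (b x q).
#' @return An a x b score matrix.
#' @export
score_pairs <- function(model, F_d_rows, F_t_rows) {
  F_d_rows <- as_values(F_d_rows); F_t_rows <- as_values(F_t_rows)
  if (is.null(dim(F_d_rows))) F_d_rows <- matrix(F_d_rows, nrow = 1)
  if (is.null(dim(F_t_rows))) F_t_rows <- matrix(F_t_rows, nrow = 1)
  if (ncol(F_d_rows) != nrow(model$B_d)) stop("drug feature width mismatch")
  if (ncol(F_t_rows) != nrow(model$B_t)) stop("target feature width mismatch")
  if (anyNA(F_d_rows) || anyNA(F_t_rows)) stop("NA/NaN in feature rows")
  tcrossprod(F_d_rows %*% model$B_d, F_t_rows %*% model$B_t)
}

#' Score a screening scenario
#'
#' Dispatches to [score_pairs()] with the scenario's feature-row selection:
#' S1 scores every (known drug, known target) cell; S2 scores supplied new
#' drugs against all training targets; S3 all training drugs against new
#' targets; S4 new drugs against new targets.
#'
#' @param dataset A [dti_dataset()] carrying `F_d` / `F_t`.
#' @param model A fitted `tmf_model`.
#' @param scenario `"S1"`, `"S2"`, `"S3"` or `"S4"`.
#' @param new_drug_features,new_target_features [feature_matrix()] rows for
#'   the cold-start entities (required by S2/S4 and S3/S4 respectively).
#' @return A `score_matrix`: list with `drug_ids`, `target_ids`, `scores`,
#'   `scenario`.
#' @export
predict_scenario <- function(dataset, model, scenario,
                             new_drug_features = NULL,
                             new_target_features = NULL) {
  stopifnot(inherits(dataset, "dti_dataset"))
  if (!scenario %in% c("S1", "S2", "S3", "S4")) stop("unknown scenario: ", scenario)
  need_drug <- scenario %in% c("S2", "S4")
  need_target <- scenario %in% c("S3", "S4")
  if (need_drug && is.null(new_drug_features)) {
    stop(scenario, " requires new-drug feature rows")
  }
  if (need_target && is.null(new_target_features)) {
    stop(scenario, " requires new-target feature rows")
  }
  Fd <- if (need_drug) new_drug_features else dataset$F_d
  Ft <- if (need_target) new_target_features else dataset$F_t
  if (is.null(Fd)) stop("dataset has no drug features")
  if (is.null(Ft)) stop("dataset has no target features")
  drug_ids <- if (need_drug) new_drug_features$entity_ids else dataset$drug_ids
  target_ids <- if (need_target) new_target_features$entity_ids else dataset$target_ids
  scores <- score_pairs(model, Fd, Ft)
  dimnames(scores) <- list(drug_ids, target_ids)
  structure(list(drug_ids = drug_ids, target_ids = target_ids,
                 scores = scores, scenario = scenario),
            class = "score_matrix")
}

#' @export
print.score_matrix <- function(x, ...) {
  cat(sprintf("score_matrix (%s): %d x %d, range [%.4g, %.4g]\n", x$scenario,
              nrow(x$scores), ncol(x$scores), min(x$scores), max(x$scores)))
  invisible(x)
}

#' Rank unlabeled pairs as novel-interaction candidates
#'
#' Transductive repositioning: with the model fitted on the full dataset,
#' every cell with `A = 0` is ranked by confidence score descending (known
#' positives never appear). Ties are broken by (drug index, target index)
#' ascending.
#'
#' @param dataset A [dti_dataset()] with features.
#' @param model A `tmf_model` fitted on the full dataset.
#' @param k Number of candidates to return; if it exceeds the number of
#'   unlabeled cells, all are returned with a warning.
#' @return Data frame with `rank`, `drug_id`, `target_id`, `score`.
#' @export
top_novel <- function(dataset, model, k) {
  stopifnot(inherits(dataset, "dti_dataset"), k >= 1)
  scores <- score_pairs(model, dataset$F_d, dataset$F_t)
  zero <- which(dataset$A == 0, arr.ind = TRUE)
  if (k > nrow(zero)) {
    warning("k = ", k, " exceeds the ", nrow(zero), " unlabeled pairs; returning all")
    k <- nrow(zero)
  }
  s <- scores[zero]
  ord <- order(-s, zero[, 1], zero[, 2])[seq_len(k)]
  data.frame(rank = seq_len(k),
             drug_id = dataset$drug_ids[zero[ord, 1]],
             target_id = dataset$target_ids[zero[ord, 2]],
             score = s[ord],
             stringsAsFactors = FALSE)
}
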