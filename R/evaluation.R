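fold_plan_new <- function(scenario, rounds, K, seed) {
  structure(list(scenario = scenario, rounds = rounds, K = K, seed = seed),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("fold_plan (%s): %d rounds, seed %d\n",
              x$scenario, length(x$rounds), x$seed))
  invisible(x)
}

# Random near-equal partition of n items into K folds.
partition_folds <- function(n, K) {
  split(sample.int(n), rep_len(seq_len(K), n))
}

#' Pair-completion (S1) cross-validation split
#'
#' Only cells whose drug has at least 2 known targets and whose target has
#' at least 2 known drugs are eligible (degrees taken on the full A before
#' splitting); both positive and zero cells at those coordinates count.
#' Eligible cells are randomly partitioned into K folds; in each round the
#' test fold's cells are blinded in the training mask and everything else is
#' observed.
#'
#' @param A Binary adjacency matrix.
#' @param K Number of folds (default 10).
#' @param seed Integer seed.
#' @return A `fold_plan`; each round holds `train_mask` and `test_cells`
#'   (2-column index matrix).
#' @export
split_s1 <- function(A, K = 10, seed = 1) {
  ddeg <- rowSums(A); tdeg <- colSums(A)
  eligible <- which(outer(ddeg >= 2, tdeg >= 2, `&`), arr.ind = TRUE)
  if (nrow(eligible) < K) {
    stop("only ", nrow(eligible), " eligible cells for S1 but K = ", K)
  }
  set.seed(seed)
  folds <- partition_folds(nrow(eligible), K)
  rounds <- lapply(folds, function(f) {
    cells <- eligible[f, , drop = FALSE]
    mask <- matrix(1, nrow(A), ncol(A))
    mask[cells] <- 0
    list(train_mask = mask, test_cells = cells)
  })
  fold_plan_new("S1", unname(rounds), K, seed)
}

#' Leave-entities-out (S2/S3) cross-validation split
#'
#' Drugs (S2) or targets (S3) are randomly partitioned into K near-equal
#' folds; each round blinds the held-out rows (columns) entirely — all their
#' cells are test cells — and keeps the remaining rows (columns) fully
#' observed.
#'
#' @param A Binary adjacency matrix.
#' @param axis `"drugs"` (S2) or `"targets"` (S3).
#' @param K Number of folds (default 10).
#' @param seed Integer seed.
#' @return A `fold_plan`; each round holds `train_entities`,
#'   `test_entities`, `train_mask`, `test_cells`.
#' @export
split_entities <- function(A, axis = c("drugs", "targets"), K = 10, seed = 1) {
  axis <- match.arg(axis)
  n_ent <- if (axis == "drugs") nrow(A) else ncol(A)
  if (K > n_ent) stop("K = ", K, " exceeds the ", n_ent, " ", axis)
  set.seed(seed)
  folds <- partition_folds(n_ent, K)
  rounds <- lapply(folds, function(f) {
    mask <- matrix(1, nrow(A), ncol(A))
    if (axis == "drugs") {
      mask[f, ] <- 0
      cells <- cbind(rep(f, each = ncol(A)), rep(seq_len(ncol(A)), length(f)))
    } else {
      mask[, f] <- 0
      cells <- cbind(rep(seq_len(nrow(A)), length(f)), rep(f, each = nrow(A)))
    }
    list(train_entities = setdiff(seq_len(n_ent), f), test_entities = sort(f),
         train_mask = mask, test_cells = cells)
  })
  fold_plan_new(if (axis == "drugs") "S2" else "S3", unname(rounds), K, seed)
}

#' Blocked (S4) double cold-start cross-validation split
#'
#' Drugs are partitioned into `K_d` folds and targets into `K_t` folds; one
#' round per (drug fold, target fold) pair. Test cells are the held-out
#' block, training cells the retained block, and the two mixed blocks attend
#' neither phase — no observed training cell shares a row or column with a
#' test cell.
#'
#' @param A Binary adjacency matrix.
#' @param K_d,K_t Fold counts (default 5 x 5).
#' @param seed Integer seed.
#' @return A `fold_plan` with `K_d * K_t` rounds; each round holds
#'   `train_drugs`, `train_targets`, `test_drugs`, `test_targets`,
#'   `train_mask`, `test_cells`.
#' @export
split_s4 <- function(A, K_d = 5, K_t = 5, seed = 1) {
  if (K_d > nrow(A)) stop("K_d exceeds the number of drugs")
  if (K_t > ncol(A)) stop("K_t exceeds the number of targets")
  set.seed(seed)
  dfolds <- partition_folds(nrow(A), K_d)
  tfolds <- partition_folds(ncol(A), K_t)
  rounds <- list()
  for (fd in dfolds) {
    for (ft in tfolds) {
      trn_d <- setdiff(seq_len(nrow(A)), fd)
      trn_t <- setdiff(seq_len(ncol(A)), ft)
      mask <- matrix(0, nrow(A), ncol(A))
      mask[trn_d, trn_t] <- 1
      cells <- cbind(rep(sort(fd), each = length(ft)),
                     rep(sort(ft), length(fd)))
      rounds[[length(rounds) + 1L]] <- list(
        train_drugs = trn_d, train_targets = trn_t,
        test_drugs = sort(fd), test_targets = sort(ft),
        train_mask = mask, test_cells = cells)
    }
  }
  plan <- fold_plan_new("S4", rounds, K_d * K_t, seed)
  plan$K_d <- K_d; plan$K_t <- K_t
  plan
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-wise average precision: sort by score descending (ties broken by
#' input index ascending) and average the precision at each positive's rank.
#' Preferred over AUC for heavily class-imbalanced interaction ranking, and
#' over trapezoidal PR interpolation, which overestimates the area.
#'
#' @param scores Real score vector.
#' @param labels Binary labels (same length; both classes present).
#' @return AUPR in (0, 1].
#' @export
average_precision_aupr <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  np <- sum(labels == 1)
  if (np == 0 || np == length(labels)) {
    stop("AUPR undefined: need at least one positive and one negative label")
  }
  ord <- order(-scores, seq_along(scores))
  lab <- labels[ord]
  pos_ranks <- which(lab == 1)
  mean(seq_along(pos_ranks) / pos_ranks)
}

#' Area under the ROC curve (rank statistic)
#'
#' Probability that a random positive outscores a random negative, with
#' ties counting one half (Wilcoxon/Mann-Whitney form).
#'
#' @param scores Real score vector.
#' @param labels Binary labels (both classes present).
#' @return AUC in [0, 1].
#' @export
auc_roc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  np <- sum(labels == 1); nn <- sum(labels == 0)
  if (np == 0 || nn == 0) {
    stop("AUC undefined: need at least one positive and one negative label")
  }
  rk <- rank(scores, ties.method = "average")
  (sum(rk[labels == 1]) - np * (np + 1) / 2) / (np * nn)
}

#' Cross-validated evaluation of the TMF model
#'
#' Runs scenario-correct cross-validation over `N` repetitions. Repetition i
#' uses seed `seed + i - 1` to build its fold plan. Per round the model is
#' fitted on training data only — S1 with [tmf_fit_masked()] on the masked
#' full matrix; S2/S3/S4 with [tmf_fit()] on the retained sub-block — with
#' the latent dimension resolved from the training matrix when
#' `hp$r == "auto"`. Test-cell scores and labels are pooled across a
#' repetition's rounds into one AUPR and one AUC; the report carries the
#' per-repetition lists and their mean and standard deviation. A repetition
#' whose pooled test set lacks a class is dropped with a warning.
#'
#' @param dataset A [dti_dataset()] with `F_d` and `F_t` (or similarity
#'   matrices, which are featurized via [features_from_similarity()]).
#' @param scenario `"S1"`, `"S2"`, `"S3"` or `"S4"`.
#' @param hp Optional [tmf_hyperparameters()]; defaults to
#'   [default_hyperparameters()] for the scenario.
#' @param K Fold count for S1-S3 (default 10).
#' @param K_d,K_t Fold counts for S4 (default 5 x 5).
#' @param N Number of repetitions (default 5).
#' @param seed Integer base seed.
#' @return A `metric_report`.
#' @export
run_cv <- function(dataset, scenario, hp = NULL, K = 10, K_d = 5, K_t = 5,
                   N = 5, seed = 1) {
  stopifnot(inherits(dataset, "dti_dataset"))
  if (!scenario %in% c("S1", "S2", "S3", "S4")) stop("unknown scenario: ", scenario)
  if (is.null(hp)) hp <- default_hyperparameters(scenario)
  Fd <- dataset$F_d
  Ft <- dataset$F_t
  if (is.null(Fd)) {
    if (is.null(dataset$S_d)) stop("dataset has neither drug features nor drug similarities")
    Fd <- features_from_similarity(dataset$S_d)
  }
  if (is.null(Ft)) {
    if (is.null(dataset$S_t)) stop("dataset has neither target features nor target similarities")
    Ft <- features_from_similarity(dataset$S_t)
  }
  Fd <- as_values(Fd); Ft <- as_values(Ft)
  A <- dataset$A
  aupr <- auc <- numeric(0)
  for (rep_i in seq_len(N)) {
    rep_seed <- seed + rep_i - 1L
    plan <- switch(scenario,
      S1 = split_s1(A, K, rep_seed),
      S2 = split_entities(A, "drugs", K, rep_seed),
      S3 = split_entities(A, "targets", K, rep_seed),
      S4 = split_s4(A, K_d, K_t, rep_seed))
    scores <- labels <- numeric(0)
    for (round in plan$rounds) {
      res <- tryCatch(
        cv_round(A, Fd, Ft, scenario, round, hp),
        error = function(e) {
          warning("round skipped: ", conditionMessage(e))
          NULL
        })
      if (is.null(res)) next
      scores <- c(scores, res$scores)
      labels <- c(labels, res$labels)
    }
    if (!length(labels) || sum(labels) == 0 || sum(labels) == length(labels)) {
      warning("repetition ", rep_i, " has a single-class pooled test set; reported as missing")
      next
    }
    aupr <- c(aupr, average_precision_aupr(scores, labels))
    auc <- c(auc, auc_roc(scores, labels))
  }
  structure(list(
    scenario = scenario,
    K = if (scenario == "S4") c(K_d = K_d, K_t = K_t) else K,
    N = N, seed = seed,
    aupr_per_rep = aupr, auc_per_rep = auc,
    aupr_mean = mean(aupr), aupr_std = stats::sd(aupr),
    auc_mean = mean(auc), auc_std = stats::sd(auc)
  ), class = "metric_report")
}

cv_round <- function(A, Fd, Ft, scenario, round, hp) {
  if (scenario == "S1") {
    model <- suppressMessages(tmf_fit_masked(A, round$train_mask, Fd, Ft, hp))
    S <- score_pairs(model, Fd, Ft)
    cells <- round$test_cells
    return(list(scores = S[cells], labels = A[cells]))
  }
  if (scenario == "S2") {
    trn <- round$train_entities; tst <- round$test_entities
    A_trn <- A[trn, , drop = FALSE]
    model <- tmf_fit(A_trn, Fd[trn, , drop = FALSE], Ft, hp)
    S <- score_pairs(model, Fd[tst, , drop = FALSE], Ft)
    return(list(scores = as.vector(S), labels = as.vector(A[tst, , drop = FALSE])))
  }
  if (scenario == "S3") {
    trn <- round$train_entities; tst <- round$test_entities
    A_trn <- A[, trn, drop = FALSE]
    model <- tmf_fit(A_trn, Fd, Ft[trn, , drop = FALSE], hp)
    S <- score_pairs(model, Fd, Ft[tst, , drop = FALSE])
    return(list(scores = as.vector(S), labels = as.vector(A[, tst, drop = FALSE])))
  }
  # S4
  A_trn <- A[round$train_drugs, round$train_targets, drop = FALSE]
  model <- tmf_fit(A_trn, Fd[round$train_drugs, , drop = FALSE],
                   Ft[round$train_targets, , drop = FALSE], hp)
  S <- score_pairs(model, Fd[round$test_drugs, , drop = FALSE],
                   Ft[round$test_targets, , drop = FALSE])
  list(scores = as.vector(S),
       labels = as.vector(A[round$test_drugs, round$test_targets, drop = FALSE]))
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("metric_report (%s, N = %d, seed = %d):\n", x$scenario,
              x$N, x$seed))
  cat(sprintf("  AUPR %.4f +/- %.4f  AUC %.4f +/- %.4f  (%d repetition(s))\n",
              x$aupr_mean, x$aupr_std, x$auc_mean, x$auc_std,
              length(x$aupr_per_rep)))
  invisible(x)
}
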