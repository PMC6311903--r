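#' Hyperparameters for the triple matrix factorization
#'
#' The objective fitted by [tmf_fit()] is
#' \deqn{J = ||A - A_d A_t'||_F^2 + ||A_d - F_d B_d||_F^2 + ||A_t - F_t B_t||_F^2
#'       + \lambda ||A_d||_F^2 + \mu ||A_t||_F^2 + \alpha ||B_d||_F^2 + \beta ||B_t||_F^2}
#'
#' @param lambda,mu Ridge penalties on the drug / target latent factors.
#' @param alpha,beta Ridge penalties on the drug / target regression
#'   coefficient matrices.
#' @param r Latent dimension, or `"auto"` for half the numerical rank of the
#'   training adjacency matrix.
#' @param max_iter Maximum number of full ALS cycles.
#' @param rel_tol Relative objective-change convergence threshold.
#' @return An object of class `tmf_hyperparameters`.
#' @export
tmf_hyperparameters <- function(lambda, mu, alpha, beta, r = "auto",
                                max_iter = 200, rel_tol = 1e-6) {
  stopifnot(lambda >= 0, mu >= 0, alpha >= 0, beta >= 0,
            max_iter >= 1, rel_tol > 0)
  if (!identical(r, "auto")) {
    r <- as.integer(r)
    stopifnot(length(r) == 1L, r >= 1L)
  }
  structure(list(lambda = lambda, mu = mu, alpha = alpha, beta = beta,
                 r = r, max_iter = max_iter, rel_tol = rel_tol),
            class = "tmf_hyperparameters")
}

#' Default hyperparameters per screening scenario
#'
#' Regularizer settings selected by grid search on the public benchmark:
#' S1 (pair completion) lambda = mu = 1.0, alpha = beta = 0.5;
#' S2 (new drug) 0.05 / 0.5; S3 (new target) 0.5 / 0.05;
#' S4 (new drug x new target) 0.05 / 0.5. Latent dimension defaults to
#' `"auto"` (half the training rank).
#'
#' @param scenario One of `"S1"`, `"S2"`, `"S3"`, `"S4"`.
#' @return A [tmf_hyperparameters()] object.
#' @export
default_hyperparameters <- function(scenario) {
  pars <- switch(scenario,
    S1 = c(1.0, 1.0, 0.5, 0.5),
    S2 = c(0.05, 0.05, 0.5, 0.5),
    S3 = c(0.5, 0.5, 0.05, 0.05),
    S4 = c(0.05, 0.05, 0.5, 0.5),
    stop("unknown scenario: ", scenario)
  )
  tmf_hyperparameters(pars[1], pars[2], pars[3], pars[4])
}

numerical_rank <- function(A) {
  sv <- svd(A, nu = 0, nv = 0)$d
  if (!length(sv) || max(sv) == 0) return(0L)
  sum(sv > max(dim(A)) * .Machine$double.eps * max(sv))
}

#' Resolve the latent dimension r
#'
#' `"auto"` gives `max(1, floor(rank(A_trn) / 2))`, with the numerical rank
#' taken as the count of singular values above
#' `max(m, n) * eps * sigma_max`.
#'
#' @param A_trn Training adjacency matrix (must be nonzero).
#' @param mode `"auto"` or an explicit positive integer (bounds-checked
#'   against `min(m, n)`).
#' @return A positive integer.
#' @export
resolve_latent_dimension <- function(A_trn, mode = "auto") {
  stopifnot(is.matrix(A_trn))
  if (identical(mode, "auto")) {
    rk <- numerical_rank(A_trn)
    if (rk == 0L) stop("training matrix has rank 0; cannot resolve latent dimension")
    return(max(1L, as.integer(floor(rk / 2))))
  }
  r <- as.integer(mode)
  if (r < 1L || r > min(dim(A_trn))) {
    stop("latent dimension ", r, " out of bounds for a ",
         nrow(A_trn), " x ", ncol(A_trn), " matrix")
  }
  r
}

#' SVD initialization of the latent factors
#'
#' Truncated rank-r SVD `A ~ U_r S_r V_r'` split symmetrically:
#' `A_d0 = U_r sqrt(S_r)`, `A_t0 = V_r sqrt(S_r)`, so `A_d0 %*% t(A_t0)` is
#' the best rank-r approximation of A.
#'
#' @param A Adjacency matrix.
#' @param r Latent dimension, `r <= min(m, n)`.
#' @return List with `A_d0` (m x r) and `A_t0` (n x r).
#' @export
init_factors <- function(A, r) {
  stopifnot(is.matrix(A))
  if (r > min(dim(A))) stop("r = ", r, " exceeds matrix dimensions")
  sv <- svd(A, nu = r, nv = r)
  sq <- sqrt(sv$d[seq_len(r)])
  list(A_d0 = sv$u %*% diag(sq, nrow = r),
       A_t0 = sv$v %*% diag(sq, nrow = r))
}

# NIPALS PLS2: centering on, scaling off. Returns the f x r coefficient
# matrix on the raw (uncentered) scale plus the implied intercept.
nipals_pls <- function(X, Y, ncomp) {
  Xm <- colMeans(X); Ym <- colMeans(Y)
  Xc <- sweep(X, 2, Xm); Yc <- sweep(Y, 2, Ym)
  W <- P <- C <- NULL
  for (a in seq_len(ncomp)) {
    if (sum(Xc^2) < 1e-12 || sum(Yc^2) < 1e-12) break
    u <- Yc[, which.max(colSums(Yc^2))]
    w <- NULL
    for (it in 1:500) {
      w_new <- crossprod(Xc, u)
      nw <- sqrt(sum(w_new^2))
      if (nw < 1e-12) break
      w_new <- w_new / nw
      tsc <- Xc %*% w_new
      cc <- crossprod(Yc, tsc) / sum(tsc^2)
      u_new <- (Yc %*% cc) / sum(cc^2)
      done <- !is.null(w) && sum((w_new - w)^2) < 1e-24
      w <- w_new
      u <- u_new
      if (done) break
    }
    if (is.null(w)) break
    tsc <- Xc %*% w
    tt <- sum(tsc^2)
    if (tt < 1e-12) break
    p <- crossprod(Xc, tsc) / tt
    cc <- crossprod(Yc, tsc) / tt
    Xc <- Xc - tsc %*% t(p)
    Yc <- Yc - tsc %*% t(cc)
    W <- cbind(W, w); P <- cbind(P, p); C <- cbind(C, cc)
  }
  if (is.null(W)) {
    B <- matrix(0, ncol(X), ncol(Y))
  } else {
    B <- W %*% solve(crossprod(P, W), t(C))
  }
  list(B = B, intercept = as.numeric(Ym - crossprod(B, Xm)))
}

#' PLSR initialization of a regression coefficient matrix
#'
#' Partial least-squares regression (NIPALS deflation, centering on, scaling
#' off) of a latent factor on the feature matrix; robust to the
#' multicollinearity expected among fingerprint bits and to p > m. Used only
#' to produce the ALS starting point for `B_d` / `B_t`.
#'
#' @param F Feature matrix (k x f), plain matrix or [feature_matrix()].
#' @param A_factor Latent factor (k x r).
#' @param n_components Number of PLS components; silently clipped to
#'   `min(k - 1, f, r)`.
#' @return An f x r coefficient matrix with attribute `"intercept"`.
#' @export
init_regressors <- function(F, A_factor, n_components) {
  if (inherits(F, "feature_matrix")) F <- F$values
  stopifnot(is.matrix(F), is.matrix(A_factor), nrow(F) == nrow(A_factor))
  if (anyNA(F) || anyNA(A_factor)) stop("NA/NaN in PLSR inputs")
  k <- nrow(F)
  if (k < 2L) stop("PLSR initialization needs at least 2 rows")
  nc_max <- min(k - 1L, ncol(F), ncol(A_factor))
  nc <- min(as.integer(n_components), nc_max)
  if (nc < n_components) {
    message("PLSR components clipped from ", n_components, " to ", nc)
  }
  fit <- nipals_pls(F, A_factor, nc)
  if (any(!is.finite(fit$B))) stop("PLSR produced non-finite coefficients")
  structure(fit$B, intercept = fit$intercept)
}

#' Evaluate the TMF objective J
#'
#' Sum of the reconstruction term `||A - A_d A_t'||^2` (restricted to the
#' observed cells when `mask` is given), the two feature-regression terms and
#' the four ridge penalties.
#'
#' @param A Adjacency matrix.
#' @param F_d,F_t Feature matrices (plain or [feature_matrix()]).
#' @param model A `tmf_model` (or a bare list with `A_d`, `A_t`, `B_d`,
#'   `B_t`, `hp`).
#' @param mask Optional binary observation mask (1 = observed).
#' @return Nonnegative scalar J.
#' @export
tmf_objective <- function(A, F_d, F_t, model, mask = NULL) {
  F_d <- as_values(F_d); F_t <- as_values(F_t)
  hp <- model$hp
  R <- A - tcrossprod(model$A_d, model$A_t)
  if (!is.null(mask)) {
    if (!all(dim(mask) == dim(A))) stop("mask shape mismatch")
    R <- R * mask
  }
  sum(R^2) +
    sum((model$A_d - F_d %*% model$B_d)^2) +
    sum((model$A_t - F_t %*% model$B_t)^2) +
    hp$lambda * sum(model$A_d^2) + hp$mu * sum(model$A_t^2) +
    hp$alpha * sum(model$B_d^2) + hp$beta * sum(model$B_t^2)
}

as_values <- function(x) {
  if (inherits(x, "feature_matrix")) x$values else x
}

# Closed-form single-factor updates (each the exact minimizer of J in that
# block with the others fixed).
update_Ad <- function(A, A_t, FdBd, lambda) {
  r <- ncol(A_t)
  (A %*% A_t + FdBd) %*% solve(crossprod(A_t) + diag(1 + lambda, r))
}
update_At <- function(A, A_d, FtBt, mu) {
  r <- ncol(A_d)
  (crossprod(A, A_d) + FtBt) %*% solve(crossprod(A_d) + diag(1 + mu, r))
}
update_B <- function(F, A_factor, reg) {
  solve(crossprod(F) + diag(reg, ncol(F)), crossprod(F, A_factor))
}
# Entry-form update for the masked objective: row i of the side being updated
# solves (sum_{j in Omega_i} g_j g_j' + (1+reg) I) x = sum_j a_ij g_j + prior_i
# where g_j are the rows of the fixed opposite factor.
update_rows_masked <- function(Avals, obs, G, prior, reg) {
  r <- ncol(G)
  out <- matrix(0, nrow(Avals), r)
  base <- diag(1 + reg, r)
  for (i in seq_len(nrow(Avals))) {
    j <- which(obs[i, ] != 0)
    if (length(j)) {
      Gi <- G[j, , drop = FALSE]
      M <- crossprod(Gi) + base
      rhs <- crossprod(Gi, Avals[i, j]) + prior[i, ]
    } else {
      M <- base
      rhs <- prior[i, ]
    }
    out[i, ] <- solve(M, rhs)
  }
  out
}

tmf_model_new <- function(A_d, A_t, B_d, B_t, hp, trace, converged) {
  structure(list(A_d = A_d, A_t = A_t, B_d = B_d, B_t = B_t, hp = hp,
                 objective_trace = trace, converged = converged),
            class = "tmf_model")
}

#' @export
print.tmf_model <- function(x, ...) {
  cat(sprintf(
    "tmf_model: r = %d, %d ALS cycles, final J = %.6g, converged = %s\n",
    ncol(x$A_d), length(x$objective_trace),
    x$objective_trace[length(x$objective_trace)], x$converged))
  invisible(x)
}

tmf_fit_engine <- function(A, F_d, F_t, hp, mask = NULL) {
  F_d <- as_values(F_d); F_t <- as_values(F_t)
  stopifnot(is.matrix(A), nrow(F_d) == nrow(A), nrow(F_t) == ncol(A))
  A_init <- if (is.null(mask)) A else A * mask
  r <- resolve_latent_dimension(A_init, hp$r)
  fac <- init_factors(A_init, r)
  A_d <- fac$A_d0; A_t <- fac$A_t0
  nc <- min(r, ncol(F_d), nrow(F_d) - 1L)
  B_d <- unclass(init_regressors(F_d, A_d, nc))
  attr(B_d, "intercept") <- NULL
  nc <- min(r, ncol(F_t), nrow(F_t) - 1L)
  B_t <- unclass(init_regressors(F_t, A_t, nc))
  attr(B_t, "intercept") <- NULL
  hp_res <- hp; hp_res$r <- r
  trace <- numeric(0)
  J_prev <- tmf_objective(A, F_d, F_t,
                          list(A_d = A_d, A_t = A_t, B_d = B_d, B_t = B_t, hp = hp_res),
                          mask = mask)
  converged <- FALSE
  for (it in seq_len(hp$max_iter)) {
    if (is.null(mask)) {
      A_d <- update_Ad(A, A_t, F_d %*% B_d, hp$lambda)
      A_t <- update_At(A, A_d, F_t %*% B_t, hp$mu)
    } else {
      A_d <- update_rows_masked(A, mask, A_t, F_d %*% B_d, hp$lambda)
      A_t <- update_rows_masked(t(A), t(mask), A_d, F_t %*% B_t, hp$mu)
    }
    B_d <- update_B(F_d, A_d, hp$alpha)
    B_t <- update_B(F_t, A_t, hp$beta)
    J <- tmf_objective(A, F_d, F_t,
                       list(A_d = A_d, A_t = A_t, B_d = B_d, B_t = B_t, hp = hp_res),
                       mask = mask)
    if (J > J_prev * (1 + 1e-9) + 1e-12) {
      stop("objective increased during ALS (", J_prev, " -> ", J,
           "); update formulas are inconsistent")
    }
    trace <- c(trace, J)
    if (abs(J_prev - J) <= hp$rel_tol * max(J_prev, .Machine$double.eps)) {
      converged <- TRUE
      J_prev <- J
      break
    }
    J_prev <- J
  }
  tmf_model_new(A_d, A_t, B_d, B_t, hp_res, trace, converged)
}

#' Fit the TMF model by alternating least squares
#'
#' Iterates the closed-form updates in the fixed order
#' `A_d -> A_t -> B_d -> B_t`:
#' \deqn{A_d = (A A_t + F_d B_d)(A_t' A_t + I + \lambda I)^{-1}}
#' \deqn{A_t = (A' A_d + F_t B_t)(A_d' A_d + I + \mu I)^{-1}}
#' \deqn{B_d = (F_d' F_d + \alpha I)^{-1} F_d' A_d}
#' \deqn{B_t = (F_t' F_t + \beta I)^{-1} F_t' A_t}
#' starting from the SVD factor split and PLSR coefficients, until the
#' relative objective change drops below `rel_tol` or `max_iter` cycles.
#' Every unlabeled cell of `A` is treated as a hard zero (fully observed
#' training); use [tmf_fit_masked()] when some cells are blinded.
#'
#' @param A Binary adjacency matrix (m x n, rows = drugs).
#' @param F_d,F_t Drug (m x p) / target (n x q) feature matrices.
#' @param hp A [tmf_hyperparameters()] object.
#' @return A `tmf_model` with factors, hyperparameters (r resolved), the
#'   per-cycle objective trace and a convergence flag.
#' @export
tmf_fit <- function(A, F_d, F_t, hp) {
  tmf_fit_engine(A, F_d, F_t, hp, mask = NULL)
}

#' Fit the TMF model with partially observed training cells
#'
#' Entry-form alternating least squares for the pair-completion scenario:
#' the reconstruction term is summed only over observed cells, so the
#' matrix-form `A_d` / `A_t` updates are replaced by exact per-row solves
#' `(sum_{j in Omega_i} a_tj a_tj' + (1 + lambda) I) x = sum_j a_ij a_tj + (F_d B_d)_i`
#' (and symmetrically per target column). `B_d` / `B_t` updates are
#' unchanged. With an all-ones mask this reduces exactly to [tmf_fit()].
#' Initialization uses `A * mask`, so blinded values never enter the fit.
#'
#' @param A Binary adjacency matrix.
#' @param mask Binary observation mask of the same shape (1 = observed).
#' @param F_d,F_t Feature matrices.
#' @param hp A [tmf_hyperparameters()] object.
#' @return A `tmf_model`.
#' @export
tmf_fit_masked <- function(A, mask, F_d, F_t, hp) {
  stopifnot(is.matrix(mask))
  if (!all(dim(mask) == dim(A))) stop("mask shape mismatch")
  if (!all(mask %in% c(0, 1))) stop("mask must be binary")
  empty_rows <- sum(rowSums(mask) == 0)
  empty_cols <- sum(colSums(mask) == 0)
  if (empty_rows || empty_cols) {
    message("mask leaves ", empty_rows, " row(s) and ", empty_cols,
            " column(s) with no observed cell; their factors rest on the feature prior")
  }
  tmf_fit_engine(A, F_d, F_t, hp, mask = mask)
}
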