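test_that("per-scenario default regularizers and latent-dimension rule", {
  expect_equal(unlist(default_hyperparameters("S1")[c("lambda", "mu", "alpha", "beta")]),
               c(lambda = 1.0, mu = 1.0, alpha = 0.5, beta = 0.5))
  expect_equal(unlist(default_hyperparameters("S2")[c("lambda", "mu", "alpha", "beta")]),
               c(lambda = 0.05, mu = 0.05, alpha = 0.5, beta = 0.5))
  expect_equal(unlist(default_hyperparameters("S3")[c("lambda", "mu", "alpha", "beta")]),
               c(lambda = 0.5, mu = 0.5, alpha = 0.05, beta = 0.05))
  expect_equal(unlist(default_hyperparameters("S4")[c("lambda", "mu", "alpha", "beta")]),
               c(lambda = 0.05, mu = 0.05, alpha = 0.5, beta = 0.5))
  expect_error(default_hyperparameters("S5"), "unknown scenario")

  expect_equal(resolve_latent_dimension(diag(4)), 2L)
  expect_equal(resolve_latent_dimension(diag(c(1, 1, 1, 0))), 1L)  # floor(3/2)... rank 3
  expect_error(resolve_latent_dimension(matrix(0, 3, 3)), "rank 0")
  expect_error(resolve_latent_dimension(diag(3), 5), "out of bounds")
})

test_that("SVD initialization gives the best rank-r split", {
  f <- init_factors(diag(2), 2)
  expect_equal(tcrossprod(f$A_d0, f$A_t0), diag(2), tolerance = 1e-12)
  f2 <- init_factors(matrix(1, 2, 2), 1)
  expect_equal(tcrossprod(f2$A_d0, f2$A_t0), matrix(1, 2, 2), tolerance = 1e-12)
  set.seed(3)
  A <- matrix(rbinom(80, 1, 0.3), 10, 8)
  rk <- qr(A)$rank
  f3 <- init_factors(A, rk)
  expect_lt(norm(A - tcrossprod(f3$A_d0, f3$A_t0), "F"), 1e-8)
  expect_error(init_factors(A, 20), "exceeds")
})

test_that("PLSR initialization fits exactly, survives rank deficiency, clips", {
  F1 <- matrix(c(1, 2, 3), 3, 1)
  B <- init_regressors(F1, F1, 1)
  pred <- F1 %*% B + rep(attr(B, "intercept"), each = 3)
  expect_equal(pred, F1, tolerance = 1e-8)

  # identical columns: coefficients finite, fitted values match the
  # minimum-norm least-squares oracle
  set.seed(2)
  X <- cbind(rnorm(6), rnorm(6))
  X <- cbind(X, X[, 1])
  Y <- matrix(rnorm(12), 6, 2)
  B2 <- init_regressors(X, Y, 2)
  expect_true(all(is.finite(B2)))
  fitted <- X %*% B2 + rep(attr(B2, "intercept"), each = 6)
  Xc <- sweep(X, 2, colMeans(X))
  Yc <- sweep(Y, 2, colMeans(Y))
  oracle <- pinv_fit(Xc, Yc) + rep(colMeans(Y), each = 6)
  expect_equal(fitted, oracle, tolerance = 1e-6)

  expect_message(init_regressors(X, Y, 10), "clipped")
  expect_error(init_regressors(X[1, , drop = FALSE], Y[1, , drop = FALSE], 1),
               "at least 2 rows")
  Xna <- X; Xna[1] <- NA
  expect_error(init_regressors(Xna, Y, 1), "NA")
})

test_that("objective J reduces to hand-computed values", {
  A <- matrix(c(1, 0, 0, 1, 1, 0), 2, 3)
  hp <- tmf_hyperparameters(1, 1, 1, 1, r = 1)
  zero_model <- list(A_d = matrix(0, 2, 1), A_t = matrix(0, 3, 1),
                     B_d = matrix(0, 2, 1), B_t = matrix(0, 2, 1), hp = hp)
  expect_equal(tmf_objective(A, matrix(0, 2, 2), matrix(0, 3, 2), zero_model),
               sum(A))
  one <- matrix(1, 1, 1)
  m1 <- list(A_d = one, A_t = one, B_d = one, B_t = one, hp = hp)
  expect_equal(tmf_objective(one, one, one, m1), 4)
  # all-zero mask kills the reconstruction term
  expect_equal(tmf_objective(one, one, one, m1, mask = matrix(0, 1, 1)), 4 - 0)
  m0 <- list(A_d = matrix(0, 1, 1), A_t = matrix(0, 1, 1),
             B_d = matrix(0, 1, 1), B_t = matrix(0, 1, 1), hp = hp)
  expect_equal(tmf_objective(one, one, one, m0, mask = matrix(0, 1, 1)), 0)
})

test_that("one ALS cycle equals the literal closed-form transcription", {
  inst <- random_instance(10, m = 2, n = 2, p = 2, q = 2)
  hp <- tmf_hyperparameters(0.3, 0.7, 0.2, 0.9, r = 1, max_iter = 1)
  model <- tmf_fit(inst$A, inst$Fd, inst$Ft, hp)
  f <- init_factors(inst$A, 1)
  B_d0 <- unclass(init_regressors(inst$Fd, f$A_d0, min(1, ncol(inst$Fd), 1)))
  attr(B_d0, "intercept") <- NULL
  B_t0 <- unclass(init_regressors(inst$Ft, f$A_t0, min(1, ncol(inst$Ft), 1)))
  attr(B_t0, "intercept") <- NULL
  oracle <- literal_als_cycle(inst$A, f$A_t0, B_d0, B_t0, inst$Fd, inst$Ft,
                              0.3, 0.7, 0.2, 0.9)
  expect_equal(model$A_d, oracle$A_d, tolerance = 1e-12)
  expect_equal(model$A_t, oracle$A_t, tolerance = 1e-12)
  expect_equal(model$B_d, oracle$B_d, tolerance = 1e-12)
  expect_equal(model$B_t, oracle$B_t, tolerance = 1e-12)
})

test_that("ALS descends monotonically in full and masked fits", {
  for (seed in c(1, 2, 3)) {
    inst <- random_instance(seed)
    hp <- tmf_hyperparameters(0.1, 0.1, 0.2, 0.2, max_iter = 25)
    m <- tmf_fit(inst$A, inst$Fd, inst$Ft, hp)
    expect_true(all(diff(m$objective_trace) <=
                      1e-9 * pmax(1, m$objective_trace[-length(m$objective_trace)])))
    set.seed(seed + 100)
    W <- matrix(rbinom(length(inst$A), 1, 0.8), nrow(inst$A))
    mm <- suppressMessages(tmf_fit_masked(inst$A, W, inst$Fd, inst$Ft, hp))
    expect_true(all(diff(mm$objective_trace) <=
                      1e-9 * pmax(1, mm$objective_trace[-length(mm$objective_trace)])))
  }
})

test_that("masked fit with an all-ones mask reduces to the full fit", {
  inst <- random_instance(7, m = 12, n = 9, p = 5, q = 4)
  hp <- tmf_hyperparameters(0.5, 0.5, 0.3, 0.3, max_iter = 40)
  full <- tmf_fit(inst$A, inst$Fd, inst$Ft, hp)
  masked <- tmf_fit_masked(inst$A, matrix(1, 12, 9), inst$Fd, inst$Ft, hp)
  expect_equal(masked$A_d, full$A_d, tolerance = 1e-9)
  expect_equal(masked$A_t, full$A_t, tolerance = 1e-9)
  expect_equal(masked$B_d, full$B_d, tolerance = 1e-9)
  expect_equal(masked$B_t, full$B_t, tolerance = 1e-9)
})

test_that("masked fit beats the full fit on the masked objective", {
  set.seed(9)
  A <- matrix(c(1, 0, 0, 1), 2, 2)
  Fd <- matrix(rnorm(4), 2, 2)
  Ft <- matrix(rnorm(4), 2, 2)
  W <- matrix(c(1, 1, 1, 0), 2, 2)
  hp <- tmf_hyperparameters(0.1, 0.1, 0.1, 0.1, r = 1, max_iter = 100)
  full <- tmf_fit(A, Fd, Ft, hp)
  masked <- tmf_fit_masked(A, W, Fd, Ft, hp)
  J_masked <- tmf_objective(A, Fd, Ft, masked, mask = W)
  J_full_on_masked <- tmf_objective(A, Fd, Ft, full, mask = W)
  expect_lte(J_masked, J_full_on_masked + 1e-9)
})

test_that("each single-factor update is a coordinate minimizer", {
  inst <- random_instance(21, m = 8, n = 6, p = 4, q = 3)
  hp <- tmf_hyperparameters(0.2, 0.3, 0.4, 0.5, r = 2)
  f <- init_factors(inst$A, 2)
  A_d <- f$A_d0; A_t <- f$A_t0
  B_d <- matrix(rnorm(8), 4, 2); B_t <- matrix(rnorm(6), 3, 2)
  J_of <- function(Ad, At, Bd, Bt) {
    tmf_objective(inst$A, inst$Fd, inst$Ft,
                  list(A_d = Ad, A_t = At, B_d = Bd, B_t = Bt, hp = hp))
  }
  perturb <- function(M) M + matrix(sample(c(-1e-3, 1e-3), length(M), TRUE), nrow(M))
  A_d <- tmfdti:::update_Ad(inst$A, A_t, inst$Fd %*% B_d, hp$lambda)
  J <- J_of(A_d, A_t, B_d, B_t)
  for (i in 1:20) expect_gt(J_of(perturb(A_d), A_t, B_d, B_t), J)
  A_t <- tmfdti:::update_At(inst$A, A_d, inst$Ft %*% B_t, hp$mu)
  J <- J_of(A_d, A_t, B_d, B_t)
  for (i in 1:20) expect_gt(J_of(A_d, perturb(A_t), B_d, B_t), J)
  B_d <- tmfdti:::update_B(inst$Fd, A_d, hp$alpha)
  J <- J_of(A_d, A_t, B_d, B_t)
  for (i in 1:20) expect_gt(J_of(A_d, A_t, perturb(B_d), B_t), J)
  B_t <- tmfdti:::update_B(inst$Ft, A_t, hp$beta)
  J <- J_of(A_d, A_t, B_d, B_t)
  for (i in 1:20) expect_gt(J_of(A_d, A_t, B_d, perturb(B_t)), J)
})

test_that("B updates equal an independent ridge solver", {
  set.seed(31)
  F <- matrix(rnorm(40), 10, 4)
  Afac <- matrix(rnorm(30), 10, 3)
  got <- tmfdti:::update_B(F, Afac, 0.7)
  # ridge via augmented least squares with qr, an independent route
  Xaug <- rbind(F, sqrt(0.7) * diag(4))
  Yaug <- rbind(Afac, matrix(0, 4, 3))
  oracle <- qr.solve(Xaug, Yaug)
  expect_equal(got, oracle, tolerance = 1e-8)
})

test_that("permuting drugs permutes A_d rows and leaves B and J unchanged", {
  inst <- random_instance(17, m = 10, n = 7, p = 4, q = 4)
  hp <- tmf_hyperparameters(0.3, 0.3, 0.3, 0.3, r = 2, max_iter = 15)
  base <- tmf_fit(inst$A, inst$Fd, inst$Ft, hp)
  set.seed(99)
  perm <- sample(10)
  permuted <- tmf_fit(inst$A[perm, ], inst$Fd[perm, ], inst$Ft, hp)
  # the latent basis is defined up to a joint column sign; align before comparing
  s <- sign(colSums(permuted$A_d * base$A_d[perm, ]))
  flip <- function(M) sweep(M, 2, s, `*`)
  expect_equal(flip(permuted$A_d), base$A_d[perm, ], tolerance = 1e-6)
  expect_equal(flip(permuted$A_t), base$A_t, tolerance = 1e-6)
  expect_equal(flip(permuted$B_d), base$B_d, tolerance = 1e-6)
  expect_equal(flip(permuted$B_t), base$B_t, tolerance = 1e-6)
  expect_equal(permuted$objective_trace[length(permuted$objective_trace)],
               base$objective_trace[length(base$objective_trace)],
               tolerance = 1e-8)
})

test_that("fit reconstruction approaches the best rank-r approximation", {
  g <- generate_dataset(synthetic_spec(m = 30, n = 20, p = 8, q = 8, r = 3,
                                       density = 0.1, noise = 0, seed = 3))
  hp <- tmf_hyperparameters(1e-3, 1e-3, 1e-3, 1e-3, r = 3, max_iter = 200)
  m <- tmf_fit(g$dataset$A, g$dataset$F_d, g$dataset$F_t, hp)
  A <- g$dataset$A
  rel_err <- norm(A - tcrossprod(m$A_d, m$A_t), "F") / norm(A, "F")
  sv <- svd(A)$d
  floor_ey <- sqrt(sum(sv[-(1:3)]^2)) / sqrt(sum(sv^2))  # Eckart-Young bound
  expect_lt(rel_err, floor_ey + 0.15)
})
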