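# Shared fixtures and independent oracles for the test suite.

# Small random problem instance (binary A, Gaussian features).
random_instance <- function(seed, m = NULL, n = NULL, p = NULL, q = NULL) {
  set.seed(seed)
  if (is.null(m)) m <- sample(5:40, 1)
  if (is.null(n)) n <- sample(5:40, 1)
  if (is.null(p)) p <- sample(3:12, 1)
  if (is.null(q)) q <- sample(3:12, 1)
  A <- matrix(rbinom(m * n, 1, 0.25), m, n)
  if (sum(A) == 0) A[1, 1] <- 1
  list(A = A,
       Fd = matrix(rnorm(m * p), m, p),
       Ft = matrix(rnorm(n * q), n, q))
}

# Literal transcription of the closed-form ALS updates, written with plain
# t() / %*% / solve() so it is an independent oracle for one update cycle.
literal_als_cycle <- function(A, At, Bd, Bt, Fd, Ft, lambda, mu, alpha, beta) {
  r <- ncol(At)
  Ad <- (A %*% At + Fd %*% Bd) %*% solve(t(At) %*% At + diag(r) + lambda * diag(r))
  At <- (t(A) %*% Ad + Ft %*% Bt) %*% solve(t(Ad) %*% Ad + diag(r) + mu * diag(r))
  Bd <- solve(t(Fd) %*% Fd + alpha * diag(ncol(Fd))) %*% t(Fd) %*% Ad
  Bt <- solve(t(Ft) %*% Ft + beta * diag(ncol(Ft))) %*% t(Ft) %*% At
  list(A_d = Ad, A_t = At, B_d = Bd, B_t = Bt)
}

# Brute-force average precision: walk every prefix of the sorted list.
brute_force_aupr <- function(scores, labels) {
  ord <- order(-scores, seq_along(scores))
  lab <- labels[ord]
  precisions <- numeric(0)
  tp <- 0
  for (k in seq_along(lab)) {
    if (lab[k] == 1) {
      tp <- tp + 1
      precisions <- c(precisions, tp / k)
    }
  }
  mean(precisions)
}

# Brute-force AUC: compare every (positive, negative) pair, ties = 1/2.
brute_force_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (sp in pos) for (sn in neg) {
    total <- total + if (sp > sn) 1 else if (sp == sn) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Minimum-norm least-squares fit via the pseudoinverse (oracle for PLSR
# fitted values on rank-deficient designs).
pinv_fit <- function(X, Y) {
  sv <- svd(X)
  keep <- sv$d > max(dim(X)) * .Machine$double.eps * max(sv$d)
  B <- sv$v[, keep, drop = FALSE] %*%
    (t(sv$u[, keep, drop = FALSE]) %*% Y / sv$d[keep])
  X %*% B
}

write_lines_tmp <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}
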