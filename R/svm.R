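# RBF-kernel support vector machine trained by solving the soft-margin
# dual quadratic program with quadprog; multiclass via one-vs-one
# voting.

rbf_kernel <- function(A, B, gamma) {
  # squared Euclidean cross-distances via the expansion trick
  an <- rowSums(A^2)
  bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  exp(-gamma * pmax(d2, 0))
}

# Binary soft-margin SVM, labels in {-1, +1}.
svm_binary_fit <- function(X, y, C, gamma) {
  n <- nrow(X)
  K <- rbf_kernel(X, X, gamma)
  Dmat <- (y %o% y) * K + diag(1e-8, n)
  Amat <- cbind(y, diag(n), -diag(n))
  bvec <- c(0, rep(0, n), rep(-C, n))
  sol <- quadprog::solve.QP(Dmat, rep(1, n), Amat, bvec, meq = 1)
  alpha <- pmin(pmax(sol$solution, 0), C)
  sv <- alpha > 1e-8 * C
  f0 <- as.numeric(K %*% (alpha * y))
  margin <- sv & alpha < C * (1 - 1e-6)
  ref <- if (any(margin)) margin else sv
  b <- mean(y[ref] - f0[ref])
  list(X = X[sv, , drop = FALSE], coef = (alpha * y)[sv], b = b,
       gamma = gamma)
}

svm_binary_decision <- function(fit, Xnew) {
  as.numeric(rbf_kernel(Xnew, fit$X, fit$gamma) %*% fit$coef) + fit$b
}

# One-vs-one multiclass RBF SVM. Returns per-row predicted level index
# and a score matrix (vote counts softened by mean decision values,
# used only for tie-breaking).
svm_ovo <- function(X, y_idx, Xtest, levels_n, C, gamma) {
  pairs <- utils::combn(levels_n, 2)
  votes <- matrix(0, nrow(Xtest), levels_n)
  dsum <- matrix(0, nrow(Xtest), levels_n)
  for (p in seq_len(ncol(pairs))) {
    a <- pairs[1, p]; b <- pairs[2, p]
    rows <- y_idx %in% c(a, b)
    yy <- ifelse(y_idx[rows] == a, 1, -1)
    fit <- svm_binary_fit(X[rows, , drop = FALSE], yy, C, gamma)
    d <- svm_binary_decision(fit, Xtest)
    winner <- ifelse(d >= 0, a, b)
    for (r in seq_along(winner)) votes[r, winner[r]] <- votes[r, winner[r]] + 1
    dsum[, a] <- dsum[, a] + d
    dsum[, b] <- dsum[, b] - d
  }
  score <- votes + 1e-3 * tanh(dsum)
  list(pred = max.col(score, ties.method = "first"), score = score)
}
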