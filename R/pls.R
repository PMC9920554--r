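# PLS1 regression by NIPALS.
#
# A compact univariate-response partial-least-squares kernel. It is written
# here (rather than wrapped from an external package) because the nested
# cross-validation grid needs held-out predictions for every latent-variable
# count 1..A from a single fit, and the VIP importance profile needs direct
# access to the weight vectors W, scores T and response loadings q. Tests
# cross-check both predictions and VIP scores against mixOmics.
#
# Features are standardized (training statistics) before decomposition;
# zero-variance columns get unit scale so they contribute nothing.

pls1_fit <- function(X, y, ncomp) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  cap <- min(p, n - 1)
  ncomp_used <- min(ncomp, cap)
  x_mean <- colMeans(X)
  x_sd <- apply(X, 2, stats::sd)
  x_sd[x_sd < .Machine$double.eps] <- 1
  y_mean <- mean(y)
  E <- sweep(sweep(X, 2, x_mean), 2, x_sd, "/")
  f <- y - y_mean
  W <- matrix(0, p, ncomp_used); P <- matrix(0, p, ncomp_used)
  Tm <- matrix(0, n, ncomp_used); q <- numeric(ncomp_used)
  a <- 0
  for (h in seq_len(ncomp_used)) {
    w <- drop(crossprod(E, f))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break   # residual exhausted; later components are null
    w <- w / nw
    t_h <- drop(E %*% w)
    tt <- sum(t_h^2)
    if (tt < 1e-12) break
    p_h <- drop(crossprod(E, t_h)) / tt
    q_h <- sum(f * t_h) / tt
    E <- E - tcrossprod(t_h, p_h)
    f <- f - q_h * t_h
    W[, h] <- w; P[, h] <- p_h; Tm[, h] <- t_h; q[h] <- q_h
    a <- h
  }
  if (a == 0) { a <- 1; q[1] <- 0 }  # degenerate constant response
  structure(list(W = W[, seq_len(a), drop = FALSE],
                 P = P[, seq_len(a), drop = FALSE],
                 T = Tm[, seq_len(a), drop = FALSE],
                 q = q[seq_len(a)],
                 x_mean = x_mean, x_sd = x_sd, y_mean = y_mean,
                 ncomp_requested = ncomp, ncomp = a, cap = cap),
            class = "pls1")
}

# Predictions for every latent-variable count 1..object$ncomp.
# Returns an n x ncomp matrix; column A is the A-component prediction.
pls1_predict_all <- function(object, X) {
  X <- as.matrix(X)
  Xs <- sweep(sweep(X, 2, object$x_mean), 2, object$x_sd, "/")
  PW <- crossprod(object$P, object$W)
  R <- object$W %*% solve(PW)          # Xs %*% R reproduces the scores
  Tn <- Xs %*% R
  contrib <- sweep(Tn, 2, object$q, "*")
  A <- ncol(contrib)
  U <- matrix(0, A, A); U[upper.tri(U, diag = TRUE)] <- 1  # column-wise cumsum
  object$y_mean + contrib %*% U
}

pls1_predict <- function(object, X, ncomp = object$ncomp) {
  ncomp <- min(ncomp, object$ncomp)
  pred <- pls1_predict_all(object, X)
  pred[, ncomp]
}
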