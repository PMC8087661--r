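# Independent oracles used to cross-check the package's computations.
# Each deliberately takes a different route from the implementation it
# checks: eigendecomposition of the small covariance instead of SVD,
# proximal-gradient minimization of the penalized objective instead of
# coordinate descent, and a generic interior-point QP solve of the SVM dual
# instead of libsvm.

# PCA oracle: eigendecomposition of the n x n covariance of the centered,
# scaled matrix. Returns proportions and the p-dimensional component
# vectors (columns), oriented largest-|entry|-positive.
oracle_pca <- function(X) {
  n <- ncol(X)
  Xc <- sweep(X, 2, colMeans(X))
  Xs <- Xc / sqrt(n - 1)
  C <- crossprod(Xs) # n x n
  eig <- eigen(C, symmetric = TRUE)
  lambda <- pmax(eig$values, 0)
  U <- matrix(0, nrow(X), n)
  for (k in seq_len(n)) {
    if (lambda[k] > 1e-12) {
      u <- Xs %*% eig$vectors[, k] / sqrt(lambda[k])
      i <- which.max(abs(u))
      if (u[i] < 0) u <- -u
      U[, k] <- u
    }
  }
  list(
    proportions = lambda / sum(lambda),
    singular_values = sqrt(lambda),
    components = U
  )
}

# LASSO-logistic oracle: FISTA (accelerated proximal gradient) on the
# standardized penalized objective
#   (1/N) sum_i [log(1 + exp(eta_i)) - y_i eta_i] + lambda * ||beta||_1,
# intercept unpenalized. Features are standardized with population SDs
# (denominator N) and coefficients mapped back to the original scale, the
# same reporting convention as the fitting routine under test.
oracle_lasso_logistic <- function(X, y, lambda, max_iter = 200000L,
                                  tol = 1e-12) {
  N <- nrow(X)
  mu <- colMeans(X)
  s <- apply(X, 2, function(x) sqrt(mean((x - mean(x))^2)))
  s[s == 0] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, s, `/`)
  Z <- cbind(1, Xs)
  L <- max(eigen(crossprod(Z), symmetric = TRUE, only.values = TRUE)$values) / (4 * N)
  step <- 1 / L
  p1 <- ncol(X)
  beta <- numeric(p1)
  b0 <- 0
  yb <- beta
  yb0 <- b0
  t_k <- 1
  soft <- function(v, thr) sign(v) * pmax(abs(v) - thr, 0)
  obj <- function(b0, beta) {
    eta <- b0 + Xs %*% beta
    mean(log1p(exp(eta)) - y * eta) + lambda * sum(abs(beta))
  }
  last <- obj(b0, beta)
  for (it in seq_len(max_iter)) {
    eta <- yb0 + Xs %*% yb
    p <- 1 / (1 + exp(-eta))
    g_beta <- as.numeric(crossprod(Xs, p - y)) / N
    g_b0 <- mean(p - y)
    beta_new <- soft(yb - step * g_beta, step * lambda)
    b0_new <- yb0 - step * g_b0
    t_new <- (1 + sqrt(1 + 4 * t_k^2)) / 2
    yb <- beta_new + ((t_k - 1) / t_new) * (beta_new - beta)
    yb0 <- b0_new + ((t_k - 1) / t_new) * (b0_new - b0)
    beta <- beta_new
    b0 <- b0_new
    t_k <- t_new
    if (it %% 200L == 0L) {
      cur <- obj(b0, beta)
      if (abs(last - cur) < tol * (abs(last) + 1)) break
      last <- cur
    }
  }
  list(
    intercept = b0 - sum(beta * mu / s),
    coefficients = beta / s
  )
}

# SVM dual oracle: solve
#   min 1/2 a' Q a - 1'a,  0 <= a <= C,  y'a = 0,  Q = (yy') * K
# with kernlab's generic interior-point QP solver, then assemble the
# decision function f(x) = sum_i a_i y_i K(x_i, x) + b.
oracle_svm_decision <- function(X, y01, C, gamma, newX = X) {
  yy <- ifelse(y01 == 1, 1, -1)
  rbf <- function(A, B) {
    d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * A %*% t(B)
    exp(-gamma * pmax(d2, 0))
  }
  K <- rbf(X, X)
  n <- nrow(X)
  Q <- (yy %o% yy) * K + diag(1e-8, n)
  # the interior-point solve can go singular at the highest precision once
  # most multipliers sit on their bounds; back off sigf until it solves
  sol <- NULL
  for (sigf in c(9, 8, 7, 6)) {
    sol <- tryCatch(
      kernlab::ipop(
        c = matrix(-1, n, 1), H = Q,
        A = matrix(yy, 1, n), b = 0,
        l = matrix(0, n, 1), u = matrix(C, n, 1), r = 0,
        sigf = sigf, maxiter = 400
      ),
      error = function(e) NULL
    )
    if (!is.null(sol)) break
  }
  if (is.null(sol)) stop("dual QP oracle failed to converge")
  a <- as.numeric(kernlab::primal(sol))
  eps <- C * 1e-5
  free <- which(a > eps & a < C - eps)
  sv_term <- function(Knew) as.numeric(Knew %*% (a * yy))
  b <- if (length(free) > 0) {
    mean(yy[free] - sv_term(K[free, , drop = FALSE]))
  } else {
    # all multipliers on their bounds: take the midpoint of the KKT
    # interval for the bias (libsvm's convention)
    g <- sv_term(K)
    lo <- suppressWarnings(max(
      (1 - g)[a <= eps & yy == 1],
      (-1 - g)[a >= C - eps & yy == -1]
    ))
    hi <- suppressWarnings(min(
      (-1 - g)[a <= eps & yy == -1],
      (1 - g)[a >= C - eps & yy == 1]
    ))
    (lo + hi) / 2
  }
  sv_term(rbf(newX, X)) + b
}

# Closed-form null-model LOOCV binomial deviance: each held-out probability
# is the training-fold class rate.
null_loocv_deviance <- function(y, clip = 1e-8) {
  m <- length(y)
  total <- 0
  for (i in seq_len(m)) {
    p <- mean(y[-i])
    p <- min(max(p, clip), 1 - clip)
    total <- total - 2 * (y[i] * log(p) + (1 - y[i]) * log(1 - p))
  }
  total
}

# Small helper: a seeded random feature table.
random_feature_table <- function(p, m, seed, family = "features",
                                 labels = rep_len(c(1L, 0L), m)) {
  set.seed(seed)
  feature_table(matrix(rnorm(p * m), p, m),
    feature_names = sprintf("F%03d", seq_len(p)),
    labels = labels, family = family
  )
}
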