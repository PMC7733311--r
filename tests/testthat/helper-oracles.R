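# Independent oracles and fixture builders. Everything here must stay
# independent of the package code paths it is used to check.

# direct-formula E-step (responsibilities via mvtnorm densities)
ref_estep <- function(X, weights, means, covs) {
  dens <- sapply(seq_along(weights), function(k) {
    weights[k] * mvtnorm::dmvnorm(X, means[k, ], covs[[k]])
  })
  dens <- matrix(dens, nrow = nrow(X))
  dens / rowSums(dens)
}

# brute-force M-step as elementwise weighted sums
ref_mstep <- function(X, R) {
  K <- ncol(R); N <- nrow(X)
  w <- colSums(R) / N
  mu <- matrix(0, K, 2); covs <- vector("list", K)
  for (k in seq_len(K)) {
    nk <- sum(R[, k])
    mu[k, ] <- c(sum(R[, k] * X[, 1]), sum(R[, k] * X[, 2])) / nk
    s <- matrix(0, 2, 2)
    for (i in seq_len(N)) {
      d <- X[i, ] - mu[k, ]
      s <- s + R[i, k] * (d %*% t(d))
    }
    covs[[k]] <- s / nk
  }
  list(weights = w, means = mu, covs = covs)
}

# generic QP reference for the soft-margin SVM dual via quadprog;
# a ridge keeps the (PSD) kernel strictly positive definite
ref_qp_svm <- function(K, y, C, ridge = 1e-8) {
  n <- length(y)
  D <- (y %*% t(y)) * K + diag(ridge, n)
  d <- rep(1, n)
  A <- cbind(y, diag(n), -diag(n))
  b0 <- c(0, rep(0, n), rep(-C, n))
  sol <- quadprog::solve.QP(D, d, A, b0, meq = 1)
  alpha <- pmin(pmax(sol$solution, 0), C)
  sv <- which(alpha > 1e-6 & alpha < C - 1e-6)
  f0 <- as.numeric(K %*% (alpha * y))
  b <- if (length(sv)) mean(y[sv] - f0[sv]) else {
    mean(range(y - f0))
  }
  list(alpha = alpha, b = b,
       decision = function(Kq) as.numeric(Kq %*% (alpha * y) + b))
}

# construct a gmm_model directly from known parameters
make_model <- function(weights, means, covs, n_obs = 100L) {
  gazexpert:::new_gmm_model(weights, means, covs,
                            log_likelihood = NA_real_, n_obs = n_obs,
                            converged = TRUE, n_iter = 1L)
}

# random well-formed fixation records
random_records <- function(n, subjects = c("E01", "E02", "L01"),
                           images = c("P1", "P2")) {
  sid <- sample(subjects, n, replace = TRUE)
  data.frame(subject_id = sid,
             group = ifelse(grepl("^E", sid), "expert", "layman"),
             image_id = sample(images, n, replace = TRUE),
             x = runif(n, 0, 1920), y = runif(n, 0, 1200),
             duration_ms = runif(n, 40, 600))
}

# a small labelled feature matrix with optional planted separation in
# column `signal_col`
make_fm <- function(n_per_group = 8, p = 6, signal_col = NULL,
                    delta = 4, K = p / 2) {
  n <- 2 * n_per_group
  v <- matrix(rnorm(n * p), n, p)
  labels <- rep(c("expert", "layman"), each = n_per_group)
  if (!is.null(signal_col)) {
    v[labels == "expert", signal_col] <- v[labels == "expert",
                                           signal_col] + delta
  }
  gazexpert:::new_feature_matrix(
    v, sprintf("S%02d", seq_len(n)), labels, "P1", K,
    normalization = "Z0")
}

# two separable Gaussian blobs in d dimensions
make_blobs <- function(n_per_class = 10, d = 2, sep = 8) {
  x <- rbind(matrix(rnorm(n_per_class * d), ncol = d),
             matrix(rnorm(n_per_class * d, mean = sep), ncol = d))
  y <- rep(c("expert", "layman"), each = n_per_class)
  list(x = x, y = y)
}
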