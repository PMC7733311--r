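test_that("component density matches closed forms and integrates to 1", {
  expect_equal(component_density(c(0, 0), c(0, 0), diag(2)), 1 / (2 * pi),
               tolerance = 1e-12)
  expect_equal(component_density(c(1, 0), c(0, 0), diag(2)),
               exp(-0.5) / (2 * pi), tolerance = 1e-12)

  S <- matrix(c(4, 1.2, 1.2, 2), 2, 2)
  # quadrature over a wide grid
  g <- seq(-12, 12, length.out = 401)
  h <- g[2] - g[1]
  grid <- as.matrix(expand.grid(g, g))
  expect_equal(sum(component_density(grid, c(0, 0), S)) * h^2, 1,
               tolerance = 1e-4)

  skip_if_not_installed("mvtnorm")
  set.seed(2)
  pts <- matrix(rnorm(20, sd = 3), ncol = 2)
  expect_equal(component_density(pts, c(0.5, -1), S),
               mvtnorm::dmvnorm(pts, c(0.5, -1), S), tolerance = 1e-12)

  expect_error(component_density(c(0, 0), c(0, 0),
                                 matrix(c(1, 1, 1, 1), 2, 2)),
               class = "gazexpert_numeric_error")
})

test_that("e_step matches the direct responsibility formula", {
  # K = 1: certain membership
  m1 <- make_model(1, matrix(c(5, 5), 1), list(diag(2)))
  a1 <- e_step(matrix(rnorm(10), ncol = 2), m1)
  expect_equal(unname(a1$responsibilities[, 1]), rep(1, 5))

  # identical components: symmetric split
  m2 <- make_model(c(0.5, 0.5), rbind(c(0, 0), c(0, 0)),
                   list(diag(2), diag(2)))
  a2 <- e_step(matrix(rnorm(12), ncol = 2), m2)
  expect_equal(unname(a2$responsibilities),
               matrix(0.5, 6, 2), tolerance = 1e-12)

  # random instance vs direct formula
  skip_if_not_installed("mvtnorm")
  set.seed(31)
  X <- matrix(rnorm(10, sd = 2), 5, 2)
  w <- c(0.2, 0.5, 0.3)
  mu <- matrix(rnorm(6, sd = 3), 3, 2)
  covs <- replicate(3, {
    A <- matrix(rnorm(4), 2, 2); crossprod(A) + diag(0.5, 2)
  }, simplify = FALSE)
  m3 <- make_model(w, mu, covs)
  a3 <- e_step(X, m3)
  expect_equal(a3$responsibilities, ref_estep(X, w, mu, covs),
               tolerance = 1e-10)
  expect_equal(rowSums(a3$responsibilities), rep(1, 5), tolerance = 1e-9)
  expect_equal(a3$cluster_mass, colSums(a3$responsibilities))
})

test_that("m_step matches brute-force weighted estimation", {
  set.seed(17)
  X <- matrix(rnorm(12, sd = 2), 6, 2)

  # hard assignment reduces to per-subset moments
  lab <- c(1, 1, 1, 2, 2, 2)
  R <- outer(lab, 1:2, "==") * 1
  m <- m_step(X, R)
  expect_equal(m$means[1, ], colMeans(X[1:3, ]), ignore_attr = TRUE)
  expect_equal(m$covs[[1]], crossprod(scale(X[1:3, ], scale = FALSE)) / 3,
               ignore_attr = TRUE)

  # uniform responsibilities: both means at the grand mean
  mu2 <- m_step(X, matrix(0.5, 6, 2))$means
  expect_equal(mu2[1, ], colMeans(X), ignore_attr = TRUE)
  expect_equal(mu2[2, ], colMeans(X), ignore_attr = TRUE)

  # random responsibilities vs elementwise oracle
  R3 <- matrix(runif(18), 6, 3)
  R3 <- R3 / rowSums(R3)
  got <- m_step(X, R3)
  ref <- ref_mstep(X, R3)
  expect_equal(got$weights, ref$weights, tolerance = 1e-10)
  expect_equal(got$means, ref$means, tolerance = 1e-10)
  for (k in 1:3) expect_equal(got$covs[[k]], ref$covs[[k]],
                              tolerance = 1e-10)

  expect_error(m_step(X, cbind(rep(1, 6), 0)),
               class = "gazexpert_degenerate_error")
})

test_that("fit_em: K = 1 closed form, recovery, restart dominance", {
  set.seed(5)
  X <- matrix(rnorm(200, sd = 3), ncol = 2)
  f1 <- fit_em(X, 1)
  expect_equal(f1$means[1, ], colMeans(X), ignore_attr = TRUE)
  expect_equal(f1$covs[[1]], crossprod(scale(X, scale = FALSE)) / nrow(X),
               tolerance = 1e-4, ignore_attr = TRUE)

  # two well-separated clusters: parameter recovery
  X2 <- rbind(matrix(rnorm(400), ncol = 2),
              matrix(rnorm(400, mean = 10), ncol = 2))
  f2 <- fit_em(X2, 2, seed = 9)
  ord <- order(f2$means[, 1])
  expect_lt(max(abs(f2$means[ord[1], ] - 0)), 0.5)
  expect_lt(max(abs(f2$means[ord[2], ] - 10)), 0.5)
  expect_lt(max(abs(f2$weights - 0.5)), 0.05)

  # best-of-restarts dominates a single restart
  single <- fit_em(X2, 3, n_restarts = 1, seed = 4)
  multi <- fit_em(X2, 3, n_restarts = 8, seed = 4)
  expect_gte(multi$log_likelihood, single$log_likelihood - 1e-8)

  expect_error(fit_em(X[1:2, ], 5),
               class = "gazexpert_insufficient_data_error")
})

test_that("EM log-likelihood is non-decreasing and reaches a fixed point", {
  set.seed(12)
  for (rep in 1:20) {
    n <- sample(30:80, 1)
    K <- sample(1:4, 1)
    X <- matrix(rnorm(2 * n, sd = sample(1:5, 1)), ncol = 2)
    f <- fit_em(X, K, n_restarts = 2, seed = rep)
    expect_true(all(diff(f$ll_trace) > -1e-8))
  }

  # E/M applied to a converged model barely moves the parameters
  X <- rbind(matrix(rnorm(300), ncol = 2),
             matrix(rnorm(300, mean = 8), ncol = 2))
  f <- fit_em(X, 2, seed = 3, tol = 1e-10, max_iter = 2000)
  refit <- m_step(X, e_step(X, f), eps = f$eps)
  expect_equal(refit$means, f$means, tolerance = 1e-4)
  expect_equal(refit$weights, f$weights, tolerance = 1e-6)
})

test_that("translation invariance of the fitted mixture", {
  set.seed(21)
  X <- rbind(matrix(rnorm(200, sd = 2), ncol = 2),
             matrix(rnorm(200, mean = 15, sd = 2), ncol = 2))
  shift <- c(100, -50)
  fa <- fit_em(X, 2, seed = 6)
  fb <- fit_em(sweep(X, 2, -shift), 2, seed = 6)
  ord_a <- order(fa$means[, 1])
  ord_b <- order(fb$means[, 1])
  expect_equal(fb$means[ord_b, ],
               sweep(fa$means[ord_a, ], 2, -shift), tolerance = 1e-3)
  expect_equal(fb$weights[ord_b], fa$weights[ord_a], tolerance = 1e-6)
  for (i in 1:2) {
    expect_equal(fb$covs[[ord_b[i]]], fa$covs[[ord_a[i]]],
                 tolerance = 1e-3)
  }
  # BIC differences between K are translation-invariant
  ga <- fit_em(X, 1)
  gb <- fit_em(sweep(X, 2, -shift), 1)
  expect_equal(bic(fa) - bic(ga), bic(fb) - bic(gb), tolerance = 1e-3)
})

test_that("bic follows -2 logLik + (6K - 1) log N", {
  m <- make_model(1, matrix(c(0, 0), 1), list(diag(2)), n_obs = 100L)
  m$log_likelihood <- -100
  expect_equal(bic(m), 200 + 5 * log(100), tolerance = 1e-9)

  m2 <- m
  m2$n_obs <- 200L
  expect_equal(bic(m2) - bic(m), 5 * log(2), tolerance = 1e-12)

  m$n_obs <- 0L
  expect_error(bic(m), class = "gazexpert_numeric_error")
})

test_that("select_k finds a single blob and keeps the full trace", {
  set.seed(14)
  X <- matrix(rnorm(600, sd = 2), ncol = 2)
  sel <- select_k(X, 1, 5, n_restarts = 3, seed = 2)
  expect_equal(sel$best_k, 1L)
  expect_equal(nrow(sel$trace), 5L)
  expect_equal(sel$trace$K, 1:5)
  expect_true(all(is.finite(sel$trace$bic)))
})

test_that("assignment rules: ratio vs MAP", {
  set.seed(33)
  X <- matrix(rnorm(40, sd = 4), ncol = 2)
  m1 <- make_model(1, matrix(c(0, 0), 1), list(diag(2)))
  expect_true(all(assign_clusters(X, m1, "paper_ratio")$labels == 1))
  expect_true(all(assign_clusters(X, m1, "map")$labels == 1))

  # equal cluster masses: the rules agree (common positive factor)
  msym <- make_model(c(0.5, 0.5), rbind(c(-3, 0), c(3, 0)),
                     list(diag(2), diag(2)))
  Xs <- rbind(matrix(rnorm(30, -3, 1), ncol = 2),
              matrix(rnorm(30, 3, 1), ncol = 2))
  Xs <- rbind(Xs, -Xs)  # symmetrize so masses match exactly
  ar <- assign_clusters(Xs, msym, "paper_ratio")
  am <- assign_clusters(Xs, msym, "map")
  if (max(abs(ar$cluster_mass - rev(ar$cluster_mass))) < 1e-6) {
    expect_equal(ar$labels, am$labels)
  }

  # brute-force p_ik / p_k labels on an asymmetric instance
  masym <- make_model(c(0.8, 0.2), rbind(c(0, 0), c(4, 0)),
                      list(diag(2), diag(2) * 2))
  Xa <- matrix(rnorm(24, 1, 3), ncol = 2)
  a <- assign_clusters(Xa, masym, "paper_ratio")
  resp <- e_step(Xa, masym)$responsibilities
  pk <- colSums(resp)
  ref_labels <- apply(sweep(resp, 2, pk, "/"), 1, which.max)
  expect_equal(a$labels, ref_labels)
})

test_that("cluster ellipses: geometry and Monte-Carlo coverage", {
  m <- make_model(c(0.5, 0.5), rbind(c(0, 0), c(10, 10)),
                  list(diag(2), diag(c(4, 1))))
  e <- cluster_ellipses(m, 0.95)
  expect_equal(e$semi_major[1], sqrt(qchisq(0.95, 2)), tolerance = 1e-9)
  expect_equal(e$semi_major[1], e$semi_minor[1], tolerance = 1e-9)
  expect_equal(e$semi_major[2] / e$semi_minor[2], 2, tolerance = 1e-9)
  expect_equal(abs(cos(e$angle[2])), 1, tolerance = 1e-9)  # along x

  set.seed(99)
  S <- matrix(c(9, 3, 3, 4), 2, 2)
  msing <- make_model(1, matrix(c(0, 0), 1), list(S))
  es <- cluster_ellipses(msing, 0.95)
  pts <- matrix(rnorm(2e4), ncol = 2) %*% chol(S)
  ev <- eigen(S, symmetric = TRUE)
  proj <- pts %*% ev$vectors
  inside <- (proj[, 1] / es$semi_major)^2 + (proj[, 2] / es$semi_minor)^2 <= 1
  expect_equal(mean(inside), 0.95, tolerance = 0.02)
})

test_that("gmm models survive a JSON round-trip", {
  set.seed(55)
  X <- matrix(rnorm(120, sd = 3), ncol = 2)
  f <- fit_em(X, 2, seed = 1)
  path <- withr::local_tempfile(fileext = ".json")
  write_gmm(f, path)
  back <- read_gmm(path)
  expect_equal(back$weights, f$weights, tolerance = 1e-12)
  expect_equal(back$means, f$means, tolerance = 1e-12)
  expect_equal(back$covs, f$covs, tolerance = 1e-12)
  expect_equal(back$log_likelihood, f$log_likelihood, tolerance = 1e-12)
})
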