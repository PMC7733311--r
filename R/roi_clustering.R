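#' @title Gaussian-mixture ROI models
#'
#' @description Regions of interest are modelled as components of a
#' bivariate Gaussian mixture over fixation positions,
#' \deqn{f(x) = \sum_{k=1}^{K} \pi_k \, f(x; \mu_k, R_k),}
#' fitted by expectation-maximization. A fitted model (class `gmm_model`)
#' stores component weights \eqn{\pi_k}, mean vectors \eqn{\mu_k} (pixels)
#' and 2x2 covariance matrices \eqn{R_k} (pixels^2), together with the
#' final log-likelihood, the number of observations, and convergence
#' bookkeeping.
#'
#' @name gmm_model
NULL

new_gmm_model <- function(weights, means, covs, log_likelihood, n_obs,
                          converged = NA, n_iter = NA_integer_,
                          eps = 0, ll_trace = numeric()) {
  w <- as.numeric(weights)
  stopifnot(length(w) >= 1L, abs(sum(w) - 1) < 1e-9)
  structure(list(weights = w,
                 means = matrix(as.numeric(means), ncol = 2),
                 covs = lapply(covs, function(s) {
                   s <- matrix(as.numeric(s), 2, 2)
                   (s + t(s)) / 2
                 }),
                 log_likelihood = log_likelihood,
                 n_obs = as.integer(n_obs),
                 converged = converged, n_iter = n_iter,
                 eps = eps, ll_trace = ll_trace),
            class = "gmm_model")
}

n_components <- function(model) length(model$weights)

#' @export
print.gmm_model <- function(x, ...) {
  cat(sprintf(
    "<gmm_model> K = %d, N = %d, logLik = %.3f, BIC = %.3f, %s (%d iter)\n",
    n_components(x), x$n_obs, x$log_likelihood, bic(x),
    if (isTRUE(x$converged)) "converged" else "not converged", x$n_iter))
  invisible(x)
}

#' Bivariate normal component density
#'
#' Density of a single mixture component at one or more points, computed
#' from the closed-form 2x2 inverse. Units are 1/pixels^2.
#'
#' @param point length-2 vector or N x 2 matrix.
#' @param mean component mean, length-2 vector.
#' @param cov 2x2 symmetric positive-definite covariance.
#' @param log return log-density?
#' @return Numeric vector of densities.
#' @export
component_density <- function(point, mean, cov, log = FALSE) {
  p <- if (is.matrix(point)) point else matrix(point, ncol = 2)
  a <- cov[1, 1]; b <- (cov[1, 2] + cov[2, 1]) / 2; d <- cov[2, 2]
  det <- a * d - b * b
  if (!(det > 0) || !(a > 0)) {
    stop_gx("covariance matrix is not positive definite",
            "gazexpert_numeric_error")
  }
  dx <- p[, 1] - mean[1]; dy <- p[, 2] - mean[2]
  q <- (d * dx^2 - 2 * b * dx * dy + a * dy^2) / det
  lg <- -log(2 * pi) - 0.5 * base::log(det) - 0.5 * q
  if (log) lg else exp(lg)
}

#' E-step: posterior responsibilities
#'
#' Computes, in log-space, the posterior probability \eqn{p_{ik}} that
#' fixation i arose from component k,
#' \eqn{p_{ik} = \pi_k f(x_i;\Theta_k) / \sum_j \pi_j f(x_i;\Theta_j)},
#' plus the observed-data log-likelihood.
#'
#' @param points N x 2 matrix (or [fixation_dataset()]).
#' @param model a `gmm_model`.
#' @return List of class `cluster_assignment` with `responsibilities`
#'   (N x K, rows sum to 1), `cluster_mass` (column sums \eqn{p_k}),
#'   `log_likelihood`, and `labels` (`NULL`; see [assign_clusters()]).
#' @export
e_step <- function(points, model) {
  X <- as_points(points)
  K <- n_components(model)
  lp <- vapply(seq_len(K), function(k) {
    log(model$weights[k]) +
      component_density(X, model$means[k, ], model$covs[[k]], log = TRUE)
  }, numeric(nrow(X)))
  lp <- matrix(lp, nrow = nrow(X))
  mx <- apply(lp, 1L, max)
  if (any(!is.finite(mx))) {
    stop_gx(sprintf("all component densities underflow at observation %d",
                    which(!is.finite(mx))[1L]),
            "gazexpert_numeric_error")
  }
  lse <- mx + log(rowSums(exp(lp - mx)))
  resp <- exp(lp - lse)
  structure(list(responsibilities = resp,
                 cluster_mass = colSums(resp),
                 log_likelihood = sum(lse), labels = NULL),
            class = "cluster_assignment")
}

#' M-step: re-estimate mixture parameters
#'
#' Given responsibilities, computes the weighted maximum-likelihood
#' update: \eqn{\pi_k = N_k/N}, \eqn{\mu_k} the responsibility-weighted
#' mean and \eqn{R_k} the responsibility-weighted covariance about
#' \eqn{\mu_k} (denominator \eqn{N_k}), with `eps` added to the diagonal
#' as a regularization floor.
#'
#' @param points N x 2 matrix (or [fixation_dataset()]).
#' @param resp a `cluster_assignment` (or bare N x K matrix) whose rows
#'   sum to 1.
#' @param eps diagonal regularization added to each covariance.
#' @return A `gmm_model` (log-likelihood not evaluated: `NA`).
#' @export
m_step <- function(points, resp, eps = 0) {
  X <- as_points(points)
  R <- if (inherits(resp, "cluster_assignment")) resp$responsibilities
  else as.matrix(resp)
  stopifnot(nrow(R) == nrow(X))
  if (max(abs(rowSums(R) - 1)) > 1e-6) {
    stop("responsibility rows must sum to 1")
  }
  nk <- colSums(R)
  if (any(nk < 1e-12)) {
    stop_gx(sprintf("cluster %d has vanishing responsibility mass",
                    which(nk < 1e-12)[1L]),
            "gazexpert_degenerate_error")
  }
  N <- nrow(X)
  mu <- sweep(crossprod(R, X), 1L, nk, "/")
  covs <- lapply(seq_along(nk), function(k) {
    Xc <- sweep(X, 2L, mu[k, ])
    S <- crossprod(Xc * R[, k], Xc) / nk[k]
    S + diag(eps, 2)
  })
  new_gmm_model(weights = nk / N, means = mu, covs = covs,
                log_likelihood = NA_real_, n_obs = N, eps = eps)
}

# k-means++-style seeding: first centre uniform, later centres with
# probability proportional to squared distance to the nearest chosen one
kmeanspp_init <- function(X, K) {
  N <- nrow(X)
  centres <- integer(K)
  centres[1L] <- sample.int(N, 1L)
  if (K > 1L) {
    d2 <- colSums((t(X) - X[centres[1L], ])^2)
    for (k in 2L:K) {
      p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / N, N)
      centres[k] <- sample.int(N, 1L, prob = p)
      d2 <- pmin(d2, colSums((t(X) - X[centres[k], ])^2))
    }
  }
  X[centres, , drop = FALSE]
}

default_eps <- function(X) {
  g <- cov(X)
  1e-6 * sum(diag(g)) / 2
}

# Ward agglomeration on a deterministic subsample: a restart-free way to
# cover every well-separated basin at once (small clusters that random
# seeding misses survive agglomeration until late merges)
hc_seeds <- function(X, K, max_points = 1000L) {
  idx <- unique(round(seq(1L, nrow(X), length.out = min(max_points,
                                                        nrow(X)))))
  Xs <- X[idx, , drop = FALSE]
  grp <- stats::cutree(stats::hclust(dist(Xs), method = "ward.D2"), k = K)
  t(vapply(seq_len(K), function(k)
    colMeans(Xs[grp == k, , drop = FALSE]), numeric(2)))
}

# refine seeded means with a short Lloyd k-means pass and start EM from
# the hard partition's local moments; a start at the global covariance
# makes the initial responsibilities nearly uniform and strands EM in
# merged/split local optima
em_start <- function(X, seeds, gcov, eps) {
  K <- nrow(seeds)
  N <- nrow(X)
  km <- tryCatch(
    suppressWarnings(stats::kmeans(X, centers = seeds, iter.max = 10L,
                                   algorithm = "Lloyd")),
    error = function(e) NULL)
  if (is.null(km)) {
    return(list(mu = seeds, S = array(gcov, dim = c(2, 2, K)),
                w = rep(1 / K, K)))
  }
  mu <- km$centers
  S <- array(0, dim = c(2, 2, K))
  w <- pmax(km$size, 1) / sum(pmax(km$size, 1))
  for (k in seq_len(K)) {
    idx <- which(km$cluster == k)
    S[, , k] <- if (length(idx) >= 3L) {
      cov(X[idx, , drop = FALSE]) + diag(eps, 2)
    } else {
      gcov / K
    }
  }
  list(mu = mu, S = S, w = w)
}

#' Fit a Gaussian mixture by EM
#'
#' Alternates E and M steps until the absolute change in log-likelihood
#' falls below `tol` or `max_iter` is reached. Because EM is sensitive to
#' its starting point, `n_restarts` independent initializations are run
#' (k-means++-style seeding of the means from the data; covariances start
#' at the global covariance, weights uniform) and the fit with the highest
#' final log-likelihood is returned. Covariances carry a diagonal
#' regularization floor `eps` (default `1e-6 * trace(global cov)/2`) so
#' near-degenerate clusters cannot collapse to singular matrices.
#'
#' @param points N x 2 matrix (or [fixation_dataset()]).
#' @param K number of components, `1 <= K <= N`.
#' @param init `"kmeans++"` (default) or `"random"` (uniform draw of K
#'   distinct points as means).
#' @param tol absolute log-likelihood convergence tolerance.
#' @param max_iter iteration cap per restart.
#' @param n_restarts number of random initializations.
#' @param seed optional integer seed controlling initialization.
#' @param eps covariance regularization; `NULL` = data-driven default.
#' @return A `gmm_model`.
#' @export
fit_em <- function(points, K, init = c("kmeans++", "random"),
                   tol = 1e-6, max_iter = 500L, n_restarts = 10L,
                   seed = NULL, eps = NULL) {
  init <- match.arg(init)
  X <- as_points(points)
  N <- nrow(X)
  K <- as.integer(K)
  if (K < 1L) stop("K must be >= 1")
  if (N < K) {
    stop_gx(sprintf("insufficient data: N = %d < K = %d", N, K),
            "gazexpert_insufficient_data_error")
  }
  eps <- eps %||% default_eps(X)
  if (!is.null(seed)) set.seed(seed)
  if (K == 1L) {
    # closed-form MLE, no latent structure
    mu <- colMeans(X)
    S <- crossprod(sweep(X, 2L, mu)) / N + diag(eps, 2)
    model <- new_gmm_model(1, matrix(mu, 1), list(S), NA_real_, N,
                           converged = TRUE, n_iter = 1L, eps = eps)
    model$log_likelihood <- e_step(X, model)$log_likelihood
    model$ll_trace <- model$log_likelihood
    return(model)
  }
  gcov <- cov(X) + diag(eps, 2)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    # first restart: deterministic Ward agglomeration; the rest explore
    # random k-means++ seedings
    seeds <- if (r == 1L && init == "kmeans++") {
      hc_seeds(X, K)
    } else {
      switch(init,
             "kmeans++" = kmeanspp_init(X, K),
             "random" = X[sample.int(N, K), , drop = FALSE])
    }
    st <- em_start(X, seeds, gcov, eps)
    fit <- gmm_em_cpp(X, st$mu, st$S, st$w, tol, max_iter, eps)
    if (fit$status != 0) next
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  if (is.null(best)) {
    stop_gx("all EM restarts ended in a degenerate fit",
            "gazexpert_fit_error")
  }
  new_gmm_model(weights = best$weights, means = best$means,
                covs = lapply(seq_len(K), function(k) best$covs[, , k]),
                log_likelihood = best$loglik, n_obs = N,
                converged = best$converged, n_iter = best$n_iter,
                eps = eps, ll_trace = best$ll_trace)
}

#' Bayesian information criterion of a fitted mixture
#'
#' `-2 logLik + m log(N)` with `m = 6K - 1` free parameters for a
#' K-component bivariate mixture with full covariances (K-1 weights, 2K
#' means, 3K covariance entries). Smaller is better.
#'
#' @param model a fitted `gmm_model`.
#' @return The BIC value.
#' @export
bic <- function(model) {
  stopifnot(inherits(model, "gmm_model"))
  if (model$n_obs == 0L) {
    stop_gx("BIC undefined for a model fitted on zero observations",
            "gazexpert_numeric_error")
  }
  K <- n_components(model)
  -2 * model$log_likelihood + (6 * K - 1) * log(model$n_obs)
}

#' Choose the number of ROIs by BIC
#'
#' Fits mixtures for every K in `k_min:k_max` and returns the fit that
#' minimizes the BIC together with the whole BIC-versus-K trace. A K whose
#' every restart degenerates is recorded in the trace (`error` column) and
#' skipped.
#'
#' @inheritParams fit_em
#' @param k_min,k_max inclusive search range.
#' @return List of class `gmm_selection`: `model` (best fit), `best_k`,
#'   and `trace` (data frame: `K`, `log_likelihood`, `bic`, `converged`,
#'   `error`).
#' @export
select_k <- function(points, k_min = 2L, k_max = 20L, init = "kmeans++",
                     tol = 1e-6, max_iter = 500L, n_restarts = 10L,
                     seed = NULL) {
  X <- as_points(points)
  stopifnot(k_min >= 1L, k_min <= k_max)
  if (k_max > nrow(X)) stop("k_max may not exceed the number of points")
  ks <- seq.int(k_min, k_max)
  seeds <- if (is.null(seed)) rep(list(NULL), length(ks)) else
    as.list(child_seeds(seed, length(ks), salt = 7L))
  rows <- lapply(seq_along(ks), function(i) {
    fit <- tryCatch(
      fit_em(X, ks[i], init = init, tol = tol, max_iter = max_iter,
             n_restarts = n_restarts, seed = seeds[[i]]),
      gazexpert_error = function(e) e)
    if (inherits(fit, "error")) {
      list(model = NULL,
           row = data.frame(K = ks[i], log_likelihood = NA_real_,
                            bic = NA_real_, converged = NA,
                            error = conditionMessage(fit)))
    } else {
      list(model = fit,
           row = data.frame(K = ks[i], log_likelihood = fit$log_likelihood,
                            bic = bic(fit), converged = fit$converged,
                            error = NA_character_))
    }
  })
  trace <- do.call(rbind, lapply(rows, `[[`, "row"))
  ok <- which(!is.na(trace$bic))
  if (!length(ok)) {
    stop_gx("model fitting failed for every K in the search range",
            "gazexpert_fit_error")
  }
  best <- ok[which.min(trace$bic[ok])]
  structure(list(model = rows[[best]]$model, best_k = trace$K[best],
                 trace = trace),
            class = "gmm_selection")
}

#' @export
print.gmm_selection <- function(x, ...) {
  cat(sprintf("<gmm_selection> best K = %d by BIC (searched %d..%d)\n",
              x$best_k, min(x$trace$K), max(x$trace$K)))
  invisible(x)
}

#' Assign fixations to clusters
#'
#' Two rules are available. `"paper_ratio"` (default) assigns observation
#' i to the component maximizing \eqn{p_{ik}/p_k}, where
#' \eqn{p_k = \sum_i p_{ik}} is the total responsibility mass of component
#' k — a mass-normalized rule that favours small clusters relative to the
#' plain posterior. `"map"` assigns by \eqn{\arg\max_k p_{ik}}. Ties break
#' toward the lower cluster index. When all cluster masses are equal, the
#' two rules coincide.
#'
#' @param points N x 2 matrix (or [fixation_dataset()]).
#' @param model a fitted `gmm_model`.
#' @param rule `"paper_ratio"` or `"map"`.
#' @return A `cluster_assignment` with `labels` filled in.
#' @export
assign_clusters <- function(points, model, rule = c("paper_ratio", "map")) {
  rule <- match.arg(rule)
  a <- e_step(points, model)
  score <- switch(rule,
                  paper_ratio = sweep(a$responsibilities, 2L,
                                      a$cluster_mass, "/"),
                  map = a$responsibilities)
  a$labels <- apply(score, 1L, which.max)  # which.max: first max wins
  a$rule <- rule
  a
}

#' Confidence ellipses of ROI components
#'
#' Describes each component by the ellipse containing `coverage`
#' probability mass: centre \eqn{\mu_k}, semi-axes
#' \eqn{\sqrt{\chi^2_2(c)\,\lambda_j}} from the covariance eigenvalues,
#' and the orientation of the principal eigenvector (radians,
#' counter-clockwise from the x-axis).
#'
#' @param model a `gmm_model`.
#' @param coverage probability mass inside the ellipse, in (0, 1).
#' @return Data frame: `cluster`, `weight`, `center_x`, `center_y`,
#'   `semi_major`, `semi_minor`, `angle`.
#' @export
cluster_ellipses <- function(model, coverage = 0.95) {
  stopifnot(inherits(model, "gmm_model"), coverage > 0, coverage < 1)
  q <- qchisq(coverage, df = 2)
  rows <- lapply(seq_len(n_components(model)), function(k) {
    e <- eigen(model$covs[[k]], symmetric = TRUE)
    v <- e$vectors[, 1L]
    data.frame(cluster = k, weight = model$weights[k],
               center_x = model$means[k, 1], center_y = model$means[k, 2],
               semi_major = sqrt(q * e$values[1L]),
               semi_minor = sqrt(q * e$values[2L]),
               angle = atan2(v[2L], v[1L]))
  })
  do.call(rbind, rows)
}

#' Serialize / restore a mixture model as JSON
#'
#' @param model a `gmm_model`.
#' @param path output file.
#' @return `path` (write) or a `gmm_model` (read), invisibly for write.
#' @export
write_gmm <- function(model, path) {
  obj <- list(weights = model$weights, means = model$means,
              covs = model$covs, log_likelihood = model$log_likelihood,
              n_obs = model$n_obs, converged = model$converged,
              n_iter = model$n_iter, eps = model$eps, bic = bic(model))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_gmm
#' @export
read_gmm <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  covs <- if (is.array(obj$covs) && length(dim(obj$covs)) == 3) {
    lapply(seq_len(dim(obj$covs)[1]), function(k) obj$covs[k, , ])
  } else if (is.list(obj$covs)) {
    lapply(obj$covs, function(s) matrix(unlist(s), 2, 2, byrow = TRUE))
  } else {
    list(matrix(unlist(obj$covs), 2, 2))
  }
  new_gmm_model(obj$weights, obj$means, covs, obj$log_likelihood,
                obj$n_obs, obj$converged, obj$n_iter, obj$eps)
}
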