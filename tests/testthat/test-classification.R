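test_that("knn: identity, majority, and brute-force agreement", {
  x <- rbind(c(0, 0), c(1, 1), c(5, 5))
  y <- c("expert", "expert", "layman")
  expect_equal(knn_predict(x, y, c(1, 1), k = 1), "expert")
  expect_equal(knn_predict(x, y, c(2, 2), k = 3), "expert")

  set.seed(60)
  for (rep in 1:50) {
    tx <- matrix(rnorm(40), 20, 2)
    ty <- sample(c("expert", "layman"), 20, replace = TRUE)
    q <- rnorm(2)
    d <- sqrt(colSums((t(tx) - q)^2))
    nn <- order(d, seq_along(d))[1:3]
    ref <- names(which.max(table(ty[nn])))
    expect_equal(knn_predict(tx, ty, q, k = 3), ref)
  }
  expect_error(knn_predict(x[0, , drop = FALSE], character(0), c(0, 0)),
               "empty")
})

test_that("knn predictions are invariant to common feature scaling", {
  set.seed(61)
  tx <- matrix(rnorm(60), 30, 2)
  ty <- sample(c("expert", "layman"), 30, replace = TRUE)
  q <- matrix(rnorm(10), 5, 2)
  expect_equal(knn_predict(tx, ty, q, k = 3),
               knn_predict(tx * 100, ty, q * 100, k = 3))
})

test_that("svm on two points: perpendicular bisector symmetry", {
  x <- rbind(c(0, 0), c(2, 0))
  y <- c("expert", "layman")
  m <- svm_train(x, y, classifier_spec("svm", kernel = "linear", C = 1e3))
  pred <- svm_predict(m, x, decision = TRUE)
  expect_equal(pred$label, y)
  expect_equal(abs(pred$decision[1]), abs(pred$decision[2]),
               tolerance = 1e-6)
  # midpoint sits on the boundary
  expect_equal(svm_predict(m, c(1, 0), decision = TRUE)$decision, 0,
               tolerance = 1e-6)
})

test_that("svm separable blobs: perfect training accuracy, all kernels", {
  set.seed(62)
  blob <- make_blobs(n_per_class = 12, sep = 10)
  for (kern in c("linear", "rbf")) {
    m <- svm_train(blob$x, blob$y, classifier_spec("svm", kernel = kern))
    expect_equal(svm_predict(m, blob$x), blob$y)
  }
  # the sigmoid (tanh) kernel saturates far from the origin, so give it
  # centred blobs -- near 0 it behaves like a scaled linear kernel
  cblob <- blob
  cblob$x <- scale(blob$x, scale = FALSE)
  ms <- svm_train(cblob$x, cblob$y,
                  classifier_spec("svm", kernel = "sigmoid"))
  expect_equal(svm_predict(ms, cblob$x), cblob$y)
  # rbf kernel at x = x' is exp(0) = 1
  Kd <- gazexpert:::kernel_matrix(blob$x, blob$x,
                                  classifier_spec("svm", kernel = "rbf"),
                                  gamma = 0.5)
  expect_equal(unname(diag(Kd)), rep(1, nrow(blob$x)))
})

test_that("svm agrees with a generic QP reference on small instances", {
  skip_if_not_installed("quadprog")
  set.seed(63)
  for (rep in 1:10) {
    n <- 10
    x <- matrix(rnorm(2 * n), n, 2) +
      rep(c(0, 2.5), each = n / 2)
    y_lab <- rep(c("expert", "layman"), each = n / 2)
    for (kern in c("linear", "rbf")) {
      spec <- classifier_spec("svm", kernel = kern, C = 1, gamma = 0.5)
      m <- svm_train(x, y_lab, spec)
      Kfull <- gazexpert:::kernel_matrix(x, x, spec, 0.5)
      ref <- ref_qp_svm(Kfull, ifelse(y_lab == "expert", 1, -1), C = 1)
      q <- matrix(rnorm(20), 10, 2)
      Kq <- gazexpert:::kernel_matrix(q, x, spec, 0.5)
      ref_lab <- ifelse(ref$decision(Kq) >= 0, "expert", "layman")
      got <- svm_predict(m, q, decision = TRUE)
      # labels must agree except within a hair of the boundary
      clear <- abs(ref$decision(Kq)) > 1e-3
      expect_equal(got$label[clear], ref_lab[clear])
    }
  }
})

test_that("svm input validation", {
  x <- matrix(rnorm(10), 5, 2)
  expect_error(svm_train(x, rep("expert", 5)),
               class = "gazexpert_degenerate_training_error")
  m <- svm_train(rbind(x, x + 10),
                 rep(c("expert", "layman"), each = 5))
  expect_error(svm_predict(m, c(1, 2, 3)),
               class = "gazexpert_dimension_error")
})

test_that("loocv: one fold per subject, perfect separation, determinism", {
  set.seed(64)
  fm <- make_fm(n_per_group = 6, p = 4, signal_col = 1, delta = 15, K = 2)
  for (spec in list(classifier_spec("knn"),
                    classifier_spec("svm", kernel = "linear"))) {
    cv <- loocv(fm, spec)
    expect_equal(cv$n_folds, 12L)
    expect_setequal(names(cv$predictions), fm$subject_ids)
    expect_equal(cv$accuracy, 1.0)
  }
  a <- loocv(fm, classifier_spec("svm", kernel = "sigmoid"))
  b <- loocv(fm, classifier_spec("svm", kernel = "sigmoid"))
  expect_identical(a$predictions, b$predictions)
})

test_that("loocv accuracy matches its own confusion counts", {
  set.seed(65)
  fm <- make_fm(n_per_group = 8, p = 4, signal_col = 2, delta = 1, K = 2)
  cv <- loocv(fm, classifier_spec("knn"))
  expect_equal(cv$accuracy, mean(cv$predictions == cv$truth))
  expect_equal(cv$accuracy, sum(cv$per_fold$correct) / cv$n_folds)
})

test_that("strict mode recomputes fold-local statistics", {
  set.seed(66)
  fm <- make_fm(n_per_group = 6, p = 6, signal_col = 3, delta = 6, K = 3)
  cv <- loocv(fm, classifier_spec("knn"), mode = "strict",
              normalization = "Z1",
              selector = list(method = "t_statistic", n = 2))
  expect_equal(cv$n_folds, 12L)
  expect_gte(cv$accuracy, 0.8)  # strong planted signal survives nesting
})
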