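#' Classifier specification
#'
#' A small record naming the classifier family and its hyperparameters.
#' The study grid uses 3-NN with the Euclidean metric and soft-margin SVMs
#' with linear, RBF and sigmoid ("MLP") kernels; kernel hyperparameters
#' were not reported there, so reproducible conventional defaults are
#' used: `C = 1`, `gamma = "auto"` (`1 / (n_features * var(x))`, the
#' scale-aware convention), `coef0 = 0`.
#'
#' @param family `"knn"` or `"svm"`.
#' @param k neighbour count for k-NN (odd avoids vote ties; default 3).
#' @param kernel SVM kernel: `"linear"`, `"rbf"` or `"sigmoid"`
#'   (`tanh(gamma * x.y + coef0)`, not positive semi-definite for all
#'   parameters — the solver takes bounded steps on indefinite kernels).
#' @param C soft-margin cost, > 0.
#' @param gamma kernel scale, > 0 or `"auto"`.
#' @param coef0 sigmoid offset.
#' @return A list of class `classifier_spec`.
#' @export
classifier_spec <- function(family = c("knn", "svm"), k = 3L,
                            kernel = c("linear", "rbf", "sigmoid"),
                            C = 1, gamma = "auto", coef0 = 0) {
  family <- match.arg(family)
  kernel <- match.arg(kernel)
  stopifnot(C > 0, k >= 1)
  if (!identical(gamma, "auto")) stopifnot(is.numeric(gamma), gamma > 0)
  structure(list(family = family, k = as.integer(k), kernel = kernel,
                 C = C, gamma = gamma, coef0 = coef0),
            class = "classifier_spec")
}

#' @export
print.classifier_spec <- function(x, ...) {
  cat(if (x$family == "knn") sprintf("<classifier_spec> %d-NN (Euclidean)\n",
                                     x$k)
      else sprintf("<classifier_spec> SVM-%s (C = %g, gamma = %s)\n",
                   x$kernel, x$C, format(x$gamma)))
  invisible(x)
}

#' k-nearest-neighbour prediction
#'
#' Majority vote among the `k` training rows nearest to the query in
#' Euclidean distance. Distance ties break toward the lower training-row
#' index; with two classes and odd `k`, vote ties cannot occur (a residual
#' vote tie — even `k` — breaks toward the class with the smaller summed
#' neighbour distance, then alphabetically).
#'
#' @param train_x numeric training matrix (rows = subjects).
#' @param train_y training labels.
#' @param query numeric vector, or matrix of query rows.
#' @param k neighbour count, `<= nrow(train_x)`.
#' @return Predicted label(s).
#' @export
knn_predict <- function(train_x, train_y, query, k = 3L) {
  train_x <- as.matrix(train_x)
  if (nrow(train_x) == 0L) stop("empty training set")
  stopifnot(k <= nrow(train_x))
  q <- if (is.matrix(query)) query else matrix(query, nrow = 1)
  vapply(seq_len(nrow(q)), function(i) {
    d <- sqrt(colSums((t(train_x) - q[i, ])^2))
    nn <- order(d, seq_along(d))[seq_len(k)]
    votes <- table(train_y[nn])
    winners <- names(votes)[votes == max(votes)]
    if (length(winners) > 1L) {
      sums <- vapply(winners,
                     function(lb) sum(d[nn][train_y[nn] == lb]),
                     numeric(1))
      winners <- winners[order(sums, winners)][1L]
    }
    winners
  }, character(1))
}

kernel_matrix <- function(x, y, spec, gamma) {
  G <- x %*% t(y)
  switch(spec$kernel,
         linear = G,
         rbf = {
           dx <- rowSums(x^2); dy <- rowSums(y^2)
           exp(-gamma * (outer(dx, dy, "+") - 2 * G))
         },
         sigmoid = tanh(gamma * G + spec$coef0))
}

resolve_gamma <- function(spec, x) {
  if (!identical(spec$gamma, "auto")) return(spec$gamma)
  v <- var(as.numeric(x))
  if (!is.finite(v) || v == 0) v <- 1
  1 / (ncol(x) * v)
}

#' Train a soft-margin kernel SVM
#'
#' Solves the dual by sequential minimal optimization (deterministic
#' maximal-violating-pair variant, tolerance 1e-6). The positive class is
#' the first label in sorted order (`"expert"` before `"layman"`); the
#' decision value is `sum(alpha_i y_i K(x_i, .)) + b` and a decision value
#' of exactly 0 predicts the positive class.
#'
#' @param train_x numeric matrix, rows = subjects.
#' @param train_y labels; exactly two classes must be present.
#' @param spec a [classifier_spec()] with `family = "svm"`.
#' @return An object of class `svm_model`.
#' @export
svm_train <- function(train_x, train_y, spec = classifier_spec("svm")) {
  stopifnot(spec$family == "svm")
  x <- as.matrix(train_x)
  lev <- sort(unique(as.character(train_y)))
  if (length(lev) != 2L) {
    stop_gx("SVM training needs exactly two classes",
            "gazexpert_degenerate_training_error")
  }
  y <- ifelse(train_y == lev[1L], 1, -1)
  gamma <- resolve_gamma(spec, x)
  K <- kernel_matrix(x, x, spec, gamma)
  fit <- svm_smo_cpp(K, y, spec$C, 1e-6, 5L, 200L * nrow(x))
  structure(list(x = x, y = y, levels = lev, alpha = fit$alpha, b = fit$b,
                 gamma = gamma, spec = spec),
            class = "svm_model")
}

#' Predict with a trained SVM
#'
#' @param model an `svm_model` from [svm_train()].
#' @param query numeric vector or matrix of query rows.
#' @param decision also return raw decision values?
#' @return Predicted label(s), or a list with `label` and `decision`.
#' @export
svm_predict <- function(model, query, decision = FALSE) {
  q <- if (is.matrix(query)) query else matrix(query, nrow = 1)
  if (ncol(q) != ncol(model$x)) {
    stop_gx(sprintf("query has %d feature(s), model expects %d",
                    ncol(q), ncol(model$x)),
            "gazexpert_dimension_error")
  }
  Kq <- kernel_matrix(q, model$x, model$spec, model$gamma)
  dv <- as.numeric(Kq %*% (model$alpha * model$y) + model$b)
  lab <- ifelse(dv >= 0, model$levels[1L], model$levels[2L])
  if (decision) list(label = lab, decision = dv) else lab
}

train_predict <- function(train_x, train_y, test_x, spec) {
  if (spec$family == "knn") {
    knn_predict(train_x, train_y, test_x, k = spec$k)
  } else {
    svm_predict(svm_train(train_x, train_y, spec), test_x)
  }
}

#' Leave-one-subject-out cross-validation
#'
#' Each subject (row of the feature matrix) serves as the test set exactly
#' once; the classifier is trained on the remaining subjects; accuracy is
#' (TP + TN) / N over the collected predictions.
#'
#' Two leakage regimes: in `"replicate_paper"` mode (default) the feature
#' matrix is used as given — normalization statistics and any feature
#' selection were computed once on all subjects, matching the study's
#' single-pass design but optimistically biased. In `"strict"` mode `fm`
#' must be raw (`Z0`); per fold, Z1 statistics are recomputed from the
#' training subjects only and applied to the held-out subject, and the
#' selector (if any) is re-run on the training fold (nested CV). Z2/Z3
#' pool within-subject only, so they carry no cross-subject leakage and
#' are applied as usual in strict mode.
#'
#' @param fm a `feature_matrix`.
#' @param spec a [classifier_spec()].
#' @param selection optional `selection_result` restricting the feature
#'   columns (replicate_paper mode).
#' @param mode `"replicate_paper"` or `"strict"`.
#' @param normalization strict mode: normalization to apply per fold
#'   (`"Z0"`, `"Z1"`, or `"Z3"`).
#' @param selector strict mode: `list(method = "t_statistic"|"sfs", n =)`
#'   re-run inside each training fold.
#' @param seed optional seed forwarded to an inner SFS.
#' @return List of class `cv_result`: `predictions`, `truth`, `accuracy`,
#'   `per_fold` (data frame), `n_folds`.
#' @export
loocv <- function(fm, spec, selection = NULL,
                  mode = c("replicate_paper", "strict"),
                  normalization = NULL, selector = NULL, seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(fm, "feature_matrix"))
  if (min(table(fm$labels)) < 3L) {
    stop("need at least 3 subjects per class for leave-one-subject-out")
  }
  if (mode == "replicate_paper" && !is.null(selection)) {
    fm <- subset_features(fm, features = selection$selected)
  }
  n <- nrow(fm$values)
  preds <- character(n)
  fold_rows <- vector("list", n)
  for (i in seq_len(n)) {
    tr_idx <- setdiff(seq_len(n), i)
    if (length(unique(fm$labels[tr_idx])) < 2L) {
      warning(sprintf("fold %d: training set lost a class; skipped", i))
      preds[i] <- NA_character_
      next
    }
    if (mode == "strict") {
      trs <- strict_fold_features(fm, tr_idx, i, normalization, selector,
                                  spec, seed)
      tr_x <- trs$train; te_x <- trs$test
    } else {
      tr_x <- fm$values[tr_idx, , drop = FALSE]
      te_x <- fm$values[i, , drop = FALSE]
    }
    preds[i] <- train_predict(tr_x, fm$labels[tr_idx], te_x, spec)
    fold_rows[[i]] <- data.frame(subject_id = fm$subject_ids[i],
                                 truth = fm$labels[i],
                                 prediction = preds[i],
                                 correct = preds[i] == fm$labels[i])
  }
  ok <- !is.na(preds)
  acc <- sum(preds[ok] == fm$labels[ok]) / sum(ok)
  structure(list(predictions = setNames(preds, fm$subject_ids),
                 truth = setNames(fm$labels, fm$subject_ids),
                 accuracy = acc,
                 per_fold = do.call(rbind, fold_rows[ok]),
                 n_folds = n),
            class = "cv_result")
}

strict_fold_features <- function(fm, tr_idx, te_idx, normalization,
                                 selector, spec, seed) {
  norm <- normalization %||% "Z0"
  tr <- subset_features(fm, subjects = tr_idx)
  te_row <- fm$values[te_idx, , drop = FALSE]
  if (norm == "Z1") {
    m <- colMeans(tr$values)
    s <- apply(tr$values, 2L, sd)
    s[!is.finite(s) | s == 0] <- Inf  # zero-variance column -> z = 0
    tr$values <- sweep(sweep(tr$values, 2L, m), 2L, s, "/")
    te_row <- sweep(sweep(te_row, 2L, m), 2L, s, "/")
  } else if (norm == "Z3") {
    tr <- normalize_features(tr, "Z3")
    te_fm <- subset_features(fm, subjects = te_idx)
    te_row <- normalize_features(te_fm, "Z3")$values
  }
  if (!is.null(selector)) {
    sel <- if (selector$method == "t_statistic") {
      t_rank_select(tr, selector$n)
    } else {
      sfs_select(tr, selector$n, spec = spec, seed = seed)
    }
    tr <- subset_features(tr, features = sel$selected)
    te_row <- te_row[, sel$selected, drop = FALSE]
  }
  list(train = tr$values, test = te_row)
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> leave-one-subject-out, %d fold(s), accuracy %.3f\n",
              x$n_folds, x$accuracy))
  invisible(x)
}

#' Serialize a cross-validation result
#' @param cv a `cv_result`.
#' @param path output JSON file.
#' @export
write_cv_result <- function(cv, path) {
  jsonlite::write_json(list(accuracy = cv$accuracy, n_folds = cv$n_folds,
                            per_fold = cv$per_fold),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
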