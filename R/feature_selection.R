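#' Two-sample t-statistic
#'
#' Pooled-variance Student's t (default) with
#' `df = n_a + n_b - 2` and a two-sided p-value; the sign follows
#' `mean(a) - mean(b)`. With small, nearly balanced expert/layman groups
#' the pooled form is the conventional choice; set `welch = TRUE` for the
#' unequal-variance statistic. Zero pooled variance with equal means gives
#' `t = 0, p = 1`; with unequal means, `t = +-Inf, p = 0`.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @param welch use the Welch (unequal-variance) statistic?
#' @return List: `t`, `p`, `df`, `mean_a`, `mean_b`.
#' @export
two_sample_t <- function(a, b, welch = FALSE) {
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L) {
    stop_gx("each group needs at least 2 values",
            "gazexpert_insufficient_group_error")
  }
  ma <- mean(a); mb <- mean(b)
  if (welch) {
    se2 <- var(a) / na + var(b) / nb
    df <- se2^2 / ((var(a) / na)^2 / (na - 1) + (var(b) / nb)^2 / (nb - 1))
  } else {
    sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
    se2 <- sp2 * (1 / na + 1 / nb)
    df <- na + nb - 2
  }
  if (se2 == 0) {
    if (ma == mb) return(list(t = 0, p = 1, df = df, mean_a = ma,
                              mean_b = mb))
    return(list(t = sign(ma - mb) * Inf, p = 0, df = df, mean_a = ma,
                mean_b = mb))
  }
  t <- (ma - mb) / sqrt(se2)
  list(t = t, p = 2 * pt(-abs(t), df), df = df, mean_a = ma, mean_b = mb)
}

new_selection_result <- function(selected, criterion_values, method,
                                 n_requested) {
  stopifnot(!anyDuplicated(selected))
  structure(list(selected = as.integer(selected),
                 criterion_values = criterion_values, method = method,
                 n_requested = as.integer(n_requested)),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %s: features [%s]\n", x$method,
              paste(x$selected, collapse = ", ")))
  invisible(x)
}

split_by_group <- function(fm) {
  stopifnot(length(unique(fm$labels)) == 2L)
  list(a = fm$values[fm$labels == GROUP_LEVELS[1L], , drop = FALSE],
       b = fm$values[fm$labels == GROUP_LEVELS[2L], , drop = FALSE])
}

#' Rank features by |t| and keep the top n
#'
#' A filter selector: every feature column is scored by the absolute
#' two-sample t-statistic between experts and laymen, independently of any
#' classifier. Ties break toward the lower column index, so duplicated
#' columns appear adjacently and runs are deterministic.
#'
#' @param fm a `feature_matrix` with both groups present.
#' @param n number of features to keep (capped at the number available).
#' @param welch passed to [two_sample_t()].
#' @return A `selection_result` (criterion values are the |t| scores).
#' @export
t_rank_select <- function(fm, n, welch = FALSE) {
  if (n <= 0) stop("n must be positive")
  g <- split_by_group(fm)
  tt <- vapply(seq_len(ncol(fm$values)), function(j) {
    abs(two_sample_t(g$a[, j], g$b[, j], welch = welch)$t)
  }, numeric(1))
  ord <- order(-tt, seq_along(tt))
  keep <- ord[seq_len(min(n, length(ord)))]
  new_selection_result(keep, tt[keep], "t_statistic", n)
}

#' Sequential forward selection by cross-validated accuracy
#'
#' A wrapper selector: starting from the empty set, each step adds the
#' feature whose inclusion maximizes leave-one-subject-out accuracy of the
#' given classifier on the working set, until `n` features are chosen.
#' Accuracy ties break toward the lower feature index. The recorded
#' criterion values are the accuracy trajectory, one per step.
#'
#' @param fm a `feature_matrix`.
#' @param n number of features to select.
#' @param spec a [classifier_spec()] used for the inner evaluations.
#' @param seed optional seed (the procedure is deterministic anyway; the
#'   seed only guards classifiers with stochastic elements).
#' @return A `selection_result`.
#' @export
sfs_select <- function(fm, n, spec = classifier_spec("svm",
                                                     kernel = "sigmoid"),
                       seed = NULL) {
  stopifnot(n >= 1L)
  if (!is.null(seed)) set.seed(seed)
  p <- ncol(fm$values)
  chosen <- integer(0)
  trajectory <- numeric(0)
  for (step in seq_len(min(n, p))) {
    candidates <- setdiff(seq_len(p), chosen)
    acc <- vapply(candidates, function(j) {
      loocv(subset_features(fm, features = c(chosen, j)), spec)$accuracy
    }, numeric(1))
    best <- candidates[which.max(acc)]  # first max = lowest index
    chosen <- c(chosen, best)
    trajectory <- c(trajectory, max(acc))
  }
  new_selection_result(chosen, trajectory, "sfs", n)
}

#' Serialize a selection result to JSON
#' @param sel a `selection_result`.
#' @param path output file.
#' @export
write_selection <- function(sel, path) {
  jsonlite::write_json(unclass(sel), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
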