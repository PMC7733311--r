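#' Per-cluster group-difference statistics
#'
#' For a raw (`Z0`) feature matrix of one image: per cluster and feature
#' type (count, duration), the expert and layman group means plus pooled
#' two-sample t and two-sided p (via [two_sample_t()]); and the per-image
#' summaries — the sum of |t| over clusters per feature type, the minimum
#' ("best cluster") p per feature type, and the BIC-optimal K if supplied.
#' No multiple-testing correction is applied; the number of tests (2K) is
#' recorded instead.
#'
#' @param fm a `Z0` `feature_matrix` with both groups present.
#' @param optimal_k BIC-chosen cluster count for the image (optional).
#' @param welch passed to [two_sample_t()].
#' @return List of class `group_stats`: `table` (data frame: `cluster`,
#'   `type`, `mean_expert`, `mean_layman`, `t`, `p`), `summary` (list with
#'   `sum_abs_t_count`, `sum_abs_t_duration`, `best_p_count`,
#'   `best_p_duration`, `optimal_k`, `n_tests`), `image_id`.
#' @export
group_cluster_stats <- function(fm, optimal_k = NULL, welch = FALSE) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (!identical(fm$normalization, "Z0")) {
    stop("group statistics are defined on raw (Z0) features")
  }
  if (length(unique(fm$labels)) < 2L) {
    stop_gx("both groups must be present", "gazexpert_single_group_error")
  }
  g <- split_by_group(fm)
  rows <- lapply(seq_len(fm$K), function(k) {
    do.call(rbind, lapply(c("count", "duration"), function(type) {
      j <- if (type == "count") k else fm$K + k
      tt <- two_sample_t(g$a[, j], g$b[, j], welch = welch)
      data.frame(cluster = k, type = type, mean_expert = tt$mean_a,
                 mean_layman = tt$mean_b, t = tt$t, p = tt$p)
    }))
  })
  tab <- do.call(rbind, rows)
  cnt <- tab[tab$type == "count", ]
  dur <- tab[tab$type == "duration", ]
  structure(list(
    table = tab,
    summary = list(sum_abs_t_count = sum(abs(cnt$t)),
                   sum_abs_t_duration = sum(abs(dur$t)),
                   best_p_count = min(cnt$p),
                   best_p_duration = min(dur$p),
                   optimal_k = optimal_k %||% NA_integer_,
                   n_tests = 2L * fm$K),
    image_id = fm$image_id),
    class = "group_stats")
}

#' Summarize t-sums and best-cluster p-values across images
#'
#' Collects the per-image summaries of [group_cluster_stats()] into one
#' table and appends their arithmetic means: mean t-sum per feature type,
#' mean best-cluster p per feature type, and mean optimal K. Input order
#' is immaterial.
#'
#' @param stats_list list of `group_stats`, one per image.
#' @return Data frame with one row per image plus a `"mean"` row; columns
#'   `picture`, `t_sum_count`, `t_sum_duration`, `optimal_k`,
#'   `best_p_count`, `best_p_duration`.
#' @export
summarize_t_sums <- function(stats_list) {
  stopifnot(length(stats_list) >= 1L)
  rows <- do.call(rbind, lapply(stats_list, function(s) {
    data.frame(picture = s$image_id,
               t_sum_count = s$summary$sum_abs_t_count,
               t_sum_duration = s$summary$sum_abs_t_duration,
               optimal_k = as.numeric(s$summary$optimal_k),
               best_p_count = s$summary$best_p_count,
               best_p_duration = s$summary$best_p_duration)
  }))
  means <- data.frame(picture = "mean",
                      t_sum_count = mean(rows$t_sum_count),
                      t_sum_duration = mean(rows$t_sum_duration),
                      optimal_k = mean(rows$optimal_k),
                      best_p_count = mean(rows$best_p_count),
                      best_p_duration = mean(rows$best_p_duration))
  out <- rbind(rows, means)
  rownames(out) <- NULL
  out
}

#' Accuracy grid over pictures and normalizations
#'
#' Arranges leave-one-subject-out accuracies into the standard pictures x
#' normalizations table with row means, column means and the grand mean
#' over all cells. Values are stored at full precision; rounding (2
#' decimals) happens only when printing.
#'
#' @param cells either a numeric matrix with pictures as rownames and
#'   normalization tags as colnames, or a data frame with columns
#'   `picture`, `normalization`, `accuracy` covering the complete grid.
#' @return List of class `accuracy_grid`: `cells`, `row_means`,
#'   `col_means`, `grand_mean`.
#' @export
build_accuracy_grid <- function(cells) {
  if (is.data.frame(cells)) {
    pictures <- unique(cells$picture)
    norms <- unique(cells$normalization)
    m <- matrix(NA_real_, length(pictures), length(norms),
                dimnames = list(pictures, norms))
    for (r in seq_len(nrow(cells))) {
      m[cells$picture[r], cells$normalization[r]] <- cells$accuracy[r]
    }
    cells <- m
  }
  cells <- as.matrix(cells)
  if (anyNA(cells)) {
    idx <- which(is.na(cells), arr.ind = TRUE)
    keys <- paste0(rownames(cells)[idx[, 1]], "/", colnames(cells)[idx[, 2]])
    stop_gx(sprintf("incomplete accuracy grid; missing: %s",
                    paste(keys, collapse = ", ")),
            "gazexpert_incomplete_grid_error")
  }
  structure(list(cells = cells,
                 row_means = rowMeans(cells),
                 col_means = colMeans(cells),
                 grand_mean = mean(cells)),
            class = "accuracy_grid")
}

#' @export
print.accuracy_grid <- function(x, digits = 2, ...) {
  m <- cbind(x$cells, mean = x$row_means)
  m <- rbind(m, mean = c(x$col_means, x$grand_mean))
  print(round(m, digits))
  invisible(x)
}

#' Pool accuracy grids into per-normalization means
#'
#' The overall mean accuracy per normalization tag, cellwise over every
#' picture of every grid (so each of the grids' cells counts once).
#'
#' @param grids list of `accuracy_grid` objects sharing normalization
#'   columns.
#' @return Named numeric vector, one mean per normalization tag.
#' @export
aggregate_grids <- function(grids) {
  stopifnot(length(grids) >= 1L)
  cols <- colnames(grids[[1L]]$cells)
  for (g in grids) {
    if (!identical(colnames(g$cells), cols)) {
      stop_gx("grids have mismatching normalization columns",
              "gazexpert_grid_mismatch_error")
    }
  }
  stacked <- do.call(rbind, lapply(grids, `[[`, "cells"))
  colMeans(stacked)
}

#' Published reference tables from the original expert/layman study
#'
#' The package ships, as plain CSV, the printed result tables of the
#' original study of 23 experts and 21 laymen viewing five paintings:
#' the seven accuracy grids (classifier x selector x normalization x
#' picture), the per-picture group-difference summary (t-sums,
#' best-cluster p-values, BIC-optimal K), and the per-cluster group means
#' for the second painting. The underlying recordings were never
#' released; these tables serve as worked-example inputs for the
#' aggregation operations and as the scale reference for the synthetic
#' generator.
#'
#' @return `reference_accuracy_grids()`: named list of `accuracy_grid`
#'   objects keyed by grid id, with a `meta` attribute describing each
#'   grid. `reference_group_summary()` and `reference_cluster_stats()`:
#'   data frames.
#' @export
reference_accuracy_grids <- function() {
  path <- system.file("extdata", "reference_accuracy_grids.csv",
                      package = "gazexpert", mustWork = TRUE)
  df <- read.csv(path, check.names = FALSE)
  ids <- unique(df$grid_id)
  grids <- lapply(ids, function(id) {
    sub <- df[df$grid_id == id, ]
    m <- as.matrix(sub[, c("Z0", "Z1", "Z2", "Z3")])
    rownames(m) <- sub$picture
    build_accuracy_grid(m)
  })
  names(grids) <- ids
  attr(grids, "meta") <- unique(df[c("grid_id", "classifier", "selector",
                                     "n_features")])
  grids
}

#' @rdname reference_accuracy_grids
#' @export
reference_group_summary <- function() {
  read.csv(system.file("extdata", "reference_group_summary.csv",
                       package = "gazexpert", mustWork = TRUE))
}

#' @rdname reference_accuracy_grids
#' @export
reference_cluster_stats <- function() {
  read.csv(system.file("extdata", "reference_cluster_stats.csv",
                       package = "gazexpert", mustWork = TRUE))
}

#' Render an accuracy grid as Markdown
#'
#' Presentation-only rounding to two decimals, matching the conventional
#' table layout (pictures as rows, a trailing `mean` column and row).
#'
#' @param grid an `accuracy_grid`.
#' @param digits decimals shown.
#' @return Character vector of Markdown lines.
#' @export
format_grid_markdown <- function(grid, digits = 2) {
  m <- cbind(grid$cells, mean = grid$row_means)
  m <- rbind(m, mean = c(grid$col_means, grid$grand_mean))
  header <- paste0("| Picture | ", paste(colnames(m), collapse = " | "),
                   " |")
  sep <- paste0("|", paste(rep("---", ncol(m) + 1), collapse = "|"), "|")
  body <- vapply(seq_len(nrow(m)), function(i) {
    paste0("| ", rownames(m)[i], " | ",
           paste(formatC(m[i, ], digits = digits, format = "f"),
                 collapse = " | "), " |")
  }, character(1))
  c(header, sep, body)
}
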