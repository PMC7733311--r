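#' @title Per-subject ROI features
#'
#' @description For a K-cluster ROI model of one image, each subject is
#' described by 2K features: `l_1..l_K`, the number of the subject's
#' fixations assigned to each cluster, followed by `t_1..t_K`, the mean
#' duration (ms) of those fixations. A subject with no fixation in a
#' cluster gets `l_k = 0` and, by convention, `t_k = 0` (matrices stay
#' complete and deterministic). A `feature_matrix` carries the value
#' matrix plus subject ids, group labels, the image id, K, and a
#' normalization tag (`Z0` = raw).
#'
#' @name feature_matrix
NULL

new_feature_matrix <- function(values, subject_ids, labels, image_id, K,
                               normalization = "Z0") {
  stopifnot(nrow(values) == length(subject_ids),
            length(labels) == length(subject_ids),
            ncol(values) == 2L * K)
  colnames(values) <- c(paste0("l_", seq_len(K)), paste0("t_", seq_len(K)))
  rownames(values) <- subject_ids
  structure(list(values = values, feature_names = colnames(values),
                 subject_ids = subject_ids, labels = labels,
                 image_id = image_id, K = as.integer(K),
                 normalization = normalization),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf(
    "<feature_matrix> %d subject(s) x %d features (K = %d), image %s, %s\n",
    nrow(x$values), ncol(x$values), x$K, x$image_id, x$normalization))
  invisible(x)
}

# column indices of the count block and the duration block
count_cols <- function(fm) seq_len(fm$K)
duration_cols <- function(fm) fm$K + seq_len(fm$K)

#' Extract count and mean-duration features
#'
#' @param ds a [fixation_dataset()]; only records of `image_id` are used.
#' @param assignment a `cluster_assignment` with `labels`, aligned with
#'   the `image_id` records of `ds` in order.
#' @param K number of clusters of the ROI model.
#' @param image_id image to extract; defaults to the single image present.
#' @return A `feature_matrix` tagged `Z0`, one row per subject with at
#'   least one fixation on the image (subjects in order of first
#'   appearance).
#' @export
extract_features <- function(ds, assignment, K, image_id = NULL) {
  stopifnot(inherits(ds, "fixation_dataset"))
  image_id <- image_id %||% {
    ids <- unique(ds$image_id)
    if (length(ids) != 1L) stop("image_id required for multi-image data")
    ids
  }
  sub <- as.data.frame(ds)[ds$image_id == image_id, , drop = FALSE]
  labels <- if (inherits(assignment, "cluster_assignment"))
    assignment$labels else as.integer(assignment)
  if (length(labels) != nrow(sub)) {
    stop_gx(sprintf(
      "assignment covers %d fixations but image '%s' has %d records",
      length(labels), image_id, nrow(sub)),
      "gazexpert_alignment_error")
  }
  subjects <- unique(sub$subject_id)
  vals <- matrix(0, nrow = length(subjects), ncol = 2L * K)
  for (i in seq_along(subjects)) {
    rows <- sub$subject_id == subjects[i]
    lab <- labels[rows]
    dur <- sub$duration_ms[rows]
    for (k in seq_len(K)) {
      ink <- lab == k
      vals[i, k] <- sum(ink)
      vals[i, K + k] <- if (any(ink)) mean(dur[ink]) else 0
    }
  }
  grp <- vapply(subjects,
                function(s) sub$group[match(s, sub$subject_id)],
                character(1))
  new_feature_matrix(vals, subjects, unname(grp), image_id, K)
}

# z-score with the sample (n-1) convention; zero-variance groups map to 0
zscore <- function(x, m = mean(x), s = sd(x)) {
  if (!is.finite(s) || s == 0) rep(0, length(x)) else (x - m) / s
}

#' Standardize ROI features
#'
#' Four schemes, all of the form \eqn{z = (x - m)/\sigma} with the sample
#' (n-1) standard deviation; they differ in the pooling set over which m
#' and \eqn{\sigma} are taken:
#' \describe{
#'   \item{Z0}{identity — raw counts and durations.}
#'   \item{Z1}{per feature column, over all subjects of the image
#'     ("all data together").}
#'   \item{Z2}{per subject, over that subject's values across clusters
#'     *and* images — count features and duration features pooled
#'     separately, since they live on incommensurable scales. Requires
#'     `all_images`, the subject's Z0 feature matrices for every image.}
#'   \item{Z3}{as Z2 but within the single image, so individual
#'     differences are removed separately per image.}
#' }
#' Degenerate pooling sets (zero standard deviation) map to z = 0.
#'
#' @param fm a `feature_matrix` (must be `Z0` for `Z2`/`Z3`).
#' @param method one of `"Z0"`, `"Z1"`, `"Z2"`, `"Z3"`.
#' @param all_images list of Z0 `feature_matrix` objects, one per image
#'   (required for `Z2`; `fm`'s own image may be included or not).
#' @return A `feature_matrix` with the normalization tag updated.
#' @export
normalize_features <- function(fm, method = c("Z0", "Z1", "Z2", "Z3"),
                               all_images = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(fm, "feature_matrix"))
  out <- fm
  if (method == "Z0") {
    out$normalization <- "Z0"
    return(out)
  }
  v <- fm$values
  if (method == "Z1") {
    out$values <- apply(v, 2L, zscore)
    dimnames(out$values) <- dimnames(v)
  } else if (method == "Z3") {
    for (block in list(count_cols(fm), duration_cols(fm))) {
      for (i in seq_len(nrow(v))) {
        out$values[i, block] <- zscore(v[i, block])
      }
    }
  } else {  # Z2
    if (is.null(all_images)) {
      stop_gx("Z2 normalization needs `all_images` (the subject's feature matrices across all viewed images)",
              "gazexpert_context_error")
    }
    mats <- all_images
    if (!any(vapply(mats, function(m) identical(m$image_id, fm$image_id),
                    logical(1)))) {
      mats <- c(mats, list(fm))
    }
    for (type in c("count", "duration")) {
      block <- if (type == "count") count_cols(fm) else duration_cols(fm)
      for (i in seq_len(nrow(v))) {
        sid <- fm$subject_ids[i]
        pool <- unlist(lapply(mats, function(m) {
          j <- match(sid, m$subject_ids)
          if (is.na(j)) return(NULL)
          b <- if (type == "count") count_cols(m) else duration_cols(m)
          m$values[j, b]
        }))
        out$values[i, block] <- zscore(v[i, block], mean(pool), sd(pool))
      }
    }
  }
  out$normalization <- method
  out
}

#' Write / read a feature matrix as CSV plus JSON sidecar
#'
#' The CSV holds `subject_id`, `group`, then the 2K feature columns; the
#' sidecar (same path with `.json` appended) records image id, K and the
#' normalization tag.
#'
#' @param fm a `feature_matrix`.
#' @param path CSV path.
#' @return `path` (write) or a `feature_matrix` (read).
#' @export
write_features <- function(fm, path) {
  df <- data.frame(subject_id = fm$subject_ids, group = fm$labels,
                   fm$values, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(list(image_id = fm$image_id, K = fm$K,
                            normalization = fm$normalization),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  vals <- as.matrix(df[, -(1:2), drop = FALSE])
  new_feature_matrix(vals, as.character(df$subject_id),
                     as.character(df$group), meta$image_id, meta$K,
                     meta$normalization)
}

# subset a feature matrix by feature column indices and/or subject rows
subset_features <- function(fm, features = NULL, subjects = NULL) {
  out <- fm
  if (!is.null(subjects)) {
    out$values <- out$values[subjects, , drop = FALSE]
    out$subject_ids <- out$subject_ids[subjects]
    out$labels <- out$labels[subjects]
  }
  if (!is.null(features)) {
    out$values <- out$values[, features, drop = FALSE]
    out$feature_names <- out$feature_names[features]
  }
  out
}
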