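#' @title Fixation datasets
#'
#' @description A fixation dataset is a data frame with one row per
#' detected fixation and the fixed column set `subject_id`, `group`,
#' `image_id`, `x`, `y`, `duration_ms`. Coordinates are screen pixels with
#' the origin at the top-left corner (x rightward, y downward; the
#' reference display is 1920 x 1200). Durations are milliseconds and must
#' be strictly positive. Off-screen coordinates are permitted (they are
#' flagged, not rejected, by [validate_fixations()]). Every subject must
#' carry a single group label, `"expert"` or `"layman"`.
#'
#' @param records data frame holding the six canonical columns.
#' @param provenance free-text metadata kept alongside the records.
#'
#' @return An object of class `fixation_dataset` (a data frame).
#' @seealso [load_fixations()], [write_fixations()], [validate_fixations()]
#' @export
fixation_dataset <- function(records, provenance = character()) {
  required <- c("subject_id", "group", "image_id", "x", "y", "duration_ms")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols)) {
    stop_gx(sprintf("missing column(s): %s",
                    paste(missing_cols, collapse = ", ")),
            "gazexpert_schema_error")
  }
  rec <- as.data.frame(records)[required]
  rec$subject_id <- as.character(rec$subject_id)
  rec$image_id <- as.character(rec$image_id)
  rec$group <- normalize_group(rec$group)
  for (col in c("x", "y", "duration_ms")) {
    v <- rec[[col]]
    if (!is.numeric(v)) {
      bad <- suppressWarnings(is.na(as.numeric(as.character(v))) &
                                !is.na(v))
      if (any(bad)) {
        stop_gx(sprintf("non-numeric value in column '%s' at row %d",
                        col, which(bad)[1L]),
                "gazexpert_parse_error")
      }
      v <- as.numeric(as.character(v))
    }
    rec[[col]] <- v
  }
  if (any(!is.finite(rec$x)) || any(!is.finite(rec$y))) {
    stop_gx("non-finite coordinate", "gazexpert_parse_error")
  }
  if (any(!is.finite(rec$duration_ms) | rec$duration_ms <= 0)) {
    stop_gx(sprintf("non-positive duration at row %d",
                    which(!is.finite(rec$duration_ms) |
                            rec$duration_ms <= 0)[1L]),
            "gazexpert_parse_error")
  }
  check_group_consistency(rec)
  rownames(rec) <- NULL
  structure(rec, provenance = provenance,
            class = c("fixation_dataset", "data.frame"))
}

normalize_group <- function(g) {
  g <- tolower(trimws(as.character(g)))
  bad <- !g %in% GROUP_LEVELS
  if (any(bad)) {
    stop_gx(sprintf(
      "unknown group label '%s' (expected one of: %s)",
      g[bad][1L], paste(GROUP_LEVELS, collapse = ", ")),
      "gazexpert_schema_error")
  }
  g
}

check_group_consistency <- function(rec) {
  tab <- unique(rec[c("subject_id", "group")])
  dup <- tab$subject_id[duplicated(tab$subject_id)]
  if (length(dup)) {
    stop_gx(sprintf("subject '%s' appears with more than one group label",
                    dup[1L]),
            "gazexpert_consistency_error")
  }
  invisible(TRUE)
}

#' Read a fixation table from CSV/TSV
#'
#' Expects a header row naming the six canonical columns (see
#' [fixation_dataset()]). Group labels are matched case-insensitively and
#' canonicalized to lowercase. Record order in the file is preserved.
#'
#' @param path file to read.
#' @param dialect `"auto"` (by extension; default), `"csv"` or `"tsv"`.
#' @return A [fixation_dataset()].
#' @export
load_fixations <- function(path, dialect = c("auto", "csv", "tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    stop_gx(sprintf("file not found: %s", path), "gazexpert_io_error")
  }
  if (dialect == "auto") {
    dialect <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "tsv"
    else "csv"
  }
  sep <- if (dialect == "tsv") "\t" else ","
  raw <- read.csv(path, sep = sep, colClasses = "character",
                  check.names = TRUE, fileEncoding = "UTF-8")
  fixation_dataset(raw, provenance = sprintf("loaded from %s", path))
}

#' Write a fixation table to CSV/TSV
#'
#' Numeric fields are written at full double precision so that
#' write-then-read round-trips are lossless well past 6 decimal digits.
#'
#' @param ds a [fixation_dataset()].
#' @param path output file.
#' @param dialect `"csv"` (default) or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_fixations <- function(ds, path, dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(ds, "fixation_dataset"))
  out <- as.data.frame(ds)
  for (col in c("x", "y", "duration_ms")) {
    out[[col]] <- formatC(out[[col]], digits = 15, format = "g")
  }
  write.table(out, path, sep = if (dialect == "tsv") "\t" else ",",
              row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Restrict a dataset to one image
#'
#' ROI models are fitted per image, so the pipeline repeatedly narrows the
#' cohort to the records of a single stimulus. Order is preserved; an
#' unknown `image_id` yields an empty dataset with a warning, not an error.
#'
#' @param ds a [fixation_dataset()].
#' @param image_id stimulus identifier to keep.
#' @return A [fixation_dataset()] with the matching records.
#' @export
filter_image <- function(ds, image_id) {
  stopifnot(inherits(ds, "fixation_dataset"))
  keep <- ds$image_id == image_id
  if (!any(keep)) {
    warning(sprintf("no records for image '%s'", image_id))
  }
  out <- as.data.frame(ds)[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, provenance = attr(ds, "provenance"),
            class = c("fixation_dataset", "data.frame"))
}

#' Validate a fixation dataset
#'
#' Report-only quality checks: per-subject and per-image record counts,
#' fixations outside the screen frame, and exact duplicate rows. Never
#' mutates or filters the data.
#'
#' @param ds a [fixation_dataset()].
#' @param frame screen size in pixels, default `c(1920, 1200)`.
#' @return A list of class `fixation_validation` with elements `issues`
#'   (data frame: `type`, `row`, `detail`), `per_subject`, `per_image`,
#'   and `n_records`.
#' @export
validate_fixations <- function(ds, frame = c(SCREEN_W, SCREEN_H)) {
  stopifnot(inherits(ds, "fixation_dataset"))
  issues <- list()
  off <- which(ds$x < 0 | ds$y < 0 | ds$x > frame[1] | ds$y > frame[2])
  if (length(off)) {
    issues[[length(issues) + 1L]] <- data.frame(
      type = "off_screen", row = off,
      detail = sprintf("(%.1f, %.1f) outside %dx%d frame",
                       ds$x[off], ds$y[off], frame[1], frame[2]))
  }
  dup <- which(duplicated(as.data.frame(ds)))
  if (length(dup)) {
    issues[[length(issues) + 1L]] <- data.frame(
      type = "duplicate_row", row = dup, detail = "exact duplicate")
  }
  issues <- if (length(issues)) do.call(rbind, issues) else
    data.frame(type = character(), row = integer(), detail = character())
  per_subject <- as.data.frame(table(subject_id = ds$subject_id),
                               responseName = "n")
  per_image <- as.data.frame(table(image_id = ds$image_id),
                             responseName = "n")
  structure(list(issues = issues, per_subject = per_subject,
                 per_image = per_image, n_records = nrow(ds)),
            class = "fixation_validation")
}

#' @export
print.fixation_validation <- function(x, ...) {
  cat(sprintf("Fixation validation: %d records, %d subject(s), %d image(s)\n",
              x$n_records, nrow(x$per_subject), nrow(x$per_image)))
  if (nrow(x$issues) == 0) {
    cat("No issues found.\n")
  } else {
    cat(sprintf("%d issue(s):\n", nrow(x$issues)))
    print(utils::head(x$issues, 20))
  }
  invisible(x)
}

#' @export
print.fixation_dataset <- function(x, ...) {
  cat(sprintf(
    "<fixation_dataset> %d fixations, %d subject(s), %d image(s)\n",
    nrow(x), length(unique(x$subject_id)), length(unique(x$image_id))))
  NextMethod()
}
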