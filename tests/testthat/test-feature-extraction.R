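make_tiny_ds <- function() {
  fixation_dataset(data.frame(
    subject_id = c("S1", "S1", "S1", "S2"),
    group = c("expert", "expert", "expert", "layman"),
    image_id = "P1",
    x = c(10, 20, 500, 40), y = c(10, 20, 500, 40),
    duration_ms = c(200, 100, 300, 150)))
}

test_that("counts and mean durations per cluster, empty-cluster zeros", {
  ds <- make_tiny_ds()
  fm <- extract_features(ds, c(1L, 1L, 2L, 1L), K = 2)
  expect_equal(fm$feature_names, c("l_1", "l_2", "t_1", "t_2"))
  expect_equal(unname(fm$values["S1", ]), c(2, 1, 150, 300))
  # S2 never fixates cluster 2: l_2 = 0 and t_2 = 0 by convention
  expect_equal(unname(fm$values["S2", ]), c(1, 0, 150, 0))
  expect_equal(fm$labels, c("expert", "layman"))
  expect_identical(fm$normalization, "Z0")
})

test_that("per-subject cluster counts sum to total fixations", {
  set.seed(40)
  co <- generate_cohort(default_spec(seed = 40))
  ds <- co$dataset
  fm <- extract_features(ds, co$truth$cluster, K = 14)
  totals <- table(ds$subject_id)[fm$subject_ids]
  expect_equal(unname(rowSums(fm$values[, 1:14])),
               as.numeric(totals))
})

test_that("alignment mismatches are caught", {
  ds <- make_tiny_ds()
  expect_error(extract_features(ds, c(1L, 2L), K = 2),
               class = "gazexpert_alignment_error")
})

test_that("Z1 standardizes columns; idempotent; known closed form", {
  fm <- make_fm(n_per_group = 6, p = 4)
  fm$values[, 1] <- rep(c(1, 2, 3), 4)
  z <- normalize_features(fm, "Z1")
  col1 <- rep(c(1, 2, 3), 4)
  expect_equal(z$values[, 1], (col1 - mean(col1)) / sd(col1),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(colMeans(z$values), rep(0, 4), ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_equal(apply(z$values, 2, sd), rep(1, 4), ignore_attr = TRUE,
               tolerance = 1e-12)
  z2 <- normalize_features(z, "Z1")
  expect_equal(z2$values, z$values, tolerance = 1e-9)

  # the documented 3-value example
  fm3 <- make_fm(n_per_group = 2, p = 2, K = 1)
  fm3$values <- matrix(c(1, 2, 3, 0, 0, 0), 3, 2)[, , drop = FALSE]
  fm3$subject_ids <- fm3$subject_ids[1:3]
  fm3$labels <- fm3$labels[1:3]
  expect_equal(normalize_features(fm3, "Z1")$values[, 1], c(-1, 0, 1),
               ignore_attr = TRUE)
})

test_that("Z3 blocks have mean 0 / sd 1 per subject and feature type", {
  set.seed(41)
  fm <- make_fm(n_per_group = 5, p = 8, K = 4)
  fm$values <- abs(fm$values) + 1
  z <- normalize_features(fm, "Z3")
  for (i in seq_len(nrow(z$values))) {
    for (block in list(1:4, 5:8)) {
      expect_equal(mean(z$values[i, block]), 0, tolerance = 1e-12)
      expect_equal(sd(z$values[i, block]), 1, tolerance = 1e-12)
    }
  }
})

test_that("Z2 pools each subject across images; errors without context", {
  set.seed(42)
  fm_a <- make_fm(n_per_group = 4, p = 4, K = 2)
  fm_b <- make_fm(n_per_group = 4, p = 4, K = 2)
  fm_b$image_id <- "P2"
  expect_error(normalize_features(fm_a, "Z2"),
               class = "gazexpert_context_error")
  z <- normalize_features(fm_a, "Z2", all_images = list(fm_a, fm_b))
  # manual z-score of subject 1's first count feature over both images
  pool <- c(fm_a$values[1, 1:2], fm_b$values[1, 1:2])
  expect_equal(z$values[1, 1],
               (fm_a$values[1, 1] - mean(pool)) / sd(pool),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("z-scores are invariant to unit rescaling of raw features", {
  set.seed(43)
  fm_ms <- make_fm(n_per_group = 5, p = 6, K = 3)
  fm_ms$values <- abs(fm_ms$values) * 100
  fm_s <- fm_ms
  fm_s$values[, 4:6] <- fm_s$values[, 4:6] / 1000  # durations in seconds
  for (method in c("Z1", "Z3")) {
    za <- normalize_features(fm_ms, method)
    zb <- normalize_features(fm_s, method)
    expect_equal(za$values[, 4:6], zb$values[, 4:6], tolerance = 1e-9)
  }
})

test_that("feature matrices round-trip through CSV + sidecar", {
  set.seed(44)
  fm <- make_fm(n_per_group = 4, p = 6, K = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_features(fm, path)
  back <- read_features(path)
  expect_equal(back$values, fm$values, tolerance = 1e-12)
  expect_equal(back$subject_ids, fm$subject_ids)
  expect_equal(back$labels, fm$labels)
  expect_equal(back$K, fm$K)
  expect_equal(back$normalization, fm$normalization)
})
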