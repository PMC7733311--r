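#' Pipeline configuration
#'
#' One declarative object drives the whole experiment grid: where the
#' fixations come from (a file or the synthetic generator), which images
#' to process, the EM/BIC settings, the normalizations, selectors and
#' classifiers to cross, the cross-validation mode, and the mandatory
#' seed. Defaults encode the canonical grid of the reference study
#' (pictures x Z0..Z3, SVM-sigmoid with SFS-5).
#'
#' @param input `"synthetic"` or a path to a fixation CSV/TSV.
#' @param spec `synthetic_spec` used when `input = "synthetic"`; `NULL`
#'   means [default_spec()].
#' @param images image ids to process; `NULL` = all present.
#' @param k_range BIC search range `c(kmin, kmax)`, or a single fixed K.
#' @param em list of EM settings (`tol`, `max_iter`, `n_restarts`).
#' @param normalizations subset of `c("Z0","Z1","Z2","Z3")`.
#' @param selector `list(method = "t_statistic"|"sfs"|"none", n = count)`.
#' @param classifiers list of [classifier_spec()] objects.
#' @param cv_mode `"replicate_paper"` or `"strict"`.
#' @param assignment_rule `"paper_ratio"` or `"map"`.
#' @param seed integer seed (mandatory).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(input = "synthetic", spec = NULL,
                            images = NULL, k_range = c(2L, 20L),
                            em = list(tol = 1e-6, max_iter = 500L,
                                      n_restarts = 10L),
                            normalizations = c("Z0", "Z1", "Z2", "Z3"),
                            selector = list(method = "sfs", n = 5L),
                            classifiers = list(
                              classifier_spec("svm", kernel = "sigmoid")),
                            cv_mode = "replicate_paper",
                            assignment_rule = "paper_ratio",
                            seed) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  stopifnot(all(normalizations %in% c("Z0", "Z1", "Z2", "Z3")),
            selector$method %in% c("t_statistic", "sfs", "none"),
            cv_mode %in% c("replicate_paper", "strict"),
            assignment_rule %in% c("paper_ratio", "map"))
  for (cl in classifiers) stopifnot(inherits(cl, "classifier_spec"))
  structure(list(input = input, spec = spec, images = images,
                 k_range = k_range, em = em,
                 normalizations = normalizations, selector = selector,
                 classifiers = classifiers, cv_mode = cv_mode,
                 assignment_rule = assignment_rule,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Scalar fields mirror [pipeline_config()] arguments; `classifiers` is a
#' list of records with `family`, and family-specific fields (`k`,
#' `kernel`, `C`, `gamma`, `coef0`).
#'
#' @param path config file.
#' @return A `pipeline_config`.
#' @export
load_config <- function(path) {
  obj <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the 'yaml' package is required for YAML configs")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE,
                        simplifyDataFrame = FALSE)
  }
  classifiers <- lapply(obj$classifiers %||%
                          list(list(family = "svm", kernel = "sigmoid")),
                        function(cl) {
    do.call(classifier_spec, cl)
  })
  pipeline_config(
    input = obj$input %||% "synthetic",
    spec = if (!is.null(obj$spec_file)) read_spec(obj$spec_file),
    images = obj$images,
    k_range = obj$k_range %||% c(2L, 20L),
    em = utils::modifyList(list(tol = 1e-6, max_iter = 500L,
                                n_restarts = 10L), obj$em %||% list()),
    normalizations = obj$normalizations %||% c("Z0", "Z1", "Z2", "Z3"),
    selector = obj$selector %||% list(method = "sfs", n = 5L),
    classifiers = classifiers,
    cv_mode = obj$cv_mode %||% "replicate_paper",
    assignment_rule = obj$assignment_rule %||% "paper_ratio",
    seed = obj$seed)
}

classifier_tag <- function(spec) {
  if (spec$family == "knn") sprintf("%d-nn", spec$k)
  else sprintf("svm-%s", spec$kernel)
}

#' Run the full analysis pipeline
#'
#' simulate/load -> per image: cluster (EM + BIC) -> features -> per
#' normalization: select -> classify (LOOCV) -> report. Every stage's
#' artifact is written under `output_dir` so stages can be inspected and
#' re-run; a manifest records the configuration, seed, package version,
#' per-stage timings and md5 hashes of all outputs. Reruns with an
#' identical config and seed reproduce identical numbers.
#'
#' @param cfg a `pipeline_config`.
#' @param output_dir directory for artifacts (created if needed).
#' @return The manifest, invisibly; its `grids` element holds one
#'   `accuracy_grid` per classifier and its `summary` element the pooled
#'   per-normalization means.
#' @export
run_pipeline <- function(cfg, output_dir) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  timings <- list()
  clock <- function(tag, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- force(expr)
    timings[[tag]] <<- proc.time()[["elapsed"]] - t0
    out
  }

  # stage 1: data
  ds <- clock("data", {
    if (identical(cfg$input, "synthetic")) {
      spec <- cfg$spec %||% default_spec(seed = cfg$seed)
      cohort <- generate_cohort(spec, seed = cfg$seed)
      write.csv(cohort$truth, file.path(output_dir, "ground_truth.csv"),
                row.names = FALSE)
      cohort$dataset
    } else {
      load_fixations(cfg$input)
    }
  })
  write_fixations(ds, file.path(output_dir, "fixations.csv"))
  images <- cfg$images %||% unique(ds$image_id)

  grid_cells <- list()
  stats_list <- list()
  fm0_list <- list()
  for (img in images) {
    ds_img <- filter_image(ds, img)
    pts <- as_points(ds_img)

    # stage 2: ROI model
    model_info <- clock(paste0("cluster_", img), {
      if (length(cfg$k_range) == 1L) {
        m <- fit_em(pts, cfg$k_range, tol = cfg$em$tol,
                    max_iter = cfg$em$max_iter,
                    n_restarts = cfg$em$n_restarts, seed = cfg$seed)
        list(model = m, best_k = length(m$weights), trace = NULL)
      } else {
        sel <- select_k(pts, cfg$k_range[1], cfg$k_range[2],
                        tol = cfg$em$tol, max_iter = cfg$em$max_iter,
                        n_restarts = cfg$em$n_restarts, seed = cfg$seed)
        list(model = sel$model, best_k = sel$best_k, trace = sel$trace)
      }
    })
    write_gmm(model_info$model,
              file.path(output_dir, sprintf("model_%s.json", img)))
    if (!is.null(model_info$trace)) {
      write.csv(model_info$trace,
                file.path(output_dir, sprintf("bic_trace_%s.csv", img)),
                row.names = FALSE)
    }
    write.csv(cluster_ellipses(model_info$model),
              file.path(output_dir, sprintf("ellipses_%s.csv", img)),
              row.names = FALSE)

    # stage 3: features
    assign <- assign_clusters(pts, model_info$model,
                              rule = cfg$assignment_rule)
    fm0 <- clock(paste0("features_", img),
                 extract_features(ds_img, assign, model_info$best_k, img))
    write_features(fm0, file.path(output_dir,
                                  sprintf("features_%s_Z0.csv", img)))
    stats_list[[img]] <- group_cluster_stats(fm0,
                                             optimal_k = model_info$best_k)
    fm0_list[[img]] <- fm0
  }

  # stages 4-5: selection + classification per image and normalization
  # (second pass: Z2 pools each subject's features across all images)
  for (img in images) {
    fm0 <- fm0_list[[img]]
    for (norm in cfg$normalizations) {
      fm <- normalize_features(fm0, norm, all_images = fm0_list)
      for (cl in cfg$classifiers) {
        tag <- classifier_tag(cl)
        key <- paste(tag, img, norm, sep = "_")
        res <- clock(paste0("cv_", key), {
          if (cfg$cv_mode == "strict") {
            loocv(fm0, cl, mode = "strict", normalization = norm,
                  selector = if (cfg$selector$method == "none") NULL
                  else cfg$selector, seed = cfg$seed)
          } else {
            sel <- switch(cfg$selector$method,
                          none = NULL,
                          t_statistic = t_rank_select(fm, cfg$selector$n),
                          sfs = sfs_select(fm, cfg$selector$n, spec = cl,
                                           seed = cfg$seed))
            if (!is.null(sel)) {
              write_selection(sel, file.path(
                output_dir, sprintf("selection_%s.json", key)))
            }
            loocv(fm, cl, selection = sel)
          }
        })
        write_cv_result(res, file.path(output_dir,
                                       sprintf("cv_%s.json", key)))
        grid_cells[[key]] <- data.frame(classifier = tag, picture = img,
                                        normalization = norm,
                                        accuracy = res$accuracy)
      }
    }
  }

  # stage 6: report
  cells <- do.call(rbind, grid_cells)
  grids <- lapply(split(cells, cells$classifier), build_accuracy_grid)
  for (tag in names(grids)) {
    writeLines(format_grid_markdown(grids[[tag]]),
               file.path(output_dir, sprintf("grid_%s.md", tag)))
    write.csv(data.frame(picture = rownames(grids[[tag]]$cells),
                         grids[[tag]]$cells, check.names = FALSE),
              file.path(output_dir, sprintf("grid_%s.csv", tag)),
              row.names = FALSE)
  }
  tsum <- summarize_t_sums(stats_list)
  write.csv(tsum, file.path(output_dir, "group_stats_summary.csv"),
            row.names = FALSE)

  files <- setdiff(list.files(output_dir), "manifest.json")
  manifest <- list(
    config = manifest_config(cfg), seed = cfg$seed,
    package_version = as.character(packageVersion("gazexpert")),
    timings = timings,
    outputs = data.frame(
      file = files,
      md5 = unname(tools::md5sum(file.path(output_dir, files)))),
    grids = grids,
    summary = list(per_normalization = aggregate_grids(grids),
                   t_sums = tsum))
  jsonlite::write_json(
    manifest[c("config", "seed", "package_version", "timings", "outputs")],
    file.path(output_dir, "manifest.json"), digits = NA,
    auto_unbox = TRUE)
  invisible(manifest)
}

manifest_config <- function(cfg) {
  list(input = cfg$input, images = cfg$images, k_range = cfg$k_range,
       em = cfg$em, normalizations = cfg$normalizations,
       selector = cfg$selector,
       classifiers = lapply(cfg$classifiers, unclass),
       cv_mode = cfg$cv_mode, assignment_rule = cfg$assignment_rule,
       seed = cfg$seed)
}
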