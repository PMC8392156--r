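#' Pipeline configuration
#'
#' Bundles every knob of the end-to-end run — design choice, grids, noise
#' profile, top-level seed, analysis modalities, classifier list, number of
#' classification runs, PLSR component ranges and output directory — into a
#' single validated object that round-trips losslessly through JSON or YAML
#' (`write_pipeline_config()` / `read_pipeline_config()`).
#'
#' The single top-level `seed` expands deterministically into per-stage
#' seeds: generation uses `seed`, the classification/augmentation run `i`
#' uses `seed + i - 1`, and the quantification (deterministic given the
#' data) none. This makes each stage independently reproducible.
#'
#' @param design `"mexican"`, `"kenyan"` or `"both"`.
#' @param noise `"default"` or `"clean"` (see [noise_profile()]).
#' @param seed Top-level integer seed.
#' @param n_measurements Repeat measurements per prepared sample.
#' @param modality Analysis modality for classification.
#' @param classifiers Character vector of classification methods (may be
#'   empty to skip the classification stage).
#' @param n_runs Number of repeated classification runs.
#' @param quantify_modalities Modalities for the quantification suite
#'   (empty to skip).
#' @param quantify_series `"all"` or a vector of series ids.
#' @param ncomp_max Upper PLSR component bound for Mexican series.
#' @param out_dir Output directory of [run_pipeline()].
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(design = "mexican", noise = "default", seed = 1,
                            n_measurements = 5, modality = "fused",
                            classifiers = c("DT", "LD", "KNN", "SVMl", "SVMc"),
                            n_runs = 10,
                            quantify_modalities = "fused",
                            quantify_series = "all",
                            ncomp_max = 32,
                            out_dir = "oilspec_run") {
  stopifnot(design %in% c("mexican", "kenyan", "both"),
            noise %in% c("default", "clean"))
  ## JSON/YAML round-trips turn empty vectors into lists; normalize
  classifiers <- as.character(unlist(classifiers))
  quantify_modalities <- as.character(unlist(quantify_modalities))
  quantify_series <- as.character(unlist(quantify_series))
  bad <- setdiff(classifiers, c("DT", "LD", "KNN", "SVMl", "SVMc"))
  if (length(bad) > 0) {
    abort(sprintf("Unknown classifier(s): %s.", paste(bad, collapse = ", ")))
  }
  structure(list(design = design, noise = noise, seed = as.integer(seed),
                 n_measurements = as.integer(n_measurements),
                 modality = modality, classifiers = classifiers,
                 n_runs = as.integer(n_runs),
                 quantify_modalities = quantify_modalities,
                 quantify_series = quantify_series,
                 ncomp_max = as.integer(ncomp_max),
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path File path; `.json` or `.yaml`/`.yml`.
#' @export
write_pipeline_config <- function(config, path) {
  lst <- unclass(config)
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      abort("The 'yaml' package is required for YAML configs; use JSON instead.")
    }
    yaml::write_yaml(lst, path)
  } else {
    jsonlite::write_json(lst, path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  lst <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      abort("The 'yaml' package is required for YAML configs; use JSON instead.")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  do.call(pipeline_config, lst)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat(sprintf("<pipeline_config: %s design, %s noise, seed %d, %d classifiers x %d runs>\n",
              x$design, x$noise, x$seed, length(x$classifiers), x$n_runs))
  invisible(x)
}

pipeline_log <- function(log_path, msg) {
  cat(msg, "\n", sep = "", file = log_path, append = TRUE)
}

#' Run the full pipeline
#'
#' Orchestrates generate -> preprocess -> augment -> classify / quantify
#' end-to-end and writes, under `config$out_dir`: the generated raw spectra
#' CSVs (`spectra/`), the preprocessed feature matrix
#' (`preprocessed_<modality>.csv`), the 1125-row labelled classification
#' table (`labeled_<modality>.csv`, Mexican designs only), per-run
#' confusion matrices (`confusion/`), the classification summary
#' (`classification_summary.json`, one entry per method and run),
#' the quantification table (`quantification.csv`), a stage-granular run
#' log with record counts and seeds (`run.log`) and a manifest of output
#' file hashes (`manifest.json`). A failing stage aborts with a
#' stage-named error; outputs of completed stages are preserved.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the output paths and the in-memory
#'   classification / quantification results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  cat(sprintf("oilspec %s | seed %d | design %s | noise %s\n",
              as.character(utils::packageVersion("oilspec")),
              config$seed, config$design, config$noise),
      file = log_path)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  ## -- generate
  dataset <- stage("generate", {
    design <- switch(config$design, mexican = design_mexican(),
                     kenyan = design_kenyan(), both = design_both())
    ds <- generate_dataset(design, endmember_library(1), default_grids(),
                           noise_profile(config$noise, seed = config$seed),
                           n_measurements = config$n_measurements)
    write_spectra_csv(ds, file.path(out_dir, "spectra"))
    pipeline_log(log_path, sprintf(
      "generate: %d design rows, %d spectra per modality (seed %d)",
      nrow(design), nrow(ds) / 3L, config$seed))
    ds
  })

  ## -- preprocess
  features <- stage("preprocess", {
    f <- preprocess_dataset(dataset, config$modality)
    df <- dplyr::bind_cols(f[, c("sample_label", "preparation", "measurement")],
                           tibble::as_tibble(f$x, .name_repair = "minimal"))
    readr::write_csv(df, file.path(out_dir,
                                   sprintf("preprocessed_%s.csv", config$modality)))
    pipeline_log(log_path, sprintf("preprocess: %d x %d feature matrix (%s)",
                                   nrow(f$x), ncol(f$x), config$modality))
    f
  })

  ## -- augment + classify (Mexican 5-class task)
  class_results <- NULL
  if (length(config$classifiers) > 0 && config$design != "kenyan") {
    class_results <- stage("classify", {
      lab <- assemble_classification_set(features, seed = config$seed)
      lab_df <- dplyr::bind_cols(
        lab[, c("class", "source", "sample_label")],
        tibble::as_tibble(lab$x, .name_repair = "minimal"))
      readr::write_csv(lab_df, file.path(out_dir,
                                         sprintf("labeled_%s.csv", config$modality)))
      pipeline_log(log_path, sprintf("augment: %d labelled spectra (seed %d)",
                                     nrow(lab), config$seed))
      dir.create(file.path(out_dir, "confusion"), showWarnings = FALSE)
      seeds <- config$seed + seq_len(config$n_runs) - 1L
      res <- lapply(config$classifiers, function(meth) {
        rs <- repeat_runs(dataset, meth, seeds = seeds,
                          modality = config$modality)
        for (i in seq_along(rs$runs)) {
          readr::write_csv(
            tibble::as_tibble(rs$runs[[i]]$confusion, rownames = "true"),
            file.path(out_dir, "confusion",
                      sprintf("%s_seed%d.csv", meth, seeds[i])))
        }
        pipeline_log(log_path, sprintf(
          "classify: %s median TPR %.1f%% over %d runs", meth,
          rs$summary$median[rs$summary$metric == "tpr"], config$n_runs))
        rs
      })
      names(res) <- config$classifiers
      summary_json <- list(
        modality = config$modality, n_runs = config$n_runs,
        runs = purrr::map_dfr(res, function(rs) {
          purrr::map_dfr(rs$runs, glance)
        }),
        summary = purrr::map_dfr(res, tidy, .id = "method")
      )
      jsonlite::write_json(summary_json,
                           file.path(out_dir, "classification_summary.json"),
                           dataframe = "rows", auto_unbox = TRUE, digits = NA)
      res
    })
  } else {
    pipeline_log(log_path, "classify: skipped")
  }

  ## -- quantify
  quant <- NULL
  if (length(config$quantify_modalities) > 0) {
    quant <- stage("quantify", {
      q <- run_quantification_suite(dataset,
                                    modalities = config$quantify_modalities,
                                    series = config$quantify_series,
                                    ncomp_max = config$ncomp_max)
      readr::write_csv(q, file.path(out_dir, "quantification.csv"))
      pipeline_log(log_path, sprintf("quantify: %d series x modality fits", nrow(q)))
      q
    })
  } else {
    pipeline_log(log_path, "quantify: skipped")
  }

  ## -- manifest
  files <- setdiff(list.files(out_dir, recursive = TRUE), basename(log_path))
  manifest <- tibble::tibble(
    file = files,
    md5 = unname(tools::md5sum(file.path(out_dir, files)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE)
  invisible(list(out_dir = out_dir, dataset = dataset,
                 classification = class_results, quantification = quant))
}
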