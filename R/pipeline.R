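#' Run the full extraction pipeline over a directory or phantom set
#'
#' Batch orchestration: images are read from `input_dir` (one subfolder
#' per class, names mapped to labels via `config$labels`) or generated by
#' the phantom module when `phantom` is supplied. Each image goes through
#' contrast enhancement, masking, adaptive thresholding and segmentation;
#' per-image failures are logged and skipped. The feature table is written
#' as CSV (`source_id`, `label`, then the 17 features in fixed order).
#' Optional stages rank the features and evaluate a classifier.
#'
#' @param config A `pipeline_config` (see [default_config()]).
#' @param input_dir Directory of class subfolders with PNG/JPEG images, or
#'   NULL when using phantoms.
#' @param phantom NULL, or a list of arguments for
#'   [generate_phantom_dataset()] (e.g. `list(n_per_stage = 25)`).
#' @param output_dir Where to write `features.csv` (and reports); NULL to
#'   skip writing.
#' @param rank `"mrmr"`, `"chi2"` or NULL (skip ranking).
#' @param classify Logical; run [split_and_evaluate()] with
#'   `config$classifier` (default FALSE).
#' @return List: `features` (data frame), `failures`, and optionally
#'   `ranking`, `evaluation`, `csv_path`.
#' @export
run_pipeline <- function(config = default_config(), input_dir = NULL,
                         phantom = NULL, output_dir = NULL,
                         rank = NULL, classify = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(input_dir) && is.null(phantom))
    stop("provide input_dir or a phantom argument list")

  if (!is.null(phantom)) {
    phantom$seed <- phantom$seed %||% config$seed
    ds <- do.call(generate_phantom_dataset, phantom)
    images <- ds$images
    labels <- ds$labels
    ids <- sprintf("phantom_stage%d_%03d", labels,
                   stats::ave(seq_along(labels), labels, FUN = seq_along))
  } else {
    classes <- list.dirs(input_dir, recursive = FALSE, full.names = FALSE)
    if (!length(classes)) stop("no class subfolders in ", input_dir)
    files <- character(0); labels <- integer(0)
    for (cl in classes) {
      fs <- list.files(file.path(input_dir, cl),
                       pattern = "\\.(png|jpe?g)$", ignore.case = TRUE,
                       full.names = TRUE)
      lb <- config$labels[[cl]]
      if (is.null(lb)) {
        warning("no label mapping for folder '", cl, "'; skipped")
        next
      }
      files <- c(files, fs)
      labels <- c(labels, rep(as.integer(lb), length(fs)))
    }
    if (!length(files)) stop("no images found under ", input_dir)
    images <- lapply(files, load_image)
    ids <- basename(files)
  }

  tab <- extract_feature_table(images, labels = labels, ids = ids,
                               config = config)
  failures <- attr(tab, "failures")
  if (nrow(failures) > length(images) / 2)
    stop(sprintf("aborting: %d of %d extractions failed",
                 nrow(failures), length(images)))
  message(sprintf("extracted %d/%d images (%d failures)",
                  nrow(tab), length(images), nrow(failures)))

  out <- list(features = tab, failures = failures)
  fx <- tab[, .FEATURE_NAMES, drop = FALSE]

  if (!is.null(rank)) {
    out$ranking <- switch(rank,
      mrmr = mrmr_rank(fx, tab$label, bins = config$ranking$mrmr_bins),
      chi2 = chi2_rank(fx, tab$label, bins = config$ranking$chi2_bins),
      stop("rank must be 'mrmr' or 'chi2'"))
  }
  if (isTRUE(classify)) {
    out$evaluation <- split_and_evaluate(
      fx, tab$label, classifier = config$classifier$model,
      seed = config$seed, n_repeats = config$classifier$n_repeats,
      mode = config$classifier$mode)
  }
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    csv <- file.path(output_dir, "features.csv")
    write.csv(tab, csv, row.names = FALSE)
    if (nrow(failures))
      write.csv(failures, file.path(output_dir, "failures.csv"),
                row.names = FALSE)
    if (!is.null(out$ranking))
      write.csv(out$ranking$ranking, file.path(output_dir, "ranking.csv"),
                row.names = FALSE)
    if (!is.null(out$evaluation)) {
      ev <- out$evaluation
      jsonlite::write_json(
        list(classifier = ev$classifier, seed = ev$seed,
             mean = as.list(ev$mean), sd = as.list(ev$sd),
             confusion = ev$confusion),
        file.path(output_dir, "evaluation.json"), auto_unbox = TRUE,
        digits = NA)
    }
    out$csv_path <- csv
  }
  out
}
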