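#' Default pipeline configuration
#'
#' All tunables of the pipeline with their defaults: bit depth, brain-mask
#' options, lowpass filter design, thresholding rule and leakage floor,
#' ranking discretization, classifier setup and the master seed.
#' `transition_width = NULL` means the design default
#' `0.15 * (1 - passband_edge)`.
#'
#' @return Nested named list of class `pipeline_config`.
#' @export
default_config <- function() {
  structure(
    list(
      bit_depth = 8L,
      mask = list(threshold = 0L, brush_size = 3L),
      filter = list(passband_edge = 0.005, stopband_atten = 60,
                    transition_width = NULL),
      threshold = list(th1_rule = "second_minimum", floor_rel = 0.005),
      ranking = list(mrmr_bins = 16L, chi2_bins = 10L),
      classifier = list(model = "svm", n_repeats = 10L, mode = "holdout"),
      labels = list(NonDemented = 0L, VeryMildDemented = 1L,
                    MildDemented = 2L, ModerateDemented = 3L),
      seed = 1L
    ),
    class = "pipeline_config"
  )
}

#' Save / load a pipeline configuration as YAML
#'
#' Round-trip safe: `load_config(save_config(cfg, path))` reproduces the
#' configuration. Missing fields are filled from [default_config()].
#'
#' @param config A `pipeline_config`.
#' @param path YAML file path.
#' @return `save_config` returns `path` invisibly; `load_config` returns a
#'   `pipeline_config`.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- default_config()
  merge_into <- function(base, upd) {
    for (nm in names(upd)) {
      if (is.null(upd[[nm]])) base[nm] <- list(NULL)
      else if (is.list(base[[nm]]) && is.list(upd[[nm]]))
        base[[nm]] <- merge_into(base[[nm]], upd[[nm]])
      else base[[nm]] <- upd[[nm]]
    }
    base
  }
  out <- merge_into(unclass(cfg), raw)
  # integer-valued fields come back from YAML as integer already; enforce
  # types that matter downstream
  out$bit_depth <- as.integer(out$bit_depth)
  out$seed <- as.integer(out$seed)
  structure(out, class = "pipeline_config")
}
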