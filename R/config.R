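## Run configuration: YAML in, validated + default-filled RunConfig out.

threshold_schema <- function() {
  ## name -> list(default, min, max, integer?)
  list(
    pol_cutoff = list(default = 0.25, min = 0, max = 1),
    area_cutoff = list(default = 0.1, min = 0, max = 1),
    ratio_delta = list(default = 0.05, min = 0, max = 0.5),
    band_depth_um = list(default = 1.5, min = 1e-6, max = 20),
    central_fraction = list(default = 0.5, min = 0.05, max = 1),
    spot_min_size = list(default = 4, min = 1, max = 1e4, integer = TRUE),
    spot_k_mad = list(default = 5, min = 0.5, max = 100),
    max_link_um = list(default = 1, min = 1e-6, max = 100),
    min_track_len = list(default = 3, min = 2, max = 1e4, integer = TRUE),
    rim_fraction = list(default = 0.5, min = 0.05, max = 0.95),
    slab_depth_um = list(default = 1.5, min = 0.1, max = 20)
  )
}

top_level_keys <- function() {
  c("mode", "n_scenes", "seed", "out_dir", "input", "scene",
    "polarized_fraction", "thresholds")
}

#' Validate and normalize a run configuration
#'
#' Accepts a YAML file path or an R list. Unknown keys are rejected;
#' thresholds outside their documented domain produce an error naming the
#' key and the valid range; missing values are filled with the documented
#' defaults (polarization cutoff 0.25, area-ratio cutoff 0.1, ratio
#' tolerance 0.05, IS band depth 1.5 um, central fraction 0.5, minimum spot
#' size 4 px, ...).
#'
#' @param config path to a YAML file, or a named list.
#' @return normalized `run_config` list with every effective value filled.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config))
      sp_stop("unreadable_input", sprintf("config file not found: %s", config))
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  if (!is.list(config)) sp_stop("invalid_config", "config must be a mapping")
  unknown <- setdiff(names(config), top_level_keys())
  if (length(unknown) > 0)
    sp_stop("unknown_key",
            sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  mode <- config$mode %||% "simulate_measure"
  if (!mode %in% c("simulate", "measure", "simulate_measure", "cohort"))
    sp_stop("invalid_config",
            "mode must be one of simulate, measure, simulate_measure, cohort")
  schema <- threshold_schema()
  thr_in <- config$thresholds %||% list()
  unknown <- setdiff(names(thr_in), names(schema))
  if (length(unknown) > 0)
    sp_stop("unknown_key",
            sprintf("unknown threshold key(s): %s",
                    paste(unknown, collapse = ", ")))
  thresholds <- lapply(names(schema), function(k) {
    s <- schema[[k]]
    v <- thr_in[[k]] %||% s$default
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) ||
        v < s$min || v > s$max)
      sp_stop("invalid_config",
              sprintf("threshold '%s' = %s outside valid range [%g, %g]",
                      k, format(v), s$min, s$max))
    if (isTRUE(s$integer)) v <- as.integer(v)
    v
  })
  names(thresholds) <- names(schema)
  pf <- config$polarized_fraction %||% 0.7
  if (pf < 0 || pf > 1)
    sp_stop("invalid_config",
            "polarized_fraction outside valid range [0, 1]")
  n_scenes <- as.integer(config$n_scenes %||% 10L)
  if (n_scenes < 1) sp_stop("invalid_config", "n_scenes must be >= 1")
  scene_over <- config$scene %||% list()
  spec0 <- tryCatch(do.call(scene_spec, scene_over),
                    error = function(e) {
                      if (inherits(e, "synapsepol_error")) stop(e)
                      sp_stop("unknown_key",
                              sprintf("bad scene field: %s", conditionMessage(e)))
                    })
  structure(list(mode = mode, n_scenes = n_scenes,
                 seed = as.integer(config$seed %||% 1L),
                 out_dir = config$out_dir %||% "synapsepol_out",
                 input = config$input,
                 scene = spec0, polarized_fraction = pf,
                 thresholds = thresholds),
            class = "run_config")
}
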