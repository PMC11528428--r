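#' Analysis run configuration
#'
#' Bundles the tunable parameters of the pipeline with validation and
#' defaults.  Parameters mirror the quantities that control each stage:
#' the expansion factors `f_d`, `f_v`, `f_k` scale the mean first
#' nearest-neighbour distance into the acceptance thresholds of the
#' Delaunay, Voronoi and ks-density area estimators; `th_constant` is the
#' ks-density rejection-threshold constant c in TH = c / (2 pi sigma^2 N);
#' `proximity_nm` is the pair-association distance criterion; and
#' `tirf_depth_nm` converts occupied area to an observation volume for
#' molar-scale dissociation constants (must lie in 100-250 nm, the span of
#' TIRF evanescent-field depths).
#'
#' @param pixel_size_nm Camera pixel size (nm), used only at I/O boundaries.
#' @param f_d,f_v,f_k Dimensionless expansion factors (> 0).
#' @param th_constant ks-density threshold constant (> 0).
#' @param proximity_nm Proximity criterion for association (nm).
#' @param tirf_depth_nm TIRF depth (nm), in `[100, 250]`.
#' @param seed Integer seed for all stochastic stages.
#' @param frame_interval_s Camera frame interval (s).
#' @return A validated list of class `smlmeq_config`.
#' @export
run_config <- function(pixel_size_nm = 130,
                       f_d = 3, f_v = 3, f_k = 1,
                       th_constant = 1.5,
                       proximity_nm = 25,
                       tirf_depth_nm = 100,
                       seed = 1L,
                       frame_interval_s = 0.1) {
  cfg <- list(pixel_size_nm = pixel_size_nm, f_d = f_d, f_v = f_v, f_k = f_k,
              th_constant = th_constant, proximity_nm = proximity_nm,
              tirf_depth_nm = tirf_depth_nm, seed = as.integer(seed),
              frame_interval_s = frame_interval_s)
  validate_config(cfg)
  structure(cfg, class = "smlmeq_config")
}

validate_config <- function(cfg) {
  for (nm in c("f_d", "f_v", "f_k", "th_constant")) {
    if (!is.numeric(cfg[[nm]]) || cfg[[nm]] <= 0) {
      abort(sprintf("`%s` must be a positive number.", nm))
    }
  }
  if (cfg$proximity_nm <= 0) abort("`proximity_nm` must be positive.")
  if (cfg$tirf_depth_nm < 100 || cfg$tirf_depth_nm > 250) {
    abort("`tirf_depth_nm` must lie in [100, 250] nm.")
  }
  if (cfg$frame_interval_s <= 0) abort("`frame_interval_s` must be positive.")
  invisible(cfg)
}

#' Read a run configuration from a YAML file
#'
#' Flat keys mirror the arguments of [run_config()]; keys absent from the
#' file keep their defaults, and entries in `overrides` (e.g. parsed CLI
#' flags) take precedence over the file.
#'
#' @param path YAML file path, or `NULL` for defaults only.
#' @param overrides Named list overriding file values.
#' @return A validated `smlmeq_config` list.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  vals <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) abort(sprintf("Config file not found: %s", path))
    vals <- yaml::read_yaml(path)
  }
  vals[names(overrides)] <- overrides
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0L) {
    abort(sprintf("Unknown configuration key(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  do.call(run_config, vals)
}
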