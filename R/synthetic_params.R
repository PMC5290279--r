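#' Parameters for the synthetic single-cell count generator
#'
#' Bundles and validates every knob of [generate_counts()]. The defaults
#' emulate the study design the package targets: three planted interneuron
#' types sampled at three developmental stages (E18, P2, P5), 25 cells per
#' type per stage, 2,000 genes with 50 disjoint marker genes per type
#' planted at a log2 fold change of 3 over baseline.
#'
#' Counts are negative binomial with gene-specific means drawn log-uniform
#' over `baseline_mean_log_range` (natural-log bounds, count scale) and a
#' shared size (dispersion) parameter. Marker-gene baselines are drawn from
#' `marker_mean_log_range` so that planted markers are decently expressed,
#' as real type markers are. On top of NB sampling, each count is zeroed
#' (dropout) with probability
#' `plogis(-dropout_slope * (log(mu) - log(dropout_midpoint)))`,
#' i.e. a logistic in the log NB mean with 50% dropout at
#' `dropout_midpoint`.
#'
#' @param n_genes number of genes (in addition to the six interneuron
#'   housekeeping markers Dlx1/2/5/6, Gad1/2 that are always prepended).
#' @param cells_per_type_per_stage cells per planted type per stage.
#' @param n_types number of planted cell types (>= 1).
#' @param n_stages number of developmental stages.
#' @param stage_labels labels for the stages; length `n_stages`.
#' @param markers_per_type planted marker genes per type (disjoint sets).
#' @param marker_log2fc log2 fold change of a marker in its own type.
#' @param baseline_mean_log_range length-2 numeric, natural-log bounds of
#'   the baseline NB mean (count scale).
#' @param marker_mean_log_range natural-log bounds of marker baselines.
#' @param dispersion NB size parameter (smaller = more overdispersed).
#' @param dropout_midpoint NB mean (counts) at which dropout probability
#'   is 0.5.
#' @param dropout_slope slope of the dropout logistic in log-mean; 0 gives
#'   a flat 0.5 dropout probability everywhere.
#' @param qc_fail_fraction fraction of cells planted to fail exactly one
#'   QC criterion.
#' @param stage_shift_fraction fraction of genes given a global per-stage
#'   log2 shift (default 0 = off); used to exercise time-course code.
#' @param stage_shift_log2fc per-stage increment (log2) for shifted genes.
#' @param seed integer seed; fixed seed gives bit-identical output.
#' @return an object of class `synthetic_params` (a validated list).
#' @export
synthetic_params <- function(n_genes = 2000,
                             cells_per_type_per_stage = 25,
                             n_types = 3,
                             n_stages = 3,
                             stage_labels = c("E18", "P2", "P5"),
                             markers_per_type = 50,
                             marker_log2fc = 3,
                             baseline_mean_log_range = log(c(0.5, 100)),
                             marker_mean_log_range = log(c(10, 100)),
                             dispersion = 1,
                             dropout_midpoint = 10,
                             dropout_slope = 1,
                             qc_fail_fraction = 0,
                             stage_shift_fraction = 0,
                             stage_shift_log2fc = 0,
                             seed = 1L) {
  p <- list(
    n_genes = n_genes,
    cells_per_type_per_stage = cells_per_type_per_stage,
    n_types = n_types,
    n_stages = n_stages,
    stage_labels = stage_labels,
    markers_per_type = markers_per_type,
    marker_log2fc = marker_log2fc,
    baseline_mean_log_range = baseline_mean_log_range,
    marker_mean_log_range = marker_mean_log_range,
    dispersion = dispersion,
    dropout_midpoint = dropout_midpoint,
    dropout_slope = dropout_slope,
    qc_fail_fraction = qc_fail_fraction,
    stage_shift_fraction = stage_shift_fraction,
    stage_shift_log2fc = stage_shift_log2fc,
    seed = seed
  )
  validate_synthetic_params(p)
  class(p) <- "synthetic_params"
  p
}

validate_synthetic_params <- function(p) {
  stop_param <- function(msg) stop("invalid synthetic parameters: ", msg,
                                   call. = FALSE)
  is_count <- function(x) length(x) == 1L && is.numeric(x) &&
    is.finite(x) && x >= 0 && x == round(x)
  if (!is_count(p$n_genes) || p$n_genes < 1) stop_param("n_genes must be a positive integer")
  if (!is_count(p$cells_per_type_per_stage) || p$cells_per_type_per_stage < 1)
    stop_param("cells_per_type_per_stage must be a positive integer")
  if (!is_count(p$n_types) || p$n_types < 1) stop_param("n_types must be >= 1")
  if (!is_count(p$n_stages) || p$n_stages < 1) stop_param("n_stages must be >= 1")
  if (length(p$stage_labels) != p$n_stages) stop_param("stage_labels length must equal n_stages")
  if (!is_count(p$markers_per_type)) stop_param("markers_per_type must be a nonnegative integer")
  if (p$markers_per_type * p$n_types > p$n_genes)
    stop_param("marker sets (disjoint) cannot exceed n_genes")
  if (!is.finite(p$marker_log2fc)) stop_param("marker_log2fc must be finite")
  if (length(p$baseline_mean_log_range) != 2L ||
      any(!is.finite(p$baseline_mean_log_range)) ||
      diff(p$baseline_mean_log_range) < 0)
    stop_param("baseline_mean_log_range must be an increasing length-2 range")
  if (!is.finite(p$dispersion) || p$dispersion <= 0) stop_param("dispersion must be positive")
  if (!is.finite(p$dropout_midpoint) || p$dropout_midpoint <= 0)
    stop_param("dropout_midpoint must be positive")
  if (!is.finite(p$dropout_slope)) stop_param("dropout_slope must be finite")
  if (!is.finite(p$qc_fail_fraction) || p$qc_fail_fraction < 0 || p$qc_fail_fraction > 1)
    stop_param("qc_fail_fraction must be in [0, 1]")
  if (!is_count(abs(p$seed))) stop_param("seed must be an integer")
  invisible(TRUE)
}

#' Parameters for the synthetic migration-track generator
#'
#' Tracks are correlated (biased-persistence) random walks sampled every
#' `dt` minutes, emulating time-lapse movies of grafted migrating
#' interneurons imaged every 10 minutes over 8 hours.
#'
#' @param n_tracks number of tracks (cells).
#' @param n_steps number of steps per track (>= 2); a track has
#'   `n_steps + 1` time-stamped samples.
#' @param dt frame interval in minutes (default 10).
#' @param step_length_mean mean step length in micrometers per frame.
#' @param turning_concentration nonnegative; turning angles are
#'   `Normal(0, 1/turning_concentration)` wrapped; 0 means isotropic
#'   (uniform) turning, larger values give straighter, more persistent
#'   walks.
#' @param seed integer seed.
#' @return an object of class `track_params`.
#' @export
track_params <- function(n_tracks = 50,
                         n_steps = 48,
                         dt = 10,
                         step_length_mean = 10,
                         turning_concentration = 1,
                         seed = 1L) {
  p <- list(n_tracks = n_tracks, n_steps = n_steps, dt = dt,
            step_length_mean = step_length_mean,
            turning_concentration = turning_concentration, seed = seed)
  stop_param <- function(msg) stop("invalid track parameters: ", msg, call. = FALSE)
  if (!is.numeric(p$n_steps) || p$n_steps < 2) stop_param("n_steps must be >= 2")
  if (!is.numeric(p$dt) || p$dt <= 0) stop_param("dt must be positive")
  if (!is.numeric(p$n_tracks) || p$n_tracks < 1) stop_param("n_tracks must be >= 1")
  if (!is.numeric(p$step_length_mean) || p$step_length_mean < 0)
    stop_param("step_length_mean must be nonnegative")
  if (!is.numeric(p$turning_concentration) || p$turning_concentration < 0)
    stop_param("turning_concentration must be nonnegative")
  class(p) <- "track_params"
  p
}
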