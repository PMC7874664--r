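#' Pipeline run configuration
#'
#' Collects every stage parameter of the DPDR pipeline in one validated
#' object that is serialised alongside the outputs, so a run can be
#' reproduced from its artifacts alone. Validation happens before any
#' computation: in particular a high-pass cutoff at or above the Nyquist
#' frequency is rejected here.
#'
#' @param out_dir output directory for stage artifacts.
#' @param seed integer seed governing both the imaging and cohort
#'   simulations (stage-specific seeds are derived from it).
#' @param imaging named list of overrides for [synth_imaging_params()].
#' @param cohort named list of overrides for [cohort_params()].
#' @param cutoff_hz high-pass cutoff (Hz).
#' @param window_frames CCv window length, or `NULL` for one estimated
#'   cardiac period.
#' @param spatial_bin k for k x k binning before correlation (1 = off).
#' @param clip_negative clip negative MaxCCv values when summing.
#' @param affected_side side used for the BFR reduction.
#' @param stages contiguous subset of
#'   `c("simulate", "perfmap", "bfr", "ppo", "agree")` to execute.
#' @param log_level `"info"` or `"quiet"`.
#' @return an object of class `run_config`.
#' @export
run_config <- function(out_dir,
                       seed = 1L,
                       imaging = list(),
                       cohort = list(),
                       cutoff_hz = 0.85,
                       window_frames = NULL,
                       spatial_bin = 1L,
                       clip_negative = FALSE,
                       affected_side = "left",
                       stages = c("simulate", "perfmap", "bfr", "ppo", "agree"),
                       log_level = c("info", "quiet")) {
  all_stages <- c("simulate", "perfmap", "bfr", "ppo", "agree")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  pos <- match(stages, all_stages)
  if (any(diff(sort(pos)) != 1L))
    stopf("`stages` must be a contiguous subset of %s",
          paste(all_stages, collapse = " -> "))
  cfg <- list(out_dir = out_dir, seed = as.integer(seed),
              imaging = imaging, cohort = cohort,
              cutoff_hz = cutoff_hz, window_frames = window_frames,
              spatial_bin = as.integer(spatial_bin),
              clip_negative = isTRUE(clip_negative),
              affected_side = match.arg(affected_side, c("left", "right")),
              stages = all_stages[sort(pos)],
              log_level = match.arg(log_level))
  class(cfg) <- "run_config"
  validate_run_config(cfg)
  cfg
}

validate_run_config <- function(cfg) {
  ip <- do.call(synth_imaging_params,
                modifyList(cfg$imaging, list(rng_seed = cfg$seed)))
  if (cfg$cutoff_hz >= ip$frame_rate_hz / 2 || cfg$cutoff_hz <= 0)
    stopf("cutoff_hz (%g) must lie in (0, Nyquist = %g)",
          cfg$cutoff_hz, ip$frame_rate_hz / 2)
  if (cfg$spatial_bin < 1L) stopf("spatial_bin must be >= 1")
  invisible(cfg)
}

#' Load / save a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @param cfg a [run_config()].
#' @return `load_run_config()` returns a [run_config()];
#'   `save_run_config()` returns `path` invisibly.
#' @export
load_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  y$stages <- unlist(y$stages)
  do.call(run_config, y)
}

#' @rdname load_run_config
#' @export
save_run_config <- function(cfg, path) {
  y <- unclass(cfg)
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Run the DPDR analysis pipeline
#'
#' Executes the configured stages in order — simulate (synthetic sequence
#' + cohort), perfmap (reference signal + CCv map), bfr (left/right
#' reduction), ppo (postoperative predictions), agree (agreement and
#' complication statistics) — writing each stage's artifacts into
#' `cfg$out_dir` together with a manifest (`manifest.json`) listing every
#' file with its MD5 hash and the configuration that produced it. Stages
#' later in the chain read the artifacts of earlier ones from the output
#' directory, so a later subset can be re-run against existing files.
#' On error, files written by the failed invocation are removed.
#'
#' @param cfg a [run_config()] (or a path to a YAML file for one).
#' @return invisibly, a named list of the in-memory stage results.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- load_run_config(cfg)
  stopifnot(inherits(cfg, "run_config"))
  validate_run_config(cfg)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  note <- function(...) {
    if (cfg$log_level == "info") message(sprintf(...))
  }
  emit <- function(path) written <<- c(written, path)
  results <- list()

  pth <- function(f) file.path(cfg$out_dir, f)
  ok <- FALSE
  on.exit(if (!ok && length(written) > 0) unlink(written), add = TRUE)

  for (stage in cfg$stages) {
    note("stage: %s", stage)
    if (stage == "simulate") {
      ip <- do.call(synth_imaging_params,
                    modifyList(cfg$imaging, list(rng_seed = cfg$seed)))
      sim <- generate_sequence(ip)
      write_frame_sequence(sim$sequence, pth("sequence.tif"),
                           truth = sim$truth, rng_seed = cfg$seed)
      emit(pth("sequence.tif")); emit(pth("sequence.tif.json"))
      write_masks(sim$masks, pth("masks.tif")); emit(pth("masks.tif"))
      cp <- do.call(cohort_params,
                    modifyList(cfg$cohort, list(rng_seed = cfg$seed + 1L)))
      cohort <- generate_cohort(cp)
      write_cohort(cohort, pth("cohort.csv")); emit(pth("cohort.csv"))
      results$simulate <- sim
      results$cohort <- cohort
    } else if (stage == "perfmap") {
      seq_ <- results$simulate$sequence %||% read_frame_sequence(pth("sequence.tif"))
      masks <- results$simulate$masks %||% read_masks(pth("masks.tif"))
      cardiac <- extract_ventricle_signal(seq_, masks, cutoff_hz = cfg$cutoff_hz)
      map <- compute_ccv(seq_, cardiac, masks,
                         window_frames = cfg$window_frames,
                         cutoff_hz = cfg$cutoff_hz,
                         spatial_bin = cfg$spatial_bin, store_ccv = FALSE)
      write_perfusion_map(map, pth("max_ccv.tif"))
      emit(pth("max_ccv.tif")); emit(pth("max_ccv.tif.json"))
      results$perfmap <- map
      results$masks <- masks
    } else if (stage == "bfr") {
      masks <- results$masks %||% read_masks(pth("masks.tif"))
      map <- results$perfmap
      if (is.null(map)) {
        rm_ <- read_perfusion_map(pth("max_ccv.tif"))
        map <- structure(list(max_ccv = rm_$max_ccv,
                              undefined = matrix(FALSE, nrow(rm_$max_ccv),
                                                 ncol(rm_$max_ccv)),
                              valid_frames = rm_$valid_frames,
                              window_frames = rm_$window_frames,
                              cardiac_freq_hz_est = rm_$cardiac_freq_hz_est),
                         class = "perfusion_map")
      }
      sums <- sum_max_ccv(map, masks, clip_negative = cfg$clip_negative)
      bfr <- blood_flow_ratio(sums, cfg$affected_side)
      write_bfr_json(bfr, sums, pth("bfr.json"),
                     provenance = list(seed = cfg$seed,
                                       cutoff_hz = cfg$cutoff_hz,
                                       input_md5 = as.list(file_md5(pth("max_ccv.tif")))))
      emit(pth("bfr.json"))
      results$bfr <- bfr
      results$sums <- sums
    } else if (stage == "ppo") {
      cohort <- results$cohort %||% read_cohort(pth("cohort.csv"))
      ppo <- ppo_cohort(cohort)
      write_cohort(ppo, pth("ppo.csv")); emit(pth("ppo.csv"))
      results$ppo <- ppo
    } else if (stage == "agree") {
      ppo <- results$ppo %||% read_cohort(pth("ppo.csv"))
      rep_ <- cohort_agreement(ppo)
      jsonlite::write_json(rep_, pth("agreement.json"), auto_unbox = TRUE,
                           digits = NA, force = TRUE)
      emit(pth("agreement.json"))
      results$agree <- rep_
    }
  }

  manifest <- list(config = unclass(cfg),
                   files = as.list(file_md5(unique(written))))
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  ok <- TRUE
  note("wrote %d artifacts to %s", length(unique(written)) + 1L, cfg$out_dir)
  invisible(results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Agreement and complication statistics for a predicted cohort
#'
#' The statistical battery applied to a cohort that has been through
#' [ppo_cohort()]: method agreement between the DPDR and comparator BFRs
#' (Pearson/regression and Bland-Altman, on the percent scale), correlation
#' of predicted against measured postoperative values at months 1 and 3,
#' an unpaired t test of ppo%DLco by respiratory-complication status, and
#' complication-rate tables by risk band.
#'
#' @param ppo a cohort data frame with prediction columns (see
#'   [ppo_cohort()]) and measured/complication columns (see
#'   [generate_cohort()]).
#' @return a named list of results (lists and data frames, JSON-ready).
#' @export
cohort_agreement <- function(ppo) {
  out <- list()
  if (all(c("dpdr_bfr_affected", "pps_bfr_affected") %in% names(ppo))) {
    x <- 100 * ppo$dpdr_bfr_affected   # percent scale for agreement stats
    y <- 100 * ppo$pps_bfr_affected
    out$bfr_methods <- list(
      pearson = pearson_regression(x, y),
      bland_altman = unclass(bland_altman(x, y))[
        c("n", "mean_difference", "sd_difference", "loa_low", "loa_high",
          "pct_within_2sd", "prop_error_slope", "prop_error_intercept")]
    )
  }
  pred_meas <- list(
    fev1_m1 = c("ppo_fev1_perfusion_l", "measured_fev1_m1_l"),
    fev1_m3 = c("ppo_fev1_perfusion_l", "measured_fev1_m3_l"),
    dlco_m1 = c("ppo_dlco_perfusion", "measured_dlco_m1"),
    dlco_m3 = c("ppo_dlco_perfusion", "measured_dlco_m3")
  )
  for (nm in names(pred_meas)) {
    cols <- pred_meas[[nm]]
    if (all(cols %in% names(ppo)))
      out[[paste0("predicted_vs_measured_", nm)]] <-
        pearson_regression(ppo[[cols[1L]]], ppo[[cols[2L]]])
  }
  if (all(c("ppo_pct_dlco", "complication_respiratory") %in% names(ppo))) {
    grp <- as.logical(ppo$complication_respiratory)
    if (sum(grp) >= 2L && sum(!grp) >= 2L)
      out$ppo_pct_dlco_by_resp_complication <-
        unpaired_t_test(ppo$ppo_pct_dlco[grp], ppo$ppo_pct_dlco[!grp])
  }
  if (all(c("dlco_band", "complication_respiratory") %in% names(ppo)))
    out$resp_rate_by_dlco_band <- as.data.frame(
      complication_rates(ppo$dlco_band, as.logical(ppo$complication_respiratory)))
  if (all(c("fev1_band", "complication_any") %in% names(ppo)))
    out$any_rate_by_fev1_band <- as.data.frame(
      complication_rates(ppo$fev1_band, as.logical(ppo$complication_any)))
  if (all(c("complication_respiratory", "complication_cardiovascular") %in% names(ppo)))
    out$complication_summary <- complication_summary(ppo)
  out
}
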