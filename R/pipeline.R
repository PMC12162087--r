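# End-to-end pipeline: run configuration, the scan protocol, dataset
# simulation with file export, and single-hemisphere localization
# (simulate -> GLM -> contrasts -> delineation -> metrics).

#' Default run configuration
#'
#' One nested list holding every tunable of the pipeline: the master seed,
#' hemisphere geometry/tuning, the three localizer schedules, the scan
#' protocol (2 x 2D runs, 1 x 3D run, 1 opponent run, 12 pRF-mapping runs),
#' noise/drift/baseline of the BOLD simulator, the mapping-aperture
#' specification (12.2 deg radius), pRF-fit settings and ROI-delineation
#' settings. Round-trips losslessly through JSON.
#'
#' @param seed Master seed; every stochastic stage derives its own seed from
#'   it via [derive_seed()].
#' @return A config list.
#' @export
default_config <- function(seed = 1) {
  list(
    seed = seed,
    tr = 1,
    hemisphere = hemisphere_config(),
    schedules = list(
      motion2d = list(block_s = 15, reps_per_direction = 3, blank_s = 15),
      motion3d = list(block_s = 10, reps = 15, blank_s = 15),
      opponent = list(block_s = 15, n_blocks = 21)),
    runs = list(n_2d = 2, n_3d = 1, n_opponent = 1, n_prf = 12),
    noise_sd = 0.5, drift_slope = 1, baseline = 100,
    aperture = list(radius = 12.2, grid_size = 101, n_steps = 8, step_s = 3),
    fit = list(pos_step = 1, sigma_min = 0.25, sigma_max = 24, n_sigma = 20,
               refine_tol = 1e-4),
    roi = list(q_start = 95, q_floor = 90, q_step = 1, adjacency = 3, min_size = 5),
    bias = list(sizes = c(1, 5, 10, 15, 20), eccs = c(0, 3, 6, 9, 12),
                noise_levels = c(0, 0.5, 2), n_voxels = 50, n_boot = 100))
}

#' Validate a run configuration
#'
#' Checks that every required field is present and well-formed; errors name
#' the offending field.
#'
#' @param config A config list.
#' @return `config`, invisibly.
#' @export
validate_config <- function(config) {
  required <- c("seed", "tr", "hemisphere", "schedules", "runs", "noise_sd",
                "drift_slope", "baseline", "aperture", "fit", "roi", "bias")
  missing <- setdiff(required, names(config))
  if (length(missing) > 0)
    stop("config is missing required field(s): ", paste(missing, collapse = ", "))
  if (!is.numeric(config$seed)) stop("config field 'seed' must be numeric")
  if (config$noise_sd < 0) stop("config field 'noise_sd' must be >= 0")
  if (config$tr <= 0) stop("config field 'tr' must be positive")
  invisible(config)
}

#' Serialize / restore a run configuration
#' @param config A config list.
#' @param path JSON path.
#' @return `path` / the restored config.
#' @export
write_config <- function(config, path) {
  # named atomic vectors become JSON objects so their names survive
  namify <- function(x) {
    if (is.list(x)) lapply(x, namify)
    else if (is.atomic(x) && !is.null(names(x))) as.list(x)
    else x
  }
  jsonlite::write_json(namify(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  # named vectors come back as named lists; consumers coerce with unlist()
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Scan protocol implied by a configuration
#'
#' One row per scan. The default protocol has two 2D-motion localizer runs,
#' one 3D-motion run, one opponent-motion run, and twelve pRF-mapping runs
#' (half translating-bar apertures, half wedge+ring apertures, in both cases
#' split between the static and the moving-carrier variant of the mapping
#' stimulus).
#'
#' @param config From [default_config()].
#' @return Data.frame: `run_id`, `type`, `variant`, `aperture`.
#' @export
build_protocol <- function(config = default_config()) {
  r <- config$runs
  rows <- list()
  add <- function(type, variant = NA_character_, aperture = NA_character_) {
    rows[[length(rows) + 1]] <<- data.frame(type = type, variant = variant,
                                            aperture = aperture)
  }
  for (i in seq_len(r$n_2d)) add("motion2d")
  for (i in seq_len(r$n_3d)) add("motion3d")
  for (i in seq_len(r$n_opponent)) add("opponent")
  n_bar <- ceiling(r$n_prf / 2)
  for (i in seq_len(r$n_prf)) {
    ap <- if (i <= n_bar) "bar" else "wedge_ring"
    variant <- if (i %% 2 == 1) "static" else "moving"
    add("prf", variant, ap)
  }
  out <- do.call(rbind, rows)
  cbind(run_id = seq_len(nrow(out)), out)
}

config_schedule <- function(config, type) {
  s <- config$schedules
  switch(type,
    motion2d = build_2d_schedule(s$motion2d$block_s, s$motion2d$reps_per_direction,
                                 config$tr, s$motion2d$blank_s),
    motion3d = build_3d_schedule(s$motion3d$block_s, s$motion3d$reps,
                                 config$tr, s$motion3d$blank_s),
    opponent = build_opponent_schedule(s$opponent$block_s, s$opponent$n_blocks,
                                       config$tr),
    stop("unknown run type: ", type))
}

config_apertures <- function(config, which = c("bar", "wedge_ring")) {
  which <- match.arg(which)
  a <- config$aperture
  if (which == "bar")
    gen_prf_apertures("bar", a$radius, a$grid_size, a$n_steps, config$tr, a$step_s)
  else
    concat_apertures(
      gen_prf_apertures("wedge", a$radius, a$grid_size, a$n_steps, config$tr, a$step_s),
      gen_prf_apertures("ring", a$radius, a$grid_size, a$n_steps, config$tr, a$step_s))
}

#' Simulate a dataset and write it to disk
#'
#' Generates the hemisphere ground truth and, for every scan of the
#' protocol, the events table and (optionally) the simulated time series.
#' Logs one line per stage with the derived seed and output path. Outputs
#' are byte-identical across calls with the same config.
#'
#' @param config From [default_config()].
#' @param out_dir Output directory (created if missing).
#' @param write_ts Also simulate and write time series (binary + JSON
#'   sidecar) for every run; the localizer runs are always cheap, the 12 pRF
#'   runs dominate the cost.
#' @param export_apertures Write the dense aperture-movie binaries for the
#'   pRF runs (large files; defaults to `write_ts`).
#' @param quiet Suppress log lines.
#' @return Invisibly, a manifest data.frame of written files.
#' @export
sim_dataset <- function(config = default_config(), out_dir, write_ts = FALSE,
                        export_apertures = write_ts, quiet = FALSE) {
  validate_config(config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if (file.access(out_dir, 2) != 0) stop("output directory is not writable: ", out_dir)
  log1 <- function(...) if (!quiet) message(sprintf(...))
  hemi <- make_hemisphere(do.call(hemisphere_config, config$hemisphere[
    intersect(names(config$hemisphere), names(formals(hemisphere_config)))]),
    seed = config$seed)
  hpath <- file.path(out_dir, "hemisphere.csv")
  write_hemisphere_csv(hemi, hpath)
  log1("stage=hemisphere seed=%d out=%s", derive_seed(config$seed, "hemisphere"), hpath)

  proto <- build_protocol(config)
  files <- list(data.frame(run_id = 0, type = "truth", path = hpath))
  for (i in seq_len(nrow(proto))) {
    type <- proto$type[i]
    if (type == "prf") {
      epath <- file.path(out_dir, sprintf("run-%02d_%s_apertures", i, proto$aperture[i]))
      if (export_apertures || write_ts) {
        ap <- config_apertures(config, proto$aperture[i])
        if (export_apertures) write_apertures(ap, epath)
        if (write_ts) {
          ts <- simulate_prf_run(hemi, ap, config$noise_sd, config$drift_slope,
                                 config$baseline, derive_seed(config$seed, "run", i))
          write_ts_bin(ts, file.path(out_dir, sprintf("run-%02d_bold", i)))
        }
      }
      files[[length(files) + 1]] <- data.frame(run_id = i, type = type,
                                               path = paste0(epath, ".bin"))
      log1("stage=sim run=%02d type=prf aperture=%s", i, proto$aperture[i])
    } else {
      sched <- config_schedule(config, type)
      epath <- file.path(out_dir, sprintf("run-%02d_%s_events.tsv", i, type))
      write_events_tsv(sched, epath)
      if (write_ts) {
        ts <- simulate_run(hemi, sched, config$noise_sd, config$drift_slope,
                           config$baseline, derive_seed(config$seed, "run", i))
        write_ts_bin(ts, file.path(out_dir, sprintf("run-%02d_bold", i)))
      }
      files[[length(files) + 1]] <- data.frame(run_id = i, type = type, path = epath)
      log1("stage=sim run=%02d type=%s seed=%d", i, type,
           derive_seed(config$seed, "run", i))
    }
  }
  invisible(do.call(rbind, files))
}

#' Localize hMT/MST and pFST on one synthetic hemisphere
#'
#' Runs the localizer half of the pipeline in memory: simulates the 2D, 3D
#' and opponent runs, converts to percent signal change, fits the GLM per
#' run (averaging betas across the repeated 2D runs), forms the three
#' contrasts, delineates the ROIs, and computes validation statistics and
#' overlap metrics against the ground truth and the jittered atlas.
#'
#' @param hemi A `synthetic_hemisphere` (built from `config` when NULL).
#' @param config From [default_config()].
#' @param seed Overrides `config$seed` for the BOLD noise draws.
#' @return List: `contrasts` (named list of matrices), `roi` (`roi_set`),
#'   `metrics` (data.frame of DICE / centroid distance / area / scenario /
#'   thresholds vs truth and atlas), `stats` (list of `roi_comparison`),
#'   `r1` (vertex map), `hemi`.
#' @export
localize_hemisphere <- function(hemi = NULL, config = default_config(),
                                seed = config$seed) {
  if (is.null(hemi))
    hemi <- make_hemisphere(do.call(hemisphere_config, config$hemisphere[
      intersect(names(config$hemisphere), names(formals(hemisphere_config)))]),
      seed = seed)
  dims <- hemi$shape
  betas_of <- function(type, n_runs) {
    sched <- config_schedule(config, type)
    X <- build_design(sched)
    bl <- lapply(seq_len(n_runs), function(r) {
      ts <- simulate_run(hemi, sched, config$noise_sd, config$drift_slope,
                         config$baseline, derive_seed(seed, type, r))
      fit_glm(to_psc(ts), X)
    })
    average_runs(bl)
  }
  b2 <- betas_of("motion2d", config$runs$n_2d)
  b3 <- betas_of("motion3d", config$runs$n_3d)
  bo <- betas_of("opponent", config$runs$n_opponent)
  cmap <- function(v) matrix(v, dims[1], dims[2])
  contrasts <- list(
    motion2d = cmap(contrast_map(b2, c("radial_in", "radial_out", "cw", "ccw"),
                                 "static", name = "motion2d")),
    motion3d = cmap(contrast_map(b3, "coherent", "scrambled", name = "motion3d")),
    opponency = cmap(contrast_map(bo, "unpaired", "paired", name = "opponency")))

  roi <- delineate(contrasts$motion2d, contrasts$motion3d,
                   q_start = config$roi$q_start, q_floor = config$roi$q_floor,
                   q_step = config$roi$q_step, adjacency = config$roi$adjacency,
                   min_size = config$roi$min_size)

  truth_h <- region_mask(hemi, "hMTMST")
  truth_p <- region_mask(hemi, "pFST")
  atlas_h <- region_mask(hemi, "hMTMST", atlas = TRUE)
  atlas_p <- region_mask(hemi, "pFST", atlas = TRUE)
  metrics <- data.frame(
    roi = c("hMTMST", "pFST"),
    n_vertices = c(sum(roi$hMTMST), sum(roi$pFST)),
    dice_truth = c(dice(roi$hMTMST, truth_h), dice(roi$pFST, truth_p)),
    dice_atlas = c(dice(roi$hMTMST, atlas_h), dice(roi$pFST, atlas_p)),
    centroid_dist_truth = c(
      centroid_distance(roi$hMTMST, truth_h),
      if (sum(roi$pFST) > 0) centroid_distance(roi$pFST, truth_p) else NA_real_),
    area_mm2 = c(surface_area(roi$hMTMST), surface_area(roi$pFST)),
    threshold = roi$threshold_2d,
    scenario = roi$scenario)

  r1 <- cmap(r1_from_t1(hemi$tuning$t1))
  hm <- roi$hMTMST; pm <- roi$pFST
  # degenerate samples (e.g. a zero-spread hemisphere) yield no test
  try_t <- function(expr) tryCatch(expr, error = function(e) NULL)
  stats_list <- list(
    motion2d_hMTMST = try_t(one_sample_t(contrasts$motion2d[hm], measure = "motion2d")),
    motion3d_hMTMST = try_t(one_sample_t(contrasts$motion3d[hm], measure = "motion3d")),
    opponency_between = try_t(two_sample_t(contrasts$opponency[hm],
                                           contrasts$opponency[pm], measure = "opponency")),
    r1_between = try_t(two_sample_t(r1[hm], r1[pm], measure = "r1")))
  if (sum(pm) >= 2) {
    stats_list$motion2d_pFST <- try_t(one_sample_t(contrasts$motion2d[pm], measure = "motion2d"))
    stats_list$motion3d_pFST <- try_t(one_sample_t(contrasts$motion3d[pm], measure = "motion3d"))
  }
  list(contrasts = contrasts, roi = roi, metrics = metrics,
       stats = stats_list, r1 = r1, hemi = hemi)
}

#' Localize every hemisphere of a simulated cohort
#'
#' Runs [localize_hemisphere()] for 2 hemispheres x `n_subjects` independent
#' synthetic hemispheres and assembles the per-hemisphere ROI values of the
#' four validation measures into the structure [group_report()] consumes.
#'
#' @param config From [default_config()].
#' @param n_subjects Number of subjects (default 9).
#' @param quiet Suppress per-hemisphere log lines.
#' @return List: `cohort` (for [group_report()]), `metrics` (row-bound
#'   per-hemisphere delineation metrics).
#' @export
run_cohort <- function(config = default_config(), n_subjects = 9, quiet = FALSE) {
  hemis <- list(); metr <- list()
  for (s in seq_len(n_subjects)) {
    for (h in c("L", "R")) {
      sd0 <- derive_seed(config$seed, "subject", s, h)
      loc <- localize_hemisphere(config = config, seed = sd0)
      hm <- loc$roi$hMTMST; pm <- loc$roi$pFST
      vals <- list(
        motion2d = list(hMTMST = loc$contrasts$motion2d[hm],
                        pFST = loc$contrasts$motion2d[pm]),
        motion3d = list(hMTMST = loc$contrasts$motion3d[hm],
                        pFST = loc$contrasts$motion3d[pm]),
        opponency = list(hMTMST = loc$contrasts$opponency[hm],
                         pFST = loc$contrasts$opponency[pm]),
        r1 = list(hMTMST = loc$r1[hm], pFST = loc$r1[pm]))
      hemis[[length(hemis) + 1]] <- list(subject = s, hemisphere = h, values = vals)
      metr[[length(metr) + 1]] <- cbind(subject = s, hemisphere = h, loc$metrics)
      if (!quiet) message(sprintf("stage=localize subject=%d hemi=%s seed=%d q=%g scenario=%s",
                                  s, h, sd0, loc$roi$threshold_2d, loc$roi$scenario))
    }
  }
  list(cohort = structure(list(hemispheres = hemis, n_subjects = n_subjects,
                               seed = config$seed), class = "cohort"),
       metrics = do.call(rbind, metr))
}
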