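#' Condition presets for the simulator
#'
#' Named parameter sets emulating the experimental conditions of a
#' WNT-stimulation single-molecule experiment. Dissociation rates are the
#' printed estimates for the corresponding conditions
#' (WNT-3A early/late 0.65 / 0.3 s^-1; WNT-16B early/late 1.32 / 0.64 s^-1);
#' association-rate targets are feasible choices under the simulator's 1:1
#' binding model (which caps kon at koff / rho_B; see the methods vignette):
#' the printed kon = 0.72 um^2 molecule^-1 s^-1 is paired with the
#' short-dwell condition, and conditions whose kon is not printed use
#' moderate values. Stimulated presets raise the confinement-zone area
#' fraction relative to basal. The control pair has zero binding and feeds
#' the random-colocalization null.
#'
#' @param name one of `"basal"`, `"wnt3a-early-like"`, `"wnt3a-late-like"`,
#'   `"wnt16b-early-like"`, `"wnt16b-late-like"`, `"control-pair"`.
#' @param seed integer seed stamped into the config.
#' @return list with elements `config` (a [sim_config()], hazard not yet
#'   calibrated), `kon_target` (um^2 molecule^-1 s^-1), and
#'   `size_distribution` (photobleaching cluster-size probabilities).
#' @export
sim_preset <- function(name = c("basal", "wnt3a-early-like",
                                "wnt3a-late-like", "wnt16b-early-like",
                                "wnt16b-late-like", "control-pair"),
                       seed = 1L) {
  name <- match.arg(name)
  par <- switch(name,
    "basal"            = list(kon = 0.05, koff = 1.32, conf = 0.08,
                              sizes = size_preset("monomer-weighted")),
    "wnt3a-early-like" = list(kon = 0.30, koff = 0.65, conf = 0.12,
                              sizes = size_preset("monomer-weighted")),
    "wnt3a-late-like"  = list(kon = 0.20, koff = 0.30, conf = 0.15,
                              sizes = size_preset("cluster-weighted")),
    "wnt16b-early-like" = list(kon = 0.72, koff = 1.32, conf = 0.12,
                               sizes = size_preset("monomer-weighted")),
    "wnt16b-late-like" = list(kon = 0.30, koff = 0.64, conf = 0.15,
                              sizes = size_preset("monomer-weighted")),
    "control-pair"     = list(kon = 0, koff = 1, conf = 0.08,
                              sizes = size_preset("monomer-weighted"))
  )
  cfg <- sim_config(koff_per_s = par$koff,
                    reaction_radius_um = 0.30,
                    release_radius_um = 0.35,
                    confinement_area_fraction = par$conf,
                    seed = seed)
  list(name = name, config = cfg, kon_target = par$kon,
       size_distribution = par$sizes)
}

#' Photobleaching cluster-size presets
#'
#' `"monomer-weighted"`: mostly single fluorophores (emulating conditions
#' without higher-order clustering); `"cluster-weighted"`: ~20% monomeric
#' with the rest spread over sizes 2-15 (higher-order clusters).
#'
#' @param name preset name.
#' @return probability vector over sizes 1..15.
#' @export
size_preset <- function(name = c("monomer-weighted", "cluster-weighted")) {
  name <- match.arg(name)
  p <- if (name == "monomer-weighted") {
    c(0.7, 0.17, 0.08, 0.05, rep(0, 11))
  } else {
    tail_w <- 0.8 * stats::dgeom(0:13, prob = 0.3)
    c(0.2, tail_w / sum(tail_w) * 0.8, rep(0, 0))
  }
  p / sum(p)
}

#' Pipeline configuration
#'
#' Bundles every stage parameter of [run_pipeline()] into a serializable
#' object. Round-trips through JSON unchanged; a resolved copy is written
#' next to the outputs of every run.
#'
#' @param preset condition preset name ([sim_preset()]).
#' @param n_cells fields (cells) simulated for the condition.
#' @param n_control_cells fields for the random-colocalization control.
#' @param seed master seed; every stage seed derives from it.
#' @param search_radius_um colocalization radius.
#' @param coloc_gap_frames gap tolerance of event extension (default 0, the
#'   strict f+1 rule; detection dropouts are handled upstream by
#'   [interpolate_gaps()]).
#' @param link_gap_frames,link_distance_um segment-linking parameters.
#' @param min_duration_frames kinetics minimum event duration.
#' @param lr_iterations Lucy-Richardson iterations.
#' @param n_boot bootstrap resamples.
#' @param n_bleach_particles photobleaching traces simulated.
#' @param hazard pre-calibrated per-frame binding hazard; NULL (default)
#'   calibrates against the preset's kon target at run time.
#' @param out_dir output directory (NULL: nothing written).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(preset = "wnt16b-late-like", n_cells = 25L,
                            n_control_cells = 25L, seed = 1L,
                            search_radius_um = 0.15, coloc_gap_frames = 0L,
                            link_gap_frames = 2L, link_distance_um = 0.3,
                            min_duration_frames = 2L, lr_iterations = 50L,
                            n_boot = 1000L, n_bleach_particles = 300L,
                            hazard = NULL, out_dir = NULL) {
  cfg <- list(preset = preset, n_cells = as.integer(n_cells),
              n_control_cells = as.integer(n_control_cells),
              seed = as.integer(seed),
              search_radius_um = search_radius_um,
              coloc_gap_frames = as.integer(coloc_gap_frames),
              link_gap_frames = as.integer(link_gap_frames),
              link_distance_um = link_distance_um,
              min_duration_frames = as.integer(min_duration_frames),
              lr_iterations = as.integer(lr_iterations),
              n_boot = as.integer(n_boot),
              n_bleach_particles = as.integer(n_bleach_particles),
              hazard = hazard, out_dir = out_dir)
  class(cfg) <- "pipeline_config"
  cfg
}

#' @rdname pipeline_config
#' @param file JSON path.
#' @export
write_pipeline_config <- function(cfg, file) {
  jsonlite::write_json(unclass(cfg), file, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(file)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(file) {
  j <- jsonlite::read_json(file, simplifyVector = TRUE)
  do.call(pipeline_config, j[!vapply(j, is.null, logical(1))])
}

#' Simulate a multi-cell condition
#'
#' Simulates `n_cells` independent fields from a preset (hazard calibrated
#' to the preset's kon target) and pools them into two channel-level track
#' sets plus the per-field truth logs.
#'
#' @param preset a [sim_preset()] result (or preset name).
#' @param n_cells number of fields.
#' @param seed master seed.
#' @param hazard optional pre-calibrated hazard (skips calibration).
#' @return list `a`, `b` (pooled [track_set()]s), `truths` (list of
#'   `sim_truth`), `hazard`.
#' @export
simulate_condition <- function(preset, n_cells = 25L, seed = 1L,
                               hazard = NULL) {
  if (is.character(preset)) preset <- sim_preset(preset, seed)
  cfg <- preset$config
  if (is.null(hazard)) {
    hazard <- if (preset$kon_target > 0) {
      as.numeric(calibrate_binding_hazard(cfg, preset$kon_target,
                                          n_reps = 6L, seed = seed,
                                          cal_frames = cfg$n_frames))
    } else 0
  }
  cfg$kon_hazard <- as.numeric(hazard)
  sims <- lapply(seq_len(n_cells), function(i) {
    ci <- cfg
    ci$seed <- seed + i * 1009L
    simulate_field(ci, field_id = sprintf("%s_c%02d", preset$name, i))
  })
  pool <- function(chan) {
    locs <- data.table::rbindlist(lapply(sims, function(s) s[[chan]]$tracks))
    track_set(locs, cfg$field_width_um, cfg$field_height_um, cfg$dt_s,
              cfg$n_frames, periodic = TRUE)
  }
  list(a = pool("a"), b = pool("b"),
       truths = lapply(sims, `[[`, "truth"),
       hazard = as.numeric(hazard))
}

#' Parameter-recovery experiment for one condition preset
#'
#' Simulates `n_cells` fields from a preset (with run-time hazard
#' calibration), repairs and interpolates tracks, detects colocalizations,
#' and estimates kinetics against a supplied random-colocalization null.
#' This is the validation loop behind the dissociation- and
#' association-rate recovery checks.
#'
#' @param preset preset name ([sim_preset()]).
#' @param n_cells simulated cells.
#' @param seed master seed.
#' @param null `dwell_dist` of kind "null" ([null_distribution()]).
#' @param n_boot bootstrap resamples.
#' @param coloc_gap_frames event-extension gap tolerance (default 1;
#'   bridges single-frame excursions of interpolated localizations).
#' @return list: `kinetics` (a `kinetics_estimate`), `kon_truth` (truth-log
#'   kon of the simulated fields), `koff_true`, `kon_target`, `events`,
#'   `tracks` (linked/interpolated channel track sets).
#' @export
recovery_experiment <- function(preset, n_cells = 25L, seed = 1L, null,
                                n_boot = 200L, coloc_gap_frames = 1L) {
  pre <- sim_preset(preset, seed)
  cond <- simulate_condition(pre, n_cells, seed)
  a <- interpolate_gaps(link_segments(cond$a))
  b <- interpolate_gaps(link_segments(cond$b))
  ev <- detect_colocalizations(a, b, 0.15, coloc_gap_frames)
  kin <- estimate_kinetics(ev, a, b, null, n_boot = n_boot, seed = seed)
  list(kinetics = kin, kon_truth = kon_from_truth(cond$truths),
       koff_true = pre$config$koff_per_s, kon_target = pre$kon_target,
       events = ev, tracks = list(a = a, b = b), hazard = cond$hazard)
}

#' Random-colocalization null from simulated control cells
#'
#' @param n_cells control cells.
#' @param seed master seed.
#' @param coloc_gap_frames as in [recovery_experiment()].
#' @export
control_null <- function(n_cells = 25L, seed = 990L,
                         coloc_gap_frames = 1L) {
  ctrl <- simulate_condition("control-pair", n_cells, seed)
  null_distribution(interpolate_gaps(link_segments(ctrl$a)),
                    interpolate_gaps(link_segments(ctrl$b)),
                    0.15, coloc_gap_frames)
}

#' Run the full simulate-and-analyze pipeline
#'
#' Executes, in order: condition and control simulation (with hazard
#' calibration), segment linking, confinement annotation, colocalization
#' detection, null construction, dwell-time deconvolution and kinetics
#' estimation, co-confinement classification, and photobleaching
#' cluster sizing. Writes per-stage artifacts and a JSON summary when
#' `out_dir` is set; rerunning with the same config and seed reproduces the
#' summary byte for byte.
#'
#' @param cfg a [pipeline_config()].
#' @return list with the stage outputs and the `summary` list.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  preset <- sim_preset(cfg$preset, cfg$seed)
  is_control <- cfg$preset == "control-pair"

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  cond <- stage("simulate", simulate_condition(preset, cfg$n_cells, cfg$seed,
                                               hazard = cfg$hazard))
  ctrl <- stage("simulate-control",
                simulate_condition(sim_preset("control-pair",
                                              cfg$seed + 77L),
                                   cfg$n_control_cells, cfg$seed + 77L))

  link2 <- function(x) {
    list(a = interpolate_gaps(link_segments(x$a, cfg$link_gap_frames,
                                            cfg$link_distance_um)),
         b = interpolate_gaps(link_segments(x$b, cfg$link_gap_frames,
                                            cfg$link_distance_um)))
  }
  condL <- stage("link", link2(cond))
  ctrlL <- stage("link-control", link2(ctrl))

  ann_a <- stage("confinement", annotate_confinement(condL$a))
  ann_b <- stage("confinement", annotate_confinement(condL$b))

  events <- stage("colocalize",
                  detect_colocalizations(condL$a, condL$b,
                                         cfg$search_radius_um,
                                         cfg$coloc_gap_frames))
  null <- stage("null", null_distribution(ctrlL$a, ctrlL$b,
                                          cfg$search_radius_um,
                                          cfg$coloc_gap_frames))

  kin <- NULL; states <- NULL
  if (!is_control && nrow(events)) {
    kin <- stage("kinetics",
                 estimate_kinetics(events, condL$a, condL$b, null,
                                   cfg$min_duration_frames,
                                   cfg$lr_iterations, cfg$n_boot,
                                   seed = cfg$seed))
    states <- stage("states",
                    classify_interaction_state(events, ann_a, ann_b,
                                               n_boot = cfg$n_boot,
                                               seed = cfg$seed))
  }

  bleach <- stage("photobleach", {
    sim <- simulate_photobleaching_traces(
      cfg$n_bleach_particles, preset$size_distribution,
      seed = cfg$seed + 13L)
    fits <- apply(sim$traces, 2, fit_steps, max_steps = 15L,
                  simplify = FALSE)
    list(sim = sim, fits = fits,
         distribution = cluster_size_distribution(fits))
  })

  conf <- stage("confinement-summary",
                confinement_proportions(rbind(ann_a, ann_b),
                                        n_boot = cfg$n_boot,
                                        seed = cfg$seed))

  summary <- list(
    preset = cfg$preset, seed = cfg$seed,
    n_cells = cfg$n_cells,
    hazard = cond$hazard,
    kon = if (!is.null(kin)) kin$kon_um2_per_molecule_s,
    kon_ci95 = if (!is.null(kin)) kin$ci95_kon,
    koff = if (!is.null(kin)) kin$koff_per_s,
    koff_ci95 = if (!is.null(kin)) kin$ci95_koff,
    mean_dwell_s = if (!is.null(kin)) kin$mean_dwell_s,
    n_events = nrow(events),
    confinement_proportion = conf$summary$median[1],
    confinement_ci95 = c(conf$summary$ci_lower[1], conf$summary$ci_upper[1]),
    fraction_co_confined = if (!is.null(states)) states$fraction_co_confined,
    fraction_co_diffusing = if (!is.null(states)) states$fraction_co_diffusing,
    fraction_monomeric = bleach$distribution$fraction_monomeric,
    cluster_size_counts = bleach$distribution$counts,
    package_version = as.character(utils::packageVersion("sptkin"))
  )

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_pipeline_config(cfg, file.path(cfg$out_dir, "config.json"))
    write_tracks(condL$a, file.path(cfg$out_dir, "tracks_a.csv"))
    write_tracks(condL$b, file.path(cfg$out_dir, "tracks_b.csv"))
    utils::write.csv(events, file.path(cfg$out_dir, "events.csv"),
                     row.names = FALSE)
    jsonlite::write_json(summary, file.path(cfg$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = 10, null = "null")
  }

  list(condition = condL, control = ctrlL, events = events, null = null,
       kinetics = kin, states = states, confinement = conf,
       photobleach = bleach, summary = summary)
}
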