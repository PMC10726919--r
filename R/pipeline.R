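# Pipeline wiring: a validated config drives the subcommands the CLI exposes
# (simulate / extract / score / calibrate / sweep / compare). Artifacts are
# written atomically and every run leaves a manifest JSON recording the
# package version, parameters, seed and input checksums.

config_defaults <- function() {
  list(
    seed = 1L,
    out_dir = ".",
    vibe = list(),        # vibe_params() arguments
    video = list(),       # video_spec() arguments
    sim = list(),         # sim_spec() arguments
    noise = list(),       # trace_noise_spec() arguments
    scoring = list(threshold_pct = 5, immobility_min_s = 40,
                   reference_count = NULL, bin_s = 1, aggregate = "max"),
    calibrate = list(grid_step_pct = 5),
    sweep = list(T_values = c(35, 40, 45)),
    compare = list(epoch_s = 10, consistency_formula = "sum-abs"),
    simulate_out = list(render = FALSE,
                        reference = list(sensitivity = 0.95,
                                         specificity = 0.95,
                                         rem_fraction = 0.12, epoch_s = 10)),
    paths = list()
  )
}

merge_config <- function(base, override, prefix = "", problems = NULL) {
  probs <- problems %||% character(0)
  for (nm in names(override)) {
    key <- if (prefix == "") nm else paste0(prefix, ".", nm)
    if (!nm %in% names(base)) {
      probs <- c(probs, sprintf("unknown config key '%s'", key))
    } else if (is.list(base[[nm]]) && !is.null(names(base[[nm]])) &&
               length(base[[nm]]) > 0 && is.list(override[[nm]])) {
      merged <- merge_config(base[[nm]], override[[nm]], key, probs)
      base[[nm]] <- merged$config
      probs <- merged$problems
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  list(config = base, problems = probs)
}

#' Build and validate a pipeline configuration
#'
#' Merges user settings over the defaults; unknown keys and values violating
#' any module's invariants are all reported together.
#'
#' @param config Named list of overrides (possibly nested), e.g. from a YAML
#'   file.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(config = list()) {
  merged <- merge_config(config_defaults(), config)
  cfg <- merged$config
  problems <- merged$problems
  try_field <- function(label, expr) {
    tryCatch({ force(expr); NULL },
             error = function(e) sprintf("%s: %s", label, conditionMessage(e)))
  }
  known_args <- function(block, fn) block[names(block) %in% names(formals(fn))]
  unknown_args <- function(block, fn, label) {
    bad <- setdiff(names(cfg[[block]]), names(formals(fn)))
    if (length(bad) > 0) {
      sprintf("unknown config key%s %s", if (length(bad) > 1) "s" else "",
              paste(sprintf("'%s.%s'", label, bad), collapse = ", "))
    }
  }
  problems <- c(
    problems,
    unknown_args("vibe", vibe_params, "vibe"),
    unknown_args("video", video_spec, "video"),
    unknown_args("sim", sim_spec, "sim"),
    unknown_args("noise", trace_noise_spec, "noise"),
    try_field("seed", check_number(cfg$seed, "seed", integerish = TRUE)),
    try_field("vibe", do.call(vibe_params, known_args(cfg$vibe, vibe_params))),
    try_field("video", do.call(video_spec, known_args(cfg$video, video_spec))),
    try_field("sim", do.call(sim_spec, known_args(cfg$sim, sim_spec))),
    try_field("noise", do.call(trace_noise_spec,
                               known_args(cfg$noise, trace_noise_spec))),
    try_field("scoring.threshold_pct",
              check_number(cfg$scoring$threshold_pct, "threshold_pct",
                           min = 0, max = 100)),
    try_field("scoring.immobility_min_s",
              check_number(cfg$scoring$immobility_min_s, "immobility_min_s",
                           min = cfg$scoring$bin_s)),
    try_field("sweep.T_values",
              if (length(cfg$sweep$T_values) < 1 || any(cfg$sweep$T_values <= 0))
                abort("T_values must be positive")),
    try_field("compare.consistency_formula",
              match.arg(cfg$compare$consistency_formula,
                        c("sum-abs", "total-ratio", "ccc")))
  )
  problems <- problems[!vapply(problems, is.null, TRUE)]
  if (length(problems) > 0) {
    abort(paste0("invalid pipeline config:\n",
                 paste0("  - ", unlist(problems), collapse = "\n")))
  }
  structure(cfg, class = "pipeline_config")
}

write_manifest <- function(out_dir, subcommand, cfg, inputs, outputs) {
  checksum <- function(paths) {
    paths <- paths[file.exists(paths)]
    as.list(tools::md5sum(paths))
  }
  write_atomic(function(p) {
    jsonlite::write_json(
      list(tool = "sleepcam",
           version = as.character(utils::packageVersion("sleepcam")),
           subcommand = subcommand,
           seed = cfg$seed,
           config = unclass(cfg)[setdiff(names(cfg), "paths")],
           inputs = checksum(inputs),
           outputs = checksum(outputs)),
      p, auto_unbox = TRUE, digits = NA, null = "null"
    )
  }, file.path(out_dir, paste0("manifest_", subcommand, ".json")))
}

#' Run a pipeline subcommand
#'
#' Dispatches a validated config to one of the pipeline stages. Inputs are
#' never mutated; artifacts are written atomically into `out_dir` together
#' with a manifest.
#'
#' @param config A [pipeline_config()] (or a plain list passed through it).
#' @param subcommand One of `"simulate"`, `"extract"`, `"score"`,
#'   `"calibrate"`, `"sweep"`, `"compare"`.
#' @return Named list of written artifact paths, invisibly.
#' @export
run_pipeline <- function(config,
                         subcommand = c("simulate", "extract", "score",
                                        "calibrate", "sweep", "compare")) {
  subcommand <- match.arg(subcommand)
  cfg <- if (inherits(config, "pipeline_config")) config else pipeline_config(config)
  out_dir <- cfg$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pth <- function(name) cfg$paths[[name]] %||%
    abort(sprintf("config paths.%s is required for '%s'", name, subcommand))
  out <- switch(subcommand,
    simulate = {
      spec <- do.call(sim_spec, cfg$sim)
      gt <- simulate_hypnogram(spec, cfg$seed)
      trace <- simulate_trace(gt, do.call(trace_noise_spec, cfg$noise),
                              cfg$seed + 1L)
      rp <- cfg$simulate_out$reference
      ref <- degrade_reference(gt, rp$sensitivity, rp$specificity,
                               rp$rem_fraction, rp$epoch_s, cfg$seed + 2L)
      files <- list(
        truth = file.path(out_dir, "truth_hypnogram.csv"),
        bouts = file.path(out_dir, "truth_bouts.csv"),
        trace = file.path(out_dir, "trace.csv"),
        reference = file.path(out_dir, "reference.csv")
      )
      write_hypnogram(gt$hypnogram, files$truth)
      write_bouts(gt$bouts, files$bouts)
      write_trace(trace, files$trace)
      write_reference(ref, files$reference)
      if (isTRUE(cfg$simulate_out$render)) {
        stream <- render_video(gt, do.call(video_spec, cfg$video), cfg$seed + 3L)
        files$frames <- file.path(out_dir, "frames")
        write_frames(stream, files$frames)
      }
      files
    },
    extract = {
      stream <- read_frames(pth("video"))
      trace <- motion_trace(stream, do.call(vibe_params, cfg$vibe),
                            bin_s = cfg$scoring$bin_s, seed = cfg$seed,
                            aggregate = cfg$scoring$aggregate)
      f <- file.path(out_dir, "trace.csv")
      write_trace(trace, f)
      list(trace = f)
    },
    score = {
      trace <- read_trace(pth("trace"))
      h <- score_trace(trace, cfg$scoring$threshold_pct,
                       cfg$scoring$immobility_min_s,
                       cfg$scoring$reference_count)
      files <- list(hypnogram = file.path(out_dir, "hypnogram.csv"),
                    bouts = file.path(out_dir, "bouts.csv"))
      write_hypnogram(h, files$hypnogram)
      write_bouts(to_bouts(h), files$bouts)
      files
    },
    calibrate = {
      trace <- read_trace(pth("trace"))
      ref <- collapse_reference(read_reference(pth("reference"),
                                               epoch_s = cfg$compare$epoch_s))
      cal <- calibrate_threshold(trace, ref, cfg$calibrate$grid_step_pct,
                                 cfg$scoring$immobility_min_s,
                                 cfg$scoring$reference_count)
      f <- file.path(out_dir, "calibration.json")
      write_atomic(function(p) jsonlite::write_json(
        list(best_pct = cal$best_pct, reference_count = cal$reference_count,
             immobility_min_s = cal$immobility_min_s, curve = cal$curve),
        p, auto_unbox = TRUE, digits = NA), f)
      list(calibration = f)
    },
    sweep = {
      trace <- read_trace(pth("trace"))
      ref <- read_reference(pth("reference"), epoch_s = cfg$compare$epoch_s)
      tab <- parameter_sweep(trace, ref, cfg$sweep$T_values,
                             cfg$scoring$threshold_pct,
                             cfg$scoring$reference_count,
                             cfg$compare$consistency_formula)
      f <- file.path(out_dir, "sweep.csv")
      write_atomic(function(p) readr::write_csv(tab, p), f)
      list(sweep = f)
    },
    compare = {
      h <- read_hypnogram(pth("video_hyp"))
      ref <- read_reference(pth("reference"), epoch_s = cfg$compare$epoch_s)
      rep <- compare_hypnograms(h, ref,
                                consistency_formula = cfg$compare$consistency_formula)
      f <- file.path(out_dir, "report.json")
      write_report(rep, f)
      list(report = f)
    }
  )
  write_manifest(out_dir, subcommand, cfg,
                 inputs = unlist(cfg$paths, use.names = FALSE) %||% character(0),
                 outputs = unlist(out[names(out) != "frames"], use.names = FALSE))
  invisible(out)
}
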