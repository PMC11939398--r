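.config_blocks <- c("name", "description", "configuration", "heart_rate",
                    "ventricles", "coupling", "valves", "vascular",
                    "chambers", "ecmo", "fs", "waveform", "initial_state",
                    "targets")

#' Load a circuit configuration from JSON
#'
#' Reads a preset/parameter document, validates it against the expected
#' schema (unknown keys are rejected; missing optional blocks receive
#' defaults; field invariants are checked via [validate_params()]) and
#' returns an [mcl_params()] object.  The optional `targets` block and
#' `name` are attached as attributes.
#'
#' @param path path to a JSON configuration file.
#' @param configuration optional configuration override (`"SV"`, `"BV"`,
#'   `"BVFS"`).
#' @return an `mcl_params` object with attributes `preset_name` and
#'   `targets`.
#' @export
load_config <- function(path, configuration = NULL) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  unknown <- setdiff(names(doc), .config_blocks)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  fs <- doc$fs
  if (!is.null(fs$e_max_bounds)) fs$e_max_bounds <- lapply(fs$e_max_bounds, as.numeric)
  p <- mcl_params(
    configuration = doc$configuration %||% "BVFS",
    heart_rate = doc$heart_rate %||% 60,
    ventricles = doc$ventricles %||% list(),
    coupling = doc$coupling %||% list(),
    valves = doc$valves %||% list(),
    vascular = doc$vascular %||% list(),
    chambers = doc$chambers %||% list(),
    ecmo = doc$ecmo %||% list(),
    fs = fs %||% list(),
    waveform = doc$waveform %||% list(),
    initial_state = if (is.null(doc$initial_state)) NULL
      else unlist(doc$initial_state)
  )
  if (!is.null(configuration)) p <- set_configuration(p, configuration)
  attr(p, "preset_name") <- doc$name %||% sub("\\.json$", "", basename(path))
  attr(p, "targets") <- if (is.null(doc$targets)) NULL else unlist(doc$targets)
  validate_params(p)
  p
}

#' Serialize a parameter set to JSON
#'
#' Canonical, diff-friendly serialization that round-trips through
#' [load_config()].
#'
#' @param params an [mcl_params()] object.
#' @param path output file path.
#' @param name stored preset name (defaults to the `preset_name`
#'   attribute).
#' @param description optional one-line description.
#' @param targets optional named numeric targets to store.
#' @return `path`, invisibly.
#' @export
write_config <- function(params, path, name = NULL, description = NULL,
                         targets = NULL) {
  doc <- list(
    name = name %||% attr(params, "preset_name") %||% "custom",
    description = description %||% "",
    configuration = params$configuration,
    heart_rate = params$heart_rate,
    ventricles = params$ventricles,
    coupling = params$coupling,
    valves = params$valves,
    vascular = params$vascular,
    chambers = params$chambers,
    ecmo = params$ecmo,
    fs = params$fs,
    waveform = params$waveform,
    initial_state = as.list(params$initial_state),
    targets = if (is.null(targets))
      as.list(attr(params, "targets")) else as.list(targets)
  )
  if (!length(doc$targets)) doc$targets <- NULL
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Load a shipped calibrated preset
#'
#' The package ships four calibrated cardiac-state presets: `normal`,
#' `lvf` (left ventricular failure), `rvf` (right ventricular failure)
#' and `bvf` (biventricular failure).  Each stores the full circuit
#' parameter set, the converged operating point as its initial state, and
#' the bench target values it was calibrated against.
#'
#' @param name preset name.
#' @param configuration optional configuration override.
#' @return an `mcl_params` object.
#' @export
#' @examples
#' p <- mcl_preset("normal")
#' p
mcl_preset <- function(name = c("normal", "lvf", "rvf", "bvf"),
                       configuration = NULL) {
  name <- match.arg(name)
  path <- system.file("extdata", "presets", paste0(name, ".json"),
                      package = "mcloop", mustWork = TRUE)
  load_config(path, configuration = configuration)
}

#' Write a simulated trajectory to CSV
#'
#' Fixed column order (`time_s`, pressures, loop flows in L/min, volumes,
#' valve flows in L/min), six significant digits, one row per recorded
#' sample.
#'
#' @param sim an `mcl_sim` trajectory.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_timeseries_csv <- function(sim, path) {
  if (!nrow(sim)) stop("empty trajectory", call. = FALSE)
  df <- data.frame(
    time_s = sim[, "time_s"],
    p_lv = sim[, "p_lv"], p_rv = sim[, "p_rv"],
    p_la = sim[, "p_la"], p_ra = sim[, "p_ra"],
    p_ao = sim[, "p_ao"], p_pa = sim[, "p_pa"],
    q_systemic = sim[, "q_systemic"] * 0.06,
    q_ecmo = sim[, "q_ecmo"] * 0.06,
    v_lv = sim[, "v_lv"], v_rv = sim[, "v_rv"],
    v_la = sim[, "v_la"], v_ra = sim[, "v_ra"],
    water_aoc = sim[, "water_aoc"], water_svc = sim[, "water_svc"],
    water_pac = sim[, "water_pac"], water_pvc = sim[, "water_pvc"],
    q_mitral = sim[, "q_mitral"] * 0.06,
    q_aortic = sim[, "q_aortic"] * 0.06,
    q_tricuspid = sim[, "q_tricuspid"] * 0.06,
    q_pulmonary = sim[, "q_pulmonary"] * 0.06
  )
  df[] <- lapply(df, signif, digits = 6)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run manifest for reproducibility
#'
#' Collects the tool version, a canonical configuration hash (stable under
#' key reordering), experiment name, seed and output file list.  The
#' timestamp is excluded from the hash scope.
#'
#' @param params the `mcl_params` used.
#' @param experiment experiment name.
#' @param seed RNG seed used (simulations themselves are deterministic).
#' @param outputs character vector of output files.
#' @return a named list.
#' @export
run_manifest <- function(params, experiment, seed = NA, outputs = character()) {
  list(
    tool = "mcloop",
    version = as.character(utils::packageVersion("mcloop")),
    experiment = experiment,
    config_hash = config_hash(params),
    seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = as.list(outputs)
  )
}

#' Canonical configuration hash
#'
#' MD5 of the canonicalized (recursively key-sorted) JSON serialization of
#' a parameter set, so the hash is stable under key reordering.
#'
#' @param params an `mcl_params` object or plain list.
#' @return hex string.
#' @export
config_hash <- function(params) {
  canon <- function(x) {
    if (is.list(x)) {
      if (!is.null(names(x)) && any(nzchar(names(x))))
        x <- x[order(names(x))]
      lapply(x, canon)
    } else x
  }
  x <- canon(unclass(params))
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Write an experiment summary to JSON
#'
#' Canonical key order with an embedded [run_manifest()]; the document is
#' structurally validated before writing (experiment name, points table
#' and statistics where the protocol attaches them).
#'
#' @param result an `mcl_experiment`.
#' @param path output JSON path.
#' @param params the parameter set the experiment ran on (for the
#'   manifest); optional.
#' @param seed seed recorded in the manifest.
#' @return `path`, invisibly.
#' @export
write_summary_json <- function(result, path, params = NULL, seed = NA) {
  if (!inherits(result, "mcl_experiment"))
    stop("validation error: not an experiment result", call. = FALSE)
  if (is.null(result$experiment_name) ||
      (is.null(result$points) && is.null(result$summary)))
    stop("validation error: experiment result is missing its points",
         call. = FALSE)
  doc <- list(
    experiment = result$experiment_name,
    configuration = result$configuration,
    preset = result$preset,
    swept_variable = result$swept_variable,
    points = result$points,
    stats = if (!is.null(result$stats)) unclass(result$stats),
    manifest = if (!is.null(params))
      run_manifest(params, result$experiment_name, seed,
                   outputs = basename(path))
  )
  extras <- setdiff(names(result),
                    c("experiment_name", "configuration", "preset",
                      "swept_variable", "points", "stats"))
  for (nm in extras) {
    v <- result[[nm]]
    if (is.numeric(v) || is.logical(v) || is.character(v))
      doc[[nm]] <- v
    else if (inherits(v, "steady_summary"))
      doc[[nm]] <- list(mean = as.list(v$mean), sd = as.list(v$sd))
    else if (is.data.frame(v)) doc[[nm]] <- v
  }
  doc <- Filter(Negate(is.null), doc)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "rows")
  invisible(path)
}

#' Re-simulate all shipped presets and report their validation checks
#'
#' Runs every shipped cardiac-state preset through [run_cardiac_state()]
#' (target bounds), compares the steady metrics against the stored bench
#' targets, and runs the BV clamp test for the coupling ratio.  Prints a
#' pass/fail table and returns it invisibly.
#'
#' @param presets preset names to check.
#' @param clamp_preset preset used for the clamp-ratio check (its
#'   `targets` must include `clamp_ratio`).
#' @return (invisibly) a data frame of checks.
#' @export
validate_presets <- function(presets = c("normal", "lvf", "rvf", "bvf"),
                             clamp_preset = "normal") {
  rows <- list()
  for (nm in presets) {
    exp <- run_cardiac_state(nm)
    tg <- attr(mcl_preset(nm), "targets")
    m <- exp$summary$mean
    for (i in seq_len(nrow(exp$points))) {
      pt <- exp$points[i, ]
      rows[[length(rows) + 1]] <- data.frame(
        preset = nm, check = paste(pt$metric, pt$bound),
        value = pt$value, pass = pt$pass)
    }
    for (k in intersect(names(tg), c("maop", "lap", "rap", "flow"))) {
      val <- if (k == "flow") m[["systemic_flow"]] else m[[k]]
      rows[[length(rows) + 1]] <- data.frame(
        preset = nm, check = sprintf("%s within 10%% of %.1f", k, tg[[k]]),
        value = val, pass = abs(val - tg[[k]]) <= 0.1 * abs(tg[[k]]))
    }
  }
  cl <- run_clamp_test(mcl_preset(clamp_preset), "BV")
  rows[[length(rows) + 1]] <- data.frame(
    preset = clamp_preset, check = "clamp ratio 0.47 +/- 0.02",
    value = cl$ratio, pass = abs(cl$ratio - 0.47) <= 0.02)
  tab <- do.call(rbind, rows)
  print(tab, digits = 3, row.names = FALSE)
  invisible(tab)
}
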