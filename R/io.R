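# Trace CSV readers/writers, YAML run-configuration loading, run manifests.

trace_schema <- c("time_min", "map_mmHg", "cvp_mmHg", "lactate_mmol_L",
                  "hct_frac", "infusion_mL_min", "fluid", "bag_volume_mL")

#' Write a trace to CSV
#'
#' Writes the standard trace schema (`time_min, map_mmHg, cvp_mmHg,
#' lactate_mmol_L, hct_frac, infusion_mL_min, fluid, bag_volume_mL`), plus any
#' extra columns present, with a header row, UTF-8, and "." as the decimal
#' separator. Values round-trip through [read_trace()] to at least 12
#' significant digits.
#'
#' @param trace a trace tibble.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  missing <- setdiff(trace_schema, names(trace))
  if (length(missing)) {
    stop("trace is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  extra <- setdiff(names(trace), trace_schema)
  readr::write_csv(trace[, c(trace_schema, extra)], path)
  invisible(path)
}

#' Read a trace CSV
#'
#' Validates the schema: every mandatory column present, time strictly
#' increasing and uniformly sampled to within 1e-6 min.
#'
#' @param path CSV file path.
#' @return a trace tibble.
#' @export
read_trace <- function(path) {
  tr <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(trace_schema, names(tr))
  if (length(missing)) {
    stop("trace file missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  t <- tr$time_min
  if (length(t) > 1) {
    d <- diff(t)
    bad <- which(d <= 0)
    if (length(bad)) {
      stop("non-monotone time at row ", bad[1] + 1L, call. = FALSE)
    }
    bad <- which(abs(d - d[1]) > 1e-6)
    if (length(bad)) {
      stop("non-uniform timestep at row ", bad[1] + 1L, call. = FALSE)
    }
  }
  tr
}

# Known configuration keys per section, with the constructors that validate
# their values.
config_sections <- function() list(
  subject = names(subject_defaults()),
  arc = names(formals(arc_config)),
  autobleed = setdiff(names(formals(autobleed_config)), "decision_table"),
  protocol = names(formals(protocol_config))
)

#' Load and validate a run configuration
#'
#' Plain-text YAML with optional sections `subject`, `arc`, `autobleed`,
#' `protocol`, and top-level `seed` and `out`. Unknown keys are rejected with
#' their full path; omitted keys take the package defaults (resuscitation
#' target 65 mmHg, pace 6 mmHg/min, hemorrhage target 35 mmHg, ...). An empty
#' file yields the all-defaults configuration.
#'
#' @param path YAML file path.
#' @return a `run_config` list with elements `subject_overrides`, `arc`,
#'   `autobleed`, `protocol`, `seed`, `out`.
#' @export
load_config <- function(path) {
  raw <- if (is.character(path) && file.exists(path)) yaml::read_yaml(path) else
    stop("config file not found: ", path, call. = FALSE)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("config must be a key/value mapping", call. = FALSE)

  known <- config_sections()
  top_known <- c(names(known), "seed", "out")
  unknown <- setdiff(names(raw), top_known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  for (sec in names(known)) {
    if (is.null(raw[[sec]])) next
    if (!is.list(raw[[sec]])) {
      stop("config section '", sec, "' must be a mapping", call. = FALSE)
    }
    bad <- setdiff(names(raw[[sec]]), known[[sec]])
    if (length(bad)) {
      stop("unknown config key(s): ", paste(paste0(sec, ".", bad), collapse = ", "),
           call. = FALSE)
    }
  }

  build <- function(ctor, args) do.call(ctor, args %||% list())
  cfg <- list(
    subject_overrides = raw$subject %||% list(),
    arc = build(arc_config, raw$arc),
    autobleed = build(autobleed_config, raw$autobleed),
    protocol = build(protocol_config, raw$protocol),
    seed = as.integer(raw$seed %||% 1L),
    out = raw$out %||% "."
  )
  # constructors validate ranges; subject overrides validate here
  make_subject(cfg$subject_overrides)
  structure(cfg, class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a run manifest
#'
#' Plain-text `key: value` lines capturing the effective configuration hash,
#' the seed, and package/R versions; the manifest suffices to re-run the
#' simulation bit-identically.
#'
#' @param path output file path.
#' @param config a `run_config` (or any list describing the run).
#' @param seed the seed used.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, config, seed) {
  lines <- c(
    paste0("config_hash: ", rlang::hash(config)),
    paste0("seed: ", seed),
    paste0("package_version: ", as.character(utils::packageVersion("arcsim"))),
    paste0("r_version: ", R.version.string),
    paste0("created: ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  )
  writeLines(lines, path)
  invisible(path)
}

# Sparse-lactate trace in the external schema from a protocol trace.
as_external_trace <- function(trace) {
  trace[, c(trace_schema, intersect(c("target_mmHg", "phase"), names(trace)))]
}
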