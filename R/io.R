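# File I/O, configuration loading, run manifests and the CLI entry point.

fmt9 <- function(x) formatC(x, digits = 9, format = "g")

#' Read an event stream from CSV
#'
#' Expects a header `time` or `time,stream`, rows sorted by time, times
#' in seconds. Unsorted or duplicate timestamps are rejected with the
#' offending line number (header is line 1).
#'
#' @param path CSV file path.
#' @return An [event_stream()].
#' @export
read_event_stream <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"time" %in% names(df))
    stop("event stream CSV must have a 'time' column: ", path)
  tt <- as.numeric(df$time)
  if (any(is.na(tt)))
    stop("malformed time at line ", which(is.na(tt))[1] + 1L, " of ", path)
  bad <- which(diff(tt) <= 0)
  if (length(bad) > 0)
    stop("event times not strictly increasing at line ", bad[1] + 2L,
         " of ", path)
  labels <- if ("stream" %in% names(df)) as.character(df$stream) else NULL
  event_stream(tt, labels)
}

#' Write an event stream to CSV
#'
#' @param events An [event_stream()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_event_stream <- function(events, path) {
  stopifnot(inherits(events, "event_stream"))
  df <- data.frame(time = sprintf("%.6f", events$times))
  if (!is.null(events$labels)) df$stream <- events$labels
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a filter trajectory to CSV
#'
#' One row per grid point; floats carry 9 significant digits so reruns
#' diff cleanly. 1D trajectories get columns
#' `time,mu,V,Lambda,event`; 2D trajectories get
#' `time,mu_phi,mu_theta,V_pp,V_pt,V_tt,Lambda,event`.
#'
#' @param trajectory A `filter_trajectory` or `filter_trajectory_2d`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  df <- trajectory_df(trajectory)
  num <- vapply(df, is.numeric, logical(1)) & names(df) != "event"
  df[num] <- lapply(df[num], fmt9)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

trajectory_df <- function(trajectory) {
  if (inherits(trajectory, "filter_trajectory")) {
    data.frame(time = trajectory$times, mu = trajectory$mu,
               V = trajectory$V, Lambda = trajectory$Lambda,
               event = trajectory$event)
  } else if (inherits(trajectory, "filter_trajectory_2d")) {
    data.frame(time = trajectory$times, mu_phi = trajectory$mu_phi,
               mu_theta = trajectory$mu_theta, V_pp = trajectory$V_pp,
               V_pt = trajectory$V_pt, V_tt = trajectory$V_tt,
               Lambda = trajectory$Lambda, event = trajectory$event)
  } else stop("not a filter trajectory")
}

#' Load a filter configuration from a JSON document
#'
#' Key names mirror the model symbols (`dt`, `sigma`, `sigma_theta`,
#' `mu0`, `V0`, `mu2_0`, `V2_0`, `t_end`). If `sigma_theta` (or a 2D
#' prior) is present a [patippet_config()] is built, otherwise a
#' [filter_config()]. Unknown keys are rejected; omitted keys take the
#' constructor defaults.
#'
#' @param path JSON file path.
#' @return A `filter_config` or `patippet_config`.
#' @export
load_config <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  keys_1d <- c("dt", "sigma", "mu0", "V0", "t_end")
  keys_2d <- c("dt", "sigma", "sigma_theta", "mu2_0", "V2_0", "t_end")
  is_2d <- any(c("sigma_theta", "mu2_0", "V2_0") %in% names(doc))
  allowed <- if (is_2d) keys_2d else keys_1d
  unknown <- setdiff(names(doc), allowed)
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (is_2d) {
    if (!is.null(doc$V2_0)) doc$V2_0 <- matrix(unlist(doc$V2_0), 2, 2,
                                               byrow = TRUE)
    do.call(patippet_config, doc)
  } else {
    do.call(filter_config, doc)
  }
}

#' Write a run manifest
#'
#' Records everything needed to replay a run bit-exactly: the config,
#' the seed, the package version and any warnings raised during the run.
#'
#' @param path Output JSON path.
#' @param config The config object used.
#' @param seed Seed used (or `NA` for deterministic runs).
#' @param warnings Character vector of warnings captured during the run.
#' @param extra Optional named list of additional fields.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, config, seed = NA, warnings = character(),
                           extra = list()) {
  doc <- c(list(
    package = "pippet",
    version = as.character(utils::packageVersion("pippet")),
    config = unclass(config),
    seed = seed,
    warnings = warnings
  ), extra)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Command-line entry point
#'
#' Usage: `pippet simulate|filter|experiment <name> [options]`
#' \describe{
#'   \item{`simulate`}{`--config FILE --out DIR [--seed N]`: simulate a
#'     world from a generative config (needs a template file via
#'     `--template FILE`), writing `events.csv`, `truth.csv` and
#'     `manifest.json`.}
#'   \item{`filter`}{`--config FILE --template FILE --events FILE --out
#'     DIR`: run the 1D or 2D filter (decided by the config) over an
#'     event CSV, writing `trajectory.csv` and `manifest.json`.}
#'   \item{`experiment`}{`<name> --out DIR [--seed N]`: run a named
#'     experiment (`event_response`, `swing_tracking`, `syncopation`,
#'     `tempo_inference`, `alpha_vs_ioi`, `filled_duration`) with its
#'     frozen configuration, writing its tables and `manifest.json`.}
#' }
#'
#' @param args Character vector of command-line arguments.
#' @return Invisibly, the output directory.
#' @export
pippet_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) < 1)
    stop("usage: pippet simulate|filter|experiment <name> [options]")
  cmd <- args[1]
  opts <- parse_cli_opts(args[-1])
  out <- opts$options$out
  if (is.null(out)) stop("--out DIR is required")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  seed <- if (is.null(opts$options$seed)) 1L else
    as.integer(opts$options$seed)
  warns <- character()
  withCallingHandlers({
    switch(cmd,
      simulate = {
        config <- load_config(req_opt(opts, "config"))
        template <- read_template(req_opt(opts, "template"))
        if (!inherits(config, "patippet_config"))
          config <- as_patippet_reduction(config)
        world <- simulate_patippet_world(config, template, seed)
        write_event_stream(world$events, file.path(out, "events.csv"))
        truth <- data.frame(time = fmt9(world$times),
                            phi = fmt9(world$true_phase),
                            theta = fmt9(world$true_tempo))
        utils::write.csv(truth, file.path(out, "truth.csv"),
                         row.names = FALSE, quote = FALSE)
        write_manifest(file.path(out, "manifest.json"), config, seed, warns)
      },
      filter = {
        config <- load_config(req_opt(opts, "config"))
        template <- read_template(req_opt(opts, "template"))
        events <- read_event_stream(req_opt(opts, "events"))
        traj <- if (inherits(config, "patippet_config"))
          run_patippet(template, events, config)
        else run_pippet(template, events, config)
        write_trajectory(traj, file.path(out, "trajectory.csv"))
        write_manifest(file.path(out, "manifest.json"), config, NA, warns)
      },
      experiment = {
        if (length(opts$positional) < 1)
          stop("experiment name required")
        name <- opts$positional[1]
        res <- run_experiment(name, seed = seed)
        write_experiment_result(res, out)
        write_manifest(file.path(out, "manifest.json"),
                       structure(res$params, class = "list"), seed, warns,
                       extra = list(experiment = name))
      },
      stop("unknown command: ", cmd)
    )
  }, warning = function(w) {
    warns <<- c(warns, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
  invisible(out)
}

parse_cli_opts <- function(args) {
  options <- list(); positional <- character()
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      if (i == length(args)) stop("missing value for option ", a)
      options[[substring(a, 3)]] <- args[i + 1]
      i <- i + 2
    } else {
      positional <- c(positional, a)
      i <- i + 1
    }
  }
  list(options = options, positional = positional)
}

req_opt <- function(opts, name) {
  v <- opts$options[[name]]
  if (is.null(v)) stop("--", name, " is required")
  v
}
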