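#' Write / read the package's tab-separated tables
#'
#' All tables travel as UTF-8 TSV with a header row; numeric columns are
#' written at full precision (15 significant digits) so a write/read round
#' trip reproduces values to storage precision.
#'
#' @param x data frame.
#' @param path file path.
#' @return `write_tsv` returns `path` invisibly; `read_tsv` the data frame.
#' @export
write_tsv <- function(x, path) {
  xx <- x
  num <- vapply(xx, is.numeric, logical(1))
  for (j in which(num)) xx[[j]] <- formatC(xx[[j]], digits = 15, format = "g")
  utils::write.table(xx, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, encoding = "UTF-8")
}

#' Write / read a simulation configuration as flat YAML
#'
#' The file mirrors the [simulation_config()] fields exactly; unknown keys
#' are rejected on read (strict parsing).
#'
#' @param cfg a [simulation_config()].
#' @param path file path.
#' @return `write_sim_config` returns `path` invisibly; `read_sim_config`
#'   the validated configuration.
#' @export
write_sim_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path, precision = 15)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(simulation_config, vals)
}

#' Screen geometry for pixel-to-degree conversion
#'
#' @param distance_cm eye-to-screen distance (default 80 cm).
#' @param width_cm,height_cm physical screen size (default 54 x 30 cm).
#' @param width_px,height_px resolution (default 1920 x 1080).
#' @return named list of class `saccmix_screen`.
#' @export
screen_geometry <- function(distance_cm = 80, width_cm = 54, height_cm = 30,
                            width_px = 1920, height_px = 1080) {
  stopifnot(distance_cm > 0, width_cm > 0, height_cm > 0,
            width_px > 0, height_px > 0)
  structure(list(distance_cm = distance_cm, width_cm = width_cm,
                 height_cm = height_cm, width_px = width_px,
                 height_px = height_px),
            class = "saccmix_screen")
}

#' Convert screen pixels to degrees of visual angle
#'
#' Per-axis arctangent about the screen center (not a flat
#' pixels-per-degree constant): a sample `d` cm off-center at viewing
#' distance `D` subtends `atan(d / D)`.
#'
#' @param px_x,px_y pixel coordinates (origin top-left, x right, y down).
#' @param screen a [screen_geometry()].
#' @return data frame `x_deg`, `y_deg` (x right, y up, fixation-centered).
#' @export
pixels_to_degrees <- function(px_x, px_y, screen = screen_geometry()) {
  cm_x <- (px_x - screen$width_px / 2) * screen$width_cm / screen$width_px
  cm_y <- (screen$height_px / 2 - px_y) * screen$height_cm / screen$height_px
  data.frame(x_deg = atan(cm_x / screen$distance_cm) * 180 / pi,
             y_deg = atan(cm_y / screen$distance_cm) * 180 / pi)
}

#' Parse a minimal eye-tracker ASCII sample file
#'
#' Line dialect: `MSG <time> TRIALID <id>` opens a trial; sample lines are
#' `<time_ms> <x_px> <y_px> <pupil>` (whitespace-separated); a `.` in the x
#' or y field marks a missing sample (recorded as invalid).  Gaze is
#' converted from screen pixels to degrees via [pixels_to_degrees()].
#'
#' @param path file path.
#' @param screen a [screen_geometry()]; required for the conversion.
#' @return named list of traces (`time_ms`, `x_deg`, `y_deg`, `valid`)
#'   keyed by trial id.
#' @export
parse_ascii_samples <- function(path, screen = screen_geometry()) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (!inherits(screen, "saccmix_screen")) {
    stop("a screen_geometry() is required to convert pixels to degrees")
  }
  lines <- readLines(path, encoding = "UTF-8")
  trials <- list()
  cur_id <- NULL
  cur <- NULL
  flush <- function() {
    if (!is.null(cur_id) && length(cur$time)) {
      deg <- pixels_to_degrees(cur$x, cur$y, screen)
      deg$x_deg[!cur$valid] <- NA_real_
      deg$y_deg[!cur$valid] <- NA_real_
      trials[[cur_id]] <<- data.frame(time_ms = cur$time, x_deg = deg$x_deg,
                                      y_deg = deg$y_deg, valid = cur$valid)
    }
  }
  for (ln in seq_along(lines)) {
    line <- trimws(lines[ln])
    if (!nzchar(line)) next
    tok <- strsplit(line, "\\s+")[[1]]
    if (tok[1] == "MSG") {
      if (length(tok) >= 4 && tok[3] == "TRIALID") {
        flush()
        cur_id <- tok[4]
        cur <- list(time = numeric(0), x = numeric(0), y = numeric(0),
                    valid = logical(0))
      }
      next
    }
    if (is.null(cur_id)) next  # samples before the first trial are ignored
    if (length(tok) < 3) {
      stop("malformed sample line ", ln, ": '", lines[ln], "'")
    }
    t <- suppressWarnings(as.numeric(tok[1]))
    if (is.na(t)) stop("malformed sample line ", ln, ": '", lines[ln], "'")
    missing <- tok[2] == "." || tok[3] == "."
    x <- suppressWarnings(as.numeric(tok[2]))
    y <- suppressWarnings(as.numeric(tok[3]))
    if (!missing && (is.na(x) || is.na(y))) {
      stop("malformed sample line ", ln, ": '", lines[ln], "'")
    }
    cur$time <- c(cur$time, t)
    cur$x <- c(cur$x, if (missing) screen$width_px / 2 else x)
    cur$y <- c(cur$y, if (missing) screen$height_px / 2 else y)
    cur$valid <- c(cur$valid, !missing)
  }
  flush()
  trials
}

#' Write an experiment to a directory with a manifest
#'
#' Writes `trials.tsv`, `truth.tsv` and a `manifest.yaml` recording the
#' configuration, the master seed and the package version, which together
#' make the tables exactly reproducible.
#'
#' @param experiment list from [generate_experiment()].
#' @param config the configuration used.
#' @param seed the master seed used.
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_experiment <- function(experiment, config, seed, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (file.access(outdir, 2) != 0) stop("output directory not writable")
  write_tsv(experiment$trials, file.path(outdir, "trials.tsv"))
  write_tsv(experiment$truth, file.path(outdir, "truth.tsv"))
  yaml::write_yaml(
    list(seed = as.integer(seed),
         package_version = as.character(utils::packageVersion("saccmix")),
         config = unclass(config)),
    file.path(outdir, "manifest.yaml"))
  invisible(outdir)
}
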