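# Click-log CSV contract and session configuration.

CLICK_LOG_COLUMNS <- c("participant_id", "trial_index", "function_label",
                       "click_index", "x", "y", "distance",
                       "radius_in_force", "reinforced", "in_target",
                       "ended_early")

#' Write a click log to CSV
#'
#' One row per click with the fixed column schema shared by the simulate
#' and analyze stages; the round trip through [read_click_log()] is
#' lossless.
#'
#' @param click_log A click-log tibble from [run_session()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_click_log <- function(click_log, path) {
  stopifnot(all(CLICK_LOG_COLUMNS %in% names(click_log)))
  readr::write_csv(click_log[CLICK_LOG_COLUMNS], path)
  invisible(path)
}

#' Read and validate a click log
#'
#' Reads a click-log CSV and checks the record-level invariants: a target
#' click must be reinforced, the reinforcement flag must agree with the
#' click's distance and the radius in force, click indices must be
#' consecutive from 1, and the radius in force must be non-increasing
#' within each trial. The first violation is reported with its row number.
#'
#' @param path CSV path written by [write_click_log()].
#' @return A validated click-log tibble.
#' @export
read_click_log <- function(path) {
  log <- readr::read_csv(path, col_types = readr::cols(
    participant_id = readr::col_character(),
    trial_index = readr::col_integer(),
    function_label = readr::col_character(),
    click_index = readr::col_integer(),
    x = readr::col_double(),
    y = readr::col_double(),
    distance = readr::col_double(),
    radius_in_force = readr::col_double(),
    reinforced = readr::col_logical(),
    in_target = readr::col_logical(),
    ended_early = readr::col_logical()
  ))
  if (!identical(names(log), CLICK_LOG_COLUMNS)) {
    stop("click log header does not match the expected schema",
         call. = FALSE)
  }
  validate_click_log(log)
  log
}

validate_click_log <- function(log, tol = 1e-8) {
  fail <- function(rows, what) {
    if (any(rows)) {
      stop(sprintf("click log invariant violated (%s) at row %d",
                   what, which(rows)[1]), call. = FALSE)
    }
  }
  fail(log$in_target & !log$reinforced, "in_target implies reinforced")
  fail(xor(log$reinforced, log$distance <= log$radius_in_force + tol),
       "reinforced iff distance <= radius_in_force")
  by_trial <- split(seq_len(nrow(log)),
                    paste(log$participant_id, log$trial_index))
  for (idx in by_trial) {
    ord <- idx[order(log$click_index[idx])]
    if (!identical(log$click_index[ord], seq_along(ord))) {
      stop(sprintf("click log invariant violated (click indices) at row %d",
                   ord[1]), call. = FALSE)
    }
    r <- log$radius_in_force[ord]
    if (any(diff(r) > tol)) {
      bad <- ord[which(diff(r) > tol)[1] + 1]
      stop(sprintf(
        "click log invariant violated (radius non-increasing) at row %d",
        bad), call. = FALSE)
    }
  }
  invisible(log)
}

#' Session configuration
#'
#' Loads the experiment configuration: screen geometry, the three shaping
#' arms, trial counts, agent kind and parameters, metric options and the
#' master seed. Defaults ship with the package
#' (`inst/extdata/default-config.yaml`) and encode the experimental
#' constants: a 1920 x 1080 screen, 400 px initial and 100 px target radii
#' contracting over 10 reinforcements with `b` in {-0.3, 0, 0.3}, 54
#' participants, 15 trials per shaping function, 50 clicks per trial with
#' early stop after 10 consecutive target clicks, and the calibrated
#' win-stay/shift agent defaults.
#'
#' @param path Optional YAML file whose entries override the defaults
#'   (nested lists are merged).
#' @param ... Named top-level overrides applied after the file (e.g.
#'   `seed = 7`).
#' @return A `session_config` list.
#' @export
session_config <- function(path = NULL, ...) {
  defaults <- yaml::read_yaml(system.file("extdata", "default-config.yaml",
                                          package = "shapesim"))
  cfg <- defaults
  if (!is.null(path)) {
    cfg <- modify_deep(cfg, yaml::read_yaml(path))
  }
  dots <- list(...)
  if (length(dots) > 0) cfg <- modify_deep(cfg, dots)
  structure(cfg, class = "session_config")
}

modify_deep <- function(base, new) {
  for (nm in names(new)) {
    if (is.list(base[[nm]]) && is.list(new[[nm]])) {
      base[[nm]] <- modify_deep(base[[nm]], new[[nm]])
    } else {
      base[[nm]] <- new[[nm]]
    }
  }
  base
}

#' Shaping arms defined by a session configuration
#'
#' @param config A [session_config()].
#' @return Named list of [shaping_spec()] objects, one per arm.
#' @export
config_specs <- function(config) {
  sh <- config$shaping
  specs <- lapply(sh$arms, shaping_spec, r_init = sh$r_init,
                  r_target = sh$r_target, n_max = sh$n_max)
  specs[intersect(FUNCTION_LEVELS, names(specs))]
}

# short stable digest of a config for run logging
config_digest <- function(config) {
  rlang::hash(unclass(config))
}

#' @export
print.session_config <- function(x, ...) {
  cat("<session_config>", "digest:", config_digest(x), "\n")
  utils::str(unclass(x), max.level = 2, give.attr = FALSE)
  invisible(x)
}
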