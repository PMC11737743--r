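# Trial and session state machine for the hidden-target click task: random
# target placement, click evaluation against the reinforcement window in
# force, reinforcement-contingent contraction, and early termination.

#' Configure a single trial
#'
#' @param shaping A [shaping_spec()] governing window contraction.
#' @param screen_width,screen_height Screen size in pixels.
#' @param max_clicks Maximum clicks per trial.
#' @param consec_stop Number of consecutive target clicks that ends the
#'   trial early.
#' @return A `trial_config` object.
#' @export
trial_config <- function(shaping, screen_width = 1920, screen_height = 1080,
                         max_clicks = 50, consec_stop = 10) {
  stopifnot(inherits(shaping, "shaping_spec"),
            screen_width > 0, screen_height > 0,
            max_clicks >= 1, consec_stop >= 1, consec_stop <= max_clicks)
  structure(
    list(shaping = shaping, screen_width = screen_width,
         screen_height = screen_height, max_clicks = as.integer(max_clicks),
         consec_stop = as.integer(consec_stop)),
    class = "trial_config"
  )
}

#' Randomly place the target for one trial
#'
#' The shared center of the target and reinforcement circles is drawn
#' uniformly, constrained so the entire initial reinforcement circle stays
#' on screen: each coordinate lies in `[r_init, extent - r_init]`.
#'
#' @param config A [trial_config()].
#' @return Numeric `c(x, y)` center in pixels.
#' @export
place_target <- function(config) {
  stopifnot(inherits(config, "trial_config"))
  r <- config$shaping$r_init
  if (config$screen_width < 2 * r || config$screen_height < 2 * r) {
    stop(sprintf(
      "screen %g x %g cannot contain a reinforcement circle of radius %g",
      config$screen_width, config$screen_height, r), call. = FALSE)
  }
  c(stats::runif(1, r, config$screen_width - r),
    stats::runif(1, r, config$screen_height - r))
}

#' Initialize engine state for one trial
#'
#' @param config A [trial_config()].
#' @param target Target center `c(x, y)`; drawn via [place_target()] when
#'   `NULL`.
#' @return A `trial_state` list tracking the target, the radius in force,
#'   the reinforcement count and the consecutive-target counter.
#' @export
new_trial_state <- function(config, target = NULL) {
  stopifnot(inherits(config, "trial_config"))
  if (is.null(target)) target <- place_target(config)
  stopifnot(is.numeric(target), length(target) == 2L)
  structure(
    list(config = config, target = target, n_reinf = 0L,
         radius = shaping_radius(config$shaping, 0L), consec = 0L,
         n_clicks = 0L),
    class = "trial_state"
  )
}

#' Evaluate one click against the current reinforcement window
#'
#' The click is judged under the radius in force *before* the click: a
#' click is reinforced iff its Euclidean distance to the target center is
#' at most that radius (closed disk), and is a target click iff the
#' distance is at most the target radius. A reinforced click increments the
#' reinforcement count, and the contracted radius applies from the next
#' click on; after `n_max` reinforcements the radius is held constant.
#'
#' @param state A `trial_state` from [new_trial_state()].
#' @param x,y Click coordinates in pixels; must be on screen.
#' @return `list(record, state)`: `record` is a one-row tibble with the
#'   click's coordinates, distance, the radius in force, the `reinforced`
#'   and `in_target` flags and the updated reinforcement count; `state` is
#'   the advanced engine state.
#' @export
evaluate_click <- function(state, x, y) {
  stopifnot(inherits(state, "trial_state"))
  cfg <- state$config
  if (!is.finite(x) || !is.finite(y) || x < 0 || x > cfg$screen_width ||
      y < 0 || y > cfg$screen_height) {
    stop("click lies outside the screen", call. = FALSE)
  }
  d <- sqrt((x - state$target[1])^2 + (y - state$target[2])^2)
  radius_in_force <- state$radius
  reinforced <- d <= radius_in_force
  in_target <- d <= cfg$shaping$r_target
  if (reinforced && state$n_reinf < cfg$shaping$n_max) {
    state$n_reinf <- state$n_reinf + 1L
    state$radius <- shaping_radius(cfg$shaping, state$n_reinf)
  }
  state$consec <- if (in_target) state$consec + 1L else 0L
  state$n_clicks <- state$n_clicks + 1L
  record <- tibble::tibble(
    click_index = state$n_clicks, x = x, y = y, distance = d,
    radius_in_force = radius_in_force, reinforced = reinforced,
    in_target = in_target, n_reinforcements_after = state$n_reinf
  )
  list(record = record, state = state)
}

#' Run one trial to completion
#'
#' Repeatedly queries the agent for a click and evaluates it, feeding the
#' reinforcement outcome back to the agent, until either `consec_stop`
#' consecutive clicks land in the target circle (early stop) or
#' `max_clicks` clicks have been made.
#'
#' @param agent A `shaping_agent` (see [agent_win_stay_shift()] and
#'   friends).
#' @param config A [trial_config()].
#' @param target Optional fixed target center; random placement when
#'   `NULL`.
#' @return A `trial_result`: a tibble of click records (one row per actual
#'   click) with attributes `target` (center), `ended_early` (flag) and
#'   `config`.
#' @export
run_trial <- function(agent, config, target = NULL) {
  stopifnot(inherits(agent, "shaping_agent"), inherits(config, "trial_config"))
  state <- new_trial_state(config, target)
  env <- list(width = config$screen_width, height = config$screen_height,
              target = state$target)
  astate <- agent$init(env)
  feedback <- "none"
  max_clicks <- config$max_clicks
  # preallocated click-evaluation loop; semantics identical to
  # evaluate_click(), which remains the single-click reference surface
  spec <- config$shaping
  radii_by_n <- shaping_radius(spec, 0:spec$n_max)
  tx <- state$target[1]; ty <- state$target[2]
  xs <- numeric(max_clicks); ys <- numeric(max_clicks)
  ds <- numeric(max_clicks); rs <- numeric(max_clicks)
  reinf <- logical(max_clicks); intg <- logical(max_clicks)
  nafter <- integer(max_clicks)
  n_reinf <- 0L; consec <- 0L
  ended_early <- FALSE
  k <- 0L
  while (k < max_clicks) {
    mv <- agent$step(astate, feedback, env)
    astate <- mv$state
    x <- mv$x; y <- mv$y
    if (!is.finite(x) || !is.finite(y) || x < 0 || x > env$width ||
        y < 0 || y > env$height) {
      stop("click lies outside the screen", call. = FALSE)
    }
    k <- k + 1L
    d <- sqrt((x - tx)^2 + (y - ty)^2)
    r_now <- radii_by_n[n_reinf + 1L]
    reinforced <- d <= r_now
    in_target <- d <= spec$r_target
    if (reinforced && n_reinf < spec$n_max) n_reinf <- n_reinf + 1L
    consec <- if (in_target) consec + 1L else 0L
    xs[k] <- x; ys[k] <- y; ds[k] <- d; rs[k] <- r_now
    reinf[k] <- reinforced; intg[k] <- in_target; nafter[k] <- n_reinf
    feedback <- if (reinforced) "reinforced" else "not_reinforced"
    if (consec >= config$consec_stop) {
      ended_early <- TRUE
      break
    }
  }
  idx <- seq_len(k)
  out <- tibble::tibble(
    click_index = idx, x = xs[idx], y = ys[idx], distance = ds[idx],
    radius_in_force = rs[idx], reinforced = reinf[idx],
    in_target = intg[idx], n_reinforcements_after = nafter[idx]
  )
  attr(out, "target") <- state$target
  attr(out, "ended_early") <- ended_early
  attr(out, "config") <- config
  class(out) <- c("trial_result", class(out))
  out
}

#' Total clicks actually made in a trial
#'
#' Counts only actual clicks; clicks imputed after an early stop are
#' excluded. Under the default configuration the count lies in
#' `[consec_stop, max_clicks]`.
#'
#' @param trial A `trial_result` from [run_trial()].
#' @return Integer click count.
#' @export
trial_total_clicks <- function(trial) {
  stopifnot(inherits(trial, "trial_result"))
  nrow(trial)
}

#' Simulate a full session for a cohort
#'
#' For each participant, builds a trial sequence with `trials_per_function`
#' trials of each of the three shaping arms, shuffles it with the
#' participant's own RNG stream, freshly instantiates the participant's
#' agent, and runs every trial with an independently placed target. A
#' master seed spawns one substream per participant (placement, trial-order
#' shuffle and agent noise), so cohorts replay exactly and participants are
#' mutually independent.
#'
#' @param agent_factory A function `factory(i)` returning participant `i`'s
#'   agent (e.g. from [make_cohort()]), or a single `shaping_agent` used
#'   for everyone.
#' @param n_participants Cohort size.
#' @param trials_per_function Trials per shaping arm per participant.
#' @param specs Named list of [shaping_spec()] arms (default: the three
#'   experimental presets).
#' @param screen_width,screen_height,max_clicks,consec_stop Trial
#'   configuration shared by all arms.
#' @param seed Master seed (required, for reproducibility).
#' @return A click-log tibble, one row per click, with columns
#'   `participant_id`, `trial_index`, `function_label`, `click_index`, `x`,
#'   `y`, `distance`, `radius_in_force`, `reinforced`, `in_target`, and the
#'   trial-level `ended_early` flag repeated on each row.
#' @examples
#' \donttest{
#' log <- run_session(agent_oracle(), n_participants = 2,
#'                    trials_per_function = 1, seed = 1)
#' dplyr::count(log, participant_id, function_label)
#' }
#' @export
run_session <- function(agent_factory, n_participants = 54,
                        trials_per_function = 15, specs = shaping_presets(),
                        screen_width = 1920, screen_height = 1080,
                        max_clicks = 50, consec_stop = 10, seed) {
  stopifnot(n_participants >= 1, trials_per_function >= 1)
  if (missing(seed)) stop("a master seed is required", call. = FALSE)
  if (inherits(agent_factory, "shaping_agent")) {
    agent <- agent_factory
    agent_factory <- function(i) agent
  }
  configs <- lapply(specs, trial_config,
                    screen_width = screen_width,
                    screen_height = screen_height,
                    max_clicks = max_clicks, consec_stop = consec_stop)
  labels <- names(specs)
  set.seed(seed)
  pseeds <- sample.int(.Machine$integer.max - 1L, n_participants)
  id_width <- max(2L, nchar(n_participants))
  logs <- vector("list", n_participants)
  for (i in seq_len(n_participants)) {
    set.seed(pseeds[i])
    order_i <- sample(rep(labels, each = trials_per_function))
    agent_i <- agent_factory(i)
    pid <- sprintf("P%0*d", id_width, i)
    trials <- vector("list", length(order_i))
    for (t in seq_along(order_i)) {
      tr <- run_trial(agent_i, configs[[order_i[t]]])
      flat <- tibble::as_tibble(tr)
      attr(flat, "target") <- NULL
      attr(flat, "ended_early") <- NULL
      attr(flat, "config") <- NULL
      class(flat) <- setdiff(class(flat), "trial_result")
      trials[[t]] <- dplyr::mutate(
        flat,
        participant_id = pid, trial_index = t, function_label = order_i[t],
        ended_early = attr(tr, "ended_early"), .before = 1
      )
    }
    logs[[i]] <- dplyr::bind_rows(trials)
  }
  dplyr::bind_rows(logs) |>
    dplyr::select("participant_id", "trial_index", "function_label",
                  "click_index", "x", "y", "distance", "radius_in_force",
                  "reinforced", "in_target", "ended_early")
}
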