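# Shared fixtures, built in code.

default_specs <- shaping_presets()

# A scripted agent replaying a fixed coordinate sequence (recycled).
agent_scripted <- function(xs, ys) {
  stopifnot(length(xs) == length(ys))
  structure(
    list(
      kind = "scripted",
      init = function(env) list(i = 0L),
      step = function(state, feedback, env) {
        state$i <- state$i + 1L
        j <- ((state$i - 1L) %% length(xs)) + 1L
        list(x = xs[j], y = ys[j], state = state)
      },
      params = list()
    ),
    class = "shaping_agent"
  )
}

# Independent straight-line re-simulation of the engine rules for a
# scripted click sequence: recomputes distances, flags and radii from
# first principles, without the engine's state machine.
resimulate_clicks <- function(xs, ys, target, spec, max_clicks = 50,
                              consec_stop = 10) {
  n_reinf <- 0
  consec <- 0
  rows <- list()
  for (k in seq_along(xs)) {
    if (k > max_clicks) break
    d <- sqrt((xs[k] - target[1])^2 + (ys[k] - target[2])^2)
    r <- if (abs(spec$b) < 1e-8) {
      spec$r_init - min(n_reinf, spec$n_max) *
        (spec$r_init - spec$r_target) / spec$n_max
    } else {
      spec$r_init - (spec$r_init - spec$r_target) *
        (1 - exp(spec$b * min(n_reinf, spec$n_max))) /
        (1 - exp(spec$b * spec$n_max))
    }
    reinforced <- d <= r
    in_target <- d <= spec$r_target
    if (reinforced && n_reinf < spec$n_max) n_reinf <- n_reinf + 1
    consec <- if (in_target) consec + 1 else 0
    rows[[k]] <- data.frame(distance = d, radius_in_force = r,
                            reinforced = reinforced, in_target = in_target)
    if (consec >= consec_stop) break
  }
  do.call(rbind, rows)
}

# Synthetic outcome tables with known generative parameters, for
# parameter-recovery checks of the inference layer.
make_aa_data <- function(n = 54, delta_down = -2.3, delta_up = 2.3,
                         mu = 31, sd_between = 2.5, sd_resid = 2) {
  b <- rnorm(n, 0, sd_between)
  tidyr::expand_grid(participant = seq_len(n),
                     function_label = c("linear", "concave_down",
                                        "concave_up")) |>
    dplyr::mutate(
      participant_id = sprintf("P%02d", .data$participant),
      aa = mu + b[.data$participant] +
        ifelse(.data$function_label == "concave_down", delta_down,
               ifelse(.data$function_label == "concave_up", delta_up, 0)) +
        rnorm(dplyr::n(), 0, sd_resid)
    ) |>
    dplyr::select("participant_id", "function_label", "aa")
}

make_clicks_data <- function(n_per_group = 810, mu = 25,
                             irr_down = 1.07, irr_up = 0.92, theta = 8) {
  tidyr::expand_grid(function_label = c("linear", "concave_down",
                                        "concave_up"),
                     i = seq_len(n_per_group)) |>
    dplyr::mutate(
      participant_id = sprintf("P%02d", (.data$i - 1) %% 54 + 1),
      rate = mu * ifelse(.data$function_label == "concave_down", irr_down,
                         ifelse(.data$function_label == "concave_up",
                                irr_up, 1)),
      total_clicks = MASS::rnegbin(dplyr::n(), mu = .data$rate,
                                   theta = theta)
    ) |>
    dplyr::select("participant_id", "function_label", "total_clicks")
}

# Small seeded cohort log shared across metric/stat tests.
small_cohort_log <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- session_config(trials = list(n_participants = 8,
                                          trials_per_function = 4))
      cache <<- simulate_experiment(cfg, seed = 42)
    }
    cache
  }
})
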