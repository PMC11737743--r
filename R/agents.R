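# Synthetic participants. An agent is a list with an `init(env)` method
# returning its per-trial state and a `step(state, feedback, env)` method
# returning list(x, y, state). `env` carries the screen and (for the
# test-only oracle) the target center. All randomness comes from the global
# RNG so that seeded sessions replay exactly.

new_agent <- function(kind, init, step, params = list()) {
  structure(list(kind = kind, init = init, step = step, params = params),
            class = "shaping_agent")
}

#' @export
print.shaping_agent <- function(x, ...) {
  cat(sprintf("<shaping_agent> kind = %s\n", x$kind))
  invisible(x)
}

#' Uniform random clicker
#'
#' Clicks uniformly over the whole screen on every click, ignoring feedback.
#' Useful as a shaping-insensitive baseline: its outcomes cannot depend on
#' the shaping schedule.
#'
#' @return A `shaping_agent`.
#' @export
agent_random <- function() {
  new_agent(
    "random",
    init = function(env) list(),
    step = function(state, feedback, env) {
      list(x = stats::runif(1, 0, env$width),
           y = stats::runif(1, 0, env$height), state = state)
    }
  )
}

#' Oracle clicker (test helper)
#'
#' Clicks the exact target center on every click. Real participants cannot
#' see the target; the oracle exists to pin down the engine's early-stop
#' behavior and the maximal achievable outcomes.
#'
#' @return A `shaping_agent`.
#' @export
agent_oracle <- function() {
  new_agent(
    "oracle",
    init = function(env) list(),
    step = function(state, feedback, env) {
      list(x = env$target[1], y = env$target[2], state = state)
    }
  )
}

#' Fixed-point clicker
#'
#' Clicks the same screen location on every click, regardless of feedback.
#'
#' @param x,y The fixed click location in pixels.
#' @return A `shaping_agent`.
#' @export
agent_fixed_point <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == 1L, length(y) == 1L)
  new_agent(
    "fixed_point",
    init = function(env) {
      if (x < 0 || x > env$width || y < 0 || y > env$height) {
        stop("fixed point lies off screen", call. = FALSE)
      }
      list()
    },
    step = function(state, feedback, env) list(x = x, y = y, state = state),
    params = list(x = x, y = y)
  )
}

#' Win-stay/shift searcher
#'
#' A reinforcement-sensitive searcher, the default model of a participant.
#' Before any reinforcement it explores uniformly. After a reinforced click
#' it re-centers its search on that location and samples an isotropic
#' Gaussian around it, multiplying its spread by `shrink` (search narrows
#' where reward was found). After a non-reinforced click it returns to the
#' last reinforced location but widens its spread by `grow`, capped at
#' `spread_cap`. With probability `lapse` any click is replaced by a uniform
#' off-policy click. Off-screen draws are rejected and redrawn so no
#' probability mass piles on the screen edge.
#'
#' Because the searcher narrows wherever it is reinforced, the shaping
#' schedule matters: a schedule that contracts the reinforcement window
#' quickly only rewards clicks near the target, pulling the search onto the
#' target early, whereas a slowly contracting schedule rewards — and
#' entrenches — clicks far from it.
#'
#' @param sigma_exploit Initial local-search spread in pixels.
#' @param shrink Multiplicative spread factor applied on reinforcement
#'   (in (0, 1)).
#' @param grow Multiplicative spread factor applied on non-reinforcement
#'   (> 1).
#' @param lapse Probability of an off-policy uniform click (in \[0, 1)).
#' @param spread_min,spread_cap Bounds on the search spread in pixels.
#' @return A `shaping_agent`.
#' @export
agent_win_stay_shift <- function(sigma_exploit = 250, shrink = 0.7,
                                 grow = 1.05, lapse = 0.02,
                                 spread_min = 8, spread_cap = 500) {
  stopifnot(sigma_exploit > 0, shrink > 0, shrink < 1, grow > 1,
            lapse >= 0, lapse < 1, spread_min > 0, spread_cap > spread_min)
  params <- list(sigma_exploit = sigma_exploit, shrink = shrink, grow = grow,
                 lapse = lapse, spread_min = spread_min,
                 spread_cap = spread_cap)
  new_agent(
    "win_stay_shift",
    init = function(env) {
      list(anchor = NULL, spread = sigma_exploit, last_click = NULL)
    },
    step = function(state, feedback, env) {
      if (identical(feedback, "reinforced")) {
        state$anchor <- state$last_click
        state$spread <- max(state$spread * shrink, spread_min)
      } else if (identical(feedback, "not_reinforced")) {
        state$spread <- min(state$spread * grow, spread_cap)
      }
      if (stats::runif(1) < lapse || is.null(state$anchor)) {
        xy <- c(stats::runif(1, 0, env$width), stats::runif(1, 0, env$height))
      } else {
        repeat {
          xy <- state$anchor + stats::rnorm(2, 0, state$spread)
          if (xy[1] >= 0 && xy[1] <= env$width &&
              xy[2] >= 0 && xy[2] <= env$height) break
        }
      }
      state$last_click <- xy
      list(x = xy[1], y = xy[2], state = state)
    },
    params = params
  )
}

#' Construct an agent from a kind string and parameter list
#'
#' @param kind One of `"random"`, `"oracle"`, `"fixed_point"`,
#'   `"win_stay_shift"`.
#' @param params Named list of parameters passed to the matching
#'   constructor.
#' @return A `shaping_agent`.
#' @export
make_agent <- function(kind = c("win_stay_shift", "random", "oracle",
                                "fixed_point"),
                       params = list()) {
  kind <- match.arg(kind)
  ctor <- switch(kind,
    random = agent_random, oracle = agent_oracle,
    fixed_point = agent_fixed_point, win_stay_shift = agent_win_stay_shift)
  do.call(ctor, params)
}

#' Build a heterogeneous cohort of win-stay/shift participants
#'
#' Returns an agent factory: a function mapping a participant index to that
#' participant's agent. Each participant's search spread is perturbed
#' log-normally and their lapse probability logit-normally, both with
#' standard deviation `skill_sd`, drawn once per participant (from the
#' current RNG state) and held fixed across all of that participant's
#' trials. This induces a stable between-participant variance component in
#' the outcomes, as a human cohort shows.
#'
#' @param params Named list of baseline [agent_win_stay_shift()] parameters
#'   (`sigma_exploit`, `shrink`, `grow`, `lapse`, ...).
#' @param n_participants Cohort size.
#' @param skill_sd Cohort-level standard deviation (log / logit scale) for
#'   per-participant perturbation of `sigma_exploit` and `lapse`; 0 makes
#'   all participants identical.
#' @return A function `factory(i)` returning participant `i`'s
#'   `shaping_agent`; the per-participant parameter draws are attached as
#'   the `"cohort_params"` attribute.
#' @export
make_cohort <- function(params = list(), n_participants = 54,
                        skill_sd = 0.6) {
  stopifnot(n_participants >= 1, skill_sd >= 0)
  base <- utils::modifyList(formals_defaults(agent_win_stay_shift), params)
  sig <- base$sigma_exploit * exp(stats::rnorm(n_participants, 0, skill_sd))
  lap <- if (base$lapse > 0) {
    stats::plogis(stats::qlogis(base$lapse) +
                    stats::rnorm(n_participants, 0, skill_sd))
  } else {
    rep(0, n_participants)
  }
  tab <- tibble::tibble(participant = seq_len(n_participants),
                        sigma_exploit = sig, lapse = lap)
  factory <- function(i) {
    stopifnot(i >= 1, i <= n_participants)
    p <- base
    p$sigma_exploit <- sig[i]
    p$lapse <- lap[i]
    do.call(agent_win_stay_shift, p)
  }
  attr(factory, "cohort_params") <- tab
  factory
}

# default formals of a function as an evaluated named list
formals_defaults <- function(fn) {
  f <- formals(fn)
  lapply(f, eval, envir = baseenv())
}
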