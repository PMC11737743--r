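cfg_default <- trial_config(default_specs$linear)

test_that("target placement stays within the feasible rectangle", {
  set.seed(101)
  centers <- t(replicate(10000, place_target(cfg_default)))
  expect_true(all(centers[, 1] >= 400 & centers[, 1] <= 1520))
  expect_true(all(centers[, 2] >= 400 & centers[, 2] <= 680))
  # draws fill the rectangle rather than clustering
  expect_gt(diff(range(centers[, 1])), 1000)
})

test_that("degenerate feasible region collapses to a single point", {
  cfg <- trial_config(default_specs$linear, screen_width = 800,
                      screen_height = 800)
  set.seed(1)
  expect_equal(place_target(cfg), c(400, 400))
})

test_that("infeasible geometry is a configuration error", {
  cfg <- trial_config(default_specs$linear, screen_width = 700,
                      screen_height = 700)
  expect_error(place_target(cfg), "cannot contain")
})

test_that("evaluate_click sets flags from the pre-contraction radius", {
  state <- new_trial_state(cfg_default, target = c(960, 540))
  # first click at distance 350: inside the 400 px window, outside target
  res <- evaluate_click(state, 960 + 350, 540)
  expect_true(res$record$reinforced)
  expect_false(res$record$in_target)
  expect_equal(res$record$radius_in_force, 400)
  expect_equal(res$state$radius, shaping_radius(default_specs$linear, 1))
  # distance 90: inside target implies reinforced
  res2 <- evaluate_click(res$state, 960 + 90, 540)
  expect_true(res2$record$in_target)
  expect_true(res2$record$reinforced)
  # distance 380 now exceeds the contracted 370 px window
  res3 <- evaluate_click(res2$state, 960 + 380, 540)
  expect_false(res3$record$reinforced)
  expect_error(evaluate_click(res3$state, -5, 540), "outside the screen")
})

test_that("radius plateaus at the target radius after n_max reinforcements", {
  state <- new_trial_state(cfg_default, target = c(960, 540))
  for (i in 1:12) {
    res <- evaluate_click(state, 960, 540)
    state <- res$state
  }
  expect_equal(state$radius, 100)
  expect_equal(state$n_reinf, 10L)
  res <- evaluate_click(state, 960 + 95, 540)
  expect_true(res$record$reinforced)
  expect_equal(res$state$radius, 100)
})

test_that("oracle trials stop at exactly consec_stop clicks", {
  tr <- run_trial(agent_oracle(), cfg_default, target = c(960, 540))
  expect_equal(nrow(tr), 10)
  expect_true(attr(tr, "ended_early"))
  expect_true(all(tr$in_target))
  expect_equal(trial_total_clicks(tr), 10)
})

test_that("a never-reinforced agent runs the full 50 clicks", {
  tr <- run_trial(agent_fixed_point(10, 10), cfg_default,
                  target = c(960, 540))
  expect_equal(nrow(tr), 50)
  expect_false(attr(tr, "ended_early"))
  expect_true(all(!tr$reinforced))
  expect_equal(unique(tr$radius_in_force), 400)
})

test_that("run_trial agrees with a straight-line re-simulation", {
  set.seed(7)
  for (arm in names(default_specs)) {
    spec <- default_specs[[arm]]
    cfg <- trial_config(spec)
    target <- c(700, 500)
    xs <- runif(50, 300, 1100)
    ys <- runif(50, 200, 800)
    tr <- run_trial(agent_scripted(xs, ys), cfg, target = target)
    ref <- resimulate_clicks(xs, ys, target, spec)
    expect_equal(nrow(tr), nrow(ref), info = arm)
    expect_equal(tr$distance, ref$distance, info = arm)
    expect_equal(tr$radius_in_force, ref$radius_in_force, info = arm)
    expect_equal(tr$reinforced, ref$reinforced, info = arm)
    expect_equal(tr$in_target, ref$in_target, info = arm)
  }
})

test_that("trial invariants hold across random reinforcement-driven trials", {
  set.seed(33)
  for (i in 1:20) {
    arm <- sample(names(default_specs), 1)
    tr <- run_trial(agent_win_stay_shift(), trial_config(default_specs[[arm]]))
    expect_true(all(diff(tr$radius_in_force) <= 0))
    expect_true(all(tr$radius_in_force >= 100 & tr$radius_in_force <= 400))
    expect_true(all(tr$in_target <= tr$reinforced))
    # radius reaches 100 exactly when >= 10 reinforced clicks occurred
    if (sum(tr$reinforced) >= 10) {
      expect_equal(min(shaping_radius(default_specs[[arm]],
                                      max(tr$n_reinforcements_after))), 100)
    }
    n <- nrow(tr)
    if (attr(tr, "ended_early")) {
      expect_true(all(tr$in_target[(n - 9):n]))
      if (n > 10) expect_false(all(tr$in_target[(n - 10):(n - 1)]))
    } else {
      expect_equal(n, 50)
    }
  }
})

test_that("sessions give each participant 15 trials per arm, shuffled", {
  log <- run_session(agent_oracle(), n_participants = 3,
                     trials_per_function = 15, seed = 9)
  counts <- log |>
    dplyr::distinct(.data$participant_id, .data$trial_index,
                    .data$function_label) |>
    dplyr::count(.data$participant_id, .data$function_label)
  expect_equal(nrow(counts), 9)
  expect_true(all(counts$n == 15))
  trials <- dplyr::distinct(log, .data$participant_id, .data$trial_index)
  expect_equal(nrow(trials), 3 * 45)
  # shuffled: arms are interleaved for at least one participant
  ord <- log |>
    dplyr::filter(.data$participant_id == "P01") |>
    dplyr::distinct(.data$trial_index, .data$function_label)
  expect_gt(length(rle(ord$function_label)$lengths), 3)
})

test_that("a single trial per arm appears exactly once per participant", {
  log <- run_session(agent_oracle(), n_participants = 2,
                     trials_per_function = 1, seed = 4)
  counts <- dplyr::count(
    dplyr::distinct(log, .data$participant_id, .data$trial_index,
                    .data$function_label),
    .data$participant_id, .data$function_label)
  expect_true(all(counts$n == 1))
})

test_that("identical master seeds replay the session exactly", {
  f <- function() {
    set.seed(999)  # interference check: outer RNG state must not matter
    run_session(agent_win_stay_shift(), n_participants = 3,
                trials_per_function = 2, seed = 77)
  }
  expect_identical(f(), f())
})
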