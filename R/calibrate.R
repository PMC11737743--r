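# One-time grid search used to fix the default win-stay/shift parameters.

#' Calibrate default agent parameters
#'
#' Runs a small seeded grid search over win-stay/shift parameters, scoring
#' each combination on a reduced cohort by (i) whether mean AA is ordered
#' concave-up > linear > concave-down with mean total clicks reversed —
#' the qualitative structure the analysis layer is meant to detect — and
#' (ii) the spread of the click counts. The shipped defaults were fixed
#' once from this search and frozen in the default configuration; this
#' function documents and reproduces that choice.
#'
#' @param grid A data frame of candidate parameter columns (any of
#'   `sigma_exploit`, `shrink`, `grow`, `lapse`, `skill_sd`).
#' @param n_participants,trials_per_function Reduced cohort size used for
#'   scoring.
#' @param seed Master seed.
#' @return The grid with per-arm mean AA and clicks, an `ordered` flag and
#'   the gap `aa_up_minus_down`, sorted by the gap.
#' @export
calibrate_agents <- function(grid = default_calibration_grid(),
                             n_participants = 12, trials_per_function = 5,
                             seed = 1) {
  grid <- tibble::as_tibble(grid)
  res <- purrr::pmap_dfr(grid, function(...) {
    p <- list(...)
    cfg <- session_config(
      trials = list(n_participants = n_participants,
                    trials_per_function = trials_per_function),
      agent = p
    )
    log <- simulate_experiment(cfg, seed = seed)
    aa <- aa_table(log)
    ck <- clicks_table(log)
    m <- aa |>
      dplyr::group_by(.data$function_label) |>
      dplyr::summarise(aa = mean(.data$aa), .groups = "drop")
    k <- ck |>
      dplyr::group_by(.data$function_label) |>
      dplyr::summarise(clicks = mean(.data$total_clicks), .groups = "drop")
    g <- function(df, col, lab) df[[col]][df$function_label == lab]
    tibble::tibble(
      aa_up = g(m, "aa", "concave_up"), aa_lin = g(m, "aa", "linear"),
      aa_down = g(m, "aa", "concave_down"),
      clicks_up = g(k, "clicks", "concave_up"),
      clicks_lin = g(k, "clicks", "linear"),
      clicks_down = g(k, "clicks", "concave_down"),
      sd_clicks = stats::sd(ck$total_clicks)
    )
  })
  dplyr::bind_cols(grid, res) |>
    dplyr::mutate(
      ordered = .data$aa_up > .data$aa_lin & .data$aa_lin > .data$aa_down &
        .data$clicks_up < .data$clicks_lin &
        .data$clicks_lin < .data$clicks_down,
      aa_up_minus_down = .data$aa_up - .data$aa_down
    ) |>
    dplyr::arrange(dplyr::desc(.data$ordered),
                   dplyr::desc(.data$aa_up_minus_down))
}

#' @rdname calibrate_agents
#' @export
default_calibration_grid <- function() {
  tidyr::expand_grid(
    sigma_exploit = c(150, 220, 300),
    shrink = c(0.55, 0.62, 0.7),
    grow = c(1.15, 1.25),
    lapse = c(0.02, 0.05)
  )
}
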