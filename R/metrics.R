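# Outcome measures: per-click target probabilities (with post-early-stop
# imputation), loess smoothing, accumulation area (AA), and total clicks.

#' Impute target flags for a trial
#'
#' Expands a trial's observed in-target flags to a full-length 0/1 vector.
#' When a trial ended early (the consecutive-target rule fired), the
#' remaining click slots up to `max_clicks` are scored as target clicks —
#' the participant had demonstrably located the target. A trial that did
#' not end early must already have `max_clicks` clicks.
#'
#' @param in_target Logical (or 0/1) vector of observed per-click flags, in
#'   click order.
#' @param ended_early Did the trial stop on the consecutive-target rule?
#' @param max_clicks Full trial length.
#' @return Numeric 0/1 vector of length `max_clicks`.
#' @examples
#' target_flags(c(0, 0, 1, rep(1, 9)), ended_early = TRUE, max_clicks = 20)
#' @export
target_flags <- function(in_target, ended_early, max_clicks = 50) {
  k <- length(in_target)
  if (k > max_clicks) stop("more clicks than max_clicks", call. = FALSE)
  if (k < max_clicks && !ended_early) {
    stop("a trial that did not end early must have max_clicks clicks",
         call. = FALSE)
  }
  c(as.numeric(in_target), rep(1, max_clicks - k))
}

#' Per-click target probability trajectory
#'
#' Element-wise mean of the imputed target-flag vectors over a set of
#' trials (typically one participant's trials under one shaping function):
#' the empirical probability of a target click at each click index.
#'
#' @param flag_list A list of equal-length 0/1 vectors from
#'   [target_flags()].
#' @return Numeric probability vector.
#' @export
trajectory_raw <- function(flag_list) {
  if (length(flag_list) == 0) stop("no trials supplied", call. = FALSE)
  lens <- lengths(flag_list)
  stopifnot(all(lens == lens[1]))
  Reduce(`+`, flag_list) / length(flag_list)
}

#' Loess-smooth a probability trajectory
#'
#' Locally weighted polynomial regression over click index: for each index,
#' the `ceiling(span * n)` nearest points are fitted by weighted least
#' squares with tricube weights, and the local fit is evaluated at that
#' index. Defaults follow the smoother's conventional form: local degree 2,
#' tricube kernel, span as the nearest-neighbor fraction, no robustness
#' iterations. Fitted probabilities are clamped to `[0, 1]`, since local
#' polynomials can overshoot. If the window is too small to support the
#' local polynomial, a single global polynomial fit of the same degree is
#' used instead.
#'
#' @param y Numeric vector to smooth (at unit-spaced indices).
#' @param span Fraction of points in each local window, in (0, 1].
#' @param degree Local polynomial degree (1 or 2).
#' @param clamp Length-2 numeric bounds for the fitted values, or `NULL`
#'   for no clamping.
#' @return Numeric vector of fitted values, same length as `y`.
#' @export
smooth_loess <- function(y, span = 0.4, degree = 2, clamp = c(0, 1)) {
  stopifnot(is.numeric(y), span > 0, span <= 1, degree %in% c(1, 2))
  n <- length(y)
  x <- seq_len(n)
  q <- ceiling(span * n)
  if (q < degree + 2 || n < degree + 2) {
    X <- stats::poly(x, degree = min(degree, n - 1), raw = TRUE)
    fit <- stats::lm.fit(cbind(1, X), y)
    out <- cbind(1, X) %*% ifelse(is.na(fit$coefficients), 0,
                                  fit$coefficients)
    out <- as.numeric(out)
  } else {
    out <- vapply(seq_len(n), function(i) {
      d <- abs(x - x[i])
      idx <- order(d)[seq_len(q)]
      dmax <- max(d[idx])
      w <- (1 - (d[idx] / dmax)^3)^3
      xc <- x[idx] - x[i]
      X <- if (degree == 2) cbind(1, xc, xc^2) else cbind(1, xc)
      fit <- stats::lm.wfit(X, y[idx], w)
      co <- fit$coefficients
      co[is.na(co)] <- 0
      co[1]
    }, numeric(1))
  }
  if (!is.null(clamp)) out <- pmin(pmax(out, clamp[1]), clamp[2])
  out
}

#' Accumulation area under a trajectory
#'
#' Area under the per-click probability curve over unit-spaced click
#' indices. The default trapezoidal rule gives a maximum of
#' `length(y) - 1` (49 for a 50-click trial); a left Riemann sum (maximum
#' `length(y)`) is available as an alternative convention.
#'
#' @param y Numeric trajectory (typically smoothed probabilities).
#' @param rule Integration rule, `"trapezoid"` (default) or `"riemann"`.
#' @return The area, a scalar.
#' @examples
#' accumulation_area(rep(1, 50))  # 49
#' @export
accumulation_area <- function(y, rule = c("trapezoid", "riemann")) {
  rule <- match.arg(rule)
  stopifnot(is.numeric(y), length(y) >= 2)
  switch(rule,
    trapezoid = sum((y[-1] + y[-length(y)]) / 2),
    riemann = sum(y)
  )
}

# Per-trial summary rows from a click log: one row per trial with its
# flags, length and early-stop status.
trial_summaries <- function(click_log) {
  click_log |>
    dplyr::arrange(.data$participant_id, .data$trial_index,
                   .data$click_index) |>
    dplyr::group_by(.data$participant_id, .data$trial_index,
                    .data$function_label) |>
    dplyr::summarise(
      total_clicks = dplyr::n(),
      ended_early = .data$ended_early[1],
      flags = list(as.numeric(.data$in_target)),
      .groups = "drop"
    )
}

#' Smoothed trajectories and AA per participant and shaping function
#'
#' Builds, for every participant and shaping arm in a click log, the raw
#' target-probability trajectory (trial-averaged imputed target flags), its
#' loess-smoothed version, and the accumulation area under the smoothed
#' curve.
#'
#' @param click_log A click-log tibble as produced by [run_session()] or
#'   [read_click_log()].
#' @param max_clicks Full trial length used for flag imputation.
#' @param span Loess span, see [smooth_loess()].
#' @param degree Loess local polynomial degree.
#' @param rule AA integration rule, see [accumulation_area()].
#' @return A tibble with one row per participant x function:
#'   `participant_id`, `function_label`, list-columns `raw` and `smoothed`
#'   (length-`max_clicks` trajectories), and `aa`. Class
#'   `shaping_trajectories`.
#' @export
trajectories <- function(click_log, max_clicks = 50, span = 0.4, degree = 2,
                         rule = c("trapezoid", "riemann")) {
  rule <- match.arg(rule)
  out <- trial_summaries(click_log) |>
    dplyr::mutate(flags = purrr::map2(.data$flags, .data$ended_early,
                                      target_flags,
                                      max_clicks = max_clicks)) |>
    dplyr::group_by(.data$participant_id, .data$function_label) |>
    dplyr::summarise(raw = list(trajectory_raw(.data$flags)),
                     .groups = "drop") |>
    dplyr::mutate(
      smoothed = purrr::map(.data$raw, smooth_loess, span = span,
                            degree = degree),
      aa = purrr::map_dbl(.data$smoothed, accumulation_area, rule = rule)
    )
  class(out) <- c("shaping_trajectories", class(out))
  out
}

#' AA outcome table
#'
#' One accumulation-area value per participant and shaping function
#' (54 x 3 rows under the default experiment), the input to
#' [fit_aa_model()].
#'
#' @inheritParams trajectories
#' @return A tibble `participant_id`, `function_label`, `aa`.
#' @export
aa_table <- function(click_log, max_clicks = 50, span = 0.4, degree = 2,
                     rule = c("trapezoid", "riemann")) {
  tr <- trajectories(click_log, max_clicks = max_clicks, span = span,
                     degree = degree, rule = rule)
  dplyr::select(tibble::as_tibble(tr), "participant_id", "function_label",
                "aa")
}

#' Total-clicks outcome table
#'
#' Actual clicks per trial (imputed clicks excluded), one row per trial,
#' the input to [fit_clicks_model()].
#'
#' @inheritParams trajectories
#' @return A tibble `participant_id`, `trial_index`, `function_label`,
#'   `total_clicks`, `ended_early`.
#' @export
clicks_table <- function(click_log) {
  trial_summaries(click_log) |>
    dplyr::select("participant_id", "trial_index", "function_label",
                  "total_clicks", "ended_early")
}

#' Plot smoothed target-probability trajectories
#'
#' Mean raw and smoothed per-click target probability by shaping function,
#' averaged over participants.
#'
#' @param object A `shaping_trajectories` from [trajectories()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.shaping_trajectories <- function(object, ...) {
  dat <- object |>
    tibble::as_tibble() |>
    dplyr::mutate(click = purrr::map(.data$raw, seq_along)) |>
    tidyr::unnest(c("click", "raw", "smoothed")) |>
    dplyr::group_by(.data$function_label, .data$click) |>
    dplyr::summarise(raw = mean(.data$raw), smoothed = mean(.data$smoothed),
                     .groups = "drop")
  ggplot2::ggplot(dat, ggplot2::aes(.data$click, colour =
                                      .data$function_label)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$raw), alpha = 0.35,
                        size = 0.8) +
    ggplot2::geom_line(ggplot2::aes(y = .data$smoothed), linewidth = 0.8) +
    ggplot2::labs(x = "Click index", y = "P(target click)",
                  colour = "Shaping function") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
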