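# Shaping-function family: reinforcement-window radius as a function of the
# number of reinforcements delivered so far.

# |b| below this dispatches to the closed linear form; the exponential form
# is singular (0/0) at b = 0.
B_LINEAR_EPS <- 1e-8

#' Define a shaping schedule
#'
#' A shaping schedule governs how the radius of the reinforcement circle
#' contracts toward the target circle as reinforcements accumulate. The
#' family is
#' \deqn{r(n) = r_0 - (r_0 - r_T)\,\frac{1 - e^{bn}}{1 - e^{b n_{max}}}}
#' for contraction rate \eqn{b \ne 0}, with the \eqn{b \to 0} limit
#' \eqn{r(n) = r_0 - n (r_0 - r_T)/n_{max}} (a straight line). Negative
#' \eqn{b} gives a concave-up schedule (rapid initial narrowing), positive
#' \eqn{b} a concave-down one (slow initial narrowing). With the default
#' geometry (\eqn{r_0 = 400}, \eqn{r_T = 100}, \eqn{n_{max} = 10}) the
#' linear limit is \eqn{r(n) = -30n + 400}.
#'
#' @param b Contraction rate (dimensionless). `abs(b) < 1e-8` is treated as
#'   the linear case.
#' @param r_init Initial reinforcement-circle radius in pixels.
#' @param r_target Target-circle radius in pixels; the schedule contracts to
#'   this value after `n_max` reinforcements and stays there.
#' @param n_max Number of reinforcements needed to reach `r_target`.
#' @param label Optional concavity label; if supplied it must be consistent
#'   with the sign of `b`.
#' @return An object of class `shaping_spec`.
#' @examples
#' sp <- shaping_spec(b = -0.3)
#' shaping_radius(sp, 0:12)
#' @export
shaping_spec <- function(b, r_init = 400, r_target = 100, n_max = 10,
                         label = NULL) {
  stopifnot(is.numeric(b), length(b) == 1L, is.finite(b))
  if (!(r_init > r_target && r_target > 0)) {
    stop("shaping_spec requires r_init > r_target > 0", call. = FALSE)
  }
  if (!(is.numeric(n_max) && length(n_max) == 1L && n_max >= 1 &&
        n_max == trunc(n_max))) {
    stop("n_max must be an integer >= 1", call. = FALSE)
  }
  implied <- if (b < -B_LINEAR_EPS) "concave_up"
             else if (b > B_LINEAR_EPS) "concave_down"
             else "linear"
  if (!is.null(label)) {
    label <- match.arg(label, c("concave_up", "linear", "concave_down"))
    if (label != implied) {
      stop(sprintf("label '%s' inconsistent with b = %g (implies '%s')",
                   label, b, implied), call. = FALSE)
    }
  }
  structure(
    list(b = b, r_init = r_init, r_target = r_target,
         n_max = as.integer(n_max), label = implied),
    class = "shaping_spec"
  )
}

#' @export
print.shaping_spec <- function(x, ...) {
  cat(sprintf(
    "<shaping_spec> %s: b = %g, r %g -> %g px over %d reinforcements\n",
    x$label, x$b, x$r_init, x$r_target, x$n_max))
  invisible(x)
}

#' Reinforcement-circle radius after n reinforcements
#'
#' Evaluates the shaping schedule at reinforcement counts `n`. Counts above
#' `n_max` are clamped: once the window has contracted to the target radius
#' it is held constant for the remainder of the trial.
#'
#' @param spec A [shaping_spec()].
#' @param n Non-negative integer reinforcement count(s); vectorized.
#' @return Radius in pixels, same length as `n`, within
#'   `[r_target, r_init]` and non-increasing in `n`.
#' @examples
#' shaping_radius(shaping_spec(0.3), c(0, 5, 10, 15))
#' @export
shaping_radius <- function(spec, n) {
  stopifnot(inherits(spec, "shaping_spec"))
  if (!is.numeric(n) || any(!is.finite(n)) || any(n < 0) ||
      any(n != trunc(n))) {
    stop("n must be non-negative integer reinforcement counts", call. = FALSE)
  }
  n <- pmin(n, spec$n_max)
  drop_total <- spec$r_init - spec$r_target
  if (abs(spec$b) < B_LINEAR_EPS) {
    frac <- n / spec$n_max
  } else {
    frac <- (1 - exp(spec$b * n)) / (1 - exp(spec$b * spec$n_max))
  }
  r <- spec$r_init - drop_total * frac
  pmin(pmax(r, spec$r_target), spec$r_init)
}

#' Linear limiting schedule
#'
#' The closed form of the shaping schedule as the contraction rate tends to
#' zero: a straight line from `r_init` down to `r_target` in `n_max` equal
#' steps. With the default geometry this is `-30 * n + 400`.
#'
#' @param n Reinforcement count(s) in `[0, n_max]`.
#' @inheritParams shaping_spec
#' @return Radius in pixels.
#' @export
shaping_radius_linear <- function(n, r_init = 400, r_target = 100,
                                  n_max = 10) {
  if (!is.numeric(n) || any(!is.finite(n)) || any(n < 0) || any(n > n_max)) {
    stop("n must lie in [0, n_max]", call. = FALSE)
  }
  r_init - n * (r_init - r_target) / n_max
}

#' Classify the concavity of a shaping schedule
#'
#' Classifies via second finite differences of the radius over
#' `n = 0..n_max`: all positive is concave-up, all negative concave-down,
#' all within tolerance of zero linear. The result always agrees with the
#' sign of `b`.
#'
#' @param spec A [shaping_spec()].
#' @param tol Tolerance below which second differences count as zero.
#' @return One of `"concave_up"`, `"linear"`, `"concave_down"`.
#' @export
classify_concavity <- function(spec, tol = 1e-6) {
  stopifnot(inherits(spec, "shaping_spec"))
  r <- shaping_radius(spec, 0:spec$n_max)
  d2 <- diff(r, differences = 2)
  if (all(abs(d2) < tol)) "linear"
  else if (all(d2 > 0)) "concave_up"
  else if (all(d2 < 0)) "concave_down"
  else stop("mixed concavity: schedule is not in the shaping family",
            call. = FALSE)
}

#' The three experimental shaping arms
#'
#' Named presets for the three schedules used in the experiment:
#' concave-up (`b = -0.3`), linear (`b = 0`), and concave-down (`b = 0.3`),
#' all with the default 400 px to 100 px geometry over 10 reinforcements.
#'
#' @param r_init,r_target,n_max Geometry shared by the three arms.
#' @return A named list of three [shaping_spec()] objects.
#' @examples
#' shaping_presets()$concave_up
#' @export
shaping_presets <- function(r_init = 400, r_target = 100, n_max = 10) {
  list(
    concave_up   = shaping_spec(-0.3, r_init, r_target, n_max),
    linear       = shaping_spec(0,    r_init, r_target, n_max),
    concave_down = shaping_spec(0.3,  r_init, r_target, n_max)
  )
}

#' Tabulate shaping schedules for plotting
#'
#' @param specs A named list of [shaping_spec()] objects (default: the three
#'   experimental presets).
#' @return A tibble with columns `function_label`, `n`, `radius`.
#' @export
shaping_table <- function(specs = shaping_presets()) {
  purrr::imap_dfr(specs, function(sp, nm) {
    tibble::tibble(function_label = nm, n = 0:sp$n_max,
                   radius = shaping_radius(sp, 0:sp$n_max))
  })
}

#' Plot shaping schedules
#'
#' Radius of the reinforcement circle against the number of reinforcements
#' for each schedule.
#'
#' @inheritParams shaping_table
#' @return A ggplot object.
#' @export
plot_shaping_functions <- function(specs = shaping_presets()) {
  dat <- shaping_table(specs)
  ggplot2::ggplot(dat, ggplot2::aes(.data$n, .data$radius,
                                    colour = .data$function_label)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "Reinforcement count n", y = "Radius (px)",
                  colour = "Shaping function") +
    ggplot2::theme_minimal()
}
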