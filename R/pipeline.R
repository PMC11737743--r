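# simulate -> analyze -> report pipeline over a session configuration.

#' Simulate the default shaping experiment
#'
#' Builds the agent cohort and runs the full session described by a
#' configuration: `n_participants` synthetic participants, each completing
#' `trials_per_function` trials under each of the three shaping arms in a
#' per-participant shuffled order.
#'
#' @param config A [session_config()].
#' @param seed Optional master seed overriding `config$seed`.
#' @return A click-log tibble (see [run_session()]).
#' @examples
#' \donttest{
#' cfg <- session_config(trials = list(n_participants = 4,
#'                                     trials_per_function = 2))
#' log <- simulate_experiment(cfg, seed = 1)
#' }
#' @export
simulate_experiment <- function(config = session_config(), seed = NULL) {
  stopifnot(inherits(config, "session_config"))
  seed <- seed %||% config$seed
  if (is.null(seed)) stop("simulate requires a master seed", call. = FALSE)
  tr <- config$trials
  ag <- config$agent
  set.seed(seed)
  factory <- if (identical(ag$kind, "win_stay_shift")) {
    params <- ag[setdiff(names(ag), c("kind", "skill_sd"))]
    make_cohort(params, n_participants = tr$n_participants,
                skill_sd = ag$skill_sd %||% 0)
  } else {
    agent <- make_agent(ag$kind, ag[setdiff(names(ag), "kind")])
    function(i) agent
  }
  run_session(
    factory,
    n_participants = tr$n_participants,
    trials_per_function = tr$trials_per_function,
    specs = config_specs(config),
    screen_width = config$screen$width,
    screen_height = config$screen$height,
    max_clicks = tr$max_clicks,
    consec_stop = tr$consec_stop,
    seed = seed
  )
}

#' Analyze a click log
#'
#' Computes both outcome tables (AA per participant x function, total
#' clicks per trial), the smoothed trajectories behind the AA, and fits
#' both outcome models.
#'
#' @param click_log A click-log tibble from [simulate_experiment()] /
#'   [run_session()] / [read_click_log()].
#' @param config A [session_config()] supplying metric options.
#' @return A `shaping_analysis` list: `aa`, `clicks`, `trajectories`,
#'   `aa_fit`, `clicks_fit`.
#' @export
analyze_experiment <- function(click_log, config = session_config()) {
  m <- config$metrics
  tr <- trajectories(click_log, max_clicks = config$trials$max_clicks,
                     span = m$span, degree = m$degree, rule = m$rule)
  aa <- dplyr::select(tibble::as_tibble(tr), "participant_id",
                      "function_label", "aa")
  clicks <- clicks_table(click_log)
  structure(
    list(aa = aa, clicks = clicks, trajectories = tr,
         aa_fit = fit_aa_model(aa), clicks_fit = fit_clicks_model(clicks)),
    class = "shaping_analysis"
  )
}

#' Summary tables for an analysis
#'
#' Renders the descriptive table (mean/SD of both outcomes per shaping
#' function and pooled) and the model-comparison table (AA coefficients
#' with intervals alongside total-click IRRs with intervals, one row per
#' pairwise comparison).
#'
#' @param analysis A `shaping_analysis` from [analyze_experiment()].
#' @return A list with tibbles `descriptives` and `comparisons`, plus
#'   `variance_partition`.
#' @export
report_experiment <- function(analysis) {
  stopifnot(inherits(analysis, "shaping_analysis"))
  comp <- dplyr::full_join(
    dplyr::select(tidy(analysis$aa_fit), "comparison",
                  aa_coef = "estimate", aa_conf.low = "conf.low",
                  aa_conf.high = "conf.high"),
    dplyr::select(tidy(analysis$clicks_fit), "comparison", "irr",
                  irr_conf.low = "irr.conf.low",
                  irr_conf.high = "irr.conf.high"),
    by = "comparison"
  )
  list(
    descriptives = outcome_descriptives(analysis$aa, analysis$clicks),
    comparisons = comp,
    variance_partition = variance_partition(analysis$aa_fit)
  )
}

#' @export
print.shaping_analysis <- function(x, ...) {
  rep <- report_experiment(x)
  cat("Shaping experiment analysis\n\nDescriptives:\n")
  print(as.data.frame(rep$descriptives), digits = 4, row.names = FALSE)
  cat("\nComparisons (AA coefficient / total-clicks IRR, 95% Wald CI):\n")
  print(as.data.frame(rep$comparisons), digits = 3, row.names = FALSE)
  cat(sprintf("\nPoisson Pearson dispersion: %.2f (NB theta = %.2f)\n",
              x$clicks_fit$dispersion, x$clicks_fit$theta))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
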