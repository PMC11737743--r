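# Inference layer: random-intercept Gaussian mixed model for AA with a
# variance partition, and negative-binomial regression for total clicks
# with IRRs and an overdispersion diagnostic.

FUNCTION_LEVELS <- c("linear", "concave_down", "concave_up")

check_levels <- function(x, referent) {
  present <- unique(as.character(x))
  missing <- setdiff(FUNCTION_LEVELS, present)
  if (length(missing) > 0) {
    stop("missing shaping-function level(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!referent %in% present) {
    stop("referent level not present in data", call. = FALSE)
  }
  factor(as.character(x),
         levels = c(referent, setdiff(FUNCTION_LEVELS, referent)))
}

wald_ci <- function(estimate, se, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(low = estimate - z * se, high = estimate + z * se)
}

# Coefficient tibble (non-referent vs referent) plus the remaining pairwise
# contrast, via a contrast vector on the fixed-effect covariance matrix.
coef_and_contrasts <- function(beta, V, referent, exponentiate = FALSE) {
  terms <- names(beta)[-1]
  lvls <- sub("^function_label", "", terms)
  rows <- purrr::map2_dfr(terms, lvls, function(tm, lv) {
    ci <- wald_ci(beta[[tm]], sqrt(V[tm, tm]))
    tibble::tibble(comparison = paste(referent, "vs", lv),
                   term = lv, estimate = beta[[tm]],
                   std.error = sqrt(V[tm, tm]),
                   conf.low = ci$low, conf.high = ci$high)
  })
  if (length(terms) == 2) {
    # contrast: second non-referent level minus the first
    cvec <- stats::setNames(c(0, -1, 1), c("(Intercept)", terms))
    est <- sum(cvec * beta)
    se <- sqrt(drop(t(cvec) %*% V %*% cvec))
    ci <- wald_ci(est, se)
    rows <- dplyr::bind_rows(rows, tibble::tibble(
      comparison = paste(lvls[1], "vs", lvls[2]),
      term = paste0(lvls[2], "_vs_", lvls[1]),
      estimate = est, std.error = se, conf.low = ci$low, conf.high = ci$high
    ))
  }
  if (exponentiate) {
    rows <- dplyr::mutate(rows, irr = exp(.data$estimate),
                          irr.conf.low = exp(.data$conf.low),
                          irr.conf.high = exp(.data$conf.high))
  }
  rows
}

#' Fit the accumulation-area mixed model
#'
#' Regresses AA on the shaping function in a random-intercept Gaussian
#' mixed-effects model (REML), with participant as the random effect and
#' the linear arm as the referent level. Reports Wald (normal
#' approximation) 95% intervals for the fixed effects and the remaining
#' pairwise contrast between the two non-referent arms via a contrast
#' vector. A singular random-effects fit is flagged, not dropped.
#'
#' @param aa A tibble with columns `participant_id`, `function_label`,
#'   `aa`, as from [aa_table()].
#' @param referent Referent shaping-function level.
#' @return An object of class `aa_fit` with elements `model` (the `lmerMod`
#'   fit), `coefficients` (tibble of comparisons with intervals),
#'   `variance_components`, `referent` and `singular`.
#' @export
fit_aa_model <- function(aa, referent = "linear") {
  stopifnot(all(c("participant_id", "function_label", "aa") %in% names(aa)))
  if (dplyr::n_distinct(aa$participant_id) < 2) {
    stop("need at least 2 participants", call. = FALSE)
  }
  dat <- dplyr::mutate(
    aa, function_label = check_levels(.data$function_label, referent))
  model <- lme4::lmer(aa ~ function_label + (1 | participant_id),
                      data = dat, REML = TRUE)
  beta <- lme4::fixef(model)
  V <- as.matrix(stats::vcov(model))
  vc <- as.data.frame(lme4::VarCorr(model))
  var_between <- vc$vcov[vc$grp == "participant_id"]
  var_resid <- vc$vcov[vc$grp == "Residual"]
  var_fixed <- stats::var(as.numeric(stats::model.matrix(model) %*% beta))
  structure(
    list(model = model,
         coefficients = coef_and_contrasts(beta, V, referent),
         variance_components = c(between_participant = var_between,
                                 fixed_effects = var_fixed,
                                 residual = var_resid),
         referent = referent,
         singular = lme4::isSingular(model)),
    class = "aa_fit"
  )
}

#' Partition the variance of the AA model
#'
#' Two decompositions of the AA variance are reported side by side. The
#' classical variance partition coefficient (VPC) is the between-participant
#' intercept variance over (between + residual). The fixed-effect share
#' uses the variance of the fixed-effect (shaping function) predictor and
#' divides each component by the exhaustive total
#' (fixed + between + residual). A two-component reading that normalizes
#' between-participant and shaping-function variance over their own sum
#' (ignoring the residual, so the two shares add to 1) is also returned,
#' labelled as such.
#'
#' @param fit An `aa_fit` from [fit_aa_model()].
#' @return A tibble with one row per component (`between_participant`,
#'   `fixed_effects`, `residual`) and columns `variance`,
#'   `share_of_total`, plus attributes `vpc_classic` and
#'   `two_component_shares`.
#' @export
variance_partition <- function(fit) {
  stopifnot(inherits(fit, "aa_fit"))
  v <- fit$variance_components
  total <- sum(v)
  out <- tibble::tibble(
    component = names(v),
    variance = unname(v),
    share_of_total = unname(v) / total
  )
  attr(out, "vpc_classic") <-
    unname(v["between_participant"] / (v["between_participant"] +
                                         v["residual"]))
  two <- v[c("between_participant", "fixed_effects")]
  attr(out, "two_component_shares") <- two / sum(two)
  out
}

#' Fit the total-clicks count model
#'
#' Negative-binomial regression (log link) of per-trial total clicks on the
#' shaping function, referent linear, without a hierarchical structure.
#' Effect sizes are incidence rate ratios (IRR, the exponentiated
#' coefficients) with Wald 95% intervals, including the pairwise contrast
#' between the two non-referent arms. As an overdispersion diagnostic, the
#' matching Poisson model is also fitted and its Pearson dispersion (sum of
#' squared Pearson residuals over residual degrees of freedom) reported: a
#' value near 1 is consistent with equidispersion, a much larger value
#' indicates overdispersion and supports the negative-binomial choice.
#'
#' @param clicks A tibble with columns `participant_id`, `function_label`,
#'   `total_clicks`, as from [clicks_table()].
#' @param referent Referent shaping-function level.
#' @return An object of class `clicks_fit` with elements `model` (the
#'   `glm.nb` fit), `coefficients` (tibble with `estimate`, intervals and
#'   `irr` columns), `theta` (NB size), `dispersion` (Poisson Pearson
#'   dispersion) and `referent`.
#' @export
fit_clicks_model <- function(clicks, referent = "linear") {
  stopifnot(all(c("function_label", "total_clicks") %in% names(clicks)))
  y <- clicks$total_clicks
  if (any(!is.finite(y)) || any(y < 0) || any(y != trunc(y))) {
    stop("total_clicks must be non-negative integers", call. = FALSE)
  }
  dat <- dplyr::mutate(
    clicks, function_label = check_levels(.data$function_label, referent))
  model <- MASS::glm.nb(total_clicks ~ function_label, data = dat)
  pois <- stats::glm(total_clicks ~ function_label, data = dat,
                     family = stats::poisson())
  dispersion <- sum(stats::residuals(pois, type = "pearson")^2) /
    stats::df.residual(pois)
  beta <- stats::coef(model)
  V <- as.matrix(stats::vcov(model))
  structure(
    list(model = model,
         coefficients = coef_and_contrasts(beta, V, referent,
                                           exponentiate = TRUE),
         theta = model$theta,
         dispersion = dispersion,
         referent = referent),
    class = "clicks_fit"
  )
}

#' Residual diagnostics for a fitted outcome model
#'
#' Exports the material behind the usual visual normality checks: ordered
#' (theoretical, observed) normal quantile pairs and a kernel-density
#' summary of the residuals. Deviance residuals are used for the count
#' model, response residuals for the mixed model. A (near-)constant
#' residual vector is flagged as degenerate.
#'
#' @param fit An `aa_fit` or `clicks_fit`.
#' @return A list with `qq` (tibble `theoretical`, `observed`, one row per
#'   residual), `density` (tibble `x`, `density`) and `degenerate`.
#' @export
residual_diagnostics <- function(fit) {
  r <- if (inherits(fit, "aa_fit")) {
    stats::residuals(fit$model)
  } else if (inherits(fit, "clicks_fit")) {
    stats::residuals(fit$model, type = "deviance")
  } else {
    stop("fit must be an aa_fit or clicks_fit", call. = FALSE)
  }
  r <- as.numeric(r)
  n <- length(r)
  degenerate <- stats::sd(r) < 1e-12
  qq <- tibble::tibble(
    theoretical = stats::qnorm(stats::ppoints(n)),
    observed = sort(r)
  )
  dens <- if (degenerate) {
    tibble::tibble(x = numeric(0), density = numeric(0))
  } else {
    d <- stats::density(r)
    tibble::tibble(x = d$x, density = d$y)
  }
  list(qq = qq, density = dens, degenerate = degenerate)
}

#' @export
print.aa_fit <- function(x, ...) {
  cat("Accumulation-area mixed model (random intercept per participant)\n")
  cat(sprintf("referent: %s%s\n", x$referent,
              if (x$singular) "  [singular random-effects fit]" else ""))
  print(x$coefficients)
  invisible(x)
}

#' @export
print.clicks_fit <- function(x, ...) {
  cat("Total-clicks negative-binomial model\n")
  cat(sprintf("referent: %s; theta = %.2f; Poisson Pearson dispersion = %.2f\n",
              x$referent, x$theta, x$dispersion))
  print(x$coefficients)
  invisible(x)
}

#' @rdname tidy.aa_fit
#' @export
tidy.clicks_fit <- function(x, ...) x$coefficients

#' Tidy and glance methods for shaping model fits
#'
#' `tidy()` returns the comparison table (estimates, Wald intervals and,
#' for the count model, IRRs); `glance()` returns one-row model summaries.
#'
#' @param x An `aa_fit` or `clicks_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.aa_fit <- function(x, ...) x$coefficients

#' @rdname tidy.aa_fit
#' @export
glance.aa_fit <- function(x, ...) {
  vp <- variance_partition(x)
  tibble::tibble(
    nobs = stats::nobs(x$model),
    sigma = stats::sigma(x$model),
    var_between = x$variance_components[["between_participant"]],
    var_residual = x$variance_components[["residual"]],
    vpc_classic = attr(vp, "vpc_classic"),
    singular = x$singular
  )
}

#' @rdname tidy.aa_fit
#' @export
glance.clicks_fit <- function(x, ...) {
  tibble::tibble(
    nobs = stats::nobs(x$model),
    theta = x$theta,
    dispersion_poisson = x$dispersion,
    aic = stats::AIC(x$model)
  )
}

#' Q-Q plot of model residuals
#'
#' @param fit An `aa_fit` or `clicks_fit`.
#' @return A ggplot object.
#' @export
plot_residual_qq <- function(fit) {
  d <- residual_diagnostics(fit)
  ggplot2::ggplot(d$qq, ggplot2::aes(.data$theoretical, .data$observed)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.6) +
    ggplot2::geom_qq_line(ggplot2::aes(sample = .data$observed),
                          inherit.aes = FALSE) +
    ggplot2::labs(x = "Theoretical quantiles", y = "Observed residuals") +
    ggplot2::theme_minimal()
}

#' Descriptive statistics for the two outcomes
#'
#' Mean and standard deviation of AA (per participant x function) and total
#' clicks (per trial), by shaping function and pooled over all functions.
#'
#' @param aa An AA table from [aa_table()].
#' @param clicks A clicks table from [clicks_table()].
#' @return A tibble with one row per shaping function plus a pooled
#'   `all_functions` row.
#' @export
outcome_descriptives <- function(aa, clicks) {
  one <- function(df, col) {
    df |>
      dplyr::group_by(.data$function_label) |>
      dplyr::summarise(mean = mean(.data[[col]]), sd = stats::sd(.data[[col]]),
                       .groups = "drop") |>
      dplyr::bind_rows(tibble::tibble(
        function_label = "all_functions",
        mean = mean(df[[col]]), sd = stats::sd(df[[col]])))
  }
  dplyr::full_join(
    dplyr::rename(one(aa, "aa"), aa_mean = "mean", aa_sd = "sd"),
    dplyr::rename(one(clicks, "total_clicks"),
                  clicks_mean = "mean", clicks_sd = "sd"),
    by = "function_label"
  )
}
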