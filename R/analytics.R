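# Quantitative layer: growth rate and doubling time, four-parameter
# dose-response with IC50, sampling plans, normalization.

#' Growth rate and doubling time from a growth series
#'
#' Fits `ln(Nt) = ln(N0) + gr * t` by ordinary least squares over all
#' timepoints (with two points this reduces exactly to the closed form
#' `gr = ln(Nt/N0) / t`); the doubling time is `Td = ln(2) / gr`.
#'
#' @param series A [growth_series()] (timepoints in hours).
#' @return A `doubling_time_result`: `gr` (per day), `td_days`,
#'   `td_hours`, per-point log residuals, and a `flag` of
#'   `"non-positive-growth"` with infinite `td` when `gr <= 0`.
#' @export
doubling_time <- function(series) {
  stopifnot(inherits(series, "growth_series"))
  if (length(series$hours) < 2) stop("need at least 2 timepoints")
  if (any(series$values <= 0)) stop("values must be positive")
  t_days <- series$hours / 24
  fit <- stats::lm(log(series$values) ~ t_days)
  gr <- unname(stats::coef(fit)[2])
  flag <- NULL
  td <- if (gr > 0) log(2) / gr else { flag <- "non-positive-growth"; Inf }
  structure(list(gr = gr, td_days = td, td_hours = td * 24,
                 residuals = unname(stats::residuals(fit)), flag = flag),
            class = "doubling_time_result")
}

#' @export
print.doubling_time_result <- function(x, ...) {
  cat(sprintf("<doubling_time> gr %.4f /day, Td %.3g days (%.3g h)%s\n",
              x$gr, x$td_days, x$td_hours,
              if (is.null(x$flag)) "" else paste0(" [", x$flag, "]")))
  invisible(x)
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Nonlinear least squares (Levenberg-Marquardt, multi-start) of
#' [four_param_logistic()] on a dose-response table, GraphPad-style
#' log10-dose parameterization with `hill > 0` meaning viability
#' decreases with dose. The 95% CI of IC50 is asymptotic (from the
#' Jacobian, t-based on `log_ic50`). Zero doses are fitted at a log
#' offset of `min(nonzero dose) / 10` (configurable).
#'
#' @param table A `dose_response_table` (or data frame with `dose`,
#'   `response`).
#' @param zero_dose_offset Dose substituted for zero doses on the log
#'   axis; default smallest nonzero dose / 10.
#' @return A `dose_response_fit`: `top`, `bottom`, `log_ic50`,
#'   `hill_slope`, `ic50`, `ci_95`, `r_squared`, `converged`.
#' @export
fit_4pl <- function(table, zero_dose_offset = NULL) {
  stopifnot(all(c("dose", "response") %in% names(table)))
  if (length(unique(table$dose)) < 4)
    stop("need at least 4 distinct doses")
  d <- table$dose
  if (any(d == 0)) {
    if (is.null(zero_dose_offset)) zero_dose_offset <- min(d[d > 0]) / 10
    d[d == 0] <- zero_dose_offset
  }
  ld <- log10(d); y <- table$response
  model_fun <- function(top, bottom, log_ic50, hill)
    bottom + (top - bottom) / (1 + 10^((ld - log_ic50) * hill))
  one_fit <- function(li, hi) tryCatch(minpack.lm::nlsLM(
    y ~ bottom + (top - bottom) / (1 + 10^((ld - log_ic50) * hill)),
    start = list(top = max(y), bottom = min(y), log_ic50 = li, hill = hi),
    control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  # data-driven start first; fall back to a coarse multi-start grid
  best <- one_fit(stats::median(ld), 1)
  best_ss <- if (is.null(best)) Inf else sum(stats::residuals(best)^2)
  ss_tot0 <- sum((y - mean(y))^2)
  if (is.null(best) || best_ss > 0.05 * ss_tot0) {
    starts <- expand.grid(
      log_ic50 = stats::quantile(ld, c(0.25, 0.75), names = FALSE),
      hill = c(0.5, 2))
    for (i in seq_len(nrow(starts))) {
      fit <- one_fit(starts$log_ic50[i], starts$hill[i])
      if (!is.null(fit)) {
        ss <- sum(stats::residuals(fit)^2)
        if (ss < best_ss) { best <- fit; best_ss <- ss }
      }
    }
  }
  if (is.null(best))
    return(structure(list(converged = FALSE, flag = "non-convergence"),
                     class = "dose_response_fit"))
  cf <- stats::coef(best)
  se <- tryCatch(sqrt(diag(stats::vcov(best)))["log_ic50"],
                 error = function(e) NA_real_)
  tq <- stats::qt(0.975, df = length(y) - 4)
  ci <- if (is.na(se)) c(NA_real_, NA_real_)
        else 10^(cf["log_ic50"] + c(-1, 1) * tq * se)
  ss_tot <- sum((y - mean(y))^2)
  structure(list(
    top = unname(cf["top"]), bottom = unname(cf["bottom"]),
    log_ic50 = unname(cf["log_ic50"]), hill_slope = unname(cf["hill"]),
    ic50 = unname(10^cf["log_ic50"]), ci_95 = unname(ci),
    r_squared = if (ss_tot > 0) 1 - best_ss / ss_tot else 0,
    converged = TRUE, flag = NULL),
    class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  if (!x$converged) { cat("<dose_response_fit> did not converge\n")
                      return(invisible(x)) }
  cat(sprintf(
    "<dose_response_fit> IC50 %.4g [%.4g, %.4g], hill %.3g, top %.3g, bottom %.3g, R2 %.4f\n",
    x$ic50, x$ci_95[1], x$ci_95[2], x$hill_slope, x$top, x$bottom,
    x$r_squared))
  invisible(x)
}

#' Minimum sampling plan for a target confluency SD
#'
#' Estimates, by bootstrap resampling of observed per-field confluencies,
#' the smallest number of imaged fields whose mean has a standard
#' deviation below the target (default 5 percentage points), and reports
#' the corresponding fraction of the vessel area.
#'
#' @param field_values Per-field confluency percentages (>= 10 values).
#' @param vessel_area,field_area Areas in consistent units.
#' @param target_sd Target SD of the n-field mean, percentage points.
#' @param max_fields Largest n considered.
#' @param n_boot Bootstrap replicates.
#' @param seed RNG seed for the bootstrap.
#' @return A `sample_plan`: `n_fields`, `fraction_of_area`,
#'   `achieved_sd`, and a `flag` of `"unattainable"` when even
#'   `max_fields` misses the target.
#' @export
sample_plan <- function(field_values, vessel_area, field_area,
                        target_sd = 5, max_fields = 100, n_boot = 2000,
                        seed = 1L) {
  stopifnot(length(field_values) >= 10, target_sd > 0, vessel_area > 0,
            field_area > 0)
  set.seed(seed)
  achieved <- NA_real_; n_req <- NA_integer_; flag <- NULL
  for (n in seq_len(max_fields)) {
    if (stats::sd(field_values) == 0) { achieved <- 0; n_req <- n; break }
    means <- vapply(seq_len(n_boot), function(b)
      mean(sample(field_values, n, replace = TRUE)), 0)
    s <- stats::sd(means)
    if (s < target_sd) { achieved <- s; n_req <- n; break }
  }
  if (is.na(n_req)) {
    flag <- "unattainable"
    n_req <- max_fields
    achieved <- stats::sd(vapply(seq_len(n_boot), function(b)
      mean(sample(field_values, max_fields, replace = TRUE)), 0))
  }
  structure(list(n_fields = n_req,
                 fraction_of_area = n_req * field_area / vessel_area,
                 achieved_sd = achieved, target_sd = target_sd,
                 flag = flag),
            class = "sample_plan")
}

#' @export
print.sample_plan <- function(x, ...) {
  cat(sprintf(
    "<sample_plan> %d field(s) (%.2g%% of vessel area), SD of mean %.3g%s\n",
    x$n_fields, 100 * x$fraction_of_area, x$achieved_sd,
    if (is.null(x$flag)) "" else paste0(" [", x$flag, "]")))
  invisible(x)
}

#' Normalize readouts to their maximum
#'
#' `100 * value / max(values)`, the presentation used when comparing
#' assay readouts across methods.
#'
#' @param readouts Non-negative values with a positive maximum.
#' @return Percentages with maximum 100.
#' @export
normalize_to_max <- function(readouts) {
  if (!length(readouts)) stop("empty input")
  if (any(readouts < 0)) stop("readouts must be non-negative")
  m <- max(readouts)
  if (m <= 0) stop("all-zero input")
  100 * readouts / m
}
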