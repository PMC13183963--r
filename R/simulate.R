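#' Simulate an exponential growth series
#'
#' Generates `Nt = N0 * exp(gr * t)` at the given timepoints with optional
#' multiplicative lognormal noise of coefficient of variation `cv_noise`.
#' The noise is mean-one, so log-linear regression recovers `gr` without
#' bias.
#'
#' @param n0 Initial value (> 0): cell count or confluency percent.
#' @param gr Exponential growth rate per day.
#' @param hours Strictly increasing timepoints in hours.
#' @param cv_noise Coefficient of variation of the multiplicative noise.
#' @param seed Optional seed.
#' @return A `growth_series`: list with `hours`, `values`, `n0`.
#' @export
simulate_growth_series <- function(n0, gr, hours, cv_noise = 0,
                                   seed = NULL) {
  if (n0 <= 0) stop("n0 must be positive")
  stopifnot(all(diff(hours) > 0), cv_noise >= 0)
  if (!is.null(seed)) set.seed(seed)
  mu <- n0 * exp(gr * hours / 24)
  if (cv_noise > 0) {
    sdlog <- sqrt(log(1 + cv_noise^2))
    mu <- mu * exp(stats::rnorm(length(hours), -sdlog^2 / 2, sdlog))
  }
  growth_series(hours, mu, n0 = n0)
}

#' Construct a growth series
#' @param hours Timepoints in hours (strictly increasing).
#' @param values Positive cell counts or confluency percentages.
#' @param n0 Value at time 0; defaults to the first value if `hours[1]==0`.
#' @return A `growth_series` object.
#' @export
growth_series <- function(hours, values, n0 = NULL) {
  stopifnot(length(hours) == length(values), all(diff(hours) > 0),
            all(values > 0))
  if (is.null(n0)) n0 <- if (hours[1] == 0) values[1] else NA_real_
  structure(list(hours = as.numeric(hours), values = as.numeric(values),
                 n0 = n0), class = "growth_series")
}

#' Four-parameter logistic (dose-response) curve
#'
#' `response(d) = bottom + (top - bottom) / (1 + 10^((log10 d - log10 ic50)
#' * hill))`, the GraphPad-style parameterization on log10 dose; `hill > 0`
#' means the response (viability) decreases with dose. At `d = ic50` the
#' response is exactly `(top + bottom) / 2`; `d = 0` returns `top`.
#'
#' @param dose Non-negative doses.
#' @param top,bottom Upper and lower asymptotes (`top > bottom`).
#' @param ic50 Half-maximal dose (> 0).
#' @param hill Hill slope.
#' @return Responses at `dose`.
#' @export
four_param_logistic <- function(dose, top, bottom, ic50, hill) {
  stopifnot(top > bottom, ic50 > 0, all(dose >= 0))
  r <- ifelse(dose == 0, top,
              bottom + (top - bottom) /
                (1 + 10^((log10(pmax(dose, .Machine$double.xmin)) -
                            log10(ic50)) * hill)))
  as.numeric(r)
}

#' Simulate a dose-response table
#'
#' Inverts the four-parameter logistic model with additive Gaussian noise,
#' emulating normalized-viability readouts of a drug titration.
#'
#' @param top,bottom,ic50,hill 4PL parameters (see
#'   [four_param_logistic()]).
#' @param doses Non-negative doses (at least 4 distinct values for a
#'   subsequent fit).
#' @param sd Additive Gaussian noise SD on the response scale.
#' @param replicates Replicates per dose.
#' @param seed Optional seed.
#' @return A `dose_response_table` data frame with columns `dose`,
#'   `response`, `replicate`.
#' @export
simulate_dose_response <- function(top, bottom, ic50, hill, doses, sd = 0,
                                   replicates = 1, seed = NULL) {
  if (top <= bottom) stop("top must exceed bottom")
  if (!is.null(seed)) set.seed(seed)
  tab <- expand.grid(replicate = seq_len(replicates), dose = doses)
  tab <- tab[, c("dose", "replicate")]
  tab$response <- four_param_logistic(tab$dose, top, bottom, ic50, hill) +
    stats::rnorm(nrow(tab), 0, sd)
  class(tab) <- c("dose_response_table", class(tab))
  tab
}

#' Simulate a hemocytometer dilution series
#'
#' For each dilution factor, per-field object counts are drawn Poisson
#' with mean `conc / dilution_factor x square volume`, and chamber scenes
#' are rendered with objects placed uniformly in the counted square. This
#' emulates loading serially diluted samples on a counting chamber.
#'
#' @param stock_conc Stock concentration in cells/mL.
#' @param factors Positive dilution factors; sample i has expected
#'   concentration `stock_conc / factors[i]`.
#' @param chamber A [chamber_geometry()] describing the counted square.
#' @param fields_per_sample Number of fields (squares) imaged per sample.
#' @param microns_per_px Pixel pitch used to render the fields.
#' @param object_mix Object mix for the rendered scenes (default cells).
#' @param margin_px Margin around the counted square in the rendered image.
#' @param seed Integer seed.
#' @return List with `samples` (each holding `expected_conc`, `lambda`,
#'   `roi`, and the rendered `fields`) and a `summary` data frame.
#' @export
simulate_dilution_series <- function(stock_conc, factors, chamber,
                                     fields_per_sample = 4,
                                     microns_per_px = 2,
                                     object_mix = default_object_mix(),
                                     margin_px = 10, seed = 1L) {
  stopifnot(all(factors > 0), stock_conc >= 0,
            inherits(chamber, "chamber_geometry"))
  side_px <- round(chamber$square_side_mm * 1000 / microns_per_px)
  size <- side_px + 2 * margin_px
  roi <- c(margin_px, margin_px, margin_px + side_px, margin_px + side_px)
  samples <- vector("list", length(factors))
  set.seed(seed)
  field_seeds <- sample.int(2^31 - 2, length(factors) * fields_per_sample)
  q <- 0L
  for (s in seq_along(factors)) {
    conc <- stock_conc / factors[s]
    lambda <- conc / chamber$dilution_factor * square_volume_ml(chamber)
    fields <- vector("list", fields_per_sample)
    for (f in seq_len(fields_per_sample)) {
      q <- q + 1L
      set.seed(field_seeds[q])
      n <- stats::rpois(1, lambda)
      sp <- scene_spec("chamber", width_px = size, height_px = size,
                       microns_per_px = microns_per_px, n_objects = n,
                       object_mix = object_mix, grid = chamber,
                       seed = field_seeds[q])
      sp$placement_rect <- roi
      fields[[f]] <- render_chamber_scene(sp)
    }
    samples[[s]] <- list(expected_conc = conc, lambda = lambda, roi = roi,
                         fields = fields)
  }
  summary <- data.frame(
    factor = factors, expected_conc = stock_conc / factors,
    lambda = vapply(samples, function(s) s$lambda, 0),
    mean_true_count = vapply(samples, function(s)
      mean(vapply(s$fields, function(fl) nrow(fl$objects), 0)), 0))
  list(samples = samples, summary = summary, chamber = chamber)
}
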