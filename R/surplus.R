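#' Adoption path for a technology
#'
#' Yearly adopted share of the crop's acreage over the evaluation horizon.
#' Adoption is zero until the technology is released (`release_lag` years
#' after research starts), ramps linearly to the ceiling `max_adoption`
#' over `years_to_max` years, and stays at the ceiling thereafter. The
#' linear ramp is the default shape; a logistic alternative with the same
#' endpoints is available.
#'
#' @param profile A [technology_profile()].
#' @param horizon Length of the path in years (default 25). Must cover the
#'   ramp, i.e. `horizon >= release_lag + years_to_max`.
#' @param shape `"linear"` (default) or `"logistic"`. The logistic curve is
#'   scaled so adoption is ~0 at release and reaches the ceiling at
#'   `release_lag + years_to_max`, then plateaus.
#'
#' @return Numeric vector of length `horizon` with yearly adoption shares
#'   for years t = 1..horizon.
#' @export
#' @examples
#' build_adoption_path(cowpea_exemplar())[c(5, 10, 25)]
build_adoption_path <- function(profile, horizon = 25L,
                                shape = c("linear", "logistic")) {
  shape <- match.arg(shape)
  validate_technology_profile(profile)
  horizon <- as.integer(horizon)
  ramp_end <- profile$release_lag + profile$years_to_max
  if (horizon < ramp_end)
    stop("horizon (", horizon, ") is shorter than release_lag + years_to_max (",
         ramp_end, ")", call. = FALSE)
  t <- seq_len(horizon)
  since_release <- pmax(t - profile$release_lag, 0)
  frac <- pmin(since_release / profile$years_to_max, 1)
  if (shape == "logistic") {
    # logistic in the ramp fraction, rescaled to hit exactly 0 and 1 at the
    # ramp endpoints so the ceiling and plateau are preserved
    k <- 10
    raw <- stats::plogis(k * (frac - 0.5))
    lo <- stats::plogis(-k / 2); hi <- stats::plogis(k / 2)
    frac <- (raw - lo) / (hi - lo)
    frac[since_release >= profile$years_to_max] <- 1
    frac[since_release <= 0] <- 0
  }
  path <- profile$max_adoption * frac
  validate_adoption_path(path, profile)
}

validate_adoption_path <- function(path, profile = NULL) {
  if (any(is.na(path)) || any(path < 0))
    stop("adoption path must be non-negative", call. = FALSE)
  if (any(diff(path) < -1e-12))
    stop("adoption path must be non-decreasing", call. = FALSE)
  if (!is.null(profile)) {
    if (any(path > profile$max_adoption + 1e-12))
      stop("adoption path exceeds max_adoption", call. = FALSE)
    if (profile$release_lag > 0 &&
        any(path[seq_len(profile$release_lag)] > 0))
      stop("adoption must be zero before release", call. = FALSE)
  }
  path
}

#' Per-unit supply-shift (K-shift) for one year
#'
#' The proportional vertical shift of the supply curve induced by the
#' technology: the yield gain expressed in price units through the supply
#' elasticity, net of the per-unit cost change, scaled by the probability
#' of research success and the adoption share, and clamped at zero (a
#' technology cannot shift supply the "wrong" way in this model).
#'
#' @param yield_gain,cost_change,prob_success As in [technology_profile()].
#' @param supply_elasticity Own-price supply elasticity (> 0).
#' @param adoption Adoption share (scalar or vector).
#' @return Non-negative K-shift, same length as `adoption`.
#' @keywords internal
k_shift <- function(yield_gain, cost_change, prob_success,
                    supply_elasticity, adoption) {
  k <- (yield_gain / supply_elasticity - cost_change / (1 + yield_gain)) *
    prob_success * adoption
  pmax(k, 0)
}

#' Yearly economic-surplus stream
#'
#' Change in total economic surplus (producer + consumer) from adopting a
#' technology, under a closed-economy partial-equilibrium market with
#' linear supply and demand and a parallel supply shift. For each year and
#' country the K-shift is evaluated at that year's adoption and the surplus
#' change is
#' \deqn{\Delta ES_t = \sum_n K_{t,n} P_{0n} Q_{0n} (1 + 0.5\, K_{t,n} Z_n),}
#' with \eqn{Z_n = \epsilon_n / (\epsilon_n + \eta_n)} the share of the
#' shift borne by price, \eqn{\epsilon} the supply elasticity and
#' \eqn{\eta} the (absolute) demand elasticity.
#'
#' @param profile A [technology_profile()].
#' @param macro An [environment_macro()].
#' @param path Adoption path from [build_adoption_path()].
#'
#' @return Numeric vector: total surplus change in USD per year, length
#'   equal to `length(path)`.
#' @export
surplus_stream <- function(profile, macro, path) {
  validate_technology_profile(profile)
  stopifnot(inherits(macro, "environment_macro"))
  validate_adoption_path(path)
  streams <- vapply(macro$countries, function(b) {
    k <- k_shift(profile$yield_gain, profile$cost_change,
                 profile$prob_success, b$supply_elasticity, path)
    z <- b$supply_elasticity / (b$supply_elasticity + b$demand_elasticity)
    k * b$price * b$production * (1 + 0.5 * k * z)
  }, numeric(length(path)))
  if (length(path) == 1L) sum(streams) else rowSums(streams)
}

#' Per-country surplus at one year
#'
#' @keywords internal
surplus_at_year_by_country <- function(profile, macro, path, year) {
  vapply(macro$countries, function(b) {
    k <- k_shift(profile$yield_gain, profile$cost_change,
                 profile$prob_success, b$supply_elasticity, path[year])
    z <- b$supply_elasticity / (b$supply_elasticity + b$demand_elasticity)
    k * b$price * b$production * (1 + 0.5 * k * z)
  }, numeric(1))
}

#' Yearly research and dissemination cost stream
#'
#' Research costs accrue at `research_cost_per_year` for the first
#' `research_years` years; dissemination costs accrue every year as
#' `dissemination_cost_per_ha` times the adopted area (adoption share times
#' total crop area across the environment's countries).
#'
#' @inheritParams surplus_stream
#' @return Numeric vector of USD costs per year.
#' @export
cost_stream <- function(profile, macro, path) {
  validate_technology_profile(profile)
  total_area <- sum(vapply(macro$countries, `[[`, numeric(1), "area"))
  t <- seq_along(path)
  research <- ifelse(t <= profile$research_years,
                     profile$research_cost_per_year, 0)
  dissemination <- profile$dissemination_cost_per_ha * path * total_area
  research + dissemination
}

#' Discounted benefit-cost ratio
#'
#' Ratio of the present value of the surplus stream to the present value of
#' the research-and-dissemination cost stream, discounting years t = 1..T
#' at rate `r`:
#' \deqn{BCR = \frac{\sum_t \Delta ES_t (1+r)^{-t}}{\sum_t C_t (1+r)^{-t}}.}
#'
#' @param surplus_by_year USD surplus stream.
#' @param costs_by_year USD cost stream, same length.
#' @param r Discount rate as a fraction (default 0.10).
#'
#' @return A single non-negative number; values above 1 mean discounted
#'   benefits exceed discounted costs.
#' @export
#' @examples
#' compute_bcr(c(0, 121), c(110, 0), r = 0.10)  # exactly 1
compute_bcr <- function(surplus_by_year, costs_by_year, r = 0.10) {
  if (length(surplus_by_year) != length(costs_by_year))
    stop("surplus and cost streams must have equal length", call. = FALSE)
  if (any(costs_by_year < 0))
    stop("costs must be >= 0", call. = FALSE)
  t <- seq_along(costs_by_year)
  disc <- (1 + r)^(-t)
  pv_cost <- sum(costs_by_year * disc)
  if (pv_cost <= 0)
    stop("discounted costs are zero; the benefit-cost ratio is undefined",
         call. = FALSE)
  sum(surplus_by_year * disc) / pv_cost
}

#' Poverty change from a surplus gain
#'
#' Change in the number of poor people at the year the technology reaches
#' maximum adoption: the surplus gain as a share of agricultural GDP,
#' multiplied by the poverty elasticity of agricultural productivity and
#' the baseline poor count,
#' \deqn{\Delta P = \frac{\Delta ES_T}{AgGDP} \cdot
#'       \frac{\Delta P/P}{\Delta Y/Y} \cdot P.}
#' The share and the elasticity are both per-unit quantities, so the
#' product is identical whether the share is expressed in percent with a
#' per-percent elasticity or as a plain fraction. Negative results mean
#' poverty is reduced.
#'
#' @param total_surplus_at_T Surplus gain in the evaluation year, USD.
#' @param ag_gdp Agricultural value added, USD (> 0).
#' @param poverty_elasticity Poverty elasticity (usually negative).
#' @param poor_count Baseline number of poor people.
#'
#' @return Change in the number of poor people (persons).
#' @export
compute_poverty_change <- function(total_surplus_at_T, ag_gdp,
                                   poverty_elasticity, poor_count) {
  if (is.na(ag_gdp) || ag_gdp <= 0)
    stop("ag_gdp must be > 0", call. = FALSE)
  if (poor_count < 0)
    stop("poor_count must be >= 0", call. = FALSE)
  (total_surplus_at_T / ag_gdp) * poverty_elasticity * poor_count
}

#' Full surplus outcome for one technology
#'
#' Convenience wrapper producing the surplus stream, cost stream, BCR and
#' environment-level poverty change (summed over per-country changes, each
#' country evaluated with its own surplus, agricultural GDP, elasticity and
#' poor count) at the evaluation year T = release_lag + years_to_max.
#'
#' @inheritParams surplus_stream
#' @param horizon Evaluation horizon in years (default 25).
#' @param r Discount rate (default 0.10).
#' @param shape Adoption-curve shape passed to [build_adoption_path()].
#'
#' @return An object of class `"surplus_outcome"`: a list with
#'   `surplus_by_year`, `costs_by_year`, `bcr`, `discount_rate`,
#'   `poverty_change`, `eval_year` and `adoption_path`.
#' @export
#' @examples
#' macro <- environment_macro("toy", country_baseline(
#'   "A", production = 1e5, area = 2e5, price = 400,
#'   supply_elasticity = 0.9, demand_elasticity = 0.7,
#'   ag_gdp = 2e9, poor_count = 3e6, poverty_elasticity = -0.8))
#' surplus_outcome(cowpea_exemplar(), macro)
surplus_outcome <- function(profile, macro, horizon = 25L, r = 0.10,
                            shape = "linear") {
  path <- build_adoption_path(profile, horizon, shape)
  s <- surplus_stream(profile, macro, path)
  costs <- cost_stream(profile, macro, path)
  eval_year <- profile$release_lag + profile$years_to_max
  by_country <- surplus_at_year_by_country(profile, macro, path, eval_year)
  dp <- sum(mapply(function(es, b) {
    compute_poverty_change(es, b$ag_gdp, b$poverty_elasticity, b$poor_count)
  }, by_country, macro$countries))
  out <- list(
    tech_id = profile$tech_id,
    surplus_by_year = s,
    costs_by_year = costs,
    bcr = compute_bcr(s, costs, r),
    discount_rate = r,
    poverty_change = dp,
    eval_year = eval_year,
    adoption_path = path
  )
  class(out) <- "surplus_outcome"
  out
}

#' @export
print.surplus_outcome <- function(x, ...) {
  cat("Surplus outcome for", x$tech_id, "\n")
  cat(sprintf("  BCR (r = %.0f%%): %.2f\n", 100 * x$discount_rate, x$bcr))
  cat(sprintf("  poverty change at year %d: %s persons\n", x$eval_year,
              format(round(x$poverty_change), big.mark = ",")))
  cat(sprintf("  PV surplus: US$%s; PV costs: US$%s over %d years\n",
              format(signif(sum(x$surplus_by_year /
                                  (1 + x$discount_rate)^seq_along(x$surplus_by_year)), 4),
                     big.mark = ",", scientific = FALSE),
              format(signif(sum(x$costs_by_year /
                                  (1 + x$discount_rate)^seq_along(x$costs_by_year)), 4),
                     big.mark = ",", scientific = FALSE),
              length(x$surplus_by_year)))
  invisible(x)
}
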