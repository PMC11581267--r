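#' Technology profile
#'
#' Bundle the research, agronomic, cost and adoption parameters of one
#' candidate technology, as elicited for a target crop and environment.
#'
#' @param tech_id Character identifier, unique within a study.
#' @param crop Target crop label.
#' @param environment Target environment label (e.g. a dryland class).
#' @param yield_gain Proportional yield gain on adopting plots (0.70 = +70%).
#'   Must exceed -1.
#' @param cost_change Proportional change in per-hectare production cost;
#'   negative values are savings (-0.10 = a 10% cost reduction).
#' @param prob_success Probability that the research succeeds, in [0, 1].
#' @param max_adoption Ceiling share of the crop's acreage under the
#'   technology, in [0, 1].
#' @param years_to_max Years after release needed to reach `max_adoption`
#'   (integer >= 1).
#' @param release_lag Years from the start of research to release
#'   (integer >= 0).
#' @param research_cost_per_year Research cost, USD per year.
#' @param research_years Number of years the research cost is incurred.
#' @param dissemination_cost_per_ha Dissemination cost, USD per adopted
#'   hectare per year.
#'
#' @return An object of class `"technology_profile"`.
#' @export
#' @examples
#' cowpea_exemplar()
technology_profile <- function(tech_id, crop, environment,
                               yield_gain, cost_change, prob_success,
                               max_adoption, years_to_max,
                               release_lag = 0L,
                               research_cost_per_year = 0,
                               research_years = 0L,
                               dissemination_cost_per_ha = 0) {
  p <- list(
    tech_id = as.character(tech_id),
    crop = as.character(crop),
    environment = as.character(environment),
    yield_gain = as.numeric(yield_gain),
    cost_change = as.numeric(cost_change),
    prob_success = as.numeric(prob_success),
    max_adoption = as.numeric(max_adoption),
    years_to_max = as.integer(years_to_max),
    release_lag = as.integer(release_lag),
    research_cost_per_year = as.numeric(research_cost_per_year),
    research_years = as.integer(research_years),
    dissemination_cost_per_ha = as.numeric(dissemination_cost_per_ha)
  )
  class(p) <- "technology_profile"
  validate_technology_profile(p)
}

validate_technology_profile <- function(p) {
  stopifnot(inherits(p, "technology_profile"))
  if (is.na(p$yield_gain) || p$yield_gain <= -1)
    stop("yield_gain must be > -1 (got ", p$yield_gain, ")", call. = FALSE)
  if (p$prob_success < 0 || p$prob_success > 1)
    stop("prob_success must lie in [0, 1] (got ", p$prob_success, ")",
         call. = FALSE)
  if (p$max_adoption < 0 || p$max_adoption > 1)
    stop("max_adoption must lie in [0, 1] (got ", p$max_adoption, ")",
         call. = FALSE)
  if (p$years_to_max < 1)
    stop("years_to_max must be >= 1 (got ", p$years_to_max, ")",
         call. = FALSE)
  if (p$release_lag < 0)
    stop("release_lag must be >= 0", call. = FALSE)
  costs <- c(p$research_cost_per_year, p$dissemination_cost_per_ha)
  if (any(costs < 0))
    stop("costs must be >= 0", call. = FALSE)
  if (p$research_years < 0)
    stop("research_years must be >= 0", call. = FALSE)
  p
}

#' @export
print.technology_profile <- function(x, ...) {
  cat("Technology profile:", x$tech_id, "\n")
  cat("  crop/environment:", x$crop, "/", x$environment, "\n")
  cat(sprintf("  yield gain %+.0f%%, cost change %+.0f%%, P(success) %.2f\n",
              100 * x$yield_gain, 100 * x$cost_change, x$prob_success))
  cat(sprintf("  adoption ceiling %.0f%% reached %d yr after release (lag %d)\n",
              100 * x$max_adoption, x$years_to_max, x$release_lag))
  cat(sprintf("  research US$%s/yr x %d yr; dissemination US$%s/ha\n",
              format(x$research_cost_per_year, big.mark = ","),
              x$research_years,
              format(x$dissemination_cost_per_ha, big.mark = ",")))
  invisible(x)
}

#' The printed drought-tolerant cowpea exemplar
#'
#' The one technology whose full parameter set is published: improved
#' drought-tolerant cowpea with integrated crop management for semi-arid
#' West and Central Africa. Maximum adoption 40% of cowpea acreage within
#' 10 years of release, +70% yield with an 80% chance of success, a 10%
#' per-hectare cost reduction, research at US$300,000/yr for 10 years and
#' dissemination at US$50/ha.
#'
#' @return A [technology_profile()].
#' @export
cowpea_exemplar <- function() {
  technology_profile(
    tech_id = "cowpea_dt_icm",
    crop = "cowpea",
    environment = "semi-arid West and Central Africa",
    yield_gain = 0.70,
    cost_change = -0.10,
    prob_success = 0.80,
    max_adoption = 0.40,
    years_to_max = 10L,
    release_lag = 0L,
    research_cost_per_year = 300000,
    research_years = 10L,
    dissemination_cost_per_ha = 50
  )
}

#' Country baseline for the surplus model
#'
#' @param country Country label.
#' @param production Baseline production of the target crop, tonnes/yr.
#' @param area Harvested area, hectares.
#' @param price Producer price, USD/tonne.
#' @param supply_elasticity Own-price supply elasticity (> 0).
#' @param demand_elasticity Own-price demand elasticity, absolute value (> 0).
#' @param ag_gdp Agricultural value added at the baseline year, USD.
#' @param poor_count Number of poor people at the baseline year.
#' @param poverty_elasticity Percent change in the poverty headcount per
#'   percent change in agricultural productivity; usually negative.
#'
#' @return An object of class `"country_baseline"`.
#' @export
country_baseline <- function(country, production, area, price,
                             supply_elasticity, demand_elasticity,
                             ag_gdp, poor_count, poverty_elasticity) {
  b <- list(
    country = as.character(country),
    production = as.numeric(production),
    area = as.numeric(area),
    price = as.numeric(price),
    supply_elasticity = as.numeric(supply_elasticity),
    demand_elasticity = as.numeric(demand_elasticity),
    ag_gdp = as.numeric(ag_gdp),
    poor_count = as.numeric(poor_count),
    poverty_elasticity = as.numeric(poverty_elasticity)
  )
  class(b) <- "country_baseline"
  validate_country_baseline(b)
}

validate_country_baseline <- function(b) {
  stopifnot(inherits(b, "country_baseline"))
  nonneg <- c(production = b$production, area = b$area, price = b$price,
              ag_gdp = b$ag_gdp, poor_count = b$poor_count)
  bad <- names(nonneg)[nonneg < 0 | is.na(nonneg)]
  if (length(bad))
    stop("country baseline '", b$country, "': ",
         paste(bad, collapse = ", "), " must be >= 0", call. = FALSE)
  if (is.na(b$supply_elasticity) || b$supply_elasticity <= 0 ||
      is.na(b$demand_elasticity) || b$demand_elasticity <= 0)
    stop("country baseline '", b$country,
         "': elasticities must be > 0", call. = FALSE)
  b
}

#' Environment macro table
#'
#' Group the country baselines that make up one target environment.
#'
#' @param environment Environment label.
#' @param countries A list of [country_baseline()] objects (at least one).
#'
#' @return An object of class `"environment_macro"`.
#' @export
environment_macro <- function(environment, countries) {
  if (inherits(countries, "country_baseline")) countries <- list(countries)
  if (!length(countries))
    stop("an environment needs at least one country baseline", call. = FALSE)
  lapply(countries, validate_country_baseline)
  m <- list(environment = as.character(environment), countries = countries)
  class(m) <- "environment_macro"
  m
}

#' @export
print.environment_macro <- function(x, ...) {
  cat("Environment macro table:", x$environment, "\n")
  cat(" ", length(x$countries), "country baseline(s):",
      paste(vapply(x$countries, `[[`, "", "country"), collapse = ", "), "\n")
  invisible(x)
}
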