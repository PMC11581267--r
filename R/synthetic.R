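#' Default sampling bounds for synthetic studies
#'
#' Expert-elicitation-style bounds for technology and country parameters.
#' The defaults bracket the one published exemplar technology (yield gain
#' 70%, cost change -10%, success probability 80%, adoption ceiling 40% in
#' 10 years, US$300k/yr research for 10 years, US$50/ha dissemination) and
#' typical dryland staple-crop market magnitudes.
#'
#' @return Named list of `c(low, high)` bounds per parameter.
#' @export
default_ranges <- function() {
  list(
    yield_gain = c(0.10, 0.80),
    cost_change = c(-0.20, 0.10),
    prob_success = c(0.50, 0.95),
    max_adoption = c(0.10, 0.60),
    years_to_max = c(5, 15),
    release_lag = c(0, 5),
    research_cost_per_year = c(1e5, 5e5),
    research_years = c(5, 12),
    dissemination_cost_per_ha = c(10, 100),
    production = c(5e4, 2e6),
    area = c(1e5, 3e6),
    price = c(150, 800),
    supply_elasticity = c(0.3, 1.5),
    demand_elasticity = c(0.3, 1.5),
    ag_gdp = c(5e8, 2e10),
    poor_count = c(5e5, 2e7),
    poverty_elasticity = c(-1.2, -0.3)
  )
}

#' Configuration of the synthetic-study generator
#'
#' @param seed Integer RNG seed; everything the generator emits is a
#'   deterministic function of it (base R Mersenne-Twister).
#' @param n_technologies Number of technologies to draw.
#' @param n_countries Number of countries in the environment.
#' @param environment Environment label.
#' @param ranges Per-parameter `c(low, high)` bounds; defaults from
#'   [default_ranges()], overridable per entry.
#' @param nutrition_baseline Levels for the constant-covariate nutrition
#'   baseline: `pmc0` (percent malnourished), `popc` (under-5 population),
#'   `population` (total population), `pckcal`, `lfexp_ratio`, `schl`,
#'   `water`.
#' @param include_exemplar If TRUE, the first technology is the published
#'   drought-tolerant cowpea exemplar rather than a random draw.
#'
#' @return An object of class `"generator_config"`.
#' @export
generator_config <- function(seed = 1L, n_technologies = 12L,
                             n_countries = 3L,
                             environment = "semi-arid synthetic drylands",
                             ranges = list(),
                             nutrition_baseline = list(),
                             include_exemplar = FALSE) {
  rg <- utils::modifyList(default_ranges(), ranges)
  for (nm in names(rg)) {
    b <- rg[[nm]]
    if (length(b) != 2L || any(is.na(b)) || b[1] > b[2])
      stop("invalid range for '", nm, "': need low <= high", call. = FALSE)
  }
  if (rg$prob_success[1] < 0 || rg$prob_success[2] > 1)
    stop("prob_success bounds must lie in [0, 1]", call. = FALSE)
  if (rg$max_adoption[1] < 0 || rg$max_adoption[2] > 1)
    stop("max_adoption bounds must lie in [0, 1]", call. = FALSE)
  if (rg$years_to_max[1] < 1)
    stop("years_to_max bounds must be >= 1", call. = FALSE)
  if (rg$supply_elasticity[1] <= 0 || rg$demand_elasticity[1] <= 0)
    stop("elasticity bounds must be > 0", call. = FALSE)
  nb <- utils::modifyList(
    list(pmc0 = 25, popc = 5e6, population = 3e7, pckcal = 2300,
         lfexp_ratio = 1.05, schl = 35, water = 0.6),
    nutrition_baseline)
  structure(list(seed = as.integer(seed),
                 n_technologies = as.integer(n_technologies),
                 n_countries = as.integer(n_countries),
                 environment = as.character(environment),
                 ranges = rg, nutrition_baseline = nb,
                 include_exemplar = isTRUE(include_exemplar)),
            class = "generator_config")
}

runif_range <- function(n, bounds) stats::runif(n, bounds[1], bounds[2])
rint_range <- function(n, bounds) {
  as.integer(round(stats::runif(n, bounds[1], bounds[2])))
}

#' Draw synthetic technology profiles
#'
#' Samples `n_technologies` profiles uniformly within the configured
#' bounds; deterministic given the seed. When `include_exemplar` is set,
#' the first profile is the published cowpea exemplar.
#'
#' @param cfg A [generator_config()].
#' @return List of [technology_profile()] objects.
#' @export
generate_technologies <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  rg <- cfg$ranges
  crops <- c("sorghum", "pearl millet", "finger millet", "groundnut",
             "cowpea", "chickpea", "lentil", "pigeon pea", "soybean")
  withr_seed(cfg$seed, {
    n <- cfg$n_technologies
    profs <- vector("list", n)
    for (i in seq_len(n)) {
      profs[[i]] <- technology_profile(
        tech_id = sprintf("tech_%02d", i),
        crop = sample(crops, 1),
        environment = cfg$environment,
        yield_gain = runif_range(1, rg$yield_gain),
        cost_change = runif_range(1, rg$cost_change),
        prob_success = runif_range(1, rg$prob_success),
        max_adoption = runif_range(1, rg$max_adoption),
        years_to_max = rint_range(1, rg$years_to_max),
        release_lag = rint_range(1, rg$release_lag),
        research_cost_per_year = runif_range(1, rg$research_cost_per_year),
        research_years = rint_range(1, rg$research_years),
        dissemination_cost_per_ha = runif_range(1, rg$dissemination_cost_per_ha)
      )
    }
    if (cfg$include_exemplar && n >= 1L) {
      ex <- cowpea_exemplar()
      ex$tech_id <- "tech_01"
      ex$environment <- cfg$environment
      profs[[1]] <- ex
    }
    profs
  })
}

# evaluate expr under a temporary RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(list = ".Random.seed", envir = globalenv()))
  }
  set.seed(seed, kind = "Mersenne-Twister")
  expr
}

#' Draw a synthetic environment macro table
#'
#' @param cfg A [generator_config()].
#' @return An [environment_macro()] with `n_countries` baselines drawn
#'   uniformly within bounds; deterministic given the seed (offset from the
#'   technology stream so the two tables are independently reproducible).
#' @export
generate_macro <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  rg <- cfg$ranges
  withr_seed(cfg$seed + 1000L, {
    countries <- lapply(seq_len(cfg$n_countries), function(i) {
      country_baseline(
        country = sprintf("country_%02d", i),
        production = runif_range(1, rg$production),
        area = runif_range(1, rg$area),
        price = runif_range(1, rg$price),
        supply_elasticity = runif_range(1, rg$supply_elasticity),
        demand_elasticity = runif_range(1, rg$demand_elasticity),
        ag_gdp = runif_range(1, rg$ag_gdp),
        poor_count = runif_range(1, rg$poor_count),
        poverty_elasticity = runif_range(1, rg$poverty_elasticity)
      )
    })
    environment_macro(cfg$environment, countries)
  })
}

#' Constant-covariate nutrition baseline path
#'
#' Baseline covariates held constant at the configured levels over the
#' horizon, mirroring the assumption that future climate and social
#' covariates stay at their baseline-decade values. Constant paths make
#' the baseline projection the identity on the malnourished share.
#'
#' @param cfg A [generator_config()].
#' @param horizon Path length in years (>= 1).
#' @return A [nutrition_path()] plus a `population` attribute with the
#'   environment's total population.
#' @export
generate_nutrition_paths <- function(cfg, horizon = 25L) {
  stopifnot(inherits(cfg, "generator_config"))
  horizon <- as.integer(horizon)
  if (horizon < 1L)
    stop("horizon must be >= 1", call. = FALSE)
  nb <- cfg$nutrition_baseline
  path <- nutrition_path(
    pckcal = rep(nb$pckcal, horizon),
    lfexp_ratio = rep(nb$lfexp_ratio, horizon),
    schl = rep(nb$schl, horizon),
    water = rep(nb$water, horizon),
    popc = rep(nb$popc, horizon),
    pmc0 = nb$pmc0
  )
  attr(path, "population") <- nb$population
  path
}

#' Write a complete synthetic toy study to a directory
#'
#' Emits the CSV tables the pipeline readers consume: `technologies.csv`,
#' `macro.csv`, `nutrition.csv` and `indicators.csv` (target region and
#' reference region rows).
#'
#' @param cfg A [generator_config()].
#' @param dir Output directory (created if needed).
#' @param horizon Horizon for the nutrition path.
#' @return Invisibly, the directory path.
#' @export
write_fixture_study <- function(cfg, dir, horizon = 25L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  techs <- generate_technologies(cfg)
  macro <- generate_macro(cfg)
  nut <- generate_nutrition_paths(cfg, horizon)

  tech_df <- do.call(rbind, lapply(techs, function(p)
    as.data.frame(unclass(p), stringsAsFactors = FALSE)))
  utils::write.csv(tech_df, file.path(dir, "technologies.csv"),
                   row.names = FALSE)

  macro_df <- do.call(rbind, lapply(macro$countries, function(b)
    as.data.frame(unclass(b), stringsAsFactors = FALSE)))
  macro_df <- cbind(environment = macro$environment, macro_df)
  utils::write.csv(macro_df, file.path(dir, "macro.csv"), row.names = FALSE)

  nut_df <- data.frame(year = seq_along(nut$pckcal),
                       pckcal = nut$pckcal,
                       lfexp_ratio = nut$lfexp_ratio,
                       schl = nut$schl,
                       water = nut$water,
                       popc = nut$popc,
                       population = attr(nut, "population"),
                       pmc0 = nut$pmc0)
  utils::write.csv(nut_df, file.path(dir, "nutrition.csv"),
                   row.names = FALSE)

  ind_df <- data.frame(
    region = c(cfg$environment, "reference"),
    ag_gdp_share = c(22, 16),
    poverty_headcount = c(46, 47),
    child_stunting = c(39, 33),
    role = c("target", "reference")
  )
  utils::write.csv(ind_df, file.path(dir, "indicators.csv"),
                   row.names = FALSE)
  invisible(dir)
}
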