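#' Malnutrition projection coefficients
#'
#' Coefficients of the child-malnutrition recursion. The calorie term is an
#' elasticity on the log-ratio of successive per-capita kilocalorie levels
#' (-25.24); the life-expectancy and schooling terms are coefficients on
#' first differences of the female/male life-expectancy ratio (-71.755094)
#' and of female secondary-school enrollment in percent (-0.219831). No
#' published value exists for the safe-water coefficient, so it defaults to
#' 0 and a warning is emitted unless a value is supplied explicitly.
#'
#' @param kcal_elasticity Elasticity of the malnourished share w.r.t.
#'   per-capita kilocalorie availability (negative).
#' @param lfexp_coef Coefficient on the change in the female/male
#'   life-expectancy ratio (negative).
#' @param schl_coef Coefficient on the change in percent female secondary
#'   enrollment (negative).
#' @param water_coef Coefficient on the change in the safe-water share.
#'   Default 0 (with a warning, since no published value exists).
#' @param warn_water Emit the default-water warning (default TRUE).
#'
#' @return An object of class `"nutrition_coefficients"`.
#' @export
nutrition_coefficients <- function(kcal_elasticity = -25.24,
                                   lfexp_coef = -71.755094,
                                   schl_coef = -0.219831,
                                   water_coef = NULL,
                                   warn_water = TRUE) {
  if (is.null(water_coef)) {
    water_coef <- 0
    if (warn_water)
      warning("no value supplied for water_coef; using 0 ",
              "(no published coefficient exists)", call. = FALSE)
  }
  if (kcal_elasticity >= 0 || lfexp_coef >= 0 || schl_coef >= 0)
    stop("kcal_elasticity, lfexp_coef and schl_coef must be negative",
         call. = FALSE)
  structure(list(kcal_elasticity = kcal_elasticity,
                 lfexp_coef = lfexp_coef,
                 schl_coef = schl_coef,
                 water_coef = water_coef),
            class = "nutrition_coefficients")
}

#' Nutrition covariate path
#'
#' Yearly covariates entering the malnutrition recursion, plus the under-5
#' population used to convert the malnourished share into a count and the
#' starting share itself.
#'
#' @param pckcal Per-capita kilocalorie availability, kcal/person/day
#'   (> 0), one value per year.
#' @param lfexp_ratio Female/male life-expectancy ratio per year.
#' @param schl Percent of females enrolled in secondary school per year.
#' @param water Share of the population with access to safe water per year.
#' @param popc Under-5 population per year (>= 0).
#' @param pmc0 Percent of children malnourished in the year before the
#'   path starts, in [0, 100].
#' @param pckcal0 Per-capita kilocalorie availability in the year before
#'   the path starts (the reference for the year-1 calorie increment).
#'   Defaults to `pckcal[1]`, which makes the year-1 calorie increment
#'   zero; scenario paths share the baseline's reference so that extra
#'   calories in year 1 already count.
#'
#' @return An object of class `"nutrition_path"`.
#' @export
nutrition_path <- function(pckcal, lfexp_ratio, schl, water, popc, pmc0,
                           pckcal0 = pckcal[1]) {
  n <- length(pckcal)
  lens <- c(length(lfexp_ratio), length(schl), length(water), length(popc))
  if (any(lens != n))
    stop("all covariate sequences must have equal length", call. = FALSE)
  if (any(is.na(pckcal)) || any(pckcal <= 0))
    stop("pckcal must be > 0 at every year", call. = FALSE)
  if (any(popc < 0))
    stop("popc must be >= 0", call. = FALSE)
  if (pmc0 < 0 || pmc0 > 100)
    stop("pmc0 must lie in [0, 100]", call. = FALSE)
  if (is.na(pckcal0) || pckcal0 <= 0)
    stop("pckcal0 must be > 0", call. = FALSE)
  structure(list(pckcal = as.numeric(pckcal),
                 lfexp_ratio = as.numeric(lfexp_ratio),
                 schl = as.numeric(schl),
                 water = as.numeric(water),
                 popc = as.numeric(popc),
                 pmc0 = as.numeric(pmc0),
                 pckcal0 = as.numeric(pckcal0)),
            class = "nutrition_path")
}

#' Project the malnourished-children share and count
#'
#' Runs the recursion
#' \deqn{PMC_t = PMC_{t-1}
#'   + e_{kcal}\,\log(PcKcal_t / PcKcal_{t-1})
#'   + c_{lfexp}\,(LfExp_t - LfExp_{t-1})
#'   + c_{schl}\,(Schl_t - Schl_{t-1})
#'   + c_{water}\,(Water_t - Water_{t-1}),}
#' clamping each PMC to [0, 100], and converts the share into a count with
#' \eqn{MC_t = PopC_t \cdot PMC_t / 100}. The year-1 increments are taken
#' against the pre-path state: `pmc0`, `pckcal0` and the year-1 levels of
#' the remaining covariates (whose year-1 increments therefore vanish).
#' While no clamp binds, the calorie terms telescope, so
#' \eqn{PMC_t = PMC_0 + e_{kcal} \log(PcKcal_t / PcKcal_0) + \dots};
#' scenario and baseline paths sharing the same `pckcal0` are directly
#' comparable from year 1 on.
#'
#' @param path A [nutrition_path()].
#' @param coefs A [nutrition_coefficients()] object.
#'
#' @return An object of class `"malnutrition_result"`: list with
#'   `pmc_by_year` (percent) and `mc_by_year` (children).
#' @export
project_malnutrition <- function(path, coefs = nutrition_coefficients(warn_water = FALSE)) {
  stopifnot(inherits(path, "nutrition_path"),
            inherits(coefs, "nutrition_coefficients"))
  n <- length(path$pckcal)
  pmc <- numeric(n)
  # the pre-path state: pmc0 with year-1 covariates as the reference level
  prev_pmc <- path$pmc0
  prev_kcal <- path$pckcal0
  prev_lf <- path$lfexp_ratio[1]
  prev_schl <- path$schl[1]
  prev_water <- path$water[1]
  for (t in seq_len(n)) {
    inc <- coefs$kcal_elasticity * log(path$pckcal[t] / prev_kcal) +
      coefs$lfexp_coef * (path$lfexp_ratio[t] - prev_lf) +
      coefs$schl_coef * (path$schl[t] - prev_schl) +
      coefs$water_coef * (path$water[t] - prev_water)
    pmc[t] <- min(max(prev_pmc + inc, 0), 100)
    prev_pmc <- pmc[t]
    prev_kcal <- path$pckcal[t]
    prev_lf <- path$lfexp_ratio[t]
    prev_schl <- path$schl[t]
    prev_water <- path$water[t]
  }
  structure(list(pmc_by_year = pmc,
                 mc_by_year = path$popc * pmc / 100),
            class = "malnutrition_result")
}

#' @export
print.malnutrition_result <- function(x, ...) {
  n <- length(x$pmc_by_year)
  cat("Malnutrition projection over", n, "years\n")
  cat(sprintf("  PMC: %.2f%% (year 1) -> %.2f%% (year %d)\n",
              x$pmc_by_year[1], x$pmc_by_year[n], n))
  cat(sprintf("  MC:  %s -> %s children\n",
              format(round(x$mc_by_year[1]), big.mark = ","),
              format(round(x$mc_by_year[n]), big.mark = ",")))
  invisible(x)
}

#' Calorie path under extra food production
#'
#' Reduced production-to-calories linkage: extra tonnes of the target crop
#' are converted to kilocalories and spread over the population and the
#' year, shifting the per-capita daily availability:
#' \deqn{PcKcal^{scen}_t = PcKcal^{base}_t +
#'   \frac{\Delta Q_t \cdot kcal/t}{population \cdot 365}.}
#'
#' @param extra_production Extra production per year, tonnes/yr (scalar or
#'   a vector aligned to the baseline path).
#' @param kcal_per_tonne Energy content of the crop, kcal per tonne.
#' @param population Total population sharing the calories (> 0).
#' @param baseline_pckcal Baseline per-capita kcal/day path.
#'
#' @return Scenario per-capita kcal/day path, same length as the baseline.
#' @export
kcal_shift_from_production <- function(extra_production, kcal_per_tonne,
                                       population, baseline_pckcal) {
  if (is.na(population) || population <= 0)
    stop("population must be > 0", call. = FALSE)
  baseline_pckcal + extra_production * kcal_per_tonne / (population * 365)
}

#' Scenario-minus-baseline malnourished children at a year
#'
#' @param baseline,scenario [project_malnutrition()] results on equal
#'   horizons.
#' @param T Evaluation year (index into the paths).
#' @return Difference in malnourished children at year `T`; negative means
#'   the scenario improves nutrition.
#' @export
delta_malnourished <- function(baseline, scenario, T) {
  stopifnot(inherits(baseline, "malnutrition_result"),
            inherits(scenario, "malnutrition_result"))
  if (length(baseline$mc_by_year) != length(scenario$mc_by_year))
    stop("baseline and scenario horizons differ (",
         length(baseline$mc_by_year), " vs ",
         length(scenario$mc_by_year), ")", call. = FALSE)
  if (T < 1 || T > length(baseline$mc_by_year))
    stop("evaluation year out of range", call. = FALSE)
  scenario$mc_by_year[T] - baseline$mc_by_year[T]
}

#' Nutrition outcome for one technology
#'
#' Builds the technology scenario from the extra production implied by the
#' adoption path (yield gain x success probability x adoption share x
#' baseline production, summed over countries), shifts the calorie path,
#' projects baseline and scenario, and returns the change in malnourished
#' children at the evaluation year.
#'
#' @param profile A [technology_profile()].
#' @param macro An [environment_macro()].
#' @param path Adoption path.
#' @param nutrition A [nutrition_path()] for the environment.
#' @param population Total population of the environment.
#' @param kcal_per_tonne Energy content of the crop (default 3.5e6 kcal/t,
#'   a typical cereal/legume dry-grain value).
#' @param coefs [nutrition_coefficients()].
#'
#' @return List with `delta_mc_at_T`, `baseline`, `scenario`, `eval_year`.
#' @export
nutrition_outcome <- function(profile, macro, path, nutrition, population,
                              kcal_per_tonne = 3.5e6,
                              coefs = nutrition_coefficients(warn_water = FALSE)) {
  total_production <- sum(vapply(macro$countries, `[[`, numeric(1),
                                 "production"))
  extra <- profile$yield_gain * profile$prob_success * path * total_production
  scen_kcal <- kcal_shift_from_production(extra, kcal_per_tonne,
                                          population, nutrition$pckcal)
  scen_path <- nutrition_path(scen_kcal, nutrition$lfexp_ratio,
                              nutrition$schl, nutrition$water,
                              nutrition$popc, nutrition$pmc0,
                              pckcal0 = nutrition$pckcal0)
  base <- project_malnutrition(nutrition, coefs)
  scen <- project_malnutrition(scen_path, coefs)
  eval_year <- profile$release_lag + profile$years_to_max
  list(delta_mc_at_T = delta_malnourished(base, scen, eval_year),
       baseline = base, scenario = scen, eval_year = eval_year)
}
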