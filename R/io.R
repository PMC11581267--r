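#' Run configuration for the pipeline
#'
#' @param dir Directory holding the study tables (`technologies.csv`,
#'   `macro.csv`, `nutrition.csv`, `indicators.csv`), e.g. written by
#'   [write_fixture_study()].
#' @param horizon Evaluation horizon in years (default 25).
#' @param discount_rate Discount rate (default 0.10).
#' @param adoption_shape `"linear"` or `"logistic"`.
#' @param kcal_per_tonne Crop energy content for the calorie linkage.
#' @param coefs [nutrition_coefficients()].
#' @param precision Decimal places used when serializing reports
#'   (default 4); internal values are never rounded.
#' @param seed Seed recorded in the report metadata.
#'
#' @return An object of class `"run_config"`.
#' @export
run_config <- function(dir, horizon = 25L, discount_rate = 0.10,
                       adoption_shape = "linear", kcal_per_tonne = 3.5e6,
                       coefs = nutrition_coefficients(warn_water = FALSE),
                       precision = 4L, seed = 1L) {
  if (!dir.exists(dir))
    stop("study directory not found: ", dir, call. = FALSE)
  if (precision < 0)
    stop("precision must be >= 0", call. = FALSE)
  structure(list(dir = dir, horizon = as.integer(horizon),
                 discount_rate = discount_rate,
                 adoption_shape = adoption_shape,
                 kcal_per_tonne = kcal_per_tonne,
                 coefs = coefs, precision = as.integer(precision),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Load a run configuration from YAML or JSON
#'
#' The file holds `dir` (relative paths resolved against the config file's
#' own directory) and any of the other [run_config()] fields, including
#' nutrition coefficients under `coefs:`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` config file.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (is.null(raw$dir))
    stop("config must name the study directory under 'dir'", call. = FALSE)
  dir <- raw$dir
  if (!grepl("^(/|[A-Za-z]:)", dir))
    dir <- file.path(dirname(path), dir)
  coefs <- if (!is.null(raw$coefs))
    do.call(nutrition_coefficients,
            c(raw$coefs, list(warn_water = FALSE)))
  else nutrition_coefficients(warn_water = FALSE)
  run_config(dir,
             horizon = raw$horizon %||% 25L,
             discount_rate = raw$discount_rate %||% 0.10,
             adoption_shape = raw$adoption_shape %||% "linear",
             kcal_per_tonne = raw$kcal_per_tonne %||% 3.5e6,
             coefs = coefs,
             precision = raw$precision %||% 4L,
             seed = raw$seed %||% 1L)
}

read_table_checked <- function(path, required) {
  if (!file.exists(path))
    stop("input table not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(basename(path), ": missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  num_cols <- setdiff(required, c("tech_id", "crop", "environment",
                                  "country", "region", "role", "year"))
  for (nm in num_cols) {
    v <- suppressWarnings(as.numeric(df[[nm]]))
    bad <- which(is.na(v) & !is.na(df[[nm]]))
    if (length(bad))
      stop(basename(path), ", column '", nm, "', row ", bad[1],
           ": non-numeric value '", df[[nm]][bad[1]], "'", call. = FALSE)
    df[[nm]] <- v
  }
  df
}

#' Read and validate the four study tables
#'
#' @param cfg A [run_config()].
#' @return List with `technologies` (list of profiles), `macro`
#'   (an [environment_macro()]), `nutrition` (a [nutrition_path()] with a
#'   `population` attribute) and `indicators` (list with `target` and
#'   `reference` [indicator_set()]s).
#' @export
read_study <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  tech_cols <- c("tech_id", "crop", "environment", "yield_gain",
                 "cost_change", "prob_success", "max_adoption",
                 "years_to_max", "release_lag", "research_cost_per_year",
                 "research_years", "dissemination_cost_per_ha")
  tech_df <- read_table_checked(file.path(cfg$dir, "technologies.csv"),
                                tech_cols)
  technologies <- lapply(seq_len(nrow(tech_df)), function(i)
    do.call(technology_profile, as.list(tech_df[i, tech_cols])))

  macro_cols <- c("environment", "country", "production", "area", "price",
                  "supply_elasticity", "demand_elasticity", "ag_gdp",
                  "poor_count", "poverty_elasticity")
  macro_df <- read_table_checked(file.path(cfg$dir, "macro.csv"),
                                 macro_cols)
  countries <- lapply(seq_len(nrow(macro_df)), function(i)
    do.call(country_baseline,
            as.list(macro_df[i, setdiff(macro_cols, "environment")])))
  macro <- environment_macro(macro_df$environment[1], countries)

  nut_cols <- c("year", "pckcal", "lfexp_ratio", "schl", "water", "popc",
                "population", "pmc0")
  nut_df <- read_table_checked(file.path(cfg$dir, "nutrition.csv"),
                               nut_cols)
  nut <- nutrition_path(nut_df$pckcal, nut_df$lfexp_ratio, nut_df$schl,
                        nut_df$water, nut_df$popc, nut_df$pmc0[1])
  attr(nut, "population") <- nut_df$population[1]

  ind_cols <- c("region", "ag_gdp_share", "poverty_headcount",
                "child_stunting", "role")
  ind_df <- read_table_checked(file.path(cfg$dir, "indicators.csv"),
                               ind_cols)
  pick <- function(role) {
    row <- ind_df[ind_df$role == role, ][1, ]
    if (is.na(row$region))
      stop("indicators.csv: no row with role '", role, "'", call. = FALSE)
    indicator_set(row$region, row$ag_gdp_share, row$poverty_headcount,
                  row$child_stunting)
  }
  list(technologies = technologies, macro = macro, nutrition = nut,
       indicators = list(target = pick("target"),
                         reference = pick("reference")))
}

#' Compute the three outcome criteria for every technology
#'
#' For each technology: the discounted benefit-cost ratio, the number of
#' people lifted out of poverty (the negated poverty change, so larger is
#' better) and the signed change in malnourished children at the year of
#' maximum adoption (negative is better).
#'
#' @param study Output of [read_study()] (or an equivalent list).
#' @param cfg A [run_config()].
#' @return data.frame with columns `tech_id`, `bcr`, `poverty_reduction`,
#'   `malnutrition_change`.
#' @export
compute_criteria <- function(study, cfg) {
  rows <- lapply(study$technologies, function(p) {
    path <- build_adoption_path(p, cfg$horizon, cfg$adoption_shape)
    so <- surplus_outcome(p, study$macro, cfg$horizon, cfg$discount_rate,
                          cfg$adoption_shape)
    no <- nutrition_outcome(p, study$macro, path, study$nutrition,
                            attr(study$nutrition, "population"),
                            cfg$kcal_per_tonne, cfg$coefs)
    data.frame(tech_id = p$tech_id,
               bcr = so$bcr,
               poverty_reduction = -so$poverty_change,
               malnutrition_change = no$delta_mc_at_T,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Run the full pipeline: criteria, weights, TOPSIS, report
#'
#' @param cfg A [run_config()] (or a path accepted by
#'   [read_run_config()]).
#' @return An object of class `"ranking_report"`: list with `criteria`
#'   (data.frame), `weights`, `topsis` (a `"topsis_result"`), `table`
#'   (the ranked report table) and `metadata`.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  stopifnot(inherits(cfg, "run_config"))
  study <- tryCatch(read_study(cfg), error = function(e)
    stop("[read] ", conditionMessage(e), call. = FALSE))
  crit <- tryCatch(compute_criteria(study, cfg), error = function(e)
    stop("[criteria] ", conditionMessage(e), call. = FALSE))
  w <- tryCatch(
    derive_criteria_weights(indicator_ratios(study$indicators$target,
                                             study$indicators$reference)),
    error = function(e) stop("[weights] ", conditionMessage(e),
                             call. = FALSE))
  m <- decision_matrix(as.matrix(crit[, c("bcr", "poverty_reduction",
                                          "malnutrition_change")]),
                       tech_ids = crit$tech_id,
                       directions = c("benefit", "benefit", "cost"))
  res <- tryCatch(topsis(m, w), error = function(e)
    stop("[topsis] ", conditionMessage(e), call. = FALSE))
  structure(list(criteria = crit, weights = w, topsis = res,
                 table = topsis_table(res),
                 metadata = list(
                   config_hash = config_fingerprint(cfg),
                   horizon = cfg$horizon,
                   discount_rate = cfg$discount_rate,
                   adoption_shape = cfg$adoption_shape,
                   seed = cfg$seed, precision = cfg$precision,
                   version = as.character(utils::packageVersion("exanterank")))),
            class = "ranking_report")
}

# polynomial rolling hash over the run parameters (not the study path, so the same
# configuration in a different directory hashes identically)
config_fingerprint <- function(cfg) {
  s <- paste(cfg$horizon, cfg$discount_rate, cfg$adoption_shape,
             cfg$kcal_per_tonne, paste(unlist(cfg$coefs), collapse = ","),
             cfg$precision, cfg$seed, sep = "|")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' @export
print.ranking_report <- function(x, ...) {
  cat("Ranking report —", length(x$topsis$tech_ids), "technologies,",
      "horizon", x$metadata$horizon, "yr, r =",
      sprintf("%.0f%%", 100 * x$metadata$discount_rate), "\n")
  print(x$weights)
  tab <- x$table
  num <- vapply(tab, is.double, logical(1))
  tab[num] <- lapply(tab[num], signif, digits = 4)
  print(utils::head(tab, 10), row.names = FALSE)
  if (nrow(tab) > 10) cat("  ... and", nrow(tab) - 10, "more\n")
  invisible(x)
}

#' Write a ranking report to CSV and JSON
#'
#' The CSV holds the full per-technology table; the JSON summary carries
#' the same rows plus weights and metadata. Values are rounded only here,
#' to `precision` decimals.
#'
#' @param report A `"ranking_report"`.
#' @param csv_path,json_path Output paths (either may be NULL to skip).
#' @param precision Decimals for serialization (default from the report's
#'   config).
#' @return Invisibly, the report.
#' @export
write_report <- function(report, csv_path = NULL, json_path = NULL,
                         precision = report$metadata$precision) {
  stopifnot(inherits(report, "ranking_report"))
  tab <- report$table
  num <- vapply(tab, is.double, logical(1))
  tab[num] <- lapply(tab[num], round, digits = precision)
  if (!is.null(csv_path))
    utils::write.csv(tab, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    payload <- list(
      weights = round(as.numeric(report$weights), precision),
      criteria = c("bcr", "poverty_reduction", "malnutrition_change"),
      technologies = tab,
      metadata = report$metadata)
    jsonlite::write_json(payload, json_path, auto_unbox = TRUE,
                         digits = NA, dataframe = "rows")
  }
  invisible(report)
}

#' Re-rank under alternative criteria weightings
#'
#' Recomputes only the TOPSIS stage for each weight vector in the grid,
#' leaving the criteria fixed; useful for assessing how sensitive the
#' final ranking is to the regional weights.
#'
#' @param report A `"ranking_report"` from [run_pipeline()].
#' @param weight_grid List of weight vectors, each of length 3 and summing
#'   to 1 (within 1e-9).
#' @return data.frame of rank trajectories: one row per technology, one
#'   column per weighting (`w1`, `w2`, ...), plus the base ranks.
#' @export
sensitivity_sweep <- function(report, weight_grid) {
  stopifnot(inherits(report, "ranking_report"))
  if (!length(weight_grid))
    stop("weight_grid must contain at least one weighting", call. = FALSE)
  m <- decision_matrix(report$topsis$a,
                       tech_ids = report$topsis$tech_ids,
                       directions = report$topsis$directions)
  cols <- lapply(weight_grid, function(w) {
    w <- as.numeric(w)
    if (length(w) != 3L || any(w < 0) || abs(sum(w) - 1) > 1e-9)
      stop("each weighting must be 3 non-negative values summing to 1",
           call. = FALSE)
    topsis(m, w)$rank
  })
  out <- data.frame(tech_id = report$topsis$tech_ids,
                    base_rank = report$topsis$rank)
  for (i in seq_along(cols)) out[[paste0("w", i)]] <- cols[[i]]
  out
}
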