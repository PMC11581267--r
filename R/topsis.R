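#' Regional indicator set for weight derivation
#'
#' @param region Region label.
#' @param ag_gdp_share Share of agriculture in GDP, percent.
#' @param poverty_headcount Poverty headcount, percent.
#' @param child_stunting Child stunting headcount, percent.
#'
#' @return An object of class `"indicator_set"`.
#' @export
indicator_set <- function(region, ag_gdp_share, poverty_headcount,
                          child_stunting) {
  v <- c(ag_gdp_share = ag_gdp_share,
         poverty_headcount = poverty_headcount,
         child_stunting = child_stunting)
  if (any(is.na(v)) || any(v < 0) || any(v > 100))
    stop("indicators must lie in [0, 100]", call. = FALSE)
  structure(list(region = as.character(region),
                 ag_gdp_share = as.numeric(ag_gdp_share),
                 poverty_headcount = as.numeric(poverty_headcount),
                 child_stunting = as.numeric(child_stunting)),
            class = "indicator_set")
}

#' Indicator ratios of a target region to its reference region
#'
#' Each of the three development indicators of the target region is divided
#' by the corresponding indicator of the reference region (sub-Saharan
#' Africa for African drylands, South Asia for South-Asian drylands). The
#' ratios measure how much more (or less) each criterion matters in the
#' target region than in the reference.
#'
#' @param region Target [indicator_set()].
#' @param reference Reference [indicator_set()]; all indicators must be
#'   strictly positive.
#'
#' @return Named numeric vector of three ratios (bcr, poverty, nutrition).
#' @export
indicator_ratios <- function(region, reference) {
  stopifnot(inherits(region, "indicator_set"),
            inherits(reference, "indicator_set"))
  ref <- c(reference$ag_gdp_share, reference$poverty_headcount,
           reference$child_stunting)
  if (any(ref <= 0))
    stop("reference indicators must be > 0", call. = FALSE)
  c(bcr = region$ag_gdp_share / reference$ag_gdp_share,
    poverty = region$poverty_headcount / reference$poverty_headcount,
    nutrition = region$child_stunting / reference$child_stunting)
}

#' Criteria weights from indicator ratios
#'
#' Normalizes the three indicator ratios to sum to one. The resulting
#' weights order the benefit-cost, poverty and nutrition criteria by their
#' regional importance.
#'
#' @param ratios Numeric vector of three non-negative ratios with a
#'   positive sum (e.g. from [indicator_ratios()]).
#'
#' @return An object of class `"criteria_weights"`: numeric vector of
#'   three weights summing to 1, named bcr / poverty / nutrition.
#' @export
#' @examples
#' derive_criteria_weights(c(1.38, 0.98, 1.18))  # ~ (0.39, 0.28, 0.33)
derive_criteria_weights <- function(ratios) {
  ratios <- as.numeric(ratios)
  if (length(ratios) != 3L)
    stop("exactly three criteria ratios are required", call. = FALSE)
  if (any(is.na(ratios)) || any(ratios < 0))
    stop("ratios must be non-negative", call. = FALSE)
  s <- sum(ratios)
  if (s <= 0)
    stop("ratios sum to zero; weights are undefined", call. = FALSE)
  w <- ratios / s
  names(w) <- c("bcr", "poverty", "nutrition")
  class(w) <- "criteria_weights"
  w
}

#' @export
print.criteria_weights <- function(x, ...) {
  cat("Criteria weights (sum to 1):\n")
  print(round(unclass(x), 4))
  invisible(x)
}

#' Decision matrix for TOPSIS
#'
#' @param a Numeric matrix, one row per technology, one column per
#'   criterion. No missing cells.
#' @param tech_ids Row labels (default from rownames or T1..TI).
#' @param criteria Column labels (default `c("bcr", "poverty",
#'   "nutrition")` when 3 columns).
#' @param directions Character vector, `"benefit"` (larger is better) or
#'   `"cost"` (smaller is better) per criterion. Default for the standard
#'   three criteria: BCR and poverty reduction are benefits, the signed
#'   change in malnourished children is a cost.
#'
#' @return An object of class `"decision_matrix"`.
#' @export
decision_matrix <- function(a, tech_ids = NULL, criteria = NULL,
                            directions = NULL) {
  a <- as.matrix(a)
  if (!nrow(a))
    stop("the decision matrix needs at least one technology", call. = FALSE)
  if (any(is.na(a)))
    stop("the decision matrix has missing cells", call. = FALSE)
  if (is.null(tech_ids))
    tech_ids <- rownames(a) %||% paste0("T", seq_len(nrow(a)))
  if (is.null(criteria))
    criteria <- colnames(a) %||%
      (if (ncol(a) == 3L) c("bcr", "poverty", "nutrition")
       else paste0("C", seq_len(ncol(a))))
  if (is.null(directions))
    directions <- if (ncol(a) == 3L) c("benefit", "benefit", "cost")
      else rep("benefit", ncol(a))
  if (length(directions) != ncol(a))
    stop("one direction flag is required per criterion", call. = FALSE)
  if (!all(directions %in% c("benefit", "cost")))
    stop("directions must be 'benefit' or 'cost'", call. = FALSE)
  dimnames(a) <- list(tech_ids, criteria)
  structure(list(a = a, tech_ids = tech_ids, criteria = criteria,
                 directions = directions),
            class = "decision_matrix")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Vector (Euclidean) normalization of a decision matrix
#'
#' Each raw column is divided by its Euclidean norm, so every nonzero
#' column of the result has unit norm and signs are preserved.
#'
#' @param m A [decision_matrix()] or plain numeric matrix.
#' @return Normalized numeric matrix r with `r[i, j] = a[i, j] /
#'   sqrt(sum(a[, j]^2))`.
#' @export
normalize_decision_matrix <- function(m) {
  a <- if (inherits(m, "decision_matrix")) m$a else as.matrix(m)
  norms <- sqrt(colSums(a^2))
  zero <- norms == 0
  if (any(zero)) {
    nm <- colnames(a) %||% paste0("C", seq_len(ncol(a)))
    stop("criterion '", nm[which(zero)[1]],
         "' is identically zero and cannot be normalized", call. = FALSE)
  }
  sweep(a, 2, norms, "/")
}

#' Apply criteria weights to a normalized matrix
#'
#' @param r Normalized matrix from [normalize_decision_matrix()].
#' @param w A [criteria_weights()] vector (or any numeric weights, one per
#'   criterion).
#' @return Weighted normalized matrix `v[i, j] = w[j] * r[i, j]`.
#' @export
apply_weights <- function(r, w) {
  r <- as.matrix(r)
  if (length(w) != ncol(r))
    stop("got ", length(w), " weights for ", ncol(r), " criteria",
         call. = FALSE)
  sweep(r, 2, as.numeric(w), "*")
}

#' Positive- and negative-ideal solutions
#'
#' The positive ideal takes, per criterion, the best weighted value across
#' technologies (max for benefit criteria, min for cost criteria); the
#' negative ideal takes the worst.
#'
#' @param v Weighted normalized matrix.
#' @param directions `"benefit"` or `"cost"` per criterion.
#' @return List with `v_plus` and `v_minus` vectors.
#' @export
ideal_solutions <- function(v, directions) {
  v <- as.matrix(v)
  if (length(directions) != ncol(v))
    stop("one direction flag is required per criterion", call. = FALSE)
  if (!all(directions %in% c("benefit", "cost")))
    stop("unknown direction flag: ",
         paste(setdiff(directions, c("benefit", "cost")), collapse = ", "),
         call. = FALSE)
  v_plus <- vapply(seq_len(ncol(v)), function(j)
    if (directions[j] == "benefit") max(v[, j]) else min(v[, j]), numeric(1))
  v_minus <- vapply(seq_len(ncol(v)), function(j)
    if (directions[j] == "benefit") min(v[, j]) else max(v[, j]), numeric(1))
  names(v_plus) <- names(v_minus) <- colnames(v)
  list(v_plus = v_plus, v_minus = v_minus)
}

#' Euclidean distances to the ideal solutions
#'
#' @param v Weighted normalized matrix.
#' @param v_plus,v_minus Ideal vectors from [ideal_solutions()].
#' @return List with `s_plus` and `s_minus`, one distance per technology.
#' @export
euclidean_distances <- function(v, v_plus, v_minus) {
  v <- as.matrix(v)
  if (length(v_plus) != ncol(v) || length(v_minus) != ncol(v))
    stop("ideal vectors must have one entry per criterion", call. = FALSE)
  s_plus <- sqrt(rowSums(sweep(v, 2, v_plus)^2))
  s_minus <- sqrt(rowSums(sweep(v, 2, v_minus)^2))
  list(s_plus = s_plus, s_minus = s_minus)
}

#' Closeness index
#'
#' Relative closeness of each technology to the positive-ideal solution,
#' `C+ = S- / (S- + S+)`, in [0, 1]; higher is better. If a technology has
#' both distances zero (the ideals coincide, e.g. a single-technology
#' matrix) its closeness is defined as 1 with a warning.
#'
#' @param s_plus,s_minus Distances from [euclidean_distances()].
#' @return Numeric vector of closeness indices.
#' @export
closeness_index <- function(s_plus, s_minus) {
  if (length(s_plus) != length(s_minus))
    stop("distance vectors must have equal length", call. = FALSE)
  tot <- s_plus + s_minus
  degenerate <- tot == 0
  if (any(degenerate))
    warning("positive and negative ideals coincide for ",
            sum(degenerate), " technology(ies); closeness set to 1",
            call. = FALSE)
  out <- ifelse(degenerate, 1, s_minus / ifelse(degenerate, 1, tot))
  pmin(pmax(out, 0), 1)
}

#' Competition ranks from closeness indices
#'
#' Higher closeness ranks better; ties share the smallest applicable rank
#' (competition ranking), so a k-way tie at the bottom of n technologies
#' shares rank n - k + 1.
#'
#' @param closeness Numeric vector of closeness indices.
#' @return Integer ranks, 1 = best.
#' @export
rank_technologies <- function(closeness) {
  if (!length(closeness))
    stop("cannot rank an empty closeness vector", call. = FALSE)
  as.integer(rank(-closeness, ties.method = "min"))
}

#' Run the full six-step TOPSIS procedure
#'
#' Normalizes the raw decision matrix by column Euclidean norms, applies
#' the criteria weights, forms the positive- and negative-ideal solutions
#' respecting each criterion's direction, computes Euclidean distances to
#' both ideals, converts them into closeness indices and ranks the
#' technologies (ties share the minimum rank).
#'
#' @param m A [decision_matrix()].
#' @param w A [criteria_weights()] vector.
#' @return An object of class `"topsis_result"`: list with `a`, `r`, `v`,
#'   `v_plus`, `v_minus`, `s_plus`, `s_minus`, `closeness`, `rank`,
#'   `weights`, `directions`, `tech_ids`.
#' @export
#' @examples
#' m <- decision_matrix(rbind(c(21, 4.75e5, -3.8e4), c(3, 5e4, 1e3)),
#'                      tech_ids = c("sorghum_dt", "lentil_dr"))
#' topsis(m, derive_criteria_weights(c(1.38, 0.98, 1.18)))
topsis <- function(m, w) {
  stopifnot(inherits(m, "decision_matrix"))
  r <- normalize_decision_matrix(m)
  v <- apply_weights(r, w)
  ideals <- ideal_solutions(v, m$directions)
  d <- euclidean_distances(v, ideals$v_plus, ideals$v_minus)
  cl <- closeness_index(d$s_plus, d$s_minus)
  structure(list(a = m$a, r = r, v = v,
                 v_plus = ideals$v_plus, v_minus = ideals$v_minus,
                 s_plus = d$s_plus, s_minus = d$s_minus,
                 closeness = cl, rank = rank_technologies(cl),
                 weights = as.numeric(w), directions = m$directions,
                 tech_ids = m$tech_ids),
            class = "topsis_result")
}

#' @export
print.topsis_result <- function(x, digits = 4, ...) {
  cat("TOPSIS ranking of", length(x$tech_ids), "technologies\n")
  cat("  weights:", paste(sprintf("%s=%.*f", colnames(x$a) %||%
                                    seq_along(x$weights),
                                  2, x$weights), collapse = ", "), "\n")
  tab <- data.frame(tech_id = x$tech_ids,
                    closeness = round(x$closeness, digits),
                    rank = x$rank)
  print(tab[order(tab$rank), ], row.names = FALSE)
  invisible(x)
}

#' Tidy table view of a TOPSIS result
#'
#' @param x A `"topsis_result"`.
#' @param digits Rounding applied for display columns (default no
#'   rounding).
#' @return data.frame with raw criteria, per-criterion ranks, distances,
#'   closeness and final rank.
#' @export
topsis_table <- function(x, digits = NULL) {
  stopifnot(inherits(x, "topsis_result"))
  crit_rank <- sapply(seq_len(ncol(x$a)), function(j) {
    vals <- if (x$directions[j] == "benefit") -x$a[, j] else x$a[, j]
    as.integer(rank(vals, ties.method = "min"))
  })
  colnames(crit_rank) <- paste0("rank_", colnames(x$a))
  out <- data.frame(tech_id = x$tech_ids, x$a, crit_rank,
                    s_plus = x$s_plus, s_minus = x$s_minus,
                    closeness = x$closeness, rank = x$rank,
                    row.names = NULL, check.names = FALSE)
  if (!is.null(digits)) {
    num <- vapply(out, is.double, logical(1))
    out[num] <- lapply(out[num], round, digits = digits)
  }
  out[order(out$rank), ]
}
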