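# shared fixtures and independent oracles

toy_country <- function(country = "A", production = 1e5, area = 2e5,
                        price = 400, supply_elasticity = 0.9,
                        demand_elasticity = 0.7, ag_gdp = 2e9,
                        poor_count = 3e6, poverty_elasticity = -0.8) {
  country_baseline(country, production, area, price, supply_elasticity,
                   demand_elasticity, ag_gdp, poor_count,
                   poverty_elasticity)
}

toy_macro <- function(...) environment_macro("toy", list(...))

constant_nutrition <- function(horizon = 25, pckcal = 2300, pmc0 = 20,
                               popc = 5e6) {
  nutrition_path(rep(pckcal, horizon), rep(1.05, horizon),
                 rep(35, horizon), rep(0.6, horizon),
                 rep(popc, horizon), pmc0)
}

# straight-line loop-based recomputation of all six TOPSIS steps,
# independent of the package's vectorized path
topsis_oracle <- function(a, w, directions) {
  I <- nrow(a); J <- ncol(a)
  r <- matrix(0, I, J)
  for (j in 1:J) {
    nrm <- sqrt(sum(a[, j]^2))
    for (i in 1:I) r[i, j] <- a[i, j] / nrm
  }
  v <- matrix(0, I, J)
  for (i in 1:I) for (j in 1:J) v[i, j] <- w[j] * r[i, j]
  vp <- vm <- numeric(J)
  for (j in 1:J) {
    if (directions[j] == "benefit") {
      vp[j] <- max(v[, j]); vm[j] <- min(v[, j])
    } else {
      vp[j] <- min(v[, j]); vm[j] <- max(v[, j])
    }
  }
  sp <- sm <- numeric(I)
  for (i in 1:I) {
    sp[i] <- sqrt(sum((v[i, ] - vp)^2))
    sm[i] <- sqrt(sum((v[i, ] - vm)^2))
  }
  cl <- numeric(I)
  for (i in 1:I) cl[i] <- if (sp[i] + sm[i] == 0) 1
    else sm[i] / (sm[i] + sp[i])
  cl
}

# loop-based present-value summation, independent of compute_bcr
pv_oracle <- function(stream, r) {
  total <- 0
  for (t in seq_along(stream)) total <- total + stream[t] / (1 + r)^t
  total
}
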