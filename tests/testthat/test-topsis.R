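test_that("indicator ratios divide region by reference", {
  ref <- indicator_set("ref", 15, 30, 20)
  reg <- indicator_set("reg", 30, 15, 20)
  expect_equal(unname(indicator_ratios(reg, ref)), c(2.0, 0.5, 1.0))
  expect_equal(unname(indicator_ratios(ref, ref)), c(1, 1, 1))
  expect_error(indicator_ratios(reg, indicator_set("z", 0, 30, 20)),
               "> 0")
})

test_that("weights are normalized ratios and reproduce the published rows", {
  # three dryland rows whose printed ratios are self-consistent
  expect_equal(round(unclass(derive_criteria_weights(c(1.38, 0.98, 1.18))), 2),
               c(bcr = 0.39, poverty = 0.28, nutrition = 0.33))
  expect_equal(round(unclass(derive_criteria_weights(c(0.97, 1.46, 1.54))), 2),
               c(bcr = 0.24, poverty = 0.37, nutrition = 0.39))
  expect_equal(round(unclass(derive_criteria_weights(c(1.67, 0.58, 1.32))), 2),
               c(bcr = 0.47, poverty = 0.16, nutrition = 0.37))
  expect_equal(unname(unclass(derive_criteria_weights(c(1, 1, 1)))),
               rep(1 / 3, 3))
})

test_that("weight derivation is scale invariant and guards its domain", {
  set.seed(3)
  for (i in 1:10) {
    ratios <- runif(3, 0.1, 3)
    expect_equal(unclass(derive_criteria_weights(ratios)),
                 unclass(derive_criteria_weights(42 * ratios)))
    expect_equal(sum(derive_criteria_weights(ratios)), 1, tolerance = 1e-9)
  }
  expect_error(derive_criteria_weights(c(0, 0, 0)), "zero")
  expect_error(derive_criteria_weights(c(-1, 1, 1)), "non-negative")
})

test_that("vector normalization yields unit columns and keeps signs", {
  expect_equal(unname(normalize_decision_matrix(matrix(c(3, 4), 2))[, 1]),
               c(0.6, 0.8))
  expect_equal(unname(normalize_decision_matrix(matrix(c(-3, 4), 2))[, 1]),
               c(-0.6, 0.8))
  set.seed(9)
  a <- matrix(rnorm(18), 6, 3)
  r <- normalize_decision_matrix(a)
  expect_equal(unname(sqrt(colSums(r^2))), rep(1, 3), tolerance = 1e-12)
  expect_equal(sign(r), sign(a))
  zero <- matrix(c(1, 2, 0, 0), 2, dimnames = list(NULL, c("x", "y")))
  expect_error(normalize_decision_matrix(zero), "y")
})

test_that("weighted matrix scales columns; renormalized weights change nothing", {
  r <- matrix(runif(12), 4, 3)
  v <- apply_weights(r, c(1, 0, 0))
  expect_true(all(v[, 2:3] == 0))
  expect_equal(v[, 1], r[, 1])
  w <- c(0.2, 0.3, 0.5)
  expect_equal(apply_weights(r, w),
               apply_weights(r, (2 * w) / sum(2 * w)))
  expect_error(apply_weights(r, c(0.5, 0.5)), "2 weights for 3")
})

test_that("the published worked weighting is reproduced within rounding", {
  # semi-arid West and Central Africa: unrounded weights applied to the
  # top technology's normalized row give the printed weighted row
  w <- derive_criteria_weights(c(1.38, 0.98, 1.18))
  v <- apply_weights(matrix(c(0.4532, 0.6027, -0.4722), 1), w)
  expect_lt(max(abs(unname(v[1, ]) - c(0.1763, 0.1664, -0.1582))), 1e-3)
})

test_that("ideal solutions respect criterion directions", {
  v <- rbind(c(1, 0), c(0, 1))
  both_benefit <- ideal_solutions(v, c("benefit", "benefit"))
  expect_equal(unname(both_benefit$v_plus), c(1, 1))
  expect_equal(unname(both_benefit$v_minus), c(0, 0))
  mixed <- ideal_solutions(v, c("benefit", "cost"))
  expect_equal(unname(mixed$v_plus), c(1, 0))
  expect_equal(unname(mixed$v_minus), c(0, 1))
  single <- ideal_solutions(matrix(c(0.3, -0.2), 1), c("benefit", "cost"))
  expect_equal(single$v_plus, single$v_minus)
  expect_error(ideal_solutions(v, c("benefit", "up")), "direction")
})

test_that("the published distance and closeness arithmetic is reproduced", {
  v_row <- c(0.1763, 0.1664, -0.1581)
  v_plus <- c(0.1763, 0.1664, -0.1581)
  v_minus <- c(0.0153, 0.0048, 0.0000)
  d <- euclidean_distances(matrix(v_row, 1), v_plus, v_minus)
  expect_equal(unname(d$s_plus), 0)
  expect_equal(unname(d$s_minus), 0.2776, tolerance = 5e-4)
  expect_equal(closeness_index(d$s_plus, d$s_minus), 1)
})

test_that("distances agree with hand-computed hypotenuses", {
  v <- rbind(c(3, 0), c(0, 4))
  d <- euclidean_distances(v, c(3, 4), c(0, 0))
  expect_equal(unname(d$s_plus), c(4, 3))
  expect_equal(unname(d$s_minus), c(3, 4))
})

test_that("closeness index spans [0, 1] with the stated edge cases", {
  expect_equal(closeness_index(0.3, 0.3), 0.5)
  expect_equal(closeness_index(0.5, 0), 0)
  expect_warning(cl <- closeness_index(0, 0), "coincide")
  expect_equal(cl, 1)
})

test_that("ranking is competition-style with shared minimum ranks", {
  expect_equal(rank_technologies(c(1.0, 0.4, 0.7)), c(1L, 3L, 2L))
  set.seed(21)
  for (i in 1:20) {
    cl <- runif(sample(2:40, 1))
    rk <- rank_technologies(cl)
    expect_equal(rk[which.max(cl)], 1L)
    expect_true(all(sort(unique(rk)) %in% seq_along(cl)))
  }
})

test_that("a two-way bottom tie among 38 technologies shares rank 37", {
  cl <- c(seq(0.99, 0.10, length.out = 36), 0.05, 0.05)
  rk <- rank_technologies(cl)
  expect_equal(rk[37], 37L)
  expect_equal(rk[38], 37L)
  expect_equal(max(rk), 37L)
})

test_that("pipeline closeness matches the straight-line oracle to 1e-12", {
  set.seed(17)
  for (i in 1:25) {
    I <- sample(2:4, 1)
    a <- matrix(runif(I * 3, -5, 50), I, 3)
    dirs <- sample(c("benefit", "cost"), 3, replace = TRUE)
    w <- derive_criteria_weights(runif(3, 0.1, 2))
    m <- decision_matrix(a, directions = dirs)
    got <- suppressWarnings(topsis(m, w))
    want <- suppressWarnings(topsis_oracle(a, as.numeric(w), dirs))
    expect_equal(unname(got$closeness), want, tolerance = 1e-12)
  }
})

test_that("ranking is invariant to positive rescaling of any criterion", {
  set.seed(29)
  a <- matrix(runif(21, 1, 30), 7, 3)
  m <- decision_matrix(a)
  w <- derive_criteria_weights(c(1.2, 0.8, 1.0))
  base_rank <- topsis(m, w)$rank
  for (j in 1:3) {
    b <- a; b[, j] <- b[, j] * runif(1, 0.01, 100)
    expect_equal(topsis(decision_matrix(b), w)$rank, base_rank)
  }
})

test_that("ranking commutes with permutation of the technology rows", {
  set.seed(31)
  a <- matrix(runif(18, 1, 10), 6, 3)
  w <- derive_criteria_weights(c(1, 1.5, 0.7))
  base <- topsis(decision_matrix(a), w)
  perm <- sample(6)
  permuted <- topsis(decision_matrix(a[perm, , drop = FALSE]), w)
  expect_equal(permuted$rank, base$rank[perm])
  expect_equal(unname(permuted$closeness), unname(base$closeness[perm]))
})

test_that("dominant and dominated technologies pin the closeness ends", {
  a <- rbind(c(30, 20, -500),   # best on all three (nutrition is a cost)
             c(10, 8, -100),
             c(2, 1, 300))      # worst on all three
  res <- topsis(decision_matrix(a), derive_criteria_weights(c(1, 1, 1)))
  expect_equal(unname(res$closeness[1]), 1)
  expect_equal(res$rank[1], 1L)
  expect_equal(unname(res$closeness[3]), 0)
  expect_equal(res$rank[3], 3L)
})

test_that("degenerate single-technology matrix gets closeness 1", {
  m <- decision_matrix(matrix(c(5, 3, -2), 1))
  expect_warning(res <- topsis(m, derive_criteria_weights(c(1, 1, 1))),
                 "coincide")
  expect_equal(unname(res$closeness), 1)
  expect_equal(res$rank, 1L)
})

test_that("decision matrices reject missing cells and bad directions", {
  expect_error(decision_matrix(matrix(c(1, NA), 1)), "missing")
  expect_error(decision_matrix(matrix(1, 1, 3),
                               directions = c("benefit", "cost")),
               "direction")
  expect_error(decision_matrix(matrix(numeric(0), 0, 3)),
               "at least one")
})
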