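test_that("distribution CV matches hand-computed values and is scale-invariant", {
  expect_equal(distribution_cv(rep(20, 7)), 0)
  expect_equal(distribution_cv(c(2, 1, 1), "population"), 0.35355, tolerance = 1e-4)
  expect_equal(distribution_cv(c(2, 1, 1), "sample"), 0.43301, tolerance = 1e-4)
  set.seed(42)
  for (i in 1:10) {
    counts <- rpois(7, 5)
    if (sum(counts) == 0) next
    k <- runif(1, 0.1, 50)
    expect_equal(distribution_cv(counts * k), distribution_cv(counts))
  }
  expect_error(distribution_cv(c(5)), "at least two")
  expect_error(distribution_cv(c(0, 0, 0)), "zero")
})

test_that("type distribution tabulates counts, weights, CV and mean index", {
  s <- scored_from_vectors(list(c(1, 1, 1), c(1, 1, 1), c(1, 0, 0), c(0, 0, 0)))
  d <- type_distribution(s)
  expect_equal(d$table$weight, c(50, 0, 0, 25, 0, 0, 25))
  expect_equal(sum(d$table$weight), 100)
  expect_equal(sum(d$table$count), d$n)
  expect_equal(d$mean_index, (7 + 7 + 4 + 0) / 4)
  all_I <- scored_from_vectors(rep(list(c(1, 1, 1)), 5))
  dI <- type_distribution(all_I)
  expect_equal(dI$table$weight[1], 100)
  expect_equal(dI$mean_index, 7)
  expect_equal(dI$cv, distribution_cv(c(5, 0, 0, 0, 0, 0, 0)))
  # records outside the typology are named, not silently dropped
  un <- scored_from_vectors(list(c(0, 1, 1)))
  expect_error(type_distribution(un), "UNOBSERVED")
  expect_silent(type_distribution(un, typology = malus_typology(TRUE)))
  expect_error(type_distribution(s, group = "absent"), "group")
})

test_that("type weights agree with a direct count-by-filter oracle", {
  coh <- random_assessments(80, p = 0.65, seed = 11)
  s <- score_assessments(coh)
  d <- type_distribution(s, typology = malus_typology(TRUE))
  for (i in seq_len(nrow(d$table))) {
    expect_equal(d$table$count[i], sum(s$type == d$table$label[i]))
    expect_equal(d$table$weight[i],
                 100 * mean(s$type == d$table$label[i]))
  }
})

test_that("mean symmetry index equals the distribution-weighted mean", {
  expect_equal(mean_symmetry_index(c(7, 6, 4)), 5.6667, tolerance = 1e-4)
  expect_equal(mean_symmetry_index(c(2)), 2)
  expect_error(mean_symmetry_index(numeric(0)), "no records")
  for (seed in 1:5) {
    s <- score_assessments(random_assessments(60, p = 0.6, seed = seed))
    d <- type_distribution(s, typology = malus_typology(TRUE))
    expect_equal(mean_symmetry_index(s),
                 sum(d$table$weight / 100 * d$table$index),
                 tolerance = 1e-9)
  }
})

test_that("weight ratios, relative weights and direction flags are consistent", {
  mk_dist <- function(vectors, group)
    type_distribution(scored_from_vectors(vectors, group), group)
  a <- mk_dist(c(rep(list(c(1, 1, 1)), 3), list(c(1, 0, 0))), "A")  # I 75%, IV 25%
  b <- mk_dist(c(rep(list(c(1, 1, 1)), 1), list(c(1, 0, 0)),
                 rep(list(c(0, 0, 0)), 2)), "B")  # I 25%, IV 25%, VII 50%
  r <- weight_ratio(a, b)
  expect_equal(r$ratio[r$label == "I"], 3)
  expect_equal(r$relative_weight[r$label == "I"], 2)
  expect_equal(r$direction[r$label == "I"], "A")
  expect_equal(r$ratio[r$label == "IV"], 1)
  expect_equal(r$direction[r$label == "IV"], "equal")
  expect_equal(r$direction[r$label == "VII"], "B")
  # zero-weight denominator: undefined and flagged, not infinite
  expect_true(all(is.na(r$ratio[!r$defined])))
  expect_false(r$defined[r$label == "II"])
  # reciprocity where both sides are defined
  rev <- weight_ratio(b, a)
  both <- r$defined & rev$defined
  expect_equal(r$ratio[both], 1 / rev$ratio[both])
  # typology mismatch
  a8 <- type_distribution(scored_from_vectors(list(c(1, 1, 1)), "A"), "A",
                          typology = malus_typology(TRUE))
  expect_error(weight_ratio(a8, b), "typolog")
})

test_that("dimension regularity fractions, ratios and pooled irregularity", {
  ones <- scored_from_vectors(rep(list(c(1, 1, 1)), 3), "A")
  ones_b <- scored_from_vectors(rep(list(c(1, 1, 1)), 2), "B")
  dr <- dimension_regularity(rbind(ones, ones_b), c("A", "B"))
  expect_true(all(dr$fractions == 1))
  expect_true(all(dr$ratio == 1))
  expect_true(all(dr$pooled_irregular == 0))
  a <- scored_from_vectors(list(c(1, 1, 1), c(1, 0, 0)), "A")
  b <- scored_from_vectors(list(c(0, 0, 0), c(1, 0, 0)), "B")
  dr2 <- dimension_regularity(rbind(a, b), c("A", "B"))
  expect_equal(unname(dr2$fractions["A", "X"]), 1)
  expect_equal(unname(dr2$fractions["B", "X"]), 0.5)
  expect_equal(unname(dr2$ratio[["X"]]), 2)
  expect_equal(unname(dr2$pooled_irregular[["Y"]]), 0.75)
  expect_error(dimension_regularity(a, c("A", "missing")), "empty group")
})

test_that("removing high-index members weakly decreases the mean index", {
  for (seed in 1:5) {
    s <- score_assessments(random_assessments(50, p = 0.8, seed = seed))
    top <- max(s$index)
    pruned <- s[s$index < top, , drop = FALSE]
    if (nrow(pruned) == 0) next
    expect_lte(mean_symmetry_index(pruned), mean_symmetry_index(s))
  }
})

test_that("trend fits recover noiseless model data exactly", {
  x <- 1:7
  f_pow <- fit_trend(x, 2 * x^-1.5, "power")
  expect_equal(unname(f_pow$parameters), c(2, -1.5), tolerance = 1e-6)
  expect_equal(f_pow$r_squared, 1, tolerance = 1e-6)
  f_exp <- fit_trend(x, 1 + 3 * exp(-x / 2), "expdec1")
  expect_equal(f_exp$parameters[["y0"]], 1, tolerance = 1e-5)
  expect_equal(f_exp$parameters[["A1"]], 3, tolerance = 1e-5)
  expect_equal(f_exp$parameters[["t1"]], 2, tolerance = 1e-5)
  expect_equal(f_exp$r_squared, 1, tolerance = 1e-6)
  f_log <- fit_trend(x, 4 - 1.2 * log(x), "logarithmic")
  expect_equal(unname(f_log$parameters), c(4, -1.2), tolerance = 1e-8)
  expect_equal(f_log$r_squared, 1, tolerance = 1e-9)
})

test_that("trend fitting is deterministic and guards degenerate input", {
  set.seed(99)
  x <- 1:10
  y <- 1 + 3 * exp(-x / 2) + rnorm(10, 0, 0.05)
  f1 <- fit_trend(x, y, "expdec1")
  f2 <- fit_trend(x, y, "expdec1")
  expect_identical(f1$parameters, f2$parameters)
  expect_identical(f1$ss_res, f2$ss_res)
  expect_lte(f1$r_squared, 1)
  expect_error(fit_trend(x, rep(2, 10), "power"), "constant")
  expect_error(fit_trend(1:3, c(1, 2, 3), "expdec1"), "at least 4")
  expect_error(fit_trend(0:5, 2^(0:5), "power"), "strictly positive")
})

test_that("noisy exponential-decay fit matches a dense grid-search oracle", {
  set.seed(7)
  x <- 1:10
  y <- 1 + 3 * exp(-x / 2) + rnorm(10, 0, 0.05)
  fit <- fit_trend(x, y, "expdec1")
  oracle_ss <- expdec1_grid_oracle(x, y)
  expect_lt(abs(fit$ss_res - oracle_ss), 1e-6)
  expect_lte(fit$ss_res, oracle_ss + 1e-10)  # refinement never loses to the grid
})

test_that("type-trend wrapper handles ordinal and index abscissae", {
  s <- score_assessments(random_assessments(60, p = 0.9, seed = 2))
  d <- type_distribution(s, typology = malus_typology(TRUE))
  f <- fit_type_trend(d, "power")
  expect_s3_class(f, "trend_fit")
  expect_equal(length(f$x), nrow(d$table))  # zero-weight types kept at y = 0
  f_idx <- fit_type_trend(d, "power", abscissa = "index")
  expect_false(any(f_idx$x == 0))           # index 0 dropped for x > 0 models
})
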