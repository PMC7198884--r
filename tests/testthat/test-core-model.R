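test_that("dimension encoding is the product of its sub-dimensions", {
  expect_identical(encode_dimension(1, 1), 1L)
  expect_identical(encode_dimension(1, 0), 0L)
  expect_identical(encode_dimension(0, 1), 0L)
  expect_identical(encode_dimension(0, 0), 0L)
  # vectorized and multi-sub-dimension forms
  expect_identical(encode_dimension(c(1, 1, 0), c(1, 0, 0)), c(1L, 0L, 0L))
  expect_identical(encode_dimension(1, 1, 1), 1L)
  expect_identical(encode_dimension(1, 1, 0), 0L)
  expect_error(encode_dimension(2, 1), "sub-dimension 1")
  expect_error(encode_dimension(1, NA), "sub-dimension 2")
})

test_that("assessments reduce to the binary dimension vector", {
  expect_identical(unname(reduce_assessment(c(1, 0, 1, 1, 0, 0))),
                   c(0L, 1L, 0L))
  expect_identical(unname(reduce_assessment(rep(1, 6))), c(1L, 1L, 1L))
  expect_identical(unname(reduce_assessment(rep(0, 6))), c(0L, 0L, 0L))
  expect_named(reduce_assessment(rep(1, 6)), c("X", "Y", "Z"))
  # matrix input, generalized shape
  expect_identical(unname(reduce_assessment(matrix(1, 4, 3), d = 4, s = 3)),
                   rep(1L, 4))
  expect_error(reduce_assessment(rep(1, 5)), "expected 6")
  expect_error(reduce_assessment(c(1, 0, 1, 1, 0, 2)), "non-binary")
})

test_that("weight scheme carries strictly dominant powers of two", {
  w <- weight_scheme(3)
  expect_equal(w$coefficients, c(4, 2, 1))
  for (d in 1:10) {
    cf <- weight_scheme(d)$coefficients
    # each coefficient exceeds the sum of all lower-order ones
    for (j in seq_len(d - 1))
      expect_gt(cf[j], sum(cf[(j + 1):d]))
  }
  expect_error(weight_scheme(0), "positive")
})

test_that("symmetry index matches the printed worked examples", {
  expect_equal(symmetry_index(c(1, 1, 1)), 7)
  expect_equal(symmetry_index(c(0, 1, 0)), 2)
  expect_equal(symmetry_index(c(0, 0, 0)), 0)
  expect_error(symmetry_index(c(1, 0), weight_scheme(3)), "length")
  expect_error(symmetry_index(c(1, 2, 0)), "non-binary")
})

test_that("symmetry index equals base-2 conversion for all vectors up to d = 10", {
  for (d in c(1, 3, 7, 10)) {
    w <- weight_scheme(d)
    m <- all_vectors(d)
    got <- apply(m, 1, symmetry_index, w = w)
    expect_equal(got, apply(m, 1, bits_to_int))
  }
})

test_that("classification reproduces the named typology", {
  expect_equal(classify_type(c(1, 1, 1))$label, "I")
  expect_equal(classify_type(c(1, 1, 1))$index, 7L)
  expect_equal(classify_type(c(0, 0, 0))$label, "VII")
  un <- classify_type(c(0, 1, 1))
  expect_equal(un$label, "UNOBSERVED")
  expect_equal(un$index, 3L)
  expect_error(classify_type(c(1, 0, 1, 1)), "d = 3")
  # classify . enumerate is the identity on the typology table
  st <- enumerate_state_space(weight_scheme(3))
  for (i in seq_len(nrow(st))) {
    ct <- classify_type(as.integer(st[i, c("X", "Y", "Z")]))
    expect_equal(ct$label, st$label[i])
    expect_equal(ct$index, st$index[i])
  }
})

test_that("state-space enumeration is complete, sorted and label-consistent", {
  st3 <- enumerate_state_space(weight_scheme(3))
  expect_equal(nrow(st3), 8L)
  expect_equal(st3$index, 7:0)
  expect_equal(st3$label, c("I", "II", "III", "IV", "UNOBSERVED",
                            "V", "VI", "VII"))
  st1 <- enumerate_state_space(weight_scheme(1))
  expect_equal(st1$index, c(1, 0))
  for (d in c(2, 4, 6)) {
    st <- enumerate_state_space(weight_scheme(d))
    expect_equal(nrow(st), 2^d)
    expect_equal(sort(st$index), 0:(2^d - 1))  # a permutation
    oracle <- apply(as.matrix(st[, seq_len(d)]), 1, bits_to_int)
    expect_equal(st$index, oracle)
  }
})

test_that("flower-to-taxon aggregation follows the configured rule", {
  cols <- c("X1", "X2", "Y1", "Y2", "Z1", "Z2")
  mk <- function(n_ones, n) {
    df <- data.frame(taxon_id = "t", matrix(1L, n, 6))
    names(df)[-1] <- cols
    df$X1 <- rep(c(1L, 0L), c(n_ones, n - n_ones))
    df
  }
  expect_equal(aggregate_flowers(mk(30, 30))$X1, 1L)   # unanimous
  expect_equal(aggregate_flowers(mk(16, 30))$X1, 1L)   # 16/30 majority
  expect_equal(aggregate_flowers(mk(15, 30))$X1, 0L)   # tie -> irregular
  expect_equal(aggregate_flowers(mk(29, 30), rule = "unanimity")$X1, 0L)
  expect_equal(aggregate_flowers(mk(12, 30), rule = "proportion",
                                 threshold = 0.4)$X1, 1L)
  expect_equal(aggregate_flowers(mk(11, 30), rule = "proportion",
                                 threshold = 0.4)$X1, 0L)
  # idempotence: aggregating a consensus returns itself
  cons <- aggregate_flowers(mk(16, 30))
  expect_equal(aggregate_flowers(cons)[cols], cons[cols])
  expect_error(aggregate_flowers(mk(1, 1)[0, ]), "no flowers")
  two <- rbind(mk(1, 1), transform(mk(1, 1), taxon_id = "u"))
  expect_error(aggregate_flowers(two), "single taxon")
})

test_that("scoring pipeline handles flower- and taxon-level tables", {
  taxon_tab <- data.frame(taxon_id = c("a", "b"), group = "g",
                          X1 = c(1, 1), X2 = c(1, 0), Y1 = 1, Y2 = 1,
                          Z1 = c(1, 0), Z2 = c(1, 0))
  s <- score_assessments(taxon_tab)
  expect_equal(s$index, c(7, 2))
  expect_equal(s$type, c("I", "V"))
  # replicate flowers: 2/3 majority on X2 for taxon a
  flower_tab <- data.frame(flower_id = paste0("f", 1:6),
                           taxon_id = rep(c("a", "b"), each = 3),
                           X1 = 1, X2 = c(1, 1, 0, 0, 0, 0),
                           Y1 = 1, Y2 = 1, Z1 = 1, Z2 = 1)
  sf <- score_assessments(flower_tab)
  expect_equal(sf$index[sf$taxon_id == "a"], 7)
  expect_equal(sf$index[sf$taxon_id == "b"], 3)
})
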