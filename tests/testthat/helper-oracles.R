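# Independent oracles and small fixture builders.

# Base-2 positional conversion via string parsing; independent of the
# package's weighted-sum route.
bits_to_int <- function(v) strtoi(paste(v, collapse = ""), base = 2L)

# All 2^d binary vectors as a matrix (rows), in no particular order.
all_vectors <- function(d) {
  m <- as.matrix(expand.grid(rep(list(c(0L, 1L)), d)))
  m <- m[, rev(seq_len(d)), drop = FALSE]
  dimnames(m) <- NULL
  m
}

# Pure dense-grid least-squares search for the single-exponential decay
# model y = y0 + A1*exp(-x/t1): the linear parameters are solved exactly by
# QR at each candidate decay constant, so the grid spacing is the only
# approximation.
expdec1_grid_oracle <- function(x, y, t1_grid = seq(0.05, 20, by = 0.001)) {
  best <- Inf
  for (t1 in t1_grid) {
    fit <- qr.solve(cbind(1, exp(-x / t1)), y)
    ss <- sum((y - fit[1L] - fit[2L] * exp(-x / t1))^2)
    if (ss < best) best <- ss
  }
  best
}

# Taxon-level scored records built directly from dimension vectors.
scored_from_vectors <- function(vectors, group = "g",
                                ids = sprintf("%s_%02d", group,
                                              seq_along(vectors))) {
  do.call(rbind, lapply(seq_along(vectors), function(i) {
    v <- vectors[[i]]
    ct <- classify_type(v)
    data.frame(taxon_id = ids[i], group = group,
               X = v[1L], Y = v[2L], Z = v[3L],
               index = ct$index, type = ct$label,
               stringsAsFactors = FALSE)
  }))
}

# Expand scored taxon records back into a sub-dimension assessment table
# (setting both sub-dimensions equal to the dimension value reproduces the
# vector under the product encoding).
progeny_to_assessment <- function(scored) {
  data.frame(taxon_id = scored$taxon_id, group = scored$group,
             X1 = scored$X, X2 = scored$X, Y1 = scored$Y, Y2 = scored$Y,
             Z1 = scored$Z, Z2 = scored$Z, stringsAsFactors = FALSE)
}

# A small random taxon-level assessment table.
random_assessments <- function(n, p = 0.7, group = "g", seed = 1) {
  simulate_cohort(group_spec(group, n, p), seed = seed)
}
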