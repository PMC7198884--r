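#' @keywords internal
"_PACKAGE"

# Dimension and sub-dimension column naming. The floral model uses three
# dimensions (X: corolla-level regularity of petal interval and coplanarity;
# Y: petal-level regularity of shape and size; Z: petal-local regularity of
# curling and wrinkle), each judged through two binary sub-dimensions.
dim_names <- function(d) {
  if (d == 3L) c("X", "Y", "Z") else paste0("D", seq_len(d))
}

subdim_names <- function(d = 3L, s = 2L) {
  paste0(rep(dim_names(d), each = s), rep(seq_len(s), times = d))
}

check_binary <- function(x, field) {
  v <- suppressWarnings(as.numeric(x))
  bad <- is.na(v) | !(v %in% c(0, 1))
  if (any(bad)) {
    stop(sprintf("non-binary value in '%s': %s", field,
                 paste(unique(as.character(x)[bad]), collapse = ", ")),
         call. = FALSE)
  }
  as.integer(v)
}

#' Positional weight scheme for binary-to-decimal conversion
#'
#' Builds the weight coefficients \eqn{C_j = 2^{j-1}} used to convert a
#' binary dimension vector into a decimal symmetry index, where \eqn{j}
#' counts matrix positions from right to left (the last dimension, Z in the
#' three-dimension floral model, has \eqn{j = 1}). Coefficients therefore
#' decrease left to right in matrix order, and each coefficient strictly
#' dominates the sum of all lower ones, which enforces the X > Y > Z
#' priority of the dimensions.
#'
#' @param d Number of dimensions (positive integer; default 3).
#' @return An object of class \code{"weight_scheme"}: a list with elements
#'   \code{d} and \code{coefficients} (in matrix order, left to right).
#' @examples
#' weight_scheme(3)$coefficients  # 4 2 1
#' @export
weight_scheme <- function(d = 3L) {
  d <- as.integer(d)
  if (length(d) != 1L || is.na(d) || d < 1L)
    stop("'d' must be a single positive integer", call. = FALSE)
  coef <- 2^(seq.int(d, 1L) - 1L)
  # dominance: each coefficient exceeds the sum of all lower-order ones
  stopifnot(all(coef[-d] > rev(cumsum(rev(coef)))[-1L] - 1e-9 | d == 1L))
  structure(list(d = d, coefficients = coef), class = "weight_scheme")
}

#' @export
print.weight_scheme <- function(x, ...) {
  cat("Positional weight scheme: d =", x$d, "\n")
  cat("  C_j = 2^(j-1), matrix order:",
      paste(format(x$coefficients, trim = TRUE), collapse = " "), "\n")
  invisible(x)
}

#' Encode one dimension from its binary sub-dimensions
#'
#' A dimension is regular (1) only when every one of its sub-dimensions is
#' regular; the encoding is the product of the sub-dimension flags
#' (X = X1 * X2, and likewise for Y and Z).
#'
#' @param sub1,sub2 Binary flags (0 or 1); vectors are encoded elementwise.
#' @param ... Further sub-dimension flags for models with more than two
#'   sub-dimensions per dimension.
#' @return Integer flag(s): 1 iff all sub-dimensions are 1.
#' @examples
#' encode_dimension(1, 1)  # 1
#' encode_dimension(1, 0)  # 0
#' @export
encode_dimension <- function(sub1, sub2, ...) {
  subs <- list(sub1, sub2, ...)
  subs <- lapply(seq_along(subs), function(i)
    check_binary(subs[[i]], paste0("sub-dimension ", i)))
  Reduce(`*`, subs)
}

#' Reduce a flower assessment to its binary dimension vector
#'
#' Takes the ordered sub-dimension flags of one flower (or one taxon-level
#' consensus) and multiplies within each dimension, yielding the reduced
#' binary vector of length \code{d}. Sub-dimension order is fixed:
#' dimensions in matrix order (X before Y before Z), and within a dimension
#' sub-dimension 1 before 2.
#'
#' @param subdims Numeric vector of length \code{d * s} in the fixed order,
#'   or a \code{d} x \code{s} binary matrix (one row per dimension).
#' @param d,s Dimension and sub-dimension counts (defaults 3 and 2).
#' @return Integer vector of length \code{d}, named by dimension.
#' @examples
#' reduce_assessment(c(1, 0, 1, 1, 0, 0))  # X=0 Y=1 Z=0
#' @export
reduce_assessment <- function(subdims, d = 3L, s = 2L) {
  if (is.matrix(subdims)) {
    if (nrow(subdims) != d || ncol(subdims) != s)
      stop(sprintf("expected a %d x %d sub-dimension matrix", d, s),
           call. = FALSE)
    m <- subdims
  } else {
    if (length(subdims) != d * s)
      stop(sprintf("expected %d sub-dimension values (d = %d, s = %d), got %d",
                   d * s, d, s, length(subdims)), call. = FALSE)
    m <- matrix(subdims, nrow = d, ncol = s, byrow = TRUE)
  }
  nm <- subdim_names(d, s)
  for (j in seq_len(d * s)) check_binary(m[ceiling(j / s), (j - 1L) %% s + 1L], nm[j])
  v <- as.integer(apply(m, 1L, prod))
  names(v) <- dim_names(d)
  v
}

#' Symmetry index of a binary dimension vector
#'
#' Converts the binary dimension vector to its decimal symmetry index (SI)
#' under positional weights: \eqn{SI = \sum_j v_j C_j} with
#' \eqn{C_j = 2^{j-1}} counted from the right. For the three-dimension model
#' this is \eqn{SI = X \cdot 2^2 + Y \cdot 2^1 + Z \cdot 2^0}, ranging 0-7
#' points; higher values mean a more regular, more symmetric corolla.
#'
#' @param v Binary vector of length \code{w$d}.
#' @param w A \code{\link{weight_scheme}}; defaults to one matching
#'   \code{length(v)}.
#' @return The symmetry index in points (non-negative number; distinct
#'   vectors map to distinct indices).
#' @examples
#' symmetry_index(c(1, 1, 1))  # 7
#' symmetry_index(c(0, 1, 0))  # 2
#' @export
symmetry_index <- function(v, w = weight_scheme(length(v))) {
  v <- check_binary(v, "dimension vector")
  if (length(v) != w$d)
    stop(sprintf("dimension vector has length %d but the weight scheme has d = %d",
                 length(v), w$d), call. = FALSE)
  sum(v * w$coefficients)
}

# Full state table for the three-dimension model, in descending SI order.
# [0 1 1] (SI 3) is a first-class state carrying the UNOBSERVED label: it is
# a valid point of the model that the original Malus survey simply never
# recorded in any taxon.
full_typology <- function() {
  tab <- data.frame(
    label = c("I", "II", "III", "IV", "UNOBSERVED", "V", "VI", "VII"),
    X = c(1L, 1L, 1L, 1L, 0L, 0L, 0L, 0L),
    Y = c(1L, 1L, 0L, 0L, 1L, 1L, 0L, 0L),
    Z = c(1L, 0L, 1L, 0L, 1L, 0L, 1L, 0L),
    stringsAsFactors = FALSE
  )
  tab$index <- as.integer(tab$X * 4L + tab$Y * 2L + tab$Z)
  tab[order(-tab$index), , drop = FALSE]
}

#' The named symmetry typology of the three-dimension model
#'
#' The seven named symmetry types, ordered by descending symmetry index:
#' I [1 1 1] (7), II [1 1 0] (6), III [1 0 1] (5), IV [1 0 0] (4),
#' V [0 1 0] (2), VI [0 0 1] (1) and VII [0 0 0] (0). The eighth state
#' [0 1 1] (3) was observed in no surveyed taxon and carries the label
#' \code{UNOBSERVED}; set \code{include_unobserved = TRUE} to list it.
#'
#' @param include_unobserved Include the [0 1 1] state (default FALSE).
#' @return A data frame with columns \code{label}, \code{X}, \code{Y},
#'   \code{Z}, \code{index}, ordered by descending index.
#' @export
malus_typology <- function(include_unobserved = FALSE) {
  tab <- full_typology()
  if (!include_unobserved) tab <- tab[tab$label != "UNOBSERVED", , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Classify a dimension vector into a symmetry type
#'
#' Maps a three-dimensional binary vector to its named symmetry type and
#' index. The typology is defined only for the three-dimension model; for
#' other \code{d} the index is still computable via
#' \code{\link{symmetry_index}} but no type label exists.
#'
#' @param v Binary vector of length 3.
#' @return An object of class \code{"symmetry_type"}: a list with
#'   \code{label}, \code{vector} and \code{index}.
#' @examples
#' classify_type(c(1, 1, 1))$label  # "I"
#' classify_type(c(0, 1, 1))$label  # "UNOBSERVED"
#' @export
classify_type <- function(v) {
  v <- check_binary(v, "dimension vector")
  if (length(v) != 3L)
    stop("the symmetry typology is defined only for d = 3; ",
         "use symmetry_index() for other dimension counts", call. = FALSE)
  tab <- full_typology()
  hit <- tab[tab$X == v[1L] & tab$Y == v[2L] & tab$Z == v[3L], ]
  structure(list(label = hit$label,
                 vector = stats::setNames(v, c("X", "Y", "Z")),
                 index = hit$index),
            class = "symmetry_type")
}

#' @export
print.symmetry_type <- function(x, ...) {
  cat(sprintf("Symmetry type %s [%s], SI = %d points\n",
              x$label, paste(x$vector, collapse = " "), x$index))
  invisible(x)
}

#' Enumerate the full binary state space under a weight scheme
#'
#' Materializes all \eqn{2^d} dimension vectors with their symmetry indices
#' (and, for \code{d = 3}, type labels), sorted by descending index. The
#' indices are a permutation of \eqn{0 \ldots 2^d - 1}.
#'
#' @param w A \code{\link{weight_scheme}}.
#' @return Data frame with one column per dimension, plus \code{index} and
#'   \code{label} (\code{NA} when \code{d != 3}).
#' @examples
#' enumerate_state_space(weight_scheme(3))
#' @export
enumerate_state_space <- function(w = weight_scheme(3L)) {
  d <- w$d
  grid <- as.matrix(expand.grid(rep(list(c(0L, 1L)), d))[, d:1, drop = FALSE])
  colnames(grid) <- dim_names(d)
  idx <- as.vector(grid %*% w$coefficients)
  ord <- order(-idx)
  out <- as.data.frame(grid[ord, , drop = FALSE])
  out$index <- idx[ord]
  out$label <- if (d == 3L) {
    vapply(seq_len(nrow(out)),
           function(i) classify_type(as.integer(out[i, seq_len(3L)]))$label,
           character(1L))
  } else NA_character_
  rownames(out) <- NULL
  out
}

#' Aggregate replicate flower assessments into a taxon-level consensus
#'
#' Reduces the replicate flowers judged for one taxon (the survey scored
#' about thirty per taxon) to a single consensus assessment, sub-dimension
#' by sub-dimension. Under the default \code{"majority"} rule a consensus
#' sub-dimension is 1 iff strictly more than half the flowers show 1, with
#' exact ties resolved to 0 (conservative: irregular). \code{"unanimity"}
#' requires every flower to show 1; \code{"proportion"} requires the
#' observed fraction of 1s to reach \code{threshold}.
#'
#' @param flowers Data frame of flower-level assessments for one taxon,
#'   containing the sub-dimension columns (and optionally \code{taxon_id},
#'   which must be constant).
#' @param rule One of \code{"majority"}, \code{"unanimity"},
#'   \code{"proportion"}.
#' @param threshold Proportion threshold for \code{rule = "proportion"}.
#' @param d,s Dimension and sub-dimension counts.
#' @return A one-row data frame: the taxon-level consensus assessment.
#' @export
aggregate_flowers <- function(flowers, rule = c("majority", "unanimity", "proportion"),
                              threshold = 0.5, d = 3L, s = 2L) {
  rule <- match.arg(rule)
  if (is.null(flowers) || nrow(flowers) == 0L)
    stop("no flowers to aggregate", call. = FALSE)
  if ("taxon_id" %in% names(flowers) &&
      length(unique(flowers$taxon_id)) > 1L)
    stop("aggregate_flowers() requires a single taxon; got: ",
         paste(unique(flowers$taxon_id), collapse = ", "), call. = FALSE)
  cols <- subdim_names(d, s)
  missing_cols <- setdiff(cols, names(flowers))
  if (length(missing_cols))
    stop("missing sub-dimension columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  prop <- vapply(cols, function(cc)
    mean(check_binary(flowers[[cc]], cc)), numeric(1L))
  consensus <- switch(rule,
    majority   = as.integer(prop > 0.5),
    unanimity  = as.integer(prop == 1),
    proportion = as.integer(prop >= threshold))
  out <- if ("taxon_id" %in% names(flowers))
    data.frame(taxon_id = flowers$taxon_id[1L], stringsAsFactors = FALSE)
  else data.frame(row.names = 1L)
  if ("group" %in% names(flowers)) out$group <- flowers$group[1L]
  out[cols] <- as.list(consensus)
  rownames(out) <- NULL
  out
}

#' Score an assessment table into per-taxon symmetry records
#'
#' Runs the full scoring pipeline on an assessment table: aggregates
#' flower-level replicates to one consensus per taxon (when a
#' \code{flower_id} column is present), reduces each consensus to its
#' binary dimension vector, converts it to the symmetry index, and (for
#' the three-dimension model) attaches the type label.
#'
#' @param assessments Data frame with columns \code{taxon_id}, optionally
#'   \code{flower_id} and \code{group}, and the sub-dimension columns
#'   (X1, X2, Y1, Y2, Z1, Z2 for the default model).
#' @param config A \code{\link{run_config}} controlling the model shape and
#'   aggregation rule.
#' @return Data frame with one row per taxon: \code{taxon_id}, \code{group}
#'   (if present), the dimension values, \code{index} and \code{type}.
#' @examples
#' a <- data.frame(taxon_id = "Rudolph", X1 = 1, X2 = 0,
#'                 Y1 = 1, Y2 = 1, Z1 = 0, Z2 = 0)
#' score_assessments(a)
#' @export
score_assessments <- function(assessments, config = run_config()) {
  d <- config$d; s <- config$s
  cols <- subdim_names(d, s)
  missing_cols <- setdiff(c("taxon_id", cols), names(assessments))
  if (length(missing_cols))
    stop("assessment table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if ("flower_id" %in% names(assessments)) {
    pieces <- split(assessments, assessments$taxon_id)
    pieces <- pieces[unique(assessments$taxon_id)]  # keep input order
    consensus <- do.call(rbind, lapply(pieces, aggregate_flowers,
                                       rule = config$aggregation,
                                       threshold = config$threshold,
                                       d = d, s = s))
  } else {
    consensus <- assessments
  }
  w <- weight_scheme(d)
  dimv <- t(vapply(seq_len(nrow(consensus)), function(i)
    reduce_assessment(as.numeric(consensus[i, cols]), d = d, s = s),
    integer(d)))
  colnames(dimv) <- dim_names(d)
  out <- data.frame(taxon_id = consensus$taxon_id, stringsAsFactors = FALSE)
  if ("group" %in% names(consensus)) out$group <- consensus$group
  out <- cbind(out, as.data.frame(dimv))
  out$index <- as.vector(dimv %*% w$coefficients)
  out$type <- if (d == 3L)
    vapply(seq_len(nrow(dimv)),
           function(i) classify_type(dimv[i, ])$label, character(1L))
  else NA_character_
  rownames(out) <- NULL
  out
}
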