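# Group-level analytics over scored taxon records: type-weight
# distributions, distribution CV, integrated (mean) symmetry index,
# between-group weight ratios, per-dimension regularity, and decay-trend
# curve fits.

#' Coefficient of variation of a type-count distribution
#'
#' Standard deviation of the per-type counts divided by their mean, used to
#' quantify how unbalanced a group's spread over the symmetry types is.
#' Scale-invariant: counts and percentage weights give the same value. The
#' estimator is configurable because the original survey does not state its
#' convention: \code{"sample"} uses the n-1 denominator, \code{"population"}
#' uses n.
#'
#' @param counts Non-negative counts (or weights), one per typology entry;
#'   at least two entries, not all zero.
#' @param estimator \code{"sample"} (default) or \code{"population"}.
#' @return The CV as a dimensionless ratio.
#' @examples
#' distribution_cv(c(2, 1, 1))                  # 0.4330
#' distribution_cv(c(2, 1, 1), "population")    # 0.3536
#' @export
distribution_cv <- function(counts, estimator = c("sample", "population")) {
  estimator <- match.arg(estimator)
  if (length(counts) < 2L)
    stop("need at least two typology entries", call. = FALSE)
  if (any(counts < 0) || any(is.na(counts)))
    stop("counts must be non-negative and complete", call. = FALSE)
  if (sum(counts) == 0)
    stop("all counts are zero; CV is undefined", call. = FALSE)
  n <- length(counts)
  s <- if (estimator == "sample") stats::sd(counts)
       else sqrt(sum((counts - mean(counts))^2) / n)
  s / mean(counts)
}

#' Integrated (mean) symmetry index of a group
#'
#' Arithmetic mean of the member symmetry indices; equal to the
#' distribution-weighted mean \eqn{\sum_k (w_k/100) SI_k} computed from the
#' group's type distribution.
#'
#' @param records Scored taxon records (a data frame with an \code{index}
#'   column, as returned by \code{\link{score_assessments}}), or a numeric
#'   vector of indices.
#' @return Mean symmetry index in points.
#' @export
mean_symmetry_index <- function(records) {
  idx <- if (is.data.frame(records)) records$index else records
  if (length(idx) == 0L) stop("no records", call. = FALSE)
  if (any(is.na(idx))) stop("missing symmetry indices", call. = FALSE)
  mean(idx)
}

#' Type distribution of a group
#'
#' Tabulates one group's scored records over the symmetry typology:
#' per-type counts and percentage weights (types with no members included
#' at weight 0), the coefficient of variation of the counts, and the
#' integrated (mean) symmetry index. Weights sum to 100.
#'
#' @param records Scored taxon records (see \code{\link{score_assessments}}).
#' @param group Group label to tabulate; \code{NULL} uses all records.
#' @param typology Ordered typology table (default
#'   \code{\link{malus_typology}()}).
#' @param cv_estimator Passed to \code{\link{distribution_cv}}.
#' @return An object of class \code{"type_distribution"}: list with
#'   \code{group}, \code{n}, \code{table} (label, index, count, weight),
#'   \code{cv}, \code{mean_index}.
#' @export
type_distribution <- function(records, group = NULL,
                              typology = malus_typology(),
                              cv_estimator = c("sample", "population")) {
  cv_estimator <- match.arg(cv_estimator)
  if (!is.null(group)) {
    if (!"group" %in% names(records))
      stop("records have no 'group' column", call. = FALSE)
    records <- records[records$group == group, , drop = FALSE]
  }
  if (nrow(records) == 0L)
    stop("empty group", if (!is.null(group)) paste0(": '", group, "'"),
         call. = FALSE)
  outside <- setdiff(unique(records$type), typology$label)
  if (length(outside))
    stop("record type(s) outside the typology: ",
         paste(outside, collapse = ", "), call. = FALSE)
  counts <- vapply(typology$label,
                   function(l) sum(records$type == l), integer(1L))
  n <- nrow(records)
  tab <- data.frame(label = typology$label, index = typology$index,
                    count = counts, weight = 100 * counts / n,
                    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  structure(list(group = if (is.null(group)) NA_character_ else group,
                 n = n, table = tab,
                 cv = distribution_cv(counts, cv_estimator),
                 mean_index = mean_symmetry_index(records)),
            class = "type_distribution")
}

#' @export
print.type_distribution <- function(x, ...) {
  cat(sprintf("Type distribution%s: n = %d, CV = %.4f, mean SI = %.2f points\n",
              if (is.na(x$group)) "" else paste0(" [", x$group, "]"),
              x$n, x$cv, x$mean_index))
  tab <- x$table
  tab$weight <- sprintf("%.2f%%", tab$weight)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Between-group weight ratio table
#'
#' For each symmetry type, the ratio \eqn{P_A/P_B} of its percentage weight
#' between two groups, the relative weight \eqn{|P_A/P_B - 1|}, and which
#' group the type is over-represented in. Ratios with \eqn{P_B = 0} are
#' reported as undefined (NA, flagged) rather than infinite.
#'
#' @param dist_a,dist_b \code{\link{type_distribution}} objects over the
#'   same typology.
#' @return An object of class \code{"weight_ratio_table"}: data frame with
#'   columns \code{label}, \code{index}, \code{p_a}, \code{p_b},
#'   \code{ratio}, \code{relative_weight}, \code{direction}, \code{defined},
#'   with the group labels as attributes.
#' @export
weight_ratio <- function(dist_a, dist_b) {
  if (!identical(dist_a$table$label, dist_b$table$label))
    stop("the two distributions use different typologies", call. = FALSE)
  pa <- dist_a$table$weight
  pb <- dist_b$table$weight
  defined <- pb > 0
  ratio <- ifelse(defined, pa / pb, NA_real_)
  direction <- ifelse(!defined, NA_character_,
                      ifelse(ratio > 1, "A", ifelse(ratio < 1, "B", "equal")))
  out <- data.frame(label = dist_a$table$label, index = dist_a$table$index,
                    p_a = pa, p_b = pb, ratio = ratio,
                    relative_weight = ifelse(defined, abs(ratio - 1), NA_real_),
                    direction = direction, defined = defined,
                    stringsAsFactors = FALSE)
  attr(out, "group_a") <- dist_a$group
  attr(out, "group_b") <- dist_b$group
  class(out) <- c("weight_ratio_table", "data.frame")
  out
}

#' @export
print.weight_ratio_table <- function(x, ...) {
  cat(sprintf("Weight ratio P_%s / P_%s per symmetry type\n",
              attr(x, "group_a"), attr(x, "group_b")))
  y <- as.data.frame(x)
  y$p_a <- sprintf("%.2f%%", y$p_a); y$p_b <- sprintf("%.2f%%", y$p_b)
  print(y, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Per-dimension regularity weights of two groups
#'
#' For each dimension (X, Y, Z), the fraction of taxa in each group whose
#' dimension value is 1 (the dimension-regularity weight), the cross-group
#' ratio per dimension, and the pooled irregular fraction (both groups
#' combined) per dimension.
#'
#' @param records Scored taxon records.
#' @param groups Character vector of two group labels (group1 / group2 for
#'   the ratio).
#' @return An object of class \code{"dimension_regularity"}: list with
#'   \code{groups}, \code{fractions} (2 x d matrix), \code{ratio} (length-d
#'   vector, group1/group2, NA where group2's fraction is 0), and
#'   \code{pooled_irregular}.
#' @export
dimension_regularity <- function(records, groups) {
  if (length(groups) != 2L) stop("'groups' must name two groups", call. = FALSE)
  dims <- intersect(c("X", "Y", "Z", paste0("D", 1:32)), names(records))
  if (!length(dims)) stop("records carry no dimension columns", call. = FALSE)
  sub <- lapply(groups, function(g) {
    r <- records[records$group == g, , drop = FALSE]
    if (nrow(r) == 0L) stop("empty group: '", g, "'", call. = FALSE)
    r
  })
  fr <- t(vapply(sub, function(r)
    vapply(dims, function(dd) mean(r[[dd]] == 1), numeric(1L)),
    numeric(length(dims))))
  dimnames(fr) <- list(groups, dims)
  pooled <- do.call(rbind, sub)
  structure(list(groups = groups, fractions = fr,
                 ratio = ifelse(fr[2L, ] > 0, fr[1L, ] / fr[2L, ], NA_real_),
                 pooled_irregular = vapply(dims, function(dd)
                   mean(pooled[[dd]] == 0), numeric(1L))),
            class = "dimension_regularity")
}

#' @export
print.dimension_regularity <- function(x, ...) {
  cat("Dimension regularity weights (fraction of taxa with value 1)\n")
  print(round(x$fractions, 4))
  cat("Ratio", x$groups[1L], "/", x$groups[2L], ":",
      paste(sprintf("%s = %.2f", names(x$ratio), x$ratio), collapse = ", "), "\n")
  cat("Pooled irregular fraction:",
      paste(sprintf("%s = %.2f%%", names(x$pooled_irregular),
                    100 * x$pooled_irregular), collapse = ", "), "\n")
  invisible(x)
}

# --- trend fitting ----------------------------------------------------------

trend_models <- function() c("power", "expdec1", "logarithmic")

# Profiled deterministic grid search. For each candidate of the nonlinear
# parameter the remaining parameters enter linearly and are solved exactly,
# so the grid is one-dimensional and the search deterministic.
grid_start <- function(x, y, model) {
  if (model == "power") {
    bs <- seq(-6, 6, by = 0.01)
    best <- NULL
    for (b in bs) {
      u <- x^b
      a <- sum(y * u) / sum(u * u)
      ss <- sum((y - a * u)^2)
      if (is.null(best) || ss < best$ss - 1e-10) best <- list(a = a, b = b, ss = ss)
    }
    best
  } else if (model == "expdec1") {
    span <- max(x) - min(x)
    if (span <= 0) stop("degenerate x for expdec1 fit", call. = FALSE)
    t1s <- span * 10^seq(-2, 2, by = 0.02)
    best <- NULL
    for (t1 in t1s) {
      e <- exp(-x / t1)
      fit <- stats::lm.fit(cbind(1, e), y)
      ss <- sum(fit$residuals^2)
      if (is.null(best) || ss < best$ss - 1e-10)
        best <- list(y0 = fit$coefficients[[1L]], A1 = fit$coefficients[[2L]],
                     t1 = t1, ss = ss)
    }
    best
  } else stop("no grid needed for model ", model)
}

#' Fit a decreasing-trend model to type-weight data
#'
#' Least-squares fit of one of three trend families used to describe how
#' type weights decay across the typology: power \eqn{y = a x^b},
#' single-exponential decay (ExpDec1) \eqn{y = y_0 + A_1 e^{-x/t_1}}, or
#' logarithmic \eqn{y = a + b \ln x}. The logarithmic model is solved in
#' closed form; the nonlinear families use a deterministic profiled grid
#' over the nonlinear parameter (exponent, or decay constant scaled to the
#' x-range) followed by Levenberg-Marquardt refinement, so repeated fits
#' are identical. Reports \eqn{R^2 = 1 - SS_{res}/SS_{tot}}.
#'
#' @param x Predictor values (strictly positive for power and logarithmic).
#' @param y Response values.
#' @param model One of \code{"power"}, \code{"expdec1"},
#'   \code{"logarithmic"}.
#' @return An object of class \code{"trend_fit"}: list with \code{model},
#'   \code{parameters}, \code{r_squared}, \code{ss_res}, \code{fitted},
#'   \code{x}, \code{y}.
#' @examples
#' f <- fit_trend(1:7, 2 * (1:7)^-1.5, "power")
#' f$r_squared  # 1
#' @export
fit_trend <- function(x, y, model = c("power", "expdec1", "logarithmic")) {
  model <- match.arg(model)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  npar <- switch(model, power = 2L, logarithmic = 2L, expdec1 = 3L)
  if (length(x) < npar + 1L)
    stop(sprintf("need at least %d points for the %s model", npar + 1L, model),
         call. = FALSE)
  if (model %in% c("power", "logarithmic") && any(x <= 0))
    stop("x must be strictly positive for the ", model, " model", call. = FALSE)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0)
    stop("constant response: the ", model, " trend fit is degenerate",
         call. = FALSE)

  if (model == "logarithmic") {
    fit <- stats::lm(y ~ log(x))
    pars <- c(a = unname(stats::coef(fit)[1L]), b = unname(stats::coef(fit)[2L]))
    fitted_y <- unname(stats::fitted(fit))
  } else {
    st <- grid_start(x, y, model)
    form <- switch(model,
      power   = y ~ a * x^b,
      expdec1 = y ~ y0 + A1 * exp(-x / t1))
    start <- switch(model,
      power   = list(a = st$a, b = st$b),
      expdec1 = list(y0 = st$y0, A1 = st$A1, t1 = st$t1))
    refined <- tryCatch(
      minpack.lm::nlsLM(form, data = data.frame(x = x, y = y), start = start,
                        control = minpack.lm::nls.lm.control(
                          ftol = 1e-12, ptol = 1e-12, maxiter = 500)),
      error = function(e) NULL)
    if (!is.null(refined) &&
        sum(stats::resid(refined)^2) <= st$ss + 1e-10) {
      pars <- stats::coef(refined)
      fitted_y <- unname(stats::fitted(refined))
    } else {
      pars <- unlist(start)
      fitted_y <- switch(model,
        power   = st$a * x^st$b,
        expdec1 = st$y0 + st$A1 * exp(-x / st$t1))
    }
  }
  ss_res <- sum((y - fitted_y)^2)
  structure(list(model = model, parameters = pars,
                 r_squared = 1 - ss_res / ss_tot, ss_res = ss_res,
                 fitted = fitted_y, x = x, y = y),
            class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  eqn <- switch(x$model,
    power       = sprintf("y = %.4g * x^%.4g",
                          x$parameters[["a"]], x$parameters[["b"]]),
    expdec1     = sprintf("y = %.4g + %.4g * exp(-x/%.4g)",
                          x$parameters[["y0"]], x$parameters[["A1"]],
                          x$parameters[["t1"]]),
    logarithmic = sprintf("y = %.4g + %.4g * ln(x)",
                          x$parameters[["a"]], x$parameters[["b"]]))
  cat(sprintf("Trend fit (%s): %s,  R^2 = %.4f\n", x$model, eqn, x$r_squared))
  invisible(x)
}

#' Fit a trend to a type distribution's weights
#'
#' Convenience wrapper: fits \code{\link{fit_trend}} to a group's type
#' weights (or to a ratio table's defined ratios) against either the
#' ordinal type position (1, 2, ...; the default) or the type's symmetry
#' index in points. Zero-weight types are included at y = 0.
#'
#' @param dist A \code{\link{type_distribution}} or
#'   \code{\link{weight_ratio}} table.
#' @param model Trend family (see \code{\link{fit_trend}}).
#' @param abscissa \code{"ordinal"} (default) or \code{"index"}. With
#'   \code{"index"}, zero-index types are dropped for the power and
#'   logarithmic families (which require x > 0).
#' @return A \code{"trend_fit"}.
#' @export
fit_type_trend <- function(dist, model = c("power", "expdec1", "logarithmic"),
                           abscissa = c("ordinal", "index")) {
  model <- match.arg(model)
  abscissa <- match.arg(abscissa)
  if (inherits(dist, "type_distribution")) {
    y <- dist$table$weight
    xi <- dist$table$index
  } else if (inherits(dist, "weight_ratio_table")) {
    keep <- dist$defined
    y <- dist$ratio[keep]
    xi <- dist$index[keep]
  } else stop("unsupported input for fit_type_trend()", call. = FALSE)
  x <- if (abscissa == "ordinal") seq_along(y) else xi
  if (abscissa == "index" && model %in% c("power", "logarithmic")) {
    keep <- x > 0
    x <- x[keep]; y <- y[keep]
  }
  fit_trend(x, y, model)
}
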