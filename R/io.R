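# Table readers/writers with row-level validation, configuration handling,
# and the end-to-end report bundle.

#' Run configuration
#'
#' Collects every tunable of the pipeline with defaults reproducing the
#' three-dimension, two-sub-dimension floral model.
#'
#' @param d,s Dimension and sub-dimension counts (defaults 3, 2).
#' @param aggregation Flower-to-taxon consensus rule
#'   (\code{"majority"} default, \code{"unanimity"}, \code{"proportion"}).
#' @param threshold Proportion threshold when
#'   \code{aggregation = "proportion"}.
#' @param include_unobserved Include the [0 1 1] state in the typology used
#'   for distributions (default FALSE, matching the survey's seven types).
#' @param cv_estimator \code{"sample"} (n-1, default) or
#'   \code{"population"}.
#' @param fit_abscissa \code{"ordinal"} (default) or \code{"index"} x-axis
#'   for trend fits over the typology.
#' @param seed Integer seed recorded in (and used by) seeded stages.
#' @param out Output directory for report files (optional).
#' @param verbose Logical.
#' @return An object of class \code{"run_config"}.
#' @export
run_config <- function(d = 3L, s = 2L,
                       aggregation = c("majority", "unanimity", "proportion"),
                       threshold = 0.5, include_unobserved = FALSE,
                       cv_estimator = c("sample", "population"),
                       fit_abscissa = c("ordinal", "index"),
                       seed = NULL, out = NULL, verbose = FALSE) {
  structure(list(d = as.integer(d), s = as.integer(s),
                 aggregation = match.arg(aggregation),
                 threshold = threshold,
                 include_unobserved = isTRUE(include_unobserved),
                 cv_estimator = match.arg(cv_estimator),
                 fit_abscissa = match.arg(fit_abscissa),
                 seed = if (is.null(seed)) NULL else as.integer(seed),
                 out = out, verbose = isTRUE(verbose)),
            class = "run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' Unknown keys are rejected; missing keys take the
#' \code{\link{run_config}} defaults.
#'
#' @param path Path to a \code{.yaml}/\code{.yml} or \code{.json} file.
#' @return A \code{"run_config"}.
#' @export
read_config <- function(path) {
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(formals(run_config)))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(run_config, vals)
}

#' Read and validate an assessment table
#'
#' Reads a flower- or taxon-level assessment CSV/TSV. The header must
#' contain \code{taxon_id} and the sub-dimension columns (flower-level
#' tables also carry \code{flower_id}; \code{group} is optional). Every
#' sub-dimension cell must be 0 or 1 and flower ids must be unique; rows
#' failing validation are rejected and reported with their file line
#' numbers (attribute \code{"rejected"}), while valid rows are returned.
#' A malformed header is fatal.
#'
#' @param path File path.
#' @param sep Field delimiter (\code{","} default, \code{"\t"} accepted).
#' @param config A \code{\link{run_config}} fixing the model shape.
#' @param quiet Suppress the rejected-row warning.
#' @return Validated assessment data frame; attribute \code{"rejected"}
#'   holds a data frame (line, column, value, message) of rejected rows.
#' @export
read_assessments <- function(path, sep = ",", config = run_config(),
                             quiet = FALSE) {
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, comment.char = "",
                           colClasses = "character")
  cols <- subdim_names(config$d, config$s)
  missing_cols <- setdiff(c("taxon_id", cols), names(raw))
  if (length(missing_cols))
    stop("malformed header; missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  problems <- data.frame(line = integer(), column = character(),
                         value = character(), message = character(),
                         stringsAsFactors = FALSE)
  bad_rows <- rep(FALSE, nrow(raw))
  for (cc in cols) {
    v <- suppressWarnings(as.numeric(raw[[cc]]))
    bad <- is.na(v) | !(v %in% c(0, 1))
    if (any(bad)) {
      problems <- rbind(problems, data.frame(
        line = which(bad) + 1L, column = cc, value = raw[[cc]][bad],
        message = sprintf("non-binary value '%s' in column %s",
                          raw[[cc]][bad], cc),
        stringsAsFactors = FALSE))
      bad_rows <- bad_rows | bad
    }
  }
  if ("flower_id" %in% names(raw)) {
    dup <- duplicated(raw$flower_id)
    if (any(dup)) {
      problems <- rbind(problems, data.frame(
        line = which(dup) + 1L, column = "flower_id",
        value = raw$flower_id[dup],
        message = sprintf("duplicate flower_id '%s'", raw$flower_id[dup]),
        stringsAsFactors = FALSE))
      bad_rows <- bad_rows | dup
    }
  }
  out <- raw[!bad_rows, , drop = FALSE]
  for (cc in cols) out[[cc]] <- as.integer(as.numeric(out[[cc]]))
  rownames(out) <- NULL
  attr(out, "rejected") <- problems
  if (nrow(problems) && !quiet)
    warning(sprintf("%d row(s) rejected during validation; see attr(x, 'rejected')",
                    sum(bad_rows)), call. = FALSE)
  out
}

#' Write an assessment or scored table to CSV
#'
#' @param x Data frame.
#' @param path Output path.
#' @param sep Field delimiter.
#' @export
write_assessments <- function(x, path, sep = ",") {
  attr(x, "rejected") <- NULL
  utils::write.table(x, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full analysis and assemble a report bundle
#'
#' Scores the assessment table, tabulates the type distribution of each
#' group, and -- when exactly two groups are compared -- computes the
#' between-group weight-ratio table, the per-dimension regularity weights,
#' and decreasing-trend fits (power fit to the first group's type weights,
#' ExpDec1 fit to the weight ratios, logarithmic fit to the second
#' group's weights, over the configured abscissa; a fit that is degenerate
#' for the data at hand is recorded as unavailable rather than failing the
#' run). A pedigree, when supplied, is validated against the progeny
#' symmetry-dominance rule. The bundle is deterministic for a fixed input
#' and configuration.
#'
#' @param assessments Assessment data frame (flower- or taxon-level).
#' @param groups Character vector of group labels to analyse; default: the
#'   distinct values of the \code{group} column, in order of appearance.
#' @param pedigree Optional pedigree data frame.
#' @param config A \code{\link{run_config}}.
#' @return An object of class \code{"corsym_report"}.
#' @export
run_report <- function(assessments, groups = NULL, pedigree = NULL,
                       config = run_config()) {
  scored <- score_assessments(assessments, config)
  typ <- malus_typology(include_unobserved = config$include_unobserved)
  if (is.null(groups) && "group" %in% names(scored))
    groups <- unique(scored$group)
  dists <- NULL; ratio <- NULL; regularity <- NULL; fits <- NULL
  if (!is.null(groups) && length(groups) >= 1L) {
    dists <- lapply(groups, function(g)
      type_distribution(scored, g, typology = typ,
                        cv_estimator = config$cv_estimator))
    names(dists) <- groups
    if (length(groups) == 2L) {
      ratio <- weight_ratio(dists[[1L]], dists[[2L]])
      regularity <- dimension_regularity(scored, groups)
      safe_fit <- function(obj, model) tryCatch(
        fit_type_trend(obj, model, abscissa = config$fit_abscissa),
        error = function(e) list(model = model, error = conditionMessage(e)))
      fits <- list(group1_power = safe_fit(dists[[1L]], "power"),
                   ratio_expdec1 = safe_fit(ratio, "expdec1"),
                   group2_logarithmic = safe_fit(dists[[2L]], "logarithmic"))
    }
  }
  ped_report <- if (!is.null(pedigree)) check_progeny_rule(scored, pedigree)
  structure(list(config = config,
                 n_taxa = nrow(scored),
                 scored = scored,
                 typology = typ,
                 distributions = dists,
                 weight_ratio = ratio,
                 dimension_regularity = regularity,
                 trend_fits = fits,
                 pedigree = ped_report,
                 package_version = as.character(utils::packageVersion("corsym"))),
            class = "corsym_report")
}

# Serialize a report to plain lists for stable JSON.
report_to_list <- function(report) {
  dist_l <- function(dd) list(group = dd$group, n = dd$n,
                              labels = dd$table$label,
                              indices = dd$table$index,
                              counts = dd$table$count,
                              weights = dd$table$weight,
                              cv = dd$cv, mean_index = dd$mean_index)
  fit_l <- function(ff) {
    if (is.null(ff)) return(NULL)
    if (!inherits(ff, "trend_fit")) return(ff)  # recorded fit failure
    list(model = ff$model, parameters = as.list(ff$parameters),
         r_squared = ff$r_squared, ss_res = ff$ss_res)
  }
  out <- list(
    config = report$config[c("d", "s", "aggregation", "threshold",
                             "include_unobserved", "cv_estimator",
                             "fit_abscissa")],
    seed = report$config$seed,
    package_version = report$package_version,
    n_taxa = report$n_taxa,
    scored = report$scored,
    distributions = lapply(report$distributions, dist_l),
    weight_ratio = if (!is.null(report$weight_ratio))
      as.data.frame(report$weight_ratio),
    dimension_regularity = if (!is.null(report$dimension_regularity)) list(
      groups = report$dimension_regularity$groups,
      fractions = apply(report$dimension_regularity$fractions, 1L,
                        as.list, simplify = FALSE),
      ratio = as.list(report$dimension_regularity$ratio),
      pooled_irregular = as.list(report$dimension_regularity$pooled_irregular)),
    trend_fits = lapply(report$trend_fits, fit_l),
    pedigree = if (!is.null(report$pedigree)) list(
      records = report$pedigree$records,
      summary = report$pedigree$summary))
  out[!vapply(out, is.null, logical(1L))]
}

#' Machine-readable report JSON
#'
#' Deterministic JSON rendering of a report bundle: identical inputs and
#' configuration give byte-identical strings.
#'
#' @param report A \code{"corsym_report"}.
#' @return A JSON string (class \code{json}).
#' @export
report_json <- function(report) {
  jsonlite::toJSON(report_to_list(report), auto_unbox = TRUE, digits = NA,
                   null = "null", na = "null", pretty = TRUE)
}

#' Write the report bundle to disk
#'
#' Writes \code{report.json} (machine-readable), \code{report.txt}
#' (human-readable, percentages to two decimals) and \code{scored.csv}
#' into a directory.
#'
#' @param report A \code{"corsym_report"}.
#' @param dir Output directory (created if absent).
#' @return The directory, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  writeLines(report_json(report), file.path(dir, "report.json"))
  write_assessments(report$scored, file.path(dir, "scored.csv"))
  con <- file(file.path(dir, "report.txt"), "w")
  on.exit(close(con))
  sink(con); on.exit(sink(), add = TRUE, after = FALSE)
  print(report)
  invisible(dir)
}

#' @export
print.corsym_report <- function(x, ...) {
  cat("Corolla symmetry report:", x$n_taxa, "taxa scored\n\n")
  for (dd in x$distributions) { print(dd); cat("\n") }
  if (!is.null(x$weight_ratio)) { print(x$weight_ratio); cat("\n") }
  if (!is.null(x$dimension_regularity)) { print(x$dimension_regularity); cat("\n") }
  for (ff in x$trend_fits) {
    if (inherits(ff, "trend_fit")) print(ff)
    else cat(sprintf("Trend fit (%s): unavailable (%s)\n", ff$model, ff$error))
  }
  if (!is.null(x$pedigree)) { cat("\n"); print(x$pedigree) }
  invisible(x)
}
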