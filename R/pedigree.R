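# Parent-progeny symmetry-dominance validation: a progeny's symmetry index
# should never exceed the maximum index among its known parents.

parse_parent_ids <- function(x) {
  if (is.list(x)) return(lapply(x, as.character))
  lapply(strsplit(as.character(x), ";", fixed = TRUE), trimws)
}

#' Read a pedigree table
#'
#' Reads a CSV/TSV pedigree with columns \code{progeny_id},
#' \code{parent_ids} (one or two identifiers, semicolon-separated) and
#' \code{complete} (TRUE when all parents are known).
#'
#' @param path File path.
#' @param sep Field delimiter (\code{","} default, \code{"\t"} accepted).
#' @return Data frame with \code{progeny_id}, list-column
#'   \code{parent_ids}, and logical \code{complete}.
#' @export
read_pedigree <- function(path, sep = ",") {
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, comment.char = "")
  need <- c("progeny_id", "parent_ids", "complete")
  if (!all(need %in% names(raw)))
    stop("pedigree file must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  out <- data.frame(progeny_id = as.character(raw$progeny_id),
                    stringsAsFactors = FALSE)
  out$parent_ids <- parse_parent_ids(raw$parent_ids)
  out$complete <- as.logical(raw$complete)
  validate_pedigree(out)
  out
}

validate_pedigree <- function(pedigree) {
  if (nrow(pedigree) == 0L) stop("empty pedigree", call. = FALSE)
  parents <- parse_parent_ids(pedigree$parent_ids)
  for (i in seq_len(nrow(pedigree))) {
    if (length(parents[[i]]) < 1L || !any(nzchar(parents[[i]])))
      stop("pedigree record '", pedigree$progeny_id[i],
           "' has no parents", call. = FALSE)
    if (pedigree$progeny_id[i] %in% parents[[i]])
      stop("pedigree record '", pedigree$progeny_id[i],
           "' lists itself as a parent", call. = FALSE)
  }
  invisible(pedigree)
}

#' Check the progeny symmetry-dominance rule
#'
#' Validates, for every pedigree record, that the progeny's symmetry index
#' does not exceed the maximum index among its known parents (equality
#' passes). Records whose progeny cannot be resolved against the scored
#' table, or none of whose parents can, are marked unresolvable rather
#' than failing the run. Records with an unknown parent (incomplete
#' pedigree, or a listed parent absent from the scored table) are
#' evaluated against the known parents only and flagged \code{partial}: a
#' missing parent could only raise the parental maximum, so a partial pass
#' is weaker evidence than a complete one.
#'
#' @param records Scored taxon records (see \code{\link{score_assessments}}).
#' @param pedigree Pedigree data frame (see \code{\link{read_pedigree}}):
#'   \code{progeny_id}, \code{parent_ids} (list-column or
#'   semicolon-separated strings), \code{complete}.
#' @return An object of class \code{"pedigree_report"}: list with
#'   \code{records} (per-record data frame: progeny and max-parent SI,
#'   \code{status} pass/violation/unresolvable, \code{partial}) and
#'   \code{summary} (counts; passes + violations + unresolvable = total).
#' @examples
#' scored <- data.frame(taxon_id = c("p1", "p2", "kid"),
#'                      index = c(7, 4, 2))
#' ped <- data.frame(progeny_id = "kid", parent_ids = "p1;p2",
#'                   complete = TRUE)
#' check_progeny_rule(scored, ped)
#' @export
check_progeny_rule <- function(records, pedigree) {
  validate_pedigree(pedigree)
  si <- stats::setNames(records$index, records$taxon_id)
  parents <- parse_parent_ids(pedigree$parent_ids)
  n <- nrow(pedigree)
  out <- data.frame(progeny_id = as.character(pedigree$progeny_id),
                    progeny_si = NA_real_, max_parent_si = NA_real_,
                    n_parents_known = 0L,
                    status = NA_character_, partial = NA,
                    stringsAsFactors = FALSE)
  complete <- if ("complete" %in% names(pedigree)) as.logical(pedigree$complete)
              else rep(TRUE, n)
  for (i in seq_len(n)) {
    pg <- out$progeny_id[i]
    known <- parents[[i]][parents[[i]] %in% names(si)]
    out$n_parents_known[i] <- length(known)
    if (!pg %in% names(si) || length(known) == 0L) {
      out$status[i] <- "unresolvable"
      out$partial[i] <- NA
      next
    }
    out$progeny_si[i] <- si[[pg]]
    out$max_parent_si[i] <- max(si[known])
    out$status[i] <- if (out$progeny_si[i] <= out$max_parent_si[i]) "pass"
                     else "violation"
    out$partial[i] <- !isTRUE(complete[i]) ||
                      length(known) < length(parents[[i]])
  }
  summary <- list(total = n,
                  passes = sum(out$status == "pass"),
                  violations = sum(out$status == "violation"),
                  unresolvable = sum(out$status == "unresolvable"),
                  partial = sum(out$partial %in% TRUE))
  structure(list(records = out, summary = summary),
            class = "pedigree_report")
}

#' @export
print.pedigree_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("Progeny symmetry-dominance rule: %d record(s); ",
                     "%d pass (%d partial), %d violation(s), %d unresolvable\n"),
              s$total, s$passes, s$partial, s$violations, s$unresolvable))
  if (s$violations > 0L) {
    cat("Violations:\n")
    print(x$records[x$records$status == "violation", , drop = FALSE],
          row.names = FALSE)
  }
  invisible(x)
}
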