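# Seeded synthetic cohorts and pedigrees with the statistical structure the
# downstream analytics assume: independent Bernoulli sub-dimension traits
# per taxon (optionally replicated over flowers), and crosses that obey --
# or deliberately violate -- the progeny symmetry-dominance rule.

#' Specification of one synthetic group
#'
#' Describes a group of taxa whose binary sub-dimension traits are drawn as
#' independent Bernoulli variables. \code{p} is the per-cell success
#' probability: a scalar (shared by all cells) or a \code{d} x \code{s}
#' matrix with one entry per (dimension, sub-dimension) cell. Because a
#' dimension is the product of its sub-dimensions, the expected
#' dimension-regularity fraction under a scalar \code{p} is \code{p^s}.
#'
#' @param group Group label (e.g. \code{"species"}).
#' @param n Number of taxa (positive integer).
#' @param p Bernoulli probability, scalar or \code{d} x \code{s} matrix.
#' @param d,s Dimension and sub-dimension counts.
#' @param flowers_per_taxon Replicate flowers judged per taxon (1 gives a
#'   taxon-level table directly; the original survey judged about 30).
#' @param seed Default seed used by \code{\link{simulate_cohort}}.
#' @return An object of class \code{"group_spec"}.
#' @export
group_spec <- function(group, n, p = 0.6, d = 3L, s = 2L,
                       flowers_per_taxon = 1L, seed = NULL) {
  if (length(p) == 1L) p <- matrix(p, d, s)
  if (!is.matrix(p) || nrow(p) != d || ncol(p) != s)
    stop("'p' must be a scalar or a ", d, " x ", s, " matrix", call. = FALSE)
  if (any(p < 0 | p > 1 | is.na(p)))
    stop("all Bernoulli probabilities must lie in [0, 1]", call. = FALSE)
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("'n' must be a positive integer", call. = FALSE)
  structure(list(group = as.character(group), n = n, p = p, d = d, s = s,
                 flowers_per_taxon = as.integer(flowers_per_taxon),
                 seed = seed),
            class = "group_spec")
}

#' Built-in two-group presets
#'
#' Group specifications emulating the contrast the survey analysed: a
#' high-regularity "species-like" group and a lower-regularity
#' "cultivar-like" group, at the survey's group sizes (30 species, 110
#' cultivars). The per-sub-dimension probabilities (0.95 and 0.6) are
#' chosen only to reproduce the qualitative contrast of a high versus low
#' mean symmetry index; they are configuration, not estimates.
#'
#' @param n_species,n_cultivars Group sizes.
#' @param p_species,p_cultivars Per-sub-dimension Bernoulli probabilities.
#' @param flowers_per_taxon Replicate flowers per taxon.
#' @return Named list of two \code{\link{group_spec}} objects.
#' @export
malus_presets <- function(n_species = 30L, n_cultivars = 110L,
                          p_species = 0.95, p_cultivars = 0.6,
                          flowers_per_taxon = 1L) {
  list(species = group_spec("species", n_species, p_species,
                            flowers_per_taxon = flowers_per_taxon),
       cultivar = group_spec("cultivar", n_cultivars, p_cultivars,
                             flowers_per_taxon = flowers_per_taxon))
}

#' Generate a synthetic assessment cohort
#'
#' Draws an assessment table from one or more group specifications:
#' independent Bernoulli draws per (taxon, flower, sub-dimension) cell,
#' reproducible given the seed. With \code{flowers_per_taxon = 1} the table
#' is taxon-level (no \code{flower_id} column); otherwise it is
#' flower-level and ready for consensus aggregation.
#'
#' @param spec A \code{\link{group_spec}} or a list of them (e.g.
#'   \code{\link{malus_presets}()}).
#' @param seed Integer seed; overrides the specs' own seeds. Required here
#'   or in the spec.
#' @return Assessment data frame with columns \code{taxon_id},
#'   \code{group}, optionally \code{flower_id}, and the sub-dimension
#'   columns.
#' @examples
#' coh <- simulate_cohort(group_spec("g", 5, 0.8), seed = 1)
#' @export
simulate_cohort <- function(spec, seed = NULL) {
  specs <- if (inherits(spec, "group_spec")) list(spec) else spec
  stopifnot(all(vapply(specs, inherits, logical(1L), "group_spec")))
  if (is.null(seed)) seed <- specs[[1L]]$seed
  if (is.null(seed)) stop("a seed is required for reproducible simulation",
                          call. = FALSE)
  set.seed(as.integer(seed))
  out <- do.call(rbind, lapply(specs, simulate_one_group))
  rownames(out) <- NULL
  out
}

simulate_one_group <- function(sp) {
  d <- sp$d; s <- sp$s; f <- sp$flowers_per_taxon
  cols <- subdim_names(d, s)
  taxa <- sprintf("%s_%03d", sp$group, seq_len(sp$n))
  nrows <- sp$n * f
  out <- data.frame(taxon_id = rep(taxa, each = f), stringsAsFactors = FALSE)
  if (f > 1L) out$flower_id <- paste0(out$taxon_id, "_f",
                                      rep(seq_len(f), times = sp$n))
  out$group <- sp$group
  pvec <- as.vector(t(sp$p))  # cell order matches subdim_names()
  for (j in seq_along(cols))
    out[[cols[j]]] <- stats::rbinom(nrows, 1L, pvec[j])
  out[, c("taxon_id", intersect("flower_id", names(out)), "group", cols)]
}

#' Generate a synthetic pedigree and progeny records
#'
#' Simulates crosses over a set of scored parent records. Each cross
#' samples two distinct parents; under the dominance constraint the
#' progeny's dimension vector is drawn uniformly from the states whose
#' symmetry index does not exceed the parental maximum. A requested number
#' of rule violations can be injected for testing the checker: those
#' progeny draw from states with an index strictly above the parental
#' maximum (impossible when the parental maximum is already 7, so such
#' crosses are skipped as injection sites, with a warning if the quota
#' cannot be met in full and an error if no cross can host one).
#'
#' @param parents Scored taxon records to cross (at least two rows).
#' @param n_crosses Number of crosses to simulate.
#' @param constraint Enforce progeny SI <= max parental SI (default TRUE).
#' @param violations Number of rule violations to inject (default 0).
#' @param seed Integer seed (required).
#' @param progeny_group Group label for the progeny records.
#' @return List with \code{progeny} (scored taxon records) and
#'   \code{pedigree} (data frame: \code{progeny_id}, list-column
#'   \code{parent_ids}, \code{complete}).
#' @export
simulate_pedigree <- function(parents, n_crosses, constraint = TRUE,
                              violations = 0L, seed = NULL,
                              progeny_group = "progeny") {
  if (nrow(parents) < 2L)
    stop("need at least two parent records to simulate crosses", call. = FALSE)
  if (is.null(seed)) stop("a seed is required for reproducible simulation",
                          call. = FALSE)
  n_crosses <- as.integer(n_crosses)
  violations <- as.integer(violations)
  set.seed(as.integer(seed))
  states <- enumerate_state_space(weight_scheme(3L))
  pair_idx <- lapply(seq_len(n_crosses), function(i)
    sample.int(nrow(parents), 2L))
  max_si <- vapply(pair_idx, function(pp) max(parents$index[pp]), numeric(1L))

  viol_at <- rep(FALSE, n_crosses)
  if (violations > 0L) {
    candidates <- which(max_si < 7)
    if (length(candidates) == 0L)
      stop("cannot inject violations: every sampled cross already has the ",
           "maximal parental symmetry index (7)", call. = FALSE)
    if (length(candidates) < violations) {
      warning(sprintf("only %d of %d requested violations could be injected",
                      length(candidates), violations))
      viol_at[candidates] <- TRUE
    } else {
      viol_at[sample(candidates, violations)] <- TRUE
    }
  }

  rows <- lapply(seq_len(n_crosses), function(i) {
    pool <- if (viol_at[i]) states[states$index > max_si[i], , drop = FALSE]
            else if (constraint) states[states$index <= max_si[i], , drop = FALSE]
            else states
    pool[sample.int(nrow(pool), 1L), c("X", "Y", "Z"), drop = FALSE]
  })
  vec <- do.call(rbind, rows)
  progeny <- data.frame(taxon_id = sprintf("%s_%03d", progeny_group,
                                           seq_len(n_crosses)),
                        group = progeny_group, stringsAsFactors = FALSE)
  progeny <- cbind(progeny, vec)
  rownames(progeny) <- NULL
  progeny$index <- as.vector(as.matrix(vec) %*% weight_scheme(3L)$coefficients)
  progeny$type <- vapply(seq_len(n_crosses), function(i)
    classify_type(as.integer(vec[i, ]))$label, character(1L))

  pedigree <- data.frame(progeny_id = progeny$taxon_id,
                         stringsAsFactors = FALSE)
  pedigree$parent_ids <- lapply(pair_idx, function(pp) parents$taxon_id[pp])
  pedigree$complete <- TRUE
  list(progeny = progeny, pedigree = pedigree)
}
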