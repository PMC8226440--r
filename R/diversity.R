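#' Individual increase in inbreeding
#'
#' The per-generation rate at which an individual's inbreeding accumulated
#' over its realized pedigree depth:
#' `dF = 1 - (1 - F)^(1 / (t - 1))`, where `F` is the inbreeding coefficient
#' and `t` the equivalent complete generations. Undefined (`NA`) when
#' `t <= 1`: such individuals carry no information about the rate and are
#' excluded from cohort means.
#'
#' @param f inbreeding coefficient(s) in `[0, 1]`.
#' @param t equivalent complete generations, recycled against `f`.
#' @return Numeric vector of increases in `[0, 1)`; `NA` where `t <= 1`.
#' @export
delta_F <- function(f, t) {
  stopifnot(all(f >= 0 & f <= 1, na.rm = TRUE))
  ifelse(t > 1, 1 - (1 - f)^(1 / (t - 1)), NA_real_)
}

#' Pairwise increase in coancestry
#'
#' The rate at which coancestry between two individuals accumulated, given
#' their pedigree depths: `dC = 1 - (1 - C)^(2 / (g1 + g2))`, where `C` is
#' the coancestry and `g1`, `g2` the equivalent complete generations of the
#' two individuals. Undefined (`NA`) when `g1 + g2 <= 0`.
#'
#' @param c coancestry coefficient(s) in `[0, 1]`.
#' @param g1,g2 equivalent complete generations of the two individuals.
#' @return Numeric vector of increases in `[0, 1)`.
#' @export
delta_C <- function(c, g1, g2 = g1) {
  stopifnot(all(c >= 0 & c <= 1, na.rm = TRUE))
  g <- (g1 + g2) / 2
  ifelse(g > 0, 1 - (1 - c)^(1 / g), NA_real_)
}

#' Effective size from per-individual (or per-pair) increases
#'
#' `Ne = 1 / (2 * mean(increase))`, the size of an idealized population
#' accumulating inbreeding (or coancestry) at the observed mean rate.
#' Undefined increases (`NA`) are dropped from the mean.
#'
#' @param delta vector of increases from [delta_F()] or [delta_C()].
#' @return The effective size; `Inf` when the mean increase is 0, `NA` (with
#'   a warning) when no increase is defined. Attributes `n_used` and
#'   `mean_increase` report the basis of the estimate.
#' @export
ne_from_increases <- function(delta) {
  d <- delta[!is.na(delta)]
  if (!length(d)) {
    warning("no defined increases; effective size undefined")
    out <- NA_real_
    attr(out, "n_used") <- 0L
    attr(out, "mean_increase") <- NA_real_
    return(out)
  }
  m <- mean(d)
  out <- if (m <= 0) Inf else 1 / (2 * m)
  attr(out, "n_used") <- length(d)
  attr(out, "mean_increase") <- m
  out
}

#' Realized effective size from individual increases in inbreeding (NeF)
#'
#' Computes `dF` for every cohort member from its inbreeding coefficient and
#' equivalent complete generations, then `NeF = 1 / (2 * mean dF)`.
#' Individuals with pedigree depth `t <= 1` are excluded (their rate is
#' undefined), never imputed as 0.
#'
#' @param ped a [pedigree].
#' @param cohort ids of the reference cohort.
#' @return NeF with attributes `n_used` and `mean_increase`; `Inf` when the
#'   cohort carries no inbreeding.
#' @export
ne_inbreeding <- function(ped, cohort) {
  if (!length(cohort)) stop("empty cohort")
  f <- inbreeding(ped, cohort)
  t <- equivalent_generations(ped, cohort)
  ne_from_increases(delta_F(f, t))
}

#' Realized effective size from pairwise increases in coancestry (NeC)
#'
#' Computes `dC` for every unordered distinct pair in the cohort, then
#' `NeC = 1 / (2 * mean dC)`. Self-pairs are excluded: the pairwise-increase
#' rate is defined between two individuals.
#'
#' @inheritParams ne_inbreeding
#' @return NeC with attributes `n_used` and `mean_increase`.
#' @export
ne_coancestry <- function(ped, cohort) {
  if (length(cohort) < 2L) stop("NeC needs a cohort of at least 2")
  K <- kinship_matrix(ped, cohort)
  g <- equivalent_generations(ped, cohort)
  ut <- upper.tri(K)
  gi <- matrix(g, nrow(K), ncol(K))
  ne_from_increases(delta_C(K[ut], t(gi)[ut], gi[ut]))
}

#' Mean kinship (or mean kinship-increase) weights
#'
#' For each member of a mating group, the mean coancestry (mode `"plain"`)
#' or mean pairwise increase in coancestry (mode `"increase"`) between that
#' individual and every other group member. These weights measure how well
#' represented an individual already is in the group, and enter the weighted
#' coancestry objectives (`mFm`, `dmFdm`).
#'
#' @param kinship symmetric coancestry matrix with id dimnames, e.g. from
#'   [kinship_matrix()].
#' @param group ids forming the mating group (default: all matrix ids);
#'   at least 2.
#' @param mode `"plain"` for coancestries, `"increase"` for increases.
#' @param eg named equivalent-generation values, required for
#'   `mode = "increase"`.
#' @return Named numeric weight vector over `group`.
#' @export
mean_kinship_weights <- function(kinship, group = NULL,
                                 mode = c("plain", "increase"), eg = NULL) {
  mode <- match.arg(mode)
  if (is.null(group)) group <- colnames(kinship)
  if (length(group) < 2L) stop("mating group must have at least 2 members")
  miss <- setdiff(group, colnames(kinship))
  if (length(miss)) stop("id(s) not in kinship matrix: ", paste(miss, collapse = ", "))
  K <- kinship[group, group, drop = FALSE]
  n <- length(group)
  if (mode == "plain") {
    w <- (rowSums(K) - diag(K)) / (n - 1)
  } else {
    if (is.null(eg)) stop("mode = \"increase\" requires eg values")
    g <- eg[group]
    if (anyNA(g)) stop("missing eg value for group member(s)")
    D <- delta_C(K, matrix(g, n, n), matrix(g, n, n, byrow = TRUE))
    w <- (rowSums(D) - diag(D)) / (n - 1)
  }
  setNames(as.numeric(w), group)
}

#' Expected heterozygosity of a group
#'
#' Nei's gene diversity, the complement of the mean coancestry of the group
#' (all ordered pairs, self-pairs included): `He = 1 - mean(f)`.
#'
#' @param kinship coancestry matrix with id dimnames.
#' @param ids group ids (default: all).
#' @return `He` in `[0, 1]`.
#' @export
expected_heterozygosity <- function(kinship, ids = NULL) {
  if (is.null(ids)) ids <- colnames(kinship)
  1 - mean(kinship[ids, ids])
}

#' Diversity panel for a cohort
#'
#' Mean inbreeding and pedigree depth, the two realized effective sizes
#' (NeF from individual increases in inbreeding, NeC from pairwise increases
#' in coancestry) and their ratio, with definedness flags.
#'
#' @inheritParams ne_inbreeding
#' @return A one-row data frame: `n`, `n_males`, `n_females`, `mean_f`,
#'   `mean_eg`, `ne_f`, `ne_c`, `ne_ratio` (NeC/NeF), `ne_f_defined`,
#'   `ne_c_defined`.
#' @export
cohort_diversity <- function(ped, cohort) {
  if (!length(cohort)) stop("empty cohort")
  sex <- ped$sex[match(cohort, ped$id)]
  f <- inbreeding(ped, cohort)
  eg <- equivalent_generations(ped, cohort)
  nef <- ne_inbreeding(ped, cohort)
  nec <- if (length(cohort) >= 2L) ne_coancestry(ped, cohort) else NA_real_
  fdef <- is.finite(nef)
  cdef <- is.finite(nec) && !is.na(nec)
  data.frame(n = length(cohort),
             n_males = sum(sex == "M", na.rm = TRUE),
             n_females = sum(sex == "F", na.rm = TRUE),
             mean_f = mean(f), mean_eg = mean(eg),
             ne_f = as.numeric(nef), ne_c = as.numeric(nec),
             ne_ratio = if (fdef && cdef) as.numeric(nec) / as.numeric(nef) else NA_real_,
             ne_f_defined = fdef, ne_c_defined = cdef)
}
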