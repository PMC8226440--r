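#' Scenario profile for a synthetic base population
#'
#' Bundles the statistical targets a synthetic base pedigree must hit: the
#' cohort sex counts, the cohort's mean inbreeding and its pedigree depth
#' (mean equivalent complete generations). Two presets emulate the
#' structure of well-documented captive gazelle reference populations:
#' `"almeria-like"` (6 males / 16 females, mean F 0.26, EG 8.8) and
#' `"lajita-like"` (8 males / 11 females, mean F 0.37, EG 9.0).
#'
#' @param profile preset name (`"almeria-like"` or `"lajita-like"`,
#'   abbreviations allowed) or `"custom"` with the remaining arguments.
#' @param n_males,n_females cohort sex counts.
#' @param target_mean_f target mean inbreeding of the cohort.
#' @param target_eg target mean equivalent complete generations.
#' @param seed generator seed stored with the profile.
#' @return A `scenario_profile` list.
#' @export
scenario_profile <- function(profile = c("almeria-like", "lajita-like", "custom"),
                             n_males = NULL, n_females = NULL,
                             target_mean_f = NULL, target_eg = NULL,
                             seed = 1L) {
  profile <- match.arg(profile)
  preset <- switch(profile,
    "almeria-like" = list(n_males = 6L, n_females = 16L,
                          target_mean_f = 0.26, target_eg = 8.8),
    "lajita-like" = list(n_males = 8L, n_females = 11L,
                         target_mean_f = 0.37, target_eg = 9.0),
    list(n_males = n_males, n_females = n_females,
         target_mean_f = target_mean_f, target_eg = target_eg))
  if (profile == "custom" &&
      (is.null(n_males) || is.null(n_females) || is.null(target_mean_f) ||
       is.null(target_eg)))
    stop("custom profiles need n_males, n_females, target_mean_f, target_eg")
  out <- c(list(name = profile), preset, list(seed = as.integer(seed)))
  stopifnot(out$n_males >= 1L, out$n_females >= 1L,
            out$target_mean_f >= 0, out$target_mean_f < 1, out$target_eg >= 0)
  class(out) <- "scenario_profile"
  out
}

#' @export
print.scenario_profile <- function(x, ...) {
  cat(sprintf("<scenario_profile> %s: %dM/%dF, target mean F = %.2f, target EG = %.1f (seed %d)\n",
              x$name, x$n_males, x$n_females, x$target_mean_f, x$target_eg,
              x$seed))
  invisible(x)
}

# core random-union pedigree builder on integer arrays
.build_random_union <- function(n_founders, n_generations, cohort_size,
                                final_males, final_females) {
  stopifnot(n_founders >= 2L)
  fm <- max(1L, n_founders %/% 2L)
  sex <- c(rep("M", fm), rep("F", n_founders - fm))
  sire <- rep(0L, n_founders)
  dam <- rep(0L, n_founders)
  gen <- rep(0L, n_founders)
  prev <- seq_len(n_founders)
  add_gen <- function(g, n, sexes) {
    pm <- prev[sex[prev] == "M"]
    pf <- prev[sex[prev] == "F"]
    s <- pm[sample.int(length(pm), n, replace = TRUE)]
    d <- pf[sample.int(length(pf), n, replace = TRUE)]
    idx <- length(sire) + seq_len(n)
    sire <<- c(sire, s)
    dam <<- c(dam, d)
    sex <<- c(sex, sexes)
    gen <<- c(gen, rep(g, n))
    prev <<- idx
  }
  if (n_generations >= 2L) {
    for (g in seq_len(n_generations - 1L)) {
      repeat {
        sx <- ifelse(stats::rbinom(cohort_size, 1L, 0.5) == 1L, "M", "F")
        if (any(sx == "M") && any(sx == "F")) break
      }
      add_gen(g, cohort_size, sx)
    }
  }
  nfin <- final_males + final_females
  sx <- sample(c(rep("M", final_males), rep("F", final_females)))
  add_gen(n_generations, nfin, sx)
  list(sire = sire, dam = dam, sex = sex, gen = gen, cohort = prev)
}

.arrays_to_pedigree <- function(a, flock = "synthetic") {
  ids <- sprintf("S%d_%d", a$gen, stats::ave(seq_along(a$gen), a$gen,
                                             FUN = seq_along))
  si <- ifelse(a$sire > 0L, a$sire, NA_integer_)
  di <- ifelse(a$dam > 0L, a$dam, NA_integer_)
  df <- data.frame(id = ids,
                   sire = ids[si],
                   dam = ids[di],
                   sex = a$sex, birth = a$gen, flock = flock,
                   stringsAsFactors = FALSE)
  list(pedigree = as_pedigree(df), cohort = ids[a$cohort])
}

#' Random-union pedigree
#'
#' Builds a pedigree by discrete-generation random mating: every offspring
#' draws a random sire and a random dam from the previous generation.
#' Useful as an unstructured control (its NeC/NeF ratio is close to 1) and
#' as the backbone of the synthetic scenario generator.
#'
#' @param n_founders number of unrelated founders (split evenly by sex).
#' @param n_generations number of discrete generations after the founders.
#' @param cohort_size census of the intermediate generations (default:
#'   `n_founders`).
#' @param final_males,final_females sex counts of the final cohort
#'   (default: an even split of `cohort_size`).
#' @param seed optional seed.
#' @return A `base_population` list: `pedigree`, `cohort` (final-generation
#'   ids), plus the generating parameters.
#' @export
random_union_pedigree <- function(n_founders, n_generations,
                                  cohort_size = n_founders,
                                  final_males = NULL, final_females = NULL,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(final_males)) final_males <- max(1L, cohort_size %/% 2L)
  if (is.null(final_females)) final_females <- max(1L, cohort_size - final_males)
  a <- .build_random_union(n_founders, n_generations, cohort_size,
                           final_males, final_females)
  out <- .arrays_to_pedigree(a)
  out$n_founders <- n_founders
  out$n_generations <- n_generations
  out$census <- cohort_size
  class(out) <- "base_population"
  out
}

#' Generate a synthetic base pedigree for a scenario
#'
#' Simulates unrelated founders followed by discrete-generation random
#' mating at a small constant census, so that the final cohort (with
#' exactly the requested sex counts) reaches the profile's inbreeding and
#' pedigree-depth targets. The number of generations is set to the rounded
#' EG target (a complete pedigree of depth `G` has EG exactly `G`); the
#' census that hits the inbreeding target is found by a pilot search around
#' the analytic guess `1 / (2 * (1 - (1 - F)^(1/(G-1))))`, accepting the
#' first census whose realized cohort mean F lies within `f_tol`.
#'
#' @param profile a [scenario_profile()] (or preset name).
#' @param seed seed; defaults to the profile's.
#' @param f_tol,eg_tol acceptance tolerances on the realized cohort mean
#'   inbreeding (default 0.05) and mean EG (default 1.0).
#' @return A `base_population` list: `pedigree`, `cohort`, `census`,
#'   `n_generations`, and realized `mean_f`, `mean_eg`.
#' @export
generate_base_pedigree <- function(profile, seed = NULL, f_tol = 0.05,
                                   eg_tol = 1.0) {
  if (is.character(profile)) profile <- scenario_profile(profile)
  stopifnot(inherits(profile, "scenario_profile"))
  if (is.null(seed)) seed <- profile$seed
  G <- max(1L, as.integer(round(profile$target_eg)))
  if (abs(G - profile$target_eg) > eg_tol)
    stop("target EG ", profile$target_eg,
         " unreachable with a complete pedigree at tolerance ", eg_tol)
  target_f <- profile$target_mean_f
  guess <- if (G >= 2L && target_f > 0) {
    max(4, min(80, round(1 / (2 * (1 - (1 - target_f)^(1 / (G - 1)))))))
  } else 2 * (profile$n_males + profile$n_females)
  offsets <- c(0L, as.vector(rbind(seq_len(40L), -seq_len(40L))))
  candidates <- unique(pmin(pmax(round(guess) + offsets, 4L), 120L))
  for (cen in candidates) {
    set.seed(seed)
    a <- .build_random_union(cen, G, cen, profile$n_males, profile$n_females)
    idx <- .parent_idx_arrays(a)
    K <- .kinship_tabular_cpp(idx$sire, idx$dam)
    f <- 2 * diag(K)[a$cohort] - 1
    mean_f <- mean(f)
    if (abs(mean_f - target_f) <= f_tol) {
      out <- .arrays_to_pedigree(a)
      out$census <- cen
      out$n_generations <- G
      out$mean_f <- mean_f
      out$mean_eg <- mean(equivalent_generations(out$pedigree)[out$cohort])
      out$profile <- profile
      class(out) <- "base_population"
      return(out)
    }
  }
  stop("could not reach mean F = ", target_f, " within ±", f_tol,
       "; adjust the profile targets")
}

# arrays are built parents-first already
.parent_idx_arrays <- function(a) list(sire = a$sire, dam = a$dam)

#' @export
print.base_population <- function(x, ...) {
  cat(sprintf("<base_population> %d individuals, cohort of %d", nrow(x$pedigree),
              length(x$cohort)))
  if (!is.null(x$mean_f))
    cat(sprintf(" (mean F = %.3f, mean EG = %.2f, census %d, %d generations)",
                x$mean_f, x$mean_eg, x$census, x$n_generations))
  cat("\n")
  invisible(x)
}
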