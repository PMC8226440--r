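#' Draw the size of the next cohort
#'
#' Cohort sizes follow a Poisson distribution with mean equal to the
#' reference-population size; draws below the feasibility floor of the
#' active participation constraint are clamped up to the floor (and
#' flagged), so that the constraint set stays satisfiable.
#'
#' @param n0 mean cohort size (the reference-population size).
#' @param floor minimum feasible size (default 2: the next generation needs
#'   at least one parent of each sex).
#' @return Integer cohort size with logical attribute `clamped`.
#' @export
next_cohort_size <- function(n0, floor = 2L) {
  stopifnot(n0 >= 2)
  draw <- stats::rpois(1L, n0)
  out <- max(draw, as.integer(floor))
  attr(out, "clamped") <- draw < floor
  out
}

#' Randomly assign offspring sexes
#'
#' Each offspring is male with probability `male_fraction`, independently.
#' The whole vector is redrawn (and the redraw counted) while the cohort is
#' single-sex, or - when `enforce_ratio = TRUE` (default) - while males
#' outnumber females, keeping the polygynous setting (males <= females)
#' satisfiable in every generation.
#'
#' @param n cohort size, at least 2.
#' @param male_fraction expected share of males, typically the male
#'   fraction of the base cohort.
#' @param enforce_ratio redraw while males > females (default `TRUE`).
#' @param max_tries safety cap on redraws.
#' @return Character vector of `"M"`/`"F"` with attribute `redraws`.
#' @export
assign_sexes <- function(n, male_fraction, enforce_ratio = TRUE,
                         max_tries = 10000L) {
  stopifnot(n >= 2, male_fraction > 0, male_fraction < 1)
  redraws <- -1L
  repeat {
    redraws <- redraws + 1L
    if (redraws > max_tries) stop("sex assignment failed after ", max_tries,
                                  " redraws")
    male <- stats::rbinom(n, 1L, male_fraction) == 1L
    nm <- sum(male)
    if (nm == 0L || nm == n) next
    if (enforce_ratio && nm > n - nm) next
    break
  }
  out <- ifelse(male, "M", "F")
  attr(out, "redraws") <- redraws
  out
}

#' Initialize a simulation state
#'
#' Captures the base cohort of a pedigree together with its coancestry
#' matrix and equivalent-generation values, ready for
#' [simulate_generation()]. Generations are discrete: only the current
#' cohort reproduces.
#'
#' @param ped a [pedigree].
#' @param cohort ids of the base (reference) cohort; needs both sexes.
#' @return A `sim_state` object.
#' @export
sim_state <- function(ped, cohort) {
  stopifnot(inherits(ped, "pedigree"), length(cohort) >= 2L)
  sex <- ped$sex[match(cohort, ped$id)]
  if (anyNA(sex)) stop("cohort member(s) with unknown sex")
  if (!any(sex == "M") || !any(sex == "F"))
    stop("base cohort needs at least one male and one female")
  K <- kinship_matrix(ped, cohort)
  eg <- equivalent_generations(ped, cohort)
  st <- list(
    ids = cohort, sex = sex, K = K, eg = eg,
    generation = 0L,
    n0 = length(cohort),
    male_fraction = sum(sex == "M") / length(cohort),
    # growing pedigree record of the simulated individuals
    record = data.frame(id = character(0), sire = character(0),
                        dam = character(0), sex = character(0),
                        birth = numeric(0), stringsAsFactors = FALSE),
    log = list(clamped = 0L, redraws = 0L),
    history = list())
  class(st) <- "sim_state"
  st
}

#' @export
print.sim_state <- function(x, ...) {
  cat(sprintf("<sim_state> generation %d: %d individuals (%d M / %d F), mean F = %.3f\n",
              x$generation, length(x$ids), sum(x$sex == "M"),
              sum(x$sex == "F"), mean(2 * diag(x$K) - 1)))
  invisible(x)
}

# feasibility floor of the cohort size for a participation constraint:
# "zero"/"one" require every female to contribute at least one offspring
.cohort_floor <- function(participation, n_females) {
  max(2L, if (participation == "free") 2L else n_females)
}

#' Advance the simulation by one generation
#'
#' Draws the cohort size, optimizes the mating plan of the current cohort
#' under the strategy (or draws a random plan for the `"random"` control),
#' creates one offspring per pair occurrence with randomly assigned sex,
#' and evaluates the newborn cohort's realized effective sizes against the
#' cumulative pedigree. The new cohort's coancestry matrix and EG values
#' are obtained by the one-generation kinship extension, which under
#' discrete generations coincides with recomputation from the full
#' pedigree.
#'
#' @param state a [sim_state()].
#' @param strat a [strategy()] or its name (or `"random"`).
#' @param cohort_size fixed size for the next cohort; default: Poisson draw
#'   via [next_cohort_size()].
#' @param control optimizer settings, see [optimize_plan()].
#' @return The updated `sim_state`; `state$history` gains one record with
#'   the generation's `ne_f`, `ne_c`, `mean_f` and bookkeeping flags.
#' @export
simulate_generation <- function(state, strat, cohort_size = NULL,
                                control = list()) {
  stopifnot(inherits(state, "sim_state"))
  strat <- strategy(strat)
  males <- state$ids[state$sex == "M"]
  females <- state$ids[state$sex == "F"]
  if (!length(males) || !length(females))
    stop("current cohort lacks one sex; cannot mate")
  clamped <- FALSE
  if (is.null(cohort_size)) {
    cohort_size <- next_cohort_size(state$n0,
                                    .cohort_floor(strat$participation,
                                                  length(females)))
    clamped <- attr(cohort_size, "clamped")
  }
  nt <- as.integer(cohort_size)

  plan <- if (strat$family == "random") {
    random_plan(males, females, nt, participation = "free")
  } else {
    optimize_plan(strat, state$K, males, females, nt, eg = state$eg,
                  method = "anneal", control = control)
  }
  ex <- .expand_plan(plan)
  n_off <- length(ex$sire)
  sexes <- assign_sexes(n_off, state$male_fraction)
  gen <- state$generation + 1L

  # offspring kinship/EG by one-generation extension of the recursions
  s <- match(ex$sire, state$ids)
  d <- match(ex$dam, state$ids)
  K <- state$K
  Ko <- 0.25 * (K[s, s, drop = FALSE] + K[s, d, drop = FALSE] +
                K[d, s, drop = FALSE] + K[d, d, drop = FALSE])
  f_off <- K[cbind(s, d)]
  diag(Ko) <- 0.5 * (1 + f_off)
  eg_off <- 1 + (state$eg[s] + state$eg[d]) / 2
  ids_off <- sprintf("G%d_%d", gen, seq_len(n_off))
  dimnames(Ko) <- list(ids_off, ids_off)
  names(eg_off) <- ids_off

  # realized effective sizes of the newborn cohort
  ne_f <- ne_from_increases(delta_F(f_off, eg_off))
  Gm <- matrix(eg_off, n_off, n_off)
  ut <- upper.tri(Ko)
  ne_c <- ne_from_increases(delta_C(Ko[ut], Gm[ut], t(Gm)[ut]))

  state$record <- rbind(state$record,
                        data.frame(id = ids_off, sire = ex$sire, dam = ex$dam,
                                   sex = sexes, birth = gen,
                                   stringsAsFactors = FALSE))
  state$history[[gen]] <- data.frame(
    generation = gen, n = n_off,
    n_males = sum(sexes == "M"), n_females = sum(sexes == "F"),
    mean_f = mean(f_off), mean_eg = mean(eg_off),
    ne_f = as.numeric(ne_f), ne_c = as.numeric(ne_c),
    clamped = clamped, sex_redraws = attr(sexes, "redraws"),
    stringsAsFactors = FALSE)
  state$log$clamped <- state$log$clamped + as.integer(clamped)
  state$log$redraws <- state$log$redraws + attr(sexes, "redraws")
  state$ids <- ids_off
  state$sex <- as.character(sexes)
  state$K <- Ko
  state$eg <- eg_off
  state$generation <- gen
  state
}

# deterministic per-replicate seed below 2^31
.replicate_seed <- function(master, strat_index, replicate) {
  as.integer((as.numeric(master) + 10007 * strat_index + 7919 * replicate) %%
               2147483647)
}

#' Run the multi-replicate strategy-comparison experiment
#'
#' For each strategy, runs `n_replicates` independent replicates of
#' `n_generations` discrete generations from the same base cohort, tracking
#' the realized effective sizes (NeF, NeC) of every newborn cohort.
#' Per-replicate seeds are derived deterministically from `seed`, so the
#' whole experiment is a pure function of its inputs. Replicates whose
#' constraint set becomes infeasible are aborted and counted, never
#' silently dropped.
#'
#' @param base a [pedigree], or the result of [generate_base_pedigree()]
#'   (in which case `cohort` defaults to its reference cohort).
#' @param strategies character vector of strategy names (see
#'   [list_strategies()]; `"random"` adds the unoptimized control).
#' @param cohort base cohort ids (required when `base` is a pedigree).
#' @param n_generations,n_replicates experiment size; the study design is
#'   20 generations x 100 replicates, scaled-down runs are common.
#' @param seed master seed.
#' @param control optimizer settings, see [optimize_plan()].
#' @return An `ne_experiment` object: list with `trajectories` (one row per
#'   strategy x replicate x generation), `summary` (per strategy x
#'   generation: mean/median/quartiles of finite NeF and NeC, counts of
#'   undefined values), `aborted`, and the configuration.
#' @export
run_experiment <- function(base, strategies, cohort = NULL,
                           n_generations = 20L, n_replicates = 100L,
                           seed = 1L, control = list()) {
  if (inherits(base, "base_population")) {
    if (is.null(cohort)) cohort <- base$cohort
    base <- base$pedigree
  }
  stopifnot(inherits(base, "pedigree"), !is.null(cohort),
            n_generations >= 1L, n_replicates >= 1L)
  strategies <- vapply(strategies, function(s) strategy(s)$name, character(1),
                       USE.NAMES = FALSE)
  state0 <- sim_state(base, cohort)
  rows <- vector("list", length(strategies) * n_replicates)
  aborted <- data.frame(strategy = character(0), replicate = integer(0),
                        generation = integer(0), reason = character(0),
                        stringsAsFactors = FALSE)
  k <- 0L
  for (si in seq_along(strategies)) {
    sname <- strategies[si]
    for (r in seq_len(n_replicates)) {
      set.seed(.replicate_seed(seed, si, r))
      st <- state0
      ok <- TRUE
      for (g in seq_len(n_generations)) {
        st <- tryCatch(simulate_generation(st, sname, control = control),
                       error = function(e) e)
        if (inherits(st, "error")) {
          aborted <- rbind(aborted,
                           data.frame(strategy = sname, replicate = r,
                                      generation = g,
                                      reason = conditionMessage(st),
                                      stringsAsFactors = FALSE))
          ok <- FALSE
          break
        }
      }
      k <- k + 1L
      if (ok) {
        h <- do.call(rbind, st$history)
        rownames(h) <- NULL
        h <- data.frame(strategy = sname, replicate = r, h,
                        stringsAsFactors = FALSE)
        rows[[k]] <- h
      }
    }
  }
  traj <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(traj) <- NULL
  out <- list(trajectories = traj,
              summary = .summarize_trajectories(traj),
              aborted = aborted,
              config = list(strategies = strategies,
                            n_generations = n_generations,
                            n_replicates = n_replicates, seed = seed,
                            base_n = length(cohort),
                            male_fraction = state0$male_fraction))
  class(out) <- "ne_experiment"
  out
}

.summarize_trajectories <- function(traj) {
  sp <- split(traj, list(traj$strategy, traj$generation), drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(d) {
    fin <- d$ne_f[is.finite(d$ne_f)]
    fic <- d$ne_c[is.finite(d$ne_c)]
    data.frame(strategy = d$strategy[1], generation = d$generation[1],
               n_replicates = nrow(d),
               ne_f_mean = if (length(fin)) mean(fin) else NA_real_,
               ne_f_median = if (length(fin)) stats::median(fin) else NA_real_,
               ne_f_q25 = if (length(fin)) unname(stats::quantile(fin, 0.25)) else NA_real_,
               ne_f_q75 = if (length(fin)) unname(stats::quantile(fin, 0.75)) else NA_real_,
               ne_f_undefined = sum(!is.finite(d$ne_f)),
               ne_c_mean = if (length(fic)) mean(fic) else NA_real_,
               ne_c_undefined = sum(!is.finite(d$ne_c)),
               mean_f = mean(d$mean_f),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$generation, out$strategy), ]
  rownames(out) <- NULL
  out
}

#' @export
print.ne_experiment <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<ne_experiment> %d strategies x %d replicates x %d generations (seed %s)\n",
              length(cfg$strategies), cfg$n_replicates, cfg$n_generations,
              format(cfg$seed)))
  if (nrow(x$aborted)) cat("  aborted replicates:", nrow(x$aborted), "\n")
  last <- x$summary[x$summary$generation == max(x$summary$generation), ]
  last <- last[order(-last$ne_f_mean), c("strategy", "ne_f_mean", "ne_c_mean")]
  cat("  final-generation mean NeF (top 5):\n")
  print(utils::head(last, 5L), row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
summary.ne_experiment <- function(object, ...) object$summary

#' Rank strategies by mean NeF at a generation
#'
#' @param x an `ne_experiment`.
#' @param generation generation at which to rank.
#' @return Data frame of strategies sorted by decreasing mean NeF with a
#'   `rank` column (1 = largest effective size).
#' @export
rank_strategies <- function(x, generation) {
  stopifnot(inherits(x, "ne_experiment"))
  s <- x$summary[x$summary$generation == generation, ]
  if (!nrow(s)) stop("no such generation in experiment")
  s <- s[order(-s$ne_f_mean), c("strategy", "ne_f_mean", "ne_f_undefined")]
  s$rank <- seq_len(nrow(s))
  rownames(s) <- NULL
  s
}

#' Plot effective-size trajectories
#'
#' Mean NeF of each strategy against generation, one line per strategy.
#'
#' @param x an `ne_experiment`.
#' @param strategies subset of strategies to draw (default: all).
#' @param ... passed to [graphics::matplot()].
#' @export
plot.ne_experiment <- function(x, strategies = NULL, ...) {
  s <- x$summary
  if (!is.null(strategies)) s <- s[s$strategy %in% strategies, ]
  gens <- sort(unique(s$generation))
  strat <- unique(s$strategy)
  m <- sapply(strat, function(st)
    s$ne_f_mean[s$strategy == st][order(s$generation[s$strategy == st])])
  cols <- grDevices::hcl.colors(max(3L, length(strat)), "Dark 3")
  graphics::matplot(gens, m, type = "l", lty = 1, col = cols,
                    xlab = "Generation", ylab = "Mean NeF", ...)
  graphics::legend("topright", legend = strat, col = cols[seq_along(strat)],
                   lty = 1, cex = 0.6, ncol = 2, bty = "n")
  invisible(x)
}

#' Pedigree of a finished simulation replicate
#'
#' Combines the base pedigree with the simulated records into one
#' validated [pedigree]; simulated individuals carry their generation index
#' as `birth`.
#'
#' @param base the base [pedigree].
#' @param state a [sim_state] after simulation.
#' @return A [pedigree].
#' @export
sim_pedigree <- function(base, state) {
  stopifnot(inherits(base, "pedigree"), inherits(state, "sim_state"))
  rec <- state$record
  # shift simulated generation indices past the base pedigree's birth scale
  offset <- suppressWarnings(max(base$birth, na.rm = TRUE))
  if (!is.finite(offset)) offset <- 0
  df <- rbind(data.frame(id = base$id, sire = base$sire, dam = base$dam,
                         sex = base$sex, birth = base$birth,
                         flock = base$flock, stringsAsFactors = FALSE),
              data.frame(id = rec$id, sire = rec$sire, dam = rec$dam,
                         sex = rec$sex, birth = offset + rec$birth,
                         flock = "simulated", stringsAsFactors = FALSE))
  as_pedigree(df)
}
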