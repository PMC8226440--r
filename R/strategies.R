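# The 23-strategy catalogue. Families minimize, over feasible mating plans:
#   F      sum of parent coancestries C_jk over pair occurrences
#   dF     sum of pairwise increases in parent coancestry
#   mFm    sum of m_j C_jk m_k (mean-kinship weighted)
#   dmFdm  sum of dm_j dC_jk dm_k (mean-increase weighted)
#   C      sum of coancestries C_lm over distinct prospective-offspring pairs
#   dC     sum of increases dC_lm over distinct offspring pairs
#   mix    p1 * mean(C_jk) + (1 - p1) * mean(C_lm)
# Participation: "zero" = every female contributes >= 1 offspring;
# "one" = every female and every male; "free" = no floor.
.strategy_table <- function() {
  tab <- rbind(
    data.frame(name = c("F0", "F1", "Ff"), family = "F",
               participation = c("zero", "one", "free"), p1 = NA_real_),
    data.frame(name = c("dF0", "dF1"), family = "dF",
               participation = c("zero", "one"), p1 = NA_real_),
    data.frame(name = c("mFm0", "mFm1"), family = "mFm",
               participation = c("zero", "one"), p1 = NA_real_),
    data.frame(name = c("dmFdm0", "dmFdm1"), family = "dmFdm",
               participation = c("zero", "one"), p1 = NA_real_),
    data.frame(name = c("C0", "C1", "Cf"), family = "C",
               participation = c("zero", "one", "free"), p1 = NA_real_),
    data.frame(name = c("dC0", "dC1", "dCf"), family = "dC",
               participation = c("zero", "one", "free"), p1 = NA_real_),
    data.frame(name = c("mix1-99", "mix5-95", "mix50-50", "mix95-5"),
               family = "mix", participation = "zero",
               p1 = c(0.01, 0.05, 0.50, 0.95)),
    data.frame(name = c("mixf1-99", "mixf5-95", "mixf50-50", "mixf95-5"),
               family = "mix", participation = "free",
               p1 = c(0.01, 0.05, 0.50, 0.95)))
  lab <- tab$name
  lab <- sub("^dmFdm", "ΔmΔFΔm", lab)
  lab <- sub("^dF", "ΔF", lab)
  lab <- sub("^dC", "ΔC", lab)
  lab <- sub("^(mixf?)([0-9])", "\\1 \\2", lab)
  tab$label <- lab
  tab
}

.family_code <- c(F = 1L, dF = 2L, mFm = 3L, dmFdm = 4L, C = 5L, dC = 6L,
                  mix = 7L)
.participation_code <- c(zero = 0L, one = 1L, free = 2L)

#' The 23 mate-selection strategy names
#'
#' @return Character vector of the strategy names accepted by [strategy()],
#'   [optimize_plan()] and [run_experiment()].
#' @export
list_strategies <- function() .strategy_table()$name

#' Parse a mate-selection strategy
#'
#' Accepts the printed strategy names (`F0`, `F1`, `Ff`, `dF0`, `dF1`,
#' `mFm0`, `mFm1`, `dmFdm0`, `dmFdm1`, `C0`, `C1`, `Cf`, `dC0`, `dC1`,
#' `dCf`, `mix1-99`, `mix5-95`, `mix50-50`, `mix95-5` and the `mixf`
#' variants). Greek deltas, spaces and en-dashes in names are normalized,
#' so `"ΔF0"` and `"mixf 5–95"` also parse. The special name
#' `"random"` denotes the random-assignment internal control (not one of
#' the 23 strategies).
#'
#' @param name strategy name, or an existing `strategy` object.
#' @return A `strategy` object: list with `name`, `label`, `family`,
#'   `participation` (`"zero"` = all females contribute, `"one"` = all
#'   females and males, `"free"` = no floor) and mixing weight `p1`.
#' @export
strategy <- function(name) {
  if (inherits(name, "strategy")) return(name)
  stopifnot(is.character(name), length(name) == 1L)
  norm <- gsub(" ", "", name, fixed = TRUE)
  norm <- gsub("[–—]", "-", norm)
  norm <- gsub("Δ", "d", norm)
  norm <- sub("^dmdFdm", "dmFdm", norm)  # printed name ΔmΔFΔm
  if (tolower(norm) == "random") {
    out <- list(name = "random", label = "random", family = "random",
                participation = "free", p1 = NA_real_)
    class(out) <- "strategy"
    return(out)
  }
  tab <- .strategy_table()
  i <- match(norm, tab$name)
  if (is.na(i))
    stop("unknown strategy '", name, "'; valid names are: ",
         paste(tab$name, collapse = ", "), ", random")
  out <- as.list(tab[i, c("name", "label", "family", "participation", "p1")])
  class(out) <- "strategy"
  out
}

#' @export
print.strategy <- function(x, ...) {
  cat(sprintf("<strategy> %s (family %s, participation %s%s)\n", x$label,
              x$family, x$participation,
              if (!is.na(x$p1)) sprintf(", p1 = %.2f", x$p1) else ""))
  invisible(x)
}

#' Construct a mating plan
#'
#' A mating plan assigns sires to dams for one breeding season; each pair
#' occurrence produces exactly one offspring. Pairs are aggregated to
#' `(sire, dam, n)` rows.
#'
#' @param sire,dam parallel id vectors, one entry per offspring (or per
#'   aggregated pair when `n` is given).
#' @param n offspring counts per `(sire, dam)` row; default 1 each.
#' @return A `mating_plan` data frame with columns `sire`, `dam`, `n`.
#' @export
mating_plan <- function(sire, dam, n = NULL) {
  stopifnot(length(sire) == length(dam))
  if (is.null(n)) n <- rep(1L, length(sire))
  df <- stats::aggregate(list(n = as.integer(n)),
                         by = list(sire = as.character(sire),
                                   dam = as.character(dam)), FUN = sum)
  df <- df[order(df$sire, df$dam), c("sire", "dam", "n")]
  rownames(df) <- NULL
  class(df) <- c("mating_plan", "data.frame")
  df
}

#' @export
print.mating_plan <- function(x, ...) {
  cat(sprintf("<mating_plan> %d offspring from %d matings (%d sires, %d dams)\n",
              sum(x$n), nrow(x), length(unique(x$sire)), length(unique(x$dam))))
  if (!is.null(attr(x, "fx")))
    cat(sprintf("  objective Fx = %.6g (%s, %s)\n", attr(x, "fx"),
                attr(x, "strategy") %||% "?", attr(x, "method") %||% "?"))
  print.data.frame(as.data.frame(x))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# one row per offspring
.expand_plan <- function(plan) {
  i <- rep(seq_len(nrow(plan)), plan$n)
  list(sire = plan$sire[i], dam = plan$dam[i])
}

#' Coancestry matrix of the prospective offspring of a plan
#'
#' One-generation extension of the kinship recursion: for offspring `l` of
#' `(j1, k1)` and `m` of `(j2, k2)`,
#' `C_lm = (C_j1j2 + C_j1k2 + C_k1j2 + C_k1k2) / 4`, and the diagonal is
#' the self-coancestry `C_ll = (1 + C_j1k1) / 2`.
#'
#' @param plan a [mating_plan].
#' @param kinship coancestry matrix covering all plan parents.
#' @return Symmetric matrix over the prospective offspring (one per pair
#'   occurrence), named `off1`, `off2`, ...
#' @export
offspring_kinship <- function(plan, kinship) {
  ex <- .expand_plan(plan)
  miss <- setdiff(unique(c(ex$sire, ex$dam)), colnames(kinship))
  if (length(miss)) stop("plan parent(s) not in kinship matrix: ",
                         paste(miss, collapse = ", "))
  s <- match(ex$sire, colnames(kinship))
  d <- match(ex$dam, colnames(kinship))
  Ko <- 0.25 * (kinship[s, s, drop = FALSE] + kinship[s, d, drop = FALSE] +
                kinship[d, s, drop = FALSE] + kinship[d, d, drop = FALSE])
  diag(Ko) <- 0.5 * (1 + kinship[cbind(s, d)])
  dimnames(Ko) <- list(paste0("off", seq_along(s)), paste0("off", seq_along(s)))
  Ko
}

#' Objective value of a mating plan under a strategy
#'
#' Evaluates the quantity the strategy minimizes. Parent components sum
#' over pair occurrences; offspring components sum over unordered distinct
#' prospective-offspring pairs. The `mix` family combines per-term means:
#' `p1 * mean(C_jk) + (1 - p1) * mean(C_lm)`, so that the printed weights
#' are not distorted by the different term counts of the two sums.
#'
#' @param plan a [mating_plan].
#' @param strat a [strategy()] (or its name).
#' @param kinship coancestry matrix over the full candidate mating group
#'   (all candidate males and females; mean-kinship weights are computed
#'   over every column of this matrix).
#' @param eg named equivalent-generations vector over the candidates;
#'   required for the increase-based families (`dF`, `dmFdm`, `dC`).
#' @param include_self also count offspring self-coancestries in the
#'   offspring component (sensitivity option; default `FALSE`, matching the
#'   definition over pairs of two offspring).
#' @return The scalar objective `Fx`.
#' @export
objective_value <- function(plan, strat, kinship, eg = NULL,
                            include_self = FALSE) {
  strat <- strategy(strat)
  ex <- .expand_plan(plan)
  ids <- colnames(kinship)
  miss <- setdiff(unique(c(ex$sire, ex$dam)), ids)
  if (length(miss)) stop("plan parent(s) not in kinship matrix: ",
                         paste(miss, collapse = ", "))
  needs_eg <- strat$family %in% c("dF", "dmFdm", "dC")
  if (needs_eg) {
    if (is.null(eg)) stop("strategy family '", strat$family, "' requires eg values")
    eg <- eg[ids]
    if (anyNA(eg)) stop("missing eg value for candidate(s)")
  }
  s <- match(ex$sire, ids)
  d <- match(ex$dam, ids)
  cjk <- kinship[cbind(s, d)]

  parent_terms <- switch(strat$family,
    "F" = , "mix" = cjk,
    "dF" = delta_C(cjk, eg[s], eg[d]),
    "mFm" = {
      m <- mean_kinship_weights(kinship)
      m[s] * cjk * m[d]
    },
    "dmFdm" = {
      dm <- mean_kinship_weights(kinship, mode = "increase", eg = eg)
      dm[s] * delta_C(cjk, eg[s], eg[d]) * dm[d]
    },
    NULL)

  offspring_terms <- NULL
  if (strat$family %in% c("C", "dC", "mix")) {
    Ko <- offspring_kinship(plan, kinship)
    sel <- if (include_self) upper.tri(Ko, diag = TRUE) else upper.tri(Ko)
    if (strat$family == "dC") {
      go <- 1 + (eg[s] + eg[d]) / 2
      G <- matrix(go, length(go), length(go))
      offspring_terms <- delta_C(Ko[sel], G[sel], t(G)[sel])
    } else {
      offspring_terms <- Ko[sel]
    }
  }
  switch(strat$family,
    "F" = , "dF" = , "mFm" = , "dmFdm" = sum(parent_terms),
    "C" = , "dC" = sum(offspring_terms),
    "mix" = strat$p1 * mean(parent_terms) +
      (1 - strat$p1) * (if (length(offspring_terms)) mean(offspring_terms) else 0),
    stop("objective undefined for strategy '", strat$name, "'"))
}

#' Check feasibility of a mating plan
#'
#' A plan is feasible for a strategy when every sire is a candidate male and
#' every dam a candidate female, the plan produces exactly `n_target`
#' offspring, each dam has at most one distinct sire (harem constraint,
#' reflecting polygyny; disable with `harem = FALSE`), the number of
#' distinct sires does not exceed the number of distinct dams, and the
#' strategy's participation floor holds (`"zero"`: every female >= 1
#' offspring; `"one"`: every female and every male; `"free"`: none).
#'
#' @param plan a [mating_plan].
#' @param strat a [strategy()] or its name.
#' @param males,females candidate parent ids.
#' @param n_target required number of offspring; default `sum(plan$n)`.
#' @param harem enforce the one-sire-per-dam constraint (default `TRUE`).
#' @return `TRUE`/`FALSE`, with attribute `reasons` listing violations.
#' @export
is_feasible <- function(plan, strat, males, females, n_target = NULL,
                        harem = TRUE) {
  strat <- strategy(strat)
  if (is.null(n_target)) n_target <- sum(plan$n)
  reasons <- character(0)
  if (!all(plan$sire %in% males)) reasons <- c(reasons, "sire not a candidate male")
  if (!all(plan$dam %in% females)) reasons <- c(reasons, "dam not a candidate female")
  if (sum(plan$n) != n_target)
    reasons <- c(reasons, sprintf("plan yields %d offspring, target is %d",
                                  sum(plan$n), n_target))
  sires_per_dam <- tapply(plan$sire, plan$dam, function(x) length(unique(x)))
  if (harem && any(sires_per_dam > 1L))
    reasons <- c(reasons, "harem constraint violated (dam with several sires)")
  if (length(unique(plan$sire)) > length(unique(plan$dam)))
    reasons <- c(reasons, "more distinct sires than dams")
  if (strat$participation %in% c("zero", "one") &&
      !all(females %in% plan$dam))
    reasons <- c(reasons, "some female does not contribute")
  if (strat$participation == "one" && !all(males %in% plan$sire))
    reasons <- c(reasons, "some male does not contribute")
  out <- length(reasons) == 0L
  attr(out, "reasons") <- reasons
  out
}

#' Optimize a mating plan under a strategy
#'
#' Finds the feasible mating plan minimizing the strategy objective.
#' Below a plan-space size bound the exact global minimizer is returned by
#' exhaustive enumeration (ties broken by enumeration order, which is
#' lexicographic in the dam-count and sire-assignment encoding); above the
#' bound, simulated annealing from a feasible random start, with moves that
#' reassign a dam's sire, move one offspring slot between dams or swap two
#' dams' sires, geometric cooling, a final first-improvement descent, and
#' the best plan over restarts.
#'
#' @param strat a [strategy()] or its name (the internal control
#'   `"random"` is not optimizable; use [random_plan()]).
#' @param kinship coancestry matrix over all candidates (males and
#'   females), e.g. from [kinship_matrix()].
#' @param males,females candidate ids; males must not outnumber females
#'   (harem/polygyny setting).
#' @param n_target number of offspring the plan must produce.
#' @param eg named equivalent-generations vector, required for the
#'   increase-based families.
#' @param method `"auto"` (default), `"exact"` or `"anneal"`.
#' @param seed optional integer; when given, `set.seed(seed)` is called so
#'   the annealing result is reproducible.
#' @param control list of optimizer settings: `exact_limit` (plan-space
#'   bound below which `"auto"` enumerates; default `5e5`), `n_restarts`
#'   (default 3) and `n_iter` annealing proposals per restart
#'   (default 3000).
#' @return A [mating_plan] with attributes `fx` (objective value),
#'   `method`, `strategy` and `evals`.
#' @export
optimize_plan <- function(strat, kinship, males, females, n_target,
                          eg = NULL, method = c("auto", "exact", "anneal"),
                          seed = NULL, control = list()) {
  strat <- strategy(strat)
  method <- match.arg(method)
  if (strat$family == "random")
    stop("'random' is the unoptimized control; use random_plan()")
  ctl <- modifyList(list(exact_limit = 5e5, n_restarts = 3L, n_iter = 3000L),
                    control)
  ids <- colnames(kinship)
  miss <- setdiff(c(males, females), ids)
  if (length(miss)) stop("candidate(s) not in kinship matrix: ",
                         paste(miss, collapse = ", "))
  if (length(intersect(males, females)))
    stop("candidate listed as both male and female")
  M <- length(males); F_ <- length(females)
  if (M < 1L || F_ < 1L) stop("need at least one candidate of each sex")
  if (M > F_) stop("infeasible: more males (", M, ") than females (", F_,
                   "); the harem setting requires males <= females")
  floor_f <- if (strat$participation == "free") 0L else 1L
  if (n_target < floor_f * F_)
    stop("infeasible: participation '", strat$participation, "' needs at least ",
         floor_f * F_, " offspring, target is ", n_target)
  ord <- c(males, females)
  K <- kinship[ord, ord, drop = FALSE]
  needs_eg <- strat$family %in% c("dF", "dmFdm", "dC")
  egv <- if (needs_eg) {
    if (is.null(eg)) stop("strategy family '", strat$family, "' requires eg values")
    v <- as.numeric(eg[ord])
    if (anyNA(v)) stop("missing eg value for candidate(s)")
    v
  } else numeric(M + F_)
  if (method == "auto") {
    bound <- .plan_space_bound_cpp(M, F_, as.integer(n_target),
                                   .participation_code[[strat$participation]])
    method <- if (bound <= ctl$exact_limit) "exact" else "anneal"
  }
  if (!is.null(seed)) set.seed(seed)
  res <- .optimize_plan_cpp(K, egv, M, F_,
                            .family_code[[strat$family]],
                            if (is.na(strat$p1)) 0 else strat$p1,
                            .participation_code[[strat$participation]],
                            as.integer(n_target), method,
                            as.integer(ctl$n_restarts), as.integer(ctl$n_iter))
  act <- which(res$count > 0L)
  plan <- mating_plan(males[res$sire[act]], females[act], res$count[act])
  attr(plan, "fx") <- res$fx
  attr(plan, "method") <- method
  attr(plan, "strategy") <- strat$name
  attr(plan, "evals") <- res$evals
  plan
}

#' Random feasible mating plan
#'
#' Draws a feasible harem plan uniformly at random in its encoding: after
#' the participation floor, offspring slots go to random dams and each
#' active dam gets a random sire (covering all males first under
#' participation `"one"`). Used as the unoptimized internal control of the
#' simulator and as a baseline in optimizer checks.
#'
#' @inheritParams optimize_plan
#' @param participation `"zero"`, `"one"` or `"free"`.
#' @return A [mating_plan].
#' @export
random_plan <- function(males, females, n_target,
                        participation = c("free", "zero", "one"),
                        seed = NULL) {
  participation <- match.arg(participation)
  M <- length(males); F_ <- length(females)
  stopifnot(M >= 1L, F_ >= 1L)
  if (M > F_) stop("infeasible: more males than females")
  floor_f <- if (participation == "free") 0L else 1L
  if (n_target < max(1L, floor_f * F_))
    stop("infeasible cohort size for participation '", participation, "'")
  if (!is.null(seed)) set.seed(seed)
  cnt <- rep(floor_f, F_)
  left <- n_target - sum(cnt)
  if (left > 0) {
    extra <- tabulate(sample.int(F_, left, replace = TRUE), nbins = F_)
    cnt <- cnt + extra
  }
  act <- which(cnt > 0L)
  sires <- integer(F_)
  if (participation == "one") {
    cover <- sample(act, M)
    sires[cover] <- sample.int(M, M)
    rest <- setdiff(act, cover)
    if (length(rest)) sires[rest] <- sample.int(M, length(rest), replace = TRUE)
  } else {
    sires[act] <- sample.int(M, length(act), replace = TRUE)
  }
  mating_plan(males[sires[act]], females[act], cnt[act])
}
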