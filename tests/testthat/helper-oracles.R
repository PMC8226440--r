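# Independent oracles, written without touching the package's compiled
# kinship path: a memoized recursive kinship (classical path-counting
# recursion) and a plain-R enumeration of feasible harem mating plans.

# recursive kinship oracle over a (topologically sorted) pedigree
oracle_kinship <- function(ped) {
  n <- nrow(ped)
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  memo <- new.env(hash = TRUE, parent = emptyenv())
  f <- function(a, b) {
    if (a > b) { tmp <- a; a <- b; b <- tmp }
    key <- paste0(a, "_", b)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    val <- if (a == b) {
      0.5 * (1 + if (!is.na(si[a]) && !is.na(di[a])) f(si[a], di[a]) else 0)
    } else {
      # b is the later-born of the two in topological order
      0.5 * ((if (!is.na(si[b])) f(a, si[b]) else 0) +
             (if (!is.na(di[b])) f(a, di[b]) else 0))
    }
    memo[[key]] <- val
    val
  }
  K <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) for (j in i:n) K[i, j] <- K[j, i] <- f(i, j)
  K
}

# random pedigree with consistent sexes and ~80% known parents
random_test_pedigree <- function(n, seed) {
  set.seed(seed)
  sex <- sample(c("M", "F"), n, replace = TRUE)
  sex[1] <- "M"; sex[2] <- "F"
  id <- paste0("I", seq_len(n))
  sire <- dam <- rep(NA_character_, n)
  for (i in seq_len(n)[-(1:2)]) {
    em <- which(sex[seq_len(i - 1)] == "M")
    ef <- which(sex[seq_len(i - 1)] == "F")
    if (length(em) && stats::runif(1) < 0.8)
      sire[i] <- id[em[sample.int(length(em), 1)]]
    if (length(ef) && stats::runif(1) < 0.8)
      dam[i] <- id[ef[sample.int(length(ef), 1)]]
  }
  pedigree(id = id, sire = sire, dam = dam, sex = sex)
}

# all feasible harem plans for a tiny instance, as mating_plan objects
enumerate_plans <- function(males, females, n_target, participation) {
  floor_f <- if (participation == "free") 0L else 1L
  Fn <- length(females)
  compositions <- function(left, slots) {
    if (slots == 1L) return(if (left >= floor_f) list(left) else list())
    out <- list()
    for (c1 in floor_f:(left - floor_f * (slots - 1L))) {
      if (c1 < floor_f) next
      for (rest in compositions(left - c1, slots - 1L))
        out[[length(out) + 1L]] <- c(c1, rest)
    }
    out
  }
  plans <- list()
  for (cnt in compositions(n_target, Fn)) {
    act <- which(cnt > 0L)
    grids <- rep(list(seq_along(males)), length(act))
    assign <- as.matrix(do.call(expand.grid, grids))
    for (r in seq_len(nrow(assign))) {
      sires <- assign[r, ]
      if (participation == "one" &&
          length(unique(sires)) < length(males)) next
      if (length(unique(sires)) > length(act)) next
      plans[[length(plans) + 1L]] <-
        mating_plan(males[sires], females[act], cnt[act])
    }
  }
  plans
}

# safe single draw from a vector of any length
pick1 <- function(v) v[sample.int(length(v), 1L)]

# a tiny random optimization instance drawn from a random pedigree
random_instance <- function(seed, max_m = 4L, max_f = 5L, max_nt = 6L) {
  set.seed(seed)
  repeat {
    ped <- random_test_pedigree(14L, seed = seed + 5000L)
    males <- ped$id[ped$sex == "M"]
    females <- ped$id[ped$sex == "F"]
    if (length(males) >= 1L && length(females) >= 2L) break
    seed <- seed + 11L
  }
  M <- pick1(seq_len(min(max_m, length(males), length(females))))
  Fn <- pick1(seq(max(2L, M), max(max(2L, M), min(max_f, length(females)))))
  males <- sample(males, M)
  females <- sample(females, Fn)
  nt <- pick1(seq(Fn, max(Fn, max_nt)))
  K <- kinship_matrix(ped)[c(males, females), c(males, females)]
  eg <- equivalent_generations(ped)[c(males, females)] + 1  # keep all g > 0
  list(males = males, females = females, n_target = nt, K = K, eg = eg)
}
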