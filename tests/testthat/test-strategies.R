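# a founder-only candidate set: every objective is 0 and any plan optimal
founder_instance <- function(n_m = 2L, n_f = 3L) {
  ids <- c(paste0("M", seq_len(n_m)), paste0("F", seq_len(n_f)))
  ped <- pedigree(id = ids, sire = rep(NA_character_, n_m + n_f),
                  dam = rep(NA_character_, n_m + n_f),
                  sex = rep(c("M", "F"), c(n_m, n_f)))
  list(males = ids[seq_len(n_m)], females = ids[-seq_len(n_m)],
       K = kinship_matrix(ped),
       eg = setNames(rep(2, n_m + n_f), ids))  # positive depth for dC/dF
}

test_that("the strategy catalogue holds exactly the 23 printed names", {
  nm <- list_strategies()
  expect_length(nm, 23L)
  expect_false(anyDuplicated(nm) > 0)
  for (s in nm) {
    sp <- strategy(s)
    expect_s3_class(sp, "strategy")
    expect_identical(sp$name, s)
    expect_identical(!is.na(sp$p1), sp$family == "mix")
  }
  # mix weights as printed
  expect_equal(strategy("mix1-99")$p1, 0.01)
  expect_equal(strategy("mixf5-95")$p1, 0.05)
  expect_equal(strategy("mix50-50")$p1, 0.50)
  expect_equal(strategy("mixf95-5")$p1, 0.95)
  # participation coding: 0 = all females, 1 = all females and males, f = free
  expect_identical(strategy("F0")$participation, "zero")
  expect_identical(strategy("C1")$participation, "one")
  expect_identical(strategy("dCf")$participation, "free")
  expect_identical(strategy("mix5-95")$participation, "zero")
  expect_identical(strategy("mixf5-95")$participation, "free")
})

test_that("printed aliases with deltas, spaces and en-dashes parse", {
  expect_identical(strategy("ΔF0")$name, "dF0")
  expect_identical(strategy("ΔmΔFΔm1")$name, "dmFdm1")
  expect_identical(strategy("mixf 5–95")$name, "mixf5-95")
  expect_identical(strategy("mix 50-50")$name, "mix50-50")
  expect_error(strategy("bogus"), "valid names")
})

test_that("offspring kinship follows the one-generation recursion", {
  inst <- founder_instance(3L, 3L)
  plan <- mating_plan(c("M1", "M2"), c("F1", "F2"))
  Ko <- offspring_kinship(plan, inst$K)
  expect_equal(Ko[1, 2], 0)          # unrelated founder parents
  expect_equal(diag(Ko), c(off1 = 0.5, off2 = 0.5))
  # shared sire: C_lm = C_MM / 4 = 0.125
  plan2 <- mating_plan(c("M1", "M1"), c("F1", "F2"))
  expect_equal(offspring_kinship(plan2, inst$K)[1, 2], 0.125)
  # full sibs from one repeated mating
  plan3 <- mating_plan("M1", "F1", n = 2L)
  expect_equal(offspring_kinship(plan3, inst$K)[1, 2], 0.25)
})

test_that("objective values match hand evaluations", {
  inst <- founder_instance(2L, 2L)
  K <- inst$K
  K["M1", "F1"] <- K["F1", "M1"] <- 0.25
  plan <- mating_plan(c("M1", "M2"), c("F1", "F2"))
  expect_equal(objective_value(plan, "F0", K), 0.25)
  # founders: all 23 objectives are 0
  planf <- mating_plan(c("M1", "M2"), c("F1", "F2"))
  for (s in list_strategies()) {
    expect_equal(objective_value(planf, s, inst$K, eg = inst$eg), 0,
                 info = s)
  }
  # mix combines per-term means of the two components
  p1 <- 0.5
  parent_mean <- mean(c(0.25, 0))
  Ko <- offspring_kinship(plan, K)
  off_mean <- mean(Ko[upper.tri(Ko)])
  expect_equal(objective_value(plan, "mix50-50", K),
               p1 * parent_mean + (1 - p1) * off_mean)
})

test_that("feasibility enforces participation, harem and sex-ratio rules", {
  males <- c("M1", "M2"); females <- c("F1", "F2")
  ok <- mating_plan(c("M1", "M2"), c("F1", "F2"))
  expect_true(is_feasible(ok, "F1", males, females, 2))
  miss_male <- mating_plan(c("M1", "M1"), c("F1", "F2"))
  expect_false(is_feasible(miss_male, "F1", males, females, 2))
  expect_match(attr(is_feasible(miss_male, "F1", males, females, 2), "reasons"),
               "male", all = FALSE)
  # free participation: the same plan is fine
  expect_true(is_feasible(miss_male, "Ff", males, females, 2))
  # 1M/3F zero-variant: only plans using all three dams are feasible
  expect_true(is_feasible(mating_plan(rep("M1", 3), c("F1", "F2", "F3")),
                          "F0", "M1", c("F1", "F2", "F3"), 3))
  expect_false(is_feasible(mating_plan(rep("M1", 3), c("F1", "F1", "F2")),
                           "F0", "M1", c("F1", "F2", "F3"), 3))
  # harem: one dam served by two sires (sires <= dams still holds)
  poly <- mating_plan(c("M1", "M2", "M1"), c("F1", "F1", "F2"))
  expect_false(is_feasible(poly, "Ff", males, females, 3))
  expect_true(is_feasible(poly, "Ff", males, females, 3, harem = FALSE))
  # even without the harem rule, sires may never outnumber dams
  spread <- mating_plan(c("M1", "M2"), c("F1", "F1"))
  expect_false(is_feasible(spread, "Ff", males, females, 2, harem = FALSE))
  # wrong cohort size
  expect_false(is_feasible(ok, "F1", males, females, 3))
})

test_that("optimizer returns the forced plan and the known 2x2 optimum", {
  inst <- founder_instance(1L, 1L)
  p <- optimize_plan("Ff", inst$K, "M1", "F1", 1)
  expect_equal(as.data.frame(p),
               data.frame(sire = "M1", dam = "F1", n = 1L),
               ignore_attr = TRUE)
  inst2 <- founder_instance(2L, 2L)
  K <- inst2$K
  K["M1", "F1"] <- K["F1", "M1"] <- 0.25
  p2 <- optimize_plan("F1", K, inst2$males, inst2$females, 2, method = "exact")
  expect_equal(attr(p2, "fx"), 0)
  expect_equal(as.data.frame(p2),
               data.frame(sire = c("M1", "M2"), dam = c("F2", "F1"),
                          n = c(1L, 1L)),
               ignore_attr = TRUE)
})

test_that("exact optimization equals the plain-R enumeration oracle", {
  for (seed in c(11, 31, 57)) {
    inst <- random_instance(seed, max_m = 3L, max_f = 4L, max_nt = 5L)
    for (s in c("F0", "F1", "Ff", "dF1", "mFm0", "dmFdm1", "C0", "Cf",
                "dC1", "mix5-95", "mixf50-50")) {
      sp <- strategy(s)
      plans <- enumerate_plans(inst$males, inst$females, inst$n_target,
                               sp$participation)
      expect_gt(length(plans), 0)
      fxs <- vapply(plans, objective_value, numeric(1), strat = sp,
                    kinship = inst$K, eg = inst$eg)
      p <- optimize_plan(sp, inst$K, inst$males, inst$females, inst$n_target,
                         eg = inst$eg, method = "exact")
      expect_equal(attr(p, "fx"), min(fxs), tolerance = 1e-10,
                   info = sprintf("%s seed %d", s, seed))
      # the reported fx is the objective of the reported plan
      expect_equal(objective_value(p, sp, inst$K, eg = inst$eg),
                   attr(p, "fx"), tolerance = 1e-10, info = s)
    }
  }
})

test_that("annealing matches the exact optimum on small instances", {
  for (seed in c(101, 202)) {
    inst <- random_instance(seed)
    for (s in c("F1", "Ff", "dF0", "C1", "dCf", "mixf5-95")) {
      pe <- optimize_plan(s, inst$K, inst$males, inst$females, inst$n_target,
                          eg = inst$eg, method = "exact")
      pa <- optimize_plan(s, inst$K, inst$males, inst$females, inst$n_target,
                          eg = inst$eg, method = "anneal", seed = seed)
      expect_equal(attr(pa, "fx"), attr(pe, "fx"), tolerance = 1e-9,
                   info = sprintf("%s seed %d", s, seed))
    }
  }
})

test_that("optimized plans dominate random feasible plans and pass feasibility", {
  inst <- random_instance(77, max_m = 3L, max_f = 5L, max_nt = 6L)
  for (s in list_strategies()) {
    sp <- strategy(s)
    p <- optimize_plan(sp, inst$K, inst$males, inst$females, inst$n_target,
                       eg = inst$eg, seed = 1)
    expect_true(is_feasible(p, sp, inst$males, inst$females, inst$n_target),
                info = s)
    set.seed(1000)
    rnd <- replicate(300, {
      rp <- random_plan(inst$males, inst$females, inst$n_target,
                        participation = sp$participation)
      objective_value(rp, sp, inst$K, eg = inst$eg)
    })
    expect_lte(attr(p, "fx"), min(rnd) + 1e-10)
  }
})

test_that("every strategy attains Fx = 0 on founders admitting disjoint pairings", {
  # with as many sires as dams the offspring of a perfect matching share no
  # parent, so parent AND offspring coancestry terms can all vanish
  inst <- founder_instance(4L, 4L)
  for (s in list_strategies()) {
    p <- optimize_plan(s, inst$K, inst$males, inst$females, 4, eg = inst$eg,
                       seed = 2)
    expect_equal(attr(p, "fx"), 0, info = s)
  }
  # with fewer sires than dams, parent-coancestry objectives still reach 0
  # but offspring objectives cannot: half-sib pairs are forced
  inst2 <- founder_instance(3L, 4L)
  for (s in c("F0", "F1", "Ff", "dF0", "mFm1", "dmFdm0")) {
    p <- optimize_plan(s, inst2$K, inst2$males, inst2$females, 4,
                       eg = inst2$eg, seed = 2)
    expect_equal(attr(p, "fx"), 0, info = s)
  }
  pC <- optimize_plan("C0", inst2$K, inst2$males, inst2$females, 4,
                      eg = inst2$eg, method = "exact")
  expect_equal(attr(pC, "fx"), 0.125)  # exactly one half-sib pair at C/4
})

test_that("mix at the p1 limits reproduces the F and C objective orderings", {
  inst <- random_instance(55)
  mk_mix <- function(p1) {
    structure(list(name = sprintf("mix-p%g", p1), label = "mix",
                   family = "mix", participation = "free", p1 = p1),
              class = "strategy")
  }
  set.seed(3)
  plans <- replicate(15, random_plan(inst$males, inst$females,
                                     inst$n_target), simplify = FALSE)
  fx_of <- function(sp) vapply(plans, objective_value, numeric(1), strat = sp,
                               kinship = inst$K, eg = inst$eg)
  expect_equal(rank(fx_of(mk_mix(1))), rank(fx_of(strategy("Ff"))))
  expect_equal(rank(fx_of(mk_mix(0))), rank(fx_of(strategy("Cf"))))
})

test_that("infeasible constraint sets raise explicit errors", {
  inst <- founder_instance(2L, 2L)
  # participation one with a cohort smaller than the number of females
  expect_error(optimize_plan("F1", inst$K, inst$males, inst$females, 1),
               "participation")
  # more males than females violates the harem setting
  inst2 <- founder_instance(3L, 2L)
  expect_error(optimize_plan("Ff", inst2$K, inst2$males, inst2$females, 3),
               "males")
  expect_error(optimize_plan("random", inst$K, inst$males, inst$females, 2),
               "random_plan")
})
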