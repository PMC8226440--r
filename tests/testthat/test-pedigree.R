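test_that("reading a minimal pedigree resolves parents and survives row shuffles", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,sire,dam,sex", "A,,,M", "B,,,F", "C,A,B,M"), path)
  ped <- read_pedigree(path)
  expect_s3_class(ped, "pedigree")
  expect_equal(nrow(ped), 3L)
  expect_equal(ped$sire[ped$id == "C"], "A")
  expect_equal(ped$dam[ped$id == "C"], "B")

  # same pedigree, offspring listed first: identical after topological sort
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,sire,dam,sex", "C,A,B,M", "A,,,M", "B,,,F"), path2)
  ped2 <- read_pedigree(path2)
  expect_identical(as.data.frame(ped[order(ped$id), ]),
                   as.data.frame(ped2[order(ped2$id), ]))
  expect_identical(kinship_matrix(ped)[ped$id, ped$id],
                   kinship_matrix(ped2)[ped$id, ped$id])
})

test_that("delimiters are auto-detected and unknown-parent codes mapped", {
  for (sep in c("\t", ";", ",")) {
    path <- withr::local_tempfile(fileext = ".txt")
    writeLines(c(paste(c("id", "sire", "dam", "sex", "birth"), collapse = sep),
                 paste(c("A", "0", "UNK", "M", "2001"), collapse = sep),
                 paste(c("B", "", "0", "F", "2002"), collapse = sep),
                 paste(c("C", "A", "B", "M", "2005"), collapse = sep)), path)
    ped <- read_pedigree(path)
    expect_true(all(is.na(ped$sire[ped$id %in% c("A", "B")])))
    expect_equal(ped$birth[ped$id == "C"], 2005)
  }
})

test_that("degenerate inputs are hard errors naming the culprit", {
  expect_error(pedigree(id = c("X", "B"), sire = c("X", NA),
                        dam = c(NA, NA), sex = c("M", "F")),
               "cycle.*X")
  expect_error(pedigree(id = c("A", "A"), sire = c(NA, NA), dam = c(NA, NA)),
               "duplicate")
  # P used as sire of one individual and dam of another
  expect_error(pedigree(id = c("P", "Q", "R"), sire = c(NA, "P", NA),
                        dam = c(NA, NA, "P")),
               "both as sire and as dam")
  expect_error(pedigree(id = c("A", "B"), sire = c(NA, "A"), dam = c(NA, NA),
                        sex = c("F", "M")),
               "contradicts")
})

test_that("kinship matches textbook values on hand-built pedigrees", {
  founders <- pedigree(id = c("A", "B"), sire = c(NA, NA), dam = c(NA, NA),
                       sex = c("M", "F"))
  K <- kinship_matrix(founders)
  expect_equal(unname(K), matrix(c(0.5, 0, 0, 0.5), 2))

  # parent-offspring with an unrelated founder as the other parent
  trio <- pedigree(id = c("A", "B", "C"), sire = c(NA, NA, "A"),
                   dam = c(NA, NA, "B"), sex = c("M", "F", "F"))
  expect_equal(kinship_matrix(trio)["A", "C"], 0.25)

  # full sibs and their offspring (frozen from the path-counting oracle)
  sibs <- pedigree(id = c("A", "B", "C", "D", "E"),
                   sire = c(NA, NA, "A", "A", "C"),
                   dam = c(NA, NA, "B", "B", "D"),
                   sex = c("M", "F", "M", "F", "M"))
  K <- kinship_matrix(sibs)
  expect_equal(K["C", "D"], 0.25)
  expect_equal(inbreeding(sibs)[["E"]], 0.25)
  expect_equal(unname(kinship_matrix(sibs)), unname(oracle_kinship(sibs)),
               tolerance = 1e-12)
})

test_that("inbreeding handles founders and parent-offspring matings", {
  ped <- pedigree(id = c("A", "B", "C", "D"),
                  sire = c(NA, NA, "A", "A"),
                  dam = c(NA, NA, "B", "C"),
                  sex = c("M", "F", "F", "F"))
  f <- inbreeding(ped)
  expect_equal(f[["A"]], 0)
  expect_equal(f[["C"]], 0)
  expect_equal(f[["D"]], 0.25)  # sire mated to his own daughter
  expect_error(inbreeding(ped, "nope"), "not in pedigree")
})

test_that("equivalent generations follow the (1/2)^n ancestor sum", {
  ped <- pedigree(id = c("A", "B", "C", "D", "E", "F", "G"),
                  sire = c(NA, NA, NA, NA, "A", "C", "E"),
                  dam = c(NA, NA, NA, NA, "B", "D", "F"),
                  sex = c("M", "F", "M", "F", "M", "F", "M"))
  eg <- equivalent_generations(ped)
  expect_equal(eg[["A"]], 0)
  expect_equal(eg[["E"]], 1)   # both parents founders
  expect_equal(eg[["G"]], 2)   # 2 x 1/2 + 4 x 1/4
  # single known parent contributes (1 + EG)/2
  ped2 <- pedigree(id = c("A", "B"), sire = c(NA, "A"), dam = c(NA, NA),
                   sex = c("M", "M"))
  expect_equal(equivalent_generations(ped2)[["B"]], 0.5)
})

test_that("generation interval averages parent ages over reproductive links", {
  ped <- pedigree(id = c("S", "D", "X", "Y"),
                  sire = c(NA, NA, "S", "X"),
                  dam = c(NA, NA, "D", "D"),
                  sex = c("M", "F", "M", "F"),
                  birth = c(2000, 1998, 2004, 2008))
  # X is the only offspring that itself reproduces: sire aged 4, dam aged 6
  gi <- generation_interval(ped)
  expect_equal(as.numeric(gi), 5)
  expect_equal(attr(gi, "n_links"), 2L)

  no_rep <- pedigree(id = c("S", "D", "X"), sire = c(NA, NA, "S"),
                     dam = c(NA, NA, "D"), sex = c("M", "F", "M"),
                     birth = c(2000, 2000, 2004))
  gi2 <- generation_interval(no_rep)
  expect_true(is.na(gi2))
  expect_equal(attr(gi2, "n_links"), 0L)
})

test_that("reference cohorts filter by flock and inclusive birth window", {
  ped <- pedigree(id = paste0("I", 1:6),
                  sire = rep(NA_character_, 6), dam = rep(NA_character_, 6),
                  sex = c("M", "F", "F", "M", "F", "M"),
                  birth = c(2013, 2014, 2015, 2015, 2014, 2016),
                  flock = c("A", "A", "A", "B", "B", "A"))
  coh <- reference_cohort(ped, flock = "A", years = c(2014, 2015))
  expect_setequal(coh, c("I2", "I3"))
  expect_equal(attr(coh, "counts"), c(males = 0L, females = 2L))
  expect_warning(empty <- reference_cohort(ped, years = c(1990, 1991)),
                 "empty")
  expect_length(empty, 0L)
})

test_that("kinship is symmetric with diagonal (1+F)/2 on random pedigrees", {
  for (seed in 1:10) {
    ped <- random_test_pedigree(12L, seed)
    K <- kinship_matrix(ped)
    expect_equal(K, t(K), tolerance = 1e-12)
    expect_equal(unname(diag(K)), unname((1 + inbreeding(ped)) / 2),
                 tolerance = 1e-12)
    expect_true(all(K >= 0 & K <= 1))
  }
})

test_that("kinship and EG are invariant to input row order", {
  ped <- random_test_pedigree(12L, seed = 99)
  df <- as.data.frame(ped)
  set.seed(1)
  shuffled <- as_pedigree(df[sample.int(nrow(df)), ])
  ids <- sort(ped$id)
  expect_equal(kinship_matrix(ped)[ids, ids],
               kinship_matrix(shuffled)[ids, ids], tolerance = 1e-15)
  expect_equal(equivalent_generations(ped)[ids],
               equivalent_generations(shuffled)[ids], tolerance = 1e-15)
})

test_that("discovering an ancestor never decreases a descendant's EG", {
  base <- pedigree(id = c("A", "B", "C", "D"),
                   sire = c(NA, NA, "A", "C"),
                   dam = c(NA, NA, "B", "B"),
                   sex = c("M", "F", "M", "F"))
  eg0 <- equivalent_generations(base)
  # the same pedigree after A's sire becomes known
  deeper <- pedigree(id = c("Z", "A", "B", "C", "D"),
                     sire = c(NA, "Z", NA, "A", "C"),
                     dam = c(NA, NA, NA, "B", "B"),
                     sex = c("M", "M", "F", "M", "F"))
  eg1 <- equivalent_generations(deeper)
  expect_true(all(eg1[names(eg0)] >= eg0 - 1e-12))
  expect_gt(eg1[["C"]], eg0[["C"]])
})

test_that("pedigree round-trips through write_pedigree/read_pedigree", {
  ped <- random_test_pedigree(15L, seed = 7)
  path <- withr::local_tempfile(fileext = ".csv")
  write_pedigree(ped, path)
  back <- read_pedigree(path)
  ids <- sort(ped$id)
  expect_equal(as.data.frame(ped)[match(ids, ped$id), c("id", "sire", "dam", "sex")],
               as.data.frame(back)[match(ids, back$id), c("id", "sire", "dam", "sex")],
               ignore_attr = TRUE)
  expect_equal(kinship_matrix(ped)[ids, ids], kinship_matrix(back)[ids, ids])
})

test_that("pedigree_stats reports the structure panel", {
  ped <- random_test_pedigree(20L, seed = 3)
  st <- pedigree_stats(ped)
  expect_equal(st$n, 20L)
  expect_equal(st$sex_ratio, st$n_females / st$n_males)
  expect_true(st$mean_F >= 0 && st$mean_F <= 1)
  expect_true(st$mean_EG >= 0)
  expect_output(print(st), "Ratio females/males")
})
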