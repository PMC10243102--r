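test_that("profile CSV round-trip preserves the matrix", {
  co <- generate_cohort(small_config(seed = 3))
  path <- withr::local_tempfile(fileext = ".csv")
  write_profiles(co$profiles, path)
  back <- read_profiles(path)
  expect_equal(back$values, co$profiles$values, tolerance = 1e-12)
  expect_identical(back$groups, co$profiles$groups)
})

test_that("validation rejects bad inputs, naming the offender", {
  vals <- matrix(c(1, 2, 3, 4), 2, 2,
                 dimnames = list(c("s1", "s2"), c("m1", "m2")))
  bad <- vals; bad["s2", "m1"] <- -1
  expect_error(profile_matrix(bad, c("A", "B")), "s2.*m1")
  nas <- vals; nas["s1", "m2"] <- NA
  expect_error(profile_matrix(nas, c("A", "B")), "missing.*s1.*m2")
  dup <- vals; rownames(dup) <- c("s1", "s1")
  expect_error(profile_matrix(dup, c("A", "B")), "duplicated sample ids")

  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,group,m1,m2", "s1,A,1,2", "s1,B,-3,4"), path)
  expect_error(read_profiles(path), "duplicated sample ids")
})

test_that("exclusion filter drops the named columns and nothing else", {
  co <- generate_cohort(small_config(seed = 1))
  expect_equal(ncol(co$profiles$values), 63L)
  kept <- exclude_metabolites(co$profiles, c("Glycerol", "Propylene glycol"))
  expect_equal(ncol(kept$values), 61L)
  expect_false(any(c("Glycerol", "Propylene glycol") %in%
                     colnames(kept$values)))
  # order of the survivors preserved
  expect_identical(colnames(kept$values),
                   setdiff(colnames(co$profiles$values),
                           c("Glycerol", "Propylene glycol")))
  expect_identical(exclude_metabolites(co$profiles, character(0)),
                   co$profiles)
  expect_error(exclude_metabolites(co$profiles, "unobtainium"),
               "unknown metabolite")
})

test_that("total-area normalization sums rows to one, idempotently and scale-invariantly", {
  set.seed(42)
  vals <- matrix(rexp(60) + 0.1, 6, 10,
                 dimnames = list(paste0("s", 1:6), paste0("m", 1:10)))
  m <- profile_matrix(vals, rep("G", 6))
  norm <- normalize_total_area(m)
  expect_true(norm$normalized)
  expect_equal(unname(rowSums(norm$values)), rep(1, 6), tolerance = 1e-12)
  # idempotence
  expect_equal(normalize_total_area(norm)$values, norm$values,
               tolerance = 1e-12)
  # per-sample dilution is removed
  diluted <- profile_matrix(vals * runif(6, 0.2, 5), rep("G", 6))
  expect_equal(normalize_total_area(diluted)$values, norm$values,
               tolerance = 1e-12)
  # constant row -> 1/m cells
  flat <- profile_matrix(matrix(3, 1, 10, dimnames = list("s", paste0("m", 1:10))),
                         "G")
  expect_equal(unname(normalize_total_area(flat)$values[1, ]), rep(0.1, 10))
  # all-zero row is an error
  zero <- vals; zero[2, ] <- 0
  expect_error(normalize_total_area(profile_matrix(zero, rep("G", 6))),
               "s2")
})

test_that("exclusion must precede normalization: the operations do not commute", {
  vals <- matrix(c(1, 2, 3, 5, 4, 2), 2, 3,
                 dimnames = list(c("s1", "s2"), c("a", "b", "contaminant")))
  m <- profile_matrix(vals, c("G", "G"))
  ex_then_norm <- normalize_total_area(exclude_metabolites(m, "contaminant"))
  norm_then_ex <- exclude_metabolites(normalize_total_area(m), "contaminant")
  expect_false(isTRUE(all.equal(ex_then_norm$values, norm_then_ex$values)))
})

test_that("autoscaling matches hand computation and stores invertible parameters", {
  vals <- matrix(c(0, 2, 1, 5), 2, 2,
                 dimnames = list(c("s1", "s2"), c("m1", "m2")))
  m <- profile_matrix(vals, c("A", "B"))
  s <- scale_profiles(m, "unit_variance")
  # sd with the n-1 denominator: (0, 2) -> -+1/sqrt(2)
  expect_equal(unname(s$values[, "m1"]), c(-0.7071068, 0.7071068),
               tolerance = 1e-6)
  expect_equal(unname(colMeans(s$values)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(s$values, 2, sd)), c(1, 1), tolerance = 1e-12)
  # stored parameters reproduce the scaled values on the raw data
  expect_equal(apply_scaling(s, vals), s$values, tolerance = 1e-12)
  # centering centered data changes nothing
  centered <- scale_profiles(m, "center")
  vals2 <- centered$values
  m2 <- profile_matrix(vals2 - min(vals2), c("A", "B"))  # keep nonnegative
  expect_equal(scale_profiles(m2, "center")$values,
               sweep(vals2, 2, colMeans(vals2)), tolerance = 1e-12,
               ignore_attr = TRUE)
  # constant metabolite is refused by name
  const <- profile_matrix(matrix(c(1, 1, 2, 3), 2, 2,
                                 dimnames = list(c("s1", "s2"), c("flat", "ok"))),
                          c("A", "B"))
  expect_error(scale_profiles(const, "unit_variance"), "flat")
})
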