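test_that("vote-ratio bookkeeping matches the reference worked example", {
  ref <- reference_votes()
  e12 <- vote_records(ref$sample, ref$e12_votes, ref$e12_applications)
  e3 <- vote_records(ref$sample, ref$e3_votes, ref$e3_applications)
  e4 <- vote_records(ref$sample, ref$e4_votes, ref$e4_applications)

  expect_equal(e4$ratio[e4$sample == "RODM 061"], 100 * 5 / 13)
  expect_identical(format_ratio(5, 13), "38.5% (5/13)")
  expect_equal(e12$ratio[e12$sample == "RODM 048"], 100 * 12 / 13)
  expect_identical(format_ratio(12, 13), "92.3% (12/13)")
  expect_equal(e12$ratio[e12$sample == "RODM 001"], 0)
  expect_error(vote_records("s", 5, 3), "votes")

  # per-ensemble at-risk selections
  expect_length(select_at_risk(e12), 4L)
  expect_length(select_at_risk(e3), 5L)
  expect_length(select_at_risk(e4), 12L)
  expect_setequal(select_at_risk(e12),
                  c("RODM 048", "RODM 061", "RODM 065", "RODM 071"))

  at_risk <- sort(unique(c(select_at_risk(e12), select_at_risk(e3),
                           select_at_risk(e4))))
  expect_length(at_risk, 12L)

  stage_labels <- setNames(ref$stage_label, ref$sample)
  assignment <- assign_stage(at_risk, select_at_risk(e12), stage_labels)
  expect_equal(assignment$n_early, 5L)
  expect_equal(assignment$n_late, 7L)
  expect_equal(assignment$agreement, 75)
  expect_equal(sum(!assignment$labels$concordant), 3L)

  # identical sources agree fully
  same <- assign_stage(at_risk, at_risk,
                       setNames(rep("early", 12), at_risk))
  expect_equal(same$agreement, 100)
  expect_error(assign_stage(character(0), at_risk, stage_labels), "empty")
})

test_that("all-zero vote records select nobody", {
  rec <- vote_records(c("a", "b"), c(0, 0), c(4, 0))
  expect_length(select_at_risk(rec), 0L)
  expect_true(is.na(rec$ratio[2]))
})

test_that("stage majority labels split at half, ties to late", {
  rec <- vote_records(c("a", "b", "c", "d"), c(5, 6, 2, 0),
                      c(13, 12, 4, 0))
  lab <- stage_majority_labels(rec)
  expect_identical(unname(lab[c("a", "b", "c")]),
                   c("early", "late", "late"))  # 38.5% / 50% / 50%
  expect_true(is.na(lab["d"]))
})

test_that("ensembles are seed-deterministic and keep votes within applications", {
  co <- generate_cohort(small_config(effect_size = 2, seed = 61))
  m <- preprocess(co$profiles)
  spec <- ensemble_spec("DM2", "PC_IV", n_models = 8, seed = 3,
                        external_subsample_size = 10)
  ens <- build_ensemble(m, spec)
  expect_length(ens$models, 8L)
  expect_identical(ens$qualifying, build_ensemble(m, spec)$qualifying)

  ext <- subset_profiles(m, groups = "RODM")
  rec <- classify_external(ens, ext, seed = 9)
  expect_true(all(rec$votes <= rec$applications))
  expect_true(all(rec$applications >= 0))
  expect_identical(rec, classify_external(ens, ext, seed = 9))

  # each sample's applications ~ Binomial(n_qualifying, size / cohort)
  p <- 10 / nrow(ext$values)
  expected <- length(ens$qualifying) * p
  expect_equal(mean(rec$applications), expected)  # counts are conserved
  sd3 <- 3 * sqrt(length(ens$qualifying) * p * (1 - p))
  expect_true(all(abs(rec$applications - expected) <= sd3 + 1))
})

test_that("exchangeable groups produce almost no qualifying models", {
  set.seed(67)
  vals <- matrix(rexp(60 * 20) + 0.05, 60, 20,
                 dimnames = list(sprintf("s%02d", 1:60), paste0("m", 1:20)))
  m <- profile_matrix(vals, rep(c("DM2", "PC_IV"), each = 30))
  ens <- build_ensemble(m, ensemble_spec("DM2", "PC_IV", n_models = 20,
                                         seed = 2))
  expect_lte(length(ens$qualifying), 2L)
})

test_that("the full scheme recovers planted at-risk samples", {
  co <- generate_cohort(small_config(effect_size = 2.5,
                                     rodm_pc_fraction = 0.25, seed = 71))
  m <- preprocess(co$profiles)
  rep_ <- predict_risk(m, n_models = 10, external_subsample_size = 10,
                       seed = 5)
  expect_equal(rep_$n_models_total, 30L)
  truth <- co$truth
  pc_like <- truth$sample_id[truth$group == "RODM" &
                               truth$latent_group != "DM2"]
  dm_like <- truth$sample_id[truth$group == "RODM" &
                               truth$latent_group == "DM2"]
  expect_gte(mean(pc_like %in% rep_$at_risk), 0.8)
  expect_lte(mean(dm_like %in% rep_$at_risk), 0.2)
})
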