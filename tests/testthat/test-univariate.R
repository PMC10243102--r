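test_that("exact rank-sum p-values match known cases", {
  # fully separated triples: the 2 extreme orderings out of choose(6,3)=20
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6), mode = "exact"), 0.1)
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_error(wilcoxon_rank_sum(numeric(0), 1:3), "empty group")
  expect_error(wilcoxon_rank_sum(c(1, 1, 2), c(3, 4, 5), mode = "exact"),
               "ties")
})

test_that("exact mode agrees with full enumeration for all group sizes up to 8", {
  set.seed(31)
  for (n1 in 2:8) for (n2 in n1:8) {
    a <- rnorm(n1); b <- rnorm(n2) + runif(1, -1, 1)
    expect_equal(wilcoxon_rank_sum(a, b, mode = "exact"),
                 enumerate_wilcoxon(a, b), tolerance = 1e-12,
                 info = sprintf("n1=%d n2=%d", n1, n2))
  }
})

test_that("normal approximation tracks the exact test at moderate n", {
  set.seed(13)
  for (rep in 1:5) {
    a <- rnorm(15); b <- rnorm(15) + runif(1, -0.8, 0.8)
    expect_lt(abs(wilcoxon_rank_sum(a, b, mode = "exact") -
                    wilcoxon_rank_sum(a, b, mode = "approx")), 0.02)
  }
})

test_that("BH adjustment follows the step-up rule and its invariances", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.123), 0.123)
  set.seed(17)
  p <- runif(40)^2
  adj <- bh_adjust(p)
  expect_true(all(adj >= p) && all(adj <= 1))
  ord <- sample(40)
  expect_equal(bh_adjust(p[ord]), adj[ord])  # order invariance
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("fold change is the case-over-control mean ratio", {
  expect_equal(fold_change(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(fold_change(c(1, 2, 3), 2 * c(1, 2, 3)), 2)
  expect_error(fold_change(c(0, 0), c(1, 2)), "positive")
  set.seed(23)
  for (i in 1:10) {
    a <- rexp(8) + 0.1; b <- rexp(8) + 0.1
    expect_equal(sign(log2(fold_change(a, b))), sign(mean(b) - mean(a)))
  }
})

test_that("the univariate screen finds planted effects with correct direction", {
  co <- generate_cohort(small_config(effect_size = 3, seed = 19))
  m <- preprocess(co$profiles)
  tab <- univariate_table(m, "HC", "PC_III")
  panel <- cohort_config()$panel_metabolites
  hits <- tab[tab$metabolite %in% panel, ]
  expect_true(all(hits$p_adj < 0.05))
  expect_true(all(hits$direction == 1))  # panel is elevated in PC groups
  expect_true(all(tab$p_adj >= tab$p_raw - 1e-15))
})

test_that("panel overlap is the intersection of per-comparison significant sets", {
  ref <- reference_pvalues()
  tables <- lapply(names(ref)[-1], function(cmp)
    data.frame(metabolite = ref$metabolite, comparison = cmp,
               p_adj = ref[[cmp]]))
  panel <- panel_overlap(tables, threshold = 0.05)
  expect_length(panel$metabolites, 9L)
  expect_setequal(panel$metabolites,
                  c("3-hydroxyisovalerate", "creatine", "fumarate",
                    "gluconate", "lysine", "mannose", "N-acetylcysteine",
                    "proline", "propionate"))
  # a single table returns its own significant set
  one <- panel_overlap(tables[1], threshold = 0.05)
  expect_setequal(one$metabolites,
                  ref$metabolite[ref[[2]] < 0.05])
  # membership requires significance everywhere
  for (tab in tables)
    expect_true(all(panel$metabolites %in%
                      tab$metabolite[tab$p_adj < 0.05]))
  # 3-hydroxybutyrate misses the 0.05 cut in one comparison only
  expect_false("3-hydroxybutyrate" %in% panel$metabolites)
  mism <- tables
  mism[[2]] <- mism[[2]][-1, ]
  expect_error(panel_overlap(mism), "universe")
})

test_that("the stage-trend screen reports strictly monotone metabolites", {
  vals <- cbind(up = c(1, 1, 2, 2, 3, 3), flat = rep(5, 6),
                down = c(3, 3, 2, 2, 1, 1))
  rownames(vals) <- paste0("s", 1:6)
  m <- profile_matrix(vals, rep(c("PC_I_II", "PC_III", "PC_IV"), each = 2))
  tr <- stage_trend_screen(m)
  expect_identical(tr$direction[tr$metabolite == "up"], "up")
  expect_identical(tr$direction[tr$metabolite == "down"], "down")
  expect_false("flat" %in% tr$metabolite)
  expect_error(stage_trend_screen(m, stages = c("PC_I_II", "PC_III")),
               ">= 3")
})

test_that("the screen recovers most planted trend metabolites at default noise", {
  co <- generate_cohort(cohort_config(seed = 29))
  m <- preprocess(co$profiles)
  tr <- stage_trend_screen(m)
  cfg <- cohort_config()
  up_found <- cfg$trend_up %in% tr$metabolite[tr$direction == "up"]
  down_found <- cfg$trend_down %in% tr$metabolite[tr$direction == "down"]
  expect_gte(sum(up_found) + sum(down_found), 9)
})
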