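test_that("performance metrics follow their defining arithmetic", {
  truth <- c(rep("PC", 4), rep("C", 6))      # 4 positives, 6 negatives
  pred <- c("PC", "PC", "PC", "C",           # tp 3, fn 1
            "PC", "PC", "C", "C", "C", "C")  # fp 2, tn 4
  perf <- evaluate_performance(truth, pred, "PC")
  expect_equal(perf$sensitivity, 75)
  expect_equal(perf$specificity, 200 / 3, tolerance = 1e-12)
  expect_equal(perf$accuracy, 70)
  expect_equal(c(perf$tp, perf$tn, perf$fp, perf$fn), c(3, 4, 2, 1))

  all_right <- evaluate_performance(truth, truth, "PC")
  expect_equal(c(all_right$accuracy, all_right$sensitivity,
                 all_right$specificity), c(100, 100, 100))

  balanced <- c(rep("PC", 5), rep("C", 5))
  all_pos <- evaluate_performance(balanced, rep("PC", 10), "PC")
  expect_equal(c(all_pos$sensitivity, all_pos$specificity, all_pos$accuracy),
               c(100, 0, 50))

  # permutation symmetry in sample order
  ord <- sample(10)
  perm <- evaluate_performance(truth[ord], pred[ord], "PC")
  expect_equal(perm, perf)
  expect_error(evaluate_performance(truth, pred, "X"), "unknown positive")
})

test_that("Monte-Carlo CV stratifies splits and is seed-deterministic", {
  seen_train <- integer(0)
  recorder <- list(
    fit = function(x, y) {
      seen_train <<- c(seen_train, nrow(x))
      tab <- table(y)
      expect_equal(length(tab), 2L)  # both classes in every training set
      names(which.max(tab))
    },
    predict = function(model, x) rep(model, nrow(x)))
  set.seed(99)
  x <- matrix(rnorm(60 * 4), 60, 4, dimnames = list(NULL, paste0("v", 1:4)))
  y <- rep(c("A", "B"), each = 30)
  res <- monte_carlo_cv(x, y, recorder, n_iterations = 10, seed = 3)
  expect_true(all(seen_train == 54))  # 90% of 60, stratified

  # an oracle that always answers the truth scores 100
  rownames(x) <- sprintf("s%02d", 1:60)
  truth_table <- setNames(y, rownames(x))
  oracle <- list(fit = function(x, y) NULL,
                 predict = function(model, x) unname(truth_table[rownames(x)]))
  perfect <- monte_carlo_cv(x, y, oracle, n_iterations = 10, seed = 1)
  expect_equal(perfect$mean$accuracy, 100)

  a <- monte_carlo_cv(x, y, centroid_spec(), n_iterations = 15, seed = 7)
  b <- monte_carlo_cv(x, y, centroid_spec(), n_iterations = 15, seed = 7)
  expect_identical(a$iterations, b$iterations)
  expect_error(monte_carlo_cv(x[1:32, ], c(rep("A", 30), "B", "B"),
                              centroid_spec(), n_iterations = 2, seed = 1),
               "too small to stratify")
})

test_that("exchangeable data scores at chance level", {
  set.seed(5)
  x <- matrix(rnorm(40 * 5), 40, 5, dimnames = list(NULL, paste0("v", 1:5)))
  y <- rep(c("A", "B"), each = 20)
  res <- monte_carlo_cv(x, y, centroid_spec(), n_iterations = 50, seed = 2)
  expect_gt(res$mean$accuracy, 35)
  expect_lt(res$mean$accuracy, 65)
})

test_that("the permutation p-value is the strictly-better fraction", {
  expect_equal(permutation_pvalue(149, 1000), 0.149)
  expect_equal(permutation_pvalue(0, 1000), 0)
  expect_error(permutation_pvalue(-1, 1000), "between 0")
  expect_error(permutation_pvalue(5, 0), ">= 1")
  expect_identical(format_pvalue(0, 1000), "<0.001")
  expect_identical(format_pvalue(0.0005, 1000), "<0.001")
  expect_identical(format_pvalue(0.149, 1000), "0.149")
  expect_identical(format_pvalue(0, 200), "<0.005")
})

test_that("permutation test separates signal from null and is reproducible", {
  d <- two_clusters(n_per = 10, sep = 6, seed = 11)
  strong <- permutation_test(d$x, d$y, centroid_spec(), n_permutations = 50,
                             n_cv_iterations = 5, seed = 4)
  expect_equal(strong$p_value, 0)  # nothing beats a separable model
  expect_equal(strong$p_value,
               permutation_pvalue(sum(strong$permuted > strong$observed), 50))

  again <- permutation_test(d$x, d$y, centroid_spec(), n_permutations = 50,
                            n_cv_iterations = 5, seed = 4)
  expect_identical(strong$permuted, again$permuted)

  set.seed(21)
  xnull <- matrix(rnorm(20 * 4), 20, 4,
                  dimnames = list(NULL, paste0("v", 1:4)))
  ynull <- rep(c("A", "B"), each = 10)
  pn <- permutation_test(xnull, ynull, centroid_spec(), n_permutations = 50,
                         n_cv_iterations = 5, seed = 6)
  expect_gt(pn$p_value, 0.05)  # null labels should not look significant
})
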