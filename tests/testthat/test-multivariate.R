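test_that("PCA recovers collinear structure and reconstructs at full rank", {
  set.seed(1)
  # points on a line in 4-d
  t <- rnorm(20)
  line <- outer(t, c(1, -2, 0.5, 3))
  colnames(line) <- paste0("v", 1:4)
  p1 <- fit_pca(sweep(line, 2, colMeans(line)), k = 1)
  expect_gt(p1$explained[1], 0.999999)

  x <- matrix(rnorm(20 * 4), 20, 4, dimnames = list(NULL, paste0("v", 1:4)))
  xc <- sweep(x, 2, colMeans(x))
  pf <- fit_pca(xc, k = 4)
  expect_equal(pf$scores %*% t(pf$loadings), xc, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(crossprod(pf$loadings), diag(4), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_true(all(diff(pf$explained) <= 1e-12))
  expect_lte(sum(pf$explained), 1 + 1e-12)
  # sign convention: the largest-magnitude loading of each component is +
  for (j in 1:4)
    expect_gt(pf$loadings[which.max(abs(pf$loadings[, j])), j], 0)
  expect_error(fit_pca(xc, k = 21), "between 1 and")
})

test_that("OPLS-DA separates separable clusters and predicts its training set", {
  d <- two_clusters(n_per = 10, sep = 10, seed = 2)
  s <- scale_values(d$x)
  fit <- fit_oplsda(s, d$y, k_ortho = 0)
  expect_identical(predict(fit, d$x), d$y)
  # a new sample identical to a training sample gets the training prediction
  expect_identical(predict(fit, d$x[3, , drop = FALSE]),
                   predict(fit, d$x)[3])
  expect_error(fit_oplsda(s, rep("A", 20)), "two classes")
  wrong <- d$x; colnames(wrong) <- rev(colnames(wrong))
  expect_error(predict(fit, wrong), "columns do not match")
})

test_that("OPLS-DA without orthogonal components equals an independent 1-component PLS", {
  for (seed in 1:4) {
    set.seed(seed)
    n <- sample(10:30, 1); m <- sample(3:20, 1)
    x <- matrix(rnorm(n * m), n, m, dimnames = list(NULL, paste0("v", 1:m)))
    y <- sample(rep(c("A", "B"), length.out = n))
    x[y == "B", 1] <- x[y == "B", 1] + 1
    fit <- fit_oplsda(scale_values(x), y, k_ortho = 0)
    xnew <- matrix(rnorm(5 * m), 5, m, dimnames = list(NULL, colnames(x)))
    expect_equal(predict(fit, xnew, type = "response"),
                 naive_pls1_response(x, as.numeric(y == "B"), xnew),
                 tolerance = 1e-8)
  }
})

test_that("orthogonal components absorb response-orthogonal variance", {
  set.seed(7)
  n <- 40
  y <- rep(c("A", "B"), each = n / 2)
  y01 <- as.numeric(y == "B")
  ortho <- rnorm(n, sd = 4)           # strong variance uncorrelated with y
  x <- cbind(v1 = y01 + rnorm(n, sd = 0.3) + 2 * ortho,
             v2 = y01 + rnorm(n, sd = 0.3) - 2 * ortho,
             v3 = ortho + rnorm(n, sd = 0.3),
             v4 = rnorm(n))
  s <- scale_values(x)
  plain <- fit_oplsda(s, y, k_ortho = 0)
  filtered <- fit_oplsda(s, y, k_ortho = 1)
  expect_gte(abs(cor(filtered$scores, y01)), abs(cor(plain$scores, y01)))
  # score orthogonality invariant
  f2 <- fit_oplsda(s, y, k_ortho = 2)
  expect_lt(max(abs(crossprod(f2$scores, f2$ortho_scores))), 1e-8)
})

test_that("the decision threshold breaks ties toward the first class", {
  d <- two_clusters(seed = 3)
  fit <- fit_oplsda(scale_values(d$x), d$y, k_ortho = 0)
  r <- predict(fit, d$x[1, , drop = FALSE], type = "response")
  at_threshold <- fit
  at_threshold$threshold <- unname(r)
  expect_identical(predict(at_threshold, d$x[1, , drop = FALSE]), "A")
})

test_that("component selection returns the smallest count with maximal accuracy", {
  expect_equal(pick_min_argmax(c(0.7, 0.9, 0.9, 0.85)), 2L)
  expect_equal(pick_min_argmax(rep(0.8, 4)), 1L)
  expect_error(pick_min_argmax(numeric(0)), "empty")
  # separable single-direction data needs one component
  d <- two_clusters(n_per = 12, sep = 8, seed = 4)
  sel <- select_components(d$x, d$y, max_total = 3, n_iterations = 10,
                           seed = 1)
  expect_equal(sel$n_components_total, 1L)
  expect_equal(sel$k_ortho, 0L)
})

test_that("multi-class PLS-DA has orthogonal scores and separates three clusters", {
  set.seed(9)
  n_per <- 8; m <- 6
  x <- matrix(rnorm(3 * n_per * m), 3 * n_per, m,
              dimnames = list(NULL, paste0("v", 1:m)))
  y <- rep(c("A", "B", "C"), each = n_per)
  x[y == "B", 1] <- x[y == "B", 1] + 8
  x[y == "C", 2] <- x[y == "C", 2] + 8
  fit <- fit_plsda(scale_values(x), y, k = 3)
  g <- crossprod(fit$scores)
  expect_lt(max(abs(g[upper.tri(g)])), 1e-8)
  expect_identical(predict(fit, x), y)
})

test_that("serialized models predict identically after a JSON round-trip", {
  d <- two_clusters(n_per = 8, sep = 4, seed = 5)
  fit <- fit_oplsda(scale_values(d$x), d$y, k_ortho = 1)
  path <- withr::local_tempfile(fileext = ".json")
  opls_to_json(fit, path)
  back <- opls_from_json(path)
  xnew <- matrix(rnorm(40), 8, 5, dimnames = list(NULL, colnames(d$x)))
  expect_equal(predict(back, xnew, type = "response"),
               predict(fit, xnew, type = "response"), tolerance = 1e-12)
})
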