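# Independent oracles, deliberately naive and separate from the package's
# implementation paths.

# 1-component NIPALS PLS regression on a 0/1 response, own scaling.
naive_pls1_response <- function(x_train, y01, x_new) {
  ctr <- colMeans(x_train)
  scl <- apply(x_train, 2L, sd)
  X <- sweep(sweep(x_train, 2L, ctr, "-"), 2L, scl, "/")
  yc <- y01 - mean(y01)
  w <- drop(crossprod(X, yc))
  w <- w / sqrt(sum(w^2))
  tt <- drop(X %*% w)
  cc <- sum(yc * tt) / sum(tt^2)
  Xn <- sweep(sweep(x_new, 2L, ctr, "-"), 2L, scl, "/")
  drop(Xn %*% w) * cc + mean(y01)
}

# Exact two-sided rank-sum p-value by full enumeration of all rank
# assignments (tie-free data only).
enumerate_wilcoxon <- function(a, b) {
  stopifnot(!anyDuplicated(c(a, b)))
  n1 <- length(a)
  N <- n1 + length(b)
  w_obs <- sum(rank(c(a, b))[seq_len(n1)])
  mu <- n1 * (N + 1) / 2
  ws <- colSums(matrix(utils::combn(N, n1), nrow = n1))
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-12)
}

# AUC by brute-force pair counting, ties worth one half.
auc_pair_count <- function(scores, labels, positive) {
  sp <- scores[labels == positive]
  sn <- scores[labels != positive]
  mean(outer(sp, sn, function(p, n) (p > n) + 0.5 * (p == n)))
}
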