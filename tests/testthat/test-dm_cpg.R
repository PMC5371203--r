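make_beta <- function(nr, nc, seed = 1, fun = runif) {
  set.seed(seed)
  matrix(fun(nr * nc), nr, nc,
         dimnames = list(sprintf("p%03d", seq_len(nr)),
                         sprintf("s%02d", seq_len(nc))))
}

test_that("SAM d equals the hand-computed modified t on a 3v3 toy", {
  beta <- make_beta(4, 6)
  labels <- rep(c("tumour", "normal"), each = 3)
  s0 <- 0.05
  res <- sam_d_statistic(beta, labels, s0 = s0)
  for (i in 1:4) {
    x <- beta[i, 1:3]; y <- beta[i, 4:6]
    s <- sqrt((1 / 3 + 1 / 3) * (sum((x - mean(x))^2) + sum((y - mean(y))^2)) / 4)
    expect_equal(res$d[i], (mean(x) - mean(y)) / (s + s0))
    expect_equal(res$s[i], s)
  }
})

test_that("SAM d is zero for equal means, vanishes as s0 grows, and is antisymmetric", {
  beta <- make_beta(5, 8)
  beta[1, ] <- c(0.2, 0.4, 0.3, 0.5, 0.2, 0.4, 0.3, 0.5)
  labels <- rep(c("tumour", "normal"), each = 4)
  res <- sam_d_statistic(beta, labels)
  expect_equal(res$d[1], 0)
  big <- sam_d_statistic(beta, labels, s0 = 1e9)
  expect_true(all(abs(big$d) < 1e-6))
  base <- sam_d_statistic(beta, labels, s0 = 0.01)
  flip <- sam_d_statistic(beta, ifelse(labels == "tumour", "normal", "tumour"),
                          s0 = 0.01)
  expect_equal(flip$d, -base$d)
})

test_that("with s0 = 0 the unpaired d is the classical pooled t statistic", {
  beta <- make_beta(6, 10, seed = 2)
  labels <- rep(c("tumour", "normal"), each = 5)
  res <- sam_d_statistic(beta, labels, s0 = 0)
  for (i in 1:6) {
    tt <- t.test(beta[i, 1:5], beta[i, 6:10], var.equal = TRUE)
    expect_equal(res$d[i], unname(tt$statistic), tolerance = 1e-10)
  }
})

test_that("paired d matches the one-sample t on differences", {
  beta <- make_beta(4, 8, seed = 3)
  labels <- rep(c("tumour", "normal"), 4)
  subject <- rep(paste0("S", 1:4), each = 2)
  res <- sam_d_statistic(beta, labels, s0 = 0, paired = TRUE,
                         subject = subject)
  D <- beta[, c(1, 3, 5, 7)] - beta[, c(2, 4, 6, 8)]
  for (i in 1:4) {
    tt <- t.test(D[i, ])
    expect_equal(res$d[i], unname(tt$statistic), tolerance = 1e-10)
  }
})

test_that("s0 selection: degenerate and median modes behave as documented", {
  expect_equal(choose_s0(rep(2, 100), rnorm(100)), 2)
  expect_equal(choose_s0(c(1, 2, 3), c(0, 0, 0), mode = "median"), 2)
  expect_warning(s0 <- choose_s0(rep(0, 10), rnorm(10)), "zero")
  expect_gt(s0, 0)
})

test_that("CV-minimising s0 reduces the scale-dependence of |d|", {
  set.seed(9)
  n <- 4000
  s <- rexp(n, rate = 20) + 1e-4           # heteroscedastic standard errors
  # numerators carry an s-independent variance floor, so with s0 = 0 the
  # statistic blows up at small s (the situation the fudge factor fixes)
  r <- rnorm(n, 0, s + 0.02)
  s0 <- choose_s0(s, r)
  cv_of <- function(s0v) {
    d <- abs(r / (s + s0v))
    dec <- cut(rank(s, ties.method = "first"), 10, labels = FALSE)
    v <- tapply(d, dec, mad)
    sd(v) / mean(v)
  }
  expect_lt(cv_of(s0), cv_of(0))
})

test_that("permutation FDR falls back to exhaustive enumeration and matches it", {
  beta <- make_beta(30, 6, seed = 4)
  beta[1:5, 1:3] <- beta[1:5, 1:3] + 0.6   # strong signal rows
  labels <- rep(c("tumour", "normal"), each = 3)
  res <- sam_permutation_fdr(beta, labels, s0 = 0.01, n_permutations = 100,
                             seed = 1)
  expect_true(attr(res, "exhaustive"))
  expect_equal(attr(res, "n_permutations_used"), 20)
  q_oracle <- enum_sam_q(beta, labels, s0 = 0.01)
  expect_equal(res$q, q_oracle, tolerance = 1e-12)
  # q non-increasing in |d|
  ord <- order(abs(res$d), decreasing = TRUE)
  expect_true(all(diff(res$q[ord]) >= -1e-12))
})

test_that("null data yield uninformative q and constant rows give d = 0, q = 1", {
  beta <- make_beta(400, 10, seed = 5)
  labels <- rep(c("tumour", "normal"), each = 5)
  res <- sam_permutation_fdr(beta, labels, s0 = 0.01, n_permutations = 100,
                             seed = 2)
  expect_gt(median(res$q), 0.8)
  flat <- matrix(0.3, 10, 6, dimnames = list(paste0("p", 1:10),
                                             paste0("s", 1:6)))
  res2 <- sam_permutation_fdr(flat, rep(c("tumour", "normal"), each = 3),
                              s0 = 0.01, n_permutations = 30, seed = 1)
  expect_true(all(res2$d == 0))
  expect_true(all(res2$q == 1))
})

test_that("top-K selection matches a full sort and breaks ties by probe id", {
  beta <- make_beta(10, 6, seed = 6)
  labels <- rep(c("tumour", "normal"), each = 3)
  res <- sam_d_statistic(beta, labels, s0 = 0.01)
  expect_length(select_top_k(res, nrow(res)), 10)
  expect_identical(select_top_k(res, 1),
                   res$probe_id[which.max(abs(res$d))])
  top5 <- select_top_k(res, 5)
  expect_identical(top5, res$probe_id[order(-abs(res$d))][1:5])
  expect_error(select_top_k(res, 0), "positive")
  expect_error(select_top_k(res, 11), "exceeds")
  tied <- data.frame(probe_id = c("b", "a", "c"), d = c(1, -1, 0.5))
  expect_identical(select_top_k(tied, 2), c("a", "b"))
})

test_that("group size and label validation errors are raised", {
  beta <- make_beta(3, 4)
  expect_error(sam_d_statistic(beta, c("tumour", "tumour", "tumour", "normal")),
               "at least 2")
  expect_error(sam_d_statistic(beta, rep("tumour", 4)), "non-empty")
})
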