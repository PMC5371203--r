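test_that("signed-rank p: conventions and closed forms", {
  expect_equal(paired_signed_rank(c(0.3, 0.4, 0.2), c(0.3, 0.4, 0.2)), 1)
  # n = 6, all differences positive and distinct: extreme statistic
  t6 <- c(0.5, 0.52, 0.61, 0.47, 0.55, 0.58)
  n6 <- c(0.1, 0.20, 0.15, 0.12, 0.30, 0.21)
  expect_equal(paired_signed_rank(t6, n6), 2 / 64)
  expect_equal(paired_signed_rank(n6, t6), 2 / 64)   # symmetric
  expect_error(paired_signed_rank(1:3, 1:2), "equal length")
  expect_error(paired_signed_rank(numeric(0), numeric(0)), "empty")
})

test_that("exact signed-rank p equals 2^n enumeration, with and without ties", {
  set.seed(21)
  for (rep in 1:40) {
    n <- sample(3:11, 1)
    d <- round(rnorm(n), 3)
    d <- d[d != 0]
    if (length(d) < 3) next
    expect_equal(paired_signed_rank(d, numeric(length(d))),
                 enum_signed_rank_p(d), tolerance = 1e-12)
  }
  # forced ties in |differences| exercise the convolution path
  for (rep in 1:20) {
    n <- sample(4:10, 1)
    d <- sample(c(-3, -2, -1, 1, 2, 3), n, replace = TRUE) / 10
    expect_equal(paired_signed_rank(d, numeric(n)), enum_signed_rank_p(d),
                 tolerance = 1e-12)
  }
  # zeros are dropped before ranking
  d <- c(0, 0.2, -0.1, 0.3, 0, 0.25)
  expect_equal(paired_signed_rank(d, numeric(6)), enum_signed_rank_p(d),
               tolerance = 1e-12)
})

test_that("large-n signed-rank approximation tracks the exact tail", {
  set.seed(22)
  d <- rnorm(30, 0.12, 0.3)
  p_approx <- paired_signed_rank(d, numeric(30), exact_max = 25)
  # against our exact null (forced) and the independent exact reference
  p_exact <- paired_signed_rank(d, numeric(30), exact_max = 30)
  expect_equal(p_approx, p_exact, tolerance = 0.05)
  expect_equal(p_exact, wilcox.test(d)$p.value, tolerance = 1e-9)
})

test_that("BH adjustment: closed form, validation, oracle agreement", {
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_error(bh_adjust(c(0.1, 1.2)), "0, 1")
  set.seed(23)
  for (rep in 1:30) {
    p <- runif(sample(5:200, 1))^sample(1:3, 1)
    adj <- bh_adjust(p)
    expect_equal(adj, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-12))
    # order-preserving: adjusted values are non-decreasing in p
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
  }
})

# a tiny hand-designed cohort: 3 genes x 6 probes, 2 pairs; gene g1 is
# strongly shifted in both tumours, g2 shifted only slightly, g3 null
toy_calls <- function(p_adj_max = 0.05, delta_min = 0.1) {
  set.seed(24)
  probes <- sprintf("pr%02d", 1:18)
  genes <- list(g1 = probes[1:6], g2 = probes[7:12], g3 = probes[13:18])
  samples <- c("A_T", "A_N", "B_T", "B_N")
  base <- matrix(runif(18 * 4, 0.08, 0.12), 18, 4,
                 dimnames = list(probes, samples))
  base[genes$g1, c("A_T", "B_T")] <- base[genes$g1, c("A_N", "B_N")] + 0.4
  base[genes$g2, c("A_T", "B_T")] <- base[genes$g2, c("A_N", "B_N")] + 0.05
  sheet <- data.frame(sample_id = samples,
                      subject_id = rep(c("A", "B"), each = 2),
                      tissue = rep(c("tumour", "normal"), 2),
                      batch = "c1", stringsAsFactors = FALSE)
  params <- call_parameters(p_adj_max = p_adj_max, delta_min = delta_min)
  calls <- call_island_dm(base, genes, matched_pairs(sheet), params)
  list(beta = base, genes = genes, sheet = sheet, calls = calls)
}

test_that("island calls enforce the dual p/delta criterion", {
  tc <- toy_calls()
  calls <- tc$calls
  # g1: minimal exact p = 2/2^6 = 0.03125, BH-adjusted over 3 genes still
  # < 0.05, delta 0.4 -> hyper in both tumours
  g1 <- calls[calls$gene == "g1", ]
  expect_true(all(g1$call == "hyper"))
  expect_equal(g1$p, rep(2 / 64, 2))
  # g2: significant rank pattern but delta 0.05 < 0.1 -> none
  g2 <- calls[calls$gene == "g2", ]
  expect_true(all(g2$delta_beta < 0.1))
  expect_true(all(g2$call == "none"))
  # g3: null -> none
  expect_true(all(calls$call[calls$gene == "g3"] == "none"))
  # the call column is exactly the stated predicate
  pred <- ifelse(calls$p_adj < 0.05 & calls$delta_beta >= 0.1, "hyper",
                 ifelse(calls$p_adj < 0.05 & calls$delta_beta <= -0.1,
                        "hypo", "none"))
  expect_identical(calls$call, pred)
})

test_that("hypomethylation uses the mirrored criterion", {
  tc <- toy_calls()
  beta <- tc$beta
  # swap tumour and normal for g1: mirrors every difference exactly
  beta[tc$genes$g1, ] <- tc$beta[tc$genes$g1,
                                 c("A_N", "A_T", "B_N", "B_T")]
  calls <- call_island_dm(beta, tc$genes, matched_pairs(tc$sheet),
                          call_parameters(p_adj_max = 0.05, delta_min = 0.1))
  expect_true(all(calls$call[calls$gene == "g1"] == "hypo"))
})

test_that("raising delta_min never adds a call (monotone thresholding)", {
  tc <- toy_calls()
  lo <- call_island_dm(tc$beta, tc$genes, matched_pairs(tc$sheet),
                       call_parameters(p_adj_max = 0.05, delta_min = 0.05))
  hi <- call_island_dm(tc$beta, tc$genes, matched_pairs(tc$sheet),
                       call_parameters(p_adj_max = 0.05, delta_min = 0.3))
  expect_true(all(which(hi$call == "hyper") %in% which(lo$call == "hyper")))
})

test_that("per-tumour versus global BH scope changes only the adjustment", {
  tc <- toy_calls()
  per <- tc$calls
  glob <- call_island_dm(tc$beta, tc$genes, matched_pairs(tc$sheet),
                         call_parameters(p_adj_max = 0.05, delta_min = 0.1,
                                         adjust_scope = "global"))
  expect_equal(per$p, glob$p)
  for (subj in c("A", "B")) {
    idx <- per$subject_id == subj
    expect_equal(per$p_adj[idx], bh_oracle(per$p[idx]), tolerance = 1e-12)
  }
  expect_equal(glob$p_adj, bh_oracle(glob$p), tolerance = 1e-12)
})

test_that("threshold scan maximises the CIMP-H minus CIMP-N separation", {
  tc <- toy_calls()
  labels <- c(A = "CIMP-H", B = "CIMP-N")
  sc <- scan_delta_threshold(tc$calls, grid = c(0.2), labels = labels)
  expect_equal(sc$chosen, 0.2)
  sc2 <- scan_delta_threshold(tc$calls, grid = c(0.1, 0.3, 0.45),
                              labels = labels)
  # both tumours carry g1 at delta 0.4: objective 0 below 0.4, ties -> smallest
  expect_equal(sc2$chosen, 0.1)
  expect_equal(sc2$curve$objective, rep(0, 3))
  # delta above every effect: no calls survive
  sc3 <- scan_delta_threshold(tc$calls, grid = c(0.6), labels = labels)
  expect_equal(sc3$curve$mean_H, 0)
  expect_error(scan_delta_threshold(tc$calls, numeric(0), labels), "empty")
  expect_error(scan_delta_threshold(tc$calls, 0.1, c(A = "CIMP-H", B = "CIMP-L")),
               "CIMP-N")
})

test_that("per-tumour counts match a hand tally", {
  tc <- toy_calls()
  counts <- tumour_call_counts(tc$calls, c(A = "CIMP-H", B = "CIMP-N"))
  expect_equal(sort(counts$per_tumour$n_hyper), c(1, 1))  # g1 in each tumour
  expect_equal(counts$summary$mean[counts$summary$label == "CIMP-H"], 1)
  zero <- tc$calls
  zero$call <- "none"
  zero$delta_beta <- 0
  counts0 <- tumour_call_counts(zero, c(A = "CIMP-H", B = "CIMP-N"))
  expect_true(all(counts0$per_tumour$n_hyper == 0))
})

test_that("unmatched pairs are reported by subject", {
  tc <- toy_calls()
  pairs <- matched_pairs(tc$sheet)
  pairs$normal[1] <- "missing_sample"
  expect_error(call_island_dm(tc$beta, tc$genes, pairs, call_parameters()),
               "A")
})
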