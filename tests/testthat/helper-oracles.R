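# Independent brute-force oracles used to check the package's
# implementations. These deliberately share no code with R/.

# two-sided signed-rank p by full enumeration of all 2^n sign assignments
# (average ranks for tied |differences|, zeros dropped)
enum_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  w_all <- apply(signs, 1, function(s) sum(r[s]))
  p_low <- mean(w_all <= w_obs)
  p_up <- mean(w_all >= w_obs)
  min(1, 2 * min(p_low, p_up))
}

# textbook Benjamini-Hochberg step-up
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- p[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

# naive O(n^3) agglomerative complete linkage: returns merge heights
naive_complete_linkage_heights <- function(X) {
  clusters <- as.list(seq_len(nrow(X)))
  D <- as.matrix(dist(X))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) for (j in seq_len(i - 1)) {
      h <- max(D[clusters[[i]], clusters[[j]]])
      if (h < best[1]) best <- c(h, j, i)
    }
    heights <- c(heights, best[1])
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
  }
  heights
}

# exact two-sided Fisher p (minimum-likelihood) by hypergeometric
# enumeration over all tables with the observed margins
enum_fisher_p <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  xs <- max(0, k - n):min(m, k)
  probs <- dhyper(xs, m, n, k)
  p_obs <- dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# SAM permutation FDR by direct enumeration, mirroring the definition:
# for each observed |d_i|, q_i = min over thresholds <= |d_i| of
# (mean permuted count >= threshold) / (observed count >= threshold)
enum_sam_q <- function(beta, labels, s0) {
  n <- ncol(beta)
  n1 <- sum(labels == "tumour")
  d_of <- function(z) {
    m1 <- rowMeans(beta[, z, drop = FALSE])
    m2 <- rowMeans(beta[, !z, drop = FALSE])
    ss <- apply(beta[, z, drop = FALSE], 1, function(x) sum((x - mean(x))^2)) +
      apply(beta[, !z, drop = FALSE], 1, function(x) sum((x - mean(x))^2))
    s <- sqrt((1 / n1 + 1 / (n - n1)) * ss / (n - 2))
    (m1 - m2) / (s + s0)
  }
  obs <- d_of(labels == "tumour")
  combos <- combn(n, n1)
  perm <- apply(combos, 2, function(idx) {
    z <- rep(FALSE, n); z[idx] <- TRUE; d_of(z)
  })
  ad <- unname(abs(obs))
  ratio <- vapply(ad, function(t) {
    ta <- t * (1 - 1e-9) - 1e-12   # same tie tolerance as the implementation
    e <- mean(colSums(abs(perm) >= ta))
    v <- sum(ad >= ta)
    e / v
  }, numeric(1))
  vapply(ad, function(t) min(1, min(ratio[ad <= t + 1e-12])), numeric(1))
}
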