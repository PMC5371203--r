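# internal: tumour/normal indicator checks shared by the SAM functions
.sam_groups <- function(beta, labels) {
  if (length(labels) != ncol(beta))
    stop("need one tumour/normal label per sample")
  z <- labels == "tumour"
  if (sum(z) == 0 || sum(!z) == 0) stop("both groups must be non-empty")
  z
}

# internal: modified t-statistic for one unpaired label assignment.
# Uses precomputed row sums of beta and beta^2 so permutations cost two
# matrix-vector products each.
.sam_d_unpaired <- function(beta, z, s0, S = NULL, Q = NULL) {
  n1 <- sum(z); n2 <- sum(!z)
  if (is.null(S)) S <- rowSums(beta)
  if (is.null(Q)) Q <- rowSums(beta^2)
  s1 <- as.vector(beta %*% z)
  q1 <- as.vector(beta^2 %*% z)
  m1 <- s1 / n1
  m2 <- (S - s1) / n2
  ss <- pmax(q1 - n1 * m1^2, 0) + pmax((Q - q1) - n2 * m2^2, 0)
  s <- sqrt((1 / n1 + 1 / n2) * ss / (n1 + n2 - 2))
  r <- m1 - m2
  list(r = r, s = s, d = r / (s + s0))
}

# internal: paired version over a probes x pairs difference matrix with a
# +/-1 sign vector (identity signs give the observed statistic)
.sam_d_paired <- function(D, e, s0, Q = NULL) {
  n <- ncol(D)
  if (is.null(Q)) Q <- rowSums(D^2)
  r <- as.vector(D %*% e) / n
  ss <- pmax(Q - n * r^2, 0)
  s <- sqrt(ss / (n - 1) / n)
  list(r = r, s = s, d = r / (s + s0))
}

# internal: tumour - normal difference matrix for matched pairs
.pair_diff <- function(beta, labels, subject) {
  if (is.null(subject)) stop("paired mode needs a subject id per sample")
  tum <- which(labels == "tumour")
  nor <- which(labels == "normal")
  idx <- match(subject[tum], subject[nor])
  if (anyNA(idx) || length(tum) != length(nor))
    stop("samples do not form complete tumour/normal pairs")
  D <- beta[, tum, drop = FALSE] - beta[, nor[idx], drop = FALSE]
  colnames(D) <- subject[tum]
  D
}

#' SAM modified t-statistic
#'
#' Computes, per probe, the SAM relative difference
#' \deqn{d_i = r_i / (s_i + s_0)}
#' where \eqn{r_i} is the tumour-minus-normal mean difference, \eqn{s_i}
#' the ordinary pooled standard error of that difference (or the paired
#' standard error in paired mode) and \eqn{s_0} the exchangeability
#' ("fudge") factor that damps probes whose significance rests on a tiny
#' variance.
#'
#' @param beta probes x samples beta matrix.
#' @param labels `"tumour"`/`"normal"` per sample.
#' @param s0 exchangeability factor, >= 0 (see [choose_s0()]).
#' @param paired use matched-pair differences instead of two groups.
#' @param subject subject id per sample, required when `paired = TRUE`.
#' @return `data.frame` with columns `probe_id`, `r`, `s`, `d`.
#' @export
sam_d_statistic <- function(beta, labels, s0 = 0, paired = FALSE,
                            subject = NULL) {
  stopifnot(is.matrix(beta), s0 >= 0)
  z <- .sam_groups(beta, labels)
  if (paired) {
    D <- .pair_diff(beta, labels, subject)
    if (ncol(D) < 2) stop("paired mode needs at least 2 pairs")
    res <- .sam_d_paired(D, rep(1, ncol(D)), s0)
  } else {
    if (sum(z) < 2 || sum(!z) < 2)
      stop("each group needs at least 2 samples in unpaired mode")
    res <- .sam_d_unpaired(beta, z, s0)
  }
  data.frame(probe_id = rownames(beta), r = res$r, s = res$s, d = res$d,
             row.names = NULL)
}

#' Choose the SAM exchangeability factor s0
#'
#' Default mode follows the original SAM recipe: candidate values are
#' percentiles of the standard errors `s`; for each candidate the
#' coefficient of variation of the (median-absolute-deviation) spread of
#' `d = r / (s + s0)` across 100 s-quantile windows is computed, and the
#' candidate minimising that coefficient of variation is returned, making
#' `|d|` approximately independent of `s`. The simpler `"median"` mode
#' returns `median(s)`.
#'
#' @param s vector of per-probe standard errors.
#' @param r vector of per-probe numerators (mean differences).
#' @param mode `"cv"` (default) or `"median"`.
#' @return a single non-negative `s0`.
#' @export
choose_s0 <- function(s, r, mode = c("cv", "median")) {
  mode <- match.arg(mode)
  if (length(s) == 0 || length(s) != length(r))
    stop("s and r must be non-empty vectors of equal length")
  if (all(s == 0)) {
    warning("all standard errors are zero; using a small positive floor")
    return(1e-8)
  }
  if (mode == "median") return(stats::median(s))
  cand <- unique(stats::quantile(s, seq(0, 1, by = 0.05), names = FALSE))
  n_win <- min(100L, max(2L, floor(length(s) / 10)))
  win <- cut(rank(s, ties.method = "first"), breaks = n_win, labels = FALSE)
  cv <- vapply(cand, function(s0) {
    d <- r / (s + s0)
    v <- tapply(d, win, stats::mad)
    v <- v[is.finite(v)]
    if (mean(v) == 0) return(Inf)
    stats::sd(v) / mean(v)
  }, numeric(1))
  cand[which.min(cv)]
}

#' Permutation false discovery rate for SAM statistics
#'
#' Estimates a per-probe q-value by comparing the observed `|d|` ordering
#' with the null distribution of `|d|` under label permutations. For each
#' threshold equal to an observed `|d_i|`, the expected number of false
#' positives is the mean count of permuted statistics at or above the
#' threshold, the observed count is the number of real statistics at or
#' above it, and `q_i` is the smallest expected/observed ratio over all
#' thresholds at or below `|d_i|` (so q is non-increasing in `|d|`),
#' capped at 1.
#'
#' Unpaired permutations reassign the tumour/normal labels (group sizes
#' preserved); paired permutations flip tumour/normal within pairs. When
#' the number of requested permutations is at least the number of distinct
#' assignments, all assignments are enumerated instead and the result is
#' exact (`exhaustive = TRUE` in the output attributes).
#'
#' @inheritParams sam_d_statistic
#' @param n_permutations number of label permutations (>= 1).
#' @param seed integer seed for the permutation draw.
#' @return `data.frame` with columns `probe_id`, `r`, `s`, `d`, `rank`
#'   (by decreasing `|d|`), `q`; attribute `n_permutations_used` and
#'   `exhaustive`.
#' @export
sam_permutation_fdr <- function(beta, labels, s0 = 0, n_permutations = 200,
                                seed = 1, paired = FALSE, subject = NULL) {
  stopifnot(n_permutations >= 1)
  obs <- sam_d_statistic(beta, labels, s0 = s0, paired = paired,
                         subject = subject)
  z <- .sam_groups(beta, labels)

  set.seed(seed)
  if (paired) {
    D <- .pair_diff(beta, labels, subject)
    n <- ncol(D)
    Q <- rowSums(D^2)
    n_distinct <- 2^n
    exhaustive <- n_permutations >= n_distinct
    signs <- if (exhaustive) {
      as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    } else {
      matrix(sample(c(-1, 1), n * n_permutations, replace = TRUE),
             ncol = n)
    }
    perm_d <- apply(signs, 1, function(e) .sam_d_paired(D, e, s0, Q = Q)$d)
  } else {
    n <- ncol(beta); n1 <- sum(z)
    S <- rowSums(beta); Q <- rowSums(beta^2)
    n_distinct <- choose(n, n1)
    exhaustive <- n_permutations >= n_distinct
    assignments <- if (exhaustive) {
      utils::combn(n, n1, simplify = FALSE)
    } else {
      lapply(seq_len(n_permutations), function(i) sample(n, n1))
    }
    perm_d <- vapply(assignments, function(idx) {
      zz <- rep(FALSE, n); zz[idx] <- TRUE
      .sam_d_unpaired(beta, zz, s0, S = S, Q = Q)$d
    }, numeric(nrow(beta)))
  }
  perm_d <- matrix(perm_d, nrow = nrow(beta))
  B <- ncol(perm_d)

  ad <- abs(obs$d)
  # thresholds get a relative tolerance so that permuted statistics that
  # equal an observed |d| up to floating-point noise (e.g. the identity
  # assignment or its mirror under exhaustive enumeration) count as >=
  t_adj <- ad * (1 - 1e-9) - 1e-12
  perm_sorted <- sort(abs(as.vector(perm_d)))
  n_ge_perm <- length(perm_sorted) -
    findInterval(t_adj, perm_sorted, left.open = TRUE)
  obs_sorted <- sort(ad)
  n_ge_obs <- length(obs_sorted) -
    findInterval(t_adj, obs_sorted, left.open = TRUE)

  ratio <- (n_ge_perm / B) / n_ge_obs
  # monotonize: q_i = min ratio over all thresholds <= |d_i|
  ord <- order(ad, decreasing = TRUE)
  q_desc <- rev(cummin(rev(ratio[ord])))
  q <- numeric(length(ad))
  q[ord] <- pmin(q_desc, 1)

  out <- obs
  out$rank <- rank(-ad, ties.method = "first")
  out$q <- q
  attr(out, "n_permutations_used") <- B
  attr(out, "exhaustive") <- exhaustive
  out
}

#' Select the top-K most differentially methylated probes
#'
#' Orders probes by decreasing `|d|` (both hyper- and hypomethylation count)
#' and returns the first `k`; ties in `|d|` are broken lexicographically by
#' probe id so the selection is deterministic.
#'
#' @param result a `data.frame` with `probe_id` and `d` columns, as returned
#'   by [sam_d_statistic()] or [sam_permutation_fdr()].
#' @param k number of probes to keep (`0 < k <=` number of probes).
#' @return character vector of `k` probe ids, most significant first.
#' @export
select_top_k <- function(result, k = 20000) {
  if (k <= 0) stop("k must be positive")
  if (k > nrow(result)) stop("k exceeds the number of probes")
  ord <- order(-abs(result$d), result$probe_id)
  result$probe_id[ord][seq_len(k)]
}
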