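# internal: two-sided signed-rank p for a vector of paired differences.
# Zero differences are dropped; tied |differences| get average ranks. The
# null distribution is exact up to `exact_max` non-zero differences (via
# psignrank for untied ranks, or a convolution over doubled ranks when ties
# make the rank sum half-integral), and a normal approximation with
# continuity and tie correction beyond.
.signed_rank_p <- function(d, exact_max = 25) {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  ra <- rank(abs(d))
  W <- sum(ra[d > 0])
  tie_tab <- table(ra)
  has_ties <- any(tie_tab > 1)
  if (n <= exact_max) {
    if (!has_ties) {
      # exact tail probabilities are multiples of 2^-n; snap to that grid
      # so the result matches direct enumeration bit for bit
      lower <- round(stats::psignrank(W, n) * 2^n) / 2^n
      upper <- 1 - round(stats::psignrank(W - 1, n) * 2^n) / 2^n
      return(min(1, 2 * min(lower, upper)))
    }
    # exact with ties: distribute the doubled (integer) ranks by convolution
    r2 <- round(2 * ra)
    total <- sum(r2)
    f <- numeric(total + 1)
    f[1] <- 1
    for (r in r2) {
      shifted <- c(numeric(r), f[seq_len(total + 1 - r)])
      f <- f + shifted
    }
    w2 <- round(2 * W)
    lower <- sum(f[seq_len(w2 + 1)]) / 2^n
    upper <- sum(f[seq.int(w2 + 1, total + 1)]) / 2^n
    return(min(1, 2 * min(lower, upper)))
  }
  mu <- n * (n + 1) / 4
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
    sum(tie_tab^3 - tie_tab) / 48
  if (sigma2 <= 0) return(1)
  z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' Paired Wilcoxon signed-rank test over a gene's probes
#'
#' Two-sided signed-rank test of the per-probe methylation differences
#' between one tumour and its matched normal sample, the region-level test
#' behind gene hypermethylation calls. Zero differences are dropped
#' (standard convention; an all-zero vector returns p = 1), tied absolute
#' differences receive average ranks, the exact null distribution is used
#' for up to `exact_max` non-zero differences and a normal approximation
#' with continuity and tie correction above that.
#'
#' @param tumour_betas,normal_betas equal-length beta vectors over the
#'   gene's island and shore probes, matched position by position.
#' @param exact_max largest n for which the exact null is used.
#' @return a single two-sided p-value.
#' @export
paired_signed_rank <- function(tumour_betas, normal_betas, exact_max = 25) {
  if (length(tumour_betas) != length(normal_betas))
    stop("tumour and normal beta vectors must have equal length")
  if (length(tumour_betas) == 0) stop("empty probe vectors")
  .signed_rank_p(tumour_betas - normal_betas, exact_max = exact_max)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (sort, multiply by m/rank,
#' enforce monotonicity, cap at 1, restore input order), delegated to
#' [stats::p.adjust()] after validating the input.
#'
#' @param p vector of p-values in `[0, 1]`.
#' @return adjusted p-values in the original order.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Parameters for gene-level hypermethylation calling
#'
#' @param p_adj_max significance threshold on the BH-adjusted signed-rank
#'   p-value (default 0.005).
#' @param delta_min minimum absolute tumour-minus-normal mean beta
#'   difference (default 0.1).
#' @param min_probes minimum island+shore probes for a testable gene.
#' @param adjust_scope `"per_tumour"` adjusts p-values across genes within
#'   each tumour pair (each tumour's calls feed an independent count);
#'   `"global"` pools all pairs.
#' @param exact_max exact-null cutoff for the signed-rank test.
#' @return a list of class `call_parameters`.
#' @export
call_parameters <- function(p_adj_max = 0.005, delta_min = 0.1,
                            min_probes = 3,
                            adjust_scope = c("per_tumour", "global"),
                            exact_max = 25) {
  stopifnot(p_adj_max > 0, p_adj_max < 1, delta_min > 0, min_probes >= 1)
  structure(list(p_adj_max = p_adj_max, delta_min = delta_min,
                 min_probes = min_probes,
                 adjust_scope = match.arg(adjust_scope),
                 exact_max = exact_max),
            class = "call_parameters")
}

#' Matched tumour/normal pairs from a sample sheet
#'
#' @param sheet sample sheet with `sample_id`, `subject_id`, `tissue`.
#' @return `data.frame` with columns `subject_id`, `tumour`, `normal`
#'   (sample ids), one row per complete pair.
#' @export
matched_pairs <- function(sheet) {
  tum <- sheet[sheet$tissue == "tumour", c("subject_id", "sample_id")]
  nor <- sheet[sheet$tissue == "normal", c("subject_id", "sample_id")]
  merged <- merge(tum, nor, by = "subject_id", suffixes = c(".t", ".n"))
  data.frame(subject_id = merged$subject_id,
             tumour = merged$sample_id.t,
             normal = merged$sample_id.n,
             stringsAsFactors = FALSE)
}

# internal: per-(gene, pair) raw p and delta-beta, the expensive part of
# the caller, computed once and re-thresholded cheaply by the delta scan
.island_test_matrix <- function(beta, map, pairs, params) {
  genes <- names(map)
  if (length(genes) == 0) stop("gene map is empty")
  miss_t <- setdiff(pairs$tumour, colnames(beta))
  miss_n <- setdiff(pairs$normal, colnames(beta))
  if (length(miss_t) || length(miss_n))
    stop("unmatched pair: missing samples for subject(s) ",
         paste(pairs$subject_id[pairs$tumour %in% miss_t |
                                  pairs$normal %in% miss_n], collapse = ", "))
  n_pairs <- nrow(pairs)
  P <- matrix(NA_real_, length(genes), n_pairs,
              dimnames = list(genes, pairs$subject_id))
  DB <- P
  for (g in seq_along(genes)) {
    probes <- intersect(map[[g]], rownames(beta))
    if (length(probes) < params$min_probes) next
    D <- beta[probes, pairs$tumour, drop = FALSE] -
      beta[probes, pairs$normal, drop = FALSE]
    DB[g, ] <- colMeans(D)
    P[g, ] <- apply(D, 2, .signed_rank_p, exact_max = params$exact_max)
  }
  keep <- !is.na(P[, 1])
  list(p = P[keep, , drop = FALSE], delta = DB[keep, , drop = FALSE])
}

#' Gene-level differential methylation calls per tumour pair
#'
#' For every gene (its island+shore probe set) and every matched
#' tumour/normal pair, computes the paired signed-rank p-value over the
#' probes, BH-adjusts across genes (within each tumour by default), and the
#' tumour-minus-normal mean beta difference, then emits a call: `hyper` if
#' the adjusted p is below `p_adj_max` *and* delta-beta is at least
#' `delta_min`; `hypo` under the mirrored criterion; `none` otherwise.
#'
#' @param beta probes x samples beta matrix.
#' @param map named list gene -> island+shore probe ids, from
#'   [build_gene_island_map()].
#' @param pairs matched pairs `data.frame` from [matched_pairs()].
#' @param params a [call_parameters()] list.
#' @return a long `data.frame` of class `island_calls` with columns `gene`,
#'   `subject_id`, `p`, `p_adj`, `delta_beta`, `call`; the parameters used
#'   are kept in the `params` attribute.
#' @export
call_island_dm <- function(beta, map, pairs, params = call_parameters()) {
  tm <- .island_test_matrix(beta, map, pairs, params)
  p_adj <- tm$p
  if (params$adjust_scope == "per_tumour") {
    for (j in seq_len(ncol(p_adj))) p_adj[, j] <- bh_adjust(tm$p[, j])
  } else {
    p_adj[] <- bh_adjust(as.vector(tm$p))
  }
  out <- data.frame(
    gene = rep(rownames(tm$p), times = ncol(tm$p)),
    subject_id = rep(colnames(tm$p), each = nrow(tm$p)),
    p = as.vector(tm$p),
    p_adj = as.vector(p_adj),
    delta_beta = as.vector(tm$delta),
    stringsAsFactors = FALSE)
  out$call <- ifelse(out$p_adj < params$p_adj_max & out$delta_beta >= params$delta_min,
                     "hyper",
              ifelse(out$p_adj < params$p_adj_max & out$delta_beta <= -params$delta_min,
                     "hypo", "none"))
  attr(out, "params") <- params
  class(out) <- c("island_calls", class(out))
  out
}

# internal: per-subject hyper counts at an arbitrary delta threshold
.hyper_counts <- function(calls, delta_min, p_adj_max) {
  hyper <- calls$p_adj < p_adj_max & calls$delta_beta >= delta_min
  counts <- tapply(hyper, calls$subject_id, sum)
  stats::setNames(as.integer(counts), names(counts))
}

#' Choose the delta-beta threshold separating CIMP-H from CIMP-N
#'
#' Recomputes hypermethylation calls at every candidate threshold and
#' scores each by the difference between the mean per-tumour hyper count in
#' CIMP-H tumours and that in CIMP-N tumours. The threshold maximising this
#' separation is returned (ties broken toward the smallest delta), together
#' with the full objective curve. Only the delta criterion moves with the
#' grid; p-values are reused.
#'
#' @param calls an `island_calls` frame from [call_island_dm()].
#' @param grid numeric vector of candidate delta thresholds.
#' @param labels named vector of tumour CIMP labels (subject -> label), as
#'   from [cimp_tumour_labels()].
#' @return list with `chosen` (the selected delta) and `curve`
#'   (`data.frame` of threshold, mean counts per group, objective).
#' @export
scan_delta_threshold <- function(calls, grid, labels) {
  if (length(grid) == 0) stop("empty threshold grid")
  p_adj_max <- attr(calls, "params")$p_adj_max
  subjects <- unique(calls$subject_id)
  lab <- labels[subjects]
  if (!any(lab == "CIMP-H", na.rm = TRUE) || !any(lab == "CIMP-N", na.rm = TRUE))
    stop("need at least one CIMP-H and one CIMP-N tumour")
  rows <- lapply(sort(grid), function(delta) {
    cnt <- .hyper_counts(calls, delta, p_adj_max)[subjects]
    data.frame(delta = delta,
               mean_H = mean(cnt[lab == "CIMP-H"], na.rm = TRUE),
               mean_N = mean(cnt[lab == "CIMP-N"], na.rm = TRUE))
  })
  curve <- do.call(rbind, rows)
  curve$objective <- curve$mean_H - curve$mean_N
  list(chosen = curve$delta[which.max(curve$objective)], curve = curve)
}

#' Per-tumour hypermethylation counts and group summaries
#'
#' @param calls an `island_calls` frame from [call_island_dm()].
#' @param labels named vector of tumour CIMP labels (subject -> label).
#' @return list with `per_tumour` (`data.frame` of subject, label, hyper
#'   count) and `summary` (mean/min/max count per CIMP group).
#' @export
tumour_call_counts <- function(calls, labels) {
  p_adj_max <- attr(calls, "params")$p_adj_max
  delta_min <- attr(calls, "params")$delta_min
  cnt <- .hyper_counts(calls, delta_min, p_adj_max)
  per_tumour <- data.frame(subject_id = names(cnt),
                           label = unname(labels[names(cnt)]),
                           n_hyper = unname(cnt),
                           stringsAsFactors = FALSE)
  grp <- per_tumour[!is.na(per_tumour$label), ]
  summary <- do.call(rbind, lapply(split(grp, grp$label), function(d)
    data.frame(label = d$label[1], n = nrow(d), mean = mean(d$n_hyper),
               min = min(d$n_hyper), max = max(d$n_hyper))))
  rownames(summary) <- NULL
  list(per_tumour = per_tumour, summary = summary)
}
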