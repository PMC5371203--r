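#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact p-value with fixed margins. The default (minimum-likelihood)
#' definition sums the hypergeometric probabilities of all tables whose
#' point probability does not exceed that of the observed table, as in
#' [stats::fisher.test()]; `method = "doubled"` instead doubles the smaller
#' one-sided tail (capped at 1). A table with an empty margin carries no
#' information and returns p = 1 with a warning.
#'
#' @param tab 2x2 matrix (or object coercible to one) of non-negative
#'   integer counts.
#' @param method `"minlike"` (default) or `"doubled"`.
#' @return a single two-sided p-value.
#' @examples
#' fisher_exact_two_sided(matrix(c(5, 6, 5, 31), 2))  # 0.039...
#' @export
fisher_exact_two_sided <- function(tab, method = c("minlike", "doubled")) {
  method <- match.arg(method)
  tab <- as.matrix(tab)
  if (!identical(dim(tab), c(2L, 2L))) stop("need a 2x2 table")
  if (any(tab < 0) || any(tab != round(tab)))
    stop("cells must be non-negative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("empty margin: p = 1")
    return(1)
  }
  if (method == "minlike")
    return(stats::fisher.test(tab)$p.value)
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  x <- tab[1, 1]
  lower <- stats::phyper(x, m, n, k)
  upper <- 1 - stats::phyper(x - 1, m, n, k)
  min(1, 2 * min(lower, upper))
}

#' Welch's t-test from group summaries
#'
#' Unequal-variance two-sample t-test computed from the published group
#' means, standard deviations and sizes:
#' \eqn{t = (m_1 - m_2) / \sqrt{s_1^2/n_1 + s_2^2/n_2}} with
#' Welch--Satterthwaite degrees of freedom.
#'
#' @param mean1,sd1,n1 summary of the first group (`n1 >= 2`).
#' @param mean2,sd2,n2 summary of the second group.
#' @return list with `t`, `df` and the two-sided `p`.
#' @examples
#' welch_t_summary(73.6, 7.7, 26, 69, 12.3, 37)$p  # 0.073...
#' @export
welch_t_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
  if (v1 + v2 == 0) {
    return(list(t = 0, df = n1 + n2 - 2, p = 1))
  }
  t <- (mean1 - mean2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' CIMP status from the five-gene marker panel
#'
#' Classifies a tumour from the methylation status of the Weisenberger
#' marker genes (CACNA1G, NEUROG1, RUNX3, SOCS1, IGF2): hypermethylation at
#' more than 3 of the 5 markers is CIMP-H, at 1 to 3 markers CIMP-L, and at
#' none CIMP-N.
#'
#' @param methylated_flags logical vector of exactly 5 marker states.
#' @return `"CIMP-H"`, `"CIMP-L"` or `"CIMP-N"`.
#' @export
panel_cimp_classify <- function(methylated_flags) {
  if (length(methylated_flags) != 5 || !is.logical(methylated_flags) ||
      anyNA(methylated_flags))
    stop("need exactly 5 non-missing logical marker flags")
  c <- sum(methylated_flags)
  if (c >= 4) "CIMP-H" else if (c >= 1) "CIMP-L" else "CIMP-N"
}

#' Concordance between clustering-derived and panel-derived CIMP labels
#'
#' For each class of the clustering-derived labels, the fraction of its
#' members whose marker-panel label agrees.
#'
#' @param cluster_labels,panel_labels equal-length label vectors over the
#'   same samples.
#' @return `data.frame` with columns `label`, `n`, `n_agree`, `concordance`.
#' @export
label_concordance <- function(cluster_labels, panel_labels) {
  if (length(cluster_labels) != length(panel_labels))
    stop("label vectors must have equal length")
  classes <- sort(unique(cluster_labels))
  rows <- lapply(classes, function(cl) {
    idx <- cluster_labels == cl
    data.frame(label = cl, n = sum(idx),
               n_agree = sum(panel_labels[idx] == cl),
               concordance = mean(panel_labels[idx] == cl))
  })
  do.call(rbind, rows)
}

#' Truncate a value to a number of decimals
#'
#' Published tables often truncate rather than round p-values; this helper
#' reproduces that convention for comparisons (0.0394 prints as 0.039).
#'
#' @param x numeric vector.
#' @param digits decimals to keep.
#' @export
truncate_decimals <- function(x, digits) {
  trunc(x * 10^digits) / 10^digits
}
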