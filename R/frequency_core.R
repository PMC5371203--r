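#' Hypermethylation frequency of each gene by CIMP group
#'
#' Scores every gene for the number (and fraction) of tumours in which it
#' was called hypermethylated, within each CIMP group and over all labelled
#' tumours. Group sizes are the tumour counts after any subtyping
#' exclusions.
#'
#' @param calls an `island_calls` frame from [call_island_dm()].
#' @param labels named vector of tumour CIMP labels (subject -> label).
#' @return a list of class `frequency_profile`: `table` (`data.frame` with
#'   one row per gene x group: `gene`, `group`, `n_hyper`, `group_size`,
#'   `fraction`) and `group_sizes`. Empty groups are flagged with `NA`
#'   fractions.
#' @export
gene_frequency <- function(calls, labels) {
  subjects <- unique(calls$subject_id)
  lab <- labels[subjects]
  groups <- list(`CIMP-H` = subjects[!is.na(lab) & lab == "CIMP-H"],
                 `CIMP-L` = subjects[!is.na(lab) & lab == "CIMP-L"],
                 `CIMP-N` = subjects[!is.na(lab) & lab == "CIMP-N"])
  groups$all <- unlist(groups, use.names = FALSE)
  genes <- unique(calls$gene)
  hyper <- calls$call == "hyper"
  rows <- lapply(names(groups), function(g) {
    members <- groups[[g]]
    size <- length(members)
    cnt <- if (size == 0) rep(0L, length(genes)) else {
      sel <- hyper & calls$subject_id %in% members
      tab <- table(factor(calls$gene[sel], levels = genes))
      as.integer(tab)
    }
    data.frame(gene = genes, group = g, n_hyper = cnt, group_size = size,
               fraction = if (size > 0) cnt / size else NA_real_,
               stringsAsFactors = FALSE)
  })
  structure(list(table = do.call(rbind, rows),
                 group_sizes = vapply(groups, length, integer(1))),
            class = "frequency_profile")
}

#' Genes hypermethylated above a frequency threshold
#'
#' For thresholds below 1 the rule is strict (`fraction > threshold`,
#' matching "hypermethylated in more than the specified percentage of
#' tumours"); at threshold 1 it is equality (`fraction == 1`, genes
#' hypermethylated in every tumour of the group).
#'
#' @param freq a `frequency_profile` from [gene_frequency()].
#' @param group one of `"CIMP-H"`, `"CIMP-L"`, `"CIMP-N"`, `"all"`.
#' @param threshold frequency threshold in `[0, 1]`.
#' @return character vector of qualifying gene symbols (sorted).
#' @export
core_gene_set <- function(freq, group = "CIMP-H", threshold = 1) {
  stopifnot(inherits(freq, "frequency_profile"),
            threshold >= 0, threshold <= 1)
  tab <- freq$table[freq$table$group == group, ]
  if (nrow(tab) == 0) stop("unknown group: ", group)
  if (all(is.na(tab$fraction))) stop("group ", group, " is empty")
  keep <- if (threshold == 1) tab$fraction == 1 else tab$fraction > threshold
  sort(tab$gene[keep])
}

#' Frequency curve: qualifying genes per threshold and group
#'
#' The number of genes hypermethylated in more than each threshold fraction
#' of a group's tumours, per group -- non-increasing in the threshold.
#'
#' @param freq a `frequency_profile` from [gene_frequency()].
#' @param thresholds numeric vector of thresholds in `[0, 1]`.
#' @return `data.frame` with columns `group`, `threshold`, `n_genes`.
#' @export
frequency_curve <- function(freq, thresholds = seq(0.1, 1, by = 0.1)) {
  stopifnot(all(thresholds >= 0 & thresholds <= 1))
  groups <- unique(freq$table$group)
  rows <- lapply(groups, function(g) {
    tab <- freq$table[freq$table$group == g, ]
    n <- vapply(thresholds, function(th) {
      if (all(is.na(tab$fraction))) return(0L)
      if (th == 1) sum(tab$fraction == 1) else sum(tab$fraction > th)
    }, integer(1))
    data.frame(group = g, threshold = thresholds, n_genes = n,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
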