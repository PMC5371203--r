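#' Hierarchical clustering of samples on selected probes
#'
#' Agglomerative clustering of samples with Euclidean distance and complete
#' linkage, the combination under which merge heights are the maximum
#' pairwise distance between the joined clusters and are non-decreasing
#' along the tree. A thin wrapper over [stats::hclust()] that validates the
#' input and records the metric and linkage used.
#'
#' @param X samples x probes numeric matrix (rows are clustered). Row names
#'   are sample ids.
#' @return an object of class `hclust` with extra attributes `metric` and
#'   `linkage`.
#' @export
complete_linkage_cluster <- function(X) {
  stopifnot(is.matrix(X))
  if (nrow(X) < 2) stop("need at least 2 samples to cluster")
  if (anyNA(X))
    stop("X contains missing values; filter probes upstream before clustering")
  hc <- stats::hclust(stats::dist(X, method = "euclidean"),
                      method = "complete")
  attr(hc, "metric") <- "euclidean"
  attr(hc, "linkage") <- "complete"
  hc
}

#' Assign CIMP-H/L/N labels from the sample dendrogram
#'
#' Reproducible surrogate for the visual dendrogram cut used in CIMP
#' studies. The tree over all tumour and normal samples is cut into two
#' branches; the branch with the lower mean beta over the selected probes
#' is the normal-like branch. Tumours falling in it are labelled CIMP-N
#' (tumours indistinguishable from normal tissue), and normal samples
#' falling in the tumour-like branch are flagged and excluded from
#' downstream analysis. The tumour-like branch is then cut into three
#' subclusters (by lowering the tree cut until its samples split in three),
#' which are ranked by decreasing mean beta and labelled CIMP-H, CIMP-L and
#' CIMP-N; the last merges with any normal-branch tumours.
#'
#' @param dend an `hclust` tree from [complete_linkage_cluster()] over all
#'   samples.
#' @param sheet sample sheet `data.frame` with `sample_id`, `subject_id`
#'   and `tissue` columns covering the clustered samples.
#' @param X the samples x selected-probes beta matrix the tree was built
#'   on (used for mean-beta ranking).
#' @return a list of class `cimp_assignment`: `samples` (per-sample
#'   `data.frame` with `branch`, `subcluster`, `label`), `cluster_means`
#'   (mean beta of the three tumour subclusters), and the flag vectors
#'   `tumours_in_normal_branch`, `normals_in_tumour_branch` (sample ids).
#' @export
assign_cimp_labels <- function(dend, sheet, X) {
  stopifnot(inherits(dend, "hclust"), is.matrix(X))
  ids <- dend$labels
  if (is.null(ids) || !setequal(ids, rownames(X)))
    stop("dendrogram labels and matrix row names must agree")
  sheet <- sheet[match(ids, sheet$sample_id), ]
  if (anyNA(sheet$sample_id)) stop("sample sheet does not cover all samples")
  if (!any(sheet$tissue == "tumour"))
    stop("no tumour samples: cannot identify a tumour-like branch")

  two <- stats::cutree(dend, k = 2)[ids]
  branch_mean <- tapply(rowMeans(X)[ids], two, mean)
  tumour_like <- as.integer(names(branch_mean)[which.max(branch_mean)])
  in_tumour_branch <- two == tumour_like

  tumours_in_normal <- ids[!in_tumour_branch & sheet$tissue == "tumour"]
  normals_in_tumour <- ids[in_tumour_branch & sheet$tissue == "normal"]

  branch_ids <- ids[in_tumour_branch]
  if (length(branch_ids) < 3)
    stop("tumour-like branch has fewer than 3 samples; cannot form 3 subclusters")
  sub <- NULL
  for (k in 3:length(ids)) {
    cut_k <- stats::cutree(dend, k = k)[ids]
    if (length(unique(cut_k[branch_ids])) == 3) { sub <- cut_k; break }
  }
  if (is.null(sub))
    stop("could not split the tumour-like branch into 3 subclusters")

  sub_mean <- tapply(rowMeans(X[branch_ids, , drop = FALSE]),
                     sub[branch_ids], mean)
  ranked <- names(sort(sub_mean, decreasing = TRUE))
  sub_label <- stats::setNames(c("CIMP-H", "CIMP-L", "CIMP-N"), ranked)

  label <- rep(NA_character_, length(ids))
  names(label) <- ids
  tum <- sheet$tissue == "tumour"
  label[ids[tum & in_tumour_branch]] <-
    sub_label[as.character(sub[ids[tum & in_tumour_branch]])]
  label[tumours_in_normal] <- "CIMP-N"
  label[normals_in_tumour] <- "excluded"

  samples <- data.frame(
    sample_id = ids,
    subject_id = sheet$subject_id,
    tissue = sheet$tissue,
    branch = ifelse(in_tumour_branch, "tumour_like", "normal_like"),
    subcluster = ifelse(in_tumour_branch, as.integer(sub[ids]), NA_integer_),
    label = unname(label),
    row.names = NULL)
  structure(list(samples = samples,
                 cluster_means = sub_mean[ranked],
                 tumours_in_normal_branch = tumours_in_normal,
                 normals_in_tumour_branch = normals_in_tumour),
            class = "cimp_assignment")
}

#' Tumour subtype labels from a CIMP assignment
#'
#' @param assignment a `cimp_assignment` from [assign_cimp_labels()].
#' @return named character vector of CIMP labels, one per tumour sample,
#'   named by subject id.
#' @export
cimp_tumour_labels <- function(assignment) {
  s <- assignment$samples
  t <- s[s$tissue == "tumour", ]
  stats::setNames(t$label, t$subject_id)
}
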