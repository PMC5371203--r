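#' Beta values from methylated/unmethylated intensities
#'
#' The methylation level at a CpG is summarised as
#' \deqn{\beta = M / (M + U + \mathrm{offset})}
#' where \eqn{M} and \eqn{U} are the methylated and unmethylated allele
#' intensities and the offset (100 by convention) stabilises the ratio at
#' low total intensity. Values range from 0 (fully unmethylated) towards,
#' but strictly below, 1 (fully methylated).
#'
#' @param M,U non-negative intensity matrices (or vectors) of equal shape.
#' @param offset positive regularising constant added to the denominator.
#' @return matrix (or vector) of beta values in `[0, 1)`.
#' @examples
#' compute_beta(100, 0)    # 0.5
#' compute_beta(300, 100)  # 0.6
#' @export
compute_beta <- function(M, U, offset = 100) {
  if (offset <= 0) stop("offset must be positive")
  if (any(M < 0, na.rm = TRUE) || any(U < 0, na.rm = TRUE))
    stop("intensities must be non-negative")
  M / (M + U + offset)
}

#' Assemble an intensity dataset
#'
#' Bundles the raw inputs of the pipeline: probes x samples matrices of
#' methylated (`M`) and unmethylated (`U`) intensities, detection p-values,
#' and the sample sheet. Row names are probe ids, column names sample ids;
#' all three matrices must agree on both.
#'
#' @param M,U,detection_p numeric matrices, probes x samples.
#' @param sample_sheet `data.frame` with at least `sample_id`, `subject_id`,
#'   `tissue` (`"tumour"`/`"normal"`) and `batch` columns; matched pairs
#'   share `subject_id`.
#' @return a list of class `intensity_dataset`.
#' @export
intensity_dataset <- function(M, U, detection_p, sample_sheet) {
  stopifnot(is.matrix(M), is.matrix(U), is.matrix(detection_p))
  if (!identical(dim(M), dim(U)) || !identical(dim(M), dim(detection_p)))
    stop("M, U and detection_p must share dimensions")
  if (!identical(rownames(M), rownames(U)) ||
      !identical(rownames(M), rownames(detection_p)))
    stop("M, U and detection_p must share probe row names")
  if (!identical(colnames(M), colnames(U)) ||
      !identical(colnames(M), colnames(detection_p)))
    stop("M, U and detection_p must share sample column names")
  if (any(M < 0) || any(U < 0)) stop("intensities must be non-negative")
  if (any(detection_p < 0 | detection_p > 1))
    stop("detection p-values must lie in [0, 1]")
  need <- c("sample_id", "subject_id", "tissue", "batch")
  if (!all(need %in% names(sample_sheet)))
    stop("sample sheet must have columns: ", paste(need, collapse = ", "))
  if (!setequal(sample_sheet$sample_id, colnames(M)))
    stop("sample sheet and intensity columns disagree")
  tab <- table(sample_sheet$subject_id, sample_sheet$tissue)
  if (any(tab > 1))
    stop("each subject may contribute at most one tumour and one normal sample")
  structure(list(M = M, U = U, detection_p = detection_p,
                 sample_sheet = sample_sheet),
            class = "intensity_dataset")
}

#' Probe quality-control filter
#'
#' Removes, in this priority order, (1) control probes (never part of the
#' analysis set), (2) probes whose detection p-value exceeds `alpha` in more
#' than a fraction `max_failure_fraction` of samples (the default 0 removes
#' a probe failing in *any* sample), (3) probes on the X or Y chromosome,
#' and (4) probes known to cross-react elsewhere in the genome. Each removed
#' probe is attributed to the first rule that caught it, so the report
#' counts sum to the number removed.
#'
#' @param ds an [intensity_dataset()].
#' @param manifest a validated probe manifest covering the dataset's probes.
#' @param alpha detection p-value threshold in (0, 1).
#' @param max_failure_fraction tolerated fraction of samples failing
#'   detection before a probe is dropped.
#' @return list with `retained` (character vector of probe ids) and
#'   `report` (`data.frame` of removal reasons and counts).
#' @export
filter_probes <- function(ds, manifest, alpha = 0.05,
                          max_failure_fraction = 0) {
  stopifnot(inherits(ds, "intensity_dataset"))
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie strictly in (0, 1)")
  validate_manifest(manifest)
  probes <- rownames(ds$M)
  idx <- match(probes, manifest$probe_id)
  if (anyNA(idx)) stop("dataset probes missing from the manifest")
  m <- manifest[idx, ]

  is_control <- m$is_negative_control | m$is_internal_control
  fail_frac <- rowMeans(ds$detection_p > alpha)
  detect_fail <- !is_control & fail_frac > max_failure_fraction
  sex <- !is_control & !detect_fail & m$is_sex_chromosome
  xreact <- !is_control & !detect_fail & !sex & m$cross_reactive

  removed <- is_control | detect_fail | sex | xreact
  report <- data.frame(
    reason = c("control", "detection", "sex_chromosome", "cross_reactive"),
    n_removed = c(sum(is_control), sum(detect_fail), sum(sex), sum(xreact)))
  list(retained = probes[!removed], report = report)
}

#' Rescale intensities to a common internal-control mean
#'
#' Computes, per sample, the mean total intensity (M + U) of the internal
#' control probes, and multiplies every intensity of that sample by
#' \eqn{f_s = \bar{c} / c_s}, where \eqn{c_s} is the sample's control mean
#' and \eqn{\bar{c}} the grand mean of control means across samples. After
#' rescaling, all samples share the same control mean. Rescaling acts on
#' intensities *before* beta computation; because the offset is not
#' rescaled, beta values are not exactly invariant under the factor.
#'
#' @param ds an [intensity_dataset()].
#' @param internal_control_ids character vector of internal-control probe
#'   ids present in the dataset.
#' @return list with `dataset` (rescaled [intensity_dataset()]) and
#'   `factors` (named numeric vector of per-sample factors).
#' @export
rescale_to_control_mean <- function(ds, internal_control_ids) {
  stopifnot(inherits(ds, "intensity_dataset"))
  ctl <- intersect(internal_control_ids, rownames(ds$M))
  if (length(ctl) == 0) stop("no internal control probes found in dataset")
  total <- ds$M[ctl, , drop = FALSE] + ds$U[ctl, , drop = FALSE]
  ctl_mean <- colMeans(total)
  if (any(!is.finite(ctl_mean) | ctl_mean <= 0))
    stop("zero or missing control mean in sample(s): ",
         paste(colnames(ds$M)[!is.finite(ctl_mean) | ctl_mean <= 0],
               collapse = ", "))
  f <- mean(ctl_mean) / ctl_mean
  M <- sweep(ds$M, 2, f, `*`)
  U <- sweep(ds$U, 2, f, `*`)
  list(dataset = intensity_dataset(M, U, ds$detection_p, ds$sample_sheet),
       factors = f)
}

#' Empirical-Bayes batch adjustment of beta values
#'
#' Adjusts probes x samples beta values for chip (batch) effects with the
#' ComBat location-scale model (per-probe standardisation, per-batch
#' additive and multiplicative effect estimates shrunk toward common
#' priors, back-transformation), as implemented in the \pkg{sva} package.
#' With a single batch there is nothing to adjust and the input is returned
#' unchanged. Output is clipped back into `[0, 1)`.
#'
#' @param beta probes x samples matrix of beta values.
#' @param batch vector of batch labels, one per sample.
#' @param parametric use parametric empirical-Bayes priors (default).
#' @param covariates optional factor (or vector) of biological condition
#'   labels, e.g. tissue, protected from adjustment; without it the
#'   location-scale model treats condition differences as noise and
#'   partially removes them.
#' @return list with `beta` (adjusted matrix, same shape and order),
#'   `batch_params` (`data.frame` of pre-adjustment per-batch mean shifts)
#'   and `adjusted` (logical flag).
#' @export
combat_adjust <- function(beta, batch, parametric = TRUE,
                          covariates = NULL) {
  stopifnot(is.matrix(beta))
  if (length(batch) != ncol(beta))
    stop("need one batch label per sample")
  if (any(beta < 0 | beta >= 1)) stop("beta values must lie in [0, 1)")
  batch <- as.character(batch)
  sizes <- table(batch)
  overall <- rowMeans(beta)
  shift <- vapply(names(sizes), function(b)
    mean(rowMeans(beta[, batch == b, drop = FALSE]) - overall), numeric(1))
  params <- data.frame(batch = names(sizes), n = as.integer(sizes),
                       mean_shift = unname(shift))
  if (length(sizes) < 2)
    return(list(beta = beta, batch_params = params, adjusted = FALSE))
  if (any(sizes < 2))
    stop("every batch needs at least 2 samples (variance undefined): ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  # zero-variance probes carry no batch information; pass them through
  mod <- NULL
  if (!is.null(covariates)) {
    if (length(covariates) != ncol(beta))
      stop("need one covariate value per sample")
    mod <- stats::model.matrix(~ factor(covariates))
  }
  v <- rowMeans(beta^2) - rowMeans(beta)^2
  v <- v > 1e-12
  adj <- beta
  if (any(v)) {
    adj[v, ] <- sva::ComBat(dat = beta[v, , drop = FALSE],
                            batch = batch, mod = mod,
                            par.prior = parametric, prior.plots = FALSE)
  }
  adj[adj < 0] <- 0
  adj[adj >= 1] <- 1 - 1e-9
  dimnames(adj) <- dimnames(beta)
  list(beta = adj, batch_params = params, adjusted = TRUE)
}

#' Read / write probes-by-samples matrices
#'
#' TSV serialisation with probe ids in the first column and a header row of
#' sample ids, the interchange format of all pipeline matrices.
#'
#' @param x numeric matrix with row and column names.
#' @param path file path.
#' @export
write_matrix_tsv <- function(x, path) {
  df <- data.frame(probe_id = rownames(x), x, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = c(probe_id = "character"))
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
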