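#' Pipeline configuration
#'
#' All tunable parameters of the end-to-end analysis in one declarative
#' list; the full configuration (defaults included) is snapshotted next to
#' the outputs so a run is reproducible from its report bundle alone.
#'
#' @param offset beta-value regularising offset.
#' @param alpha detection p-value threshold.
#' @param max_failure_fraction tolerated fraction of samples failing
#'   detection per probe (0 = strict any-sample rule).
#' @param s0_mode SAM fudge-factor mode, `"cv"` or `"median"`.
#' @param n_permutations SAM permutations for the FDR estimate.
#' @param sam_seed seed for the SAM permutation draw (mandatory: the only
#'   stochastic stage).
#' @param top_k probes kept for clustering.
#' @param p_adj_max,delta_min,min_probes gene-calling parameters, see
#'   [call_parameters()].
#' @param adjust_scope BH scope, `"per_tumour"` or `"global"`.
#' @param delta_grid candidate delta thresholds for the separation scan
#'   (`NULL` skips the scan and keeps `delta_min`).
#' @param frequency_thresholds thresholds for the frequency curve.
#' @param core_threshold frequency threshold defining the core gene set.
#' @param combat apply empirical-Bayes batch adjustment.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(offset = 100, alpha = 0.05,
                            max_failure_fraction = 0,
                            s0_mode = c("cv", "median"),
                            n_permutations = 200, sam_seed = 1,
                            top_k = 2500,
                            p_adj_max = 0.005, delta_min = 0.1,
                            min_probes = 3,
                            adjust_scope = "per_tumour",
                            delta_grid = seq(0.05, 0.3, by = 0.05),
                            frequency_thresholds = seq(0.1, 1, by = 0.1),
                            core_threshold = 1,
                            combat = TRUE) {
  s0_mode <- match.arg(s0_mode)
  if (is.null(sam_seed)) stop("sam_seed is mandatory: SAM permutations are stochastic")
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full methylation analysis pipeline
#'
#' Executes, in order: probe QC (detection, sex-chromosome, cross-reactive
#' and control filtering), internal-control rescaling, beta computation,
#' batch adjustment, SAM differential methylation with permutation FDR and
#' top-K selection, hierarchical CIMP subtyping, gene-level island+shore
#' hypermethylation calling, the delta-threshold separation scan, per-gene
#' frequency scoring and core-set extraction, and (when marker-panel
#' columns are present in the sample sheet) panel classification and
#' concordance. When `out_dir` is given, every stage result is written as
#' a TSV/JSON report bundle together with a configuration snapshot.
#'
#' @param ds an [intensity_dataset()].
#' @param manifest list with `manifest` and `islands` (see
#'   [generate_manifest()] / [read_manifest()]).
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory for the report bundle.
#' @return a list with the results of every stage.
#' @export
run_pipeline <- function(ds, manifest, config = pipeline_config(),
                         out_dir = NULL) {
  stopifnot(inherits(ds, "intensity_dataset"),
            inherits(config, "pipeline_config"))
  man <- manifest$manifest
  validate_manifest(man)

  qc <- filter_probes(ds, man, alpha = config$alpha,
                      max_failure_fraction = config$max_failure_fraction)
  ctl_ids <- man$probe_id[man$is_internal_control]
  resc <- rescale_to_control_mean(ds, ctl_ids)
  rds <- resc$dataset
  beta <- compute_beta(rds$M[qc$retained, , drop = FALSE],
                       rds$U[qc$retained, , drop = FALSE],
                       offset = config$offset)
  beta[beta >= 1] <- 1 - 1e-9

  sheet <- ds$sample_sheet[match(colnames(beta), ds$sample_sheet$sample_id), ]
  batch <- NULL
  if (config$combat) {
    cb <- combat_adjust(beta, sheet$batch, covariates = sheet$tissue)
    beta <- cb$beta
    batch <- cb$batch_params
  }

  labels <- ifelse(sheet$tissue == "tumour", "tumour", "normal")
  d0 <- sam_d_statistic(beta, labels, s0 = 0)
  s0 <- choose_s0(d0$s, d0$r, mode = config$s0_mode)
  sam <- sam_permutation_fdr(beta, labels, s0 = s0,
                             n_permutations = config$n_permutations,
                             seed = config$sam_seed)
  top_k <- min(config$top_k, nrow(beta))
  top <- select_top_k(sam, k = top_k)

  X <- t(beta[top, , drop = FALSE])
  dend <- complete_linkage_cluster(X)
  assignment <- assign_cimp_labels(dend, sheet, X)
  tumour_labels <- cimp_tumour_labels(assignment)

  gmap <- build_gene_island_map(man, min_probes = config$min_probes,
                                probe_universe = qc$retained)
  pairs <- matched_pairs(sheet)
  params <- call_parameters(p_adj_max = config$p_adj_max,
                            delta_min = config$delta_min,
                            min_probes = config$min_probes,
                            adjust_scope = config$adjust_scope)
  calls <- call_island_dm(beta, gmap$map, pairs, params)

  scan <- NULL
  if (!is.null(config$delta_grid)) {
    scan <- scan_delta_threshold(calls, config$delta_grid, tumour_labels)
    if (scan$chosen != params$delta_min) {
      params$delta_min <- scan$chosen
      calls$call <- ifelse(
        calls$p_adj < params$p_adj_max & calls$delta_beta >= params$delta_min,
        "hyper",
        ifelse(calls$p_adj < params$p_adj_max &
                 calls$delta_beta <= -params$delta_min, "hypo", "none"))
      attr(calls, "params") <- params
    }
  }

  counts <- tumour_call_counts(calls, tumour_labels)
  freq <- gene_frequency(calls, tumour_labels)
  core <- core_gene_set(freq, "CIMP-H", config$core_threshold)
  curve <- frequency_curve(freq, config$frequency_thresholds)

  concordance <- NULL
  marker_cols <- grep("^marker_", names(sheet), value = TRUE)
  if (length(marker_cols) == 5) {
    tum <- sheet[sheet$tissue == "tumour", ]
    panel <- apply(as.matrix(tum[, marker_cols]), 1, function(f)
      panel_cimp_classify(as.logical(f)))
    names(panel) <- tum$subject_id
    ok <- names(tumour_labels)[tumour_labels %in%
                                 c("CIMP-H", "CIMP-L", "CIMP-N")]
    concordance <- label_concordance(tumour_labels[ok], panel[ok])
  }

  result <- list(qc = qc, rescale_factors = resc$factors, beta = beta,
                 batch_params = batch, s0 = s0, sam = sam,
                 top_probes = top, dendrogram = dend,
                 assignment = assignment, tumour_labels = tumour_labels,
                 gene_map = gmap, calls = calls, scan = scan,
                 counts = counts, frequency = freq, core_genes = core,
                 frequency_curve = curve, concordance = concordance,
                 config = config)
  if (!is.null(out_dir)) .write_report_bundle(result, out_dir)
  result
}

# internal: TSV/JSON report bundle
.write_report_bundle <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name)
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  w(res$qc$report, "qc_report.tsv")
  write_matrix_tsv(res$beta, file.path(out_dir, "beta.tsv"))
  if (!is.null(res$batch_params)) w(res$batch_params, "batch_params.tsv")
  sam_out <- res$sam[order(res$sam$rank), c("probe_id", "d", "s", "q", "rank")]
  w(sam_out, "sam_results.tsv")
  w(res$assignment$samples, "cimp_labels.tsv")
  jsonlite::write_json(
    list(merge = res$dendrogram$merge, height = res$dendrogram$height,
         order = res$dendrogram$order, labels = res$dendrogram$labels,
         metric = attr(res$dendrogram, "metric"),
         linkage = attr(res$dendrogram, "linkage")),
    file.path(out_dir, "dendrogram.json"), digits = NA)
  w(as.data.frame(res$calls), "island_calls.tsv")
  w(res$counts$per_tumour, "tumour_counts.tsv")
  if (!is.null(res$scan)) w(res$scan$curve, "threshold_curve.tsv")
  w(res$frequency$table, "gene_frequency.tsv")
  writeLines(res$core_genes, file.path(out_dir, "core_genes.txt"))
  w(res$frequency_curve, "frequency_curve.tsv")
  if (!is.null(res$concordance)) w(res$concordance, "concordance.tsv")
  cfg <- res$config
  cfg$s0_used <- res$s0
  jsonlite::write_json(cfg, file.path(out_dir, "config_snapshot.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(out_dir)
}
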