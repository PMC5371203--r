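#' Configuration of the synthetic matched-cohort generator
#'
#' Describes a 450K-like matched tumour/normal cohort with planted ground
#' truth: three CIMP strata, a core hypermethylome shared by all CIMP-H
#' tumours (a subset of which -- the pan-tumour genes -- is hypermethylated
#' in every tumour, the EYA4/TFPI2/TLX1 motif), per-tumour stochastic
#' background hypermethylation with group-specific heavy-tailed rates (the
#' count continuum), chip batch effects, and intensity-level measurement
#' output consumed by the preprocessing module.
#'
#' Defaults are the study conditions the package is tested under: 40 pairs
#' split 35/15/50\% into CIMP-H/L/N, 2000 genes, a 132-gene core with mean
#' beta effect 0.35, and subtype amplitude multipliers 1 / 0.5 / 0.15 on
#' the non-pan core (the CIMP-N multiplier places those deltas near 0.05,
#' below the 0.1 calling threshold, which is what makes 0.1 the most
#' discriminating threshold in the delta scan).
#'
#' @param n_pairs matched tumour/normal pairs.
#' @param group_proportions named proportions of CIMP-H/L/N tumours
#'   (sum to 1).
#' @param n_genes genes, each with one CpG island.
#' @param island_probes,shore_probes integer ranges (min, max) of island
#'   and shore probes per gene.
#' @param core_set_size planted CIMP-H core genes.
#' @param pan_tumour_size core genes hypermethylated in *every* tumour.
#' @param pan_effect_multiplier amplitude boost of the pan-tumour genes
#'   (recurrent islands tend to show the largest effects; the boost also
#'   anchors the tumour-versus-normal branch split).
#' @param subtype_multipliers named amplitude multipliers applied to the
#'   non-pan core genes in each subtype.
#' @param effect_mean,effect_sd per-gene hypermethylation effect size on
#'   the beta scale.
#' @param background_mean,background_sdlog per-group mean count and
#'   log-scale sd of the log-normal per-tumour background
#'   hypermethylation rate.
#' @param normal_island_mean baseline island beta in normal tissue.
#' @param noise_sd,subject_sd measurement and shared subject-level noise
#'   (logit scale).
#' @param pairs_per_chip matched pairs per chip (both samples of a pair
#'   share a chip).
#' @param batch_shift_sd sd of the per-probe, per-chip additive batch
#'   effect on the beta scale.
#' @param intensity_total nominal total intensity per probe.
#' @param detection_fail_rate fraction of probes with detection failures.
#' @param n_sex_genes filler genes placed on chrX/chrY (exercise the sex
#'   filter; never planted).
#' @param cross_reactive_rate fraction of shelf/open-sea probes flagged
#'   cross-reactive.
#' @param n_negative_controls,n_internal_controls control probe counts.
#' @return a validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_pairs = 40,
                          group_proportions = c("CIMP-H" = 0.35,
                                                "CIMP-L" = 0.15,
                                                "CIMP-N" = 0.50),
                          n_genes = 2000,
                          island_probes = c(12, 18),
                          shore_probes = c(3, 6),
                          core_set_size = 132,
                          pan_tumour_size = 50,
                          pan_effect_multiplier = 1.3,
                          subtype_multipliers = c("CIMP-H" = 1,
                                                  "CIMP-L" = 0.5,
                                                  "CIMP-N" = 0.15),
                          effect_mean = 0.35, effect_sd = 0.05,
                          background_mean = c("CIMP-H" = 120,
                                              "CIMP-L" = 60,
                                              "CIMP-N" = 30),
                          background_sdlog = c("CIMP-H" = 0.5,
                                               "CIMP-L" = 0.5,
                                               "CIMP-N" = 0.7),
                          normal_island_mean = 0.10,
                          noise_sd = 0.10, subject_sd = 0.08,
                          pairs_per_chip = 6,
                          batch_shift_sd = 0.02,
                          intensity_total = 5000,
                          detection_fail_rate = 0.01,
                          n_sex_genes = 40,
                          cross_reactive_rate = 0.01,
                          n_negative_controls = 100,
                          n_internal_controls = 50) {
  cfg <- as.list(environment())
  if (abs(sum(group_proportions) - 1) > 1e-8)
    stop("group proportions must sum to 1")
  if (any(c(background_mean, effect_sd, noise_sd, subject_sd,
            batch_shift_sd) < 0))
    stop("rates and standard deviations must be non-negative")
  beta_cap <- intensity_total * 0.6 / (intensity_total * 0.6 + 100)
  if (normal_island_mean + effect_mean * (1 + 4 * effect_sd) >= beta_cap)
    stop("planted beta exceeds the intensity ceiling T/(T+100); lower the ",
         "effect size or raise intensity_total")
  if (core_set_size + n_sex_genes >= n_genes)
    stop("infeasible: core and sex-filler genes exhaust the gene count")
  if (pan_tumour_size > core_set_size)
    stop("pan-tumour genes must be a subset of the core set")
  structure(cfg, class = "cohort_config")
}

#' Generate a synthetic probe manifest and island table
#'
#' Tiles one CpG island per gene along synthetic autosomes (the last
#' `n_sex_genes` genes go to chrX/chrY), with island probes spaced 100 bp,
#' shore probes within 2 kb of the island edges, two shelf probes in the
#' 2--3 kb band, one open-sea probe beyond, and negative/internal control
#' probes with no genomic annotation. Deterministic given the seed.
#'
#' @param cfg a [cohort_config()].
#' @param seed integer seed.
#' @return list with `manifest` (probe manifest `data.frame`) and
#'   `islands` (island interval `data.frame`).
#' @export
generate_manifest <- function(cfg, seed = 1) {
  stopifnot(inherits(cfg, "cohort_config"))
  set.seed(seed)
  n <- cfg$n_genes
  genes <- sprintf("GENE%04d", seq_len(n))
  chrom <- rep(paste0("chr", 1:18), length.out = n)
  if (cfg$n_sex_genes > 0) {
    sex_idx <- seq.int(n - cfg$n_sex_genes + 1, n)
    chrom[sex_idx] <- rep(c("chrX", "chrY"), length.out = cfg$n_sex_genes)
  }
  idx_on_chr <- stats::ave(seq_len(n), chrom, FUN = seq_along)
  base <- 10000 + (idx_on_chr - 1) * 50000

  draw_range <- function(rng, n) {
    if (rng[1] == rng[2]) rep(rng[1], n)
    else sample(rng[1]:rng[2], n, replace = TRUE)
  }
  n_isl <- draw_range(cfg$island_probes, n)
  n_sho <- draw_range(cfg$shore_probes, n)
  isl_end <- base + (n_isl - 1) * 100

  shore_d <- c(200, 600, 1000, 1400, 1800)
  rows <- vector("list", n)
  for (g in seq_len(n)) {
    ip <- base[g] + (seq_len(n_isl[g]) - 1) * 100
    sd_ <- sample(shore_d, n_sho[g], replace = n_sho[g] > length(shore_d))
    side <- rep_len(c(-1, 1), n_sho[g])
    sp <- ifelse(side < 0, base[g] - sd_, isl_end[g] + sd_)
    shp <- c(base[g] - 2700, isl_end[g] + 2300)
    op <- isl_end[g] + 6000
    pos <- c(ip, sp, shp, op)
    rows[[g]] <- data.frame(
      probe_id = sprintf("cg_%s_%02d", genes[g], seq_along(pos)),
      chromosome = chrom[g],
      position = as.integer(pos),
      island_id = sprintf("ISL_%s", genes[g]),
      region_class = c(rep("island", n_isl[g]), rep("shore", n_sho[g]),
                       rep("shelf", 2), "open_sea"),
      gene_symbols = genes[g],
      feature_context = c(rep("TSS_window", min(3, n_isl[g])),
                          rep("first_exon", max(0, min(2, n_isl[g] - 3))),
                          rep("body", max(0, n_isl[g] - 5)),
                          rep("body", n_sho[g] + 2), "intergenic"),
      stringsAsFactors = FALSE)
  }
  man <- do.call(rbind, rows)
  man$island_id[man$region_class == "open_sea"] <- NA
  man$cross_reactive <- FALSE
  eligible <- which(man$region_class %in% c("shelf", "open_sea"))
  n_xr <- round(cfg$cross_reactive_rate * nrow(man))
  if (n_xr > 0)
    man$cross_reactive[sample(eligible, min(n_xr, length(eligible)))] <- TRUE
  man$is_sex_chromosome <- man$chromosome %in% c("chrX", "chrY")
  man$is_negative_control <- FALSE
  man$is_internal_control <- FALSE

  ctrl <- function(prefix, n_ctrl, internal) {
    if (n_ctrl == 0) return(NULL)
    data.frame(probe_id = sprintf("%s%04d", prefix, seq_len(n_ctrl)),
               chromosome = NA_character_, position = NA_integer_,
               island_id = NA_character_, region_class = NA_character_,
               gene_symbols = "", feature_context = "",
               cross_reactive = FALSE, is_sex_chromosome = FALSE,
               is_negative_control = !internal,
               is_internal_control = internal,
               stringsAsFactors = FALSE)
  }
  man <- rbind(man,
               ctrl("NEG", cfg$n_negative_controls, internal = FALSE),
               ctrl("CTL", cfg$n_internal_controls, internal = TRUE))
  rownames(man) <- NULL

  islands <- data.frame(island_id = sprintf("ISL_%s", genes),
                        chromosome = chrom,
                        start = as.integer(base),
                        end = as.integer(isl_end),
                        gene_symbols = genes,
                        stringsAsFactors = FALSE)
  validate_manifest(man)
  list(manifest = man, islands = islands)
}

# internal: deterministic group sizes from proportions (largest remainder)
.group_sizes <- function(n, prop) {
  raw <- n * prop
  sizes <- floor(raw)
  left <- n - sum(sizes)
  if (left > 0) {
    extra <- order(raw - sizes, decreasing = TRUE)[seq_len(left)]
    sizes[extra] <- sizes[extra] + 1
  }
  stats::setNames(as.integer(sizes), names(prop))
}

# internal: Table-1-like conditional distribution of the marker-panel label
# given the true subtype, used to simulate panel calls
.panel_mix <- list(
  "CIMP-H" = c("CIMP-H" = 27, "CIMP-L" = 4, "CIMP-N" = 1),
  "CIMP-L" = c("CIMP-H" = 1, "CIMP-L" = 1, "CIMP-N" = 11),
  "CIMP-N" = c("CIMP-H" = 7, "CIMP-L" = 7, "CIMP-N" = 30))

#' Generate a synthetic matched tumour/normal cohort
#'
#' Draws probe baselines (low island, high open-sea beta on the logit
#' scale), plants the configured hypermethylation structure additively on
#' the beta scale over each gene's island and shore probes, applies shared
#' subject-level and independent measurement noise on the logit scale,
#' adds per-chip batch effects, and converts beta values to
#' methylated/unmethylated intensities with total intensity T via
#' `M = beta * (T + 100)`, `U = T - M`, so that [compute_beta()] inverts
#' the construction exactly. Detection p-values are near zero except for a
#' configurable rate of failed probes; marker-panel labels for each tumour
#' are drawn from a subtype-conditional misclassification distribution.
#'
#' @param cfg a [cohort_config()].
#' @param manifest output of [generate_manifest()] (list with `manifest`
#'   and `islands`).
#' @param seed integer seed.
#' @return list with `dataset` (an [intensity_dataset()]) and `truth`
#'   (planted core/pan gene sets, per-tumour background genes, subtypes,
#'   per-gene effects, batch assignment).
#' @export
generate_cohort <- function(cfg, manifest, seed = 1) {
  stopifnot(inherits(cfg, "cohort_config"))
  set.seed(seed + 1L)
  man <- manifest$manifest
  analysis <- !man$is_negative_control & !man$is_internal_control
  probes <- man$probe_id
  P <- nrow(man)
  n_pairs <- cfg$n_pairs

  subjects <- sprintf("S%03d", seq_len(n_pairs))
  sizes <- .group_sizes(n_pairs, cfg$group_proportions)
  subtype <- stats::setNames(rep(names(sizes), sizes)[seq_len(n_pairs)],
                             subjects)

  genes <- unique(man$gene_symbols[analysis & nzchar(man$gene_symbols)])
  sex_genes <- unique(man$gene_symbols[analysis & man$is_sex_chromosome])
  eligible <- setdiff(genes, sex_genes)
  core <- sort(sample(eligible, cfg$core_set_size))
  pan <- sort(sample(core, cfg$pan_tumour_size))
  graded <- setdiff(core, pan)
  bg_pool <- setdiff(eligible, core)

  effect <- stats::setNames(
    pmin(pmax(stats::rnorm(length(genes), cfg$effect_mean, cfg$effect_sd),
              0.05), 0.55),
    genes)

  # per-subject shift over genes (beta scale)
  G <- matrix(0, length(genes), n_pairs, dimnames = list(genes, subjects))
  background <- vector("list", n_pairs)
  names(background) <- subjects
  for (s in subjects) {
    st <- subtype[s]
    G[pan, s] <- effect[pan] * cfg$pan_effect_multiplier
    G[graded, s] <- effect[graded] * cfg$subtype_multipliers[st]
    mu <- log(cfg$background_mean[st]) - cfg$background_sdlog[st]^2 / 2
    n_bg <- min(round(stats::rlnorm(1, mu, cfg$background_sdlog[st])),
                length(bg_pool))
    bg <- sample(bg_pool, n_bg)
    G[bg, s] <- effect[bg]
    background[[s]] <- sort(bg)
  }

  # probe baselines on logit scale
  class_mean <- c(island = cfg$normal_island_mean, shore = 0.15,
                  shelf = 0.35, open_sea = 0.70)
  base_beta <- rep(0.5, P)
  base_beta[analysis] <- class_mean[man$region_class[analysis]]
  gene_eff <- stats::setNames(stats::rnorm(length(genes), 0, 0.25), genes)
  lg <- stats::qlogis(base_beta)
  lg[analysis] <- lg[analysis] + gene_eff[man$gene_symbols[analysis]] +
    stats::rnorm(sum(analysis), 0, 0.25)

  # shifts act on the gene's island and shore probes only
  probe_gene <- ifelse(analysis & man$region_class %in% c("island", "shore"),
                       man$gene_symbols, NA)
  shift <- matrix(0, P, n_pairs)
  has_gene <- !is.na(probe_gene)
  shift[has_gene, ] <- G[probe_gene[has_gene], ]

  # pairs share a chip; chip membership is randomised so that chips are
  # not confounded with the subtype strata (as in a real scan order)
  chips <- sample(rep(sprintf("chip%02d",
                              seq_len(ceiling(n_pairs / cfg$pairs_per_chip))),
                      each = cfg$pairs_per_chip)[seq_len(n_pairs)])
  gamma <- matrix(stats::rnorm(P * length(unique(chips)), 0,
                               cfg$batch_shift_sd),
                  P, length(unique(chips)),
                  dimnames = list(NULL, unique(chips)))

  subj_wobble <- matrix(stats::rnorm(P * n_pairs, 0, cfg$subject_sd), P, n_pairs)
  clamp <- function(x) pmin(pmax(x, 0.002), 0.95)
  noise <- function() matrix(stats::rnorm(P * n_pairs, 0, cfg$noise_sd),
                             P, n_pairs)
  base_ps <- lg + subj_wobble
  beta_n <- clamp(stats::plogis(base_ps + noise()))
  beta_t <- clamp(stats::plogis(stats::qlogis(
    clamp(stats::plogis(base_ps) + shift)) + noise()))
  beta_n <- clamp(beta_n + gamma[, chips])
  beta_t <- clamp(beta_t + gamma[, chips])

  # intensities: controls get fixed characteristic levels
  samp_scale <- exp(stats::rnorm(2 * n_pairs, 0, 0.1))
  probe_scale <- exp(pmin(pmax(stats::rnorm(P, 0, 0.15), -0.35), 0.35))
  beta <- cbind(beta_t, beta_n)
  Tmat <- outer(probe_scale * cfg$intensity_total, samp_scale)
  ctrl_int <- man$is_internal_control
  ctrl_neg <- man$is_negative_control
  beta[ctrl_int | ctrl_neg, ] <- 0.5
  Tmat[ctrl_int, ] <- outer(rep(2 * cfg$intensity_total, sum(ctrl_int)),
                            samp_scale)
  Tmat[ctrl_neg, ] <- outer(rep(0.01 * cfg$intensity_total, sum(ctrl_neg)),
                            samp_scale)
  M <- beta * (Tmat + 100)
  U <- Tmat - M
  U[U < 0] <- 0

  sample_ids <- c(paste0(subjects, "_T"), paste0(subjects, "_N"))
  dimnames(M) <- dimnames(U) <- list(probes, sample_ids)

  detp <- matrix(stats::runif(P * 2 * n_pairs, 0, 0.01), P, 2 * n_pairs,
                 dimnames = list(probes, sample_ids))
  n_fail <- round(cfg$detection_fail_rate * sum(analysis))
  if (n_fail > 0) {
    fail_probes <- sample(which(analysis), n_fail)
    for (fp in fail_probes) {
      cols <- sample(2 * n_pairs, sample(1:2, 1))
      detp[fp, cols] <- stats::runif(length(cols), 0.06, 0.5)
    }
  }
  detp[ctrl_neg, ] <- stats::runif(sum(ctrl_neg) * 2 * n_pairs, 0.3, 1)

  panel_label <- vapply(subjects, function(s) {
    w <- .panel_mix[[subtype[s]]]
    sample(names(w), 1, prob = w)
  }, character(1))
  n_mark <- vapply(panel_label, function(pl)
    switch(pl, "CIMP-H" = sample(4:5, 1), "CIMP-L" = sample(1:3, 1), 0L),
    numeric(1))
  marker_names <- c("CACNA1G", "NEUROG1", "RUNX3", "SOCS1", "IGF2")
  flags <- t(vapply(n_mark, function(k) {
    f <- rep(FALSE, 5); f[sample(5, k)] <- TRUE; f
  }, logical(5)))
  colnames(flags) <- paste0("marker_", marker_names)

  sheet <- data.frame(
    sample_id = sample_ids,
    subject_id = rep(subjects, 2),
    tissue = rep(c("tumour", "normal"), each = n_pairs),
    batch = rep(chips, 2),
    stringsAsFactors = FALSE)
  tum_rows <- match(paste0(subjects, "_T"), sheet$sample_id)
  sheet$panel_cimp <- NA_character_
  sheet$panel_cimp[tum_rows] <- panel_label
  for (mn in colnames(flags)) {
    sheet[[mn]] <- NA
    sheet[[mn]][tum_rows] <- flags[, mn]
  }

  ds <- intensity_dataset(M, U, detp, sheet)
  truth <- list(core_genes = core, pan_tumour_genes = pan,
                graded_core_genes = graded,
                subtype = subtype, background = background,
                effects = effect, batch = stats::setNames(rep(chips, 2),
                                                          sample_ids),
                seed = seed)
  list(dataset = ds, truth = truth)
}

#' Write a synthetic cohort to plain-text files
#'
#' Emits the interchange files the preprocessing module consumes: `M.tsv`,
#' `U.tsv`, `detection_p.tsv`, `samples.csv`, `manifest.tsv`,
#' `islands.tsv` and `truth.json`.
#'
#' @param cohort output of [generate_cohort()].
#' @param manifest output of [generate_manifest()].
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_cohort <- function(cohort, manifest, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ds <- cohort$dataset
  write_matrix_tsv(ds$M, file.path(dir, "M.tsv"))
  write_matrix_tsv(ds$U, file.path(dir, "U.tsv"))
  write_matrix_tsv(ds$detection_p, file.path(dir, "detection_p.tsv"))
  utils::write.csv(ds$sample_sheet, file.path(dir, "samples.csv"),
                   row.names = FALSE)
  write_manifest(manifest$manifest, file.path(dir, "manifest.tsv"))
  write_islands(manifest$islands, file.path(dir, "islands.tsv"))
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
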