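# Small hand-built fixtures shared across test files.

# a toy manifest: 3 genes with island/shore/shelf/open-sea probes, one
# probe annotated to two genes, plus controls and blacklist cases
toy_manifest <- function() {
  data.frame(
    probe_id = sprintf("p%02d", 1:16),
    chromosome = c(rep("chr1", 10), rep("chr2", 3), "chrX", NA, NA),
    position = c(450, 500, 550, 900, 2100, 4000, 8000, 450, 520, 1200,
                 100, 150, 300, 500, NA, NA),
    island_id = c(rep("I1", 6), NA, rep("I2", 3), rep("I3", 3), "I4", NA, NA),
    region_class = c("island", "island", "island", "shore", "shelf",
                     "open_sea", "open_sea", "island", "island", "shore",
                     "island", "island", "shore", "island", NA, NA),
    gene_symbols = c(rep("GA", 6), "", "GB;GA", "GB", "GB",
                     "GC", "GC", "GC", "GX", "", ""),
    feature_context = c("TSS_window", "TSS_window;first_exon", "body",
                        "body", "body", "intergenic", "intergenic",
                        "TSS_window", "body", "body",
                        "TSS_window", "body", "body", "TSS_window", "", ""),
    cross_reactive = c(rep(FALSE, 12), TRUE, FALSE, FALSE, FALSE),
    is_sex_chromosome = c(rep(FALSE, 13), TRUE, FALSE, FALSE),
    is_negative_control = c(rep(FALSE, 14), TRUE, FALSE),
    is_internal_control = c(rep(FALSE, 15), TRUE),
    stringsAsFactors = FALSE)
}

# a minimal intensity dataset over the toy manifest: 2 subjects
toy_dataset <- function(detp_override = NULL) {
  man <- toy_manifest()
  probes <- man$probe_id
  samples <- c("S1_T", "S1_N", "S2_T", "S2_N")
  set.seed(7)
  Tot <- 4000
  beta <- matrix(runif(length(probes) * 4, 0.05, 0.6),
                 length(probes), 4, dimnames = list(probes, samples))
  M <- beta * (Tot + 100)
  U <- Tot - M
  detp <- matrix(0.001, length(probes), 4, dimnames = list(probes, samples))
  if (!is.null(detp_override))
    detp[rownames(detp_override), colnames(detp_override)] <- detp_override
  sheet <- data.frame(sample_id = samples,
                      subject_id = rep(c("S1", "S2"), each = 2),
                      tissue = rep(c("tumour", "normal"), 2),
                      batch = "chip01", stringsAsFactors = FALSE)
  intensity_dataset(M, U, detp, sheet)
}

# default synthetic cohort + full pipeline run, computed once per session
.cohort_cache <- new.env(parent = emptyenv())
default_cohort_run <- function() {
  if (!exists("run", envir = .cohort_cache)) {
    cfg <- cohort_config()
    mf <- generate_manifest(cfg, seed = 101)
    co <- generate_cohort(cfg, mf, seed = 101)
    res <- suppressMessages(run_pipeline(co$dataset, mf, pipeline_config()))
    assign("run", list(cfg = cfg, manifest = mf, cohort = co, result = res),
           envir = .cohort_cache)
  }
  get("run", envir = .cohort_cache)
}

# a small, fast cohort for smoke tests
small_cohort <- function(seed = 5) {
  cfg <- cohort_config(n_pairs = 12, n_genes = 300, core_set_size = 30,
                       pan_tumour_size = 12,
                       background_mean = c("CIMP-H" = 20, "CIMP-L" = 10,
                                           "CIMP-N" = 6),
                       n_sex_genes = 10, n_negative_controls = 20,
                       n_internal_controls = 10, pairs_per_chip = 6)
  mf <- generate_manifest(cfg, seed = seed)
  co <- generate_cohort(cfg, mf, seed = seed)
  list(cfg = cfg, manifest = mf, cohort = co)
}
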