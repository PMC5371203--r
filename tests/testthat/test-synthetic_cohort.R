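test_that("cohort configuration validates its invariants", {
  expect_s3_class(cohort_config(), "cohort_config")
  expect_error(cohort_config(group_proportions = c("CIMP-H" = 0.5,
                                                   "CIMP-L" = 0.4,
                                                   "CIMP-N" = 0.4)),
               "sum to 1")
  expect_error(cohort_config(effect_mean = 0.9, intensity_total = 300),
               "ceiling")
  expect_error(cohort_config(pan_tumour_size = 200, core_set_size = 132),
               "subset")
  expect_error(cohort_config(noise_sd = -1), "non-negative")
})

test_that("generated manifests obey the probe-geometry invariants", {
  cfg <- cohort_config(n_genes = 40, island_probes = c(8, 8),
                       shore_probes = c(3, 3), n_sex_genes = 4,
                       core_set_size = 8, pan_tumour_size = 4,
                       n_negative_controls = 10, n_internal_controls = 5)
  mf <- generate_manifest(cfg, seed = 3)
  man <- mf$manifest
  expect_silent(validate_manifest(man))
  expect_equal(sum(man$region_class == "island", na.rm = TRUE), 40 * 8)
  expect_equal(sum(man$region_class == "shore", na.rm = TRUE), 40 * 3)
  # every probe's recorded class matches classify_region on its chromosome
  ana <- man[!man$is_negative_control & !man$is_internal_control, ]
  for (i in sample(nrow(ana), 60)) {
    isl <- mf$islands[mf$islands$chromosome == ana$chromosome[i], ]
    expect_identical(classify_region(ana$position[i], isl),
                     ana$region_class[i])
  }
  # sex-filler genes live on chrX/chrY; controls carry no annotation
  expect_true(all(man$chromosome[man$is_sex_chromosome] %in%
                    c("chrX", "chrY")))
  expect_true(all(is.na(man$region_class[man$is_negative_control |
                                           man$is_internal_control])))
})

test_that("manifest and cohort generation are deterministic under the seed", {
  cfg <- cohort_config(n_pairs = 4, n_genes = 30, core_set_size = 6,
                       pan_tumour_size = 3, n_sex_genes = 2,
                       background_mean = c("CIMP-H" = 4, "CIMP-L" = 2,
                                           "CIMP-N" = 1),
                       n_negative_controls = 5, n_internal_controls = 3)
  mf1 <- generate_manifest(cfg, seed = 9)
  mf2 <- generate_manifest(cfg, seed = 9)
  expect_identical(mf1, mf2)
  co1 <- generate_cohort(cfg, mf1, seed = 9)
  co2 <- generate_cohort(cfg, mf1, seed = 9)
  expect_identical(co1$dataset$M, co2$dataset$M)
  expect_identical(co1$truth, co2$truth)
  mf3 <- generate_manifest(cfg, seed = 10)
  expect_false(identical(mf1$manifest, mf3$manifest))
})

test_that("a null configuration yields tumours identical to their normals", {
  cfg <- cohort_config(n_pairs = 4, n_genes = 30, core_set_size = 6,
                       pan_tumour_size = 3, effect_mean = 0, effect_sd = 0,
                       subtype_multipliers = c("CIMP-H" = 0, "CIMP-L" = 0,
                                               "CIMP-N" = 0),
                       pan_effect_multiplier = 0,
                       background_mean = c("CIMP-H" = 0.01,
                                           "CIMP-L" = 0.01,
                                           "CIMP-N" = 0.01),
                       background_sdlog = c("CIMP-H" = 0, "CIMP-L" = 0,
                                            "CIMP-N" = 0),
                       noise_sd = 0, batch_shift_sd = 0, n_sex_genes = 2,
                       n_negative_controls = 5, n_internal_controls = 3)
  mf <- generate_manifest(cfg, seed = 2)
  co <- generate_cohort(cfg, mf, seed = 2)
  man <- mf$manifest
  ana <- man$probe_id[!man$is_negative_control & !man$is_internal_control]
  beta <- compute_beta(co$dataset$M, co$dataset$U)[ana, ]
  tum <- beta[, grep("_T$", colnames(beta))]
  nor <- beta[, sub("_T$", "_N", colnames(tum))]
  expect_equal(unname(tum), unname(nor), tolerance = 1e-9)
})

test_that("planted structure is present in the generated betas", {
  sc <- small_cohort()
  co <- sc$cohort; mf <- sc$manifest
  beta <- compute_beta(co$dataset$M, co$dataset$U)
  expect_true(all(beta >= 0 & beta < 1))
  gmap <- build_gene_island_map(mf$manifest, 3)
  truth <- co$truth
  H <- names(truth$subtype)[truth$subtype == "CIMP-H"]
  # every core gene exceeds delta 0.1 in every CIMP-H tumour
  for (g in truth$core_genes) {
    p <- gmap$map[[g]]
    d <- colMeans(beta[p, paste0(H, "_T"), drop = FALSE] -
                    beta[p, paste0(H, "_N"), drop = FALSE])
    expect_true(all(d > 0.1))
  }
  # pan-tumour genes are shifted in CIMP-N tumours too
  N <- names(truth$subtype)[truth$subtype == "CIMP-N"]
  for (g in truth$pan_tumour_genes[1:3]) {
    p <- gmap$map[[g]]
    d <- colMeans(beta[p, paste0(N, "_T"), drop = FALSE] -
                    beta[p, paste0(N, "_N"), drop = FALSE])
    expect_true(all(d > 0.1))
  }
  # core genes avoid the sex chromosomes
  sex_genes <- unique(mf$manifest$gene_symbols[mf$manifest$is_sex_chromosome])
  expect_length(intersect(truth$core_genes, sex_genes), 0)
  # matched pairs share a chip
  sheet <- co$dataset$sample_sheet
  for (s in unique(sheet$subject_id))
    expect_length(unique(sheet$batch[sheet$subject_id == s]), 1)
})

test_that("cohorts round-trip through the plain-text interchange files", {
  cfg <- cohort_config(n_pairs = 3, n_genes = 20, core_set_size = 4,
                       pan_tumour_size = 2, n_sex_genes = 2,
                       background_mean = c("CIMP-H" = 3, "CIMP-L" = 2,
                                           "CIMP-N" = 1),
                       n_negative_controls = 4, n_internal_controls = 3)
  mf <- generate_manifest(cfg, seed = 4)
  co <- generate_cohort(cfg, mf, seed = 4)
  dir <- withr::local_tempdir()
  write_cohort(co, mf, dir)
  expect_true(all(file.exists(file.path(dir,
    c("M.tsv", "U.tsv", "detection_p.tsv", "samples.csv", "manifest.tsv",
      "islands.tsv", "truth.json")))))
  M2 <- read_matrix_tsv(file.path(dir, "M.tsv"))
  expect_equal(M2, co$dataset$M, tolerance = 1e-6)
  man2 <- read_manifest(file.path(dir, "manifest.tsv"))
  expect_equal(man2$probe_id, mf$manifest$probe_id)
  truth2 <- jsonlite::read_json(file.path(dir, "truth.json"),
                                simplifyVector = TRUE)
  expect_equal(sort(truth2$core_genes), sort(co$truth$core_genes))
})
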