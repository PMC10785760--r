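test_that("cohort generation matches the configured factory structure", {
  cfg <- sim_config(seed = 1)
  subjects <- generate_cohort(cfg)
  expect_equal(nrow(subjects), 137)
  expect_equal(sum(subjects$factory == "A"), 76)
  expect_equal(sum(subjects$factory == "B"), 61)
  expect_false(anyDuplicated(subjects$subject_id) > 0)
  expect_true(all(subjects$lag_years[subjects$factory == "B"] == 0))
  expect_true(all(subjects$lag_years[subjects$factory == "A"] > 0))
  expect_true(all(subjects$age > 0) && all(subjects$bmi > 0) &&
                all(subjects$alcohol >= 0))
  # empty cohort is allowed
  empty <- generate_cohort(sim_config(seed = 1, n_A = 0, n_B = 0))
  expect_equal(nrow(empty), 0)
  expect_error(sim_config(n_A = -1), "nonnegative")
})

test_that("factory-specific age distributions hold at large n", {
  big <- generate_cohort(sim_config(seed = 2, n_A = 4000, n_B = 4000))
  expect_equal(mean(big$age[big$factory == "A"]), 69.0, tolerance = 0.01)
  expect_equal(mean(big$age[big$factory == "B"]), 58.8, tolerance = 0.01)
})

test_that("targeted panel has 29 congeners in subclasses 7/10/12", {
  cfg <- sim_config(seed = 3)
  subjects <- generate_cohort(cfg)
  panel <- generate_targeted_exposures(subjects, cfg)
  expect_equal(ncol(panel$concentrations), 29)
  expect_equal(as.vector(table(panel$subclass)[c("PCDD", "PCDF", "PCB")]),
               c(7L, 10L, 12L))
  expect_true(all(panel$concentrations > 0))
  # TCDD stochastically larger in factory A
  tcdd <- panel$concentrations[, "TCDD"]
  expect_gt(median(tcdd[subjects$factory == "A"]),
            5 * median(tcdd[subjects$factory == "B"]))
  # all LODs zero -> nothing flagged
  p0 <- generate_targeted_exposures(subjects, sim_config(seed = 3, lod_quantile = 0))
  expect_equal(sum(p0$below_lod), 0)
})

test_that("within-subclass copula correlation is realized in rank correlations", {
  cfg <- sim_config(seed = 4, exposure_rho = c(PCDD = 0.5, PCDF = 0.25, PCB = 0.95))
  subjects <- generate_cohort(cfg)
  panel <- generate_targeted_exposures(subjects, cfg)
  pcb <- panel$concentrations[, panel$subclass == "PCB"]
  rs <- cor(pcb, method = "spearman")
  expect_gt(min(rs[upper.tri(rs)]), 0.9)
})

test_that("planted chlorinated compounds carry the binomial envelope", {
  cfg <- sim_config(seed = 5, chem_noise_sd = 0, n_chem_features = 200,
                    n_chlorinated = 20, n_correlated = 10)
  subjects <- generate_cohort(cfg)
  panel <- generate_targeted_exposures(subjects, cfg)
  chem <- generate_chem_features(subjects, panel, cfg)
  truth <- chem$truth$compounds
  four_cl <- truth[truth$n_cl == 4, ]
  skip_if(nrow(four_cl) == 0, "no 4-Cl compound drawn under this seed")
  ids <- four_cl$feature_ids[[1]]
  idx <- match(ids, chem$table$meta$feature_id)
  # noise-free M+2/M intensity ratio = 4 * p37/p35
  ratio <- chem$table$intensities[idx[2], ] / chem$table$intensities[idx[1], ]
  expect_equal(unname(ratio[1]), 4 * 0.2423 / 0.7577, tolerance = 1e-10)
  expect_equal(unname(ratio[1]), 1.279, tolerance = 1e-3)
  # decoys are one monoisotopic-like pair with 13C spacing, no Cl envelope
  dec <- truth[truth$n_cl == 0, ]
  dmz <- diff(chem$table$meta$mz[match(dec$feature_ids[[1]],
                                       chem$table$meta$feature_id)])
  expect_equal(dmz, 1.00335, tolerance = 2e-3)
})

test_that("planted compound-congener correlation is realized", {
  rs <- vapply(1:5, function(s) {
    cfg <- sim_config(seed = s, n_chem_features = 60, n_chlorinated = 6,
                      n_correlated = 6)
    subjects <- generate_cohort(cfg)
    panel <- generate_targeted_exposures(subjects, cfg)
    chem <- generate_chem_features(subjects, panel, cfg)
    rel <- chem$truth$related
    mono <- vapply(rel$compound_id, function(cid) {
      ids <- chem$truth$compounds$feature_ids[[
        which(chem$truth$compounds$compound_id == cid)]]
      chem$table$intensities[match(ids[1], chem$table$meta$feature_id), ]
    }, numeric(nrow(subjects)))
    mean(vapply(seq_len(nrow(rel)), function(i) {
      cor(mono[, i], panel$concentrations[, rel$congener[i]],
          method = "spearman")
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(rs > 0.65 & rs < 0.9))
})

test_that("metabolome m/z are in range and planted features sit at adduct masses", {
  cfg <- sim_config(seed = 6, n_metab_features = 300)
  subjects <- generate_cohort(cfg)
  panel <- generate_targeted_exposures(subjects, cfg)
  metab <- generate_metabolome(subjects, panel, cfg)
  for (ft in list(metab$c18neg, metab$hilicpos)) {
    expect_true(all(ft$meta$mz >= 85 & ft$meta$mz <= 1275))
    expect_equal(n_replicates(ft), cfg$replicates)
  }
  # planted C18neg features at M - proton within 5 ppm
  eff <- metab$truth$effects
  c18 <- eff[eff$mode == "C18neg", ]
  masses <- metab$db$mass[match(c18$metabolite_id, metab$db$metabolite_id)]
  mzs <- metab$c18neg$meta$mz[match(c18$feature_id, metab$c18neg$meta$feature_id)]
  ppm <- abs(mzs - (masses - 1.00728)) / (masses - 1.00728) * 1e6
  expect_true(all(ppm <= 5))
  # positive-mode features at M + proton
  hil <- eff[eff$mode == "HILICpos", ]
  masses <- metab$db$mass[match(hil$metabolite_id, metab$db$metabolite_id)]
  mzs <- metab$hilicpos$meta$mz[match(hil$feature_id, metab$hilicpos$meta$feature_id)]
  expect_true(all(abs(mzs - (masses + 1.00728)) / masses * 1e6 <= 5))
  # left-censoring removes the configured fraction of subject values
  det <- rowMeans(!is.na(subject_matrix(metab$c18neg)))
  expect_true(all(abs(det - (1 - cfg$missing_rate)) < 0.02))
})

test_that("immune markers have 21/23/7/3 categories and planted loadings", {
  cfg <- sim_config(seed = 7)
  subjects <- generate_cohort(cfg)
  panel <- generate_targeted_exposures(subjects, cfg)
  imm <- generate_immune_markers(subjects, panel, cfg)
  expect_equal(ncol(imm$markers), 54)
  expect_equal(as.vector(table(imm$categories)[c("cytokine", "hematologic",
                                                 "humoral", "lymphoma")]),
               c(21L, 23L, 7L, 3L))
  # loaded markers correlate with their driver's ln concentration
  loads <- imm$truth$marker_loadings
  r <- vapply(seq_len(nrow(loads)), function(i) {
    cor(imm$markers[, loads$marker_id[i]],
        log(panel$concentrations[, loads$driver[i]]))
  }, numeric(1))
  expect_true(all(r > 0.3))
  # zero loading -> no systematic association
  cfg0 <- sim_config(seed = 7, marker_loading = 0)
  imm0 <- generate_immune_markers(subjects, panel, cfg0)
  r0 <- vapply(seq_len(nrow(loads)), function(i) {
    cor(imm0$markers[, loads$marker_id[i]],
        log(panel$concentrations[, loads$driver[i]]))
  }, numeric(1))
  expect_lt(max(abs(r0)), 0.35)
  expect_lt(abs(mean(r0)), 0.1)
})

test_that("the generator is deterministic and its ground truth is closed", {
  cfg <- sim_config(seed = 8, n_chem_features = 150, n_chlorinated = 15,
                    n_correlated = 10, n_metab_features = 200)
  a <- simulate_cohort_data(cfg)
  b <- simulate_cohort_data(cfg)
  expect_identical(a, b)
  # every planted id exists in exactly one generated table
  feat_ids <- unlist(a$truth$compounds$feature_ids)
  expect_true(all(feat_ids %in% a$chem$meta$feature_id))
  expect_false(anyDuplicated(feat_ids) > 0)
  expect_true(all(a$truth$compounds$n_cl %in% 0:10))
  expect_true(all(a$truth$related$congener %in% congener_panel()$congener))
  eff <- a$truth$effects
  expect_true(all(eff$feature_id[eff$mode == "C18neg"] %in% a$c18neg$meta$feature_id))
  expect_true(all(eff$feature_id[eff$mode == "HILICpos"] %in% a$hilicpos$meta$feature_id))
  expect_true(all(eff$metabolite_id %in% a$pathway_db$metabolite_id))
  expect_true(all(a$truth$enriched$pathway_id %in% a$pathway_db$pathway_id))
  expect_true(all(a$truth$marker_loadings$marker_id %in% colnames(a$immune$markers)))
})

test_that("planted effects converge to configured values at large n", {
  cfg <- sim_config(seed = 9, n_A = 1000, n_B = 1000, n_metab_features = 40,
                    n_pathways = 6, n_enriched_per_subclass = 1,
                    detected_per_enriched = 4, detected_per_null = 2,
                    missing_rate = 0)
  subjects <- generate_cohort(cfg)
  panel <- generate_targeted_exposures(subjects, cfg)
  metab <- generate_metabolome(subjects, panel, cfg)
  eff <- metab$truth$effects
  eff <- eff[!is.na(eff$driver) & eff$mode == "C18neg", ]
  Y <- log(subject_matrix(metab$c18neg))
  betas <- vapply(seq_len(nrow(eff)), function(i) {
    x <- log(panel$concentrations[, eff$driver[i]])
    y <- Y[eff$feature_id[i], ]
    ok <- !is.na(y)
    unname(coef(lm(y[ok] ~ x[ok] + subjects$age[ok] + subjects$bmi[ok]))[2])
  }, numeric(1))
  expect_equal(mean(betas), cfg$beta, tolerance = 0.05)
})

test_that("synthetic tables round-trip to disk as TSV/JSON/YAML", {
  dir <- tempfile("simdata")
  sim <- simulate_cohort_data(sim_config(seed = 10, n_chem_features = 60,
                                         n_chlorinated = 6, n_correlated = 4,
                                         n_metab_features = 80))
  paths <- write_sim_data(sim, dir)
  expect_true(all(file.exists(paths)))
  subj <- read.delim(file.path(dir, "subjects.tsv"))
  expect_equal(nrow(subj), nrow(sim$subjects))
  cfg_back <- yaml::read_yaml(file.path(dir, "sim_config.yaml"))
  expect_equal(cfg_back$seed, 10)
  truth <- jsonlite::read_json(file.path(dir, "ground_truth.json"))
  expect_true("compounds" %in% names(truth))
  unlink(dir, recursive = TRUE)
})
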