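test_that("theoretical chlorine envelopes follow the binomial law", {
  # no chlorine: monoisotopic peak only
  e0 <- theoretical_cl_envelope(0)
  expect_equal(e0$k, 0)
  expect_equal(e0$abundance, 1)
  # one chlorine: M+2/M = p37/p35
  e1 <- theoretical_cl_envelope(1)
  expect_equal(e1$abundance[e1$k == 1], 0.2423 / 0.7577, tolerance = 1e-12)
  expect_equal(e1$abundance[e1$k == 1], 0.3198, tolerance = 1e-4)
  # two chlorines
  e2 <- theoretical_cl_envelope(2)
  expect_equal(e2$abundance[e2$k == 1], 2 * 0.2423 / 0.7577, tolerance = 1e-12)
  expect_equal(e2$abundance[e2$k == 2], (0.2423 / 0.7577)^2, tolerance = 1e-12)
  expect_equal(e2$abundance[e2$k == 1], 0.6396, tolerance = 1e-4)
  expect_equal(e2$abundance[e2$k == 2], 0.1023, tolerance = 5e-4)
  # TCDD-like 4 chlorines
  e4 <- theoretical_cl_envelope(4)
  expect_equal(e4$abundance[e4$k == 1], 1.279, tolerance = 1e-3)
  expect_equal(e4$abundance[e4$k == 2], 0.613, tolerance = 1e-3)
  expect_error(theoretical_cl_envelope(-1), "nonnegative")
  expect_error(theoretical_cl_envelope(11), "at most 10")
})

test_that("unnormalized envelope probabilities sum to one up to truncation", {
  for (n in 0:10) {
    s <- sum(theoretical_cl_envelope(n, k_max = 10)$prob)
    if (n <= 4) {
      s4 <- sum(theoretical_cl_envelope(n)$prob)
      expect_equal(s4, 1, tolerance = 1e-12)
    } else {
      expect_lte(sum(theoretical_cl_envelope(n)$prob), 1)
    }
    expect_equal(s, 1, tolerance = 1e-12)
  }
})

test_that("the detector recovers every chlorine count from its exact envelope", {
  consts <- isotope_constants()
  for (n in 1:10) {
    env <- theoretical_cl_envelope(n)
    cl <- make_cluster(300 + env$k * consts$dm_cl, env$abundance)
    det <- detect_chlorine_envelopes(cl, consts)
    expect_false(is.null(det))
    expect_equal(det$n_cl, n)
    expect_equal(det$mono_mz, 300)
  }
})

test_that("non-chlorine spacings and single peaks are rejected", {
  consts <- isotope_constants()
  # single peak: no envelope possible
  expect_null(detect_chlorine_envelopes(make_cluster(300, 1), consts))
  # 13C spacing (1.00335) does not match the Cl spacing at 5 mDa
  expect_null(detect_chlorine_envelopes(
    make_cluster(c(300, 301.00335), c(1, 0.3)), consts))
  # two peaks two 13C units apart (2.0067) miss the 1.99705 window too
  expect_null(detect_chlorine_envelopes(
    make_cluster(c(300, 302.0067), c(1, 0.3)), consts))
  # intensity ratio far off every theoretical envelope is rejected
  expect_null(detect_chlorine_envelopes(
    make_cluster(c(300, 300 + consts$dm_cl), c(1, 8)), consts))
})

test_that("noisy envelopes are detected with high sensitivity, decoys are not", {
  consts <- isotope_constants()
  set.seed(101)
  hits <- 0L; n_spectra <- 100L
  for (i in seq_len(n_spectra)) {
    n <- sample(1:10, 1)
    env <- theoretical_cl_envelope(n)
    noisy <- env$abundance * exp(rnorm(nrow(env), 0, 0.05))
    det <- detect_chlorine_envelopes(
      make_cluster(300 + env$k * consts$dm_cl, noisy), consts)
    if (!is.null(det)) hits <- hits + 1L
  }
  expect_gte(hits / n_spectra, 0.90)
  fp <- 0L
  for (i in seq_len(n_spectra)) {
    det <- detect_chlorine_envelopes(
      make_cluster(c(300, 301.00335), c(1, runif(1, 0.1, 0.5))), consts)
    if (!is.null(det)) fp <- fp + 1L
  }
  expect_lte(fp / n_spectra, 0.02)
})

test_that("co-varying co-eluting features cluster together, distant ones apart", {
  set.seed(7)
  z <- rnorm(20)
  meta <- data.frame(feature_id = c("a", "b", "c"),
                     mz = c(200, 201.997, 400), rt = c(100, 100, 160))
  X <- exp(rbind(z + 10, z + 9, rnorm(20) + 10))
  samp <- data.frame(sample_id = sprintf("S%02d", 1:20),
                     subject_id = sprintf("S%02d", 1:20),
                     replicate = 1L, batch = "b1")
  ft <- feature_table(meta, X, samp, mode = "GC")
  cl <- cluster_spectra(ft)
  lab <- setNames(rep(NA_integer_, 3), c("a", "b", "c"))
  for (i in seq_along(cl)) lab[cl[[i]]$feature_ids] <- i
  expect_equal(lab[["a"]], lab[["b"]])   # identical profile, identical RT
  expect_false(lab[["a"]] == lab[["c"]]) # unrelated profile, 60 s apart
  # perfectly correlated but far apart in RT -> separate clusters
  meta2 <- meta[1:2, ]; meta2$rt <- c(100, 160)
  ft2 <- feature_table(meta2, X[1:2, ], samp, mode = "GC")
  cl2 <- cluster_spectra(ft2)
  expect_length(cl2, 2)
})

test_that("clustering is invariant to feature input order", {
  sim <- simulate_cohort_data(sim_config(seed = 5, n_chem_features = 120,
                                         n_chlorinated = 12, n_correlated = 8))
  ft <- sim$chem
  perm <- sample(nrow(ft$meta))
  ft2 <- feature_table(ft$meta[perm, ], ft$intensities[perm, ], ft$samples, "GC")
  key <- function(cls) {
    sets <- lapply(cls, function(x) sort(x$feature_ids))
    sets[order(vapply(sets, `[`, character(1), 1))]
  }
  expect_equal(key(cluster_spectra(ft)), key(cluster_spectra(ft2)))
})

test_that("suspect screening recovers planted chlorinated compounds", {
  sim <- simulate_cohort_data(sim_config(seed = 9))
  clusters <- cluster_spectra(sim$chem)
  # planted groups recovered intact
  truth <- sim$truth$compounds
  chl <- truth[truth$n_cl > 0, ]
  cluster_sets <- lapply(clusters, function(x) sort(x$feature_ids))
  intact <- vapply(chl$feature_ids, function(ids) {
    any(vapply(cluster_sets, identical, logical(1), sort(ids)))
  }, logical(1))
  expect_gte(mean(intact), 0.95)
  sus <- suspect_list(clusters)
  expect_false(anyDuplicated(sus$table$cluster_id) > 0)
  # sensitivity on planted compounds and false positives on decoys
  feat2cmp <- rep(truth$compound_id, lengths(truth$feature_ids))
  names(feat2cmp) <- unlist(truth$feature_ids)
  det_cmp <- unique(unlist(lapply(clusters[match(sus$table$cluster_id,
                                  vapply(clusters, `[[`, character(1), "cluster_id"))],
                                  function(x) feat2cmp[x$feature_ids])))
  sens <- mean(chl$compound_id %in% det_cmp)
  fpr <- mean(truth$compound_id[truth$n_cl == 0] %in% det_cmp)
  expect_gte(sens, 0.90)
  expect_lte(fpr, 0.02)
  # fitted chlorine counts mostly match the planted ones
  hit <- sus$table$cluster_id[sus$table$n_cl > 0]
  expect_gt(length(hit), 0)
})

test_that("an empty cluster list yields an empty suspect table", {
  out <- suspect_list(list())
  expect_equal(nrow(out$table), 0)
  expect_null(out$abundance)
})
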