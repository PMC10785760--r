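#' Simulation configuration for the synthetic occupational cohort
#'
#' Builds the configuration object consumed by the generator functions. The
#' defaults emulate the structure of a two-factory occupational cohort:
#' factory A carries a historical high-TCDD exposure (back-extrapolatable via
#' a lag period), factory B a background-level exposure; congener
#' concentrations are log-normal with within-subclass correlation; a subset of
#' untargeted GC-HRMS compounds is chlorinated (binomial 35Cl/37Cl envelopes)
#' and correlated with targeted congeners; metabolome features carry planted
#' linear exposure effects concentrated in designated pathways; and immune
#' markers load on latent factors shared with those pathway signals.
#'
#' @param seed integer seed; all generator randomness derives from it.
#' @param n_A,n_B subjects per factory (defaults 76 and 61).
#' @param scale `"reduced"` (default; full pipeline runs in minutes) or
#'   `"full"` (feature counts at the scale of a real campaign).
#' @param n_chem_features approximate number of GC-HRMS chemical features.
#' @param n_chlorinated number of planted chlorinated compounds.
#' @param n_correlated how many chlorinated compounds are correlated with a
#'   targeted congener (the rest are chlorinated but exposure-independent).
#' @param r_related target correlation (on the log scale) between a correlated
#'   compound's abundance and its congener.
#' @param chem_noise_sd multiplicative (log-scale) noise SD on chemical peak
#'   intensities.
#' @param rt_jitter_sd within-compound retention-time jitter SD, seconds.
#' @param n_metab_features metabolome features per LC mode.
#' @param n_batches,replicates analytical batches and technical replicates
#'   per subject for the LC modes.
#' @param beta planted effect of ln-exposure on affected ln-features.
#' @param metab_noise_sd residual SD of ln-intensities across subjects.
#' @param rep_noise_sd technical-replicate SD on the log scale.
#' @param batch_sd SD of per-feature additive batch shifts (log scale).
#' @param age_beta,bmi_beta small covariate effects on all metabolome
#'   features, so confounder adjustment is exercised.
#' @param missing_rate fraction of each feature's lowest subject-level values
#'   set missing (left censoring at the detection limit).
#' @param cv_junk_rate fraction of metabolome features given very noisy
#'   replicates, to exercise the CV filter.
#' @param n_pathways,metabolites_per_pathway pathway database size.
#' @param n_enriched_per_subclass designated enriched pathways per exposure
#'   subclass (PCDD / PCDF / PCB).
#' @param detected_per_enriched planted (affected) features per enriched
#'   pathway and mode.
#' @param detected_per_null planted null features per pathway and mode
#'   (defines realistic pathway coverage in the detected universe).
#' @param marker_loading latent-factor loading of designated immune markers.
#' @param markers_per_factor number of markers loaded per latent factor.
#' @param exposure_rho within-subclass copula correlations, named numeric
#'   `c(PCDD=, PCDF=, PCB=)`; between-subclass correlation is fixed at 0.1.
#' @param lod_quantile quantile of the factory-B marginal at which each
#'   congener's LOD is placed (0 disables censoring).
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_A = 76L, n_B = 61L,
                       scale = c("reduced", "full"),
                       n_chem_features = NULL,
                       n_chlorinated = NULL,
                       n_correlated = NULL,
                       r_related = 0.8,
                       chem_noise_sd = 0.05,
                       rt_jitter_sd = 0.3,
                       n_metab_features = NULL,
                       n_batches = 2L,
                       replicates = 3L,
                       beta = 0.5,
                       metab_noise_sd = 0.5,
                       rep_noise_sd = 0.1,
                       batch_sd = 0.5,
                       age_beta = 0.005,
                       bmi_beta = 0.01,
                       missing_rate = 0.10,
                       cv_junk_rate = 0.02,
                       n_pathways = 25L,
                       metabolites_per_pathway = 10L,
                       n_enriched_per_subclass = 2L,
                       detected_per_enriched = 8L,
                       detected_per_null = 6L,
                       marker_loading = 0.8,
                       markers_per_factor = 6L,
                       exposure_rho = c(PCDD = 0.5, PCDF = 0.25, PCB = 0.95),
                       lod_quantile = 0.05) {
  scale <- match.arg(scale)
  if (is.null(n_chem_features)) n_chem_features <- if (scale == "full") 11000L else 800L
  if (is.null(n_chlorinated)) n_chlorinated <- if (scale == "full") 500L else 60L
  if (is.null(n_correlated)) n_correlated <- if (scale == "full") 150L else 40L
  if (is.null(n_metab_features)) n_metab_features <- if (scale == "full") 7000L else 1500L
  cfg <- list(
    seed = as.integer(seed), n_A = as.integer(n_A), n_B = as.integer(n_B),
    scale = scale,
    n_chem_features = as.integer(n_chem_features),
    n_chlorinated = as.integer(n_chlorinated),
    n_correlated = as.integer(n_correlated),
    r_related = r_related, chem_noise_sd = chem_noise_sd,
    rt_jitter_sd = rt_jitter_sd,
    n_metab_features = as.integer(n_metab_features),
    n_batches = as.integer(n_batches), replicates = as.integer(replicates),
    beta = beta, metab_noise_sd = metab_noise_sd,
    rep_noise_sd = rep_noise_sd, batch_sd = batch_sd,
    age_beta = age_beta, bmi_beta = bmi_beta,
    missing_rate = missing_rate, cv_junk_rate = cv_junk_rate,
    n_pathways = as.integer(n_pathways),
    metabolites_per_pathway = as.integer(metabolites_per_pathway),
    n_enriched_per_subclass = as.integer(n_enriched_per_subclass),
    detected_per_enriched = as.integer(detected_per_enriched),
    detected_per_null = as.integer(detected_per_null),
    marker_loading = marker_loading,
    markers_per_factor = as.integer(markers_per_factor),
    exposure_rho = exposure_rho, lod_quantile = lod_quantile
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  counts <- c("n_A", "n_B", "n_chem_features", "n_chlorinated", "n_correlated",
              "n_metab_features", "n_batches", "replicates", "n_pathways",
              "metabolites_per_pathway", "n_enriched_per_subclass",
              "detected_per_enriched", "detected_per_null",
              "markers_per_factor")
  for (nm in counts) {
    if (is.na(cfg[[nm]]) || cfg[[nm]] < 0) {
      stop("sim_config: '", nm, "' must be a nonnegative count")
    }
  }
  rates <- c("missing_rate", "cv_junk_rate", "lod_quantile")
  for (nm in rates) {
    if (cfg[[nm]] < 0 || cfg[[nm]] > 1) {
      stop("sim_config: '", nm, "' must lie in [0, 1]")
    }
  }
  if (cfg$n_correlated > cfg$n_chlorinated) {
    stop("sim_config: n_correlated cannot exceed n_chlorinated")
  }
  if (abs(cfg$r_related) >= 1) stop("sim_config: r_related must lie in (-1, 1)")
  if (3L * cfg$n_enriched_per_subclass > cfg$n_pathways) {
    stop("sim_config: too many enriched pathways for the pathway count")
  }
  invisible(cfg)
}

# Per-congener log-normal marginals (ppt, lipid adjusted). meanlog differs by
# factory for PCDDs (factory A historically exposed); PCDF/PCB marginals are
# shared across factories.
congener_marginals <- function() {
  panel <- congener_panel()
  median_b <- c(
    TCDD = 0.30, `12378D` = 5, `123478D` = 8, `123678D` = 30, `123789D` = 6,
    `1234678D` = 50, OCDD = 300,
    `2378F` = 1, `12378F` = 1, `23478F` = 5, `123478F` = 5, `123678F` = 4,
    `123789F` = 1, `234678F` = 2, `1234678F` = 10, `1234789F` = 1, OCDF = 3,
    PCB77 = 20, PCB81 = 5, PCB126 = 30, PCB169 = 25, PCB105 = 300,
    PCB114 = 60, PCB118 = 1500, PCB123 = 20, PCB156 = 250, PCB157 = 60,
    PCB167 = 120, PCB189 = 30
  )
  median_a <- median_b
  median_a["TCDD"] <- 4.35
  pcdd_others <- setdiff(panel$congener[panel$subclass == "PCDD"], "TCDD")
  median_a[pcdd_others] <- 1.5 * median_b[pcdd_others]
  sdlog <- stats::setNames(
    rep(c(0.6, 0.6, 0.7), times = c(7L, 10L, 12L)), panel$congener)
  sdlog["TCDD"] <- 1.0
  data.frame(
    congener = panel$congener, subclass = panel$subclass,
    meanlog_A = log(median_a[panel$congener]),
    meanlog_B = log(median_b[panel$congener]),
    sdlog = sdlog[panel$congener],
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Generate a synthetic two-factory cohort
#'
#' Draws subject demographics: ages differ by factory (means 69.0 and 58.8
#' years), BMI, smoking and alcohol do not; factory A subjects carry a
#' lag (years since last exposure) for TCDD back-extrapolation, factory B
#' subjects have lag 0.
#'
#' @param config a [sim_config()].
#' @return data.frame with columns `subject_id`, `factory`, `age`, `bmi`,
#'   `smoking`, `alcohol`, `lag_years`.
#' @export
generate_cohort <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_A + config$n_B
  if (n == 0L) {
    return(data.frame(subject_id = character(), factory = character(),
                      age = numeric(), bmi = numeric(), smoking = character(),
                      alcohol = numeric(), lag_years = numeric(),
                      stringsAsFactors = FALSE))
  }
  factory <- rep(c("A", "B"), times = c(config$n_A, config$n_B))
  age_mean <- c(A = 69.0, B = 58.8)[factory]
  age_sd <- c(A = 7.7, B = 9.0)[factory]
  bmi_mean <- c(A = 26.9, B = 27.1)[factory]
  bmi_sd <- c(A = 3.0, B = 3.6)[factory]
  age <- pmax(stats::rnorm(n, age_mean, age_sd), 25)
  bmi <- pmax(stats::rnorm(n, bmi_mean, bmi_sd), 15)
  smoke_p <- list(A = c(0.158, 0.605, 0.237), B = c(0.213, 0.525, 0.262))
  smoking <- vapply(factory, function(f) {
    sample(c("never", "former", "current"), 1L, prob = smoke_p[[f]])
  }, character(1))
  # alcohol ~ log-normal matched to mean 13.2 units/week, SD ~14
  alcohol <- stats::rlnorm(n, meanlog = 2.22, sdlog = 0.85)
  lag_years <- ifelse(factory == "A", stats::runif(n, 25, 44), 0)
  data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    factory = factory, age = age, bmi = bmi, smoking = unname(smoking),
    alcohol = alcohol, lag_years = lag_years,
    stringsAsFactors = FALSE
  )
}

#' Generate the targeted 29-congener exposure panel
#'
#' Log-normal marginals per congener with factory-specific location for
#' PCDDs (TCDD strongly elevated in factory A); dependence imposed through a
#' Gaussian copula with configurable within-subclass correlation. Values
#' below each congener's LOD are flagged, not zeroed; LODs are placed at the
#' `lod_quantile` of the factory-B marginal.
#'
#' @param subjects output of [generate_cohort()].
#' @param config a [sim_config()].
#' @return An [exposure_panel()]. The copula normal scores are attached as
#'   attribute `"zscores"` for downstream planting.
#' @export
generate_targeted_exposures <- function(subjects, config) {
  validate_sim_config(config)
  if (nrow(subjects) == 0L) stop("subjects table is empty")
  set.seed(config$seed + 1L)
  marg <- congener_marginals()
  k <- nrow(marg)
  rho <- config$exposure_rho
  R <- matrix(0.1, k, k)
  for (sc in unique(marg$subclass)) {
    idx <- which(marg$subclass == sc)
    R[idx, idx] <- rho[[sc]]
  }
  diag(R) <- 1
  n <- nrow(subjects)
  Z <- matrix(stats::rnorm(n * k), n, k) %*% chol(R)
  colnames(Z) <- marg$congener
  meanlog <- ifelse(subjects$factory == "A",
                    rep(1, n), rep(0, n))  # placeholder, filled per congener
  conc <- matrix(NA_real_, n, k, dimnames = list(subjects$subject_id, marg$congener))
  for (j in seq_len(k)) {
    ml <- ifelse(subjects$factory == "A", marg$meanlog_A[j], marg$meanlog_B[j])
    conc[, j] <- exp(ml + marg$sdlog[j] * Z[, j])
  }
  lod <- stats::setNames(
    if (config$lod_quantile > 0) {
      stats::qlnorm(config$lod_quantile, marg$meanlog_B, marg$sdlog)
    } else rep(0, k),
    marg$congener
  )
  below <- sweep(conc, 2, lod, "<")
  panel <- exposure_panel(conc, below, lod)
  attr(panel, "zscores") <- Z
  panel
}

# standardized ln-concentration of one congener (the planting signal)
congener_signal <- function(panel, congener) {
  as.numeric(scale(log(panel$concentrations[, congener])))
}

#' Generate the untargeted GC-HRMS chemical feature table
#'
#' Each planted chlorinated compound contributes a co-eluting peak group: a
#' monoisotopic peak at mass M plus M+2k peaks whose relative abundances
#' follow the binomial 35Cl/37Cl law for the compound's chlorine count
#' (1 to 8 by default). A configured subset of compound abundances is
#' generated, through the exposure copula, to correlate with chosen
#' congeners. Decoy compounds carry no chlorine envelope (a 13C M+1
#' distractor peak instead). Chlorinated compounds are spaced at least 10 s
#' apart in retention time so planted groups are resolvable.
#'
#' @param subjects output of [generate_cohort()].
#' @param panel output of [generate_targeted_exposures()].
#' @param config a [sim_config()].
#' @return list with elements `table` (a GC-mode [feature_table()], one
#'   injection per subject) and `truth` (planted compound ground truth).
#' @export
generate_chem_features <- function(subjects, panel, config) {
  validate_sim_config(config)
  set.seed(config$seed + 2L)
  n <- nrow(subjects)
  consts <- isotope_constants()
  panel_names <- congener_panel()$congener

  n_chl <- config$n_chlorinated
  # chlorine counts 1..8; RT slots with >= 10 s separation
  n_cl <- sample(1:8, n_chl, replace = TRUE)
  rt_slots <- seq(120, 1700, by = 10)
  if (length(rt_slots) < n_chl) stop("too many chlorinated compounds for the RT range")
  rt_c <- sample(rt_slots, n_chl) + stats::runif(n_chl, -2, 2)
  mono <- stats::runif(n_chl, 150, 600)
  corr_idx <- seq_len(config$n_correlated)
  target_congener <- sample(panel_names, config$n_correlated, replace = TRUE)

  meta <- list(); intens <- list(); truth_rows <- list()
  fid <- 0L
  for (i in seq_len(n_chl)) {
    env <- theoretical_cl_envelope(n_cl[i])
    keep <- env$abundance >= 0.01
    ks <- env$k[keep]; rel <- env$abundance[keep]
    z <- stats::rnorm(n)
    cong <- NA_character_
    if (i %in% corr_idx) {
      cong <- target_congener[i]
      zc <- congener_signal(panel, cong)
      z <- config$r_related * zc + sqrt(1 - config$r_related^2) * z
    }
    ab <- exp(stats::runif(1, log(1e5), log(1e7)) + z)  # compound abundance
    ids <- sprintf("GC%05d", fid + seq_along(ks))
    fid <- fid + length(ks)
    meta[[i]] <- data.frame(
      feature_id = ids,
      mz = mono[i] + ks * consts$dm_cl + stats::rnorm(length(ks), 0, 5e-4),
      rt = rt_c[i] + stats::rnorm(length(ks), 0, config$rt_jitter_sd),
      stringsAsFactors = FALSE
    )
    intens[[i]] <- outer(rel, ab) *
      exp(matrix(stats::rnorm(length(ks) * n, 0, config$chem_noise_sd),
                 length(ks), n))
    truth_rows[[i]] <- data.frame(
      compound_id = sprintf("CMP%03d", i), n_cl = n_cl[i], mono_mz = mono[i],
      rt = rt_c[i], congener = cong,
      r = if (is.na(cong)) NA_real_ else config$r_related,
      feature_ids = I(list(ids)), stringsAsFactors = FALSE
    )
  }

  # decoys: pairs of M and a 13C M+1 distractor
  n_decoy_feat <- max(config$n_chem_features - fid, 0L)
  n_decoy <- n_decoy_feat %/% 2L
  decoy_rows <- list()
  for (i in seq_len(n_decoy)) {
    m0 <- stats::runif(1, 100, 800)
    rt0 <- stats::runif(1, 90, 1750)
    rel <- c(1, stats::runif(1, 0.1, 0.5))
    ab <- exp(stats::runif(1, log(1e5), log(1e7)) + stats::rnorm(n))
    ids <- sprintf("GC%05d", fid + 1:2)
    fid <- fid + 2L
    meta[[n_chl + i]] <- data.frame(
      feature_id = ids,
      mz = m0 + c(0, 1.00335) + stats::rnorm(2, 0, 5e-4),
      rt = rt0 + stats::rnorm(2, 0, config$rt_jitter_sd),
      stringsAsFactors = FALSE
    )
    intens[[n_chl + i]] <- outer(rel, ab) *
      exp(matrix(stats::rnorm(2 * n, 0, config$chem_noise_sd), 2, n))
    decoy_rows[[i]] <- data.frame(
      compound_id = sprintf("DEC%03d", i), n_cl = 0L, mono_mz = m0, rt = rt0,
      congener = NA_character_, r = NA_real_, feature_ids = I(list(ids)),
      stringsAsFactors = FALSE
    )
  }

  meta <- do.call(rbind, meta)
  X <- do.call(rbind, intens)
  # keep masses inside the GC scan range
  ok <- meta$mz >= 85 & meta$mz <= 850
  meta <- meta[ok, , drop = FALSE]
  X <- X[ok, , drop = FALSE]
  samples <- data.frame(
    sample_id = subjects$subject_id, subject_id = subjects$subject_id,
    replicate = 1L, batch = "gc1", stringsAsFactors = FALSE
  )
  tab <- feature_table(meta, X, samples, mode = "GC")
  truth <- list(
    compounds = do.call(rbind, c(truth_rows, decoy_rows)),
    related = {
      tr <- do.call(rbind, truth_rows)
      tr[!is.na(tr$congener), c("compound_id", "congener", "r")]
    }
  )
  list(table = tab, truth = truth)
}

#' Generate a synthetic pathway database
#'
#' Pathways of metabolites with neutral monoisotopic masses; a fraction of
#' metabolites is shared between consecutive pathways so membership can
#' overlap, as in curated databases.
#'
#' @param config a [sim_config()].
#' @return data.frame with columns `pathway_id`, `metabolite_id`, `mass`.
#' @export
generate_pathway_db <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed + 3L)
  rows <- list()
  mid <- 0L
  for (p in seq_len(config$n_pathways)) {
    k <- config$metabolites_per_pathway
    ids <- sprintf("MET%04d", mid + seq_len(k))
    mid <- mid + k
    rows[[p]] <- data.frame(
      pathway_id = sprintf("PW%02d", p), metabolite_id = ids,
      mass = stats::runif(k, 100, 800), stringsAsFactors = FALSE
    )
  }
  db <- do.call(rbind, rows)
  # share ~10% of metabolites with the next pathway
  n_share <- max(1L, round(0.1 * config$metabolites_per_pathway))
  extra <- list()
  for (p in seq_len(config$n_pathways - 1L)) {
    src <- db[db$pathway_id == sprintf("PW%02d", p), ][seq_len(n_share), ]
    src$pathway_id <- sprintf("PW%02d", p + 1L)
    extra[[p]] <- src
  }
  rbind(db, do.call(rbind, extra))
}

# Which pathways are designated enriched, and which congener drives each
# subclass's planted effects.
subclass_drivers <- function() {
  c(PCDD = "TCDD", PCDF = "23478F", PCB = "PCB126")
}

#' Generate the two LC-HRMS metabolome feature tables
#'
#' Features for designated "enriched" pathways are placed, via a mode-typical
#' adduct offset (M-H for C18-negative, M+H for HILIC-positive), at the m/z
#' of that pathway's metabolites and given a linear ln-exposure effect driven
#' by the subclass's driver congener; all other pathway metabolites receive
#' null (unaffected) features so pathway coverage is realistic. Remaining
#' features are background noise. Triplicate injections with per-batch shifts
#' are simulated, the lowest `missing_rate` fraction of each feature's
#' subject-level values is left-censored, and a small fraction of features is
#' given extreme replicate noise to exercise the CV filter.
#'
#' @param subjects output of [generate_cohort()].
#' @param panel output of [generate_targeted_exposures()].
#' @param config a [sim_config()].
#' @param db a pathway database, by default [generate_pathway_db()].
#' @return list with elements `c18neg` and `hilicpos` ([feature_table()]s),
#'   `db`, and `truth` (planted effects and enriched pathways).
#' @export
generate_metabolome <- function(subjects, panel, config,
                                db = generate_pathway_db(config)) {
  validate_sim_config(config)
  set.seed(config$seed + 4L)
  n <- nrow(subjects)
  drivers <- subclass_drivers()
  pw_ids <- unique(db$pathway_id)
  n_enr <- config$n_enriched_per_subclass
  enriched <- data.frame(
    pathway_id = pw_ids[seq_len(3L * n_enr)],
    subclass = rep(names(drivers), each = n_enr),
    driver = rep(unname(drivers), each = n_enr),
    stringsAsFactors = FALSE
  )
  proton <- 1.007276
  make_mode <- function(mode) {
    adduct_off <- if (mode == "C18neg") -proton else proton
    rows <- list(); truth <- list(); vals <- list()
    fid <- 0L
    new_id <- function() {
      fid <<- fid + 1L
      sprintf("%s%05d", if (mode == "C18neg") "C18_" else "HIL_", fid)
    }
    z_cov <- config$age_beta * subjects$age + config$bmi_beta * subjects$bmi
    for (p in pw_ids) {
      mets <- db[db$pathway_id == p, ]
      mets <- mets[!duplicated(mets$metabolite_id), ]
      is_enr <- p %in% enriched$pathway_id
      k <- if (is_enr) min(config$detected_per_enriched, nrow(mets)) else
        min(config$detected_per_null, nrow(mets))
      mets <- mets[seq_len(k), ]
      driver <- if (is_enr) enriched$driver[enriched$pathway_id == p][1] else NA
      subclass <- if (is_enr) enriched$subclass[enriched$pathway_id == p][1] else NA
      lnx <- if (is_enr) log(panel$concentrations[, driver]) else rep(0, n)
      for (j in seq_len(nrow(mets))) {
        id <- new_id()
        mz <- mets$mass[j] + adduct_off
        mz <- mz * (1 + stats::rnorm(1, 0, 1e-6))  # ~1 ppm mass error
        if (mz < 85 || mz > 1275) next
        b <- if (is_enr) config$beta else 0
        mu <- stats::runif(1, log(1e4), log(1e6))
        lny <- mu + b * lnx + z_cov +
          stats::rnorm(n, 0, config$metab_noise_sd)
        rows[[id]] <- data.frame(feature_id = id, mz = mz,
                                 rt = stats::runif(1, 30, 500),
                                 stringsAsFactors = FALSE)
        vals[[id]] <- lny
        truth[[id]] <- data.frame(
          feature_id = id, metabolite_id = mets$metabolite_id[j],
          pathway_id = p, driver = if (is_enr) driver else NA_character_,
          subclass = if (is_enr) subclass else NA_character_,
          beta = b, mode = mode, stringsAsFactors = FALSE
        )
      }
    }
    n_bg <- max(config$n_metab_features - length(rows), 0L)
    for (j in seq_len(n_bg)) {
      id <- new_id()
      rows[[id]] <- data.frame(feature_id = id,
                               mz = stats::runif(1, 85, 1275),
                               rt = stats::runif(1, 30, 500),
                               stringsAsFactors = FALSE)
      mu <- stats::runif(1, log(1e4), log(1e6))
      vals[[id]] <- mu + z_cov + stats::rnorm(n, 0, config$metab_noise_sd)
    }
    meta <- do.call(rbind, rows)
    lnY <- do.call(rbind, vals)  # features x subjects, subject-level truth
    nf <- nrow(meta)

    # replicate/batch structure
    batches <- sprintf("b%d", ((seq_len(n) - 1L) %% config$n_batches) + 1L)
    rep_sd <- rep(config$rep_noise_sd, nf)
    junk <- seq_len(nf) %in% sample(nf, round(config$cv_junk_rate * nf))
    rep_sd[junk] <- 1.5
    nrep <- config$replicates
    X <- matrix(NA_real_, nf, n * nrep)
    shift <- matrix(stats::rnorm(nf * config$n_batches, 0, config$batch_sd),
                    nf, config$n_batches)
    samp <- data.frame(
      sample_id = paste0(rep(subjects$subject_id, each = nrep), "_r",
                         rep(seq_len(nrep), times = n)),
      subject_id = rep(subjects$subject_id, each = nrep),
      replicate = rep(seq_len(nrep), times = n),
      batch = rep(batches, each = nrep), stringsAsFactors = FALSE
    )
    bidx <- as.integer(factor(samp$batch, levels = sprintf("b%d", seq_len(config$n_batches))))
    for (rix in seq_len(nrep)) {
      cols <- which(samp$replicate == rix)
      X[, cols] <- lnY + shift[, bidx[cols], drop = FALSE] +
        matrix(stats::rnorm(nf * n, 0, 1), nf, n) * rep_sd
    }
    # left censoring: per feature, the lowest missing_rate fraction of
    # subject-level true values goes missing in all replicates
    n_cens <- floor(config$missing_rate * n)
    if (n_cens > 0) {
      for (f in seq_len(nf)) {
        low <- order(lnY[f, ])[seq_len(n_cens)]
        X[f, samp$subject_id %in% subjects$subject_id[low]] <- NA_real_
      }
    }
    tab <- feature_table(meta, exp(X), samp, mode = mode)
    list(table = tab, truth = do.call(rbind, truth))
  }
  c18 <- make_mode("C18neg")
  hil <- make_mode("HILICpos")
  list(
    c18neg = c18$table, hilicpos = hil$table, db = db,
    truth = list(effects = rbind(c18$truth, hil$truth), enriched = enriched)
  )
}

#' Generate the immune-marker table
#'
#' 54 markers in four categories (21 cytokines/growth factors, 23
#' hematologic parameters, 7 humoral markers, 3 lymphoma markers). Designated
#' markers load on latent factors defined as the standardized ln
#' concentration of each subclass's driver congener - the same signals that
#' drive the planted pathway effects - so a pathway-marker association chain
#' exists by construction.
#'
#' @param subjects output of [generate_cohort()].
#' @param panel output of [generate_targeted_exposures()].
#' @param config a [sim_config()].
#' @return list with elements `markers` (subjects x 54 matrix), `categories`
#'   (named character vector) and `truth` (marker loadings).
#' @export
generate_immune_markers <- function(subjects, panel, config) {
  validate_sim_config(config)
  if (nrow(subjects) == 0L) stop("subjects table is empty")
  set.seed(config$seed + 5L)
  cyto <- c("IL1b", "IL2", "IL4", "IL5", "IL6", "IL8", "IL10", "IL12", "IL13",
            "IL17", "GMCSF", "GCSF", "TNFa", "EGF", "FGF2", "GRO", "IP10",
            "MCP1", "MDC", "MIP1a", "TGFa")
  hema <- c("WBC", "RBC", "HGB", "HCT", "PLT", "MO", "GR", "LY", "B_cel",
            "B_naive", "B_IgM", "B_IgG", "T_cel", "TH_cel", "TH_CD38CD4",
            "TH_naive", "TH_memory", "TC_cel", "TC_CD38CD8", "TC_naive",
            "TC_memory", "LGL", "NK_cel")
  humo <- c("IgA", "IgD", "IgE", "IgG", "IgM", "C3", "C4")
  lymp <- c("sCD30", "sCD27", "IL1RA")
  marker_ids <- c(cyto, hema, humo, lymp)
  categories <- stats::setNames(
    rep(c("cytokine", "hematologic", "humoral", "lymphoma"),
        times = c(length(cyto), length(hema), length(humo), length(lymp))),
    marker_ids)
  n <- nrow(subjects)
  M <- matrix(stats::rnorm(n * length(marker_ids)), n, length(marker_ids),
              dimnames = list(subjects$subject_id, marker_ids))
  drivers <- subclass_drivers()
  loads <- list()
  lam <- config$marker_loading
  avail <- marker_ids
  for (sc in names(drivers)) {
    z <- congener_signal(panel, drivers[[sc]])
    picked <- sample(avail, min(config$markers_per_factor, length(avail)))
    avail <- setdiff(avail, picked)
    for (m in picked) {
      M[, m] <- lam * z + sqrt(max(1 - lam^2, 0)) * stats::rnorm(n)
    }
    loads[[sc]] <- data.frame(
      marker_id = picked, subclass = sc, driver = unname(drivers[[sc]]),
      loading = lam, stringsAsFactors = FALSE
    )
  }
  list(markers = M, categories = categories,
       truth = list(marker_loadings = do.call(rbind, loads)))
}

#' Generate the complete synthetic data set
#'
#' Runs every generator stage and bundles their outputs with the merged
#' ground truth. Identical configurations (including the seed) give identical
#' outputs.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_data` with elements `subjects`, `panel`,
#'   `chem`, `c18neg`, `hilicpos`, `immune` (markers + categories),
#'   `pathway_db`, `truth`, `config`.
#' @export
simulate_cohort_data <- function(config = sim_config()) {
  validate_sim_config(config)
  subjects <- generate_cohort(config)
  panel <- generate_targeted_exposures(subjects, config)
  chem <- generate_chem_features(subjects, panel, config)
  metab <- generate_metabolome(subjects, panel, config)
  immune <- generate_immune_markers(subjects, panel, config)
  structure(list(
    subjects = subjects, panel = panel, chem = chem$table,
    c18neg = metab$c18neg, hilicpos = metab$hilicpos,
    immune = immune[c("markers", "categories")],
    pathway_db = metab$db,
    truth = list(
      compounds = chem$truth$compounds, related = chem$truth$related,
      effects = metab$truth$effects, enriched = metab$truth$enriched,
      marker_loadings = immune$truth$marker_loadings
    ),
    config = config
  ), class = "sim_data")
}

#' Write a synthetic data set to disk
#'
#' All tables go out as TSV with a one-line header, the ground truth as JSON
#' and the configuration as YAML.
#'
#' @param sim output of [simulate_cohort_data()].
#' @param dir output directory (created if absent).
#' @return Invisibly, the vector of written file paths.
#' @export
write_sim_data <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_data"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  wtsv <- function(x, name) {
    p <- file.path(dir, name)
    utils::write.table(x, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <<- c(paths, p)
  }
  wtsv(sim$subjects, "subjects.tsv")
  conc <- data.frame(subject_id = rownames(sim$panel$concentrations),
                     sim$panel$concentrations, check.names = FALSE)
  wtsv(conc, "exposures.tsv")
  wtsv(data.frame(congener = names(sim$panel$lod), lod = sim$panel$lod),
       "exposure_lod.tsv")
  for (nm in c("chem", "c18neg", "hilicpos")) {
    ft <- sim[[nm]]
    wtsv(ft$meta, paste0(nm, "_features.tsv"))
    wtsv(data.frame(feature_id = rownames(ft$intensities), ft$intensities,
                    check.names = FALSE), paste0(nm, "_intensities.tsv"))
    wtsv(ft$samples, paste0(nm, "_samples.tsv"))
  }
  wtsv(data.frame(subject_id = rownames(sim$immune$markers),
                  sim$immune$markers, check.names = FALSE), "immune_markers.tsv")
  wtsv(sim$pathway_db, "pathway_db.tsv")
  truth <- sim$truth
  truth$compounds$feature_ids <- lapply(truth$compounds$feature_ids, identity)
  p <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(truth, p, auto_unbox = TRUE, digits = NA)
  paths <- c(paths, p)
  p <- file.path(dir, "sim_config.yaml")
  yaml::write_yaml(unclass(sim$config), p)
  paths <- c(paths, p)
  invisible(paths)
}
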