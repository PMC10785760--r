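#' Quality-filter a feature table and average technical replicates
#'
#' A feature is removed when (i) the median across subjects of its
#' within-subject replicate coefficient of variation (replicate SD /
#' replicate mean, raw intensities) is at or above `cv_max`, or (ii) it is
#' detected - non-missing in at least one replicate - in fewer than
#' `min_detect` of the subjects. Surviving features are averaged over
#' replicates (missing injections ignored), so the returned table has one
#' column per subject. Filtering is idempotent and never drops subjects.
#'
#' @param table a [feature_table()] with a replicate dimension.
#' @param cv_max CV threshold (default 1.0, i.e. 100%).
#' @param min_detect minimum detection fraction (default 0.6).
#' @return The filtered, replicate-averaged [feature_table()]; the removal
#'   log is attached as attribute `"removal_log"` (data.frame of feature_id
#'   and reason).
#' @export
filter_features <- function(table, cv_max = 1.0, min_detect = 0.6) {
  stopifnot(inherits(table, "feature_table"))
  if (n_replicates(table) < 1L) stop("feature table has no replicates")
  subjects <- unique(table$samples$subject_id)
  X <- table$intensities
  cv_med <- numeric(nrow(X)); detect <- numeric(nrow(X))
  cols_by_subject <- lapply(subjects, function(s) which(table$samples$subject_id == s))
  for (f in seq_len(nrow(X))) {
    cvs <- vapply(cols_by_subject, function(cols) {
      v <- X[f, cols]; v <- v[!is.na(v)]
      if (length(v) < 2L) return(NA_real_)
      m <- mean(v)
      if (m == 0) return(NA_real_)
      stats::sd(v) / m
    }, numeric(1))
    cv_med[f] <- stats::median(cvs, na.rm = TRUE)
    detect[f] <- mean(vapply(cols_by_subject, function(cols) {
      any(!is.na(X[f, cols]))
    }, logical(1)))
  }
  bad_cv <- !is.na(cv_med) & cv_med >= cv_max
  bad_det <- detect < min_detect
  removal <- data.frame(
    feature_id = table$meta$feature_id[bad_cv | bad_det],
    reason = ifelse(bad_cv[bad_cv | bad_det], "cv", "detection"),
    stringsAsFactors = FALSE
  )
  keep <- !(bad_cv | bad_det)
  # average over replicates -> one injection per subject
  avg <- vapply(cols_by_subject, function(cols) {
    rowMeans(X[keep, cols, drop = FALSE], na.rm = TRUE)
  }, numeric(sum(keep)))
  if (sum(keep) == 1L) avg <- matrix(avg, nrow = 1L)
  avg[is.nan(avg)] <- NA_real_
  batch_by_subject <- vapply(cols_by_subject, function(cols) {
    as.character(table$samples$batch[cols[1]])
  }, character(1))
  samples <- data.frame(
    sample_id = subjects, subject_id = subjects, replicate = 1L,
    batch = batch_by_subject, stringsAsFactors = FALSE
  )
  out <- feature_table(table$meta[keep, , drop = FALSE], avg, samples, table$mode)
  attr(out, "removal_log") <- removal
  out
}

#' Standardize batch location and scale
#'
#' Per feature, each batch's log-intensities are standardized to the pooled
#' (all-batch) mean and SD, removing additive and multiplicative batch
#' effects on the log scale. Features constant within some batch are passed
#' through unchanged with a warning. With a single batch the operation is the
#' identity.
#'
#' @param table a replicate-averaged [feature_table()] (one column per
#'   subject) with batch labels.
#' @return The corrected [feature_table()] (intensity scale); warnings about
#'   pass-through features are attached as attribute `"warning_log"`.
#' @export
correct_batches <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  batch <- as.character(table$samples$batch)
  tab <- table(batch)
  if (any(tab < 3L)) {
    stop("batch '", names(tab)[which.min(tab)], "' has fewer than 3 subjects")
  }
  L <- log(table$intensities)
  warn <- character()
  for (f in seq_len(nrow(L))) {
    x <- L[f, ]
    pooled_m <- mean(x, na.rm = TRUE)
    pooled_s <- stats::sd(x[!is.na(x)])
    sds <- vapply(split(x, batch), function(v) {
      v <- v[!is.na(v)]
      if (length(v) < 2L) 0 else stats::sd(v)
    }, numeric(1))
    if (any(sds == 0) || pooled_s == 0) {
      warn <- c(warn, table$meta$feature_id[f])
      next
    }
    for (b in names(tab)) {
      idx <- which(batch == b & !is.na(x))
      L[f, idx] <- (x[idx] - mean(x[idx])) / stats::sd(x[idx]) * pooled_s + pooled_m
    }
  }
  if (length(warn)) {
    warning(length(warn), " batch-constant feature(s) passed through unchanged")
  }
  out <- feature_table(table$meta, exp(L), table$samples, table$mode)
  attr(out, "warning_log") <- warn
  out
}

#' Impute left-censored missing values
#'
#' Missingness in filtered feature tables is assumed to arise from
#' concentrations falling below the detection limit. Per feature, a normal
#' distribution is fitted to the observed log-intensities and missing entries
#' are drawn from its left tail truncated at the feature's observed minimum,
#' so every imputed value sits below all observed values. Observed entries
#' are preserved exactly.
#'
#' @param table a replicate-averaged [feature_table()].
#' @param seed integer seed; imputation is deterministic given it.
#' @return The completed [feature_table()].
#' @export
impute_left_censored <- function(table, seed = 1L) {
  stopifnot(inherits(table, "feature_table"))
  X <- table$intensities
  if (!anyNA(X)) return(table)
  set.seed(as.integer(seed))
  L <- log(X)
  for (f in seq_len(nrow(L))) {
    miss <- which(is.na(L[f, ]))
    if (!length(miss)) next
    obs <- L[f, -miss]
    if (length(obs) < 3L) {
      stop("feature '", table$meta$feature_id[f],
           "' has fewer than 3 observed values; filter first")
    }
    m <- mean(obs); s <- stats::sd(obs)
    if (s == 0) s <- .Machine$double.eps
    pmin_ <- stats::pnorm(min(obs), m, s)
    # inverse-CDF draw from the tail below the observed minimum
    u <- stats::runif(length(miss), 0, pmin_)
    L[f, miss] <- pmin(stats::qnorm(u, m, s), min(obs) - 1e-9)
  }
  feature_table(table$meta, exp(L), table$samples, table$mode)
}

# E[X | X < lod] for a log-normal(meanlog, sdlog)
lnorm_cond_mean_below <- function(lod, meanlog, sdlog) {
  z <- (log(lod) - meanlog) / sdlog
  exp(meanlog + sdlog^2 / 2) * stats::pnorm(z - sdlog) / stats::pnorm(z)
}

#' Maximum-likelihood LOD imputation for the targeted panel
#'
#' Per congener, a censored log-normal maximum-likelihood fit (via
#' [fitdistrplus::fitdistcens()]) combines the observed concentrations with
#' the censoring bounds of flagged entries; flagged values are then replaced
#' by the conditional expectation E[X | X < LOD] under the fitted law, which
#' always lies in (0, LOD).
#'
#' @param panel an [exposure_panel()] with LOD values for flagged entries.
#' @return The imputed [exposure_panel()] (no flags remain).
#' @export
impute_targeted_lod <- function(panel) {
  stopifnot(inherits(panel, "exposure_panel"))
  if (!any(panel$below_lod)) return(panel)
  conc <- panel$concentrations
  for (j in colnames(conc)) {
    flagged <- panel$below_lod[, j]
    if (!any(flagged)) next
    if (all(flagged)) stop("congener '", j, "' has all values censored")
    lod <- panel$lod[[j]]
    cens <- data.frame(
      left = ifelse(flagged, NA_real_, conc[, j]),
      right = ifelse(flagged, lod, conc[, j])
    )
    fit <- suppressWarnings(fitdistrplus::fitdistcens(cens, "lnorm"))
    mu <- fit$estimate[["meanlog"]]; sg <- fit$estimate[["sdlog"]]
    imp <- lnorm_cond_mean_below(lod, mu, sg)
    conc[flagged, j] <- min(max(imp, .Machine$double.xmin), lod * (1 - 1e-9))
  }
  out <- exposure_panel(conc, matrix(FALSE, nrow(conc), ncol(conc),
                                     dimnames = dimnames(conc)), panel$lod)
  attr(out, "zscores") <- attr(panel, "zscores")
  out
}
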