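#' Metabolome-wide association scan for one exposure
#'
#' Regresses each ln-transformed metabolic feature on one ln-transformed
#' exposure with covariate adjustment, by ordinary least squares. Model 1
#' adjusts for age, factory and BMI; model 2 additionally for smoking status
#' (two indicators) and alcohol intake. All features share one design
#' matrix, so the scan is a single QR decomposition followed by matrix
#' products. Collinear covariate columns (e.g. the factory indicator in a
#' single-factory subset) are dropped with a warning.
#'
#' @param features a replicate-averaged, imputed [feature_table()] (natural
#'   log taken internally), or a numeric matrix of ln-intensities (features x
#'   subjects).
#' @param exposure numeric vector of ln-exposure values, aligned with the
#'   feature table's subjects.
#' @param covariates subject table with columns `age`, `factory`, `bmi` and,
#'   for model 2, `smoking` and `alcohol`.
#' @param model `"model1"` (default) or `"model2"`.
#' @return data.frame with one row per feature: `feature_id`, `beta` (per
#'   unit ln-exposure on ln-intensity), `se`, `t`, `p` (two-sided).
#' @export
run_mwas <- function(features, exposure, covariates, model = c("model1", "model2")) {
  model <- match.arg(model)
  if (inherits(features, "feature_table")) {
    Y <- log(subject_matrix(features))
  } else {
    Y <- as.matrix(features)
  }
  if (anyNA(Y)) stop("feature intensities must be complete; impute first")
  n <- ncol(Y)
  stopifnot(length(exposure) == n, nrow(covariates) == n)
  X <- cbind(`(Intercept)` = 1, ln_exposure = exposure,
             age = covariates$age,
             factoryB = as.numeric(covariates$factory == "B"),
             bmi = covariates$bmi)
  if (model == "model2") {
    X <- cbind(X,
               smoking_former = as.numeric(covariates$smoking == "former"),
               smoking_current = as.numeric(covariates$smoking == "current"),
               alcohol = covariates$alcohol)
  }
  # drop collinear columns (never the exposure)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    dropped <- setdiff(colnames(X), colnames(X)[keep])
    if ("ln_exposure" %in% dropped) stop("exposure is collinear with covariates")
    warning("dropping collinear covariate(s): ", paste(dropped, collapse = ", "))
    X <- X[, sort(keep), drop = FALSE]
    qrX <- qr(X)
  }
  p_cov <- ncol(X)
  if (n <= p_cov) stop("more covariates than subjects")
  coefs <- qr.coef(qrX, t(Y))                  # p x nf
  resid <- t(Y) - X %*% coefs
  sigma2 <- colSums(resid^2) / (n - p_cov)
  xtx_inv <- chol2inv(qr.R(qrX))
  j <- which(colnames(X) == "ln_exposure")
  beta <- coefs[j, ]
  se <- sqrt(sigma2 * xtx_inv[j, j])
  tt <- beta / se
  data.frame(
    feature_id = rownames(Y), beta = unname(beta), se = unname(se),
    t = unname(tt), p = unname(2 * stats::pt(-abs(tt), df = n - p_cov)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Benjamini-Hochberg adjustment with significance flags
#'
#' Step-up q-values and the flags used throughout the pipeline
#' (q below the nominal FDR). The family is the set of p-values passed in -
#' by convention all features of one acquisition mode for one exposure.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @param fdr nominal false discovery rate (default 0.20).
#' @return list with `q` (BH-adjusted values) and `flags` (logical).
#' @export
bh_adjust <- function(p, fdr = 0.20) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  q <- stats::p.adjust(p, method = "BH")
  list(q = q, flags = q < fdr)
}

#' Run the MWAS over every exposure and mode
#'
#' Applies [run_mwas()] for each exposure column and each feature table,
#' then adjusts p-values separately per exposure and per mode with
#' [bh_adjust()].
#'
#' @param feature_tables named list of [feature_table()]s (e.g. `C18neg`,
#'   `HILICpos`), replicate-averaged and imputed.
#' @param exposures numeric matrix of ln-exposures, subjects x exposures
#'   (columns named).
#' @param covariates subject table aligned with the feature tables.
#' @param model passed to [run_mwas()].
#' @param fdr nominal FDR (default 0.20).
#' @return data.frame with columns `mode`, `exposure`, `feature_id`, `beta`,
#'   `se`, `t`, `p`, `q`, `significant`.
#' @export
mwas_scan <- function(feature_tables, exposures, covariates,
                      model = "model1", fdr = 0.20) {
  stopifnot(is.list(feature_tables), !is.null(names(feature_tables)))
  out <- list()
  for (mode in names(feature_tables)) {
    ft <- feature_tables[[mode]]
    Y <- if (inherits(ft, "feature_table")) log(subject_matrix(ft)) else as.matrix(ft)
    for (ex in colnames(exposures)) {
      res <- run_mwas(Y, exposures[, ex], covariates, model)
      adj <- bh_adjust(res$p, fdr)
      res$q <- adj$q
      res$significant <- adj$flags
      res <- cbind(mode = mode, exposure = ex, res, stringsAsFactors = FALSE)
      out[[paste(mode, ex)]] <- res
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Aggregate MWAS hits by congener and subclass
#'
#' Reproduces the semantics of the headline summary table: per targeted
#' congener and mode, the number of features significant for the congener
#' itself, the number significant for at least one of its related compounds
#' (`NA` when it has none), and the size of their union; plus, per subclass
#' (PCDD / PCDF / PCB) and mode, the union of significant features over the
#' subclass's congeners and their related compounds.
#'
#' @param scan output of [mwas_scan()]; exposure columns must include the 29
#'   targeted congeners and the selected related compounds (cluster ids).
#' @param related a `related_set` from [spearman_select()].
#' @return list of class `subclass_sets`: `summary` (data.frame congener x
#'   mode counts), `subclass_summary`, and `sets` (nested list
#'   `sets[[mode]][[subclass]]` of feature ids).
#' @export
aggregate_subclass <- function(scan, related) {
  stopifnot(inherits(related, "related_set"))
  panel <- congener_panel()
  modes <- unique(scan$mode)
  sig <- scan[scan$significant, c("mode", "exposure", "feature_id")]
  sig_by <- function(mode, exposures) {
    unique(sig$feature_id[sig$mode == mode & sig$exposure %in% exposures])
  }
  rows <- list(); sets <- list(); sub_rows <- list()
  for (mode in modes) {
    sets[[mode]] <- list()
    for (sc in c("PCDD", "PCDF", "PCB")) {
      congeners <- panel$congener[panel$subclass == sc]
      sc_union <- character()
      for (cg in congeners) {
        targeted <- sig_by(mode, cg)
        rel_comps <- related$by_congener[[cg]]
        if (is.null(rel_comps) || length(rel_comps) == 0L) {
          rel_feats <- NULL
          rel_count <- NA_integer_
        } else {
          rel_feats <- sig_by(mode, rel_comps)
          rel_count <- length(rel_feats)
        }
        tot <- unique(c(targeted, rel_feats))
        sc_union <- unique(c(sc_union, tot))
        rows[[paste(mode, cg)]] <- data.frame(
          mode = mode, subclass = sc, congener = cg,
          targeted = length(targeted), related = rel_count,
          total = length(tot), stringsAsFactors = FALSE)
      }
      sets[[mode]][[sc]] <- sc_union
      sub_rows[[paste(mode, sc)]] <- data.frame(
        mode = mode, subclass = sc, total = length(sc_union),
        stringsAsFactors = FALSE)
    }
  }
  structure(list(
    summary = do.call(rbind, c(rows, list(make.row.names = FALSE))),
    subclass_summary = do.call(rbind, c(sub_rows, list(make.row.names = FALSE))),
    sets = sets
  ), class = "subclass_sets")
}

#' Per-subclass feature lists for pathway enrichment
#'
#' Extracts the three (possibly overlapping) per-mode feature lists -
#' features associated with PCDD(-related), PCDF(-related) and PCB(-related)
#' compounds - that feed the pathway enrichment stage.
#'
#' @param sets a `subclass_sets` from [aggregate_subclass()].
#' @return Nested list `lists[[mode]][[subclass]]` of feature-id vectors.
#' @export
categorize_features <- function(sets) {
  stopifnot(inherits(sets, "subclass_sets"))
  sets$sets
}
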