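#' Isotope constants for chlorine-envelope detection
#'
#' The 37Cl-35Cl mass difference, natural isotopic abundances and the
#' matching tolerances used when linking monoisotopic peaks to their M+2k
#' partners.
#'
#' @param mass_tol absolute m/z tolerance (Da) for isotope spacing matches.
#'   Default 5 mDa, appropriate for Orbitrap GC data at 60,000 resolution
#'   (ppm tolerances behave badly at low m/z).
#' @param ratio_tol maximum relative deviation of an observed peak intensity
#'   from the fitted theoretical envelope (fraction).
#' @return list with `dm_cl`, `p35`, `p37`, `mass_tol`, `ratio_tol`.
#' @export
isotope_constants <- function(mass_tol = 0.005, ratio_tol = 0.30) {
  consts <- list(dm_cl = 1.99705, p35 = 0.7577, p37 = 0.2423,
                 mass_tol = mass_tol, ratio_tol = ratio_tol)
  stopifnot(abs(consts$p35 + consts$p37 - 1) < 1e-4)
  consts
}

#' Theoretical chlorine isotopic envelope
#'
#' Relative abundances of the M+2k isotopologues of a compound with `n_cl`
#' chlorine atoms: the probability of drawing k 37Cl atoms is binomial,
#' `C(n_cl, k) p35^(n_cl-k) p37^k`, and abundances are reported relative to
#' the all-35Cl monoisotopic peak (k = 0).
#'
#' @param n_cl chlorine count, 0 to 10.
#' @param k_max largest isotopologue reported (default 4, i.e. up to M+8).
#' @param consts [isotope_constants()].
#' @return data.frame with columns `k`, `abundance` (monoisotopic = 1) and
#'   `prob` (unnormalized binomial probabilities, summing to at most 1).
#' @export
theoretical_cl_envelope <- function(n_cl, k_max = 4L, consts = isotope_constants()) {
  if (n_cl < 0) stop("n_cl must be nonnegative")
  if (n_cl > 10) stop("n_cl must be at most 10")
  k <- 0:min(k_max, n_cl)
  prob <- choose(n_cl, k) * consts$p35^(n_cl - k) * consts$p37^k
  data.frame(k = k, abundance = prob / prob[1], prob = prob)
}

#' Group co-varying, co-eluting GC-HRMS features into compound spectra
#'
#' Features originating from one compound co-elute and share a common
#' abundance profile across subjects. Pairwise similarity combines a
#' correlation kernel with a retention-time kernel,
#' `s = exp(-(1-r)^2 / (2 sigma_r^2)) * exp(-(rt_i-rt_j)^2 / (2 sigma_rt^2))`
#' (r = Pearson on log intensities), and average-linkage hierarchical
#' clustering on distance `1 - s` is cut at `cut`. Each cluster's abundance
#' is the intensity-weighted mean of its member features per subject, and its
#' peak list is normalized to a maximum relative intensity of 1.
#'
#' @param chem_features a GC-mode [feature_table()] with complete intensities
#'   (run preprocessing first).
#' @param sigma_rt retention-time kernel width, seconds.
#' @param sigma_r correlation kernel width.
#' @param cut dissimilarity cut height in (0, 1).
#' @return list of `spectrum_cluster` objects, each with `cluster_id`,
#'   `feature_ids`, `rt` (intensity-weighted mean), `peaks` (mz, relative
#'   intensity) and `abundance` (named per-subject vector).
#' @export
cluster_spectra <- function(chem_features, sigma_rt = 2.0, sigma_r = 0.5,
                            cut = 0.5) {
  stopifnot(inherits(chem_features, "feature_table"))
  X <- subject_matrix(chem_features)
  if (anyNA(X)) stop("intensities must be complete; run preprocessing first")
  if (nrow(X) < 2L) stop("need at least two features to cluster")
  lX <- log(X)
  vars <- apply(lX, 1, stats::var)
  keep <- vars > 0
  if (any(!keep)) {
    warning(sum(!keep), " zero-variance feature(s) excluded from clustering")
  }
  meta <- chem_features$meta[keep, , drop = FALSE]
  lX <- lX[keep, , drop = FALSE]
  X <- X[keep, , drop = FALSE]
  r <- stats::cor(t(lX))
  drt <- outer(meta$rt, meta$rt, "-")
  s <- exp(-(1 - r)^2 / (2 * sigma_r^2)) * exp(-drt^2 / (2 * sigma_rt^2))
  d <- stats::as.dist(1 - s)
  labels <- if (nrow(meta) == 2L) {
    if (as.numeric(d) <= cut) c(1L, 1L) else 1:2
  } else {
    stats::cutree(stats::hclust(d, method = "average"), h = cut)
  }
  mean_int <- rowMeans(X)
  lapply(sort(unique(labels)), function(g) {
    idx <- which(labels == g)
    w <- mean_int[idx]
    abundance <- colSums(X[idx, , drop = FALSE] * w) / sum(w)
    peaks <- data.frame(
      feature_id = meta$feature_id[idx],
      mz = meta$mz[idx],
      intensity = mean_int[idx] / max(mean_int[idx]),
      stringsAsFactors = FALSE
    )
    peaks <- peaks[order(peaks$mz), , drop = FALSE]
    structure(list(
      cluster_id = sprintf("CL%05d", g),
      feature_ids = meta$feature_id[idx],
      rt = sum(meta$rt[idx] * w) / sum(w),
      peaks = peaks,
      abundance = abundance
    ), class = "spectrum_cluster")
  })
}

#' Detect a chlorine isotopic envelope in a clustered spectrum
#'
#' Every peak with no partner one chlorine spacing below it is a candidate
#' monoisotopic peak. Peaks at `mono + k * dm_cl` (k = 1..4) within the mass
#' tolerance are collected; at least the M+2 peak is required. The chlorine
#' count is fitted by minimizing the summed squared difference between
#' observed and theoretical mono-normalized abundances over n = 1..10 (ties
#' toward smaller n), and the fit is accepted only if every matched peak
#' deviates from its theoretical abundance by at most the ratio tolerance.
#'
#' @param cluster a `spectrum_cluster` from [cluster_spectra()].
#' @param consts [isotope_constants()].
#' @return list with `mono_mz`, `matched` (k, mz, intensity), `n_cl`,
#'   `fit_rss`, or `NULL` when no acceptable envelope exists.
#' @export
detect_chlorine_envelopes <- function(cluster, consts = isotope_constants()) {
  peaks <- cluster$peaks
  if (nrow(peaks) < 2L) return(NULL)
  best <- NULL
  for (i in seq_len(nrow(peaks))) {
    mono <- peaks$mz[i]
    # candidate monoisotopic peak: nothing one Cl spacing below
    if (any(abs(peaks$mz - (mono - consts$dm_cl)) <= consts$mass_tol)) next
    matched <- data.frame(k = 0L, mz = mono, intensity = peaks$intensity[i])
    for (k in 1:4) {
      j <- which(abs(peaks$mz - (mono + k * consts$dm_cl)) <= consts$mass_tol)
      if (length(j)) {
        j <- j[which.min(abs(peaks$mz[j] - (mono + k * consts$dm_cl)))]
        matched <- rbind(matched, data.frame(k = k, mz = peaks$mz[j],
                                             intensity = peaks$intensity[j]))
      }
    }
    if (!any(matched$k == 1L)) next  # M+2 required
    obs <- matched$intensity / matched$intensity[matched$k == 0L]
    fits <- vapply(1:10, function(n) {
      th <- theoretical_cl_envelope(n, consts = consts)
      th_k <- th$abundance[match(matched$k, th$k)]
      th_k[is.na(th_k)] <- 0
      sum((obs - th_k)^2)
    }, numeric(1))
    n_hat <- which.min(fits)  # which.min takes the smallest index on ties
    th <- theoretical_cl_envelope(n_hat, consts = consts)
    th_k <- th$abundance[match(matched$k, th$k)]
    th_k[is.na(th_k)] <- 0
    rel_resid <- abs(obs[-1] - th_k[-1]) / pmax(th_k[-1], .Machine$double.eps)
    if (max(rel_resid) > consts$ratio_tol) next
    cand <- list(mono_mz = mono, matched = matched, n_cl = n_hat,
                 fit_rss = fits[n_hat], n_matched = sum(matched$k > 0))
    if (is.null(best) ||
        cand$n_matched > best$n_matched ||
        (cand$n_matched == best$n_matched && cand$fit_rss < best$fit_rss)) {
      best <- cand
    }
  }
  if (is.null(best)) return(NULL)
  best[c("mono_mz", "matched", "n_cl", "fit_rss")]
}

#' Table of suspected chlorinated compounds
#'
#' Runs envelope detection over all spectrum clusters and reports one row per
#' cluster with an accepted chlorine envelope, together with the matrix of
#' cluster abundances (subjects x suspects) used for correlation screening.
#'
#' @param clusters output of [cluster_spectra()].
#' @param consts [isotope_constants()].
#' @return list with `table` (cluster_id, mono_mz, n_cl, n_peaks, fit_rss)
#'   and `abundance` (subjects x suspects matrix, columns named by
#'   cluster_id).
#' @export
suspect_list <- function(clusters, consts = isotope_constants()) {
  ids <- vapply(clusters, `[[`, character(1), "cluster_id")
  stopifnot(!anyDuplicated(ids))
  rows <- list(); ab <- list()
  for (cl in clusters) {
    env <- detect_chlorine_envelopes(cl, consts)
    if (is.null(env)) next
    rows[[cl$cluster_id]] <- data.frame(
      cluster_id = cl$cluster_id, mono_mz = env$mono_mz, n_cl = env$n_cl,
      n_peaks = nrow(cl$peaks), fit_rss = env$fit_rss,
      stringsAsFactors = FALSE
    )
    ab[[cl$cluster_id]] <- cl$abundance
  }
  if (!length(rows)) {
    return(list(
      table = data.frame(cluster_id = character(), mono_mz = numeric(),
                         n_cl = integer(), n_peaks = integer(),
                         fit_rss = numeric(), stringsAsFactors = FALSE),
      abundance = NULL))
  }
  list(table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       abundance = do.call(cbind, ab))
}
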