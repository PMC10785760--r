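#' Construct a feature table
#'
#' The central container for untargeted mass-spectrometry data: a matrix of
#' feature intensities (features in rows, injections in columns) together with
#' per-feature metadata (m/z, retention time) and per-injection metadata
#' (subject, technical replicate, analytical batch).
#'
#' @param meta data.frame with columns `feature_id` (unique), `mz` (Th) and
#'   `rt` (seconds).
#' @param intensities numeric matrix, rows aligned with `meta`, columns
#'   aligned with `samples`. Missing (non-detected) values are `NA`.
#' @param samples data.frame with columns `sample_id` (unique), `subject_id`,
#'   `replicate` (integer) and `batch`.
#' @param mode acquisition mode, one of `"C18neg"`, `"HILICpos"`, `"GC"`.
#'
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(meta, intensities, samples, mode) {
  mode <- match.arg(mode, c("C18neg", "HILICpos", "GC"))
  stopifnot(
    is.data.frame(meta),
    all(c("feature_id", "mz", "rt") %in% names(meta)),
    !anyDuplicated(meta$feature_id),
    is.matrix(intensities),
    nrow(intensities) == nrow(meta),
    ncol(intensities) == nrow(samples),
    all(c("sample_id", "subject_id", "replicate", "batch") %in% names(samples)),
    !anyDuplicated(samples$sample_id)
  )
  scan_range <- if (mode == "GC") c(85, 850) else c(85, 1275)
  if (nrow(meta) > 0 &&
      (min(meta$mz) < scan_range[1] || max(meta$mz) > scan_range[2])) {
    stop("feature m/z outside the ", mode, " scan range [",
         scan_range[1], ", ", scan_range[2], "]")
  }
  if (nrow(meta) > 0 && any(meta$rt < 0)) stop("retention times must be >= 0")
  ok <- intensities[!is.na(intensities)]
  if (length(ok) && any(ok < 0)) stop("intensities must be nonnegative")
  rownames(intensities) <- meta$feature_id
  colnames(intensities) <- samples$sample_id
  structure(
    list(meta = as.data.frame(meta), intensities = intensities,
         samples = as.data.frame(samples), mode = mode),
    class = "feature_table"
  )
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf(
    "<feature_table> %s: %d features x %d injections (%d subjects, %d batch%s)\n",
    x$mode, nrow(x$meta), ncol(x$intensities),
    length(unique(x$samples$subject_id)),
    length(unique(x$samples$batch)),
    if (length(unique(x$samples$batch)) == 1) "" else "es"
  ))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$intensities)

#' Number of technical replicates per subject in a feature table
#' @param x a [feature_table()].
#' @return Integer, the maximum replicate index.
#' @export
n_replicates <- function(x) {
  stopifnot(inherits(x, "feature_table"))
  if (nrow(x$samples) == 0) return(0L)
  max(x$samples$replicate)
}

#' Per-subject intensity matrix
#'
#' Collapses a feature table to one column per subject. Tables that still
#' carry technical replicates are averaged (ignoring missing injections).
#'
#' @param x a [feature_table()].
#' @return Numeric matrix, features x subjects.
#' @export
subject_matrix <- function(x) {
  stopifnot(inherits(x, "feature_table"))
  subjects <- unique(x$samples$subject_id)
  out <- vapply(subjects, function(s) {
    cols <- which(x$samples$subject_id == s)
    if (length(cols) == 1L) x$intensities[, cols]
    else rowMeans(x$intensities[, cols, drop = FALSE], na.rm = TRUE)
  }, numeric(nrow(x$meta)))
  out[is.nan(out)] <- NA_real_
  if (nrow(x$meta) == 1L) out <- matrix(out, nrow = 1L,
                                        dimnames = list(x$meta$feature_id, subjects))
  else colnames(out) <- subjects
  rownames(out) <- x$meta$feature_id
  out
}

#' The 29 targeted dioxin(-like) congeners
#'
#' Names and subclass membership of the targeted panel: 7 polychlorinated
#' dibenzo-p-dioxins (PCDD), 10 dioxin-like dibenzofurans (PCDF) and 12
#' dioxin-like biphenyls (PCB).
#'
#' @return data.frame with columns `congener` and `subclass`.
#' @export
congener_panel <- function() {
  data.frame(
    congener = c(
      "TCDD", "12378D", "123478D", "123678D", "123789D", "1234678D", "OCDD",
      "2378F", "12378F", "23478F", "123478F", "123678F", "123789F", "234678F",
      "1234678F", "1234789F", "OCDF",
      "PCB77", "PCB81", "PCB126", "PCB169", "PCB105", "PCB114", "PCB118",
      "PCB123", "PCB156", "PCB157", "PCB167", "PCB189"
    ),
    subclass = rep(c("PCDD", "PCDF", "PCB"), times = c(7L, 10L, 12L)),
    stringsAsFactors = FALSE
  )
}

#' Construct a targeted exposure panel
#'
#' Lipid-adjusted congener concentrations (ppt) with below-LOD censoring
#' flags. Censored entries keep a placeholder concentration until
#' [impute_targeted_lod()] replaces them.
#'
#' @param concentrations numeric matrix, subjects x 29 congeners (columns
#'   named as in [congener_panel()]).
#' @param below_lod logical matrix of the same shape flagging censored values.
#' @param lod named numeric vector of per-congener detection limits (ppt).
#'
#' @return An object of class `exposure_panel`.
#' @export
exposure_panel <- function(concentrations, below_lod, lod) {
  panel <- congener_panel()
  stopifnot(
    is.matrix(concentrations),
    identical(colnames(concentrations), panel$congener),
    identical(dim(below_lod), dim(concentrations)),
    identical(names(lod), panel$congener),
    all(concentrations[!is.na(concentrations)] >= 0)
  )
  structure(
    list(concentrations = concentrations,
         below_lod = below_lod,
         lod = lod,
         subclass = stats::setNames(panel$subclass, panel$congener)),
    class = "exposure_panel"
  )
}

#' @export
print.exposure_panel <- function(x, ...) {
  cat(sprintf("<exposure_panel> %d subjects x %d congeners (%d values below LOD)\n",
              nrow(x$concentrations), ncol(x$concentrations),
              sum(x$below_lod)))
  invisible(x)
}
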