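#' Adduct tables for positive and negative electrospray modes
#'
#' The ion forms considered when relating a neutral monoisotopic mass M to an
#' observed m/z. Standard monoisotopic masses are used (proton 1.007276, Na
#' 22.989770, Cl 34.968853, acetonitrile 41.026549, acetic acid 60.021129,
#' water 18.010565).
#'
#' @param mode `"HILICpos"` (positive) or `"C18neg"` (negative).
#' @return data.frame with columns `adduct`, `mult` (multiplier on M),
#'   `offset` (Da) and `charge`; the computed m/z is
#'   `(mult * M + offset) / charge`.
#' @export
adduct_table <- function(mode = c("HILICpos", "C18neg")) {
  mode <- match.arg(mode)
  proton <- 1.007276; na <- 22.989770; cl <- 34.968853
  acn <- 41.026549; hac <- 60.021129; h2o <- 18.010565
  if (mode == "HILICpos") {
    data.frame(
      adduct = c("M+H", "M+2H", "M+ACN+2H", "M+Na", "M+ACN+H", "M+ACN+Na",
                 "2M+H", "M+H+H2O"),
      mult = c(1, 1, 1, 1, 1, 1, 2, 1),
      offset = c(proton, 2 * proton, acn + 2 * proton, na, acn + proton,
                 acn + na, proton, proton + h2o),
      charge = c(1, 2, 2, 1, 1, 1, 1, 1),
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(
      adduct = c("M-H", "M-H2O-H", "M+Na-2H", "M+Cl", "M+Hac-H", "2M-H"),
      mult = c(1, 1, 1, 1, 1, 2),
      offset = c(-proton, -h2o - proton, na - 2 * proton, cl, hac - proton,
                 -proton),
      charge = c(1, 1, 1, 1, 1, 1),
      stringsAsFactors = FALSE
    )
  }
}

#' Annotate features to putative metabolites by adduct mass matching
#'
#' A feature matches a database metabolite when, for some mode-appropriate
#' adduct, the observed m/z is within `ppm` parts per million of the adduct's
#' computed m/z. All qualifying (feature, metabolite, adduct) triples are
#' returned; the mapping is many-to-many by design.
#'
#' @param features a [feature_table()] or a data.frame with `feature_id` and
#'   `mz` columns plus a `mode`.
#' @param db pathway database (data.frame `pathway_id`, `metabolite_id`,
#'   `mass`).
#' @param ppm mass tolerance in parts per million (default 5).
#' @param mode required when `features` is a plain data.frame.
#' @return data.frame with columns `feature_id`, `metabolite_id`, `adduct`,
#'   `ppm_error`.
#' @export
annotate_features <- function(features, db, ppm = 5, mode = NULL) {
  if (inherits(features, "feature_table")) {
    mode <- features$mode
    meta <- features$meta
  } else {
    meta <- features
    if (is.null(mode)) stop("mode must be given for plain feature data")
  }
  if (!mode %in% c("HILICpos", "C18neg")) stop("unknown mode '", mode, "'")
  adducts <- adduct_table(mode)
  mets <- db[!duplicated(db$metabolite_id), c("metabolite_id", "mass")]
  out <- list()
  for (a in seq_len(nrow(adducts))) {
    theo <- (adducts$mult[a] * mets$mass + adducts$offset[a]) / adducts$charge[a]
    ok_theo <- theo > 0
    dm <- outer(meta$mz, theo[ok_theo], "-") /
      rep(theo[ok_theo], each = nrow(meta)) * 1e6
    hits <- which(abs(dm) <= ppm, arr.ind = TRUE)
    if (nrow(hits)) {
      out[[a]] <- data.frame(
        feature_id = meta$feature_id[hits[, 1]],
        metabolite_id = mets$metabolite_id[which(ok_theo)[hits[, 2]]],
        adduct = adducts$adduct[a],
        ppm_error = dm[hits],
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out)) {
    return(data.frame(feature_id = character(), metabolite_id = character(),
                      adduct = character(), ppm_error = numeric(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(res$feature_id, res$metabolite_id, res$adduct), , drop = FALSE]
}

#' Mummichog-style pathway over-representation with a permutation null
#'
#' Significant features are mapped to putative metabolites by adduct mass
#' matching; each pathway's overlap (significant putative metabolites in the
#' pathway) is tested against the detected-metabolite universe with a
#' one-sided hypergeometric test. Because one m/z can map to several
#' metabolites, the hypergeometric p is calibrated by permutation: feature
#' lists of the same size are drawn uniformly from all retained features and
#' the test recomputed, giving
#' `perm_p = (1 + #{fisher_p* <= fisher_p}) / (n_perm + 1)`.
#' A pathway passes when `perm_p < 0.05` and the overlap is at least 4
#' significant putative metabolites.
#'
#' @param sig_features character vector of significant feature ids (subset of
#'   the feature table's features).
#' @param features the retained [feature_table()] (defines the universe).
#' @param db pathway database.
#' @param ppm mass tolerance, ppm.
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed.
#' @param min_overlap minimum overlap for a pass (default 4).
#' @param annotations optional precomputed [annotate_features()] result for
#'   `features` (saves recomputation across subclasses).
#' @param mode passed to [annotate_features()] when `features` is a plain
#'   data.frame (default negative mode).
#' @return data.frame with one row per pathway: `pathway_id`, `overlap`,
#'   `pathway_size` (metabolites of the pathway detected in the data),
#'   `fisher_p`, `perm_p`, `pass`.
#' @export
enrich_pathways <- function(sig_features, features, db, ppm = 5,
                            n_perm = 1000L, seed = 1L, min_overlap = 4L,
                            annotations = NULL, mode = "C18neg") {
  all_ids <- if (inherits(features, "feature_table")) features$meta$feature_id
             else features$feature_id
  if (!all(sig_features %in% all_ids)) {
    stop("sig_features must be a subset of the retained features")
  }
  if (is.null(annotations)) {
    annotations <- annotate_features(features, db, ppm, mode = mode)
  }
  universe <- unique(annotations$metabolite_id)
  if (!length(universe)) stop("empty metabolite universe: no feature annotates")
  pw_pairs <- unique(db[, c("pathway_id", "metabolite_id")])
  pw <- split(pw_pairs$metabolite_id, pw_pairs$pathway_id)
  # index everything into the detected universe so the permutation loop is
  # integer arithmetic only
  pw_idx <- lapply(pw, function(m) match(intersect(m, universe), universe))
  pathway_size <- vapply(pw_idx, length, integer(1))
  feat2met <- split(match(annotations$metabolite_id, universe),
                    annotations$feature_id)
  met_of <- function(feats) {
    unique(unlist(feat2met[as.character(feats)], use.names = FALSE))
  }
  in_universe <- logical(length(universe))
  test_once <- function(sig_idx) {
    n_sig <- length(sig_idx)
    sig <- in_universe
    sig[sig_idx] <- TRUE
    overlap <- vapply(pw_idx, function(ix) sum(sig[ix]), integer(1))
    fisher_p <- stats::phyper(overlap - 1L, pathway_size,
                              length(universe) - pathway_size, n_sig,
                              lower.tail = FALSE)
    list(overlap = overlap, fisher_p = fisher_p)
  }
  obs <- test_once(met_of(sig_features))
  k <- length(sig_features)
  set.seed(as.integer(seed))
  exceed <- rep(0L, length(pw_idx))
  if (k > 0 && n_perm > 0) {
    for (b in seq_len(n_perm)) {
      perm <- test_once(met_of(sample(all_ids, k)))
      exceed <- exceed + (perm$fisher_p <= obs$fisher_p)
    }
  }
  perm_p <- if (k > 0 && n_perm > 0) (1 + exceed) / (n_perm + 1) else
    rep(1, length(pw_idx))
  data.frame(
    pathway_id = names(pw_idx),
    overlap = unname(obs$overlap),
    pathway_size = unname(pathway_size),
    fisher_p = unname(obs$fisher_p),
    perm_p = unname(perm_p),
    pass = unname(perm_p < 0.05 & obs$overlap >= min_overlap),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Pathway enrichment per exposure subclass
#'
#' Runs [enrich_pathways()] once per subclass feature list and acquisition
#' mode, and merges the results with subclass and mode provenance.
#'
#' @param subclass_lists nested list `lists[[mode]][[subclass]]` from
#'   [categorize_features()].
#' @param feature_tables named list of retained [feature_table()]s, names
#'   matching the modes of `subclass_lists`.
#' @param db pathway database.
#' @inheritParams enrich_pathways
#' @return data.frame of [enrich_pathways()] results with extra columns
#'   `subclass` and `mode`.
#' @export
enrich_by_subclass <- function(subclass_lists, feature_tables, db, ppm = 5,
                               n_perm = 1000L, seed = 1L, min_overlap = 4L) {
  out <- list()
  for (mode in names(subclass_lists)) {
    ft <- feature_tables[[mode]]
    ann <- annotate_features(ft, db, ppm)
    for (sc in names(subclass_lists[[mode]])) {
      feats <- subclass_lists[[mode]][[sc]]
      if (!length(feats)) next
      res <- enrich_pathways(feats, ft, db, ppm = ppm, n_perm = n_perm,
                             seed = seed, min_overlap = min_overlap,
                             annotations = ann)
      out[[paste(mode, sc)]] <- cbind(subclass = sc, mode = mode, res,
                                      stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(subclass = character(), mode = character(),
                      pathway_id = character(), overlap = integer(),
                      pathway_size = integer(), fisher_p = numeric(),
                      perm_p = numeric(), pass = logical(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
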