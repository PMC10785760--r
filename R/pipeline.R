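#' Pipeline configuration
#'
#' Bundles the simulation configuration with every stage parameter. One
#' global seed fans out deterministically to the per-stage seeds.
#'
#' @param sim a [sim_config()] describing the synthetic inputs.
#' @param seed global seed; overrides `sim$seed` and seeds every stochastic
#'   stage.
#' @param cv_max,min_detect feature QC thresholds ([filter_features()]).
#' @param p_max related-compound selection threshold ([spearman_select()]).
#' @param fdr MWAS false discovery rate ([mwas_scan()]).
#' @param model MWAS covariate model (`"model1"` or `"model2"`).
#' @param ppm annotation mass tolerance ([annotate_features()]).
#' @param n_perm enrichment permutations ([enrich_pathways()]).
#' @param min_overlap minimum enrichment overlap.
#' @param t_half TCDD half-life in years ([back_extrapolate_tcdd()]).
#' @param sigma_rt,sigma_r,cluster_cut spectral clustering parameters
#'   ([cluster_spectra()]).
#' @param n_comp PLS components ([pls_association()]).
#' @param score_min,assoc_p_max integration edge thresholds.
#' @param integration_factory subject subset for the integration stage
#'   (default `"A"`, the exposed factory).
#' @param outdir optional output directory; when given, every intermediate
#'   table, both networks and the run manifest are written there.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), seed = NULL,
                            cv_max = 1.0, min_detect = 0.6,
                            p_max = 0.002, fdr = 0.20, model = "model1",
                            ppm = 5, n_perm = 1000L, min_overlap = 4L,
                            t_half = 7.1,
                            sigma_rt = 2.0, sigma_r = 0.5, cluster_cut = 0.5,
                            n_comp = 3L, score_min = 0.3, assoc_p_max = 0.05,
                            integration_factory = "A", outdir = NULL) {
  if (!is.null(seed)) sim$seed <- as.integer(seed)
  stopifnot(fdr > 0, fdr < 1, p_max > 0, p_max < 1, ppm > 0,
            cluster_cut > 0, cluster_cut < 1, score_min >= 0, score_min <= 1)
  structure(list(
    sim = sim, seed = sim$seed, cv_max = cv_max, min_detect = min_detect,
    p_max = p_max, fdr = fdr, model = model, ppm = ppm,
    n_perm = as.integer(n_perm), min_overlap = as.integer(min_overlap),
    t_half = t_half, sigma_rt = sigma_rt, sigma_r = sigma_r,
    cluster_cut = cluster_cut, n_comp = as.integer(n_comp),
    score_min = score_min, assoc_p_max = assoc_p_max,
    integration_factory = integration_factory, outdir = outdir
  ), class = "pipeline_config")
}

#' Run the full chemical-wide and metabolome-wide pipeline
#'
#' Executes, in order: synthetic-data generation, targeted-panel LOD
#' imputation, metabolome QC / batch standardization / left-censored
#' imputation, TCDD back-extrapolation, GC-HRMS spectral clustering and
#' chlorine-envelope screening, related-compound selection with the exposure
#' network and its communities, the MWAS over all targeted and related
#' exposures with per-exposure FDR control and subclass aggregation, pathway
#' enrichment per subclass, and PLS integration of pathway scores with the
#' immune markers. Deterministic given the configuration.
#'
#' @param config a [pipeline_config()].
#' @return list of class `pipeline_result` holding every stage output plus a
#'   `manifest` (stages, parameters, seed, row counts). When
#'   `config$outdir` is set, tables and networks are also written to disk.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  manifest <- list(seed = config$seed,
                   parameters = unclass(config)[setdiff(names(config), c("sim", "outdir"))],
                   stages = list())
  note <- function(name, ...) {
    manifest$stages[[name]] <<- list(...)
  }

  sim <- stage("synthetic_cohort", simulate_cohort_data(config$sim))
  note("synthetic_cohort", n_subjects = nrow(sim$subjects),
       n_chem_features = nrow(sim$chem$meta),
       n_c18 = nrow(sim$c18neg$meta), n_hilic = nrow(sim$hilicpos$meta))

  panel <- stage("preprocess", impute_targeted_lod(sim$panel))
  metab <- list()
  for (mode in c("C18neg", "HILICpos")) {
    raw <- if (mode == "C18neg") sim$c18neg else sim$hilicpos
    ft <- stage("preprocess", filter_features(raw, config$cv_max, config$min_detect))
    ft <- stage("preprocess", suppressWarnings(correct_batches(ft)))
    ft <- stage("preprocess", impute_left_censored(ft, seed = config$seed + 11L))
    metab[[mode]] <- ft
  }
  note("preprocess",
       n_retained_c18 = nrow(metab$C18neg$meta),
       n_retained_hilic = nrow(metab$HILICpos$meta),
       n_lod_imputed = sum(sim$panel$below_lod))

  tmax <- stage("kinetics", tcdd_max(panel, sim$subjects, t_half = config$t_half))
  note("kinetics", background = mean(panel$concentrations[sim$subjects$factory == "B", "TCDD"]),
       max_tcdd_max = max(tmax))

  clusters <- stage("chlorine_screen",
                    cluster_spectra(sim$chem, config$sigma_rt, config$sigma_r,
                                    config$cluster_cut))
  suspects <- stage("chlorine_screen", suspect_list(clusters))
  note("chlorine_screen", n_clusters = length(clusters),
       n_suspected = nrow(suspects$table))

  related <- stage("related_compounds",
                   spearman_select(suspects$abundance, panel, config$p_max))
  exp_net <- stage("related_compounds",
                   build_exposure_network(panel, related, suspects$abundance,
                                          config$p_max))
  exp_net <- stage("related_compounds",
                   detect_communities(exp_net, seed = config$seed + 21L))
  note("related_compounds",
       n_related = length(unique(related$pairs$cluster_id)),
       n_pcdd_related = length(related$by_subclass$PCDD),
       n_pcdf_related = length(related$by_subclass$PCDF),
       n_pcb_related = length(related$by_subclass$PCB),
       n_communities = length(unique(igraph::V(exp_net)$community)))

  sel <- unique(related$pairs$cluster_id)
  exposures <- log(cbind(panel$concentrations,
                         if (length(sel)) suspects$abundance[, sel, drop = FALSE]))
  scan <- stage("mwas", mwas_scan(metab, exposures, sim$subjects,
                                  model = config$model, fdr = config$fdr))
  sets <- stage("mwas", aggregate_subclass(scan, related))
  lists <- categorize_features(sets)
  note("mwas", n_tests = nrow(scan), n_significant = sum(scan$significant))

  enr <- stage("pathway_enrichment",
               enrich_by_subclass(lists, metab, sim$pathway_db,
                                  ppm = config$ppm, n_perm = config$n_perm,
                                  seed = config$seed + 31L,
                                  min_overlap = config$min_overlap))
  note("pathway_enrichment", n_enriched = sum(enr$pass))

  integ <- stage("integration", {
    passing <- enr[enr$pass, , drop = FALSE]
    if (nrow(passing)) {
      sig_map <- integration_feature_map(passing, lists, metab,
                                         sim$pathway_db, config$ppm)
      subset_ids <- sim$subjects$subject_id[
        sim$subjects$factory == config$integration_factory]
      pcs <- pathway_pc1_scores(metab, passing, sig_map, subset_ids)
      assoc <- pls_association(pcs$scores,
                               sim$immune$markers[subset_ids, , drop = FALSE],
                               n_comp = config$n_comp,
                               score_min = config$score_min,
                               p_max = config$assoc_p_max)
      net <- suppressWarnings(
        build_integration_network(assoc, sim$immune$categories,
                                  seed = config$seed + 41L))
      list(scores = pcs, assoc = assoc, network = net)
    } else {
      list(scores = NULL, assoc = NULL,
           network = igraph::make_empty_graph(directed = FALSE))
    }
  })
  note("integration",
       n_scored_pathways = if (is.null(integ$scores)) 0L else ncol(integ$scores$scores),
       n_edges = if (is.null(integ$assoc)) 0L else sum(integ$assoc$edges$retained),
       n_communities = if (igraph::vcount(integ$network)) {
         length(unique(igraph::V(integ$network)$community))
       } else 0L)

  result <- structure(list(
    sim = sim, panel = panel, metabolome = metab, tcdd_max = tmax,
    clusters = clusters, suspects = suspects, related = related,
    exposure_network = exp_net, scan = scan, subclass_sets = sets,
    enrichment = enr, integration = integ, manifest = manifest,
    config = config
  ), class = "pipeline_result")
  if (!is.null(config$outdir)) write_pipeline_outputs(result, config$outdir)
  result
}

# significant features annotated to each passing pathway's metabolites
integration_feature_map <- function(passing, lists, metab, db, ppm) {
  out <- list()
  for (mode in names(metab)) {
    ann <- annotate_features(metab[[mode]], db, ppm)
    for (i in seq_len(nrow(passing))) {
      p <- passing$pathway_id[i]
      sc <- if ("subclass" %in% names(passing)) passing$subclass[i] else NULL
      sig <- if (is.null(sc)) unique(unlist(lists[[mode]], use.names = FALSE))
             else lists[[mode]][[sc]]
      mets <- unique(db$metabolite_id[db$pathway_id == p])
      feats <- unique(ann$feature_id[ann$metabolite_id %in% mets &
                                       ann$feature_id %in% sig])
      if (length(feats)) {
        out[[paste(mode, p, i)]] <- data.frame(
          pathway_id = p, feature_id = feats, mode = mode,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(pathway_id = character(), feature_id = character(),
                      mode = character(), stringsAsFactors = FALSE))
  }
  unique(do.call(rbind, c(out, list(make.row.names = FALSE))))
}

#' Write pipeline outputs to a directory
#'
#' Exports every intermediate table as TSV, both networks as GraphML + edge
#' TSV, the subclass and enrichment summary tables, and a JSON run manifest.
#'
#' @param result a `pipeline_result`.
#' @param dir output directory (created if absent).
#' @return Invisibly, the manifest path.
#' @export
write_pipeline_outputs <- function(result, dir) {
  stopifnot(inherits(result, "pipeline_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wtsv <- function(x, name) {
    utils::write.table(x, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  wtsv(result$sim$subjects, "subjects.tsv")
  wtsv(data.frame(subject_id = rownames(result$panel$concentrations),
                  result$panel$concentrations, check.names = FALSE),
       "exposures_imputed.tsv")
  wtsv(data.frame(subject_id = names(result$tcdd_max),
                  tcdd_max = result$tcdd_max), "tcdd_max.tsv")
  wtsv(result$suspects$table, "suspected_chlorinated.tsv")
  wtsv(result$related$pairs, "related_compounds.tsv")
  wtsv(result$scan, "mwas_results.tsv")
  wtsv(result$subclass_sets$summary, "mwas_subclass_summary.tsv")
  wtsv(result$enrichment, "pathway_enrichment.tsv")
  if (!is.null(result$integration$assoc)) {
    wtsv(result$integration$assoc$edges, "integration_edges.tsv")
  }
  export_network(result$exposure_network, file.path(dir, "exposure_network"))
  if (igraph::vcount(result$integration$network) > 0) {
    export_network(result$integration$network,
                   file.path(dir, "integration_network"))
  }
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(result$manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA)
  invisible(manifest_path)
}
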