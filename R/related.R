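#' Spearman correlation with t-approximation p-value
#'
#' Spearman's rank correlation with midranks for ties; the two-sided p-value
#' uses the t approximation `t = r sqrt((n-2)/(1-r^2))` on n-2 degrees of
#' freedom, which is ample at cohort sample sizes (a permutation oracle
#' covers small n in the test suite).
#'
#' @param x,y numeric vectors of equal length.
#' @return list with `rho` and `p`.
#' @export
spearman_test <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L || stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(rho = NA_real_, p = NA_real_))
  }
  rho <- stats::cor(x, y, method = "spearman")
  if (abs(rho) >= 1) return(list(rho = rho, p = 0))
  tt <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * stats::pt(-abs(tt), df = n - 2))
}

#' Select dioxin(-like)-related compounds by positive Spearman correlation
#'
#' A suspected chlorinated compound is "related" to a targeted congener when
#' their abundances correlate positively with a two-sided p-value below
#' `p_max` (default 0.002, corresponding to a 20% false discovery threshold
#' over the screen). Subclass sets (PCDD-, PCDF- and PCB-related) are unions
#' over the congeners of each subclass; a compound may belong to several.
#'
#' @param suspects subjects x suspects abundance matrix (columns named by
#'   cluster id), e.g. `suspect_list()$abundance`.
#' @param panel an [exposure_panel()] (after LOD imputation).
#' @param p_max selection p-value threshold.
#' @param one_sided if `TRUE`, use the one-sided (greater) p-value instead.
#' @return list of class `related_set`: `pairs` (congener, cluster_id, rho,
#'   p), `by_congener` (named list of cluster-id vectors) and `by_subclass`
#'   (named list for PCDD/PCDF/PCB).
#' @export
spearman_select <- function(suspects, panel, p_max = 0.002, one_sided = FALSE) {
  stopifnot(inherits(panel, "exposure_panel"))
  if (is.null(suspects) || ncol(as.matrix(suspects)) == 0L) {
    empty <- list(pairs = data.frame(congener = character(),
                                     cluster_id = character(),
                                     rho = numeric(), p = numeric()),
                  by_congener = list(),
                  by_subclass = list(PCDD = character(), PCDF = character(),
                                     PCB = character()))
    return(structure(empty, class = "related_set"))
  }
  suspects <- as.matrix(suspects)
  if (nrow(suspects) < 10L) stop("need at least 10 subjects")
  stopifnot(nrow(suspects) == nrow(panel$concentrations))
  congeners <- colnames(panel$concentrations)
  rows <- list()
  for (cg in congeners) {
    e <- panel$concentrations[, cg]
    for (cp in colnames(suspects)) {
      st <- spearman_test(suspects[, cp], e)
      if (is.na(st$rho)) {
        warning("constant vector for pair (", cg, ", ", cp, "); skipped")
        next
      }
      p <- if (one_sided) {
        if (st$rho > 0) st$p / 2 else 1 - st$p / 2
      } else st$p
      if (st$rho > 0 && p < p_max) {
        rows[[length(rows) + 1L]] <- data.frame(
          congener = cg, cluster_id = cp, rho = st$rho, p = p,
          stringsAsFactors = FALSE)
      }
    }
  }
  pairs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(congener = character(), cluster_id = character(),
               rho = numeric(), p = numeric(), stringsAsFactors = FALSE)
  by_congener <- lapply(stats::setNames(congeners, congeners), function(cg) {
    unique(pairs$cluster_id[pairs$congener == cg])
  })
  subclass <- panel$subclass
  by_subclass <- lapply(stats::setNames(c("PCDD", "PCDF", "PCB"),
                                        c("PCDD", "PCDF", "PCB")), function(sc) {
    unique(unlist(by_congener[names(subclass)[subclass == sc]], use.names = FALSE))
  })
  structure(list(pairs = pairs, by_congener = by_congener,
                 by_subclass = by_subclass),
            class = "related_set")
}

#' Build the exposure co-correlation network
#'
#' Nodes are the 29 targeted congeners plus every selected related compound;
#' an undirected edge joins any pair (targeted-targeted, targeted-related or
#' related-related) whose Spearman correlation is positive with p below
#' `p_max`, weighted by the correlation.
#'
#' @param panel an [exposure_panel()].
#' @param selected a `related_set` from [spearman_select()].
#' @param suspects the suspect abundance matrix used for selection.
#' @inheritParams spearman_select
#' @return An [igraph::igraph] with vertex attributes `kind`
#'   (`"targeted"`/`"related"`) and `subclass`, and edge attribute `weight`.
#' @export
build_exposure_network <- function(panel, selected, suspects, p_max = 0.002) {
  stopifnot(inherits(panel, "exposure_panel"), inherits(selected, "related_set"))
  sel <- unique(selected$pairs$cluster_id)
  M <- panel$concentrations
  if (length(sel)) M <- cbind(M, as.matrix(suspects)[, sel, drop = FALSE])
  kind <- c(rep("targeted", ncol(panel$concentrations)), rep("related", length(sel)))
  subclass <- c(unname(panel$subclass), rep(NA_character_, length(sel)))
  nodes <- colnames(M)
  edges <- list()
  for (i in seq_len(ncol(M) - 1L)) {
    for (j in (i + 1L):ncol(M)) {
      st <- spearman_test(M[, i], M[, j])
      if (!is.na(st$rho) && st$rho > 0 && st$p < p_max) {
        edges[[length(edges) + 1L]] <- data.frame(
          from = nodes[i], to = nodes[j], weight = st$rho,
          stringsAsFactors = FALSE)
      }
    }
  }
  g <- igraph::graph_from_data_frame(
    if (length(edges)) do.call(rbind, edges) else
      data.frame(from = character(), to = character(), weight = numeric()),
    directed = FALSE,
    vertices = data.frame(name = nodes, kind = kind, subclass = subclass,
                          stringsAsFactors = FALSE)
  )
  g
}

#' Multilevel (Louvain) community detection
#'
#' Weighted modularity maximization with the multilevel algorithm. Vertices
#' are processed in sorted-name order and the random seed is fixed, so the
#' partition is reproducible; labels are relabelled contiguously from 0 in
#' order of first appearance.
#'
#' @param net an [igraph::igraph] (edge attribute `weight` used if present).
#' @param seed integer seed.
#' @return The graph with an integer vertex attribute `community`.
#' @export
detect_communities <- function(net, seed = 1L) {
  stopifnot(igraph::vcount(net) > 0)
  perm <- order(igraph::V(net)$name)
  net_sorted <- igraph::permute(net, order(perm))
  set.seed(as.integer(seed))
  comm <- igraph::cluster_louvain(net_sorted)
  memb <- igraph::membership(comm)
  memb <- memb[igraph::V(net)$name]
  labels <- as.integer(factor(memb, levels = unique(memb))) - 1L
  igraph::set_vertex_attr(net, "community", value = labels)
}

#' Export a network as GraphML and an edge TSV
#'
#' The TSV (columns source, target, weight, community of the source node) is
#' directly loadable in Cytoscape.
#'
#' @param net an [igraph::igraph] with a `community` vertex attribute.
#' @param prefix output path prefix; writes `<prefix>.graphml` and
#'   `<prefix>_edges.tsv`.
#' @return Invisibly, the two file paths.
#' @export
export_network <- function(net, prefix) {
  gml <- paste0(prefix, ".graphml")
  tsv <- paste0(prefix, "_edges.tsv")
  igraph::write_graph(net, gml, format = "graphml")
  el <- igraph::as_data_frame(net, what = "edges")
  memb <- stats::setNames(igraph::V(net)$community, igraph::V(net)$name)
  out <- data.frame(source = el$from, target = el$to,
                    weight = if ("weight" %in% names(el)) el$weight else 1,
                    community = memb[el$from], stringsAsFactors = FALSE)
  utils::write.table(out, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(gml, tsv))
}
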