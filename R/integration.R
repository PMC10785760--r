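#' Summarize enriched pathways as first principal-component scores
#'
#' For each enriched pathway, PCA is run on the standardized ln-intensities
#' of the pathway's significant features over a subject subset (by
#' convention the exposed factory), and the PC1 score is kept as the
#' pathway's per-subject summary. The PC sign is fixed so the loading of
#' largest magnitude is positive; a single-feature pathway's score is the
#' standardized feature itself.
#'
#' @param metabolome named list of [feature_table()]s (replicate-averaged,
#'   imputed), one per mode.
#' @param enriched data.frame from [enrich_by_subclass()] (or
#'   [enrich_pathways()]) restricted to the pathways to score; must carry
#'   `pathway_id` and, if per-mode, `mode`.
#' @param sig_feature_map data.frame linking significant features to
#'   pathways: columns `pathway_id`, `feature_id`, `mode`.
#' @param subjects_subset character vector of subject ids to score.
#' @return list with `scores` (subjects x pathways matrix, column-centered),
#'   `explained` (PC1 variance fraction per pathway) and `loadings` (named
#'   list).
#' @export
pathway_pc1_scores <- function(metabolome, enriched, sig_feature_map,
                               subjects_subset) {
  stopifnot(length(subjects_subset) > 0)
  pw_ids <- unique(enriched$pathway_id)
  lnX <- lapply(metabolome, function(ft) log(subject_matrix(ft)))
  scores <- list(); explained <- numeric(); loadings <- list()
  for (p in pw_ids) {
    rows <- sig_feature_map[sig_feature_map$pathway_id == p, , drop = FALSE]
    Z <- list()
    for (mode in unique(rows$mode)) {
      feats <- intersect(rows$feature_id[rows$mode == mode],
                         rownames(lnX[[mode]]))
      if (length(feats)) {
        Z[[mode]] <- t(lnX[[mode]][feats, subjects_subset, drop = FALSE])
      }
    }
    if (!length(Z)) {
      warning("pathway '", p, "' has no significant features; skipped")
      next
    }
    Z <- do.call(cbind, Z)
    Z <- scale(Z)
    Z[, apply(Z, 2, function(v) anyNA(v))] <- 0  # constant features
    if (ncol(Z) == 1L) {
      v <- 1
      sc <- Z[, 1]
      expl <- 1
    } else {
      pc <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
      v <- pc$rotation[, 1]
      sc <- pc$x[, 1]
      expl <- pc$sdev[1]^2 / sum(pc$sdev^2)
    }
    if (v[which.max(abs(v))] < 0) { v <- -v; sc <- -sc }
    scores[[p]] <- sc
    explained[p] <- expl
    loadings[[p]] <- v
  }
  if (!length(scores)) stop("no pathway could be scored")
  S <- do.call(cbind, scores)
  rownames(S) <- subjects_subset
  S <- sweep(S, 2, colMeans(S))
  list(scores = S, explained = explained, loadings = loadings)
}

# NIPALS PLS2 (regression mode) on pre-standardized matrices.
# Returns orthogonal X-scores T spanning the fitted subspace.
nipals_pls <- function(X, Y, n_comp, tol = 1e-12, max_iter = 500L) {
  n <- nrow(X)
  Tmat <- matrix(0, n, n_comp)
  Xd <- X
  Yd <- Y
  for (h in seq_len(n_comp)) {
    u <- Yd[, which.max(colSums(Yd^2))]
    t_old <- rep(Inf, n)
    for (it in seq_len(max_iter)) {
      w <- crossprod(Xd, u)
      nw <- sqrt(sum(w^2))
      if (nw < tol) return(Tmat[, seq_len(h - 1L), drop = FALSE])
      w <- w / nw
      tt <- Xd %*% w
      cc <- crossprod(Yd, tt) / sum(tt^2)
      u <- Yd %*% cc / sum(cc^2)
      if (sum((tt - t_old)^2) < tol * sum(tt^2)) break
      t_old <- tt
    }
    if (sum(tt^2) < tol) return(Tmat[, seq_len(h - 1L), drop = FALSE])
    pp <- crossprod(Xd, tt) / sum(tt^2)
    Xd <- Xd - tt %*% t(pp)
    Yd <- Yd - tt %*% t(cc)
    Tmat[, h] <- tt
  }
  Tmat
}

#' PLS-based pathway-immune marker association scores
#'
#' Fits a two-block PLS (regression mode, NIPALS) of the standardized immune
#' markers on the standardized pathway PC1 scores, and reconstructs a
#' pairwise association score from the latent components:
#' `score(x_j, y_k) = sum_h cor(x_j, t_h) cor(y_k, t_h)`, where `t_h` are
#' the orthogonal X-scores of the truncated model. The score approximates
#' the pair's correlation coefficient and equals it exactly when the number
#' of components reaches the rank of X. The p-value treats the score as a
#' correlation: `t = s sqrt((n-2)/(1-s^2))` on n-2 df. Edges are retained
#' when `|score| > score_min` and `p < p_max`.
#'
#' @param X subjects x pathways score matrix.
#' @param Y subjects x markers matrix (aligned on subjects).
#' @param n_comp number of PLS components (default 3; reduced with a warning
#'   when it exceeds the data's rank).
#' @param score_min,p_max edge-retention thresholds (defaults 0.3 and 0.05).
#' @return list of class `pls_association`: `score` (pathways x markers
#'   matrix, clipped to `[-1, 1]`), `p` (matching matrix), and `edges`
#'   (data.frame `pathway_id`, `marker_id`, `score`, `p`, `retained`).
#' @export
pls_association <- function(X, Y, n_comp = 3L, score_min = 0.3, p_max = 0.05) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  stopifnot(nrow(X) == nrow(Y))
  n <- nrow(X)
  Xs <- scale(X); Ys <- scale(Y)
  Xs[is.na(Xs)] <- 0; Ys[is.na(Ys)] <- 0
  max_comp <- min(n - 1L, ncol(Xs), ncol(Ys) + ncol(Xs))
  rank_x <- qr(Xs)$rank
  if (n_comp > min(rank_x, max_comp)) {
    n_comp <- min(rank_x, max_comp)
    warning("n_comp reduced to ", n_comp, " (rank limit)")
  }
  Tmat <- nipals_pls(Xs, Ys, n_comp)
  ctx <- suppressWarnings(stats::cor(Xs, Tmat))
  cty <- suppressWarnings(stats::cor(Ys, Tmat))
  ctx[is.na(ctx)] <- 0; cty[is.na(cty)] <- 0
  S <- ctx %*% t(cty)
  S <- pmin(pmax(S, -1), 1)
  tt <- S * sqrt((n - 2) / pmax(1 - S^2, .Machine$double.eps))
  P <- 2 * stats::pt(-abs(tt), df = n - 2)
  dimnames(S) <- dimnames(P) <- list(colnames(X), colnames(Y))
  edges <- data.frame(
    pathway_id = rep(rownames(S), times = ncol(S)),
    marker_id = rep(colnames(S), each = nrow(S)),
    score = as.vector(S), p = as.vector(P), stringsAsFactors = FALSE
  )
  edges$retained <- abs(edges$score) > score_min & edges$p < p_max
  structure(list(score = S, p = P, edges = edges,
                 score_min = score_min, p_max = p_max),
            class = "pls_association")
}

#' Build the pathway-immune marker integration network
#'
#' Bipartite graph over pathways and markers with one edge per retained
#' association (weight = |score|), partitioned with the same multilevel
#' community detection used for the exposure network. Isolated nodes are
#' dropped.
#'
#' @param assoc a `pls_association` (or its `edges` data.frame).
#' @param categories optional named vector of marker categories, stored as a
#'   vertex attribute for styling.
#' @param seed integer seed for community detection.
#' @return An [igraph::igraph] with vertex attributes `kind`
#'   (`"pathway"`/`"marker"`), `category` and `community`; empty graph (with
#'   a warning) when no edge is retained.
#' @export
build_integration_network <- function(assoc, categories = NULL, seed = 1L) {
  edges <- if (inherits(assoc, "pls_association")) assoc$edges else assoc
  kept <- edges[edges$retained, , drop = FALSE]
  if (!nrow(kept)) {
    warning("no retained association edges; returning empty network")
    return(igraph::make_empty_graph(directed = FALSE))
  }
  nodes <- data.frame(
    name = c(unique(kept$pathway_id), unique(kept$marker_id)),
    kind = rep(c("pathway", "marker"),
               c(length(unique(kept$pathway_id)),
                 length(unique(kept$marker_id)))),
    stringsAsFactors = FALSE
  )
  nodes$category <- if (!is.null(categories)) {
    ifelse(nodes$kind == "marker", unname(categories[nodes$name]), "pathway")
  } else nodes$kind
  g <- igraph::graph_from_data_frame(
    data.frame(from = kept$pathway_id, to = kept$marker_id,
               weight = abs(kept$score), score = kept$score, p = kept$p,
               stringsAsFactors = FALSE),
    directed = FALSE, vertices = nodes
  )
  detect_communities(g, seed = seed)
}
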