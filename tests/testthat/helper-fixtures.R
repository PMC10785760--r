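# Shared fixtures built in code.

# Minimal replicate-bearing feature table: nf features x ns subjects x nrep
# replicates, values supplied on the log scale.
make_ft <- function(lnY, nrep = 3L, mode = "C18neg", batches = NULL,
                    rep_sd = 0, seed = 42L) {
  set.seed(seed)
  nf <- nrow(lnY); ns <- ncol(lnY)
  subjects <- sprintf("S%02d", seq_len(ns))
  if (is.null(batches)) batches <- rep("b1", ns)
  samp <- data.frame(
    sample_id = paste0(rep(subjects, each = nrep), "_r", seq_len(nrep)),
    subject_id = rep(subjects, each = nrep),
    replicate = rep(seq_len(nrep), times = ns),
    batch = rep(batches, each = nrep),
    stringsAsFactors = FALSE
  )
  X <- matrix(NA_real_, nf, ns * nrep)
  for (r in seq_len(nrep)) {
    cols <- which(samp$replicate == r)
    X[, cols] <- lnY + matrix(rnorm(nf * ns, 0, rep_sd), nf, ns)
  }
  meta <- data.frame(
    feature_id = sprintf("F%03d", seq_len(nf)),
    mz = seq(100, 200, length.out = nf),
    rt = seq(30, 300, length.out = nf)
  )
  feature_table(meta, exp(X), samp, mode = mode)
}

# A small exposure panel with given concentration matrix filled into the
# 29-congener layout (unspecified congeners get independent log-normals).
make_panel <- function(n, seed = 1L, lod_frac = 0) {
  set.seed(seed)
  cong <- congener_panel()$congener
  conc <- matrix(rlnorm(n * length(cong)), n, length(cong),
                 dimnames = list(sprintf("S%02d", seq_len(n)), cong))
  lod <- setNames(as.numeric(quantile(conc[, 1], lod_frac)) * rep(1, length(cong)),
                  cong)
  if (lod_frac == 0) lod[] <- 0
  below <- sweep(conc, 2, lod, "<")
  exposure_panel(conc, below, lod)
}

# Exhaustive Benjamini-Hochberg step-up oracle: q_i = min_{j : p_(j) >= p_i}
# of m p_(j) / j, computed directly from the definition.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(vapply(i:m, function(j) m * p[o[j]] / j, numeric(1)), 1)
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Permutation p-value oracle for the two-sided Spearman test.
spearman_perm_p <- function(x, y, n_perm = 1e4, seed = 1L) {
  set.seed(seed)
  obs <- abs(cor(x, y, method = "spearman"))
  hits <- 0L
  for (b in seq_len(n_perm)) {
    if (abs(cor(x, sample(y), method = "spearman")) >= obs - 1e-12) {
      hits <- hits + 1L
    }
  }
  (hits + 1) / (n_perm + 1)
}

# Tiny deterministic spectrum cluster for envelope tests.
make_cluster <- function(mzs, intensities, id = "CL00001") {
  structure(list(
    cluster_id = id,
    feature_ids = sprintf("F%02d", seq_along(mzs)),
    rt = 100,
    peaks = data.frame(feature_id = sprintf("F%02d", seq_along(mzs)),
                       mz = mzs, intensity = intensities / max(intensities)),
    abundance = setNames(rep(1, 3), c("S01", "S02", "S03"))
  ), class = "spectrum_cluster")
}
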