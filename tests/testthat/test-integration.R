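make_lc_table <- function(lnY, mode = "C18neg") {
  ns <- ncol(lnY)
  samp <- data.frame(sample_id = sprintf("S%02d", 1:ns),
                     subject_id = sprintf("S%02d", 1:ns),
                     replicate = 1L, batch = "b1")
  meta <- data.frame(feature_id = rownames(lnY),
                     mz = seq(100, 400, length.out = nrow(lnY)),
                     rt = seq(30, 300, length.out = nrow(lnY)))
  feature_table(meta, exp(lnY), samp, mode)
}

test_that("pathway PC1 scores match eigen-decomposition and handle rank-1 cases", {
  set.seed(71)
  ns <- 40
  lnY <- matrix(rnorm(7 * ns, 10), 7,
                dimnames = list(sprintf("f%d", 1:7), NULL))
  lnY[2, ] <- lnY[1, ] * 0.5 + 3      # perfectly correlated pair
  ft <- make_lc_table(lnY)
  subjects <- sprintf("S%02d", 1:ns)
  enriched <- data.frame(pathway_id = c("single", "pair", "five"))
  map <- data.frame(
    pathway_id = c("single", "pair", "pair", rep("five", 5)),
    feature_id = c("f1", "f1", "f2", sprintf("f%d", 3:7)),
    mode = "C18neg"
  )
  pcs <- pathway_pc1_scores(list(C18neg = ft), enriched, map, subjects)
  # single-feature pathway: the standardized feature (sign convention fixed)
  z <- as.numeric(scale(log(exp(lnY[1, ]))))
  expect_equal(unname(pcs$scores[, "single"]), z, tolerance = 1e-8)
  # two perfectly correlated features: PC1 explains everything
  expect_equal(unname(pcs$explained["pair"]), 1, tolerance = 1e-12)
  # PC1 equals the leading eigenvector route, up to sign
  Z <- scale(t(lnY[3:7, ]))
  eig <- eigen(cov(Z))
  ref <- as.numeric(Z %*% eig$vectors[, 1])
  got <- unname(pcs$scores[, "five"])
  expect_equal(abs(got), abs(ref), tolerance = 1e-8)
  expect_equal(unname(pcs$explained["five"]),
               eig$values[1] / sum(eig$values), tolerance = 1e-8)
  # sign convention: largest-|loading| entry positive
  expect_gt(pcs$loadings$five[which.max(abs(pcs$loadings$five))], 0)
  # scores column-centered
  expect_lt(max(abs(colMeans(pcs$scores))), 1e-10)
})

test_that("PC1 scores are invariant to feature ordering", {
  set.seed(72)
  lnY <- matrix(rnorm(5 * 30, 10), 5, dimnames = list(sprintf("f%d", 1:5), NULL))
  ft <- make_lc_table(lnY)
  subjects <- sprintf("S%02d", 1:30)
  m1 <- data.frame(pathway_id = "p", feature_id = sprintf("f%d", 1:5),
                   mode = "C18neg")
  m2 <- m1[5:1, ]
  p1 <- pathway_pc1_scores(list(C18neg = ft), data.frame(pathway_id = "p"),
                           m1, subjects)
  p2 <- pathway_pc1_scores(list(C18neg = ft), data.frame(pathway_id = "p"),
                           m2, subjects)
  expect_equal(p1$scores, p2$scores, tolerance = 1e-10)
})

test_that("single-pair PLS association equals the Pearson correlation", {
  set.seed(73)
  for (i in 1:100) {
    n <- sample(20:80, 1)
    x <- matrix(rnorm(n), dimnames = list(NULL, "x"))
    y <- matrix(0.5 * x + rnorm(n), dimnames = list(NULL, "y"))
    a <- pls_association(x, y, n_comp = 1)
    expect_equal(unname(a$score[1, 1]), cor(x, y)[1, 1], tolerance = 1e-6)
  }
  # identical columns: score 1 and a retained edge
  x <- matrix(rnorm(30), dimnames = list(NULL, "x"))
  a <- pls_association(x, x, n_comp = 1)
  expect_equal(unname(a$score[1, 1]), 1, tolerance = 1e-10)
  expect_true(a$edges$retained)
})

test_that("full-rank association scores equal the cross-correlation matrix", {
  set.seed(74)
  n <- 76
  X <- matrix(rnorm(n * 5), n, dimnames = list(NULL, sprintf("p%d", 1:5)))
  Y <- matrix(rnorm(n * 8), n, dimnames = list(NULL, sprintf("m%d", 1:8)))
  Y[, 1] <- 0.7 * X[, 1] + 0.3 * rnorm(n)
  a <- pls_association(X, Y, n_comp = 5)
  expect_equal(a$score, cor(X, Y), tolerance = 1e-6)
  # requesting more components than the rank warns and reduces
  expect_warning(pls_association(X[, 1, drop = FALSE], Y, n_comp = 3),
                 "reduced")
})

test_that("PLS association agrees with the mixOmics implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(75)
  n <- 40
  X <- matrix(rnorm(n * 4), n, dimnames = list(NULL, sprintf("p%d", 1:4)))
  Y <- matrix(rnorm(n * 6), n, dimnames = list(NULL, sprintf("m%d", 1:6)))
  Y[, 2] <- 0.8 * X[, 3] + 0.2 * rnorm(n)
  a <- pls_association(X, Y, n_comp = 2)
  fit <- mixOmics::pls(X, Y, ncomp = 2, mode = "regression")
  Tm <- fit$variates$X
  ref <- cor(scale(X), Tm) %*% t(cor(scale(Y), Tm))
  expect_equal(unname(a$score), unname(ref), tolerance = 1e-6)
})

test_that("edge retention shrinks monotonically as the threshold rises", {
  set.seed(76)
  n <- 50
  X <- matrix(rnorm(n * 4), n, dimnames = list(NULL, sprintf("p%d", 1:4)))
  Y <- matrix(rnorm(n * 6) + 0.4 * X[, 1], n,
              dimnames = list(NULL, sprintf("m%d", 1:6)))
  counts <- vapply(c(0.1, 0.3, 0.5, 0.7), function(thr) {
    sum(pls_association(X, Y, n_comp = 3, score_min = thr)$edges$retained)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("the integration network recovers planted latent factors", {
  set.seed(77)
  n <- 76
  recovered <- vapply(1:10, function(s) {
    set.seed(s)
    f1 <- rnorm(n); f2 <- rnorm(n)
    X <- cbind(p1 = f1 + 0.3 * rnorm(n), p2 = f1 + 0.3 * rnorm(n),
               p3 = f1 + 0.3 * rnorm(n), p4 = f2 + 0.3 * rnorm(n),
               p5 = f2 + 0.3 * rnorm(n), p6 = f2 + 0.3 * rnorm(n))
    Y <- cbind(m1 = f1 + 0.5 * rnorm(n), m2 = f1 + 0.5 * rnorm(n),
               m3 = f1 + 0.5 * rnorm(n), m4 = f2 + 0.5 * rnorm(n),
               m5 = f2 + 0.5 * rnorm(n), m6 = f2 + 0.5 * rnorm(n))
    a <- pls_association(X, Y, n_comp = 3)
    g <- build_integration_network(a, seed = 1)
    memb <- setNames(igraph::V(g)$community, igraph::V(g)$name)
    blocks <- list(c("p1", "p2", "p3", "m1", "m2", "m3"),
                   c("p4", "p5", "p6", "m4", "m5", "m6"))
    ok <- all(vapply(blocks, function(b) {
      b <- intersect(b, names(memb))
      length(unique(memb[b])) == 1
    }, logical(1))) && length(unique(memb)) == 2
    ok
  }, logical(1))
  expect_gte(mean(recovered), 0.9)
})

test_that("integration network is deterministic and handles empty edge sets", {
  set.seed(78)
  n <- 40
  X <- matrix(rnorm(n * 3), n, dimnames = list(NULL, sprintf("p%d", 1:3)))
  Y <- matrix(rnorm(n * 4) + 0.8 * X[, 1], n,
              dimnames = list(NULL, sprintf("m%d", 1:4)))
  a <- pls_association(X, Y, n_comp = 2)
  g1 <- build_integration_network(a, seed = 3)
  a2 <- a
  a2$edges <- a2$edges[sample(nrow(a2$edges)), ]
  g2 <- build_integration_network(a2, seed = 3)
  m1 <- setNames(igraph::V(g1)$community, igraph::V(g1)$name)
  m2 <- setNames(igraph::V(g2)$community, igraph::V(g2)$name)
  expect_equal(m1, m2[names(m1)])
  none <- a
  none$edges$retained <- FALSE
  expect_warning(g0 <- build_integration_network(none, seed = 1),
                 "no retained")
  expect_equal(igraph::vcount(g0), 0)
})
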