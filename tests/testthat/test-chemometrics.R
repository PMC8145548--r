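test_that("autoscaling centers, scales, drops constants and is idempotent", {
  set.seed(2)
  X <- matrix(rnorm(60, mean = 5, sd = 3), 10, 6)
  Xs <- autoscale(X)
  expect_equal(colMeans(Xs), rep(0, 6), tolerance = 1e-12)
  expect_equal(apply(Xs, 2, sd), rep(1, 6), tolerance = 1e-12)
  expect_equal(unclass(autoscale(Xs)), unclass(Xs), tolerance = 1e-12,
               ignore_attr = TRUE)
  X2 <- cbind(X, constant = 7)
  expect_warning(Xs2 <- autoscale(X2), "zero-variance")
  expect_equal(ncol(Xs2), 6L)
})

test_that("PCA explained variance and orthogonality invariants hold", {
  set.seed(8)
  # rank-1 structure: PC1 carries everything
  v <- rnorm(12)
  X1 <- outer(seq_len(6), v) + matrix(rnorm(72, sd = 1e-9), 6, 12)
  p1 <- pca_features(X1)
  expect_equal(p1$ev_pct[1], 100, tolerance = 1e-6)
  # full-rank: EV% sums to 100 (trace conservation)
  X <- matrix(rnorm(8 * 5), 8, 5)
  p <- pca_features(X)
  expect_equal(sum(p$ev_pct), 100, tolerance = 1e-8)
  expect_true(all(diff(p$ev_pct) <= 1e-12))
  # score vectors mutually orthogonal
  G <- crossprod(p$scores)
  expect_equal(G[upper.tri(G)], rep(0, sum(upper.tri(G))), tolerance = 1e-8)
  # scores * loadings' reconstructs the autoscaled matrix at full rank
  expect_equal(p$scores %*% t(p$loadings), unclass(autoscale(X)),
               tolerance = 1e-8, ignore_attr = TRUE)
  # deterministic sign convention
  expect_equal(p$loadings, pca_features(X)$loadings)
})

test_that("planted group effects separate cultivars in PC1-PC2", {
  spec <- cohort_spec(seed = 13,
                      planted = planted_effect_df(c(3, 10, 17, 35, 39, 46)),
                      n_decoys = 30)
  sim <- simulate_cohort(spec)
  ft <- sim$feature_table
  bio <- ft$groups != "QC"
  # the genotype PCA runs on the annotated compounds, not on decoy features
  planted_rows <- sim$truth$feature[sim$truth$type == "planted"]
  p <- pca_features(t(ft$intensities[planted_rows, bio]))
  sil <- mean_silhouette(p$scores[, 1:2], as.character(ft$groups[bio]))
  expect_gt(sil, 0.5)
})

test_that("pooled QCs sit near the origin of score space", {
  spec <- cohort_spec(seed = 19,
                      planted = planted_effect_df(c(3, 10, 17, 35, 39, 46)),
                      n_decoys = 30)
  sim <- simulate_cohort(spec)
  ft <- sim$feature_table
  p <- pca_features(t(ft$intensities))
  qc <- qc_proximity(p$scores, ft$groups == "QC")
  expect_true(qc$pass)
  # QC scores exactly at the origin give ratio 0
  sc <- rbind(c(0, 0), c(0, 0), c(3, 1), c(-2, 2))
  expect_equal(qc_proximity(sc, c(TRUE, TRUE, FALSE, FALSE))$ratio, 0)
  # QCs coinciding with an extreme group fail
  sc2 <- rbind(matrix(5, 2, 2), matrix(c(-1, 1, -1, 1), 2, 2))
  expect_false(qc_proximity(sc2, c(TRUE, TRUE, FALSE, FALSE))$pass)
  expect_error(qc_proximity(sc, c(TRUE, FALSE, FALSE, FALSE)), "QC")
})

test_that("PPMC matches direct correlation algebra and flags significance", {
  set.seed(44)
  pom <- matrix(rnorm(12 * 5), 12, 5,
                dimnames = list(NULL, c("L", "a", "b", "TSS", "TA")))
  feats <- cbind(f1 = pom[, "L"],                      # r = 1
                 f2 = -2 * pom[, "TA"] + 3,            # r = -1
                 f3 = rnorm(12))
  r <- ppmc(feats, pom)
  expect_equal(r$r["f1", "L"], 1)
  expect_equal(r$r["f2", "TA"], -1)
  expect_true(r$significant["f1", "L"])
  # brute-force covariance / (sigma sigma) agreement
  brute <- cov(feats[, "f3"], pom[, "b"]) /
    (sd(feats[, "f3"]) * sd(pom[, "b"]))
  expect_equal(r$r["f3", "b"], brute, tolerance = 1e-12)
  expect_true(all(abs(r$r) <= 1 + 1e-12))
})

test_that("flavanol-like planted features correlate positively with brightness", {
  # flavanols are a trait of the bright yellow cultivar: plant G-dominant folds
  planted <- data.frame(peak = c(10, 14, 20, 25),
                        GA = 2, T = 2, G = 32, J = 1)
  spec <- cohort_spec(seed = 29, planted = planted, n_decoys = 10)
  sim <- simulate_cohort(spec)
  ft <- sim$feature_table
  bio <- ft$groups != "QC"
  feats <- t(ft$intensities[paste0("P", planted$peak), bio])
  pom <- as.matrix(sim$pomology[, c("L", "a", "b", "TSS", "TA")])
  r <- ppmc(feats, pom)
  expect_true(all(r$r[, "L"] > 0))
  expect_true(any(r$significant[, "L"]))
})

test_that("pomology group test reproduces the cultivar letter structure", {
  # identical groups share a letter
  pom0 <- data.frame(cultivar = rep(c("A", "B", "C"), each = 3),
                     x = rep(c(1, 1, 1), each = 3) + rep(c(0.01, 0, -0.01), 3))
  g0 <- pomology_group_test(pom0)
  expect_equal(length(unique(g0$x$letters)), 1L)
  # GA vs T drawn from the reference means/RSDs share CIELAB letters
  set.seed(3)
  ref <- pomology_reference()
  draw <- function(cv, n = 3) {
    rows <- ref[ref$cultivar == cv, ]
    out <- as.data.frame(sapply(seq_len(nrow(rows)), function(j)
      rnorm(n, rows$mean[j], rows$mean[j] * rows$rsd[j] / 100)))
    names(out) <- rows$parameter
    cbind(cultivar = cv, out)
  }
  pom <- rbind(draw("GA"), draw("T"))
  g <- pomology_group_test(pom)
  for (pm in c("L", "a", "b"))
    expect_identical(g[[pm]]$letters[["GA"]], g[[pm]]$letters[["T"]])
  # fully separated groups at n = 6 receive distinct letters
  pom2 <- data.frame(cultivar = rep(c("A", "B", "C"), each = 6),
                     x = c(rnorm(6, 0, 0.1), rnorm(6, 50, 0.1),
                           rnorm(6, 100, 0.1)))
  g2 <- pomology_group_test(pom2)
  expect_equal(length(unique(g2$x$letters)), 3L)
})
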