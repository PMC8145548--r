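test_that("coefficient of variation handles the degenerate cases", {
  expect_equal(coefficient_of_variation(c(5, 5, 5)), 0)
  expect_equal(coefficient_of_variation(c(1, 2, 3)), 0.5)
  expect_true(is.na(coefficient_of_variation(c(0, 0, 0))))
  expect_error(coefficient_of_variation(3))
})

test_that("Kruskal-Wallis reproduces the hand-computed statistic", {
  kw <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
  expect_equal(kw$H, 7.2)
  expect_equal(kw$df, 2L)
  all_same <- kruskal_wallis(list(c(2, 2), c(2, 2), c(2, 2)))
  expect_equal(all_same$H, 0)
  expect_equal(all_same$p, 1)
  expect_error(kruskal_wallis(list(1:3, numeric(0))), "observations")
})

test_that("Kruskal-Wallis agrees with the stats reference implementation", {
  set.seed(31)
  for (i in 1:10) {
    g <- lapply(sample(3:5, 3, replace = TRUE), function(n) rnorm(n))
    if (i %% 2 == 0) g[[1]][1] <- g[[2]][1]  # force a tie
    kw <- kruskal_wallis(g)
    ref <- stats::kruskal.test(unlist(g),
                               rep(seq_along(g), lengths(g)))
    expect_equal(kw$H, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(kw$p, ref$p.value, tolerance = 1e-12)
  }
})

test_that("chi-square Kruskal-Wallis p tracks exact enumeration at tiny n", {
  set.seed(17)
  for (i in 1:10) {
    g <- list(rnorm(4), rnorm(4) + runif(1, 0.5, 2.5))
    exact <- kruskal_wallis(g, method = "exact")
    approx <- kruskal_wallis(g, method = "chisq")
    # the approximation is accurate where decisions are made (small p) and
    # never wildly off elsewhere
    if (exact$p < 0.1) expect_lt(abs(exact$p - approx$p), 0.02)
    expect_lt(abs(exact$p - approx$p), 0.2)
  }
})

test_that("rank tests are invariant under strictly monotone transforms", {
  set.seed(12)
  g <- list(rnorm(4), rnorm(4) + 0.5, rnorm(4) + 1)
  for (f in list(exp, function(x) x^3, function(x) 5 * x - 2)) {
    gt <- lapply(g, f)
    expect_equal(kruskal_wallis(g)$H, kruskal_wallis(gt)$H)
    expect_equal(dscf(g)$p, dscf(gt)$p)
  }
})

test_that("DSCF pairwise p-values behave on constructed groups", {
  # identical groups: statistic 0, p = 1
  g <- list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3))
  d <- dscf(g)
  expect_true(all(d$W == 0))
  expect_true(all(d$p == 1))
  # increasing separation: the nearer pair is never more significant
  g2 <- list(a = c(0, 1, 2), b = c(3, 4, 5), c = c(30, 40, 50))
  d2 <- dscf(g2, method = "asymptotic")
  p_near <- d2$p[d2$group1 == "a" & d2$group2 == "b"]
  p_far <- d2$p[d2$group1 == "a" & d2$group2 == "c"]
  expect_gte(p_near, p_far)
  # two identical groups plus one shifted by 100x the noise scale, n = 3
  set.seed(4)
  noise <- rnorm(9, sd = 0.1)
  g3 <- list(a = 10 + noise[1:3], b = 10 + noise[4:6], c = 20 + noise[7:9])
  d3 <- dscf(g3)
  expect_lt(d3$p[d3$group1 == "a" & d3$group2 == "c"], 0.2)
  expect_lt(d3$p[d3$group1 == "b" & d3$group2 == "c"], 0.2)
  expect_gt(d3$p[d3$group1 == "a" & d3$group2 == "b"], 0.2)
  expect_error(dscf(g[1:2]), "k >= 3")
})

test_that("DSCF is symmetric in pair order", {
  set.seed(9)
  g <- list(a = rnorm(4), b = rnorm(4) + 1, c = rnorm(4) + 2)
  d <- dscf(g)
  drev <- dscf(rev(g))
  for (i in seq_len(nrow(d))) {
    j <- which((drev$group1 == d$group1[i] & drev$group2 == d$group2[i]) |
               (drev$group1 == d$group2[i] & drev$group2 == d$group1[i]))
    expect_equal(d$p[i], drev$p[j])
  }
})

test_that("exact DSCF matches the independent enumeration oracle", {
  set.seed(23)
  for (rep in 1:6) {
    sizes <- sample(2:4, 3, replace = TRUE)
    g <- lapply(sizes, function(n) round(rnorm(n), 1))  # induce ties too
    d <- dscf(g, method = "exact")
    prs <- utils::combn(3, 2)
    for (c0 in seq_len(ncol(prs))) {
      oracle <- dscf_exact_oracle(g[[prs[1, c0]]], g[[prs[2, c0]]])
      expect_equal(d$W[c0], oracle$wstar, tolerance = 1e-12)
      expect_equal(d$p[c0], oracle$p, tolerance = 1e-12)
    }
  }
})

sim_table <- function(seed, n_null = 100, n_eff = 20, bio_cv = 0.2,
                      qc_cv = 0.05) {
  set.seed(seed)
  groups <- c("GA", "T", "G", "J")
  glab <- c(rep(groups, each = 3), rep("QC", 3))
  fold <- effect_folds()
  n <- n_null + n_eff
  mu <- matrix(1e5, n, 4, dimnames = list(NULL, groups))
  if (n_eff > 0)
    mu[seq_len(n_eff), ] <- 1e5 * matrix(fold[groups], n_eff, 4, byrow = TRUE)
  X <- matrix(0, n, length(glab))
  for (s in seq_along(glab)) {
    cv <- if (glab[s] == "QC") qc_cv else bio_cv
    m <- if (glab[s] == "QC") rowMeans(mu) else mu[, glab[s]]
    sdl <- sqrt(log(1 + cv^2))
    X[, s] <- rlnorm(n, log(m) - sdl^2 / 2, sdl)
  }
  rownames(X) <- paste0("F", seq_len(n))
  feature_table(X, glab)
}

test_that("the cascade recovers planted effect features with high power", {
  sel <- select_features(sim_table(101))
  sc <- attr(sel, "stage_counts")
  expect_gte(sum(sel$selected[1:20]), 16)
  # stage counts shrink monotonically
  expect_true(all(diff(sc[c("stage1", "stage2", "stage3")]) <= 0))
  expect_lte(sc["selected"], sc["stage3"])
})

test_that("a constant feature fails the CV stage", {
  ft <- sim_table(7, n_null = 5, n_eff = 0)
  ft$intensities[1, ] <- 42
  sel <- select_features(ft)
  expect_false(sel$stage1[1])
  expect_false(sel$selected[1])
  # all-zero intensities have no defined CV either
  ft$intensities[2, ] <- 0
  sel2 <- select_features(ft)
  expect_false(sel2$stage1[2])
})

test_that("null tables are selected at no more than the nominal KW rate", {
  rates <- vapply(1:25, function(i) {
    sel <- select_features(sim_table(1000 + i, n_null = 40, n_eff = 0))
    mean(sel$selected)
  }, numeric(1))
  phat <- mean(rates)
  se <- sqrt(0.02 * 0.98 / (25 * 40))
  expect_lte(phat, 0.02 + 2 * se)
})

test_that("the MS2 spectral-quality gate drops spectra-poor features", {
  ft <- sim_table(55, n_null = 0, n_eff = 3)
  ms2 <- list(F1 = data.frame(mz = c(100, 200), intensity = c(1, 1)),
              F2 = data.frame(mz = 100, intensity = 1))  # single peak: fails
  sel <- select_features(ft, ms2 = ms2)
  expect_true(sel$ms2_ok[1])
  expect_false(sel$ms2_ok[2])   # one-peak spectrum
  expect_false(sel$ms2_ok[3])   # no spectrum at all
  expect_false(sel$selected[2])
})
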