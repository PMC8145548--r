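kb <- load_knowledge_base()

test_that("precursor matching honors polarity, tolerance and charge state", {
  m <- match_precursor(353.0884, "negative", kb)
  expect_identical(m$name[1], "Chlorogenic acid")
  expect_equal(round(m$delta_ppm[1], 1), 1.7)
  # doubly charged feature only matches 2- records
  m2 <- match_precursor(934.0796, "negative", kb, charge = 2)
  expect_true(all(grepl("Sanguiin H-6", m2$name)))
  expect_equal(nrow(match_precursor(999.999, "negative", kb)), 0L)
  # charge mismatch excludes: 1- feature at an ellagitannin 2- m/z
  expect_equal(nrow(match_precursor(934.0796, "negative", kb, charge = 1)), 0L)
})

test_that("fragment explanation finds loss chains and diagnostic ions", {
  rec <- kb[kb$peak == 57, ]  # cyanidin-3-O-rutinoside, [M]+ 595.1663
  sp <- data.frame(mz = c(449.1072, 287.0689), intensity = c(40, 100))
  ex <- explain_fragments(sp, rec)
  expect_false(any(ex$explanation == "unexplained"))
  expect_match(ex$detail[1], "deoxyhexose")
  rec39 <- kb[kb$peak == 39, ]  # quercetin-3-O-rutinoside, [M-H]- 609.1461
  ex39 <- explain_fragments(data.frame(mz = 301.0351, intensity = 100), rec39)
  expect_true(ex39$explanation %in% c("diagnostic", "loss chain"))
  # fragment equal to the precursor: trivial empty chain
  ex_self <- explain_fragments(
    data.frame(mz = rec39$reference_mz, intensity = 100), rec39)
  expect_identical(ex_self$explanation, "precursor")
})

test_that("doubly charged precursors deconvolute to mono-charged fragment space", {
  rec <- kb[kb$peak == 24, ]  # sanguiin H-2, [M-2H]2-
  # ellagic acid and gallic acid fragments are mono-charged diagnostics
  sp <- data.frame(mz = c(300.9998, 169.0133), intensity = c(100, 20))
  ex <- explain_fragments(sp, rec)
  expect_true(all(ex$explanation == "diagnostic"))
})

kb_feature <- function(peak) {
  r <- kb[kb$peak == peak, ]
  fr <- r$fragments[[1]]
  list(feature = list(feature = peak, mz = r$reference_mz, rt = r$rt,
                      polarity = r$polarity, charge = r$charge),
       spectrum = if (nrow(fr)) data.frame(mz = fr$mz,
                                           intensity = ifelse(fr$base, 100, 50),
                                           charge = fr$charge) else NULL)
}

test_that("level assignment follows the MSI-style evidence rules", {
  g <- kb_feature(1)   # gallic acid: standard available, tR match, clean MS2
  a1 <- assign_level(g$feature, g$spectrum, kb)
  expect_identical(a1$level, "I")
  expect_identical(a1$best$name, "Gallic acid")
  f6 <- kb_feature(6)  # ferulic acid hexoside: formula + fragments, no standard
  a2 <- assign_level(f6$feature, f6$spectrum, kb)
  expect_identical(a2$level, "II")
  # diagnostic-only evidence: ellagic acid base peak with no precursor match
  a3 <- assign_level(list(mz = 700.1234, rt = 9.0, polarity = "negative"),
                     data.frame(mz = c(300.9990, 411.7), intensity = c(100, 10)),
                     kb)
  expect_identical(a3$level, "III")
  expect_match(a3$class_call, "ellagitannin")
  # nothing at all: level IV
  a4 <- assign_level(list(mz = 700.1234, rt = 9.0, polarity = "negative"),
                     data.frame(mz = 411.7, intensity = 10), kb)
  expect_identical(a4$level, "IV")
})

test_that("adding a reference standard can only raise the assigned level", {
  f <- kb_feature(41)  # kaempferol glucuronide, tabulated level II
  base_level <- assign_level(f$feature, f$spectrum, kb)$level
  kb_up <- kb
  kb_up$standard[kb_up$peak == 41] <- TRUE
  kb_up$level[kb_up$peak == 41] <- "I"
  up_level <- assign_level(f$feature, f$spectrum, kb_up)$level
  rank <- function(l) match(l, c("IV", "III", "II", "I"))
  expect_identical(base_level, "II")
  expect_gte(rank(up_level), rank(base_level))
})

test_that("isomers sharing a formula resolve by retention-time proximity", {
  for (pk in c(52L, 54L, 60L, 64L, 62L, 63L)) {
    f <- kb_feature(pk)
    a <- assign_level(f$feature, f$spectrum, kb)
    expect_identical(a$best$peak, pk)
  }
})

test_that("annotation is deterministic", {
  f <- kb_feature(13)
  a1 <- assign_level(f$feature, f$spectrum, kb)
  a2 <- assign_level(f$feature, f$spectrum, kb)
  expect_identical(a1$level, a2$level)
  expect_identical(a1$best$peak, a2$best$peak)
})

test_that("annotate_table mirrors the reference table columns", {
  feats <- data.frame(feature = "q", mz = 301.0357, rt = 17.73,
                      polarity = "negative", charge = 1L,
                      GA = 100, T = 120, G = 90, J = 300)
  sp <- list(q = data.frame(mz = c(178.9970, 151.0028, 121.0277),
                            intensity = c(100, 40, 30)))
  tab <- annotate_table(feats, kb, spectra = sp)
  expect_identical(tab$identification, "Quercetin")
  expect_equal(round(tab$delta_ppm, 1), 1.1)
  expect_identical(unlist(tab[, c("GA", "T", "G", "J")], use.names = FALSE),
                   rep("+", 4))
  expect_match(tab$fragments, "^178.9970!")
  # empty input: headers only
  empty <- annotate_table(feats[0, ], kb)
  expect_equal(nrow(empty), 0L)
  expect_true(all(c("rt", "mz", "formula", "level") %in% names(empty)))
})

test_that("planted compounds are recovered by name from simulated cohorts", {
  uniq <- unique_formula_peaks(kb)
  planted <- planted_effect_df(uniq[seq_len(min(10, length(uniq)))])
  spec <- cohort_spec(seed = 77, ppm_scale = 2, planted = planted,
                      n_decoys = 25)
  sim <- simulate_cohort(spec)
  ft <- sim$feature_table
  # consensus observed m/z per feature: intensity-weighted over all runs
  for (i in seq_len(nrow(planted))) {
    fid <- paste0("P", planted$peak[i])
    obs <- do.call(rbind, lapply(names(sim$runs), function(rn) {
      r <- sim$runs[[rn]]
      r[r$feature_id == fid, c("mz", "rt", "intensity")]
    }))
    f <- list(mz = sum(obs$mz * obs$intensity) / sum(obs$intensity),
              rt = sum(obs$rt * obs$intensity) / sum(obs$intensity),
              polarity = kb$polarity[kb$peak == planted$peak[i]],
              charge = kb$charge[kb$peak == planted$peak[i]])
    sp_key <- paste0("J_1:", fid)
    a <- assign_level(f, sim$spectra[[sp_key]], kb)
    expect_identical(a$best$peak, planted$peak[i])
  }
})
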