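# Rule-based annotation of selected features against the compound knowledge
# base: precursor matching at 5 ppm with charge-state handling, neutral-loss
# chain search (breadth-first, depth <= 3) in singly-charged fragment space,
# diagnostic-ion detection, and MSI-style confidence levels I-IV.

#' Match a feature's precursor against the knowledge base
#'
#' Candidates are knowledge-base records of the same polarity whose ion
#' arithmetic reproduces the observed m/z within `ppm_tol`; when the feature's
#' charge state is known (e.g. from isotope spacing) only records of that
#' charge qualify, so a doubly charged feature can only match records whose
#' tabulated ion is also 2-.
#'
#' @param mz observed m/z.
#' @param polarity `"negative"` or `"positive"`.
#' @param kb a knowledge base from [load_knowledge_base()].
#' @param ppm_tol precursor tolerance, ppm (default 5).
#' @param charge optional observed charge state.
#' @return The matching kb rows with a `delta_ppm` column, sorted by
#'   `|delta_ppm|`; zero rows when nothing matches.
#' @export
match_precursor <- function(mz, polarity, kb = load_knowledge_base(),
                            ppm_tol = 5, charge = NA) {
  sel <- kb$polarity == polarity
  if (!is.na(charge)) sel <- sel & kb$charge == as.integer(charge)
  cand <- kb[sel, , drop = FALSE]
  dppm <- ppm_error(mz, cand$reference_mz)
  keep <- abs(dppm) <= ppm_tol
  cand <- cand[keep, , drop = FALSE]
  cand$delta_ppm <- dppm[keep]
  cand[order(abs(cand$delta_ppm)), , drop = FALSE]
}

# all neutral-loss chain sums up to `depth` rules (combinations with
# repetition); returns data.frame(sum, chain)
loss_chain_sums <- function(depth = 3L) {
  rules <- neutral_loss_rules()
  n <- nrow(rules)
  out_sum <- numeric(0); out_chain <- character(0)
  idx <- list(seq_len(n))
  for (d in seq_len(depth)) {
    combos <- utils::combn(n + d - 1L, d, simplify = FALSE) # multisets via stars&bars
    for (cmb in combos) {
      ii <- cmb - seq_len(d) + 1L
      out_sum <- c(out_sum, sum(rules$exact[ii]))
      out_chain <- c(out_chain, paste(rules$name[ii], collapse = " + "))
    }
  }
  data.frame(sum = out_sum, chain = out_chain, stringsAsFactors = FALSE)
}

.chain_env <- new.env(parent = emptyenv())
get_loss_chains <- function(depth = 3L) {
  key <- as.character(depth)
  if (is.null(.chain_env[[key]])) .chain_env[[key]] <- loss_chain_sums(depth)
  .chain_env[[key]]
}

# m/z of the singly charged analogue used as fragment-matching space
mono_equivalent <- function(mz, charge, polarity) {
  p <- .rubusmet_constants$proton
  if (charge <= 1L) return(mz)
  if (polarity == "negative") charge * mz + (charge - 1L) * p
  else (mz * charge - (charge - 1L) * p)
}

#' Explain MS2 fragments of a candidate annotation
#'
#' Each fragment is explained as (a) a known diagnostic/aglycone ion of the
#' feature's polarity, (b) the precursor itself (trivial empty chain), or
#' (c) a previously explained ion minus a chain of at most `max_chain`
#' neutral-loss rules, searched breadth-first. Multiply charged precursors
#' (and fragments carrying a `charge` column) are deconvoluted to the singly
#' charged fragment space before matching.
#'
#' @param spectrum data.frame with `mz`, `intensity`, optional `charge`.
#' @param record one knowledge-base row (the precursor-matched candidate).
#' @param mz_tol fragment m/z tolerance, Da (default 0.01).
#' @param loss_tol neutral-loss matching tolerance, Da (default 0.05).
#' @param max_chain maximum loss-chain length (default 3).
#' @return data.frame: `mz`, `explanation` (`"diagnostic"`, `"precursor"`,
#'   `"loss chain"` or `"unexplained"`), `detail`.
#' @export
explain_fragments <- function(spectrum, record, mz_tol = 0.01,
                              loss_tol = 0.05, max_chain = 3L) {
  stopifnot(nrow(spectrum) >= 1L)
  polarity <- record$polarity
  ion <- ion_species(record$adduct)
  p <- .rubusmet_constants$proton
  M <- monoisotopic_mass(record$formula)
  # root of the loss search: singly charged pseudo-molecular analogue
  root <- switch(ion$kind,
    deprotonated = M - p,
    protonated = M + p,
    cation = M)
  prec_obs <- record$reference_mz
  fz <- if ("charge" %in% names(spectrum)) spectrum$charge else
    rep(1L, nrow(spectrum))
  fmono <- mapply(mono_equivalent, spectrum$mz, fz,
                  MoreArgs = list(polarity = polarity))
  diag <- diagnostic_ions()
  diag <- diag[diag$polarity == polarity, ]
  chains <- get_loss_chains(max_chain)
  n <- nrow(spectrum)
  expl <- rep("unexplained", n)
  detail <- rep(NA_character_, n)
  # (a) diagnostic ions, (b) trivial precursor identity
  for (i in seq_len(n)) {
    d <- abs(diag$mz - fmono[i])
    j <- which.min(d)
    if (length(j) && d[j] <= mz_tol) {
      expl[i] <- "diagnostic"
      detail[i] <- sprintf("%s (%s)", diag$name[j], diag$signifies[j])
    } else if (abs(spectrum$mz[i] - prec_obs) <= mz_tol) {
      expl[i] <- "precursor"
      detail[i] <- "precursor (empty loss chain)"
    }
  }
  # (c) breadth-first loss chains from the root and explained fragments
  sources <- data.frame(mz = root, label = "precursor",
                        stringsAsFactors = FALSE)
  repeat {
    progressed <- FALSE
    for (i in order(-fmono)) {
      if (expl[i] != "unexplained") next
      for (s in seq_len(nrow(sources))) {
        delta <- sources$mz[s] - fmono[i]
        if (delta < -loss_tol) next
        hit <- which(abs(chains$sum - delta) <= loss_tol)
        if (length(hit)) {
          hit <- hit[which.min(abs(chains$sum[hit] - delta))]
          expl[i] <- "loss chain"
          detail[i] <- sprintf("%s - [%s]", sources$label[s],
                               chains$chain[hit])
          sources <- rbind(sources,
                           data.frame(mz = fmono[i],
                                      label = sprintf("m/z %.4f",
                                                      spectrum$mz[i]),
                                      stringsAsFactors = FALSE))
          progressed <- TRUE
          break
        }
      }
    }
    if (!progressed) break
  }
  data.frame(mz = spectrum$mz, explanation = expl, detail = detail,
             stringsAsFactors = FALSE)
}

level_rank <- function(level) match(level, c("IV", "III", "II", "I"))

#' Assign an MSI-style annotation level to a feature
#'
#' Level I requires a precursor-matched record with an authentic standard,
#' retention time agreement, and MS2 purity >= `purity_min` against the
#' standard's reference spectrum. Level II requires a formula (precursor)
#' match plus at least one explained fragment. Level III is a class call from
#' diagnostic-ion evidence alone. Level IV is an unknown. Among candidates
#' the best is the lexicographic maximum of (level rank, fragment coverage,
#' -|delta ppm|); when several isomeric records share a formula, only those
#' within `rt_iso_window` of the observed retention time stay in play.
#'
#' @param feature list or one-row data.frame with `mz`, `rt`, `polarity`,
#'   optional `charge`.
#' @param spectrum optional MS2 data.frame (`mz`, `intensity`).
#' @param kb knowledge base.
#' @param ppm_tol precursor tolerance, ppm.
#' @param rt_tol_standard retention-time window for level I versus the
#'   standard, minutes (default 0.05, the alignment tR criterion).
#' @param rt_iso_window isomer-disambiguation window, minutes (default 0.3).
#' @param purity_min level I purity requirement, percent.
#' @param mz_tol fragment tolerance, Da.
#' @return list of class `"annotation_result"`: `feature`, `best` (matched kb
#'   row with `delta_ppm`, `coverage`, `n_explained`, or `NULL`), `level`,
#'   `class_call` (for level III), `fragments` (explanation table or `NULL`).
#' @export
assign_level <- function(feature, spectrum = NULL, kb = load_knowledge_base(),
                         ppm_tol = 5, rt_tol_standard = 0.05,
                         rt_iso_window = 0.3, purity_min = 80,
                         mz_tol = 0.01) {
  feature <- as.list(feature)
  charge <- if (!is.null(feature$charge)) feature$charge else NA
  cand <- match_precursor(feature$mz, feature$polarity, kb,
                          ppm_tol = ppm_tol, charge = charge)
  # isomer disambiguation: if several candidates and some lie within the tR
  # window, restrict to those
  if (nrow(cand) > 1L && !is.null(feature$rt)) {
    near <- abs(cand$rt - feature$rt) <= rt_iso_window
    if (any(near)) cand <- cand[near, , drop = FALSE]
    # isomers (same composition and ion species) have identical spectra;
    # retention-time proximity is the only discriminator
    if (nrow(cand) > 1L) {
      grp <- paste(cand$formula, cand$adduct)
      keep <- unlist(lapply(split(seq_len(nrow(cand)), grp), function(ii) {
        ii[which.min(abs(cand$rt[ii] - feature$rt))]
      }))
      cand <- cand[sort(keep), , drop = FALSE]
    }
  }
  best <- NULL; best_key <- c(-Inf, -Inf, -Inf); best_frag <- NULL
  for (i in seq_len(nrow(cand))) {
    rec <- cand[i, , drop = FALSE]
    frag_tab <- NULL
    coverage <- 0; n_expl <- 0L
    if (!is.null(spectrum) && nrow(spectrum) > 0L) {
      frag_tab <- explain_fragments(spectrum, rec, mz_tol = mz_tol)
      informative <- frag_tab$explanation %in% c("diagnostic", "loss chain")
      n_expl <- sum(informative)
      coverage <- mean(frag_tab$explanation != "unexplained")
    }
    lvl <- "IV"
    if (n_expl >= 1L) lvl <- "II"
    if (rec$standard && !is.null(feature$rt) &&
        abs(rec$rt - feature$rt) <= rt_tol_standard &&
        !is.null(spectrum) && nrow(spectrum) > 0L) {
      ref <- kb_reference_spectrum(rec)
      if (nrow(ref) > 0L &&
          spectral_purity(spectrum, ref, mz_tol = mz_tol) >= purity_min)
        lvl <- "I"
    }
    # a match can never be more confident than the library entry itself: a
    # record that is only a class-level call (III) yields class-level evidence
    if (level_rank(lvl) > level_rank(rec$level)) lvl <- rec$level
    key <- c(level_rank(lvl), coverage, -abs(rec$delta_ppm))
    if (lexi_gt(key, best_key)) {
      best_key <- key
      best <- rec
      best$assigned_level <- lvl
      best$coverage <- coverage
      best$n_explained <- n_expl
      best_frag <- frag_tab
    }
  }
  if (!is.null(best)) {
    return(structure(list(feature = feature, best = best,
                          level = best$assigned_level,
                          class_call = best$class,
                          fragments = best_frag),
                     class = "annotation_result"))
  }
  # no precursor match: class-level call from diagnostic ions (level III)
  class_call <- NA_character_
  lvl <- "IV"
  if (!is.null(spectrum) && nrow(spectrum) > 0L) {
    diag <- diagnostic_ions()
    diag <- diag[diag$polarity == feature$polarity, ]
    base_first <- spectrum[order(-spectrum$intensity), ]
    for (i in seq_len(nrow(base_first))) {
      d <- abs(diag$mz - base_first$mz[i])
      j <- which.min(d)
      if (d[j] <= mz_tol) {
        class_call <- diag$signifies[j]
        lvl <- "III"
        break
      }
    }
  }
  structure(list(feature = feature, best = NULL, level = lvl,
                 class_call = class_call, fragments = NULL),
            class = "annotation_result")
}

lexi_gt <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] > b[i] + 1e-12) return(TRUE)
    if (a[i] < b[i] - 1e-12) return(FALSE)
  }
  FALSE
}

# reference MS2 spectrum of a kb record: tabulated fragment m/z with nominal
# intensities (base peak 100, others 50; the source tables print roles, not
# intensities)
kb_reference_spectrum <- function(rec) {
  fr <- rec$fragments[[1]]
  data.frame(mz = fr$mz, intensity = ifelse(fr$base, 100, 50))
}

#' @export
print.annotation_result <- function(x, ...) {
  cat(sprintf("m/z %.4f (%s): level %s", x$feature$mz, x$feature$polarity,
              x$level))
  if (!is.null(x$best)) cat(" -", x$best$name)
  else if (!is.na(x$class_call)) cat(" - class:", x$class_call)
  cat("\n")
  invisible(x)
}

#' Annotate a table of selected features
#'
#' Runs [assign_level()] over every feature and assembles a report table
#' column-compatible with the reference annotation tables: retention time,
#' observed m/z, charge, fragment list (base peak flagged), proposed formula,
#' theoretical exact mass, ppm error, per-cultivar presence calls, tentative
#' identification and level.
#'
#' @param features data.frame with columns `feature`, `mz`, `rt`, `polarity`,
#'   optional `charge`, and optional per-cultivar mean-intensity columns
#'   (`GA`, `T`, `G`, `J`) for presence calls.
#' @param kb knowledge base.
#' @param spectra optional named list of MS2 spectra keyed by `feature`.
#' @param presence_threshold intensity above which a cultivar is called
#'   present (default 0).
#' @param ... passed to [assign_level()].
#' @return data.frame with one row per feature.
#' @export
annotate_table <- function(features, kb = load_knowledge_base(),
                           spectra = NULL, presence_threshold = 0, ...) {
  cols <- c("feature", "rt", "mz", "charge", "fragments", "formula",
            "exact_mass", "delta_ppm", "GA", "T", "G", "J",
            "identification", "level")
  if (nrow(features) == 0L) {
    out <- as.data.frame(stats::setNames(rep(list(character(0)), length(cols)),
                                         cols))
    return(out)
  }
  cultivars <- c("GA", "T", "G", "J")
  rows <- lapply(seq_len(nrow(features)), function(i) {
    f <- features[i, , drop = FALSE]
    sp <- if (!is.null(spectra)) spectra[[as.character(f$feature)]] else NULL
    ann <- assign_level(f, spectrum = sp, kb = kb, ...)
    frag_str <- if (!is.null(sp) && nrow(sp) > 0L) {
      b <- sp$intensity == max(sp$intensity)
      b[duplicated(b) & b] <- FALSE
      paste0(sprintf("%.4f", sp$mz), ifelse(b, "!", ""), collapse = ";")
    } else ""
    pres <- vapply(cultivars, function(cv) {
      if (cv %in% names(features)) {
        v <- f[[cv]]
        if (is.na(v)) "-" else if (v > presence_threshold) "+" else "-"
      } else NA_character_
    }, character(1))
    data.frame(feature = f$feature, rt = f$rt, mz = f$mz,
               charge = if (!is.null(f$charge)) f$charge else NA_integer_,
               fragments = frag_str,
               formula = if (!is.null(ann$best)) ann$best$formula else "",
               exact_mass = if (!is.null(ann$best))
                 ann$best$reference_mz else NA_real_,
               delta_ppm = if (!is.null(ann$best)) ann$best$delta_ppm
                           else NA_real_,
               GA = pres["GA"], T = pres["T"], G = pres["G"], J = pres["J"],
               identification = if (!is.null(ann$best)) ann$best$name
                                else if (!is.na(ann$class_call))
                                  paste0("unknown ", ann$class_call)
                                else "unknown",
               level = ann$level,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
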