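# Ground-truth-known synthetic cohorts emulating the study design: four
# cultivar groups (3 biological replicates each) plus pooled QC injections,
# log-normal intensities with per-group fold effects, ppm-scale mass error,
# retention-time jitter, MS2 spectra built from the knowledge base's
# fragment lists plus Poisson-count decoy peaks, and a pomology table drawn
# from the built-in cultivar means/RSDs.

#' Specify a synthetic cohort
#'
#' The defaults are the study conditions this generator emulates: four
#' cultivar groups of three biological replicates plus three pooled-QC
#' injections, 2 ppm mass-error scale, 0.01 min retention-time jitter, 20%
#' biological and 5% QC intensity CV.
#'
#' @param groups cultivar group labels.
#' @param replicates biological replicates per group.
#' @param qc number of pooled-QC injections.
#' @param seed integer RNG seed; a fixed seed makes the cohort byte-identical
#'   across runs.
#' @param ppm_scale standard deviation of the relative mass error, ppm.
#' @param rt_jitter standard deviation of retention-time jitter, minutes.
#' @param bio_cv biological intensity CV (fraction).
#' @param qc_cv QC intensity CV (fraction).
#' @param planted data.frame with column `peak` (knowledge-base peak id) and
#'   one fold column per group (e.g. `GA`, `T`, `G`, `J`; fold 0 = absent in
#'   that group), or `NULL` for none.
#' @param n_decoys number of decoy (non-library) features.
#' @param decoy_fragment_rate Poisson mean of decoy peaks added to every MS2
#'   spectrum.
#' @param fragment_dropout per-fragment dropout probability in simulated MS2
#'   (the base peak is never dropped).
#' @param base_intensity reference intensity scale (arbitrary units).
#' @return list of class `"cohort_spec"`.
#' @export
cohort_spec <- function(groups = c("GA", "T", "G", "J"), replicates = 3L,
                        qc = 3L, seed = 1L, ppm_scale = 2, rt_jitter = 0.01,
                        bio_cv = 0.2, qc_cv = 0.05, planted = NULL,
                        n_decoys = 50L, decoy_fragment_rate = 3,
                        fragment_dropout = 0.1, base_intensity = 1e5) {
  stopifnot(bio_cv > 0, qc_cv > 0, replicates >= 2L, qc >= 2L,
            ppm_scale >= 0, rt_jitter >= 0)
  if (!is.null(planted)) {
    stopifnot(is.data.frame(planted), "peak" %in% names(planted),
              all(groups %in% names(planted)))
    if (any(as.matrix(planted[, groups]) < 0))
      stop("fold patterns must be >= 0")
  }
  structure(list(groups = groups, replicates = as.integer(replicates),
                 qc = as.integer(qc), seed = as.integer(seed),
                 ppm_scale = ppm_scale, rt_jitter = rt_jitter,
                 bio_cv = bio_cv, qc_cv = qc_cv, planted = planted,
                 n_decoys = as.integer(n_decoys),
                 decoy_fragment_rate = decoy_fragment_rate,
                 fragment_dropout = fragment_dropout,
                 base_intensity = base_intensity),
            class = "cohort_spec")
}

rlnorm_mean_cv <- function(n, mean, cv) {
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

# decoy m/z grid: values guaranteed >= 20 ppm away from every kb ion
decoy_mz_grid <- function(kb, n) {
  grid <- seq(100.05, 999.55, by = 0.379)
  ok <- vapply(grid, function(m)
    all(abs(ppm_error(m, c(kb$theoretical_mz, kb$reference_mz))) >= 20),
    logical(1))
  grid <- grid[ok]
  if (length(grid) < n) stop("decoy grid exhausted")
  sample(grid, n)
}

#' Simulate a ground-truth-known cohort
#'
#' Planted features get m/z `ion_mz(formula) * (1 + eps)` with
#' `eps ~ Normal(0, ppm_scale * 1e-6)`, retention times jittered around the
#' library value, and log-normal intensities around `base_intensity * fold`
#' per group. QC intensities are log-normal around the arithmetic mean of the
#' group means (the pooled-aliquot construction) with the QC noise CV. MS2
#' spectra contain the library fragment list (with dropout, base peak
#' retained) plus a Poisson number of decoy peaks; decoy features draw their
#' m/z from a grid offset >= 20 ppm from every library ion so they can never
#' precursor-match.
#'
#' @param spec a [cohort_spec()].
#' @param kb knowledge base (defaults to the built-in one).
#' @return list with elements
#'   \describe{
#'     \item{runs}{named list of per-sample feature data.frames (`feature_id`,
#'       `mz`, `rt`, `intensity`, `polarity`, `iso_ratio`,
#'       `iso_theoretical`).}
#'     \item{spectra}{named list of MS2 spectra keyed `"<run>:<feature_id>"`.}
#'     \item{feature_table}{a [feature_table()] of the true feature x sample
#'       intensities.}
#'     \item{features}{feature metadata (consensus m/z, rt, polarity, charge,
#'       per-cultivar mean intensity).}
#'     \item{truth}{ground-truth map: `feature`, `compound` (kb peak id or
#'       `NA` for decoys), `type` (`"planted"`/`"decoy"`).}
#'     \item{pomology}{replicate-level pomology table drawn from the built-in
#'       cultivar means/RSDs.}
#'   }
#' @export
simulate_cohort <- function(spec = cohort_spec(), kb = load_knowledge_base()) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  groups <- spec$groups
  samples <- c(paste(rep(groups, each = spec$replicates),
                     seq_len(spec$replicates), sep = "_"),
               paste("QC", seq_len(spec$qc), sep = "_"))
  sample_group <- c(rep(groups, each = spec$replicates),
                    rep("QC", spec$qc))
  planted <- spec$planted
  if (!is.null(planted) && nrow(planted) > 0L) {
    miss <- setdiff(planted$peak, kb$peak)
    if (length(miss))
      stop("planted compounds not in knowledge base: ",
           paste(miss, collapse = ", "))
  }
  n_p <- if (is.null(planted)) 0L else nrow(planted)
  feat <- data.frame(
    feature = c(if (n_p) paste0("P", planted$peak),
                if (spec$n_decoys) paste0("D", seq_len(spec$n_decoys))),
    type = c(rep("planted", n_p), rep("decoy", spec$n_decoys)),
    compound = c(if (n_p) planted$peak, rep(NA_integer_, spec$n_decoys)),
    stringsAsFactors = FALSE)
  nfeat <- nrow(feat)
  if (nfeat == 0L) stop("cohort has no features (no planted, no decoys)")
  # per-feature reference values
  ref_mz <- numeric(nfeat); ref_rt <- numeric(nfeat)
  polarity <- character(nfeat); charge <- integer(nfeat)
  iso_theo <- rep(NA_real_, nfeat)
  folds <- matrix(1, nfeat, length(groups), dimnames = list(NULL, groups))
  if (n_p) {
    ki <- match(planted$peak, kb$peak)
    ref_mz[seq_len(n_p)] <- kb$reference_mz[ki]
    ref_rt[seq_len(n_p)] <- kb$rt[ki]
    polarity[seq_len(n_p)] <- kb$polarity[ki]
    charge[seq_len(n_p)] <- kb$charge[ki]
    folds[seq_len(n_p), ] <- as.matrix(planted[, groups])
    iso_theo[seq_len(n_p)] <- vapply(ki, function(k) {
      ip <- isotope_pattern(kb$formula[k], kb$adduct[k], n_peaks = 2L)
      ip$abundance[2] / ip$abundance[1]
    }, numeric(1))
  }
  if (spec$n_decoys) {
    di <- n_p + seq_len(spec$n_decoys)
    ref_mz[di] <- decoy_mz_grid(kb, spec$n_decoys)
    ref_rt[di] <- stats::runif(spec$n_decoys, 1, 30)
    polarity[di] <- sample(c("negative", "positive"), spec$n_decoys,
                           replace = TRUE)
    charge[di] <- 1L
    folds[di, ] <- stats::runif(spec$n_decoys, 0.5, 2)  # group-constant scale
    folds[di, ] <- folds[di, 1L]
  }
  base_mu <- spec$base_intensity *
    c(rep(1, n_p), if (spec$n_decoys) stats::runif(spec$n_decoys, 0.2, 2))
  mu <- sweep(folds, 1L, base_mu, `*`)          # nfeat x groups group means
  mu_qc <- rowMeans(mu)                         # pooled-aliquot construction
  rules <- neutral_loss_rules()
  runs <- list(); spectra <- list()
  X <- matrix(0, nfeat, length(samples),
              dimnames = list(feat$feature, samples))
  for (s in seq_along(samples)) {
    g <- sample_group[s]
    present <- if (g == "QC") mu_qc > 0 else mu[, g] > 0
    idx <- which(present)
    m <- mu_qc[idx]
    cv <- spec$qc_cv
    if (g != "QC") { m <- mu[idx, g]; cv <- spec$bio_cv }
    ints <- rlnorm_mean_cv(length(idx), m, cv)
    mzs <- ref_mz[idx] * (1 + stats::rnorm(length(idx), 0, spec$ppm_scale * 1e-6))
    rts <- ref_rt[idx] + stats::rnorm(length(idx), 0, spec$rt_jitter)
    iso_obs <- iso_theo[idx] * (1 + stats::rnorm(length(idx), 0, 0.02))
    runs[[samples[s]]] <- data.frame(
      feature_id = feat$feature[idx], mz = mzs, rt = rts, intensity = ints,
      polarity = polarity[idx], iso_ratio = iso_obs,
      iso_theoretical = iso_theo[idx], stringsAsFactors = FALSE)
    X[idx, s] <- ints
    # MS2 spectra
    for (jj in seq_along(idx)) {
      i <- idx[jj]
      if (feat$type[i] == "planted") {
        k <- match(feat$compound[i], kb$peak)
        fr <- kb$fragments[[k]]
        keep <- fr$base | stats::runif(nrow(fr)) > spec$fragment_dropout
        fr <- fr[keep, , drop = FALSE]
        sp_mz <- fr$mz
        sp_int <- ifelse(fr$base, 100, stats::runif(nrow(fr), 30, 70))
        sp_ch <- fr$charge
      } else {
        sp_mz <- numeric(0); sp_int <- numeric(0); sp_ch <- integer(0)
      }
      nd <- stats::rpois(1L, spec$decoy_fragment_rate)
      if (nd > 0L) {
        dmz <- stats::runif(nd, 100, max(ref_mz[i], 150))
        sp_mz <- c(sp_mz, dmz)
        sp_int <- c(sp_int, stats::runif(nd, 1, 20))
        sp_ch <- c(sp_ch, rep(1L, nd))
      }
      if (length(sp_mz)) {
        sp <- data.frame(mz = sp_mz, intensity = sp_int, charge = sp_ch)
        attr(sp, "precursor_mz") <- mzs[jj]
        attr(sp, "rt") <- rts[jj]
        attr(sp, "charge") <- charge[i]
        spectra[[paste0(samples[s], ":", feat$feature[i])]] <- sp
      }
    }
  }
  cult_means <- matrix(NA_real_, nfeat, length(groups),
                       dimnames = list(feat$feature, groups))
  for (g in groups)
    cult_means[, g] <- rowMeans(X[, sample_group == g, drop = FALSE])
  features <- data.frame(feature = feat$feature, mz = ref_mz, rt = ref_rt,
                         polarity = polarity, charge = charge,
                         stringsAsFactors = FALSE)
  features <- cbind(features, as.data.frame(cult_means))
  # pomology: replicate-level draws from the built-in means/RSDs
  pref <- pomology_reference()
  pom <- do.call(rbind, lapply(groups, function(g) {
    rows <- pref[pref$cultivar == g, ]
    if (nrow(rows) == 0L) return(NULL)
    vals <- sapply(seq_len(nrow(rows)), function(j)
      stats::rnorm(spec$replicates, rows$mean[j],
                   rows$mean[j] * rows$rsd[j] / 100))
    df <- as.data.frame(vals)
    names(df) <- rows$parameter
    cbind(data.frame(cultivar = g, stringsAsFactors = FALSE), df)
  }))
  list(runs = runs, spectra = spectra,
       feature_table = feature_table(X, sample_group),
       features = features,
       truth = feat[, c("feature", "compound", "type")],
       pomology = pom)
}

#' Simulate a null cohort (no group effects)
#'
#' All fold patterns equal to 1: every feature shares one mean across
#' cultivar groups, so any selection is a false positive. Used to estimate
#' the type-I error of the selection cascade.
#'
#' @param spec a [cohort_spec()]; `planted` is ignored.
#' @param n_features number of null features.
#' @return A [feature_table()].
#' @export
simulate_null_cohort <- function(spec = cohort_spec(), n_features = 100L) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  groups <- spec$groups
  sample_group <- c(rep(groups, each = spec$replicates), rep("QC", spec$qc))
  nsamp <- length(sample_group)
  mu <- spec$base_intensity * stats::runif(n_features, 0.2, 2)
  X <- matrix(0, n_features, nsamp)
  for (s in seq_len(nsamp)) {
    cv <- if (sample_group[s] == "QC") spec$qc_cv else spec$bio_cv
    X[, s] <- rlnorm_mean_cv(n_features, mu, cv)
  }
  rownames(X) <- paste0("N", seq_len(n_features))
  colnames(X) <- c(paste(rep(groups, each = spec$replicates),
                         seq_len(spec$replicates), sep = "_"),
                   paste("QC", seq_len(spec$qc), sep = "_"))
  feature_table(X, sample_group)
}
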