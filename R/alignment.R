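# Replicate feature alignment under the four acceptance criteria used for
# aligned chromatograms: (i) precursor mass accuracy < 5 ppm, (ii) isotope
# ratio deviation from the theoretical profile < 20%, (iii) MS2 purity score
# >= 80% where spectra exist, (iv) retention-time tolerance <= 0.05 min.

#' Read an MGF peak-list file
#'
#' Minimal Mascot-generic-format reader for DIA-style MS2 spectra: each
#' BEGIN IONS/END IONS block with TITLE, PEPMASS, optional CHARGE and RTINSECONDS
#' headers and mz/intensity peak rows.
#'
#' @param path MGF file path.
#' @return Named list of spectra; each spectrum is a data.frame with columns
#'   `mz`, `intensity`, and attributes `precursor_mz`, `rt`, `charge`. Names
#'   are the TITLE fields.
#' @export
read_mgf <- function(path) {
  lines <- readLines(path)
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (trimws(lines[i]) == "BEGIN IONS") {
      title <- NA_character_; pep <- NA_real_; rt <- NA_real_; ch <- NA_integer_
      peaks_mz <- numeric(0); peaks_int <- numeric(0)
      i <- i + 1L
      while (i <= length(lines) && trimws(lines[i]) != "END IONS") {
        ln <- trimws(lines[i])
        if (startsWith(ln, "TITLE=")) title <- sub("^TITLE=", "", ln)
        else if (startsWith(ln, "PEPMASS=")) {
          pep <- as.numeric(strsplit(sub("^PEPMASS=", "", ln), "[ \t]")[[1]][1])
        } else if (startsWith(ln, "RTINSECONDS=")) {
          rt <- as.numeric(sub("^RTINSECONDS=", "", ln)) / 60
        } else if (startsWith(ln, "CHARGE=")) {
          ch <- as.integer(gsub("[^0-9]", "", ln))
        } else if (grepl("^[0-9]", ln)) {
          xy <- as.numeric(strsplit(ln, "[ \t]+")[[1]])
          peaks_mz <- c(peaks_mz, xy[1]); peaks_int <- c(peaks_int, xy[2])
        }
        i <- i + 1L
      }
      sp <- data.frame(mz = peaks_mz, intensity = peaks_int)
      attr(sp, "precursor_mz") <- pep
      attr(sp, "rt") <- rt
      attr(sp, "charge") <- ch
      out[[title]] <- sp
    }
    i <- i + 1L
  }
  out
}

#' Write spectra to MGF
#'
#' @param spectra named list of spectra as returned by [read_mgf()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (ttl in names(spectra)) {
    sp <- spectra[[ttl]]
    writeLines("BEGIN IONS", con)
    writeLines(paste0("TITLE=", ttl), con)
    pm <- attr(sp, "precursor_mz")
    if (!is.null(pm) && !is.na(pm))
      writeLines(sprintf("PEPMASS=%.6f", pm), con)
    rt <- attr(sp, "rt")
    if (!is.null(rt) && !is.na(rt))
      writeLines(sprintf("RTINSECONDS=%.3f", rt * 60), con)
    ch <- attr(sp, "charge")
    if (!is.null(ch) && !is.na(ch))
      writeLines(sprintf("CHARGE=%d", ch), con)
    writeLines(sprintf("%.6f %.6g", sp$mz, sp$intensity), con)
    writeLines("END IONS", con)
  }
  invisible(path)
}

#' MS2 spectral purity score
#'
#' Normalized spectral dot product (cosine similarity) on tolerance-matched,
#' intensity-normalized peaks, expressed as a percentage. Peaks are matched
#' greedily by smallest m/z difference within `mz_tol`; unmatched peaks
#' contribute to the norms but not to the dot product, so the score is 100
#' only for spectra matching peak-for-peak and 0 when no peaks match.
#'
#' @param s1,s2 spectra: data.frames with columns `mz` and `intensity`
#'   (non-empty).
#' @param mz_tol peak-matching tolerance, Da.
#' @return Score in \[0, 100\]; symmetric and invariant to uniform intensity
#'   scaling.
#' @export
spectral_purity <- function(s1, s2, mz_tol = 0.01) {
  if (is.null(s1) || is.null(s2) || nrow(s1) == 0L || nrow(s2) == 0L)
    stop("spectral_purity requires two non-empty spectra")
  pairs <- expand.grid(i = seq_len(nrow(s1)), j = seq_len(nrow(s2)))
  pairs$d <- abs(s1$mz[pairs$i] - s2$mz[pairs$j])
  pairs <- pairs[pairs$d <= mz_tol, , drop = FALSE]
  pairs <- pairs[order(pairs$d), , drop = FALSE]
  used_i <- logical(nrow(s1)); used_j <- logical(nrow(s2))
  dot <- 0
  for (k in seq_len(nrow(pairs))) {
    i <- pairs$i[k]; j <- pairs$j[k]
    if (used_i[i] || used_j[j]) next
    used_i[i] <- TRUE; used_j[j] <- TRUE
    dot <- dot + s1$intensity[i] * s2$intensity[j]
  }
  denom <- sqrt(sum(s1$intensity^2)) * sqrt(sum(s2$intensity^2))
  100 * dot / denom
}

#' Align features across replicate runs
#'
#' Pools per-run centroided feature lists and clusters them by (m/z,
#' retention time) with a deterministic single-pass greedy scheme: features
#' are sorted by retention time then m/z (so the result does not depend on
#' run order), and each feature joins the nearest existing cluster centroid
#' within both tolerances (ties by smallest ppm distance) or opens a new
#' cluster. Centroids are intensity-weighted means. Clusters are then scored
#' against the four acceptance criteria; the isotope-ratio criterion applies
#' only to features carrying both an observed and a theoretical (A+1)/A
#' ratio, and the purity criterion only when MS2 spectra are present in at
#' least two runs.
#'
#' @param runs named list (>= 2) of per-run feature data.frames with columns
#'   `mz`, `rt`, `intensity`, optional `feature_id`, `iso_ratio` (observed
#'   (A+1)/A) and `iso_theoretical`.
#' @param spectra optional named list of MS2 spectra keyed
#'   `"<run>:<feature_id>"`.
#' @param ppm_tol precursor accuracy criterion, ppm (default 5).
#' @param rt_tol retention-time tolerance, minutes (default 0.05).
#' @param iso_tol isotope-ratio deviation criterion, percent (default 20).
#' @param purity_min MS2 purity criterion, percent (default 80).
#' @param mz_tol_ms2 peak tolerance for purity scoring, Da.
#' @return data.frame of class `"aligned_features"`: one row per cluster with
#'   consensus `mz` and `rt`, size `n`, per-run intensity columns, quality
#'   columns (`ppm_spread`, `rt_spread`, `iso_dev`, `purity`) and logical
#'   `aligned` (TRUE when the cluster spans >= 2 runs and satisfies every
#'   applicable criterion; singletons and failing clusters are emitted
#'   flagged, not dropped). A `members` list-column records run/feature ids.
#' @export
align_features <- function(runs, spectra = NULL, ppm_tol = 5, rt_tol = 0.05,
                           iso_tol = 20, purity_min = 80, mz_tol_ms2 = 0.01) {
  stopifnot(is.list(runs), length(runs) >= 2L)
  if (is.null(names(runs)) || any(names(runs) == ""))
    names(runs) <- paste0("run", seq_along(runs))
  pooled <- do.call(rbind, lapply(names(runs), function(rn) {
    df <- runs[[rn]]
    stopifnot(all(c("mz", "rt", "intensity") %in% names(df)))
    stopifnot(all(df$intensity >= 0))
    data.frame(run = rn,
               feature_id = if ("feature_id" %in% names(df))
                 as.character(df$feature_id) else as.character(seq_len(nrow(df))),
               mz = df$mz, rt = df$rt, intensity = df$intensity,
               iso_ratio = if ("iso_ratio" %in% names(df)) df$iso_ratio
                           else NA_real_,
               iso_theoretical = if ("iso_theoretical" %in% names(df))
                 df$iso_theoretical else NA_real_,
               stringsAsFactors = FALSE)
  }))
  pooled <- pooled[order(pooled$rt, pooled$mz, pooled$run, pooled$feature_id), ]
  n <- nrow(pooled)
  cl_mz <- numeric(0); cl_rt <- numeric(0); cl_w <- numeric(0)
  cl_rtmin <- numeric(0); cl_rtmax <- numeric(0)
  assign <- integer(n)
  for (i in seq_len(n)) {
    # joining must keep the cluster's total tR spread within rt_tol and the
    # feature within ppm_tol of the running centroid (=> ppm spread < 2 tol)
    ok <- which(pmax(cl_rtmax, pooled$rt[i]) - pmin(cl_rtmin, pooled$rt[i]) <= rt_tol &
                abs(pooled$mz[i] - cl_mz) / cl_mz * 1e6 <= ppm_tol)
    if (length(ok) == 0L) {
      cl_mz <- c(cl_mz, pooled$mz[i]); cl_rt <- c(cl_rt, pooled$rt[i])
      cl_rtmin <- c(cl_rtmin, pooled$rt[i]); cl_rtmax <- c(cl_rtmax, pooled$rt[i])
      cl_w <- c(cl_w, max(pooled$intensity[i], .Machine$double.eps))
      assign[i] <- length(cl_mz)
    } else {
      ppm_d <- abs(pooled$mz[i] - cl_mz[ok]) / cl_mz[ok] * 1e6
      k <- ok[which.min(ppm_d)]
      assign[i] <- k
      w <- max(pooled$intensity[i], .Machine$double.eps)
      cl_mz[k] <- (cl_mz[k] * cl_w[k] + pooled$mz[i] * w) / (cl_w[k] + w)
      cl_rt[k] <- (cl_rt[k] * cl_w[k] + pooled$rt[i] * w) / (cl_w[k] + w)
      cl_rtmin[k] <- min(cl_rtmin[k], pooled$rt[i])
      cl_rtmax[k] <- max(cl_rtmax[k], pooled$rt[i])
      cl_w[k] <- cl_w[k] + w
    }
  }
  run_names <- names(runs)
  rows <- lapply(seq_along(cl_mz), function(k) {
    m <- pooled[assign == k, , drop = FALSE]
    w <- pmax(m$intensity, .Machine$double.eps)
    cons_mz <- sum(m$mz * w) / sum(w)
    cons_rt <- sum(m$rt * w) / sum(w)
    ppm_spread <- if (nrow(m) > 1L)
      (max(m$mz) - min(m$mz)) / min(m$mz) * 1e6 else 0
    rt_spread <- max(m$rt) - min(m$rt)
    iso_dev <- {
      have <- !is.na(m$iso_ratio) & !is.na(m$iso_theoretical)
      if (any(have))
        max(abs(m$iso_ratio[have] - m$iso_theoretical[have]) /
            m$iso_theoretical[have]) * 100
      else NA_real_
    }
    purity <- NA_real_
    if (!is.null(spectra)) {
      keys <- paste0(m$run, ":", m$feature_id)
      sp <- spectra[intersect(keys, names(spectra))]
      sp <- Filter(function(s) !is.null(s) && nrow(s) > 0L, sp)
      if (length(sp) >= 2L) {
        cmb <- utils::combn(length(sp), 2L)
        purity <- min(apply(cmb, 2L, function(ij)
          spectral_purity(sp[[ij[1]]], sp[[ij[2]]], mz_tol = mz_tol_ms2)))
      }
    }
    ints <- stats::setNames(rep(NA_real_, length(run_names)),
                            paste0("intensity.", run_names))
    agg <- tapply(m$intensity, m$run, sum)
    ints[paste0("intensity.", names(agg))] <- agg
    aligned <- length(unique(m$run)) >= 2L &&
      (is.na(iso_dev) || iso_dev < iso_tol) &&
      (is.na(purity) || purity >= purity_min)
    c(list(cluster = k, mz = cons_mz, rt = cons_rt, n = nrow(m),
           ppm_spread = ppm_spread, rt_spread = rt_spread,
           iso_dev = iso_dev, purity = purity, aligned = aligned),
      as.list(ints))
  })
  out <- do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
  out$members <- lapply(seq_along(cl_mz), function(k) {
    m <- pooled[assign == k, c("run", "feature_id")]
    rownames(m) <- NULL
    m
  })
  out <- out[order(out$rt, out$mz), ]
  out$cluster <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("aligned_features", "data.frame")
  out
}

#' Read a per-run delimited feature list
#' @param path tab-separated file with columns `mz`, `rt`, `intensity` and
#'   optional `feature_id`, `polarity`, `iso_ratio`, `iso_theoretical`.
#' @return data.frame.
#' @export
read_feature_list <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write an aligned-feature table (quality columns included) as TSV
#' @param x an `"aligned_features"` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_aligned_features <- function(x, path) {
  out <- x[, setdiff(names(x), "members")]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
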