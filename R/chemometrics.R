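# Genotype chemometrics: autoscaled PCA with pooled-QC diagnostics (run
# separately per ionization mode), Pearson product-moment correlation of
# feature intensities against pomological traits, and the Kruskal-Wallis /
# DSCF group comparison with compact-letter display for the pomology table.

#' Autoscale a data matrix
#'
#' Centers every column to mean 0 and scales to unit variance.
#' Zero-variance columns cannot be autoscaled and are dropped with a warning.
#'
#' @param x numeric matrix (samples x features).
#' @return Autoscaled matrix; dropped column names in
#'   `attr(, "dropped")`.
#' @export
autoscale <- function(x) {
  x <- as.matrix(x)
  v <- apply(x, 2L, stats::var)
  drop <- !is.finite(v) | v < .Machine$double.eps
  if (any(drop)) {
    warning(sum(drop), " zero-variance column(s) dropped before autoscaling")
    x <- x[, !drop, drop = FALSE]
  }
  out <- scale(x, center = TRUE, scale = TRUE)
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  attr(out, "dropped") <- names(v)[drop]
  out
}

#' Principal component analysis of autoscaled feature intensities
#'
#' Singular-value decomposition of the autoscaled matrix (correlation-matrix
#' PCA). Explained variance per component is the eigenvalue as a percentage
#' of the total; the number of components with eigenvalue > 1 (the usual
#' retention heuristic) is reported. For reproducible score plots each
#' loading vector's largest-magnitude element is forced positive.
#'
#' @param x samples x features matrix of intensities (raw intensities by
#'   default; pass `log = TRUE` to analyze log10 intensities).
#' @param log analyze log10(x + 1) instead of raw intensities.
#' @return list of class `"pca_result"`: `scores` (samples x components),
#'   `loadings` (features x components), `eigenvalues`, `ev_pct`,
#'   `n_above_1` (eigenvalues > 1), `dropped` (zero-variance features).
#' @export
pca_features <- function(x, log = FALSE) {
  x <- as.matrix(x)
  if (nrow(x) < 2L || ncol(x) < 2L)
    stop("PCA needs >= 2 samples and >= 2 features")
  if (log) x <- log10(x + 1)
  xs <- autoscale(x)
  if (ncol(xs) < 2L) stop("degenerate matrix: fewer than 2 usable features")
  sv <- svd(xs)
  ncomp <- min(nrow(xs) - 1L, ncol(xs))
  d <- sv$d[seq_len(ncomp)]
  eig <- d^2 / (nrow(xs) - 1L)
  # sign convention: largest-|loading| element positive
  load <- sv$v[, seq_len(ncomp), drop = FALSE]
  flip <- apply(load, 2L, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  load <- sweep(load, 2L, flip, `*`)
  scores <- xs %*% load
  dimnames(scores) <- list(rownames(x), paste0("PC", seq_len(ncomp)))
  dimnames(load) <- list(colnames(xs), paste0("PC", seq_len(ncomp)))
  total_var <- sum(apply(xs, 2L, stats::var))
  structure(list(scores = scores, loadings = load, eigenvalues = eig,
                 ev_pct = 100 * eig / total_var,
                 n_above_1 = sum(eig > 1),
                 dropped = attr(xs, "dropped")),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("PCA:", nrow(x$scores), "samples,", nrow(x$loadings), "features\n")
  cat("EV%:", paste(sprintf("%.1f", utils::head(x$ev_pct, 6)),
                    collapse = " / "), "\n")
  cat("components with eigenvalue > 1:", x$n_above_1, "\n")
  invisible(x)
}

#' Pooled-QC proximity diagnostic in PCA score space
#'
#' Quality control of the whole analytical workflow: replicated injections of
#' the pooled QC sample should fall near the origin of the PC1-PC2 score
#' plane. The diagnostic is the ratio of the mean QC distance-to-origin to
#' the mean biological-sample distance-to-origin; the check passes when the
#' ratio falls below `threshold`.
#'
#' @param scores score matrix (samples x components, >= 2 components).
#' @param qc_labels logical vector marking QC rows (>= 2 required).
#' @param threshold pass threshold on the distance ratio (default 0.3).
#' @return list: `ratio`, `pass`, `qc_dist`, `sample_dist`.
#' @export
qc_proximity <- function(scores, qc_labels, threshold = 0.3) {
  stopifnot(ncol(scores) >= 2L, length(qc_labels) == nrow(scores))
  if (sum(qc_labels) < 2L) stop("need >= 2 QC samples")
  d <- sqrt(scores[, 1L]^2 + scores[, 2L]^2)
  qc_dist <- mean(d[qc_labels])
  sample_dist <- mean(d[!qc_labels])
  ratio <- qc_dist / sample_dist
  list(ratio = ratio, pass = ratio < threshold,
       qc_dist = qc_dist, sample_dist = sample_dist)
}

#' Pearson product-moment correlation of features against pomology traits
#'
#' Pearson r for every feature x trait pair over matched samples, with
#' two-sided p-values from the t reference (t = r sqrt(n-2)/sqrt(1-r^2)) and
#' significance flags at `alpha`. Zero-variance vectors give `NA` r and are
#' flagged undefined.
#'
#' @param features samples x features intensity matrix (QC excluded).
#' @param pomology samples x traits matrix, rows matched to `features`
#'   (cultivar-level traits repeated per replicate).
#' @param alpha significance level for the flags (default 0.05).
#' @return list of class `"ppmc_result"`: matrices `r`, `p`, `significant`.
#' @export
ppmc <- function(features, pomology, alpha = 0.05) {
  features <- as.matrix(features); pomology <- as.matrix(pomology)
  stopifnot(nrow(features) == nrow(pomology))
  n <- nrow(features)
  r <- suppressWarnings(stats::cor(features, pomology))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  p[abs(r) >= 1 - 1e-12] <- 0
  structure(list(r = r, p = p, significant = !is.na(p) & p < alpha),
            class = "ppmc_result")
}

#' Built-in pomology reference table
#'
#' Cultivar-level means and relative standard deviations (percent, n = 3) of
#' the pomological parameters: CIELAB coordinates (L brightness, a green-red,
#' b blue-yellow), total soluble solids (TSS, degrees Brix) and titratable
#' acidity (TA, g citric acid per kg fresh weight).
#'
#' @return data.frame with columns `cultivar`, `parameter`, `mean`, `rsd`.
#' @export
pomology_reference <- function() {
  data.frame(
    cultivar = rep(c("GA", "T", "G", "J"), each = 5L),
    parameter = rep(c("L", "a", "b", "TSS", "TA"), times = 4L),
    mean = c(35, 23, 16, 11.1, 19.7,
             35, 23, 16, 11.8, 19.9,
             53, 12, 34, 8.1, 12.4,
             25, 2, 3, 13.1, 10.7),
    rsd = c(1, 3, 3, 1.1, 1.4,
            3, 3, 3, 1.7, 1.3,
            1, 2, 2, 1.1, 1.0,
            1, 1, 1, 1.1, 1.0),
    stringsAsFactors = FALSE)
}

#' Kruskal-Wallis group comparison of pomological parameters
#'
#' Per parameter: Kruskal-Wallis p across cultivars, DSCF pairwise p-values,
#' and a compact-letter display built by greedy merging of pairs that are not
#' significantly different at `alpha`.
#'
#' @param pomology data.frame with a `cultivar` column and one numeric column
#'   per parameter (>= 2 replicates per cultivar).
#' @param alpha significance level (default 0.05).
#' @return list per parameter: `kw_p`, `dscf` (pair table), `letters` (named
#'   character vector of group letters).
#' @export
pomology_group_test <- function(pomology, alpha = 0.05) {
  stopifnot("cultivar" %in% names(pomology))
  params <- setdiff(names(pomology), "cultivar")
  out <- list()
  for (pm in params) {
    gl <- split(pomology[[pm]], pomology$cultivar)
    kw <- kruskal_wallis(gl)
    if (kw$p < alpha && length(gl) >= 3L) {
      d <- dscf(gl)
      differ <- d[d$p < alpha, c("group1", "group2")]
    } else {
      d <- NULL
      differ <- data.frame(group1 = character(0), group2 = character(0))
    }
    out[[pm]] <- list(kw_p = kw$p, dscf = d,
                      letters = compact_letters(names(gl), differ))
  }
  out
}

# Greedy compact-letter display: groups sorted by name are merged into the
# first letter class containing no group they differ from.
compact_letters <- function(groups, differ) {
  classes <- list()
  differs_from <- function(g, members) {
    any((differ$group1 == g & differ$group2 %in% members) |
        (differ$group2 == g & differ$group1 %in% members))
  }
  for (g in groups) {
    placed <- FALSE
    for (k in seq_along(classes)) {
      if (!differs_from(g, classes[[k]])) {
        classes[[k]] <- c(classes[[k]], g)
        placed <- TRUE
        break
      }
    }
    if (!placed) classes[[length(classes) + 1L]] <- g
  }
  lab <- stats::setNames(rep("", length(groups)), groups)
  for (k in seq_along(classes)) {
    for (g in classes[[k]]) lab[g] <- paste0(lab[g], letters[k])
  }
  lab
}
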